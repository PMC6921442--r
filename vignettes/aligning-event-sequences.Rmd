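---
title: "Aligning daily-event sequences from medical records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning daily-event sequences from medical records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehralign)
```

## The model

A patient record is modelled as an ordered sequence
$X = [X_1, \dots, X_n]$ of *daily events*: $X_i$ is the set of diagnosis
codes recorded on the $i$-th active date. All codes of one date form one
event regardless of how many visits produced them, because the order of
same-day encounters is not reliably recorded. Alignment operates on event
order only; calendar gaps between events carry no cost. That is a deliberate
simplification — a three-day gap and a three-year gap read identically — and
it is the main assumption to keep in mind when interpreting scores.

Two events are compared through the Jaccard index
$J(X,Y) = |X \cap Y| / |X \cup Y|$. The scoring scheme
(`scoring_scheme()`, defaults match $=1$, mismatch $=-1$, gap $=-1$) induces
two similarities:

* an aligned **pair** scores $s(X,Y) = 2J(X,Y) - 1$, interpolating from $-1$
  (disjoint) to $+1$ (identical);
* an **inserted copy** created by warping scores $s(X,Y) = J(X,Y) - 1$,
  from $-1$ to $0$: an invented observation can avoid a penalty but never
  earn a reward.

Both generalize to other schemes as
$\mathrm{mm} + (\mathrm{M}-\mathrm{mm})\,J$ and $\mathrm{mm}\,(1-J)$. The
dominance guarantees discussed below additionally assume a non-negative
match reward, which every sensible scheme satisfies.

## The four aligners

All four methods fill an accumulated score matrix $A_{(n+1)\times(m+1)}$ and
trace an optimal path back through it (`align_events()`).

**NWA** (global, gap-based) uses the classic recurrence with border
penalties $A_{i,0} = i\,\mathrm{gp}$, $A_{0,j} = j\,\mathrm{gp}$; unmatched
events face explicit gap columns. **SWA** is its zero-floored local variant:
negative cells are reset to zero, the traceback starts at the matrix maximum
and stops *before* emitting the zero cell, so the reported subalignment
always begins and ends on a pair column.

**DTW** (global, warping) allows no gaps: a vertical or horizontal move
re-uses an element of one sequence, stretching the other. Its borders are
$-\infty$ sentinels except $A_{0,0} = 0$, which forces the first and last
indices of both sequences to match. **DTWL** applies the zero-floor/maximal-
cell logic to the warping recurrence, so the best-matching region is found
without gap columns.

### Scoring a warp run

A 1-to-$n$ match contains one genuine pairing and $n-1$ inserted copies. The
printed worked cases never disambiguate *which* copy is the genuine one,
because their runs repeat identical events; for heterogeneous runs the choice
matters. This package scores each warp run as: one cell of the run receives
the pair similarity, every other cell the insertion similarity, and the
placement is optimized. Operationally the DP carries two pair-credit bits per
cell (whether the run sharing the current column, and the run sharing the
current row, has already used its credit), giving four states per cell.

The naive alternative — score the move into a cell, so the *first* cell of a
run is always the pair — is simpler but asymmetric: it forces the pair onto
the earliest copy. When a mutation removes the very first seed event, that
asymmetry makes DTW pay a mismatch NWA can avoid with a leading gap, and DTW
would fall below NWA on exactly the scenario warping is supposed to win.
Under optimal pair placement one can map any NWA path to a warping path of
at least the same score (replace each gap column with an insertion column,
which never scores below the gap penalty), so

$$\mathrm{DTW} \ge \mathrm{NWA} \ge \mathrm{REF}_{global}, \qquad
  \mathrm{DTWL} \ge \mathrm{SWA} \ge \mathrm{REF}_{local}$$

hold for *every* input pair, matching the qualitative behaviour these
methods are reported to have on real records. The property suite asserts
both chains across a full synthesized benchmark.

### Tie-breaking

Optimal paths are rarely unique. Fixed rules keep output deterministic:
within the fill, diagonal moves are preferred over vertical (seed-consuming)
over horizontal; among prior credit states, pair-credited histories win
ties, so degenerate zero-credit "warp" columns between diagonal moves do not
appear. For the local methods, when several cells tie for the matrix
maximum the traceback starts from the largest $(i,j)$ in row-major order;
`tiebreak = "first"` exposes the opposite rule. Scores are tie-invariant;
only the reported path (hence, for local alignments, the coverage) can
differ between co-optimal solutions, and the test suite only pins coverage
where the optimum is unique.

## Normalization, coverage, reference alignments

Raw scores are sums of exact small rationals; they are kept at full
precision and only rounded (3 decimals) for display. The normalized score
$S_n$ divides by the *seed* length $N$, so a benchmark column is comparable
across mutations of one seed. Coverage $C$ of a local alignment is the
*span* of seed indices from first to last aligned event divided by $N$; seed
events facing a gap column inside the span count as covered, which is the
reading under which a one-gap full-width alignment has $C = 1$. An
alternative — counting only matched events — would systematically lower SWA
coverage; span counting was chosen because it is the only rule consistent
with full-coverage gapped alignments being described as such in the worked
cases this design follows.

The **reference** alignment of a synthetic record is reconstructed from its
provenance, not inferred: surviving seed positions pair with the synthetic
positions they map to (updates and switches stay positional pairs, scored
by Jaccard on the actual events), deleted positions become gap columns. A
positional overlay without provenance would misalign everything after a
deletion; the provenance-derived reading reproduces the published worked
values. The local reference is the longest contiguous run of exact-match
pair columns of the global reference (earliest run on ties). The
maximum-scoring contiguous segment would be a stronger baseline, but it is
not what the published local baselines describe: for a deletion flanked by
exact matches they report the flanking run, not the best segment.

## The synthetic benchmark

`generate_seed_sequence()` emulates the record features that make alignment
non-trivial, with defaults fixed once:

* vocabulary of 582 synthetic category codes (the size of the grouped
  diagnosis-category universe the benchmark design emulates);
* 30% of days carry 2–3 codes (multi-diagnosis days and merged same-day
  visits); the rest carry one;
* one chronic-style code recurring in $\max(2, \lfloor 0.4\,N \rfloor)$
  events, one acute-style code occurring exactly once;
* inter-visit gaps uniform on 1–21 days (dates are carried through I/O but
  ignored by alignment).

`synthesize_benchmark()` applies the 20-row design of delete/update/switch
operations at daily and block level (`block_size()` $= \max(2, \lfloor N/10
\rfloor)$), drawing positions without replacement within a row where length
permits. Every record carries replayable provenance; `replay_provenance()`
must reproduce it bit for bit, and the benchmark refuses records that fail
that integrity check. Block updates redraw each replaced event with the same
per-day code count, keeping the length and code-count profile of the block
while destroying its content.

What the generator does *not* emulate: real inter-visit time statistics,
medication/procedure/lab events, code co-occurrence structure (comorbidity),
coding drift between providers, and the long-tailed record-length
distribution of a real population (length is a parameter here). Passing the
benchmark therefore shows that the aligners behave correctly under
controlled, known mutations — not that any of them is clinically superior on
real records.

## Numerical and testing choices

Scores are IEEE doubles over small rationals; equality comparisons in the
benchmark summaries use a $10^{-9}$ tolerance purely as a float guard.
The DP fills run in C++; tracebacks and everything user-facing run in R.
Correctness is cross-checked against `brute_force_alignment_score()`, an
exhaustive path enumeration (capped at 7 events per side) that optimizes
warp-run pair placement independently per path — several hundred random
pairs per run, including multi-code events — and, for the gap-based methods,
against an independent pairwise aligner on single-code sequences. The
dominance and replay property suites use seed lengths 9 and 84 with five
replicates of the 20-row design (200 records), sizes chosen to exercise both
the small-N block-size floor and a realistically long record while keeping
the default test run fast.

## Limitations

Scores depend on the seed direction only through $N$; there is no
significance calibration (a raw-score null model would need a permutation
scheme respecting chronic-code autocorrelation); the scheme treats all codes
as equally distant, so a clinically near-miss recode costs as much as an
unrelated one. Knowledge-based scoring (e.g. separating acute from chronic
categories) would slot into `scoring_scheme()` but is out of scope here.
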