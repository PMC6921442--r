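# Builders used across the suite.

# Sequence of single-code daily events, one per character/string supplied.
seq1 <- function(codes, id = "p") {
  event_sequence(as.list(codes), patient_id = id)
}

# Random sequence over a small alphabet; multi = max codes per daily event.
rand_seq <- function(len, alphabet = c("a", "b", "c"), multi = 1L, id = "r") {
  events <- lapply(seq_len(len), function(i) {
    sample(alphabet, sample.int(multi, 1L))
  })
  event_sequence(events, patient_id = id)
}

all_methods <- c("dtw", "nwa", "swa", "dtwl")

# Column-level legality checks shared by several tests: score bookkeeping,
# index monotonicity, and (global methods) full index coverage.
expect_legal_alignment <- function(aln, global = TRUE) {
  cols <- aln$columns
  expect_equal(sum(cols$score), aln$raw_score, tolerance = 1e-12)
  si <- cols$seed_index[!is.na(cols$seed_index)]
  yj <- cols$synth_index[!is.na(cols$synth_index)]
  if (length(si) > 1L) expect_true(all(diff(si) >= 0))
  if (length(yj) > 1L) expect_true(all(diff(yj) >= 0))
  gap_rows <- grepl("^gap", cols$role)
  expect_true(all(xor(is.na(cols$seed_index), is.na(cols$synth_index)) == gap_rows))
  if (global) {
    expect_setequal(unique(si), seq_len(aln$n_seed))
    expect_setequal(unique(yj), seq_len(aln$n_synth))
  }
  # a warp column must share its repeated index with an adjacent column
  warp <- which(grepl("^warp", cols$role))
  for (t in warp) {
    side <- if (cols$role[t] == "warp_repeat_synth") "synth_index" else "seed_index"
    nb <- c(if (t > 1L) cols[[side]][t - 1L], if (t < nrow(cols)) cols[[side]][t + 1L])
    expect_true(cols[[side]][t] %in% nb)
  }
  invisible(aln)
}
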