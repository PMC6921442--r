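#' Ground-truth (reference) global alignment of a synthetic record
#'
#' Builds the baseline alignment implied by the record's synthesis provenance
#' rather than by any optimization: every surviving seed position is paired
#' with the synthetic position it maps to under the index map (scored by
#' [pair_similarity()] on the actual, possibly updated or switched, events),
#' and every deleted seed position becomes a gap column charged the gap
#' penalty. This is the evaluation baseline the optimizing aligners are
#' compared against.
#'
#' @param seed Seed [event_sequence()].
#' @param record A [record_from_operations()] synthetic record derived from
#'   `seed`.
#' @param scheme A [scoring_scheme()].
#' @param check Verify that replaying the provenance reproduces the record
#'   (integrity error if not).
#' @return An `event_alignment` with method `"reference_global"`.
#' @export
reference_global <- function(seed, record, scheme = scoring_scheme(),
                             check = TRUE) {
  scheme <- as_scheme(scheme)
  stopifnot(inherits(seed, "event_sequence"), inherits(record, "synthetic_record"))
  if (check && !record_is_consistent(seed, record)) {
    stop("record provenance is inconsistent with this seed", call. = FALSE)
  }
  n <- length(seed)
  map <- record$index_map
  si <- integer(); yj <- integer(); role <- character(); sc <- numeric()
  for (i in seq_len(n)) {
    j <- match(i, map)
    if (is.na(j)) {
      si <- c(si, i); yj <- c(yj, NA); role <- c(role, "gap_in_synth")
      sc <- c(sc, scheme$gap)
    } else {
      si <- c(si, i); yj <- c(yj, j); role <- c(role, "pair")
      sc <- c(sc, pair_similarity(seed$events[[i]],
                                  record$sequence$events[[j]], scheme))
    }
  }
  cols <- data.frame(seed_index = si, synth_index = as.integer(yj), role = role,
                     score = sc, stringsAsFactors = FALSE)
  new_event_alignment(list(columns = cols, raw = sum(sc), matrix = NULL),
                      "reference_global", seed, record$sequence, scheme)
}

#' Ground-truth (reference) local alignment of a synthetic record
#'
#' The local baseline is the longest contiguous run of exactly-matching pair
#' columns of the [reference_global()] alignment (gap columns and
#' mismatching pairs break a run); ties between equal-length runs go to the
#' earliest. Its coverage and normalized score coincide under the default
#' scheme, since each run column scores the match reward.
#'
#' With `min_pair_score` the run-membership rule can be relaxed for
#' partially-overlapping events: any pair column scoring at least the
#' threshold counts toward a run. The default (`NULL`) requires the full
#' match score.
#'
#' @inheritParams reference_global
#' @param min_pair_score Optional score threshold for run membership.
#' @return An `event_alignment` with method `"reference_local"`.
#' @export
reference_local <- function(seed, record, scheme = scoring_scheme(),
                            min_pair_score = NULL, check = TRUE) {
  scheme <- as_scheme(scheme)
  ref <- reference_global(seed, record, scheme, check = check)
  cols <- ref$columns
  thr <- if (is.null(min_pair_score)) scheme$match else min_pair_score
  ok <- cols$role == "pair" & cols$score >= thr - 1e-9
  best_start <- 0L; best_len <- 0L
  t <- 1L
  while (t <= length(ok)) {
    if (ok[t]) {
      s <- t
      while (t < length(ok) && ok[t + 1L]) t <- t + 1L
      if (t - s + 1L > best_len) { best_len <- t - s + 1L; best_start <- s }
    }
    t <- t + 1L
  }
  run <- if (best_len > 0L) cols[best_start:(best_start + best_len - 1L), ,
                                 drop = FALSE]
         else empty_columns()
  new_event_alignment(list(columns = run, raw = sum(run$score), matrix = NULL),
                      "reference_local", seed, record$sequence, scheme)
}
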