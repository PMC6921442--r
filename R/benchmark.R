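#' Run the full aligner benchmark over a suite of synthetic records
#'
#' For each synthetic record, aligns the seed against it with all four
#' optimizing aligners plus the two provenance-derived references, and
#' collects normalized similarity scores (and seed coverage for the local
#' methods) into one row per record. Scores are stored at full precision;
#' the print method rounds to 3 decimals.
#'
#' @param seed Seed [event_sequence()].
#' @param records List of [record_from_operations()] synthetic records
#'   derived from `seed`.
#' @param scheme A [scoring_scheme()].
#' @param tiebreak Passed to [align_events()] for the local methods.
#' @return A data frame of class `benchmark_table` with columns `id`,
#'   `operation`, global `dtw`/`nwa`/`ref` normalized scores, and local
#'   `dtwl_C`, `dtwl_Sn`, `swa_C`, `swa_Sn`, `ref_C`, `ref_Sn`.
#' @export
run_benchmark <- function(seed, records, scheme = scoring_scheme(),
                          tiebreak = "last") {
  scheme <- as_scheme(scheme)
  stopifnot(length(records) >= 1L)
  rows <- lapply(seq_along(records), function(r) {
    rec <- records[[r]]
    if (!record_is_consistent(seed, rec)) {
      stop(sprintf("record %d: provenance inconsistent with seed", r),
           call. = FALSE)
    }
    synth <- rec$sequence
    dtw <- align_events(seed, synth, "dtw", scheme)
    nwa <- align_events(seed, synth, "nwa", scheme)
    refg <- reference_global(seed, rec, scheme, check = FALSE)
    dtwl <- align_events(seed, synth, "dtwl", scheme, tiebreak)
    swa <- align_events(seed, synth, "swa", scheme, tiebreak)
    refl <- reference_local(seed, rec, scheme, check = FALSE)
    data.frame(
      id = r, operation = rec$operation_label,
      dtw = dtw$normalized_score, nwa = nwa$normalized_score,
      ref = refg$normalized_score,
      dtwl_C = dtwl$coverage, dtwl_Sn = dtwl$normalized_score,
      swa_C = swa$coverage, swa_Sn = swa$normalized_score,
      ref_C = refl$coverage, ref_Sn = refl$normalized_score,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed_id") <- seed$patient_id
  attr(out, "seed_length") <- length(seed)
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("Alignment benchmark: seed '%s' (N = %d), %d synthetic records\n",
              attr(x, "seed_id"), attr(x, "seed_length"), nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "id"
  df[num] <- lapply(df[num], function(v) sprintf("%.3f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

compare_counts <- function(a, b, tol) {
  c(better = sum(a > b + tol), equal = sum(abs(a - b) <= tol),
    worse = sum(a < b - tol))
}

compare_local <- function(ca, sa, cb, sb, tol) {
  eqC <- abs(ca - cb) <= tol
  better <- (ca > cb + tol) | (eqC & sa > sb + tol)
  worse <- (ca < cb - tol) | (eqC & sa < sb - tol)
  c(better = sum(better), equal = sum(eqC & abs(sa - sb) <= tol),
    worse = sum(worse), equal_C_better_Sn = sum(eqC & sa > sb + tol))
}

#' Summarize pairwise method comparisons over a benchmark
#'
#' Counts, for each method pair, how often the first method scored better,
#' equal, or worse than the second over a benchmark table. Global methods are
#' compared on the normalized score; local methods lexicographically on
#' (coverage, normalized score), with an additional count of the
#' equal-coverage-but-better-score cases. Ties are declared within
#' `tolerance` (scores are small rationals, so exact ties are expected and
#' the tolerance only guards float arithmetic).
#'
#' @param rows A `benchmark_table` from [run_benchmark()], or several
#'   row-bound together.
#' @param tolerance Score-equality tolerance.
#' @return A list of class `comparison_summary`: one named count vector per
#'   method pair, plus `n` (rows compared).
#' @export
summarize_comparison <- function(rows, tolerance = 1e-9) {
  stopifnot(nrow(rows) >= 1L)
  out <- list(
    dtw_vs_ref = compare_counts(rows$dtw, rows$ref, tolerance),
    nwa_vs_ref = compare_counts(rows$nwa, rows$ref, tolerance),
    dtw_vs_nwa = compare_counts(rows$dtw, rows$nwa, tolerance),
    dtwl_vs_ref = compare_local(rows$dtwl_C, rows$dtwl_Sn,
                                rows$ref_C, rows$ref_Sn, tolerance),
    swa_vs_ref = compare_local(rows$swa_C, rows$swa_Sn,
                               rows$ref_C, rows$ref_Sn, tolerance),
    dtwl_vs_swa = compare_local(rows$dtwl_C, rows$dtwl_Sn,
                                rows$swa_C, rows$swa_Sn, tolerance),
    n = nrow(rows)
  )
  class(out) <- "comparison_summary"
  out
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("Method comparison over %d alignments\n", x$n))
  for (nm in setdiff(names(x), "n")) {
    v <- x[[nm]]
    extra <- if ("equal_C_better_Sn" %in% names(v)) {
      sprintf("  (equal C, better S_n: %d)", v[["equal_C_better_Sn"]])
    } else ""
    cat(sprintf("  %-12s better %3d / equal %3d / worse %3d%s\n",
                sub("_vs_", " vs ", nm), v[["better"]], v[["equal"]],
                v[["worse"]], extra))
  }
  invisible(x)
}
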