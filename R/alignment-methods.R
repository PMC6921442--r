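method_label <- function(method) {
  switch(method,
    dtw = "DTW (global warping)",
    nwa = "NWA (Needleman-Wunsch, global)",
    swa = "SWA (Smith-Waterman, local)",
    dtwl = "DTWL (local warping)",
    reference_global = "reference (provenance-derived, global)",
    reference_local = "reference (provenance-derived, local)",
    method)
}

#' @export
print.event_alignment <- function(x, max_columns = 12L, ...) {
  cat(sprintf("Event-sequence alignment: %s\n", method_label(x$method)))
  cat(sprintf("  seed '%s' (N = %d)  vs  '%s' (M = %d)\n",
              x$seed_id, x$n_seed, x$synth_id, x$n_synth))
  cat(sprintf("  raw score %.3f   normalized S_n = %.3f", x$raw_score,
              x$normalized_score))
  if (!is.na(x$coverage)) cat(sprintf("   coverage C = %.3f", x$coverage))
  cat("\n")
  k <- nrow(x$columns)
  if (k == 0L) {
    cat("  (empty alignment)\n")
    return(invisible(x))
  }
  shown <- seq_len(min(k, max_columns))
  fmt <- function(idx, events) {
    ifelse(is.na(idx), "_",
           vapply(idx, function(i) if (is.na(i)) "_" else format_event(events[[i]]),
                  character(1)))
  }
  top <- fmt(x$columns$seed_index[shown], x$seed_events)
  bot <- fmt(x$columns$synth_index[shown], x$synth_events)
  wid <- pmax(nchar(top), nchar(bot))
  pad <- function(v) {
    paste(vapply(seq_along(v), function(t) formatC(v[t], width = wid[t]),
                 character(1)), collapse = " ")
  }
  cat("  seed : ", pad(top), if (k > max_columns) " ..." else "", "\n", sep = "")
  cat("  synth: ", pad(bot), if (k > max_columns) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.event_alignment <- function(object, ...) {
  print(object, max_columns = 1000L)
  cat("\nColumns:\n")
  df <- object$columns
  df$score <- round(df$score, 3)
  print(df, row.names = FALSE)
  if (!is.null(object$seed_span)) {
    cat(sprintf("\nSeed span %d..%d; synthetic span %d..%d\n",
                object$seed_span[1], object$seed_span[2],
                object$synth_span[1], object$synth_span[2]))
  }
  invisible(object)
}

#' @export
as.data.frame.event_alignment <- function(x, ...) x$columns

#' Plot the accumulated score matrix and alignment path
#'
#' Draws the accumulated dynamic-programming matrix as an image, seed events
#' on the vertical axis, and overlays the traced alignment path. Gap columns
#' show as steps along one axis, warp runs as straight segments.
#'
#' @param x An `event_alignment`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.event_alignment <- function(x, ...) {
  mat <- x$matrix
  if (is.null(mat)) stop("alignment has no stored matrix", call. = FALSE)
  ii <- seq_len(nrow(mat)); jj <- seq_len(ncol(mat))
  graphics::image(jj, ii, t(mat), xlab = sprintf("synthetic '%s'", x$synth_id),
                  ylab = sprintf("seed '%s'", x$seed_id),
                  main = method_label(x$method), ...)
  cols <- x$columns
  keep <- !is.na(cols$seed_index) & !is.na(cols$synth_index)
  if (any(keep)) {
    graphics::lines(cols$synth_index[keep] + (nrow(mat) > x$n_seed),
                    cols$seed_index[keep] + (nrow(mat) > x$n_seed), lwd = 2)
    graphics::points(cols$synth_index[keep] + (nrow(mat) > x$n_seed),
                     cols$seed_index[keep] + (nrow(mat) > x$n_seed), pch = 16)
  }
  invisible(x)
}

#' Normalize a raw alignment score by the seed length
#'
#' Divides a raw alignment score by the number of daily events in the seed
#' sequence, giving the normalized similarity score reported by the benchmark
#' tables.
#'
#' @param raw Raw alignment score.
#' @param seed_length Number of daily events in the seed sequence (>= 1).
#' @return `raw / seed_length`.
#' @export
normalized_score <- function(raw, seed_length) {
  seed_length <- as.integer(seed_length)
  if (length(seed_length) != 1L || is.na(seed_length) || seed_length < 1L) {
    stop("'seed_length' must be a positive count", call. = FALSE)
  }
  raw / seed_length
}
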