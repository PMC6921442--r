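#' Align two daily-event sequences
#'
#' Computes an optimal pairwise alignment of two patient event sequences under
#' a Jaccard-based scoring scheme, by one of four dynamic-programming methods:
#'
#' * `"dtw"` — dynamic time warping, global. Every index in one sequence
#'   matches one or more indices in the other (no gaps); first and last indices
#'   must match; 1-to-n matches stretch one sequence by repeating an element.
#'   Within each warp run one copy is the genuinely paired event, scored by
#'   [pair_similarity()]; the extra inserted copies are scored by
#'   [warp_similarity()]. The paired copy is placed optimally.
#' * `"nwa"` — Needleman-Wunsch, global. Instead of warping, unmatched events
#'   face gap columns charged the gap penalty.
#' * `"swa"` — Smith-Waterman, local: the NWA recurrence floored at zero, with
#'   traceback from the maximal cell until a zero cell; returns the
#'   best-scoring contiguous subalignment.
#' * `"dtwl"` — warping DP with the local zero floor: like `"dtw"` but a path
#'   may start and end anywhere, so the best-matching region is found without
#'   gap columns.
#'
#' The raw score is the accumulated-matrix optimum and always equals the sum
#' of the per-column scores. The normalized score divides the raw score by the
#' number of daily events in `seed` (the first argument), so it is asymmetric
#' even though the raw score is not. For the local methods, coverage is the
#' fraction of the seed sequence spanned by the alignment: the span runs from
#' the first to the last aligned seed event and includes seed events facing
#' gap columns inside it.
#'
#' @param seed,synth [event_sequence()] objects. `seed` supplies the
#'   normalization denominator and the coverage reference.
#' @param method One of `"dtw"`, `"nwa"`, `"swa"`, `"dtwl"`.
#' @param scheme A [scoring_scheme()].
#' @param tiebreak For the local methods, which cell to trace back from when
#'   several tie for the matrix maximum: `"last"` (largest `(i, j)` in
#'   row-major order, the default) or `"first"`. Scores are tie-invariant;
#'   only the reported path can differ.
#' @return An object of class `event_alignment`: a list with the aligned
#'   `columns` (data frame of `seed_index`, `synth_index`, `role`, `score`),
#'   `raw_score`, `normalized_score`, `coverage` (local methods, else `NA`),
#'   `seed_span`/`synth_span`, the accumulated score `matrix`, and metadata.
#' @examples
#' seed <- event_sequence(list("a", "b", "b", "c"), "seed")
#' synth <- event_sequence(list("a", "b", "c"), "synthetic")
#' align_events(seed, synth, "dtw")$normalized_score   # 0.75
#' align_events(seed, synth, "nwa")$normalized_score   # 0.50
#' @export
align_events <- function(seed, synth, method = c("dtw", "nwa", "swa", "dtwl"),
                         scheme = scoring_scheme(),
                         tiebreak = c("last", "first")) {
  method <- match.arg(method)
  tiebreak <- match.arg(tiebreak)
  scheme <- as_scheme(scheme)
  stopifnot(inherits(seed, "event_sequence"), inherits(synth, "event_sequence"))
  n <- length(seed); m <- length(synth)
  sm <- score_matrices(seed, synth, scheme)
  res <- switch(method,
    nwa  = traceback_gap(sm$P, scheme$gap, local = FALSE, tiebreak = tiebreak),
    swa  = traceback_gap(sm$P, scheme$gap, local = TRUE,  tiebreak = tiebreak),
    dtw  = traceback_warp(sm$P, sm$W, local = FALSE, tiebreak = tiebreak),
    dtwl = traceback_warp(sm$P, sm$W, local = TRUE,  tiebreak = tiebreak)
  )
  new_event_alignment(res, method, seed, synth, scheme)
}

new_event_alignment <- function(res, method, seed, synth, scheme) {
  n <- length(seed)
  cols <- res$columns
  local <- method %in% c("swa", "dtwl", "reference_local")
  si <- cols$seed_index[!is.na(cols$seed_index)]
  yj <- cols$synth_index[!is.na(cols$synth_index)]
  seed_span <- if (length(si)) range(si) else NULL
  synth_span <- if (length(yj)) range(yj) else NULL
  coverage <- if (!local) NA_real_
              else if (is.null(seed_span)) 0
              else (seed_span[2] - seed_span[1] + 1) / n
  structure(list(
    method = method,
    columns = cols,
    raw_score = res$raw,
    normalized_score = res$raw / n,
    coverage = coverage,
    seed_span = seed_span,
    synth_span = synth_span,
    matrix = res$matrix,
    n_seed = n, n_synth = length(synth),
    seed_id = seed$patient_id, synth_id = synth$patient_id,
    seed_events = seed$events, synth_events = synth$events,
    scheme = scheme
  ), class = "event_alignment")
}

empty_columns <- function() {
  data.frame(seed_index = integer(), synth_index = integer(),
             role = character(), score = numeric(), stringsAsFactors = FALSE)
}

# --- gap-based DPs (NWA global / SWA local) --------------------------------

traceback_gap <- function(P, gp, local, tiebreak) {
  n <- nrow(P); m <- ncol(P)
  dp <- if (local) .dp_swa(P, gp) else .dp_nwa(P, gp)
  V <- dp$V; M <- dp$move
  if (local) {
    raw <- max(V)
    if (raw <= 0) {
      return(list(columns = empty_columns(), raw = 0, matrix = V))
    }
    hit <- which(V == raw, arr.ind = TRUE)
    # row-major order on (i, j); "last" picks the largest
    ord <- order(hit[, 1], hit[, 2])
    pick <- hit[if (tiebreak == "last") ord[length(ord)] else ord[1], ]
    i <- as.integer(pick[[1]]) - 1L        # convert to 0-based grid offsets
    j <- as.integer(pick[[2]]) - 1L
  } else {
    raw <- V[n + 1, m + 1]
    i <- n; j <- m
  }
  si <- integer(); yj <- integer(); role <- character(); sc <- numeric()
  repeat {
    if (local) { if (V[i + 1, j + 1] <= 0) break } else if (i == 0 && j == 0) break
    mv <- M[i + 1, j + 1]
    if (mv == 1L) {
      si <- c(i, si); yj <- c(j, yj); role <- c("pair", role)
      sc <- c(P[i, j], sc); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      si <- c(i, si); yj <- c(NA, yj); role <- c("gap_in_synth", role)
      sc <- c(gp, sc); i <- i - 1L
    } else {
      si <- c(NA, si); yj <- c(j, yj); role <- c("gap_in_seed", role)
      sc <- c(gp, sc); j <- j - 1L
    }
  }
  cols <- data.frame(seed_index = as.integer(si), synth_index = as.integer(yj),
                     role = role, score = sc, stringsAsFactors = FALSE)
  list(columns = cols, raw = raw, matrix = V)
}

# --- warping DPs (DTW global / DTWL local) ---------------------------------

traceback_warp <- function(P, W, local, tiebreak) {
  n <- nrow(P); m <- ncol(P)
  dp <- .dp_warp(P, W, local)
  V <- dp$V; PTR <- dp$ptr
  red <- apply(V, c(1, 2), max)          # accumulated matrix over credit states
  state_order <- c(4L, 3L, 2L, 1L)
  if (local) {
    raw <- max(red, 0)
    if (raw <= 0) {
      return(list(columns = empty_columns(), raw = 0, matrix = pmax(red, 0)))
    }
    hit <- which(red == raw, arr.ind = TRUE)
    ord <- order(hit[, 1], hit[, 2])
    pick <- hit[if (tiebreak == "last") ord[length(ord)] else ord[1], ]
    i <- as.integer(pick[[1]]); j <- as.integer(pick[[2]])
  } else {
    raw <- max(V[n, m, ])
    i <- n; j <- m
  }
  s <- state_order[which(V[i, j, state_order] == max(V[i, j, ]))[1]]
  cells <- list()
  repeat {
    ptr <- PTR[i, j, s]
    mv <- ptr %% 10L; prev <- (ptr %/% 10L) %% 10L; f <- ptr %/% 100L
    cells[[length(cells) + 1L]] <- c(i = i, j = j, f = f, mv = mv)
    if (mv == 4L || prev == 0L) break    # local start, or the (0,0) base
    if (mv == 1L) { i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
    s <- prev
  }
  cells <- rev(cells)
  k <- length(cells)
  si <- integer(k); yj <- integer(k); role <- character(k); sc <- numeric(k)
  for (t in seq_len(k)) {
    cl <- cells[[t]]
    si[t] <- cl["i"]; yj[t] <- cl["j"]
    if (cl["f"] == 1L) {
      role[t] <- "pair"; sc[t] <- P[cl["i"], cl["j"]]
    } else {
      sc[t] <- W[cl["i"], cl["j"]]
      mv <- cl["mv"]
      if (mv == 1L || mv == 4L) {
        # diagonal-entered insert: the shared index comes from the next move
        mv <- if (t < k) cells[[t + 1L]]["mv"] else 1L
      }
      role[t] <- if (mv == 2L) "warp_repeat_synth"
                 else if (mv == 3L) "warp_repeat_seed"
                 else "pair"                     # degenerate tie: P == W here
    }
  }
  cols <- data.frame(seed_index = si, synth_index = yj, role = role,
                     score = sc, stringsAsFactors = FALSE)
  list(columns = cols, raw = raw, matrix = if (local) pmax(red, 0) else red)
}
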