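#' Exhaustive-enumeration alignment score (test oracle)
#'
#' Computes the optimal raw alignment score by brute force: every legal
#' alignment path under the chosen method's move and boundary rules is
#' enumerated explicitly and scored, and the maximum is returned. For the
#' warping methods the placement of the genuinely paired copy inside each
#' 1-to-n warp run is likewise optimized by explicit enumeration over the
#' run segments of each path. This is deliberately independent of the
#' dynamic-programming implementation in [align_events()] and exists to
#' cross-check it on small instances; both sequences are capped at 7 events.
#'
#' @inheritParams align_events
#' @return The optimal raw score (a single number).
#' @examples
#' a <- event_sequence(list("a", "b", "b", "c"))
#' b <- event_sequence(list("a", "b", "c"))
#' brute_force_alignment_score(a, b, "dtw")   # 3
#' @export
brute_force_alignment_score <- function(seed, synth,
                                        method = c("dtw", "nwa", "swa", "dtwl"),
                                        scheme = scoring_scheme()) {
  method <- match.arg(method)
  scheme <- as_scheme(scheme)
  stopifnot(inherits(seed, "event_sequence"), inherits(synth, "event_sequence"))
  n <- length(seed); m <- length(synth)
  if (n > 7L || m > 7L) {
    stop("brute-force enumeration is limited to sequences of at most 7 events",
         call. = FALSE)
  }
  sm <- score_matrices(seed, synth, scheme)
  switch(method,
    nwa  = brute_gap(sm$P, scheme$gap, n, m, local = FALSE),
    swa  = brute_gap(sm$P, scheme$gap, n, m, local = TRUE),
    dtw  = brute_warp(sm$P, sm$W, n, m, local = FALSE),
    dtwl = brute_warp(sm$P, sm$W, n, m, local = TRUE)
  )
}

brute_gap <- function(P, gp, n, m, local) {
  env <- new.env()
  env$best <- if (local) 0 else -Inf
  if (local) {
    step <- function(i, j, acc) {
      if (acc > env$best) env$best <- acc
      if (i < n && j < m) step(i + 1L, j + 1L, acc + P[i + 1L, j + 1L])
      if (i < n) step(i + 1L, j, acc + gp)
      if (j < m) step(i, j + 1L, acc + gp)
    }
    for (i in seq_len(n)) for (j in seq_len(m)) step(i, j, P[i, j])
  } else {
    step <- function(i, j, acc) {
      if (i == n && j == m) {
        if (acc > env$best) env$best <- acc
        return(invisible())
      }
      if (i < n && j < m) step(i + 1L, j + 1L, acc + P[i + 1L, j + 1L])
      if (i < n) step(i + 1L, j, acc + gp)
      if (j < m) step(i, j + 1L, acc + gp)
    }
    step(0L, 0L, 0)
  }
  env$best
}

# DFS over all monotone warping paths. Within one path, each maximal
# vertical run shares one synthetic index and each maximal horizontal run one
# seed index, so a run holds at most one genuinely paired copy; a corner cell
# belongs to two runs and would consume both quotas. Runs along a monotone
# path form a chain where only consecutive runs share (corner) cells, and the
# best pair-credit assignment is maintained incrementally along the path:
#   acc_w   running sum of warp scores over path cells
#   free_d  summed credit of cells outside every run (always taken, D >= 0)
#   bf/bb   chain values over the CLOSED runs: best credit with the corner
#           into the open run unchosen (bf) or chosen (bb)
#   grp     credits of the open run's choosable members (corner head excluded)
#   last_d  credit of the most recent cell while no run is open
#   acc_w   running sum of warp scores over path cells
#   free_d  summed credit of cells outside every run (always taken, D >= 0)
#   bf/bb   chain values over the CLOSED runs: best credit with the corner
#           into the open run unchosen (bf) or chosen (bb)
#   grp     credits of the open run's choosable members (corner head excluded)
#   last_d  credit of the most recent cell while no run is open
brute_warp <- function(P, W, n, m, local) {
  D <- P - W
  env <- new.env()
  env$best <- if (local) 0 else -Inf
  fold <- function(bf, bb, grp, corner) {
    nf <- max(bf, bb); nb <- -Inf
    k <- length(grp)
    for (t in seq_len(k)) {
      val <- bf + grp[t]
      if (corner && t == k) { if (val > nb) nb <- val }
      else if (val > nf) nf <- val
    }
    c(nf, nb)
  }
  step <- function(i, j, dir, acc_w, free_d, bf, bb, grp, last_d) {
    if (local || (i == n && j == m)) {
      cred <- if (dir == 0L) max(bf, bb) else max(fold(bf, bb, grp, FALSE))
      val <- acc_w + free_d + cred
      if (val > env$best) env$best <- val
    }
    if (i < n && j < m) {                       # diagonal: run (if any) closes
      dc <- D[i + 1L, j + 1L]
      if (dir == 0L) {
        step(i + 1L, j + 1L, 0L, acc_w + W[i + 1L, j + 1L], free_d + dc,
             bf, bb, numeric(), dc)
      } else {
        s <- fold(bf, bb, grp, FALSE)
        step(i + 1L, j + 1L, 0L, acc_w + W[i + 1L, j + 1L], free_d + dc,
             s[1], s[2], numeric(), dc)
      }
    }
    for (mv in 2:3) {
      if (mv == 2L) { if (i >= n) next; i2 <- i + 1L; j2 <- j }
      else { if (j >= m) next; i2 <- i; j2 <- j + 1L }
      dc <- D[i2, j2]; wc <- W[i2, j2]
      if (dir == 0L) {
        # previous (free) cell becomes the run head, choosable
        step(i2, j2, mv, acc_w + wc, free_d - last_d, bf, bb,
             c(last_d, dc), dc)
      } else if (dir == mv) {                   # run continues
        step(i2, j2, mv, acc_w + wc, free_d, bf, bb, c(grp, dc), dc)
      } else {                                  # corner: old run closes into
        s <- fold(bf, bb, grp, TRUE)            # the head of the new one
        step(i2, j2, mv, acc_w + wc, free_d, s[1], s[2], dc, dc)
      }
    }
  }
  starts <- if (local) expand.grid(i = seq_len(n), j = seq_len(m))
            else data.frame(i = 1L, j = 1L)
  for (r in seq_len(nrow(starts))) {
    i0 <- starts$i[r]; j0 <- starts$j[r]
    step(i0, j0, 0L, W[i0, j0], D[i0, j0], 0, -Inf, numeric(), D[i0, j0])
  }
  env$best
}
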