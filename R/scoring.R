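#' Scoring scheme for daily-event alignment
#'
#' The scoring system used by all four aligners. With the defaults, two
#' identical daily events score `+1`, two disjoint ones `-1`, and a gap costs
#' `-1`, i.e. mismatching and gapping are penalized equally; partial code-set
#' overlap interpolates through the Jaccard index (see [pair_similarity()]).
#' Extra events inserted by warping are scored on the shifted scale of
#' [warp_similarity()], between `-1` and `0`.
#'
#' @param match Score of a perfectly matching event pair (Jaccard 1).
#' @param mismatch Score of a fully mismatching pair (Jaccard 0); must be
#'   below `match`.
#' @param gap Gap penalty, non-positive.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -1) {
  match <- as.numeric(match); mismatch <- as.numeric(mismatch); gap <- as.numeric(gap)
  stopifnot(length(match) == 1L, length(mismatch) == 1L, length(gap) == 1L,
            is.finite(match), is.finite(mismatch), is.finite(gap))
  if (match <= mismatch) stop("'match' must exceed 'mismatch'", call. = FALSE)
  if (gap > 0) stop("'gap' must be non-positive", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("Scoring scheme: match %+g, mismatch %+g, gap %+g\n",
              x$match, x$mismatch, x$gap))
  invisible(x)
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "scoring_scheme")) return(scheme)
  do.call(scoring_scheme, as.list(scheme))
}

#' Jaccard index of two code sets
#'
#' `|a n b| / |a u b|`, the fraction of shared diagnosis codes between two
#' daily events. Symmetric; 1 exactly when the sets are equal, 0 when disjoint.
#'
#' @param a,b Daily events (character vectors of codes; validated through
#'   [daily_event()]).
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c("487", "486"), c("486", "250"))  # 1/3
#' @export
jaccard <- function(a, b) {
  a <- daily_event(a); b <- daily_event(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Similarity of two aligned daily events
#'
#' The score of a regular (diagonal) alignment pair:
#' `mismatch + (match - mismatch) * J(x, y)`, which is `2 J - 1` under the
#' default scheme. Jaccard 1 yields the match score, Jaccard 0 the mismatch
#' score.
#'
#' @param x,y Daily events.
#' @param scheme A [scoring_scheme()].
#' @return A number in `[mismatch, match]`.
#' @examples
#' pair_similarity(c("487", "486"), c("486", "250"))  # -1/3
#' @export
pair_similarity <- function(x, y, scheme = scoring_scheme()) {
  scheme <- as_scheme(scheme)
  scheme$mismatch + (scheme$match - scheme$mismatch) * jaccard(x, y)
}

#' Similarity of a warp-inserted daily event
#'
#' The score of an extra event inserted by warping (DTW/DTWL stretching one
#' sequence by repeating an element) against the original event it faces:
#' `mismatch * (1 - J(x, y))`, i.e. `J - 1` under the default scheme. The range
#' is shifted so a perfectly matching inserted copy costs 0 rather than earning
#' the match reward, and a fully mismatching one costs the mismatch penalty.
#'
#' @inheritParams pair_similarity
#' @return A number in `[mismatch, 0]`.
#' @examples
#' warp_similarity(c("487", "486"), c("486", "250"))  # -2/3
#' @export
warp_similarity <- function(x, y, scheme = scoring_scheme()) {
  scheme <- as_scheme(scheme)
  scheme$mismatch * (1 - jaccard(x, y))
}

# Pairwise score matrices between all events of two sequences.
# Returns list(P = pair similarity, W = warp similarity); both n x m.
score_matrices <- function(seed, synth, scheme) {
  n <- length(seed$events); m <- length(synth$events)
  J <- matrix(0, n, m)
  for (i in seq_len(n)) {
    a <- seed$events[[i]]
    for (j in seq_len(m)) {
      b <- synth$events[[j]]
      J[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  list(P = scheme$mismatch + (scheme$match - scheme$mismatch) * J,
       W = scheme$mismatch * (1 - J))
}
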