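#' Construct a daily event
#'
#' A daily event is the set of all diagnosis codes recorded for one patient on
#' one calendar date. It is the atomic symbol of the alignment alphabet: two
#' daily events are compared by the Jaccard index of their code sets, never by
#' code order. Duplicate codes collapse silently (set semantics) and codes are
#' stored sorted so that equal sets compare `identical()`.
#'
#' @param codes Character vector of diagnosis codes; must be non-empty and
#'   contain no empty strings.
#' @return A sorted character vector of unique codes.
#' @examples
#' daily_event(c("487", "480", "487"))
#' @export
daily_event <- function(codes) {
  codes <- as.character(codes)
  if (length(codes) == 0L || anyNA(codes) || any(!nzchar(codes))) {
    stop("a daily event needs at least one non-empty diagnosis code", call. = FALSE)
  }
  sort(unique(codes))
}

#' Construct a patient event sequence
#'
#' An event sequence is the ordered list of a patient's daily events. Its
#' length N is the normalization denominator for alignment scores when the
#' sequence plays the seed role. Dates are optional: the aligners consume only
#' event order, never inter-event time gaps.
#'
#' @param events List of daily events (each a character vector of codes; see
#'   [daily_event()]).
#' @param patient_id Single identifier string.
#' @param dates Optional `Date` vector (or anything `as.Date()` accepts), one
#'   per event, strictly increasing.
#' @return An object of class `event_sequence`.
#' @examples
#' event_sequence(list("250", c("487", "480"), "250"), patient_id = "p1")
#' @export
event_sequence <- function(events, patient_id = "patient", dates = NULL) {
  if (!is.list(events)) events <- as.list(events)
  if (length(events) < 1L) {
    stop("an event sequence needs at least one daily event", call. = FALSE)
  }
  events <- lapply(events, daily_event)
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    if (length(dates) != length(events)) {
      stop("'dates' must have one entry per daily event", call. = FALSE)
    }
    if (anyNA(dates)) stop("'dates' contains unparseable dates", call. = FALSE)
    if (length(dates) > 1L && any(diff(dates) <= 0)) {
      stop("'dates' must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id)[1L], events = events, dates = dates),
    class = "event_sequence"
  )
}

#' @export
length.event_sequence <- function(x) length(x$events)

#' @export
`[.event_sequence` <- function(x, i) {
  event_sequence(x$events[i], patient_id = x$patient_id,
                 dates = if (!is.null(x$dates)) x$dates[i])
}

format_event <- function(codes) paste0("{", paste(codes, collapse = ","), "}")

#' @export
print.event_sequence <- function(x, n = 10L, ...) {
  cat(sprintf("Event sequence '%s': %d daily events%s\n", x$patient_id,
              length(x), if (is.null(x$dates)) "" else " (dated)"))
  shown <- utils::head(seq_along(x$events), n)
  lab <- vapply(x$events[shown], format_event, character(1))
  if (!is.null(x$dates)) lab <- paste0(format(x$dates[shown]), " ", lab)
  cat(" ", paste(lab, collapse = " "), if (length(x) > n) "..." else "", "\n")
  invisible(x)
}

#' @export
as.character.event_sequence <- function(x, ...) {
  vapply(x$events, format_event, character(1))
}

seq_equal <- function(a, b) {
  identical(lapply(a$events, identity), lapply(b$events, identity))
}

#' Group a diagnosis code into its broader category
#'
#' Truncates a hierarchical diagnosis code at the first period, the usual way
#' phenotype codes are collapsed into broader disease categories (e.g.
#' `"195.1"` belongs to category `"195"`). Codes without a period are returned
#' unchanged. This is an explicit, opt-in preprocessing step; no function in
#' this package applies it implicitly.
#'
#' @param code Character vector of codes.
#' @return Character vector of the same length with everything from the first
#'   `"."` on removed.
#' @examples
#' group_code(c("195.1", "250", "008.45"))
#' @export
group_code <- function(code) {
  code <- as.character(code)
  if (length(code) == 0L || anyNA(code) || any(!nzchar(code))) {
    stop("codes must be non-empty strings", call. = FALSE)
  }
  sub("\\..*$", "", code)
}

#' Synthetic diagnosis-category vocabulary
#'
#' A vector of synthetic category codes used as the default code universe for
#' the record generator. The default size, 582, is the number of grouped
#' disease categories in the EHR corpus this package's benchmark design
#' emulates; it is configurable.
#'
#' @param n Number of codes.
#' @return Character vector `"D001" ... `.
#' @export
event_code_vocabulary <- function(n = 582L) {
  sprintf("D%03d", seq_len(n))
}
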