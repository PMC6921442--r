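#' Read event sequences from a file
#'
#' Two dialects are supported. `"csv"` is the one-row-per-code table EHR
#' extracts usually arrive in: header `patient_id,date,code`, ISO-8601 dates.
#' All rows sharing a `(patient_id, date)` are merged into one daily event
#' whose code set is their union, and events are sorted by date within each
#' patient, so an unordered extract reads correctly. `"jsonl"` holds one JSON
#' object per line, one per patient:
#' `{"patient_id": "...", "events": [{"date": "..."|null, "codes": [...]}, ...]}`,
#' preserving authored event order exactly (dates optional).
#'
#' @param file Path to the input file.
#' @param format `"csv"` or `"jsonl"`.
#' @return A list of [event_sequence()] objects, in order of first appearance.
#' @seealso [write_event_sequences()]
#' @export
read_event_sequences <- function(file, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") read_sequences_csv(file) else read_sequences_jsonl(file)
}

read_sequences_csv <- function(file) {
  df <- utils::read.csv(file, colClasses = "character")
  need <- c("patient_id", "date", "code")
  if (!all(need %in% names(df))) {
    stop("csv input must have columns patient_id, date, code", call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  bad <- which(is.na(df$code) | !nzchar(trimws(df$code)))
  if (length(bad)) {
    stop(sprintf("row %d: empty code field", bad[1L]), call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) {
    stop(sprintf("row %d: unparseable date '%s'", bad[1L], df$date[bad[1L]]),
         call. = FALSE)
  }
  out <- list()
  for (pid in unique(df$patient_id)) {
    sel <- df$patient_id == pid
    d <- dates[sel]
    codes <- df$code[sel]
    days <- sort(unique(d))
    events <- lapply(days, function(day) daily_event(codes[d == day]))
    out[[pid]] <- event_sequence(events, patient_id = pid, dates = days)
  }
  out
}

read_sequences_jsonl <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    if (is.null(rec$patient_id) || is.null(rec$events) || !length(rec$events)) {
      stop("jsonl record needs 'patient_id' and a non-empty 'events' array",
           call. = FALSE)
    }
    events <- lapply(rec$events, function(ev) {
      codes <- unlist(ev$codes, use.names = FALSE)
      if (is.null(codes) || !length(codes)) {
        stop(sprintf("patient '%s': event with empty code list", rec$patient_id),
             call. = FALSE)
      }
      daily_event(codes)
    })
    raw_dates <- lapply(rec$events, function(ev) ev$date)
    has_date <- !vapply(raw_dates, is.null, logical(1))
    if (all(has_date)) {
      dates <- as.Date(unlist(raw_dates, use.names = FALSE))
    } else if (any(has_date)) {
      stop(sprintf("patient '%s': events must be all dated or all undated",
                   rec$patient_id), call. = FALSE)
    } else {
      dates <- NULL
    }
    event_sequence(events, patient_id = rec$patient_id, dates = dates)
  })
}

#' Write event sequences to a file
#'
#' Inverse of [read_event_sequences()]: reading the written file reproduces the
#' sequences (patient ids, event order, code sets, dates). The `"csv"` dialect
#' needs dates to carry the event order, so undated sequences must be written
#' as `"jsonl"`. Multi-code events become one csv row per code on the same
#' date.
#'
#' @param seqs A list of [event_sequence()] objects (a single sequence is
#'   accepted too).
#' @param file Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `file`, invisibly.
#' @export
write_event_sequences <- function(seqs, file, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (inherits(seqs, "event_sequence")) seqs <- list(seqs)
  stopifnot(all(vapply(seqs, inherits, logical(1), "event_sequence")))
  if (format == "csv") {
    rows <- lapply(seqs, function(s) {
      if (is.null(s$dates)) {
        stop(sprintf("sequence '%s' has no dates; use format = \"jsonl\"",
                     s$patient_id), call. = FALSE)
      }
      nc <- lengths(s$events)
      data.frame(patient_id = rep(s$patient_id, sum(nc)),
                 date = format(rep(s$dates, nc), "%Y-%m-%d"),
                 code = unlist(s$events, use.names = FALSE),
                 stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      data.frame(patient_id = character(), date = character(),
                 code = character())
    }
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  } else {
    lines <- vapply(seqs, function(s) {
      events <- lapply(seq_along(s$events), function(i) {
        list(date = if (is.null(s$dates)) NULL else format(s$dates[i], "%Y-%m-%d"),
             codes = I(s$events[[i]]))
      })
      jsonlite::toJSON(list(patient_id = s$patient_id, events = events),
                       auto_unbox = TRUE, null = "null")
    }, character(1))
    writeLines(lines, file)
  }
  invisible(file)
}
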