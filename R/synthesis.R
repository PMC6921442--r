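sample_one <- function(v) v[sample.int(length(v), 1L)]

#' Event-block size for a sequence of length n
#'
#' Block-level mutation operations act on runs of consecutive daily events of
#' size `max(2, floor(n / 10))`, so blocks scale with the record length but
#' never drop below two events.
#'
#' @param n Sequence length (number of daily events).
#' @return Integer block size.
#' @examples
#' block_size(c(9, 84, 224, 458))  # 2, 8, 22, 45
#' @export
block_size <- function(n) {
  n <- as.integer(n)
  if (anyNA(n) || any(n < 1L)) stop("'n' must be a positive count", call. = FALSE)
  pmax(2L, n %/% 10L)
}

#' Construct a mutation operation record
#'
#' The record of one synthesis operation: what was done, where, and with what
#' replacement material. Operation records are deterministic — applying one to
#' the same sequence always yields the same result — which is what makes a
#' synthetic record's provenance replayable ground truth.
#'
#' @param kind `"delete"`, `"update"`, or `"switch"`.
#' @param level `"daily"` (one event) or `"block"` (a run of consecutive
#'   events, see [block_size()]).
#' @param positions Affected 1-based positions: one position (delete/update
#'   daily), one interval (delete/update block), a length-2 vector (switch
#'   daily), or `list(first =, second =)` of two disjoint equal-length
#'   intervals (switch block).
#' @param details For update daily, `list(action = "replace"|"remove",
#'   old =, new =)`; for update block, `list(replacements = <list of events>)`.
#' @return An object of class `event_operation`.
#' @export
event_operation <- function(kind = c("delete", "update", "switch"),
                            level = c("daily", "block"),
                            positions, details = NULL) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  structure(list(kind = kind, level = level, positions = positions,
                 details = details),
            class = "event_operation")
}

#' @export
print.event_operation <- function(x, ...) {
  pos <- if (is.list(x$positions)) {
    paste0(paste(range(x$positions$first), collapse = "-"), " <-> ",
           paste(range(x$positions$second), collapse = "-"))
  } else paste(x$positions, collapse = ",")
  cat(sprintf("%s %s @ %s\n", x$kind, x$level, pos))
  invisible(x)
}

affected_positions <- function(op) {
  if (is.list(op$positions)) c(op$positions$first, op$positions$second)
  else op$positions
}

# Re-express positions in post-deletion coordinates; deleted ones drop out.
shift_after_delete <- function(positions, deleted) {
  positions <- setdiff(positions, deleted)
  vapply(positions, function(p) p - sum(deleted < p), integer(1))
}

#' Apply a recorded operation to a sequence
#'
#' Deterministic replay of one [event_operation()]. Dates are dropped: the
#' synthesis pipeline regenerates a fresh date grid on the finished record.
#'
#' @param x An [event_sequence()].
#' @param op An [event_operation()].
#' @return The mutated `event_sequence`.
#' @export
apply_recorded_operation <- function(x, op) {
  stopifnot(inherits(x, "event_sequence"), inherits(op, "event_operation"))
  events <- x$events
  n <- length(events)
  pos <- op$positions
  check_pos <- function(p) {
    if (any(p < 1L | p > n)) stop("operation positions out of range", call. = FALSE)
  }
  if (op$kind == "delete") {
    check_pos(pos)
    if (length(pos) >= n) stop("cannot delete every daily event", call. = FALSE)
    events <- events[-pos]
  } else if (op$kind == "update" && op$level == "daily") {
    check_pos(pos)
    ev <- events[[pos]]
    d <- op$details
    if (d$action == "replace") {
      events[[pos]] <- daily_event(c(setdiff(ev, d$old), d$new))
    } else {
      if (length(ev) < 2L) {
        stop("cannot remove the only code of a daily event", call. = FALSE)
      }
      events[[pos]] <- daily_event(setdiff(ev, d$old))
    }
  } else if (op$kind == "update") {            # block
    check_pos(pos)
    events[pos] <- lapply(op$details$replacements, daily_event)
  } else if (op$kind == "switch" && op$level == "daily") {
    check_pos(pos)
    events[pos] <- events[rev(pos)]
  } else {                                     # switch block
    a <- pos$first; b <- pos$second
    check_pos(c(a, b))
    tmp <- events[a]; events[a] <- events[b]; events[b] <- tmp
  }
  event_sequence(events, patient_id = x$patient_id)
}

#' Randomly draw and apply one mutation operation
#'
#' Draws the operation's positions (and, for updates, its replacement codes)
#' at random, applies it, and returns both the mutated sequence and the
#' operation record. Daily updates on a multi-code event choose between
#' replacing one code and removing one code with equal probability; a
#' single-code event is always replaced (its only code may not be removed).
#' Block operations act on [block_size()] consecutive events of the current
#' sequence; a block switch swaps two disjoint equal-length blocks.
#'
#' @inheritParams apply_recorded_operation
#' @param kind,level As in [event_operation()].
#' @param vocab Code universe replacement codes are drawn from.
#' @param exclude Positions (current coordinates) to avoid when drawing, used
#'   to keep the operations of one benchmark row from hitting the same events
#'   twice; ignored when it would make the draw impossible.
#' @return `list(sequence =, operation =)`.
#' @export
apply_operation <- function(x, kind = c("delete", "update", "switch"),
                            level = c("daily", "block"),
                            vocab = event_code_vocabulary(),
                            exclude = integer()) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  stopifnot(inherits(x, "event_sequence"))
  n <- length(x)
  pick <- function(cands, k = 1L) {
    ok <- setdiff(cands, NULL)
    free <- ok[!ok %in% exclude]
    from <- if (length(free) >= k) free else ok
    from[sample.int(length(from), k)]
  }
  pick_start <- function(bs, avoid_blocks = TRUE) {
    starts <- seq_len(n - bs + 1L)
    free <- starts[vapply(starts, function(s) !any(s:(s + bs - 1L) %in% exclude),
                          logical(1))]
    if (length(free)) sample_one(free) else sample_one(starts)
  }
  if (level == "block") {
    bs <- block_size(n)
    min_n <- switch(kind, delete = bs + 1L, update = bs, switch = 2L * bs)
    if (n < min_n) {
      stop(sprintf("block %s needs a sequence of at least %d events (block size %d)",
                   kind, min_n, bs), call. = FALSE)
    }
  }
  op <- if (kind == "delete" && level == "daily") {
    if (n < 2L) stop("cannot delete from a single-event sequence", call. = FALSE)
    event_operation("delete", "daily", positions = pick(seq_len(n)))
  } else if (kind == "delete") {
    s <- pick_start(bs)
    event_operation("delete", "block", positions = s:(s + bs - 1L))
  } else if (kind == "update" && level == "daily") {
    p <- pick(seq_len(n))
    ev <- x$events[[p]]
    action <- if (length(ev) > 1L) sample_one(c("replace", "remove")) else "replace"
    old <- sample_one(ev)
    details <- if (action == "replace") {
      list(action = "replace", old = old, new = sample_one(setdiff(vocab, ev)))
    } else {
      list(action = "remove", old = old)
    }
    event_operation("update", "daily", positions = p, details = details)
  } else if (kind == "update") {
    s <- pick_start(bs)
    blk <- s:(s + bs - 1L)
    replacements <- lapply(x$events[blk], function(ev) sample(vocab, length(ev)))
    event_operation("update", "block", positions = blk,
                    details = list(replacements = replacements))
  } else if (kind == "switch" && level == "daily") {
    if (n < 2L) stop("switching needs at least two daily events", call. = FALSE)
    event_operation("switch", "daily", positions = pick(seq_len(n), 2L))
  } else {
    starts <- seq_len(n - bs + 1L)
    pairs <- expand.grid(s1 = starts, s2 = starts)
    pairs <- pairs[pairs$s2 >= pairs$s1 + bs, , drop = FALSE]
    blk <- function(s) s:(s + bs - 1L)
    free <- !vapply(seq_len(nrow(pairs)), function(r) {
      any(c(blk(pairs$s1[r]), blk(pairs$s2[r])) %in% exclude)
    }, logical(1))
    if (any(free)) pairs <- pairs[free, , drop = FALSE]
    r <- sample.int(nrow(pairs), 1L)
    event_operation("switch", "block",
                    positions = list(first = blk(pairs$s1[r]),
                                     second = blk(pairs$s2[r])))
  }
  list(sequence = apply_recorded_operation(x, op), operation = op)
}

synth_date_grid <- function(n, start = as.Date("2001-01-01")) {
  start + seq_len(n) - 1L
}

#' Construct a synthetic record from explicit operations
#'
#' Applies a list of [event_operation()]s to a seed sequence left to right and
#' packages the result with its provenance and index map. The index map gives,
#' for each synthetic position, the seed position it originates from
#' (positional origin: updates and switches leave it unchanged, deletions
#' remove entries), and is the ground truth that reference alignments are
#' built from. Synthetic sequences get a fresh strictly-increasing daily date
#' grid; alignment ignores dates.
#'
#' @param seed Seed [event_sequence()].
#' @param ops List of [event_operation()] (a single operation is accepted).
#' @param patient_id Identifier for the synthetic sequence.
#' @param operation_label Optional short label (e.g. `"x u"`).
#' @return An object of class `synthetic_record` with fields `sequence`,
#'   `provenance`, `index_map`, `seed_id`, `seed_length`, `operation_label`.
#' @export
record_from_operations <- function(seed, ops, patient_id = "synthetic",
                                   operation_label = NA_character_) {
  stopifnot(inherits(seed, "event_sequence"))
  if (inherits(ops, "event_operation")) ops <- list(ops)
  x <- seed
  map <- seq_len(length(seed))
  for (op in ops) {
    stopifnot(inherits(op, "event_operation"))
    x <- apply_recorded_operation(x, op)
    if (op$kind == "delete") map <- map[-op$positions]
  }
  sequence <- event_sequence(x$events, patient_id = patient_id,
                             dates = synth_date_grid(length(x)))
  structure(list(sequence = sequence, provenance = ops, index_map = map,
                 seed_id = seed$patient_id, seed_length = length(seed),
                 operation_label = operation_label),
            class = "synthetic_record")
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf("Synthetic record '%s' from seed '%s' (N = %d -> %d events)\n",
              x$sequence$patient_id, x$seed_id, x$seed_length,
              length(x$sequence)))
  if (!is.na(x$operation_label)) cat(sprintf("  operations: %s\n", x$operation_label))
  for (op in x$provenance) { cat("  - "); print(op) }
  invisible(x)
}

#' Replay a synthetic record's provenance
#'
#' Applies the recorded operations to the seed from scratch. For a consistent
#' record this reproduces the synthetic sequence bit for bit (events and date
#' grid), which is how record integrity is checked.
#'
#' @param seed Seed [event_sequence()].
#' @param provenance List of [event_operation()]s.
#' @param patient_id Identifier for the replayed sequence.
#' @return An [event_sequence()].
#' @export
replay_provenance <- function(seed, provenance, patient_id = "replay") {
  x <- seed
  for (op in provenance) x <- apply_recorded_operation(x, op)
  event_sequence(x$events, patient_id = patient_id,
                 dates = synth_date_grid(length(x)))
}

record_is_consistent <- function(seed, record) {
  replayed <- replay_provenance(seed, record$provenance)
  identical(replayed$events, record$sequence$events) &&
    length(record$index_map) == length(record$sequence) &&
    (!length(record$index_map) || all(diff(record$index_map) > 0)) &&
    all(record$index_map >= 1L & record$index_map <= length(seed))
}

#' The default 20-row benchmark operation design
#'
#' One label per synthetic record: lower-case letters are daily-event
#' operations, upper-case letters event-block operations; `x`/`X` delete,
#' `u`/`U` update, `s`/`S` switch. Multiple letters in one label are applied
#' left to right to the already-mutated sequence.
#'
#' @return Character vector of 20 labels.
#' @export
default_design <- function() {
  c("x", "x x", "u", "u u", "s", "s s", "x u", "x s", "u s", "x u s",
    "X", "X X", "U", "U U", "S", "S S", "X U", "X S", "U S", "X U S")
}

parse_op_token <- function(token) {
  kind <- switch(tolower(token), x = "delete", u = "update", s = "switch",
                 stop(sprintf("unknown operation label '%s'", token), call. = FALSE))
  list(kind = kind, level = if (token %in% c("X", "U", "S")) "block" else "daily")
}

#' Synthesize a benchmark suite of mutated records
#'
#' For each design label, applies the labelled operations to the seed in
#' order, drawing positions at random but without replacement within a row
#' (two operations in one row avoid hitting the same events where the
#' sequence length permits). Fully reproducible given the RNG state
#' (`set.seed()`).
#'
#' @param seed Seed [event_sequence()].
#' @param design Character vector of operation labels; see [default_design()].
#' @param vocab Code universe for update operations.
#' @param id_prefix Prefix for synthetic patient ids.
#' @return List of [record_from_operations()] synthetic records, one per
#'   design row.
#' @export
synthesize_benchmark <- function(seed, design = default_design(),
                                 vocab = event_code_vocabulary(),
                                 id_prefix = "synthetic") {
  stopifnot(inherits(seed, "event_sequence"))
  out <- vector("list", length(design))
  for (r in seq_along(design)) {
    tokens <- strsplit(trimws(design[r]), "\\s+")[[1]]
    if (!length(tokens)) stop("empty design label", call. = FALSE)
    x <- seed
    ops <- list()
    affected <- integer()
    for (token in tokens) {
      tok <- parse_op_token(token)
      res <- apply_operation(x, tok$kind, tok$level, vocab = vocab,
                             exclude = affected)
      op <- res$operation
      if (op$kind == "delete") {
        affected <- shift_after_delete(affected, op$positions)
      } else {
        affected <- union(affected, affected_positions(op))
      }
      x <- res$sequence
      ops[[length(ops) + 1L]] <- op
    }
    out[[r]] <- record_from_operations(
      seed, ops, patient_id = sprintf("%s_%02d", id_prefix, r),
      operation_label = design[r])
  }
  out
}

#' Default seed-sequence generation profile
#'
#' Parameters controlling what [generate_seed_sequence()] emulates: the share
#' of multi-diagnosis days, how many extra codes such days carry, how often
#' the chronic marker code recurs, and the largest inter-visit gap in days.
#'
#' @param p_multi Probability a day records more than one diagnosis code.
#' @param extra_max Maximum number of extra codes on a multi-code day.
#' @param chronic_frac Fraction of days carrying the chronic code; the count
#'   is `max(2, floor(chronic_frac * n))`.
#' @param max_gap Upper bound (days) on the gap between consecutive visits.
#' @return A named list.
#' @export
seed_profile <- function(p_multi = 0.3, extra_max = 2L, chronic_frac = 0.4,
                         max_gap = 21L) {
  stopifnot(p_multi >= 0, p_multi <= 1, extra_max >= 1L, chronic_frac > 0,
            max_gap >= 1L)
  list(p_multi = p_multi, extra_max = as.integer(extra_max),
       chronic_frac = chronic_frac, max_gap = as.integer(max_gap))
}

#' Generate a synthetic seed patient sequence
#'
#' Emulates the clinical-encounter scenarios that make medical-record
#' alignment non-trivial: single- and multi-diagnosis days (multiple visits on
#' one date merge into one daily event), one chronic-style code recurring
#' across many days, and one acute-style code occurring exactly once. Dates
#' increase with random inter-visit gaps. Deterministic given the RNG state.
#'
#' @param n_events Number of daily events.
#' @param vocab Code universe (at least 4 codes).
#' @param profile A [seed_profile()].
#' @param patient_id Identifier.
#' @return An [event_sequence()].
#' @export
generate_seed_sequence <- function(n_events, vocab = event_code_vocabulary(),
                                   profile = seed_profile(),
                                   patient_id = "seed") {
  n <- as.integer(n_events)
  if (is.na(n) || n < 1L) stop("'n_events' must be a positive count", call. = FALSE)
  if (length(vocab) < 4L) stop("'vocab' needs at least 4 codes", call. = FALSE)
  k_chronic <- max(2L, as.integer(profile$chronic_frac * n))
  if (k_chronic > n) {
    stop(sprintf("profile asks for %d chronic recurrences but only %d events",
                 k_chronic, n), call. = FALSE)
  }
  chronic <- sample_one(vocab)
  acute <- sample_one(setdiff(vocab, chronic))
  pool <- setdiff(vocab, c(chronic, acute))
  extra <- sample.int(profile$extra_max, n, replace = TRUE)
  sizes <- ifelse(stats::runif(n) < profile$p_multi, 1L + extra, 1L)
  sizes <- pmin(sizes, length(pool))
  events <- lapply(sizes, function(k) sample(pool, k))
  chronic_at <- sort(sample.int(n, k_chronic))
  for (p in chronic_at) events[[p]] <- c(events[[p]], chronic)
  acute_at <- sample.int(n, 1L)
  events[[acute_at]] <- c(events[[acute_at]], acute)
  dates <- as.Date("2001-01-01") +
    cumsum(sample.int(profile$max_gap, n, replace = TRUE))
  event_sequence(events, patient_id = patient_id, dates = dates)
}
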