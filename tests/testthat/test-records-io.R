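test_that("daily events are non-empty code sets", {
  expect_identical(daily_event(c("487", "480", "487")), c("480", "487"))
  expect_error(daily_event(character()), "non-empty")
  expect_error(daily_event(c("487", "")), "non-empty")
})

test_that("event sequences validate their dates", {
  s <- event_sequence(list("a", "b"), dates = c("2019-01-01", "2019-01-05"))
  expect_s3_class(s, "event_sequence")
  expect_length(s, 2L)
  expect_error(event_sequence(list(), "p"), "at least one")
  expect_error(event_sequence(list("a", "b"), dates = c("2019-01-02", "2019-01-01")),
               "strictly increasing")
  expect_error(event_sequence(list("a", "b"), dates = "2019-01-01"),
               "one entry per")
})

test_that("csv rows sharing a (patient, date) merge into one daily event", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,date,code",
               "p1,2019-01-01,487",
               "p1,2019-01-01,480",
               "p1,2019-01-03,250"), f)
  seqs <- read_event_sequences(f, "csv")
  expect_length(seqs, 1L)
  expect_identical(seqs[["p1"]]$events,
                   list(c("480", "487"), "250"))
})

test_that("csv events come out in date order regardless of row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,date,code",
               "p1,2019-03-01,c",
               "p1,2019-01-01,a",
               "p1,2019-02-01,b"), f)
  s <- read_event_sequences(f, "csv")[["p1"]]
  expect_identical(unlist(s$events), c("a", "b", "c"))
  expect_true(all(diff(s$dates) > 0))
})

test_that("csv format errors name the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,date,code", "p1,2019-01-01,487", "p1,2019-01-02,"), f)
  expect_error(read_event_sequences(f, "csv"), "row 2: empty code")
  writeLines(c("patient_id,date,code", "p1,01/02/2019,487"), f)
  expect_error(read_event_sequences(f, "csv"), "row 1: unparseable date")
})

test_that("write/read round-trips are the identity", {
  s1 <- event_sequence(list(c("487", "480"), "250", c("195", "487")),
                       patient_id = "pA",
                       dates = c("2019-01-01", "2019-01-04", "2019-02-02"))
  s2 <- event_sequence(list("008", "250"), patient_id = "pB",
                       dates = c("2018-06-01", "2018-06-09"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_sequences(list(s1, s2), f, "csv")
  back <- read_event_sequences(f, "csv")
  expect_identical(back[["pA"]]$events, s1$events)
  expect_identical(back[["pA"]]$dates, s1$dates)
  expect_identical(back[["pB"]]$events, s2$events)

  undated <- event_sequence(list(c("a", "b"), "c"), patient_id = "u")
  g <- withr::local_tempfile(fileext = ".jsonl")
  write_event_sequences(list(undated, s1), g, "jsonl")
  back2 <- read_event_sequences(g, "jsonl")
  expect_identical(back2[[1]]$events, undated$events)
  expect_null(back2[[1]]$dates)
  expect_identical(back2[[2]]$events, s1$events)
  expect_identical(back2[[2]]$dates, s1$dates)

  # merging is idempotent: re-writing the merged file changes nothing
  h <- withr::local_tempfile(fileext = ".csv")
  write_event_sequences(back, h, "csv")
  expect_identical(read_event_sequences(h, "csv")[["pA"]]$events, s1$events)
})

test_that("empty input round-trips to an empty sequence set", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_sequences(list(), f, "csv")
  expect_length(read_event_sequences(f, "csv"), 0L)
})

test_that("undated sequences refuse the csv dialect", {
  s <- event_sequence(list("a"), patient_id = "u")
  expect_error(write_event_sequences(s, tempfile(), "csv"), "jsonl")
})

test_that("code grouping truncates at the first period and is idempotent", {
  expect_identical(group_code("195.1"), "195")
  expect_identical(group_code("250"), "250")
  expect_identical(group_code("008.45"), "008")
  codes <- c("195.1", "250", "008.45", "E950.0")
  expect_identical(group_code(group_code(codes)), group_code(codes))
  expect_error(group_code(""), "non-empty")
})
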