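test_that("block size is max(2, floor(n/10))", {
  expect_identical(block_size(c(9, 84, 224, 458)), c(2L, 8L, 22L, 45L))
  expect_identical(block_size(1), 2L)
  expect_identical(block_size(20), 2L)
  expect_error(block_size(0), "positive")
})

test_that("daily operations do what their records say", {
  seed <- seq1(c("a", "b", "b", "c"), "seed")
  del <- apply_recorded_operation(seed, event_operation("delete", "daily", 3))
  expect_identical(unlist(del$events), c("a", "b", "c"))

  sw <- apply_recorded_operation(seq1(c("a", "b", "c", "d")),
                                 event_operation("switch", "daily", c(2, 3)))
  expect_identical(unlist(sw$events), c("a", "c", "b", "d"))
  # switching the same positions again restores the original
  sw2 <- apply_recorded_operation(sw, event_operation("switch", "daily", c(2, 3)))
  expect_identical(unlist(sw2$events), c("a", "b", "c", "d"))

  up <- apply_recorded_operation(
    seed, event_operation("update", "daily", 3,
                          list(action = "replace", old = "b", new = "z")))
  expect_identical(unlist(up$events), c("a", "b", "z", "c"))
})

test_that("random daily update on a single-code event is forced to replace", {
  set.seed(91)
  seed <- event_sequence(list("a"), "s")
  for (r in 1:10) {
    res <- apply_operation(seed, "update", "daily", vocab = c("a", "b", "c", "d"))
    expect_identical(res$operation$details$action, "replace")
    expect_length(res$sequence$events[[1]], 1L)
    expect_false(identical(res$sequence$events[[1]], "a"))
  }
})

test_that("operations change length exactly as specified", {
  set.seed(101)
  seed <- generate_seed_sequence(20, vocab = event_code_vocabulary(30))
  for (r in 1:15) {
    kind <- sample(c("delete", "update", "switch"), 1)
    level <- sample(c("daily", "block"), 1)
    res <- apply_operation(seed, kind, level)
    dl <- length(res$sequence) - length(seed)
    if (kind == "delete") {
      expect_equal(dl, -length(res$operation$positions))
    } else {
      expect_equal(dl, 0L)
    }
  }
})

test_that("block operations respect the block-size rule and bounds", {
  set.seed(111)
  seed <- generate_seed_sequence(30, vocab = event_code_vocabulary(40))
  bs <- block_size(30)
  res <- apply_operation(seed, "delete", "block")
  expect_length(res$operation$positions, bs)
  expect_true(all(diff(res$operation$positions) == 1L))
  res <- apply_operation(seed, "switch", "block")
  p <- res$operation$positions
  expect_length(p$first, bs)
  expect_length(p$second, bs)
  expect_length(intersect(p$first, p$second), 0L)
  # too short for a block switch
  short <- generate_seed_sequence(3, vocab = event_code_vocabulary(20))
  expect_error(apply_operation(short, "switch", "block"), "at least 4")
})

test_that("provenance replays to the identical synthetic sequence", {
  set.seed(121)
  seed <- generate_seed_sequence(25, vocab = event_code_vocabulary(50))
  records <- synthesize_benchmark(seed)
  expect_length(records, 20L)
  for (rec in records) {
    replayed <- replay_provenance(seed, rec$provenance)
    expect_identical(replayed$events, rec$sequence$events)
    expect_identical(replayed$dates, rec$sequence$dates)
    im <- rec$index_map
    expect_length(im, length(rec$sequence))
    if (length(im) > 1L) expect_true(all(diff(im) > 0))
  }
})

test_that("design labels drive the provenance composition", {
  set.seed(131)
  seed <- generate_seed_sequence(30, vocab = event_code_vocabulary(40))
  recs <- synthesize_benchmark(seed, design = c("x x", "X U S"))
  expect_length(recs[[1]]$provenance, 2L)
  expect_true(all(vapply(recs[[1]]$provenance, function(o) o$kind, "") == "delete"))
  expect_true(all(vapply(recs[[1]]$provenance, function(o) o$level, "") == "daily"))
  kinds <- vapply(recs[[2]]$provenance, function(o) o$kind, "")
  lvls <- vapply(recs[[2]]$provenance, function(o) o$level, "")
  expect_identical(kinds, c("delete", "update", "switch"))
  expect_true(all(lvls == "block"))
  expect_error(synthesize_benchmark(seed, design = "q"), "unknown operation")
  expect_length(synthesize_benchmark(seed, design = character()), 0L)
})

test_that("synthesis is reproducible under a fixed RNG seed", {
  seed <- { set.seed(141); generate_seed_sequence(15, vocab = event_code_vocabulary(30)) }
  set.seed(142); a <- synthesize_benchmark(seed, design = c("x u", "S"))
  set.seed(142); b <- synthesize_benchmark(seed, design = c("x u", "S"))
  for (r in 1:2) expect_identical(a[[r]]$sequence$events, b[[r]]$sequence$events)
})

test_that("generated seeds carry the encounter-scenario structure", {
  set.seed(151)
  vocab <- event_code_vocabulary(100)
  s <- generate_seed_sequence(9, vocab = vocab)
  expect_length(s, 9L)
  expect_true(any(lengths(s$events) > 1L))           # a multi-diagnosis day
  counts <- table(unlist(s$events))
  expect_true(any(counts >= 2))                      # a recurring (chronic) code
  expect_true(any(counts == 1))                      # an isolated (acute) code
  expect_true(all(unlist(s$events) %in% vocab))
  expect_true(all(diff(s$dates) > 0))
  set.seed(161); s1 <- generate_seed_sequence(12, vocab = vocab)
  set.seed(161); s2 <- generate_seed_sequence(12, vocab = vocab)
  expect_identical(s1$events, s2$events)
  expect_error(generate_seed_sequence(1), "chronic")
})
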