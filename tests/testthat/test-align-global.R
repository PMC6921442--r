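# Worked deletion scenario: seed [a,b,b,c], one duplicate deleted.
seed_del <- seq1(c("a", "b", "b", "c"), "seed")
synth_del <- seq1(c("a", "b", "c"), "synthetic")

test_that("DTW repairs a deletion by warping and scores 0.75", {
  a <- align_events(seed_del, synth_del, "dtw")
  expect_equal(a$raw_score, 3)
  expect_equal(a$normalized_score, 0.75)
  expect_legal_alignment(a)
  # one warp column repeating the synthetic duplicate, scored J - 1 = 0
  warp <- a$columns[grepl("warp", a$columns$role), ]
  expect_equal(nrow(warp), 1L)
  expect_equal(warp$score, 0)
})

test_that("NWA charges a gap for the same deletion and scores 0.50", {
  a <- align_events(seed_del, synth_del, "nwa")
  expect_equal(a$normalized_score, 0.5)
  expect_legal_alignment(a)
  expect_equal(sum(a$columns$role == "gap_in_synth"), 1L)
})

test_that("an adjacent switch lets NWA gap both sides for 0.25", {
  seed <- seq1(c("a", "b", "c", "d"))
  synth <- seq1(c("a", "c", "b", "d"))
  a <- align_events(seed, synth, "nwa")
  expect_equal(a$normalized_score, 0.25)
  expect_legal_alignment(a)
})

test_that("self-alignment is perfect for the global methods", {
  set.seed(21)
  for (r in 1:10) {
    s <- rand_seq(sample.int(8, 1), multi = 2L)
    for (m in c("dtw", "nwa")) {
      a <- align_events(s, s, m)
      expect_equal(a$normalized_score, 1)
      expect_true(all(a$columns$role == "pair"))
    }
  }
})

test_that("a longer warp run still scores each extra copy", {
  seed <- seq1(c("a", "b", "b", "b", "c"))
  synth <- seq1(c("a", "b", "b", "c"))
  a <- align_events(seed, synth, "dtw")
  expect_equal(a$raw_score, 4)  # frozen from exhaustive path enumeration
  expect_equal(a$normalized_score, 0.8)
})

test_that("global DP raw scores match exhaustive enumeration", {
  set.seed(31)
  for (r in 1:40) {
    A <- rand_seq(sample.int(6, 1), multi = 2L)
    B <- rand_seq(sample.int(6, 1), multi = 2L)
    for (m in c("dtw", "nwa")) {
      expect_equal(align_events(A, B, m)$raw_score,
                   brute_force_alignment_score(A, B, m),
                   tolerance = 1e-9, info = m)
    }
  }
})

test_that("DTW dominates NWA and raw scores are symmetric", {
  set.seed(41)
  for (r in 1:30) {
    A <- rand_seq(sample.int(7, 1), multi = 2L)
    B <- rand_seq(sample.int(7, 1), multi = 2L)
    dtw_ab <- align_events(A, B, "dtw")
    nwa_ab <- align_events(A, B, "nwa")
    expect_gte(dtw_ab$raw_score, nwa_ab$raw_score - 1e-9)
    expect_equal(dtw_ab$raw_score, align_events(B, A, "dtw")$raw_score)
    expect_equal(nwa_ab$raw_score, align_events(B, A, "nwa")$raw_score)
    expect_legal_alignment(dtw_ab)
    expect_legal_alignment(nwa_ab)
  }
})

test_that("DTW warping still dominates when the first seed event is deleted", {
  seed <- seq1(letters[1:9])
  synth <- seq1(letters[2:9])
  expect_equal(align_events(seed, synth, "nwa")$raw_score, 7)
  expect_equal(align_events(seed, synth, "dtw")$raw_score, 7)
})

test_that("NWA raw score agrees with an independent aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(51)
  alpha <- c("A", "C", "G", "T")
  mat <- matrix(-1, 4, 4, dimnames = list(alpha, alpha)); diag(mat) <- 1
  for (r in 1:8) {
    a <- sample(alpha, sample(2:7, 1), replace = TRUE)
    b <- sample(alpha, sample(2:7, 1), replace = TRUE)
    ours <- align_events(seq1(a), seq1(b), "nwa")$raw_score
    ref <- Biostrings::pairwiseAlignment(
      paste(a, collapse = ""), paste(b, collapse = ""), type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(ours, ref)
    ours_l <- align_events(seq1(a), seq1(b), "swa")$raw_score
    ref_l <- Biostrings::pairwiseAlignment(
      paste(a, collapse = ""), paste(b, collapse = ""), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(ours_l, ref_l)
  }
})

test_that("empty sequences are rejected", {
  expect_error(event_sequence(list()), "at least one")
})
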