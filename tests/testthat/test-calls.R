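test_that("prominence peak finding handles canonical shapes", {
  # isolated triangular bump: one peak with prominence equal to its height
  y <- c(0, 0.25, 0.5, 1, 0.5, 0.25, 0)
  pk <- findPeaksProminence(y, 0.1, offsets = -3:3)
  expect_identical(pk$offset, 0L)
  expect_equal(pk$prominence, 1)
  # minor peak below the prominence floor is dropped
  y2 <- c(0, 1.0, 0.92, 0.95, 0)
  pk2 <- findPeaksProminence(y2, 0.1, offsets = 0:4)
  expect_identical(pk2$offset, 1L)
  expect_equal(promOracle(y2, 0)$prominence[2], 0.03)
  # monotone and flat profiles have no interior peaks
  expect_identical(nrow(findPeaksProminence(1:10 / 10, 0)), 0L)
  expect_identical(nrow(findPeaksProminence(rep(0, 10), 0)), 0L)
  # plateau maxima report the center; even plateaus break toward the anchor
  y3 <- c(0, 1, 1, 1, 0)
  expect_identical(findPeaksProminence(y3, 0.1, offsets = 0:4)$offset, 2L)
  y4 <- c(0, 1, 1, 0)
  expect_identical(
    findPeaksProminence(y4, 0.1, offsets = -3:0, anchor_offset = 0)$offset,
    -1L)
  expect_identical(
    findPeaksProminence(y4, 0.1, offsets = 0:3, anchor_offset = 0)$offset,
    1L)
})

test_that("prominence calls agree with the exhaustive oracle", {
  set.seed(41)
  for (trial in 1:200) {
    n <- sample(10:500, 1)
    y <- switch(1 + trial %% 3,
                round(runif(n), 2),                     # many ties/plateaus
                cumsum(rnorm(n)),                       # random walk
                rpois(n, 2) + 0)                        # integer counts
    thr <- runif(1, 0, 0.5) * max(abs(y), 1)
    got <- findPeaksProminence(y, thr)
    want <- promOracle(y, thr)
    expect_identical(got$offset, want$index - 1L)
    expect_equal(got$height, want$height)
    expect_equal(got$prominence, want$prominence)
  }
})

test_that("raising the prominence threshold never adds peaks", {
  set.seed(42)
  y <- abs(cumsum(rnorm(300)))
  thr <- sort(runif(10, 0, max(y)))
  n_peaks <- vapply(thr, function(t) nrow(findPeaksProminence(y, t)), 1L)
  expect_true(all(diff(n_peaks) <= 0))
})

test_that("flanking selection takes the highest peak per side", {
  pk <- data.frame(offset = c(-95, 60), height = c(0.8, 0.9),
                   prominence = c(0.8, 0.9))
  sel <- selectFlankingNucleosomes(pk)
  expect_equal(sel$minus1$offset, -95)
  expect_equal(sel$plus1$offset, 60)
  pk2 <- data.frame(offset = c(-120, -80, 70), height = c(0.5, 0.9, 1.0),
                    prominence = c(0.5, 0.9, 1.0))
  expect_equal(selectFlankingNucleosomes(pk2)$minus1$offset, -80)
  # only-upstream peaks: uncallable; offset 0 counts for neither side
  pk3 <- data.frame(offset = c(-100, 0), height = c(1, 1),
                    prominence = c(1, 1))
  expect_false(selectFlankingNucleosomes(pk3)$callable)
  # equal heights break toward the anchor
  pk4 <- data.frame(offset = c(-120, -60, 80), height = c(0.9, 0.9, 1),
                    prominence = c(0.9, 0.9, 1))
  expect_equal(selectFlankingNucleosomes(pk4)$minus1$offset, -60)
  # peaks beyond the search window are ignored
  pk5 <- data.frame(offset = c(-170, -90, 90), height = c(1, 0.5, 1),
                    prominence = c(1, 0.5, 1))
  expect_equal(selectFlankingNucleosomes(pk5)$minus1$offset, -90)
})

test_that("bootstrap SEs are deterministic, shrink with depth, and vanish
           for perfectly positioned data", {
  set.seed(43)
  mo <- c(round(rnorm(1000, -95, 20)), round(rnorm(1000, 55, 20)))
  ln <- rep(160L, 2000)
  b1 <- bootstrapPositionSE(mo, ln, seed = 1)
  b1b <- bootstrapPositionSE(mo, ln, seed = 1)
  expect_identical(b1, b1b)
  b2 <- bootstrapPositionSE(rep(mo, 2), rep(ln, 2), seed = 1)
  # doubling depth shrinks the SE by about sqrt(2)
  expect_gt(b1$se_minus1 / b2$se_minus1, 1.15)
  expect_lt(b1$se_minus1 / b2$se_minus1, 1.75)
  b0 <- bootstrapPositionSE(rep(c(-95L, 55L), each = 500), rep(160L, 1000),
                            seed = 2)
  expect_lt(b0$se_minus1, 1)
  expect_lt(b0$se_plus1, 1)
  expect_false(b0$low_confidence)
  expect_error(bootstrapPositionSE(mo, ln, B = 10), "at least 50")
})

test_that("nucleosome calls recover true dyads on synthetic anchors", {
  arch <- nucArchitecture(sprintf("a%03d", 1:60), minus1_center = -95,
                          plus1_center = 55, fuzziness_sd = 20,
                          occupancy_minus1 = 900, occupancy_plus1 = 900,
                          background_rate = 0.2)
  cfg <- simConfig(seed = 17)
  fr <- simulateFragments(arch, cfg, "control")
  calls <- callNucleosomes(fr, syntheticAnchors(arch, cfg), B = 0)
  ok <- calls$status == "ok"
  expect_gt(mean(ok), 0.95)
  hit <- abs(calls$minus1_offset[ok] + 95) <= 3 &
         abs(calls$plus1_offset[ok] - 55) <= 3
  expect_gte(mean(hit), 0.95)
  expect_true(all(calls$minus1_offset[ok] < 0 & calls$plus1_offset[ok] > 0))
  expect_true(all(abs(calls$minus1_offset[ok]) <= 150 &
                  calls$plus1_offset[ok] <= 150))
})

test_that("anchors without a flanking peak are reported uncallable", {
  # all fragments downstream: no -1 peak can exist
  anc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, width = 1),
                                anchor_id = "a1")
  fr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(rep(5060 - 79, 50), width = 160))
  calls <- suppressMessages(callNucleosomes(fr, anc, B = 0))
  expect_identical(calls$status, "uncallable")
  expect_true(is.na(calls$minus1_offset))
})
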