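test_that("one-tailed z test matches the normal quantile contract", {
  # +1 moved from 70 to 34 with combined SE 10: |z| = 3.6 > qnorm(0.9)
  r <- zShiftTest(70, 34, se_ctrl = sqrt(50), se_dep = sqrt(50),
                  side = "plus1")
  expect_equal(r$z, -3.6)
  expect_true(r$significant)
  expect_equal(qnorm(0.90), 1.281552, tolerance = 1e-6)
  # no movement
  r0 <- zShiftTest(70, 70, 5, 5, side = "plus1")
  expect_equal(r0$z, 0)
  expect_false(r0$significant)
  # +1 moved AWAY from the anchor: never significant one-tailed
  expect_false(zShiftTest(70, 170, 1, 1, side = "plus1")$significant)
  expect_false(zShiftTest(-90, -190, 1, 1, side = "minus1")$significant)
  # -1 toward the anchor is the positive direction
  expect_true(zShiftTest(-108, -59, 5, 5, side = "minus1")$significant)
  # degenerate SEs
  inf <- zShiftTest(70, 34, 0, 0, side = "plus1")
  expect_identical(inf$z, -Inf)
  expect_true(inf$significant)
  eq <- zShiftTest(70, 70, 0, 0, side = "plus1")
  expect_identical(eq$z, 0)
  expect_false(eq$significant)
  expect_error(zShiftTest(1, 2, -1, 1))
})

test_that("shift labels follow the two significance flags", {
  expect_identical(classifyShift(FALSE, TRUE), "Shift1")
  expect_identical(classifyShift(TRUE, FALSE), "Shift2")
  expect_identical(classifyShift(TRUE, TRUE), "Shift3")
  expect_identical(classifyShift(FALSE, FALSE), "non-shift")
})

test_that("spacing is the +1 minus -1 offset", {
  expect_equal(nucSpacing(-88, 56), 144)
  expect_equal(nucSpacing(-93, 70), 163)
  x <- runif(5, 1, 100)
  expect_equal(nucSpacing(-x, x), 2 * x)
})

test_that("group summaries are arithmetic means with counts", {
  calls <- S4Vectors::DataFrame(
    anchor_id = c("a", "b", "c"),
    minus1_ctrl = c(-90, -100, -80), plus1_ctrl = c(60, 70, 50),
    minus1_dep = c(-90, -100, -80), plus1_dep = c(30, 28, 50),
    delta_minus1 = c(0, 0, 0), delta_plus1 = c(-30, -42, 0),
    z_minus1 = 0, z_plus1 = c(-5, -6, 0),
    sig_minus1 = FALSE, sig_plus1 = c(TRUE, TRUE, FALSE),
    label = c("Shift1", "Shift1", "non-shift"),
    spacing_ctrl = c(150, 170, 130), spacing_dep = c(120, 128, 130))
  s <- summarizeShiftGroups(calls, kind = "TSS")
  s1 <- s[s$label == "Shift1", ]
  expect_identical(s1$n, 2L)
  expect_equal(s1$shift_plus1, -36)          # mean of -30 and -42
  expect_equal(s1$spacing_ctrl, 160)
  expect_equal(s1$spacing_ctrl, s1$plus1_ctrl - s1$minus1_ctrl)
  ns <- s[s$label == "non-shift", ]
  expect_identical(ns$n, 1L)
  expect_equal(ns$spacing_dep, 130)          # single-anchor group
  expect_identical(s[s$label == "Shift2", ]$n, 0L)
  expect_true(is.na(s[s$label == "Shift2", ]$shift_minus1))
  expect_identical(sum(s$n), nrow(calls))
})

test_that("hypergeometric tail is exact and stable", {
  expect_equal(hypergeomTest(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeomTest(0, 5, 4, 10), 1)
  expect_equal(hypergeomTest(5, 5, 10, 10), 1)   # n = N forces k = K
  expect_error(hypergeomTest(5, 4, 4, 10))
  expect_error(hypergeomTest(1, 11, 4, 10))
  # stable for large counts
  expect_equal(hypergeomTest(200, 500, 200, 2000),
               exp(sum(lchoose(500, 200) - lchoose(2000, 200) + 0)))
  # agreement with the standard distribution function on random cases
  set.seed(51)
  for (i in 1:50) {
    N <- sample(20:500, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeomTest(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }
})

test_that("hypergeometric matches literal enumeration on small universes", {
  set.seed(52)
  cases <- expand.grid(N = c(6, 9, 12), frac = c(0.3, 0.6))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]
    K <- max(1, round(cases$frac[i] * N))
    for (n in c(2, N %/% 2)) {
      for (k in 0:min(K, n)) {
        expect_equal(hypergeomTest(k, K, n, N), hyperEnumOracle(k, K, n, N))
      }
    }
  }
})

test_that("association matrix has the right direction and degeneracies", {
  calls <- S4Vectors::DataFrame(
    anchor_id = sprintf("a%02d", 1:40),
    label = rep(c("Shift1", "Shift2", "Shift3", "non-shift"), each = 10))
  # Shift1 anchors entirely inside a small decreased set: strong association
  sets <- list(dec = sprintf("a%02d", 1:12),
               unrelated = sprintf("a%02d", 29:40))
  m <- associateWithSignal(calls, sets)
  expect_gt(m["Shift1", "dec"], 2)
  expect_equal(m["Shift2", "unrelated"], 0)   # zero overlap -> P = 1
  expect_true(all(m >= 0))
  expect_error(associateWithSignal(calls, list(bad = "zzz")), "universe")
  # empty group row gives P = 1 everywhere
  m2 <- associateWithSignal(calls, sets, labels = c("Shift1", "absent"))
  expect_equal(unname(m2["absent", ]), c(0, 0))
})

test_that("null association calls are calibrated", {
  set.seed(53)
  N <- 2000; K <- 500; n <- 200
  k <- rhyper(2000, K, N - K, n)
  p <- vapply(k, hypergeomTest, 1, K = K, n = n, N = N)
  frac <- mean(-log10(p) > -log10(0.05))
  attained <- sum(dhyper(0:min(K, n), K, N - K, n) *
                  (phyper(0:min(K, n) - 1, K, N - K, n,
                          lower.tail = FALSE) < 0.05))
  expect_lt(abs(frac - attained), 0.02)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.07)
})

test_that("every shift label implies narrower spacing on called anchors", {
  coh <- simulateShiftCohort(n_per_group = 15, seed = 23, occupancy = 600)
  res <- suppressMessages(runPipeline(
    coh$fragments$control, coh$fragments$depleted, coh$anchors,
    pipelineConfig(seed = 24, bootstrap_B = 100L)))
  sh <- as.data.frame(res$shifts)
  shifted <- sh$label != "non-shift"
  expect_true(all(sh$spacing_dep[shifted] < sh$spacing_ctrl[shifted]))
  expect_true(all(sh$spacing_ctrl > 0 & sh$spacing_dep > 0))
})

test_that("labels are exchangeable under condition swap on null data", {
  coh <- simulateShiftCohort(n_per_group = 60, seed = 25,
                             groups = list("non-shift" = c(0, 0)))
  cfg <- pipelineConfig(seed = 26, bootstrap_B = 100L)
  fwd <- suppressMessages(runPipeline(coh$fragments$control,
    coh$fragments$depleted, coh$anchors, cfg))
  rev <- suppressMessages(runPipeline(coh$fragments$depleted,
    coh$fragments$control, coh$anchors, cfg))
  hits <- function(x) sum(x$shifts$sig_minus1) + sum(x$shifts$sig_plus1)
  n <- function(x) 2L * nrow(x$shifts)
  # both directions see the same nominal one-tailed call rate
  p <- prop.test(c(hits(fwd), hits(rev)), c(n(fwd), n(rev)))$p.value
  expect_gt(p, 0.01)
})
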