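test_that("CPM normalization conserves totals and scale-invariance", {
  expect_equal(libsizeNormalize(200, 2e6), 100)
  counts <- c(3, 7, 90)
  expect_equal(sum(libsizeNormalize(counts, sum(counts))), 1e6)
  expect_equal(libsizeNormalize(counts * 4, sum(counts) * 4),
               libsizeNormalize(counts, sum(counts)))
  m <- cbind(a = c(10, 90), b = c(20, 180))
  norm <- libsizeNormalize(m, colSums(m))
  expect_equal(unname(colSums(norm)), c(1e6, 1e6))
  expect_equal(norm[, "a"], norm[, "b"])
  expect_error(libsizeNormalize(counts, 0))
})

test_that("spike-in factors implement the two-component formula", {
  st <- libraryStats(c("wt1", "wt2", "aid1"), c("WT", "WT", "AID"),
                     mouse_reads = c(1e6, 2e6, 3e6),
                     spike_reads = c(1e5, 1e5, 2e5),
                     is_reference = c(TRUE, FALSE, FALSE))
  f <- spikeinFactors(st)
  expect_equal(unname(f), mean(c(1e6, 2e6, 3e6)) * c(1, 1, 2))
  # identical libraries get identical factors
  st2 <- libraryStats(c("x", "y"), c("WT", "AID"), c(1e6, 1e6),
                      c(1e5, 1e5), is_reference = c(TRUE, FALSE))
  expect_equal(unname(diff(spikeinFactors(st2))), 0)
  # doubling spike reads (signal unchanged) halves the normalized density
  st3 <- st2
  st3$spike_reads[2] <- 2e5
  d2 <- 100 / spikeinFactors(st2)[2] * 1e6
  d3 <- 100 / spikeinFactors(st3)[2] * 1e6
  expect_equal(unname(d3 / d2), 0.5)
  # permutation of non-reference libraries permutes the factors
  st4 <- st[c(1, 3, 2), ]
  expect_equal(spikeinFactors(st4)[names(f)], f)
  expect_error(spikeinFactors(transform(st, is_reference = FALSE)),
               "reference")
  expect_error(spikeinFactors(transform(st, spike_reads = 0)))
})

test_that("conserved-gene selection applies the CPM floor and peak veto", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1e4, 5e4, 9e4, 13e4), width = 5000),
    strand = c("+", "+", "+", "+"))
  counts <- rbind(g_low = c(499, 499), g_ok = c(501, 501),
                  g_peak = c(900, 900), g_mixed = c(501, 499))
  sizes <- c(1e6, 1e6)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9.2e4, width = 100))
  sel <- conservedGeneFactors(counts, sizes, genes, peaks)
  # 501 CPM passes, 499 does not; the peak-overlapping gene is vetoed;
  # the floor applies in every library
  expect_identical(sel$genes, "g_ok")
  expect_equal(unname(sel$factors), c(1, 1))
  # a library with twice the depth gets roughly factor 2
  counts2 <- cbind(counts, counts[, 1] * 2, counts[, 1], counts[, 1])
  sizes2 <- c(sizes, 2e6, 1e6, 1e6)
  sel2 <- conservedGeneFactors(counts2, sizes2, genes, peaks)
  expect_equal(unname(sel2$factors[3]), 2 / 1.2)
  expect_error(conservedGeneFactors(counts, sizes, genes, peaks,
                                    cpm_threshold = 1e6), "no gene")
})

test_that("BRG1 veto extends 2 kb upstream of the gene body", {
  gene_plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e4, 1.5e4),
                                      strand = "+")
  gene_minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e4, 1.5e4),
                                       strand = "-")
  peak_up_plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 9100))
  counts <- rbind(g = c(1000, 1000))
  # upstream of a "+" gene = lower coordinates: vetoed
  expect_error(conservedGeneFactors(counts, c(1e6, 1e6), gene_plus,
                                    peak_up_plus), "no gene")
  # same peak is downstream of a "-" gene: kept
  sel <- conservedGeneFactors(counts, c(1e6, 1e6), gene_minus, peak_up_plus)
  expect_identical(sel$genes, "g")
})

test_that("background correction subtracts genome-scaled noise", {
  expect_equal(backgroundCorrect(100, 1000, 1e6, 1e9 + 1000), 0.1 - 0.001)
  expect_equal(backgroundCorrect(100, 1000, 0, 1e9), 0.1)    # zero background
  # in-peak density equal to background density corrects to zero
  expect_equal(backgroundCorrect(10, 1000, 10 * (1e6 - 1000) / 1000, 1e6), 0)
  expect_equal(backgroundCorrect(1, 1000, 1e9, 1e9), 0)      # floors at 0
  expect_error(backgroundCorrect(10, 0, 0, 1e6))
  expect_error(backgroundCorrect(10, 1000, 0, 500))
})

test_that("region scaffold follows the distance-to-TSS conventions", {
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e4, width = 1),
                                strand = "+")
  tts <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8e4, width = 1),
                                strand = "+")
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(5e4 + c(1900, 3000, 6000), width = 1))
  reg <- makeRegions(tss, tts, peaks)
  expect_equal(GenomicRanges::width(reg$fivePrime), 2001)
  expect_equal(GenomicRanges::start(reg$fivePrime), 5e4 - 1000)
  expect_equal(GenomicRanges::start(reg$threePrime), 8e4 - 1000)
  expect_identical(as.character(reg$peak_class),
                   c("TSS", "excluded", "nonTSS"))
  nostrand <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e4, width = 1))
  expect_error(makeRegions(nostrand), "strand")
})

test_that("differential summary applies the joint cutoff and partitions", {
  set.seed(61)
  res <- data.frame(
    p_value = c(rep(0.001, 50), rep(0.5, 50)),
    fold_change = c(rep(0.5, 40), rep(2, 10), runif(50, 0.9, 1.1)))
  s <- differentialSummary(res)
  expect_identical(s$n_changed, 50L)
  expect_identical(s$n_changed, s$n_down + s$n_up)
  expect_equal(s$pct_down_of_changed, 80)
  expect_equal(s$pct_changed, 50)
  # boundary: fold-change must exceed the cutoff strictly
  b <- differentialSummary(data.frame(p_value = 0.01, fold_change = 1.3))
  expect_identical(b$n_changed, 0L)
  expect_true(is.nan(b$pct_down_of_changed))
  alldown <- differentialSummary(data.frame(p_value = rep(0.01, 3),
                                            fold_change = rep(0.1, 3)))
  expect_equal(alldown$pct_down_of_changed, 100)
  expect_error(differentialSummary(data.frame(p_value = 0.1,
                                              fold_change = 0)))
})

test_that("tertiles are equal-count with stable ties", {
  expect_identical(as.character(tertileGroups(1:9)),
                   rep(c("low", "medium", "high"), each = 3))
  t2 <- tertileGroups(rep(5, 7))
  expect_lte(diff(range(table(t2))), 1)
  expect_identical(as.character(t2[1]), "low")  # stable input order
  for (n in 3:30) {
    sizes <- table(tertileGroups(rnorm(n)))
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(tertileGroups(1:2))
})
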