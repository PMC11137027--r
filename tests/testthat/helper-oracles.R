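# Independent reference implementations used to cross-check the compiled
# code paths. Deliberately simple and slow.

# Brute-force Gaussian center-weighted convolution (double loop).
convOracle <- function(S, w) {
  h <- (length(w) - 1L) %/% 2L
  n <- length(S)
  out <- numeric(n)
  for (k in seq_len(n)) {
    for (j in -h:h) {
      i <- k + j
      if (i >= 1L && i <= n) out[k] <- out[k] + S[i] * w[j + h + 1L]
    }
  }
  out
}

# Peak finding from the prominence definition, written directly: interior
# local maxima (plateaus report their center, even plateaus break toward
# the anchor index); prominence = height minus the higher of the minimal
# valleys to the nearest strictly higher point on each side, window edges
# acting as boundaries.
promOracle <- function(y, min_prom, anchor_idx = 1L) {
  n <- length(y)
  out <- data.frame(index = integer(), height = numeric(),
                    prominence = numeric())
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j + 1L <= n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        v <- y[i]
        cand <- as.integer(c(floor((i + j) / 2), ceiling((i + j) / 2)))
        centre <- cand[which.min(abs(cand - anchor_idx))]
        left <- y[seq_len(i - 1L)]
        hi <- which(left > v)
        lmin <- min(if (length(hi)) left[(max(hi) + 1L):(i - 1L)] else left)
        right <- y[(j + 1L):n]
        hi <- which(right > v)
        rmin <- min(if (length(hi)) right[seq_len(min(hi) - 1L)] else right)
        prom <- v - max(lmin, rmin)
        if (prom >= min_prom)
          out <- rbind(out, data.frame(index = centre, height = v,
                                       prominence = prom))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Exhaustive hypergeometric tail by literal enumeration of every n-subset
# of a universe of size N whose first K elements are marked.
hyperEnumOracle <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k == 0L))
  subsets <- utils::combn(N, n)
  marked <- colSums(subsets <= K)
  mean(marked >= k)
}

# Random fragment GRanges on one chromosome.
randomFragments <- function(n, chrom = "chr1", max_pos = 1e5,
                            len_range = c(100L, 220L)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = len))
}
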