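#' Keep canonical nucleosome-sized fragments
#'
#' Retains fragments whose length lies in \code{[min_len, max_len]} bp,
#' bounds inclusive (default 140-180 bp, the canonical mononucleosome
#' window). Order is preserved.
#'
#' @param fragments A [GenomicRanges::GRanges] of fragment intervals.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The filtered GRanges.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(1, width = c(139, 140, 160, 180, 181)))
#' GenomicRanges::width(filterCanonicalFragments(gr))
#' @export
filterCanonicalFragments <- function(fragments, min_len = 140L,
                                     max_len = 180L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  w <- GenomicRanges::width(fragments)
  fragments[w >= min_len & w <= max_len]
}

#' Fragment dyad midpoints
#'
#' The dyad of a fragment \code{[start, end)} (0-based half-open) is
#' \code{floor((start + end - 1) / 2)}; even-length fragments round down.
#' Returned as 1-bp ranges so midpoints stay genomic and strand-free.
#'
#' @param fragments A [GenomicRanges::GRanges] of fragment intervals.
#' @return A GRanges of 1-bp midpoint positions, parallel to the input.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 260)) # [100,260)
#' GenomicRanges::start(fragmentMidpoints(fr)) - 1L                 # 179
#' @export
fragmentMidpoints <- function(fragments) {
  mid <- (GenomicRanges::start(fragments) + GenomicRanges::end(fragments)) %/% 2L
  GenomicRanges::GRanges(GenomicRanges::seqnames(fragments),
                         IRanges::IRanges(mid, width = 1L))
}

#' Tally midpoints per base
#'
#' @param fragments A GRanges of fragments (midpoints are taken internally).
#' @return A named list per chromosome of integer count [S4Vectors::Rle]
#'   coverage vectors; counts sum to the number of fragments.
#' @export
midpointCounts <- function(fragments) {
  GenomicRanges::coverage(fragmentMidpoints(fragments))
}

#' Nucleosome center-positioning (NCP) score
#'
#' \eqn{S_k = \mathrm{count}_k / \mathrm{factor} \times 10^6}: midpoint
#' counts normalized by a library factor on a counts-per-million scale.
#' Linear in the counts; with \code{library_factor} equal to the total
#' fragment count the scores sum to \eqn{10^6}.
#'
#' @param counts Numeric vector of per-base midpoint counts.
#' @param library_factor Positive normalization divisor (library size by
#'   default upstream).
#' @return Numeric vector of \eqn{S_k}.
#' @export
ncpScore <- function(counts, library_factor) {
  if (length(library_factor) != 1L || !is.finite(library_factor) ||
      library_factor <= 0)
    stop("library_factor must be a single positive number")
  as.numeric(counts) / library_factor * 1e6
}

#' Gaussian center-weighted occupancy score
#'
#' \deqn{O_k = \sum_{j=-h}^{h} S_{k+j} w_j,\qquad w_j = e^{-(j/\sigma)^2/2}}
#' with out-of-range scores treated as zero. A linear operator; the default
#' kernel uses \eqn{\sigma = 20} bp over \eqn{j \in [-73, 73]}.
#'
#' @param S Numeric vector of per-base NCP scores.
#' @param kernel A [GaussianKernel-class] (default [gaussianKernel()]).
#' @return Numeric vector of smoothed scores, same length as \code{S}.
#' @examples
#' S <- c(rep(0, 100), 1, rep(0, 100))       # unit impulse
#' out <- centerWeightedOccupancy(S)
#' all.equal(out[101 + 20], exp(-1/2))
#' @export
centerWeightedOccupancy <- function(S, kernel = gaussianKernel()) {
  stopifnot(is(kernel, "GaussianKernel"))
  cpp_smooth(as.numeric(S), kernel@weights)
}

## Strand-oriented midpoint offsets of fragments relative to each anchor
## window; returns a list (one integer vector per anchor). Windows clipped at
## the chromosome start are handled by the caller.
.anchorOffsets <- function(fragments, anchors, window_halfwidth) {
  mids <- fragmentMidpoints(fragments)
  win <- suppressWarnings(GenomicRanges::resize(
    anchors, width = 2L * window_halfwidth + 1L, fix = "center"))
  win <- GenomicRanges::trim(win)
  hits <- GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE)
  qa <- S4Vectors::queryHits(hits)
  sa <- S4Vectors::subjectHits(hits)
  rel <- GenomicRanges::start(mids)[qa] - GenomicRanges::start(anchors)[sa]
  neg <- as.character(GenomicRanges::strand(anchors))[sa] == "-"
  rel[neg] <- -rel[neg]
  unname(split(rel, factor(sa, levels = seq_along(anchors))))
}

#' Build anchored occupancy profiles
#'
#' Extracts strand-oriented windows around each anchor, tallies canonical
#' fragment midpoints per offset, normalizes to NCP scores and applies the
#' Gaussian center-weighted smoothing. Negative offsets are always upstream
#' (5' of the anchor); strandless anchors are treated as \code{"+"}.
#' Offsets falling outside the chromosome are set to \code{NA}.
#'
#' @param fragments GRanges of fragments (already length-filtered, or pass
#'   through [filterCanonicalFragments()] first via \code{filter = TRUE}).
#' @param anchors GRanges of 1-bp anchor points with an \code{anchor_id}
#'   metadata column (added if absent).
#' @param window_halfwidth Profile half-extent in bp.
#' @param kernel [GaussianKernel-class] used for smoothing.
#' @param library_factor Normalization divisor for the NCP scores; defaults
#'   to the total number of (filtered) fragments.
#' @param filter Apply the canonical 140-180 bp filter first?
#' @param condition Condition label stored with the profiles.
#' @return An [OccupancyProfileSet-class].
#' @export
occupancyProfiles <- function(fragments, anchors, window_halfwidth = 500L,
                              kernel = gaussianKernel(),
                              library_factor = NULL, filter = TRUE,
                              condition = "control") {
  if (length(anchors) == 0L) stop("'anchors' is empty")
  if (filter) fragments <- filterCanonicalFragments(fragments)
  if (is.null(library_factor)) library_factor <- max(length(fragments), 1L)
  if (is.null(anchors$anchor_id))
    anchors$anchor_id <- paste0("anchor_", seq_along(anchors))
  W <- as.integer(window_halfwidth)
  offs <- .anchorOffsets(fragments, anchors, W)
  raw <- t(vapply(offs, function(o) as.numeric(cpp_hist_offsets(o, W)),
                  numeric(2L * W + 1L)))
  raw <- raw / library_factor * 1e6
  smoothed <- cpp_smooth_rows(raw, kernel@weights)
  ## NA out offsets beyond the chromosome start (no sequence there)
  left_room <- GenomicRanges::start(anchors) - 1L
  clipped <- which(left_room < W)
  for (i in clipped) {
    bad <- seq_len(W - left_room[i])
    ## for "-" anchors the clipped genomic left edge is the downstream end
    cols <- if (as.character(GenomicRanges::strand(anchors))[i] == "-")
      (2L * W + 2L) - bad else bad
    raw[i, cols] <- NA_real_
    smoothed[i, cols] <- NA_real_
  }
  if (length(clipped))
    warning(length(clipped), " anchor window(s) clipped at chromosome start")
  new("OccupancyProfileSet", anchors = anchors,
      offsets = seq.int(-W, W), raw = raw, smoothed = smoothed,
      libraryFactor = as.numeric(library_factor), kernel = kernel,
      condition = condition)
}

#' Aggregate profiles across anchors
#'
#' Per-offset arithmetic mean over anchors; offsets missing for an anchor
#' (clipped at a chromosome edge) are excluded from the mean, with the
#' contributing anchor count reported per offset.
#'
#' @param profiles An [OccupancyProfileSet-class].
#' @param which \code{"smoothed"} (default) or \code{"raw"}.
#' @return data.frame with columns \code{offset}, \code{mean}, \code{n}.
#' @export
aggregateProfile <- function(profiles, which = c("smoothed", "raw")) {
  stopifnot(is(profiles, "OccupancyProfileSet"))
  if (nrow(profiles@raw) == 0L) stop("no profiles to aggregate")
  which <- match.arg(which)
  m <- if (which == "smoothed") profiles@smoothed else profiles@raw
  data.frame(offset = profiles@offsets,
             mean = colMeans(m, na.rm = TRUE),
             n = as.integer(colSums(!is.na(m))))
}
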