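#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges granges strand start end width seqnames
#' @importFrom IRanges IRanges
NULL

#' Gaussian center-weighting kernel
#'
#' Discrete Gaussian weights \eqn{w_j = e^{-(j/\sigma)^2/2}} for
#' \eqn{j \in [-h, h]}, used to turn per-base nucleosome center-positioning
#' (NCP) scores into a center-weighted occupancy score. The defaults
#' (\eqn{\sigma = 20} bp, halfwidth 73 bp) weight dyads across one
#' nucleosome-sized footprint, with \eqn{w_0 = 1} at the dyad and
#' \eqn{w_{\pm 20} = e^{-1/2}}.
#'
#' @slot sigma Gaussian width in bp.
#' @slot halfwidth Kernel half-extent in bp; weights cover
#'   \code{-halfwidth:halfwidth}.
#' @slot weights Numeric vector of length \code{2*halfwidth + 1}.
#'
#' @seealso [gaussianKernel()], [centerWeightedOccupancy()]
#' @export
setClass("GaussianKernel",
  representation(sigma = "numeric", halfwidth = "integer", weights = "numeric"))

setValidity("GaussianKernel", function(object) {
  msg <- character()
  if (length(object@sigma) != 1L || object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive number")
  if (length(object@halfwidth) != 1L || object@halfwidth < 0L)
    msg <- c(msg, "'halfwidth' must be a single non-negative integer")
  if (length(object@weights) != 2L * object@halfwidth + 1L)
    msg <- c(msg, "'weights' length must equal 2*halfwidth + 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Gaussian center-weighting kernel
#'
#' @param sigma Gaussian width in bp (default 20).
#' @param halfwidth Half-extent of the kernel in bp (default 73).
#' @return A [GaussianKernel-class] object.
#' @examples
#' k <- gaussianKernel()
#' kernelWeights(k)[k@halfwidth + 1]          # w_0 == 1
#' kernelWeights(k)[k@halfwidth + 1 + 20]     # w_20 == exp(-1/2)
#' @export
gaussianKernel <- function(sigma = 20, halfwidth = 73L) {
  halfwidth <- as.integer(halfwidth)
  j <- seq.int(-halfwidth, halfwidth)
  new("GaussianKernel", sigma = as.numeric(sigma), halfwidth = halfwidth,
      weights = exp(-(j / sigma)^2 / 2))
}

#' @describeIn gaussianKernel Kernel weight vector, indexed
#'   \code{-halfwidth:halfwidth}.
#' @param kernel A [GaussianKernel-class].
#' @export
kernelWeights <- function(kernel) {
  stopifnot(is(kernel, "GaussianKernel"))
  kernel@weights
}

setMethod("show", "GaussianKernel", function(object) {
  cat("GaussianKernel: sigma =", object@sigma, "bp, halfwidth =",
      object@halfwidth, "bp (", length(object@weights), "weights )\n")
})

#' Anchored occupancy profiles
#'
#' Per-anchor, strand-oriented nucleosome occupancy profiles at single-base
#' resolution. Rows of the score matrices are anchors, columns are signed
#' offsets relative to the anchor (negative = upstream after strand
#' orientation). \code{raw} holds the normalized NCP score \eqn{S_k};
#' \code{smoothed} holds the Gaussian center-weighted score. Offsets clipped
#' at chromosome ends are \code{NA} and are excluded (with count tracking)
#' when profiles are aggregated.
#'
#' @slot anchors A [GenomicRanges::GRanges] of the anchor points (metadata
#'   columns \code{anchor_id}, \code{kind}).
#' @slot offsets Integer vector of signed offsets (the shared column axis).
#' @slot raw,smoothed Numeric matrices, anchors x offsets.
#' @slot libraryFactor The normalization divisor used for the NCP scores.
#' @slot kernel The [GaussianKernel-class] used for smoothing.
#' @slot condition Condition label for the fragment library.
#'
#' @seealso [occupancyProfiles()], [aggregateProfile()]
#' @export
setClass("OccupancyProfileSet",
  representation(anchors = "GRanges", offsets = "integer", raw = "matrix",
                 smoothed = "matrix", libraryFactor = "numeric",
                 kernel = "GaussianKernel", condition = "character"))

setValidity("OccupancyProfileSet", function(object) {
  msg <- character()
  n <- length(object@anchors)
  m <- length(object@offsets)
  if (!identical(dim(object@raw), c(n, m)))
    msg <- c(msg, "'raw' must be anchors x offsets")
  if (!identical(dim(object@smoothed), c(n, m)))
    msg <- c(msg, "'smoothed' must be anchors x offsets")
  if (any(object@raw < 0, na.rm = TRUE))
    msg <- c(msg, "raw NCP scores must be non-negative")
  if (is.unsorted(object@offsets, strictly = TRUE))
    msg <- c(msg, "'offsets' must be strictly increasing")
  if (length(object@libraryFactor) != 1L || object@libraryFactor <= 0)
    msg <- c(msg, "'libraryFactor' must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OccupancyProfileSet", function(object) {
  cat("OccupancyProfileSet:", nrow(object@raw), "anchors x",
      length(object@offsets), "offsets [", min(object@offsets), "..",
      max(object@offsets), "] bp\n")
  cat("  condition:", object@condition,
      "| library factor:", format(object@libraryFactor), "\n")
  cat("  kernel: sigma", object@kernel@sigma, "bp, halfwidth",
      object@kernel@halfwidth, "bp\n")
})

#' @describeIn OccupancyProfileSet Signed offset axis.
#' @param x An \code{OccupancyProfileSet}.
#' @export
profileOffsets <- function(x) {
  stopifnot(is(x, "OccupancyProfileSet"))
  x@offsets
}

#' @describeIn OccupancyProfileSet Raw NCP score matrix (anchors x offsets).
#' @export
rawScores <- function(x) {
  stopifnot(is(x, "OccupancyProfileSet"))
  x@raw
}

#' @describeIn OccupancyProfileSet Center-weighted score matrix.
#' @export
smoothedScores <- function(x) {
  stopifnot(is(x, "OccupancyProfileSet"))
  x@smoothed
}

#' @describeIn OccupancyProfileSet Anchor points as a GRanges.
#' @export
profileAnchors <- function(x) {
  stopifnot(is(x, "OccupancyProfileSet"))
  x@anchors
}
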