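#' Find peaks by topographic prominence
#'
#' Interior local maxima of a profile whose topographic prominence meets
#' \code{min_prominence}. The prominence of a peak is its height minus the
#' higher of the two minimal valleys separating it from the nearest strictly
#' higher point on each side; the window edge acts as a boundary when no
#' higher point exists. Plateau maxima report their center offset, with even
#' plateaus breaking toward \code{anchor_offset}. A flat or monotone profile
#' yields no peaks.
#'
#' When calling nucleosomes the profile should first be rescaled to maximum
#' 1 within the search window so the prominence threshold is
#' depth-independent; [callNucleosomes()] does this internally.
#'
#' @param y Numeric profile values.
#' @param min_prominence Minimum prominence (default 0.1, on a max-1 scale).
#' @param offsets Offset labels for \code{y} (default
#'   \code{seq_along(y) - 1}).
#' @param anchor_offset Offset of the anchor, used only to break plateau
#'   ties (default 0).
#' @return data.frame with columns \code{offset}, \code{height},
#'   \code{prominence}; zero rows when there is no qualifying peak.
#' @examples
#' y <- c(0, 0.5, 1, 0.5, 0)       # one triangular bump
#' findPeaksProminence(y, 0.1)
#' @export
findPeaksProminence <- function(y, min_prominence = 0.1,
                                offsets = seq_along(y) - 1L,
                                anchor_offset = 0L) {
  stopifnot(length(offsets) == length(y))
  ai <- match(anchor_offset, offsets)
  if (is.na(ai)) ai <- 1L
  pk <- cpp_find_peaks(as.numeric(y), min_prominence, ai - 1L)
  data.frame(offset = offsets[pk$index + 1L], height = pk$height,
             prominence = pk$prominence)
}

#' Select the -1/+1 nucleosomes flanking an anchor
#'
#' Among called peaks, the highest with offset in \code{[-search, 0)}
#' becomes the \eqn{-1} nucleosome and the highest in \code{(0, +search]}
#' the \eqn{+1}; a peak exactly at offset 0 is assigned to neither. Ties in
#' height break toward the anchor. An anchor lacking a qualifying peak on
#' either side is uncallable.
#'
#' @param peaks data.frame as returned by [findPeaksProminence()] on an
#'   anchor-oriented profile (offset 0 = anchor).
#' @param search_halfwidth Search half-extent in bp (default 150).
#' @return A list \code{(minus1, plus1, callable)} where \code{minus1} /
#'   \code{plus1} are one-row data.frames (or \code{NULL}) and
#'   \code{callable} is logical.
#' @export
selectFlankingNucleosomes <- function(peaks, search_halfwidth = 150L) {
  pick <- function(side) {
    cand <- if (side < 0)
      peaks[peaks$offset < 0 & peaks$offset >= -search_halfwidth, ]
    else
      peaks[peaks$offset > 0 & peaks$offset <= search_halfwidth, ]
    if (nrow(cand) == 0L) return(NULL)
    best <- cand[cand$height == max(cand$height), ]
    best[which.min(abs(best$offset)), ]
  }
  m1 <- pick(-1L)
  p1 <- pick(+1L)
  list(minus1 = m1, plus1 = p1, callable = !is.null(m1) && !is.null(p1))
}

#' Bootstrap standard errors of called -1/+1 positions
#'
#' Resamples an anchor's fragments with replacement \code{B} times, rerunning
#' the canonical length filter, midpoint tally, smoothing and peak calling
#' inside the loop, and reports the standard deviation of the called offsets
#' over the successful resamples. Resamples where the anchor is uncallable
#' are dropped and counted; anchors uncallable in more than half the
#' resamples are flagged low-confidence.
#'
#' @param midpoint_offsets Integer strand-oriented midpoint offsets of the
#'   anchor's fragments (pre-filter).
#' @param lengths Integer fragment lengths, parallel to
#'   \code{midpoint_offsets}.
#' @param kernel [GaussianKernel-class].
#' @param B Number of bootstrap resamples (>= 50).
#' @param seed Optional seed (set once before the loop).
#' @param search_halfwidth,min_prominence,min_len,max_len Calling
#'   parameters, as in [callNucleosomes()].
#' @param refine Sub-bp parabolic apex refinement (default TRUE).
#' @return list with \code{se_minus1}, \code{se_plus1}, \code{n_ok},
#'   \code{B}, \code{low_confidence}.
#' @export
bootstrapPositionSE <- function(midpoint_offsets, lengths,
                                kernel = gaussianKernel(), B = 200L,
                                seed = NULL, search_halfwidth = 150L,
                                min_prominence = 0.1, min_len = 140L,
                                max_len = 180L, refine = TRUE) {
  if (B < 50L) stop("B must be at least 50")
  stopifnot(length(midpoint_offsets) == length(lengths))
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_bootstrap_se(as.integer(midpoint_offsets), as.integer(lengths),
                          as.integer(min_len), as.integer(max_len),
                          kernel@weights, as.integer(search_halfwidth),
                          min_prominence, as.integer(B), refine)
  out$low_confidence <- out$n_ok < out$B / 2
  out
}

#' Call -1/+1 nucleosomes around anchors
#'
#' The full anchored calling pipeline for one condition: canonical fragment
#' filter, strand-oriented midpoint tally, Gaussian center-weighted
#' smoothing, per-anchor rescaling to maximum 1 within the +/-150 bp search
#' window, prominence peak calling, flanking-pair selection, and fragment
#' bootstrap for positional standard errors. Peak apexes are refined to
#' sub-bp resolution by 3-point parabolic interpolation unless
#' \code{refine = FALSE}.
#'
#' @param fragments GRanges of MNase fragments (unfiltered; the 140-180 bp
#'   filter runs internally and inside the bootstrap).
#' @param anchors GRanges of 1-bp anchors with \code{anchor_id} metadata
#'   (added if absent). Strandless anchors are treated as \code{"+"}.
#' @param condition Condition label attached to the calls.
#' @param kernel [GaussianKernel-class].
#' @param search_halfwidth Half-extent of the -1/+1 search window (150 bp).
#' @param min_prominence Prominence threshold on the max-1 rescaled profile
#'   (0.1).
#' @param min_len,max_len Canonical fragment length bounds (140, 180).
#' @param B Bootstrap resamples for positional SEs; 0 skips the bootstrap
#'   (SEs are \code{NA}).
#' @param seed Seed for the bootstrap resampling.
#' @param refine Sub-bp apex refinement (default TRUE).
#' @return A [S4Vectors::DataFrame] with one row per anchor: offsets,
#'   heights and prominences of the \eqn{-1}/\eqn{+1} peaks, bootstrap SEs,
#'   fragment count and a \code{status} of \code{"ok"}, \code{"uncallable"}
#'   or \code{"low_confidence"}.
#' @export
callNucleosomes <- function(fragments, anchors, condition = "control",
                            kernel = gaussianKernel(),
                            search_halfwidth = 150L, min_prominence = 0.1,
                            min_len = 140L, max_len = 180L, B = 200L,
                            seed = NULL, refine = TRUE) {
  if (length(anchors) == 0L) stop("'anchors' is empty")
  if (is.null(anchors$anchor_id))
    anchors$anchor_id <- paste0("anchor_", seq_along(anchors))
  if (!is.null(seed)) set.seed(seed)
  W <- as.integer(search_halfwidth) + kernel@halfwidth
  offs_all <- .anchorOffsets(fragments, anchors, W)
  lens_all <- {
    mids <- fragmentMidpoints(fragments)
    win <- suppressWarnings(GenomicRanges::resize(
      anchors, width = 2L * W + 1L, fix = "center"))
    win <- GenomicRanges::trim(win)
    hits <- GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE)
    unname(split(GenomicRanges::width(fragments)[S4Vectors::queryHits(hits)],
                 factor(S4Vectors::subjectHits(hits),
                        levels = seq_along(anchors))))
  }
  n <- length(anchors)
  res <- matrix(NA_real_, n, 9L)
  status <- character(n)
  for (i in seq_len(n)) {
    o <- offs_all[[i]]
    l <- lens_all[[i]]
    ok <- l >= min_len & l <= max_len
    res[i, 9L] <- sum(ok)
    call <- cpp_call_from_midpoints(o[ok], kernel@weights,
                                    as.integer(search_halfwidth),
                                    min_prominence, refine)
    if (anyNA(call[c(1L, 4L)])) {
      status[i] <- "uncallable"
      next
    }
    res[i, 1:6] <- call
    status[i] <- "ok"
    if (B > 0L) {
      bs <- cpp_bootstrap_se(o, l, as.integer(min_len), as.integer(max_len),
                             kernel@weights, as.integer(search_halfwidth),
                             min_prominence, as.integer(B), refine)
      res[i, 7L] <- bs$se_minus1
      res[i, 8L] <- bs$se_plus1
      if (bs$n_ok < B / 2) status[i] <- "low_confidence"
    }
  }
  n_bad <- sum(status != "ok")
  if (n_bad)
    message(n_bad, "/", n, " anchors uncallable or low-confidence (",
            condition, ")")
  S4Vectors::DataFrame(
    anchor_id = anchors$anchor_id, condition = condition,
    minus1_offset = res[, 1L], minus1_height = res[, 2L],
    minus1_prominence = res[, 3L],
    plus1_offset = res[, 4L], plus1_height = res[, 5L],
    plus1_prominence = res[, 6L],
    se_minus1 = res[, 7L], se_plus1 = res[, 8L],
    n_fragments = as.integer(res[, 9L]), status = status)
}
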