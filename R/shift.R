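#' One-tailed z test for a nucleosome position shift
#'
#' Tests whether a nucleosome moved toward the anchor between conditions:
#' \deqn{z = (x_{dep} - x_{ctrl}) / \sqrt{se_{ctrl}^2 + se_{dep}^2}}
#' with significance declared only in the toward-anchor direction (negative
#' displacement for the \eqn{+1} nucleosome, positive for the \eqn{-1}) at
#' the one-sided critical value \eqn{z^* = \Phi^{-1}(\mathrm{confidence})}
#' (1.2816 at the default 90\% confidence level).
#'
#' Degenerate cases: both SEs zero with equal positions gives \eqn{z = 0}
#' (not significant); both zero with different positions gives
#' \eqn{z = \pm\infty} and is significant when the movement is in the
#' expected direction.
#'
#' @param pos_ctrl,pos_dep Called offsets (bp) in control and depleted.
#' @param se_ctrl,se_dep Positional standard errors (bp, >= 0).
#' @param side \code{"minus1"} or \code{"plus1"}: which flanking nucleosome
#'   is tested (fixes the toward-anchor direction).
#' @param confidence One-sided confidence level (default 0.90).
#' @return list with \code{z} (signed, depleted minus control over combined
#'   SE) and logical \code{significant}.
#' @examples
#' zShiftTest(70, 34, se_ctrl = 8, se_dep = 6, side = "plus1")
#' @export
zShiftTest <- function(pos_ctrl, pos_dep, se_ctrl, se_dep,
                       side = c("plus1", "minus1"), confidence = 0.90) {
  side <- match.arg(side)
  if (any(c(se_ctrl, se_dep) < 0)) stop("standard errors must be >= 0")
  delta <- pos_dep - pos_ctrl
  pooled <- sqrt(se_ctrl^2 + se_dep^2)
  z <- if (pooled > 0) delta / pooled
       else if (delta == 0) 0
       else sign(delta) * Inf
  zstar <- stats::qnorm(confidence)
  significant <- if (side == "plus1") -z > zstar else z > zstar
  list(z = z, significant = isTRUE(significant))
}

#' Classify an anchor's shift pattern
#'
#' \code{Shift1}: only the \eqn{+1} nucleosome moved significantly toward
#' the anchor; \code{Shift2}: only the \eqn{-1}; \code{Shift3}: both;
#' \code{non-shift}: neither. Because only toward-anchor movement is tested
#' (one-tailed), every shift label implies narrower \eqn{-1}/\eqn{+1}
#' spacing in the depleted condition.
#'
#' @param sig_minus1,sig_plus1 Logical significance flags from
#'   [zShiftTest()].
#' @return One of \code{"non-shift"}, \code{"Shift1"}, \code{"Shift2"},
#'   \code{"Shift3"}.
#' @export
classifyShift <- function(sig_minus1, sig_plus1) {
  if (sig_minus1 && sig_plus1) "Shift3"
  else if (sig_plus1) "Shift1"
  else if (sig_minus1) "Shift2"
  else "non-shift"
}

#' -1/+1 nucleosome spacing
#'
#' @param minus1_offset,plus1_offset Called offsets in bp
#'   (\code{minus1_offset < 0 < plus1_offset}).
#' @return Spacing in bp: \code{plus1_offset - minus1_offset}.
#' @examples
#' nucSpacing(-88, 56)   # 144
#' nucSpacing(-93, 70)   # 163
#' @export
nucSpacing <- function(minus1_offset, plus1_offset) {
  plus1_offset - minus1_offset
}

#' Per-anchor shift tests and classification between two conditions
#'
#' Joins the nucleosome calls of a control and a depleted condition on
#' anchor, runs the one-tailed z test for each flanking nucleosome, and
#' labels every anchor callable in both conditions. Anchors uncallable (or
#' low-confidence) in either condition are excluded.
#'
#' @param calls_ctrl,calls_dep [callNucleosomes()] outputs for the two
#'   conditions.
#' @param confidence One-sided confidence level (default 0.90).
#' @param correction Multiple-testing correction across anchors applied to
#'   each nucleosome's one-sided p-values: \code{"none"} (default, a fixed
#'   per-test confidence level) or \code{"bh"} (Benjamini-Hochberg at
#'   \code{1 - confidence}).
#' @return A [S4Vectors::DataFrame], one row per jointly callable anchor:
#'   positions per condition, deltas, z values, significance flags,
#'   \code{label} and spacings.
#' @export
shiftCalls <- function(calls_ctrl, calls_dep, confidence = 0.90,
                       correction = c("none", "bh")) {
  correction <- match.arg(correction)
  ok_c <- calls_ctrl[calls_ctrl$status == "ok", ]
  ok_d <- calls_dep[calls_dep$status == "ok", ]
  common <- intersect(ok_c$anchor_id, ok_d$anchor_id)
  if (!length(common)) stop("no anchor is callable in both conditions")
  a <- ok_c[match(common, ok_c$anchor_id), ]
  b <- ok_d[match(common, ok_d$anchor_id), ]
  delta_m <- b$minus1_offset - a$minus1_offset
  delta_p <- b$plus1_offset - a$plus1_offset
  pooled_m <- sqrt(a$se_minus1^2 + b$se_minus1^2)
  pooled_p <- sqrt(a$se_plus1^2 + b$se_plus1^2)
  z_m <- ifelse(pooled_m > 0, delta_m / pooled_m,
                ifelse(delta_m == 0, 0, sign(delta_m) * Inf))
  z_p <- ifelse(pooled_p > 0, delta_p / pooled_p,
                ifelse(delta_p == 0, 0, sign(delta_p) * Inf))
  if (correction == "none") {
    zstar <- stats::qnorm(confidence)
    sig_m <- z_m > zstar          # -1 toward anchor = downstream (+)
    sig_p <- -z_p > zstar         # +1 toward anchor = upstream (-)
  } else {
    p_m <- stats::pnorm(z_m, lower.tail = FALSE)
    p_p <- stats::pnorm(-z_p, lower.tail = FALSE)
    alpha <- 1 - confidence
    sig_m <- stats::p.adjust(p_m, "BH") < alpha
    sig_p <- stats::p.adjust(p_p, "BH") < alpha
  }
  label <- mapply(classifyShift, sig_m, sig_p)
  S4Vectors::DataFrame(
    anchor_id = common,
    minus1_ctrl = a$minus1_offset, plus1_ctrl = a$plus1_offset,
    minus1_dep = b$minus1_offset, plus1_dep = b$plus1_offset,
    delta_minus1 = delta_m, delta_plus1 = delta_p,
    z_minus1 = z_m, z_plus1 = z_p,
    sig_minus1 = sig_m, sig_plus1 = sig_p, label = label,
    spacing_ctrl = nucSpacing(a$minus1_offset, a$plus1_offset),
    spacing_dep = nucSpacing(b$minus1_offset, b$plus1_offset))
}

#' Group-level shift summary
#'
#' Per-label arithmetic means of the \eqn{-1}/\eqn{+1} positions in each
#' condition, the spacings and the per-nucleosome shifts, with group counts
#' - the layout of the reference shift table.
#'
#' @param calls [shiftCalls()] output.
#' @param kind Anchor-kind label carried into the summary.
#' @return data.frame with one row per shift label.
#' @export
summarizeShiftGroups <- function(calls, kind = "TSS") {
  df <- as.data.frame(calls)
  labs <- c("non-shift", "Shift1", "Shift2", "Shift3")
  out <- do.call(rbind, lapply(labs, function(g) {
    x <- df[df$label == g, ]
    if (nrow(x) == 0L)
      return(data.frame(kind = kind, label = g, n = 0L, minus1_ctrl = NA_real_,
                        plus1_ctrl = NA_real_, spacing_ctrl = NA_real_,
                        minus1_dep = NA_real_, plus1_dep = NA_real_,
                        spacing_dep = NA_real_, shift_minus1 = NA_real_,
                        shift_plus1 = NA_real_))
    data.frame(kind = kind, label = g, n = nrow(x),
               minus1_ctrl = mean(x$minus1_ctrl),
               plus1_ctrl = mean(x$plus1_ctrl),
               spacing_ctrl = mean(x$spacing_ctrl),
               minus1_dep = mean(x$minus1_dep),
               plus1_dep = mean(x$plus1_dep),
               spacing_dep = mean(x$spacing_dep),
               shift_minus1 = mean(x$delta_minus1),
               shift_plus1 = mean(x$delta_plus1))
  }))
  rownames(out) <- NULL
  out
}

#' One-sided hypergeometric overlap test
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\eqn{N, K, n}): the
#' probability that drawing \code{n} anchors from a universe of \code{N}
#' containing \code{K} marked ones yields at least \code{k} marked. Exact
#' summation in log space (log-binomials combined by log-sum-exp), stable
#' for large counts.
#'
#' @param k Observed overlap.
#' @param K Marked-set size.
#' @param n Drawn-group size.
#' @param N Universe size.
#' @return The one-sided p-value.
#' @examples
#' hypergeomTest(4, 5, 4, 10)   # 5/210
#' @export
hypergeomTest <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Associate shift groups with decreased-signal region sets
#'
#' For each (shift group, region set) pair, computes the one-sided
#' hypergeometric p-value of the overlap within the universe of callable
#' anchors and reports \eqn{-\log_{10} P} - the association heatmap used to
#' relate shift patterns to decreases in BRG1 binding, accessibility,
#' H3K27ac, p300 or nascent transcription.
#'
#' @param calls [shiftCalls()] output (or any data.frame/DataFrame with
#'   \code{anchor_id} and \code{label}).
#' @param decreased_sets Named list of character vectors of anchor ids
#'   (e.g. anchors with significantly decreased signal per assay).
#' @param universe Character vector of all eligible anchor ids; defaults to
#'   the anchors present in \code{calls}. Region sets must be drawn from it.
#' @param labels Shift labels to test (default the three shift groups).
#' @return Numeric matrix (groups x sets) of \eqn{-\log_{10}} one-sided
#'   hypergeometric p-values.
#' @export
associateWithSignal <- function(calls, decreased_sets,
                                universe = NULL,
                                labels = c("Shift1", "Shift2", "Shift3")) {
  df <- as.data.frame(calls)
  if (is.null(universe)) universe <- df$anchor_id
  bad <- !vapply(decreased_sets, function(s) all(s %in% universe), TRUE)
  if (any(bad))
    stop("region set(s) outside the universe: ",
         paste(names(decreased_sets)[bad], collapse = ", "))
  N <- length(universe)
  out <- matrix(0, length(labels), length(decreased_sets),
                dimnames = list(labels, names(decreased_sets)))
  for (g in labels) {
    grp <- intersect(df$anchor_id[df$label == g], universe)
    for (s in names(decreased_sets)) {
      set <- decreased_sets[[s]]
      p <- hypergeomTest(length(intersect(grp, set)), length(set),
                         length(grp), N)
      out[g, s] <- -log10(p)
    }
  }
  out
}
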