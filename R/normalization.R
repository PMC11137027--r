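#' Per-library read statistics
#'
#' @param library_id Character library identifiers.
#' @param condition Condition label per library.
#' @param mouse_reads Reads mapped to the target (mouse) genome (> 0).
#' @param spike_reads Reads mapped to the spike-in genome (0 when no
#'   spike-in was used).
#' @param is_reference Logical; exactly one \code{TRUE} is required when
#'   spike-in normalization is requested. Defaults to the control/WT
#'   library with the median spike read count.
#' @return A validated data.frame.
#' @export
libraryStats <- function(library_id, condition, mouse_reads,
                         spike_reads = 0, is_reference = NULL) {
  df <- data.frame(library_id = as.character(library_id),
                   condition = as.character(condition),
                   mouse_reads = mouse_reads, spike_reads = spike_reads,
                   stringsAsFactors = FALSE)
  if (any(df$mouse_reads <= 0)) stop("mouse_reads must be > 0")
  if (is.null(is_reference)) {
    is_reference <- rep(FALSE, nrow(df))
    ctrl <- which(df$condition %in% c("control", "WT", "wt"))
    if (length(ctrl)) {
      sp <- df$spike_reads[ctrl]
      is_reference[ctrl[which.min(abs(sp - stats::median(sp)))]] <- TRUE
    }
  }
  df$is_reference <- is_reference
  df
}

#' Library-size (CPM) normalization
#'
#' \code{density = count / library_size * 1e6}; the whole-library count maps
#' to exactly \eqn{10^6}.
#'
#' @param counts Numeric vector or matrix of region counts (columns =
#'   libraries when a matrix).
#' @param library_size Positive library size(s); recycled across columns
#'   for a matrix.
#' @return Normalized densities, same shape as \code{counts}.
#' @export
libsizeNormalize <- function(counts, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (is.matrix(counts)) {
    stopifnot(length(library_size) %in% c(1L, ncol(counts)))
    sweep(counts, 2, library_size, "/") * 1e6
  } else counts / library_size * 1e6
}

#' Spike-in normalization factors
#'
#' Two-component factor per library: the average mouse-mapped read count
#' across libraries, times the library's spike-in read count relative to the
#' designated reference (WT) library:
#' \deqn{f_i = \overline{\mathrm{mouse}} \times
#'   \mathrm{spike}_i / \mathrm{spike}_{ref}.}
#' Normalized density is \code{count / f_i * 1e6}. Doubling a library's
#' spike reads (signal unchanged) halves its normalized signal; a global
#' technical scaling common to mouse and spike chromatin cancels.
#'
#' @param stats [libraryStats()] data.frame with one designated reference
#'   and positive spike reads everywhere.
#' @return Named numeric vector of per-library factors.
#' @export
spikeinFactors <- function(stats) {
  if (sum(stats$is_reference) != 1L)
    stop("exactly one reference library must be designated")
  if (any(stats$spike_reads <= 0))
    stop("spike_reads must be > 0 for spike-in normalization")
  ref <- stats$spike_reads[stats$is_reference]
  f <- mean(stats$mouse_reads) * stats$spike_reads / ref
  stats::setNames(f, stats$library_id)
}

#' Conserved-gene normalization factors
#'
#' Selects genes with robust expression (CPM above \code{cpm_threshold} in
#' every library) and no BRG1 enrichment (no BRG1 peak over the gene body
#' extended \code{promoter_ext} bp upstream), then scales each library by
#' the total count over the selected genes relative to the across-library
#' mean of that total.
#'
#' @param counts Gene x library count matrix (rownames = gene ids).
#' @param library_sizes Per-library total read counts (for the CPM
#'   threshold).
#' @param genes GRanges of gene bodies, parallel to \code{counts} rows
#'   (strand used for the upstream extension).
#' @param brg1_peaks GRanges of BRG1 peaks.
#' @param cpm_threshold CPM floor applied in every library (default 500).
#' @param promoter_ext Upstream extension of the gene body in bp (default
#'   2000).
#' @return list with \code{factors} (named per-library) and \code{genes}
#'   (selected gene ids).
#' @export
conservedGeneFactors <- function(counts, library_sizes, genes, brg1_peaks,
                                 cpm_threshold = 500, promoter_ext = 2000L) {
  stopifnot(is.matrix(counts), length(genes) == nrow(counts),
            length(library_sizes) == ncol(counts))
  cpm <- libsizeNormalize(counts, library_sizes)
  expressed <- rowSums(cpm > cpm_threshold) == ncol(counts)
  ext <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(genes,
                          width = GenomicRanges::width(genes) + promoter_ext,
                          fix = "end")))
  no_brg1 <- !IRanges::overlapsAny(ext, brg1_peaks, ignore.strand = TRUE)
  sel <- expressed & no_brg1
  if (!any(sel)) {
    near <- rownames(counts)[no_brg1][
      order(-apply(cpm[no_brg1, , drop = FALSE], 1, min))]
    stop("no gene passes the conserved-gene selection; closest candidates: ",
         paste(utils::head(near, 5), collapse = ", "))
  }
  tot <- colSums(counts[sel, , drop = FALSE])
  list(factors = stats::setNames(tot / mean(tot), colnames(counts)),
       genes = rownames(counts)[sel])
}

#' Background-noise correction of in-peak densities
#'
#' In-peak read density minus the genome-wide background density estimated
#' from reads outside peaks:
#' \deqn{d_p = \mathrm{reads}_p / \mathrm{len}_p -
#'   \mathrm{reads}_{out} / (G - \sum_p \mathrm{len}_p),}
#' floored at zero. Library-factor scaling is applied afterwards by the
#' caller.
#'
#' @param reads_in_peaks Numeric vector of read counts per peak.
#' @param peak_sizes Peak lengths in bp (> 0).
#' @param reads_outside Total reads outside all peaks.
#' @param effective_genome_size Effective genome size in bp (> total peak
#'   length).
#' @return Corrected densities (reads/bp), floored at 0.
#' @examples
#' backgroundCorrect(100, 1000, 1e6, 1e9)   # 0.1 - ~0.001
#' @export
backgroundCorrect <- function(reads_in_peaks, peak_sizes, reads_outside,
                              effective_genome_size) {
  if (any(peak_sizes <= 0)) stop("peak sizes must be > 0")
  tot <- sum(peak_sizes)
  if (effective_genome_size <= tot)
    stop("effective_genome_size must exceed the total peak length")
  bg <- reads_outside / (effective_genome_size - tot)
  pmax(reads_in_peaks / peak_sizes - bg, 0)
}

#' Region scaffold by distance-to-TSS conventions
#'
#' Builds the fixed-width region classes used throughout the quantification:
#' 5' regions (TSS +/- 1000 bp), 3' regions (TTS +/- 1000 bp), and a
#' TSS / nonTSS classification of peaks (within 2 kb of a TSS vs. farther
#' than 5 kb from every TSS; intermediate peaks belong to neither class).
#'
#' @param tss GRanges of strand-annotated TSS points.
#' @param tts GRanges of TTS points (optional).
#' @param peaks GRanges of peaks/DHSs to classify (optional).
#' @param prox Flank for the 5'/3' regions (default 1000 bp).
#' @param tss_max Maximum TSS distance for the TSS class (default 2000 bp).
#' @param nontss_min Minimum TSS distance for the nonTSS class (default
#'   5000 bp).
#' @return list with \code{fivePrime}, \code{threePrime} (GRanges or NULL)
#'   and \code{peak_class} (factor \code{"TSS"}, \code{"nonTSS"},
#'   \code{"excluded"} parallel to \code{peaks}).
#' @export
makeRegions <- function(tss, tts = NULL, peaks = NULL, prox = 1000L,
                        tss_max = 2000L, nontss_min = 5000L) {
  if (any(as.character(GenomicRanges::strand(tss)) == "*"))
    stop("TSS anchors must be strand-annotated")
  five <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
    tss, width = 2L * prox + 1L, fix = "center")))
  three <- if (!is.null(tts))
    suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
      tts, width = 2L * prox + 1L, fix = "center")))
  peak_class <- NULL
  if (!is.null(peaks)) {
    d <- GenomicRanges::distanceToNearest(peaks, tss, ignore.strand = TRUE)
    dist <- rep(NA_integer_, length(peaks))
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    peak_class <- factor(ifelse(is.na(dist), "excluded",
                         ifelse(dist <= tss_max, "TSS",
                         ifelse(dist > nontss_min, "nonTSS", "excluded"))),
                         levels = c("TSS", "nonTSS", "excluded"))
  }
  list(fivePrime = five, threePrime = three, peak_class = peak_class)
}

#' Summarize a differential comparison
#'
#' Applies the joint significance rule (\eqn{P < \alpha} and fold-change
#' outside \eqn{[1/\mathrm{fc}, \mathrm{fc}]}) and reports how many regions
#' changed, how many went down or up, and the corresponding fractions.
#'
#' @param results data.frame with columns \code{p_value} and
#'   \code{fold_change} (depleted / control, > 0).
#' @param alpha P-value cutoff (default 0.05).
#' @param fc_cut Fold-change cutoff (default 1.3; use 1.5 for RNA-seq style
#'   comparisons).
#' @return list with \code{n_total}, \code{n_changed}, \code{n_down},
#'   \code{n_up}, \code{pct_down_of_changed}, \code{pct_up_of_changed},
#'   \code{pct_changed} (percentages; \code{NaN} when nothing changed).
#' @examples
#' # 7987 of 8305 changed sites decreased -> 96.17%
#' @export
differentialSummary <- function(results, alpha = 0.05, fc_cut = 1.3) {
  stopifnot(all(c("p_value", "fold_change") %in% names(results)))
  if (any(results$fold_change <= 0)) stop("fold_change must be > 0")
  sig <- results$p_value < alpha &
    (results$fold_change > fc_cut | results$fold_change < 1 / fc_cut)
  down <- sig & results$fold_change < 1
  up <- sig & results$fold_change > 1
  n_changed <- sum(sig)
  list(n_total = nrow(results), n_changed = n_changed,
       n_down = sum(down), n_up = sum(up),
       pct_down_of_changed = 100 * sum(down) / n_changed,
       pct_up_of_changed = 100 * sum(up) / n_changed,
       pct_changed = 100 * n_changed / nrow(results))
}

#' Equal-count tertiles
#'
#' Ranks values and cuts them into low / medium / high groups of equal count
#' (sizes differing by at most one); ties keep stable input order.
#'
#' @param values Numeric vector (length >= 3).
#' @return Factor with levels \code{low}, \code{medium}, \code{high}.
#' @examples
#' table(tertileGroups(1:9))
#' @export
tertileGroups <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  r <- rank(values, ties.method = "first")
  factor(c("low", "medium", "high")[ceiling(3 * r / n)],
         levels = c("low", "medium", "high"))
}
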