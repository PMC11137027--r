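#' Pipeline configuration
#'
#' Collects the analysis parameters with their standard defaults: canonical
#' fragment lengths 140-180 bp, Gaussian kernel sigma 20 bp over +/-73 bp,
#' -1/+1 search window +/-150 bp, peak prominence 0.1 on the max-1 scale,
#' one-tailed confidence 0.90, differential cutoffs P < 0.05 and
#' fold-change > 1.3. Values can come from a YAML file, with arguments
#' overriding file values.
#'
#' @param yaml Optional path to a YAML file with any of the fields below.
#' @param ... Overrides: \code{min_len}, \code{max_len}, \code{sigma},
#'   \code{kernel_halfwidth}, \code{search_halfwidth}, \code{min_prominence},
#'   \code{confidence}, \code{alpha}, \code{fc_cut}, \code{bootstrap_B},
#'   \code{seed}, \code{correction}.
#' @return A list of class \code{"nucshift_config"}.
#' @export
pipelineConfig <- function(yaml = NULL, ...) {
  cfg <- list(min_len = 140L, max_len = 180L, sigma = 20,
              kernel_halfwidth = 73L, search_halfwidth = 150L,
              min_prominence = 0.1, confidence = 0.90, alpha = 0.05,
              fc_cut = 1.3, bootstrap_B = 200L, seed = 1L,
              correction = "none")
  if (!is.null(yaml)) {
    fromfile <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(fromfile)] <- fromfile
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$min_len > cfg$max_len) stop("min_len must be <= max_len")
  if (cfg$confidence <= 0 || cfg$confidence >= 1)
    stop("confidence must be in (0, 1)")
  structure(cfg, class = "nucshift_config")
}

#' Run the anchored shift pipeline end to end
#'
#' Chains nucleosome calling in both conditions, per-anchor shift testing
#' and classification, the group summary, and (optionally) the
#' hypergeometric association with decreased-signal sets. Results and a
#' machine-readable run manifest are written to \code{outdir} as TSV/JSON
#' when it is given.
#'
#' @param fragments_ctrl,fragments_dep GRanges of MNase fragments per
#'   condition (replicates pooled at the fragment level).
#' @param anchors GRanges of anchor points with \code{anchor_id}.
#' @param config [pipelineConfig()] output.
#' @param decreased_sets Optional named list of anchor-id vectors for the
#'   association step.
#' @param kind Anchor kind label for the summary.
#' @param outdir Optional output directory.
#' @return list with \code{calls_ctrl}, \code{calls_dep}, \code{shifts},
#'   \code{summary}, \code{association} (or NULL) and \code{manifest}.
#' @export
runPipeline <- function(fragments_ctrl, fragments_dep, anchors,
                        config = pipelineConfig(), decreased_sets = NULL,
                        kind = "TSS", outdir = NULL) {
  stopifnot(inherits(config, "nucshift_config"))
  if (length(anchors) == 0L) stop("anchor set is empty")
  kernel <- gaussianKernel(config$sigma, config$kernel_halfwidth)
  args <- list(anchors = anchors, kernel = kernel,
               search_halfwidth = config$search_halfwidth,
               min_prominence = config$min_prominence,
               min_len = config$min_len, max_len = config$max_len,
               B = config$bootstrap_B)
  calls_c <- do.call(callNucleosomes, c(list(fragments_ctrl,
    condition = "control", seed = config$seed), args))
  calls_d <- do.call(callNucleosomes, c(list(fragments_dep,
    condition = "depleted", seed = config$seed + 1L), args))
  shifts <- shiftCalls(calls_c, calls_d, confidence = config$confidence,
                       correction = config$correction)
  summ <- summarizeShiftGroups(shifts, kind = kind)
  assoc <- if (!is.null(decreased_sets))
    associateWithSignal(shifts, decreased_sets)
  manifest <- list(
    package = as.character(utils::packageVersion("NucShift")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    parameters = unclass(config),
    n_anchors = length(anchors),
    n_fragments = c(control = length(fragments_ctrl),
                    depleted = length(fragments_dep)),
    n_callable = nrow(shifts))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeTSV(calls_c, file.path(outdir, "calls_control.tsv"))
    writeTSV(calls_d, file.path(outdir, "calls_depleted.tsv"))
    writeTSV(shifts, file.path(outdir, "shift_calls.tsv"))
    writeTSV(summ, file.path(outdir, "shift_summary.tsv"))
    if (!is.null(assoc))
      writeTSV(cbind(group = rownames(assoc), as.data.frame(assoc)),
               file.path(outdir, "association.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(calls_ctrl = calls_c, calls_dep = calls_d, shifts = shifts,
       summary = summ, association = assoc, manifest = manifest)
}
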