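#' Reference nucleosome-shift group table
#'
#' Reported group-mean \eqn{-1}/\eqn{+1} nucleosome positions (bp relative to
#' the anchor) for the three nucleosome shifting patterns observed at
#' enhancers and TSSs after acute BRG1 depletion in mouse CD4+ T cells, in
#' the control (WT) and depleted (AID) conditions, together with the implied
#' \eqn{-1}/\eqn{+1} spacings and per-nucleosome shifts. These values are
#' used as the default architecture of the synthetic fragment generator, so
#' simulated cohorts carry displacement magnitudes of realistic size.
#'
#' Signs follow anchor-oriented coordinates: upstream is negative, so a
#' negative shift at \eqn{+1} is movement toward the anchor, and a positive
#' shift at \eqn{-1} is movement toward the anchor.
#'
#' @return A data.frame with columns \code{kind} (\code{"enhancer"} or
#'   \code{"TSS"}), \code{label} (\code{"Shift1"}, \code{"Shift2"},
#'   \code{"Shift3"}), \code{minus1_wt}, \code{plus1_wt}, \code{spacing_wt},
#'   \code{minus1_dep}, \code{plus1_dep}, \code{spacing_dep},
#'   \code{shift_minus1}, \code{shift_plus1} (all bp).
#' @examples
#' tab <- shiftReferenceTable()
#' all(tab$spacing_wt == tab$plus1_wt - tab$minus1_wt)
#' @export
shiftReferenceTable <- function() {
  data.frame(
    kind = rep(c("enhancer", "TSS"), each = 3L),
    label = rep(c("Shift1", "Shift2", "Shift3"), 2L),
    minus1_wt  = c(-88, -102, -102, -93, -108, -105),
    plus1_wt   = c(92, 71, 92, 70, 56, 70),
    spacing_wt = c(180, 173, 194, 163, 164, 175),
    minus1_dep = c(-88, -67, -66, -93, -59, -65),
    plus1_dep  = c(56, 71, 59, 34, 56, 43),
    spacing_dep = c(144, 138, 125, 127, 115, 108),
    shift_minus1 = c(0, 35, 36, 0, 49, 40),
    shift_plus1  = c(-36, 0, -33, -36, 0, -27),
    stringsAsFactors = FALSE)
}

#' Describe the -1/+1 nucleosome architecture of synthetic anchors
#'
#' Builds the per-anchor truth table consumed by [simulateFragments()]. Each
#' anchor carries a \eqn{-1} and a \eqn{+1} nucleosome whose dyads jitter
#' around the stated centers with Gaussian fuzziness, on top of a uniform
#' background of non-positioned fragments.
#'
#' @param anchor_id Character vector of unique anchor identifiers.
#' @param group Shift-group label per anchor (matched against the
#'   \code{groups} entry of the simulation config at draw time).
#' @param minus1_center,plus1_center Dyad centers in bp relative to the
#'   anchor; \code{minus1_center} must be negative and \code{plus1_center}
#'   positive (upstream is negative).
#' @param fuzziness_sd Gaussian dyad jitter in bp (>= 0).
#' @param occupancy_minus1,occupancy_plus1 Expected fragment count per
#'   nucleosome (>= 0).
#' @param background_rate Expected background fragments per bp across the
#'   simulation window (>= 0).
#' @param strand Anchor strand, \code{"+"} or \code{"-"}.
#' @return A validated data.frame, one row per anchor.
#' @export
nucArchitecture <- function(anchor_id, group = "non-shift",
                            minus1_center = -93, plus1_center = 70,
                            fuzziness_sd = 20, occupancy_minus1 = 900,
                            occupancy_plus1 = 900, background_rate = 0.2,
                            strand = "+") {
  df <- data.frame(anchor_id = as.character(anchor_id),
                   group = as.character(group),
                   minus1_center = minus1_center, plus1_center = plus1_center,
                   fuzziness_sd = fuzziness_sd,
                   occupancy_minus1 = occupancy_minus1,
                   occupancy_plus1 = occupancy_plus1,
                   background_rate = background_rate,
                   strand = strand, stringsAsFactors = FALSE)
  if (anyDuplicated(df$anchor_id))
    stop("anchor_id values must be unique")
  if (any(df$minus1_center >= 0) || any(df$plus1_center <= 0))
    stop("need minus1_center < 0 < plus1_center (upstream is negative)")
  if (any(df$fuzziness_sd < 0) || any(df$occupancy_minus1 < 0) ||
      any(df$occupancy_plus1 < 0) || any(df$background_rate < 0))
    stop("fuzziness_sd, occupancies and background_rate must be >= 0")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df
}

#' Simulation configuration
#'
#' @param n_anchors Anchors per shift group (used by cohort builders).
#' @param groups Named list mapping each group label to
#'   \code{c(delta_minus1, delta_plus1)}: the dyad displacements in bp
#'   injected into the depleted condition.
#' @param fragment_length_law Discretized truncated-normal fragment-length
#'   distribution, \code{list(mean, sd, min, max)} in bp. Its support must
#'   extend below 140 and above 180 bp so the canonical-length filter is
#'   exercised.
#' @param window_halfwidth Simulation window half-extent in bp around each
#'   anchor (background fragments are uniform over it).
#' @param seed Master seed; all draws are deterministic given it.
#' @param n_replicates Replicate libraries per condition.
#' @return A validated list of class \code{"nucshift_sim_config"}.
#' @export
simConfig <- function(n_anchors = 200L,
                      groups = list("non-shift" = c(0, 0),
                                    "Shift1" = c(0, -36),
                                    "Shift2" = c(49, 0),
                                    "Shift3" = c(40, -27)),
                      fragment_length_law = list(mean = 160, sd = 15,
                                                 min = 100, max = 220),
                      window_halfwidth = 500L, seed = 1L,
                      n_replicates = 1L) {
  law <- fragment_length_law
  stopifnot(is.list(law), all(c("mean", "sd", "min", "max") %in% names(law)))
  if (law$min >= law$max || law$min < 1)
    stop("fragment_length_law must have 1 <= min < max")
  if (!(law$min < 140 && law$max > 180))
    stop("fragment_length_law support must include lengths < 140 and > 180")
  if (window_halfwidth <= 0) stop("window_halfwidth must be positive")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named list")
  if (any(vapply(groups, length, 1L) != 2L))
    stop("each group entry must be c(delta_minus1, delta_plus1)")
  structure(list(n_anchors = as.integer(n_anchors), groups = groups,
                 fragment_length_law = law,
                 window_halfwidth = as.integer(window_halfwidth),
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "nucshift_sim_config")
}

## Deterministic sub-seed per (condition, replicate), derived from the master
## seed; kept below 2^31.
.subSeed <- function(seed, condition, replicate = 1L) {
  (as.integer(seed) * 7L +
     11L * match(condition, c("control", "depleted")) +
     101L * as.integer(replicate)) %% .Machine$integer.max
}

#' Sample fragment lengths from a discretized truncated normal law
#'
#' @param n Number of lengths to draw.
#' @param law \code{list(mean, sd, min, max)} as in [simConfig()].
#' @return Integer vector of lengths in \code{[law$min, law$max]}.
#' @export
sampleFragmentLengths <- function(n, law) {
  if (n == 0L) return(integer())
  support <- seq.int(law$min, law$max)
  p <- stats::pnorm(support + 0.5, law$mean, law$sd) -
       stats::pnorm(support - 0.5, law$mean, law$sd)
  sample(support, n, replace = TRUE, prob = p / sum(p))
}

#' Theoretical CDF of the fragment-length law
#'
#' @param law \code{list(mean, sd, min, max)}.
#' @return data.frame with columns \code{length} and \code{cdf}.
#' @export
fragmentLengthCDF <- function(law) {
  support <- seq.int(law$min, law$max)
  p <- stats::pnorm(support + 0.5, law$mean, law$sd) -
       stats::pnorm(support - 0.5, law$mean, law$sd)
  data.frame(length = support, cdf = cumsum(p / sum(p)))
}

## Genomic layout for synthetic anchors: one synthetic chromosome, anchors
## spaced far enough apart that windows never overlap.
.anchorPositions <- function(n, window_halfwidth) {
  spacing <- 2L * window_halfwidth + 2000L
  10000L + spacing * (seq_len(n) - 1L)
}

#' Synthetic anchors as a GRanges
#'
#' Lays the anchors of an architecture table along one synthetic chromosome
#' (\code{"chrS"}), spaced so that simulation windows never overlap.
#'
#' @param architectures Output of [nucArchitecture()].
#' @param config Output of [simConfig()].
#' @param kind Anchor kind label (\code{"TSS"}, \code{"enhancer"} or
#'   \code{"motif"}).
#' @return A [GenomicRanges::GRanges] of 1-bp anchor points with metadata
#'   columns \code{anchor_id}, \code{kind}.
#' @export
syntheticAnchors <- function(architectures, config, kind = "TSS") {
  pos <- .anchorPositions(nrow(architectures), config$window_halfwidth)
  GenomicRanges::GRanges("chrS", IRanges::IRanges(pos, width = 1L),
                         strand = architectures$strand,
                         anchor_id = architectures$anchor_id, kind = kind)
}

#' Simulate MNase fragments around positioned nucleosomes
#'
#' For each anchor, draws Poisson-distributed numbers of nucleosomal
#' fragments whose dyads jitter around the true \eqn{-1}/\eqn{+1} centers
#' with Gaussian fuzziness (plus the group's injected displacement in the
#' depleted condition), and uniform background fragments across the window.
#' Fragment intervals are placed so that the fragment midpoint (under the
#' floor midpoint convention) equals the drawn dyad exactly; lengths follow
#' the configured length law for nucleosomal and background fragments alike.
#'
#' @param architectures Output of [nucArchitecture()].
#' @param config Output of [simConfig()]; all randomness derives from
#'   \code{config$seed} plus the (condition, replicate) sub-seed.
#' @param condition \code{"control"} or \code{"depleted"}.
#' @param replicate Replicate index (independent redraw).
#' @return A [GenomicRanges::GRanges] of fragments with metadata column
#'   \code{library_id}.
#' @examples
#' arch <- nucArchitecture("a1", occupancy_minus1 = 50, occupancy_plus1 = 50,
#'                         background_rate = 0)
#' fr <- simulateFragments(arch, simConfig(seed = 7), "control")
#' @export
simulateFragments <- function(architectures, config, condition,
                              replicate = 1L) {
  stopifnot(inherits(config, "nucshift_sim_config"))
  condition <- match.arg(condition, c("control", "depleted"))
  if (nrow(architectures) == 0L) stop("'architectures' must be non-empty")
  missing_grp <- setdiff(unique(architectures$group), names(config$groups))
  if (length(missing_grp))
    stop("groups without injected deltas in config: ",
         paste(missing_grp, collapse = ", "))
  W <- config$window_halfwidth
  set.seed(.subSeed(config$seed, condition, replicate))
  pos <- .anchorPositions(nrow(architectures), W)

  dyads <- integer(0)
  n_per_anchor <- integer(nrow(architectures))
  for (i in seq_len(nrow(architectures))) {
    a <- architectures[i, ]
    d <- if (condition == "depleted") config$groups[[a$group]] else c(0, 0)
    cm <- a$minus1_center + d[1]
    cp <- a$plus1_center + d[2]
    nm <- stats::rpois(1L, a$occupancy_minus1)
    np <- stats::rpois(1L, a$occupancy_plus1)
    nb <- stats::rpois(1L, a$background_rate * (2L * W + 1L))
    off <- c(round(stats::rnorm(nm, cm, a$fuzziness_sd)),
             round(stats::rnorm(np, cp, a$fuzziness_sd)),
             if (nb > 0L) sample.int(2L * W + 1L, nb, replace = TRUE) - W - 1L)
    sgn <- if (a$strand == "-") -1L else 1L
    dyads <- c(dyads, pos[i] + sgn * as.integer(off))
    n_per_anchor[i] <- length(off)
  }
  lens <- sampleFragmentLengths(length(dyads), config$fragment_length_law)
  ## start chosen so floor((start0 + end0 - 1) / 2) == dyad for any length
  start1 <- dyads - (lens - 1L) %/% 2L
  gr <- GenomicRanges::GRanges(rep("chrS", length(dyads)),
          IRanges::IRanges(start = start1, width = lens),
          library_id = paste(condition, replicate, sep = "_rep"))
  S4Vectors::metadata(gr) <- list(condition = condition,
                                  replicate = replicate,
                                  n_per_anchor = n_per_anchor)
  gr
}

#' Build a full synthetic shift cohort
#'
#' Convenience wrapper that assembles architectures from the reference shift
#' table (WT group-mean positions, injected group displacements), simulates
#' control and depleted fragment libraries, and returns the pieces the
#' downstream pipeline needs along with the truth table.
#'
#' @param kind \code{"TSS"} or \code{"enhancer"}; selects the reference rows.
#' @param n_per_group Anchors per group (non-shift + the three shift groups).
#' @param fuzziness_sd,occupancy,background_rate Architecture parameters
#'   shared by all anchors; \code{occupancy} is per nucleosome.
#' @param groups Optional named list of \code{c(delta_minus1, delta_plus1)}
#'   overriding the reference displacements.
#' @param seed Master seed.
#' @param window_halfwidth Simulation window half-extent in bp.
#' @return A list with \code{fragments} (named list \code{control},
#'   \code{depleted}), \code{anchors} (GRanges), \code{architectures},
#'   \code{config} and \code{truth} (per-anchor injected deltas).
#' @export
simulateShiftCohort <- function(kind = c("TSS", "enhancer"),
                                n_per_group = 200L, fuzziness_sd = 20,
                                occupancy = 900, background_rate = 0.2,
                                groups = NULL, seed = 1L,
                                window_halfwidth = 500L) {
  kind <- match.arg(kind)
  ref <- shiftReferenceTable()
  ref <- ref[ref$kind == kind, ]
  if (is.null(groups)) {
    groups <- c(list("non-shift" = c(0, 0)),
                stats::setNames(lapply(seq_len(nrow(ref)), function(i)
                  c(ref$shift_minus1[i], ref$shift_plus1[i])), ref$label))
  }
  labs <- names(groups)
  centers <- lapply(labs, function(g) {
    i <- match(g, ref$label)
    if (is.na(i)) c(mean(ref$minus1_wt), mean(ref$plus1_wt))
    else c(ref$minus1_wt[i], ref$plus1_wt[i])
  })
  n_tot <- n_per_group * length(labs)
  ## strands only matter for TSS anchors; enhancer summits are strandless
  ## and treated as "+"
  strands <- if (kind == "TSS") rep(c("+", "-"), length.out = n_tot)
             else rep("+", n_tot)
  arch <- nucArchitecture(
    anchor_id = sprintf("%s_%05d", kind, seq_len(n_tot)),
    group = rep(labs, each = n_per_group),
    minus1_center = rep(vapply(centers, `[`, 1, 1), each = n_per_group),
    plus1_center = rep(vapply(centers, `[`, 1, 2), each = n_per_group),
    fuzziness_sd = fuzziness_sd, occupancy_minus1 = occupancy,
    occupancy_plus1 = occupancy, background_rate = background_rate,
    strand = strands)
  config <- simConfig(n_anchors = n_per_group, groups = groups, seed = seed,
                      window_halfwidth = window_halfwidth)
  truth <- data.frame(anchor_id = arch$anchor_id, group = arch$group,
                      delta_minus1 = vapply(arch$group,
                        function(g) groups[[g]][1], 1),
                      delta_plus1 = vapply(arch$group,
                        function(g) groups[[g]][2], 1),
                      stringsAsFactors = FALSE)
  list(fragments = list(control = simulateFragments(arch, config, "control"),
                        depleted = simulateFragments(arch, config, "depleted")),
       anchors = syntheticAnchors(arch, config, kind = kind),
       architectures = arch, config = config, truth = truth)
}

#' Simulate region-level signal counts for two conditions
#'
#' Draws negative-binomial counts per region and replicate for a control and
#' a depleted condition; the depleted mean is scaled by the region group's
#' fold-change. The zero-dispersion limit is Poisson.
#'
#' @param architectures Architecture table (one region per anchor).
#' @param config [simConfig()] output; \code{n_replicates} replicates per
#'   condition are drawn from \code{config$seed}.
#' @param effect Named list/vector mapping every group label to a
#'   fold-change (> 0) applied to the depleted mean.
#' @param base_mean Expected control count per region.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2); 0 gives Poisson counts.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"counts"}, rowData \code{anchor_id}, \code{group} and colData
#'   \code{condition}, \code{replicate}.
#' @export
simulateSignalCounts <- function(architectures, config, effect,
                                 base_mean = 100, dispersion = 0.05) {
  stopifnot(inherits(config, "nucshift_sim_config"))
  effect <- unlist(effect)
  if (any(effect <= 0)) stop("fold-changes must be > 0")
  missing_grp <- setdiff(unique(architectures$group), names(effect))
  if (length(missing_grp))
    stop("groups without a fold-change: ", paste(missing_grp, collapse = ", "))
  n <- nrow(architectures)
  fc <- effect[architectures$group]
  cols <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = c("control", "depleted"),
                      stringsAsFactors = FALSE)[, 2:1]
  counts <- matrix(0L, n, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    set.seed(.subSeed(config$seed + 500L, cols$condition[j],
                      cols$replicate[j]))
    mu <- if (cols$condition[j] == "depleted") base_mean * fc
          else rep(base_mean, n)
    counts[, j] <- if (dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    else stats::rpois(n, mu)
  }
  colnames(counts) <- paste(cols$condition, cols$replicate, sep = "_rep")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(anchor_id = architectures$anchor_id,
                                   group = architectures$group),
    colData = S4Vectors::DataFrame(condition = cols$condition,
                                   replicate = cols$replicate,
                                   row.names = colnames(counts)))
}

#' Simulate spike-in libraries
#'
#' Emulates libraries whose global technical scale differs: each library's
#' \code{true_global_factor} multiplies the sequencing yield of mouse and
#' spike-in chromatin alike, so spike-in normalization should cancel it.
#' Region counts additionally scale with the library's nominal mouse read
#' depth; spike-in read counts are independent of the signal in the regions.
#'
#' @param spec data.frame with columns \code{library_id}, \code{condition},
#'   \code{mouse_reads}, \code{spike_reads} (> 0), \code{true_global_factor}
#'   (> 0) and logical \code{is_reference} (exactly one \code{TRUE}, in the
#'   control/WT group).
#' @param regions GRanges (or anything with a length) defining the regions;
#'   a fixed per-region expected share is drawn once from \code{seed}.
#' @param base_mean Expected count per region in a factor-1 library.
#' @param seed Seed for all draws.
#' @return list with \code{counts} (regions x libraries matrix) and
#'   \code{stats} (a [libraryStats()] data.frame with observed mouse/spike
#'   read totals).
#' @export
simulateSpikeinLibraries <- function(spec, regions, base_mean = 200,
                                     seed = 1L) {
  need <- c("library_id", "condition", "mouse_reads", "spike_reads",
            "true_global_factor")
  stopifnot(all(need %in% names(spec)))
  if (any(spec$mouse_reads <= 0) || any(spec$spike_reads <= 0))
    stop("mouse_reads and spike_reads must be > 0")
  if (any(spec$true_global_factor <= 0))
    stop("true_global_factor must be > 0")
  if (is.null(spec$is_reference)) {
    spec$is_reference <- FALSE
    ctrl <- which(spec$condition == "control")
    if (!length(ctrl)) stop("at least one library must be control")
    spec$is_reference[ctrl[1]] <- TRUE
  }
  if (sum(spec$is_reference) != 1L)
    stop("exactly one reference library must be designated")
  n <- length(regions)
  set.seed(as.integer(seed))
  share <- stats::rgamma(n, shape = 2, rate = 2 / base_mean)
  counts <- matrix(0L, n, nrow(spec),
                   dimnames = list(NULL, spec$library_id))
  mouse_obs <- spike_obs <- numeric(nrow(spec))
  for (j in seq_len(nrow(spec))) {
    g <- spec$true_global_factor[j]
    depth <- spec$mouse_reads[j] / mean(spec$mouse_reads)
    counts[, j] <- stats::rpois(n, share * g * depth)
    mouse_obs[j] <- stats::rpois(1L, spec$mouse_reads[j] * g)
    spike_obs[j] <- stats::rpois(1L, spec$spike_reads[j] * g)
  }
  stats <- libraryStats(spec$library_id, spec$condition,
                        mouse_reads = pmax(mouse_obs, 1),
                        spike_reads = pmax(spike_obs, 1),
                        is_reference = spec$is_reference)
  list(counts = counts, stats = stats)
}
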