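---
title: "Anchored nucleosome positioning and shift classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored nucleosome positioning and shift classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NucShift)
```

# Scope and model

NucShift analyzes nucleosome organization around point anchors — TSSs,
enhancer summits (points of maximal p300 binding) and TF motif sites — from
paired-end MNase-seq fragments. The biological question it serves: when a
chromatin remodeler such as BRG1 is acutely depleted, do the −1 and +1
nucleosomes flanking regulatory elements move toward the element, narrowing
the nucleosome-free region?

The underlying signal model is simple and deliberately close to how the
data are generated. MNase digestion protects nucleosome-wrapped DNA;
fragments of 140–180 bp are taken as canonical mononucleosomes and their
midpoints approximate dyads. Around each anchor, the per-base normalized
midpoint count \(S_k\) (the NCP score) is smoothed with a Gaussian
center-weighting,

\[
O_k=\sum_{j=-73}^{73} S_{k+j}\,w_j,\qquad w_j=e^{-(j/20)^2/2},
\]

which integrates the dyad-fuzziness of a positioned nucleosome (the 20 bp
width matches typical in-vivo dyad jitter) while leaving poorly positioned
nucleosomes flat. Positioned nucleosomes appear as peaks of \(O_k\); the
highest prominent peak on each side of the anchor within ±150 bp is the
called −1 / +1 nucleosome, and the spacing is their offset difference.

Between two conditions (control vs depleted), each nucleosome's
displacement is tested with a one-tailed z statistic using bootstrap
positional standard errors, and anchors are classified as Shift 1 (+1
toward the anchor), Shift 2 (−1 toward the anchor), Shift 3 (both) or
non-shift. Only toward-anchor movement is tested: the three patterns of
interest all narrow spacing, and a two-sided test would dilute power
against a direction the classification never uses; anchors whose
nucleosomes move significantly away therefore fall into non-shift. Group
summaries average the per-anchor calls; the association of shift groups
with sets of regions losing BRG1, accessibility, H3K27ac, p300 or nascent
transcription uses one-sided hypergeometric tests over the universe of
jointly callable anchors (overlap is only defined where both
classifications exist).

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_len`, `max_len` | 140, 180 | bp | canonical mononucleosome fragment bounds, inclusive |
| `sigma` | 20 | bp | Gaussian center-weighting width |
| `kernel_halfwidth` | 73 | bp | kernel support (one nucleosome half-footprint) |
| `search_halfwidth` | 150 | bp | −1/+1 search window around the anchor |
| `min_prominence` | 0.1 | max-1 units | topographic prominence floor for peaks |
| `confidence` | 0.90 | — | one-sided level of the shift z test |
| `bootstrap_B` | 200 | — | fragment-bootstrap resamples for positional SEs |
| `alpha`, `fc_cut` | 0.05, 1.3 | — | joint differential cutoff (1.5 for RNA-seq-style comparisons) |

The prominence threshold is only meaningful on a common scale, so each
profile is rescaled to maximum 1 *within the search window* before the 0.1
floor is applied; this makes calling depth-independent. Whether profiles
should be rescaled before thresholding is genuinely open; the rescaled
reading is the one under which a fixed 0.1 makes sense across anchors of
very different coverage, and it is fixed here and documented.

# Numerical choices

* **Inclusive length bounds.** "140–180 bp" is read as a closed interval;
  boundary fragments are kept.
* **Floor midpoint.** The midpoint of a 0-based half-open fragment
  \([s,e)\) is \(\lfloor (s+e-1)/2\rfloor\); even-length fragments round
  down. The synthetic generator places fragments so this midpoint equals
  the drawn dyad exactly, for any length.
* **Zero-padded smoothing.** Out-of-range \(S\) is treated as 0. Edges
  only matter within 73 bp of the window ends, which the ±150 bp peak
  search never reaches when the profile window is ≥ 223 bp.
* **Prominence semantics.** A peak's prominence is its height minus the
  higher of the two minimal valleys separating it from the nearest
  strictly higher point on each side; window edges act as boundaries.
  Plateau maxima report their center offset, with even plateaus breaking
  toward the anchor. Interior maxima only — a monotone profile has no
  peaks. The compiled implementation is property-tested against an
  exhaustive oracle written directly from this definition.
* **Tie-breaks.** Equal-height candidate peaks on one side resolve to the
  one closer to the anchor — conservative with respect to calling shifts
  toward the anchor.
* **Sub-bp apex refinement.** Called offsets are refined by three-point
  parabolic interpolation around the integer apex (clamped to ±0.5 bp,
  disabled on plateaus and at window edges; `refine = FALSE` restores
  integer calls). At realistic depths the integer-grid standard error of a
  peak position is of order 1 bp, so without refinement the z statistic
  sits on a coarse lattice and its null distribution is visibly lumpy;
  interpolation restores approximate normality, which the calibration
  suite checks directly.
* **Bootstrap SEs.** The z test needs a positional variance the data do
  not provide per anchor; NucShift's documented choice is a fragment
  bootstrap (resample fragments with replacement, rerun the length filter,
  smoothing and calling inside the loop, take the SD of called offsets over
  successful resamples). Resamples where the anchor is uncallable are
  dropped and counted; anchors failing more than half the resamples are
  flagged low-confidence and excluded from shift testing. Degenerate SEs
  (both zero) give \(z=0\) for equal positions, \(\pm\infty\) otherwise.
* **Per-anchor testing, then group averaging.** Group tables are means of
  per-anchor calls — per-anchor calls are the only way to obtain group
  counts. Calling on group-aggregated profiles remains available by
  composing `occupancyProfiles()`, `aggregateProfile()` and
  `findPeaksProminence()`.
* **No multiple-testing correction by default.** The classification uses a
  fixed per-test 90% confidence level; `correction = "bh"` is available.
* **Hypergeometric tail.** Computed by exact summation of log binomial
  coefficients combined with log-sum-exp, checked against both the
  standard distribution function and literal enumeration of subsets.
* **NCP scores are computed within anchor windows**, not genome-wide:
  every downstream quantity depends on the profile only within the window,
  and windowed computation keeps memory linear in the number of anchors.

# The synthetic generator

`simulateFragments()` draws, per anchor, Poisson numbers of nucleosomal
fragments whose dyads jitter around the true −1/+1 centers with Gaussian
fuzziness, plus uniform background fragments over the window; fragment
lengths follow a discretized truncated normal (mean 160, SD 15, support
100–220 bp) for nucleosomal and background fragments alike, so the
canonical filter acts uniformly. Gaussian dyad jitter is the minimal
fuzziness model matching the smoothing kernel's assumptions. Injected
condition effects displace dyad *centers* (matching the
midpoint-as-position convention), never fragment ends. All randomness
derives from a master seed via deterministic (condition, replicate)
sub-seeds; identical configurations give identical output.

Defaults mirror the study conditions the pipeline is meant for: control
−1/+1 geometries and depleted-condition displacements come from the
reference group table (`shiftReferenceTable()`, e.g. TSS Shift 2: −1 at
−108 moving +49 bp), dyad fuzziness 20 bp, 900 fragments per nucleosome
and background 0.2 fragments/bp, i.e. roughly 2000 fragments per anchor
window — a well-covered deeply sequenced library.

What the generator does **not** emulate: sequence (no FASTQ, mappability,
GC or MNase sequence bias), overlapping genes or shared anchors, replicate
batch effects, fuzziness differences between conditions, or occupancy
(height) changes. Passing tests therefore demonstrate that the estimator
and test behave correctly under the stated statistical model — unbiased
recovery, calibrated error rates — not that real chromatin meets those
assumptions.

`simulateSignalCounts()` (negative-binomial region counts with group
fold-changes) and `simulateSpikeinLibraries()` (global technical scaling
applied to mouse and spike-in chromatin alike) provide matched inputs for
the association and normalization modules. In the spike-in model the
library's `true_global_factor` is a *technical* scale — spike-in
normalization exists to cancel exactly such factors, and the simulator
respects the corresponding contract: doubling it leaves spike-normalized
signal unchanged.

# Normalization details

The two-component spike-in factor is
\(f_i=\overline{\text{mouse}}\times\text{spike}_i/\text{spike}_{ref}\);
the product form is one faithful reading of a two-component description
and is isolated in `spikeinFactors()` should a different combination be
preferred. The reference is the designated library, defaulting to the WT
library with the median spike count (deterministic, outlier-robust).
Conserved-gene selection applies the 500 CPM floor in *every* library (the
robust-expression reading; configurable) and vetoes genes whose body
extended 2 kb upstream touches a BRG1 peak, matching the ≤ 2 kb
TSS-proximity convention used elsewhere. Background-corrected densities
floor at zero. The differential statistic itself is pluggable:
`differentialSummary()` consumes per-region p-values and fold-changes from
any upstream test.

# Test and acceptance problem sizes

The property suites run at sizes chosen to give tight Monte-Carlo bands
while staying desk-scale: null calibration uses 2000 anchors × 2
nucleosomes with ~2000 fragments/anchor and B = 200 (exact binomial 99%
acceptance band around the nominal 10% rate); shift recovery uses 200
anchors per group with the reference displacement magnitudes
(classification accuracy > 90%, group-mean shifts within ±4 bp of the
injected values, judged against the injected groups — means over *called*
groups additionally carry the nominal false-call dilution); prominence
calling is compared exactly with the exhaustive oracle on 1000 random
profiles; hypergeometric tails are enumerated for all universes up to
N = 12.

# Limitations

Anchored analysis only — no genome-wide de-novo nucleosome map, no
fuzziness or occupancy differential testing, no sub-nucleosomal fragment
classes, no dinucleotide or chemical-mapping support. The z test treats
the two conditions' positional errors as independent and normal; very
shallow anchors surface as uncallable or low-confidence rather than being
rescued. ROTS-style differential testing and read alignment are upstream
of this package; it consumes their outputs.
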