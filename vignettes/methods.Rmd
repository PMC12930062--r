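---
title: "Methods: puncta detection, volumetric colocalization and
  sensory-learning scoring"
author: "synaptoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: puncta detection, volumetric colocalization and sensory-learning scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoscope)
```

## Scope and scientific setting

`synaptoscope` quantifies excitatory synapses in dual-channel confocal
z-stacks of mouse cortex in which the pre-synaptic compartment is labelled
with vesicular glutamate transporter 1 (vGluT1) and the post-synaptic
compartment with the scaffolding protein Homer1. Each channel shows small,
bright, blob-like objects ("puncta") of roughly 0.2--0.6 um diameter; a
pre-channel punctum spatially overlapping a post-channel punctum is taken as
the signature of a glutamatergic synapse. The package implements:

1. a per-channel detection chain producing measured punctum objects;
2. object-based volumetric colocalization of the two channels;
3. reduction of image-level summaries to per-mouse/region records, with
   ROUT robust outlier flagging ahead of group-level statistics;
4. scheduling and scoring of a complex sensory learning task (CSLT), an
   attentional set-shifting paradigm with stages SD, CD, CDR and IDS;
5. synthetic ground-truth generators for both data types, used throughout
   the test suite and the acceptance checks.

Group-level inference (ANOVA, mixed models, post hoc contrasts) is out of
scope; the package stops at the per-group mean/SEM/n tables that feed such
models.

## Geometry and data model

Stacks are held as `VoxelGrid` objects: a numeric array ordered
`(ny, nx, nz)` with voxel sizes `c(dz, dy, dx)` in micrometres. The default
calibration follows the acquisition geometry used throughout:
60.13 nm pixels in-plane and a 0.30 um z-step. All reported coordinates use
the `(z, y, x)` convention, 0-based with half-open voxel extents, so voxel
`(z, y, x)` has its physical centre at `((z+0.5)dz, (y+0.5)dy, (x+0.5)dx)`.
The stated pixel size is treated as authoritative for all physical
conversions (nominal field-of-view figures are not used for calibration).

On disk a stack is a multi-page 16-bit grayscale TIFF (channel-fastest page
order) plus a YAML sidecar carrying calibration, channel map and image
metadata. The sidecar exists because the TIFF writer available to R cannot
embed description tags; on *read*, an OME-XML ImageDescription
(`PhysicalSizeX/Y/Z`, `SizeC`, `SizeZ`, `DimensionOrder`) is honored when a
file produced elsewhere carries one. Intensities on disk are integer
detector counts in `[0, 65535]` -- the native output of a photon-counting
detector -- which makes the write/read round trip bit-identical. Missing
calibration is always an error, never a silent default.

## The detection chain

`detectPuncta()` runs six stages per channel, all deterministic:

1. **Percentile normalization** (`p_low` = 0.1%, `p_high` = 99.9%): maps
   the two percentiles of the channel's intensities to 0 and 1 with
   clipping, removing sample-to-sample staining and gain variation.
   Normalization is per channel per stack (a cohort-wide alternative would
   couple images and was rejected to keep images independent). A constant
   grid maps to all zeros.
2. **White top-hat** (disc radius 8 px ~ 0.48 um): subtracts the
   morphological opening slice-wise, removing background structures larger
   than the disc while preserving puncta-scale features.
3. **Adaptive Wiener denoising** (3x3 window, noise variance estimated per
   slice as the mean of the local variances): pixel-wise
   `y = m + max(s^2 - nu, 0)/s^2 (x - m)`; flat noiseless regions pass
   through exactly.
4. **Multi-scale LoG** (sigmas 1.5, 2, 3 px): each slice is convolved with
   a negated, scale-normalized Laplacian-of-Gaussian kernel
   (`-sigma^2 * Laplacian(G_sigma)`, zero-sum discrete kernel so flat
   inputs respond exactly 0); the per-voxel response is the maximum over
   scales. The scales bracket the expected punctum radius at 60 nm pixels.
5. **Mask refinement**: the response is thresholded
   (`response_threshold`, default 0.12 in normalized-intensity units) into
   a binary candidate mask, then median-filtered (3x3). The median of a
   binary mask is a majority vote, computed with a separable running-sum
   box filter; it removes single-pixel speckle without eroding blob cores.
6. **Component assembly and quality filtering**: per-slice 8-connected
   components are linked across adjacent z-slices whenever their 2D
   footprints share at least one pixel; a component overlapping several
   existing puncta joins the one with the larger overlap (ties: lower id),
   so every punctum has a contiguous z-range with one footprint per slice.
   Detection is 2D-per-slice with cross-slice linking, rather than a full
   3D LoG, because colocalization downstream is defined through z-extents
   and in-plane footprint areas; per-plane footprints are the natural
   primitive for that. Surviving objects must satisfy
   `min_voxels` (4) <= size <= `max_voxels` (500) and mean normalized
   intensity >= `min_mean_intensity` (0.05).

Measured quantities per punctum: contiguous z-range, intensity-weighted
centroid in micrometres (weights from the *normalized* grid -- punctum mean
intensity is likewise computed on normalized intensities, and output
metadata records that choice), voxel count, volume
(`n_voxels * dx*dy*dz`), mean normalized intensity, and peak LoG response.

### Choosing the response threshold

The threshold is the only chain parameter without a natural physical
anchor. It was fixed once by inspecting the separation between the LoG
response distribution of background (top-hat + Wiener filtered noise) and
the response at planted puncta on the package's reference synthetic stack
(256x256x15, 150 puncta/channel, peak SNR 5): background responses stay
below ~0.13 while true puncta respond above ~0.2, so the default 0.12 sits
at the top of the background tail. It scales with normalized intensity, so
it transfers across images with similar dynamic range; for dimmer material
it should be lowered together with `min_mean_intensity`.

## Volumetric colocalization

`pairOverlap()` computes, for two puncta, the summed area of their 2D
footprint intersections over shared z-slices, converted to cubic
micrometres with the known voxel dimensions. `matchPuncta()` evaluates all
pre/post pairs with positive overlap and selects pairs greedily in
descending overlap volume (ties: ascending pre id, then post id), each
punctum participating in at most one pair. One-to-one matching keeps the
"number of colocalized puncta" per image well defined and bounded by both
channel counts; the greedy rule is deterministic and, whenever the overlap
graph is conflict-free, attains the maximum matching (the test suite
verifies it never exceeds a brute-force maximum-cardinality oracle). The
minimum overlap defaults to one voxel -- any positive overlap counts -- and
is configurable; no minimum z-extent or fractional-overlap rule is imposed,
the most permissive reading consistent with a volumetric-overlap
definition.

`summarizeImage()` reduces an image to: `n_pre`, `n_post`, `n_coloc`,
per-channel means over puncta of the punctum mean intensity, and the total
colocalized volume.

## Aggregation and ROUT outlier flagging

The analysis unit for group statistics is the mouse x region-of-interest
(MO/VO) record: the arithmetic mean of up to four image summaries
(2 hemispheres x 2 sections). Missing images are tolerated -- the mean runs
over available replicates and the count is recorded -- mirroring designs
analysed with mixed models that absorb missingness.

`routOutliers()` implements the univariate reduction of the ROUT method
(robust fit + FDR-style outlier test) at `Q` percent:

* robust location: the median (the constant model with `K = 1` parameter);
* residuals `r_i = v_i - median`; robust scale
  `RSDR = P68.27(|r|) * n/(n-K)` (the 68.27th percentile of absolute
  residuals, the percentile matching one standard deviation of a
  Gaussian, with a small-sample correction);
* residuals ranked by decreasing `|r|`; rank `i` receives the threshold
  `alpha_i = (Q/100)(n-(i-1))/n` and a two-tailed p-value from the
  t-distribution with `n-K` degrees of freedom at `t_i = |r_i|/RSDR`;
* rank `i` and all larger residuals are flagged when `p_i < alpha_i`;
  boundary ties in `|r|` are flagged together so the flag set is invariant
  to input permutation (and to affine transforms of the values).

This follows the published description of the method; the commercial
implementation's proprietary small-sample refinements are not claimed. The
68.27th percentile uses R's default (type 7) interpolation. Degenerate
inputs: all-equal values flag nothing; a zero RSDR with non-zero residuals
flags those residuals (they are infinitely many robust SDs out). Simulated
clean Gaussian samples of n = 12 at Q = 1% yield a mean flagged fraction
well below 2%, and a planted 8-sigma point is flagged in over 99% of
replicates (both recomputed by the acceptance script). Outlier removal is
applied per group x ROI cell before `groupSummary()` reports mean, SEM and
post-removal n.

## CSLT scheduling and scoring

A testing session holds 4 "free" familiarisation trials followed by up to
30 scored "closed" trials. `makeSchedule()` enumerates in the free block
each of the four bowl configurations (distractor pairing x rewarded side)
exactly once in random order, and draws closed trials with exact side
balance (15 left / 15 right), balanced pairings, and no run of same-side
trials longer than `max_run` (default 3), via seeded rejection sampling.

The learning criterion is "8 correct choices in 8--10 consecutive trials"
of a single session. Two readings are possible: any window of length 8--10
holding at least 8 corrects, or a strict run of 8 consecutive corrects
(the task description's "consecutive correct trials reset to 0" phrasing
hints at a run counter, while "8--10 consecutive trials" implies windows).
`detectCriterion()` implements the window reading as the default --
earliest closed trial `t` such that some window of length 8, 9 or 10
ending at `t`, contained in one session, holds >= 8 corrects -- and exposes
the strict-run variant via `mode = "run"`. Windows never span sessions;
omissions (no bowl choice within 120 s) count as non-correct. The window
implementation is verified exhaustively against a window-enumeration
oracle on all single-session sequences up to length 12.

`scoreStage()` excludes free trials and reports: total closed trials up to
and including the criterion trial (summed across sessions -- a mouse that
fails a 30-trial session resumes the same stage next day with the count
carried forward), total errors (incorrect + omission) among those trials,
and the median choice latency over the same trials with omissions' missing
latencies excluded (the latency window is this package's choice; only
"median latency to a bowl choice" is inherited). If the criterion is never
met, totals cover all closed trials and the criterion is reported as not
reached.

## Synthetic data generators

`simulateStack()` emulates the acquired stacks: puncta rendered as
isotropic in-plane Gaussians (sigma 1.5--2.5 px) with a triangular
intensity profile across a 3- or 5-slice z-extent, on a background of
constant level 20 counts plus a 30% linear diagonal gradient, with Poisson
shot noise on expected counts plus Gaussian read noise (sd 2 counts),
digitized to integers. Peak SNR -- punctum amplitude over the background
noise sd `sqrt(b0 + sigma_read^2)` -- has a minimum given by `snr`
(default 5; per-punctum amplitudes are jittered upward by up to 50%). A
fraction `f` of post puncta is planted within `delta` = 2 px (laterally,
same central slice) of a pre punctum and labelled a colocalized pair. All
other centre placements keep a minimum separation (8 px) from every other
punctum, including across channels: without this the planted pair labels
would be ambiguous (chance appositions would be "false" positives by
label while being true appositions by geometry), and the generator's
purpose is identifiable ground truth. Default geometry is a 256x256x15
crop of the full 1024x1024x30 acquisition format so that a full cohort
simulates in minutes; the full format is available by argument.

What the generator does *not* emulate: a realistic point-spread function
(axial elongation, Airy rings), spectral bleed-through between channels,
tissue autofluorescence texture, uneven section thickness, or spatial
clustering of synapses. Passing recovery tests on these stacks therefore
demonstrates the correctness and stability of the chain's geometry and
bookkeeping at realistic densities and noise levels -- not field
performance on tissue, whose thresholds would need tuning against expert
annotation.

`simulateBehavior()` draws closed-trial outcomes from an exponential
learning curve `p_t = p_inf - (p_inf - p0) exp(-t/tau)` (cumulative trial
index `t` across sessions, so learning persists overnight), independent
omissions at a fixed rate, and log-normal choice latencies capped at the
120 s limit. Defaults (`p0` 0.5, `pinf` 0.95, `tau` 10 trials, omission
rate 0.01, median latency 10 s) represent a mouse starting at chance and
learning within one to two sessions, consistent with the task's design
target of one stage per daily session; the omission rate is low because
omissions were rare in practice. Sessions truncate at 30 closed trials and
end early at criterion.

## Pipeline and reproducibility

`runPipeline()` executes generate/read -> detect (both channels) -> match
-> summarize -> aggregate -> ROUT flag -> group summary, plus the
behavioral arm, from a single configuration list (YAML-loadable). Every
per-image and per-mouse seed is derived deterministically from the master
seed, the fully-resolved configuration and its MD5 hash are written next
to the outputs together with a run log, and a rerun with the same
configuration reproduces all tables byte-identically. Tables are written
as CSV with 17-significant-digit numerics so they re-read losslessly. A
stage failure aborts with the stage name; completed tables are retained.
The demo cohort (2 groups x 8 mice x 2 ROIs x 4 images, plus 4 behavioral
stages per mouse) runs end-to-end on one CPU in under ten minutes.

The command-line front end (`inst/scripts/synaptoscope`) exposes each
stage as a subcommand (`simulate-stack`, `detect`, `colocalize`,
`aggregate`, `simulate-behavior`, `score-behavior`, `run-all`) as a thin
wrapper over the exported functions.

## Numerical choices and edge cases

* Percentiles everywhere use R's default type-7 interpolation.
* The candidate mask uses `response >= threshold`; the binary median uses
  strict majority (ties impossible for odd windows).
* Component linking ties (one component overlapping two previous puncta
  equally) resolve to the lower punctum id; the choice only affects object
  identity, not total volume.
* Zero-intensity puncta (possible only on degenerate input) fall back to
  unweighted centroids.
* Empty detection results, empty channels and zero-row tables are valid
  values, not errors, and propagate as zero counts / `NA` means.
* Morphological operations on float slices can leave tiny negative
  residues; outputs are clamped at 0.
* Greedy matching is O(candidates x pairs) with small constants; candidate
  overlap counting uses per-slice label maps, so cost scales with punctum
  area, not image volume.

## Problem sizes used by the test suite

Unit tests run on stacks from 32x32x1 up to 160x160x8; the end-to-end
recovery checks use the reference 256x256x15 geometry with 150 puncta per
channel (recall/precision >= 0.9 at peak SNR 5; planted pair count
recovered within 10% at f = 0.5 over 5 seeds); the behavioral criterion is
checked exhaustively over all 8,190 outcome sequences up to length 12; the
ROUT simulations use 1,000 replicates of n = 12. These sizes were chosen
so the full suite completes in minutes while exercising the documented
claims at the reference conditions.

## Known limitations

* Detection thresholds are calibrated on synthetic data; real tissue
  requires re-calibration of `response_threshold`, size bounds and
  `min_mean_intensity` against annotated examples.
* The univariate ROUT reduction follows the published formulas; exact
  numeric agreement with the commercial implementation's proprietary
  corrections is not claimed.
* Colocalization is overlap-based only; sub-voxel apposition without
  shared voxels (common at axial interfaces given 0.30 um z-steps) is not
  counted, and no chromatic-shift correction is applied.
* The criterion's window-vs-run ambiguity is resolved in favour of
  windows; both readings are available, and scores can differ between
  them for interleaved error patterns.
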