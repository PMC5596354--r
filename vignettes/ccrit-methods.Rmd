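---
title: "CCRIT: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CCRIT: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Single-molecule FISH chemistry ties a roughly constant amount of fluorophore
to each transcript, so the summed probe intensity over a cell is proportional
to its transcript count even when individual diffraction-limited spots are
too crowded to resolve. CCRIT therefore reports, per cell,

    I_cell = sum over the cell's nucleus-mask pixels of (F - b)+

where `F` is the FISH-channel image, `b` is the mean intensity over a
background mask (digital noise subtraction), and `(x)+` floors at zero.
This is a *relative* measure: it supports comparisons across cells and
genotypes imaged under the same settings, not absolute transcript counts.

Assumptions worth stating:

* the nuclear stain (e.g. DAPI) marks the compartments of interest and the
  probe signal of a cell lies within (or is attributed to) its nucleus blob;
* background noise is spatially uniform enough per slice that one scalar per
  slice captures it;
* acquisition settings (gain, laser power, pinhole) are constant within a
  comparison.

## The masking stage

All masks derive from the maximum-intensity projection (MIP) of the nuclear
channel, so masking is identical on every slice. The MIP's intensity range
`[min, max]` is split into `n_bins = 100` equal-width bins; the bin *upper
edges* are the candidate thresholds. Two readings of "the maximum intensity
value of a bin" exist — the bin's upper edge, or the largest observed value
inside the bin; the upper edge is used because it is a deterministic,
data-independent grid. With an even bin count, "the central bin" needs a tie
rule: index `n_bins/2`, i.e. the midpoint `min + 0.5 (max - min)`. Pixels
strictly above it form the nucleus mask; candidate background masks use
strictly below, so pixels exactly at a threshold belong to neither.

Each candidate background mask is scored by the area-weighted mean solidity
of its blobs, `sum(area_b * solidity_b) / sum(area_b)`, and the minimum
wins (ties to the lowest threshold). The intuition: at the correct
threshold the mask is the full inter-nuclear dark field — a ragged web whose
convex hull far exceeds its area — while thresholds inside the background's
own intensity spread produce compact (or tiny, hence convex) regions, and
thresholds up in the nuclear range start swallowing the bright discs. On
8-bit-style integer data the below-threshold masks change only when a
threshold crosses an integer level, which keeps the candidate family well
behaved.

Solidity uses an exact lattice definition: the convex area of a blob is the
number of pixel centres inside-or-on the convex hull of the blob's pixel
centres (for collinear blobs, the lattice points on the segment). This makes
`solidity <= 1` exact, and `solidity == 1` for every rasterised convex shape
including straight lines — properties the tests assert against an
independent point-in-polygon oracle. Since hull vertices are boundary
pixels, only boundary pixels are fed to the hull computation.

Refinement applies three stages in order, with the field-standard readings
of the stated sizes:

1. morphological opening with a disk of radius 5, then removal of blobs with
   area < 50 px² ("opening size 50" read as a minimum surviving area,
   "disk 5" as the structuring element);
2. erosion with a disk of radius 10 ("size 10" read as a radius; a diameter
   reading halves the effect and is available by setting
   `erosion_radius = 5`);
3. filling of interior holes of area <= 1500 px² (the stated "1500" read as
   a maximum hole area — it cannot be an opening size, as filling is not an
   opening).

Erosion matters beyond denoising: it severs the thin corridors that connect
the dark centre of each photoreceptor ring to the surrounding dark field, so
each ommatidium contributes one interior background blob whose centroid is
the natural anchor for cell assignment.

## Anchors and cell assignment

Anchors are the refined background blobs, processed in row-major order of
centroid and labelled A, B, C, … One large background component — the
inter-ommatidial web — always remains, touches the frame border, and has a
centroid near the frame centre; if used as an anchor it would compete for
the central ommatidium's nuclei. Border-touching background blobs are
therefore excluded from anchoring (`drop_border_anchors = TRUE`; the full
refined mask still serves as the noise-sampling space). In densely imaged
retina fields the genuine per-ommatidium pockets are always interior, so
this is a structural, not a tuned, rule.

For each anchor, nucleus-centroid distances are sorted ascending and their
forward differences scanned for the first positive local maximum that
dominates the rest: `d[i] > gap_factor * median(d[-i])`, with
`gap_factor = 3` and the median taken over the *other* differences (an
all-inclusive median makes a single dominant gap impossible to detect in
two-nucleus profiles; the leave-one-out form handles short and long profiles
uniformly). The index of that gap is the near count, capped at 7 — R8 nuclei
do not appear in the imaged planes. If no gap qualifies, all (up to 7)
nuclei are taken. Competing claims go to the nearer anchor, ties to the
earlier label; unclaimed nuclei are reported and excluded.

Cells are numbered counter-clockwise by the angle
`atan2(-(row - row0), col - col0)` (image north up), starting from the
smallest non-negative angle — i.e. from image east. Only the counter-clockwise
*order* is meaningful; the start cell is a convention.

## The conventional spot counter

The baseline counts connected components of the LoG-filtered image above a
threshold chosen automatically from the spot-count-versus-threshold curve
(100 thresholds spanning `(0, max response]`). The LoG kernel (default
`hsize = 8`, `sigma = 0.8`) is negated so bright spots respond positively,
and shifted to sum to exactly zero; responses below the convolution's
floating-point error bound are snapped to zero so constant images yield no
response. Borders use symmetric reflection, avoiding spurious edge
responses. With an even `hsize` the kernel origin is at index
`hsize/2 + 1`, fixed so that a unit impulse reproduces the kernel exactly.

Threshold selection restricts to the positive-count range and takes the
position of minimum absolute forward difference of the counts. When that
minimum is zero — exactly equal consecutive counts — the first position of
the *longest* equal-count run is used rather than the first zero anywhere:
a genuine plateau ("most resilient to noise") should beat an accidental
equal pair lower down the curve. Remaining ties go to the lowest threshold.

At the pipeline level, `run_spotcount` additionally requires the plateau to
be real before trusting it: the longest equal-count run must span at least
`plateau_min_frac = 0.3` of the threshold grid. A pure-noise slice produces
a steeply decaying curve whose longest accidental run covers a few bins
(extreme-value spacings of the noise maxima), far below 30; a slice with
well-separated spots at reasonable SNR produces a constant-count band
covering most of the grid (about 70 of 100 bins in the synthetic spot
fields). Slices without a qualifying plateau report 0 spots with a warning —
this is what makes the counter return zero on transcript-free specimens
instead of dignifying noise with a count. The 0.3 default is deliberately
far from both regimes; it is configurable, and the whole-curve object is
returned for inspection (`autoplot()` shows the curve with the selected
point, log count axis).

One documented alternative: differentiating log-scaled counts instead of raw
counts. Raw counts are used; on log scale the tail (counts of 1–2) acquires
artificially small derivatives and pulls the selection off the plateau.

## Quantification details

* Noise subtraction floors at zero. Allowing negative residuals would let
  background fluctuations cancel genuine signal in sparse cells; the cost is
  a small positive bias that is identical across cells and genotypes (it is
  the reason knockout specimens quantify a few percent above zero rather
  than at zero).
* `CENTRAL80` trims 10 % of slices from each end: 0-based slice indices
  `floor(0.1 n) … ceil(0.9 n) - 1` (for `n = 10`, eight central slices).
  With fewer than two slices it falls back to `ALL` with a warning.
* `MAX` takes the slice with the largest whole-frame processed total — one
  slice for all cells, the literal reading of "the maximum-intensity slice";
  its per-cell `sd` is undefined (NA).
* Stack-level summaries are reported in both averaging orders — cells
  averaged within ommatidia first (`by_ommatidium`, the headline number) and
  a direct pool over cells (`pooled`) — since the two differ when ommatidia
  have unequal cell counts.
* The optional Gaussian smoothing stage (`smooth_sigma = 0.8`, 0 disables)
  runs after masking; it redistributes intensity within the cell regions and
  slightly bleeds across mask edges, which is why the doubling-linearity
  test carries a small tolerance rather than exact equality.

## The synthetic specimen generator

The generator emulates the structure the pipeline exploits, with defaults
fixed once from geometric and SNR analysis:

* 512 × 512 px frame, 10 slices; 9 ommatidia on a jittered 3 × 3 grid of
  pitch 120 px (= 3 ring radii); 7 nuclei of radius 14.5 ± 0.5 px at
  jittered equal angles on a 40 px ring. The tight ring is deliberate:
  worst-case gaps between neighbouring nuclei (~10 px) stay below the 11 px
  opening diameter, so each ring's dark centre seals into one interior
  anchor blob, while the ring centre keeps ~25 px of clearance so the
  disk-10 erosion leaves a substantial pocket.
* Nuclear channel: soft-edged discs of amplitude 180 over a flat background
  of 20, pixel noise sd 0.15, rounded to integers. The channel is modelled
  at high SNR — it is the geometry input, and robustness of masking to
  nuclear-channel noise is not a validation target. Real data add smooth
  illumination gradients and out-of-focus structure that this deliberately
  omits; consequences of that omission are discussed below.
* FISH channel: per expressing cell, `round(level * 40)` spots of amplitude
  150 ± 10 % and PSF sigma 1.6 px, placed uniformly inside the nucleus disc
  on a uniformly chosen slice; background Gaussian noise mean 6, sd 1.2,
  the sd growing 3 % per slice (signal-to-noise decays with imaging depth);
  floored at zero and rounded. The seventh cell of every cluster receives
  no spots, mirroring one probe-negative photoreceptor per cluster.
* A genotype series maps relative expression levels to planted spot counts;
  levels 1 / 0.7 / 0 emulate wild type, heterozygote and homozygous-null
  specimens. Everything is reproducible bit-for-bit under a seed, and the
  planted ground truth (nuclei, spots) is returned and exportable so every
  downstream metric is computable without re-generation.

What passing the synthetic validation shows: the implementation of every
stage is correct against its contract, the linear intensity–transcript
relationship survives the full pipeline (R² > 0.98 across five expression
levels), assignment recovers the generating ommatidium for ≥ 95 % of nuclei,
and the spot-count baseline behaves as expected in its easy (sparse,
high-SNR) and null (no transcript) regimes. What it does not show:
robustness to optical-sectioning physics (a 3-D PSF), smooth illumination
gradients, autofluorescent structures, chromatic offsets between channels,
or segmentation of non-ring cell geometries. Parameters validated here for
photoreceptor-like layouts (opening/erosion/infill sizes in particular)
need re-validation for other cell types.

## Numerical and degenerate-input choices

* Convolutions are direct (shift-and-add) with reflective borders — exact,
  and fast for the ≤ 15 px kernels involved.
* Connected-component labeling is a compiled two-pass union-find with
  selectable 4/8-connectivity (default 8), renumbered in deterministic
  first-touch order; a pure-R flood fill serves as the test oracle.
* Boundary tracing follows the Moore neighbourhood clockwise; termination
  re-enters the start pixel from an already-seen direction, which reduces to
  the classic stopping criterion on well-behaved blobs but also terminates
  on one-pixel-wide arms, where the walk legitimately passes the start twice.
* Constant images are rejected where a threshold grid would be degenerate
  (`candidate_thresholds`, `spot_curve`); callers at the pipeline level
  convert the spot-curve case into a 0-spot report.
* Background-candidate scoring does not retain the 100 full-frame masks
  (hundreds of MB at 512²); the winning mask is re-materialised from its
  threshold, which is exact since masks are pure threshold functions.
* Problem sizes in the test-suite: unit tests run on 256 px four-ommatidium
  specimens and ≤ 40 px oracle images; the validation experiment uses the
  full default conditions (15 specimens for linearity, 10 seeds for
  assignment, 5 for discrimination).

## Known limitations

* The anchor model requires one dark pocket per cell cluster; tissues
  without enclosed dark centres need a different anchoring rule.
* A nucleus pair that touches in the mask merges into one blob and is
  quantified as one cell (the scoring utility attributes such merges by
  containment).
* Intensities are arbitrary units; nothing calibrates across imaging
  sessions.
* The spot counter is intentionally the *conventional* baseline: no spot
  quality scores, no sub-pixel localisation, no per-slice parameter
  re-optimisation.
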