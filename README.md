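# ccrit

Cell-by-cell relative integrated transcript (CCRIT) quantification for
single-molecule RNA FISH microscopy.

## The problem

smFISH and RNAscope label individual mRNA transcripts so that each appears as
a diffraction-limited fluorescent spot in a confocal z-stack. The standard
way to quantify expression is to count those spots: Laplacian-of-Gaussian
(LoG) filter each slice, threshold, and count connected components. That
works for sparse, clean signal, but fails for crowded transcripts (spots
merge into unresolvable clusters) and for noisy, deep-tissue slices — the
typical situation in a *Drosophila* whole-mount retina, where Rhodopsin 1
(*Rh1*/*ninaE*) mRNA is so abundant in photoreceptors R1–R6 that individual
spots are not separable.

`ccrit` implements an alternative: instead of counting spots, it measures
the **integrated probe intensity per cell**. Because single-molecule probes
bind a bounded number of fluorophores per transcript, total intensity scales
linearly with transcript number even when spots are not resolvable. The
workflow, for a dual-channel stack (nuclear stain + FISH signal):

1. **Maximum-intensity projection (MIP)** of the nuclear channel, so masking
   is consistent across all slices.
2. **Nucleus mask** — the MIP's intensity range is split into 100 equal bins
   whose upper edges are candidate thresholds; the central bin's threshold
   separates nuclei from background.
3. **Background mask** — every candidate threshold produces a below-threshold
   mask; each is scored by the area-weighted mean *solidity* (blob area /
   convex-hull area) of its connected components, and the minimum-solidity
   candidate wins. The mask is then refined by a disk-5 opening (dropping
   blobs under 50 px²), a disk-10 erosion, and filling of holes up to
   1500 px².
4. **Cell assignment** — each interior background blob anchors one
   ommatidium; sorted anchor-to-nucleus centroid distances show a near/far
   gap (found as a dominant peak in their forward differences), the near
   nuclei join the ommatidium, and cells are numbered 1–7 counter-clockwise.
5. **Quantification** — per FISH slice, the mean intensity over the
   background mask is subtracted (floored at zero), the nucleus mask is
   applied, the result optionally Gaussian-smoothed, and each cell's pixel
   intensities are summed. Summaries cover all slices, the central 80 % of
   slices, or the maximum-intensity slice.

The package also includes the conventional automated LoG spot counter it is
compared against (with automatic threshold selection from the noise-resilient
plateau of the spot-count-versus-threshold curve), and a ground-truthed
synthetic specimen generator, so the whole pipeline is testable without any
real microscopy data.

## Worked example

```r
library(ccrit)

# a synthetic wild-type-like specimen: 9 ommatidia x 7 nuclei, 512x512x10,
# 40 transcript spots planted per expressing cell (cells 1-6 of each cluster)
sp  <- synth_specimen(level = 1, seed = 42)
res <- run_ccrit(sp$nucleus, sp$fish)
res
#> <ccrit_result> 9 ommatidia, 62 cells, 10 slices
#>   background threshold: 21.81; mean slice noise: 6.002

glance(res)         # one-row overview (counts, threshold, mean intensity)
tidy(res)           # per-cell, per-slice integrated intensities
specimen_mean(res)  # stack-level mean (cells -> ommatidia -> stack)

autoplot(res)                       # per-cell intensity bars by ommatidium
plot_cell_map(res)                  # lettered/numbered cells on the MIP
write_cell_table(res, "out/ccrit")  # out/ccrit_cells.csv + out/ccrit_summary.csv
```

The printed background threshold (21.8) sits just above the synthetic
background ceiling (~21), i.e. the minimum-weighted-solidity rule recovered
the correct masking threshold; 62 of the 63 nuclei were detected and every
detected one was assigned to its generating ommatidium (two nuclei merged
into one blob in this seed). For the conventional baseline:

```r
counts <- run_spotcount(synth_spot_field(n_spots = 20, seed = 5)$fish)
counts$count
#> [1] 20 20 20 20 20 20 20 20 20 20
```

A thin command-line wrapper is included at `inst/cli/ccrit.R`
(`run`, `spotcount`, and `synth` subcommands over TIFF/CSV files).

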