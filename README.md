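# emdiffmap

Difference mapping of electron microscopy 2D class averages for localizing
subunit domains in large protein complexes.

## The problem

When a multi-subunit complex (for example the ~30-subunit Mediator
coactivator of RNA polymerase II transcription) is imaged by negative-stain
EM, individual subunit domains cannot be assigned directly from a class
average. A classical solution is to image a *variant* of the complex — one
carrying a fused bulky tag such as maltose-binding protein (MBP, ~40 kDa)
on a subunit terminus, or one lacking a defined domain (a truncation
mutant) — and subtract an aligned wild-type class average from the
variant's average. The extra (tag) or missing (truncation) density then
stands out in the difference image and marks the position of the labeled or
deleted domain.

`emdiffmap` implements this procedure end to end and pairs it with a
synthetic-data module that provides ground truth, so localization accuracy
and false-positive behaviour can be validated quantitatively:

1. **Normalization** — every class average is rescaled to mean density 0
   and standard deviation 1.0, making pairs comparable regardless of stain
   depth or detector gain.
2. **Alignment** — FFT cross-correlation over shifts (zero-padded, exact
   against an exhaustive integer-shift search) with an exhaustive rotation
   grid, subpixel refinement by locally upsampled correlation, and manual
   fine-tuning offsets.
3. **Difference map** — `D = variant − aligned reference`, expressed in
   standard-deviation units `z = D / σ_bg`, where `σ_bg` is the robust SD
   (1.4826·MAD) of the difference over the joint background, so `z` reads
   as a noise-referenced significance.
4. **Region extraction and localization** — 8-connected components of
   `{z ≥ z_t}` and `{z ≤ −z_t}`, area-filtered, with |z|-weighted
   centroids in pixels and Angstrom; deletion experiments are computed as
   wild type minus truncation, so the missing domain appears positive.
5. **Pair ranking** — when several averages are available for each state,
   every cross pair is scored as `cc − clutter` (correlation after
   alignment minus the fraction of stray significant pixels) to find the
   pair giving the cleanest difference map.
6. **Simulation** — Gaussian-blob phantoms of a complex, ZYZ-Euler
   projections, and simulated class averages (n jittered, noisy copies of
   a projection, averaged) with a TSV manifest of true tag/deletion
   positions.

## Worked example

Simulate an MBP-tagging experiment on the bundled 10-blob phantom (110
mass units, 3.98 A/px) and localize the tag:

```r
library(emdiffmap)

ph <- mediator_phantom()
print(ph)
#> Gaussian-blob phantom: 10 blobs, box 64^3 voxels @ 3.980 A/voxel
#> ...
#> total weight: 110

cfg <- run_config("tag", outdir = "run_tag", seed = 42)
rep <- run_pipeline(cfg)
print(rep)
#> emdiffmap run report (v0.1.0), case 'tag', seed 42
#>   best pair cc = 0.7764, rotation 8.00 deg
#>   primary region at (45.53, 33.34) px, error 0.32 px
```

The run simulates two wild-type and two MBP-tagged class averages (256
particles each at per-particle SNR 0.5), gives the tagged stack a random
in-plane pose, ranks the four cross pairs, aligns the best pair, and
thresholds the difference map at z ≥ 4. The primary positive region's
centroid lands 0.32 px (~1.3 A) from the true projected tag position
recorded in the truth manifest; `run_tag/heatmap.png` shows the difference
density coloured by standard deviation over the aligned class average, and
`run_tag/report.json` holds the full machine-readable report.

The pair-score table for the same run illustrates the cleanliness ranking:

```r
print(rep$pair_scores)
#>   ref_id variant_id cc_after_alignment    clutter     score
#> 1      2          2          0.7763758 0.03100586 0.7453699
#> 2      1          2          0.7748027 0.03417969 0.7406230
#> ...
```

`run_config("deletion", ...)` runs the truncation analogue (wild type minus
mutant, deleted domain appears as positive density) and
`run_config("control", ...)` the wild-type-vs-wild-type specificity
control, which should produce no significant region.

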