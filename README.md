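# myoquant

Automated quantification of satellite-cell (myoblast) cultures from
multi-channel immunofluorescence micrographs, with a fully synthetic test
bed.

## The problem

Satellite cells are the resident stem cells of skeletal muscle. In culture
studies of muscle regeneration — for example, comparing coating substrates
such as matrigel against fibrin-based hydrogels — their behaviour is scored
from fluorescence micrographs stained with DAPI (nuclei) plus myogenic
markers: Pax7 (satellite cells), MyoD (activated myoblasts), MyoG
(differentiating myoblasts) and MyHC (myotubes). Counting hundreds of nuclei
per field by eye is slow and subjective, so the counts are automated:

1. **Split channels** — each antibody is processed independently.
2. **Threshold** — every channel is binarized with the IsoData (iterative
   intermeans / Ridler–Calvard) auto-threshold.
3. **Segment nuclei** — watershed segmentation on the DAPI channel splits
   touching nuclei; segments outside an acceptable size window of
   **15–230 px** are artifacts, and segments at the image edge (partial
   nuclei) are discarded.
4. **Determine nucleus staining** — each nucleus outline is projected onto
   the green and red channels; the nucleus counts as stained when a
   size-filtered marker segment falls within it, and double-stained when
   both do.

From the per-field counts the package computes the field's standard
summary statistics,

- proliferation index = 100 · #(Pax7⁺MyoD⁺) / #(Pax7⁺),
- differentiation index = 100 · #(MyoD⁺MyoG⁺) / #(MyoD⁺),
- fusion index = 100 · #(nuclei inside myotubes) / #(all nuclei),

where a *myotube* is a MyHC-positive object containing at least two nuclei.
Outcomes are compared across coatings and culture days by multivariable
linear regression (categorical coating and day, reference = matrigel), with
the coating × day interaction included only when a partial F-test shows a
significant improvement, and per-day contrasts of every coating against the
reference.

Because such microscope images are rarely public, the package ships a
synthetic-field generator with complete ground truth (nucleus positions,
marker states, myotube membership), so the entire pipeline — segmentation,
marker calling, indices, statistics — can be exercised and validated
end-to-end with no external data.

## Worked example

```r
library(myoquant)

p  <- scene_params(n_nuclei = 120, p_green = 0.6, p_red = 0.45,
                   p_double = 0.25, n_myotubes = 4,
                   nuclei_per_myotube = 3, seed = 42)
fg <- generate_field(p)          # renders dapi/green/red/myhc + ground truth
q  <- quantify_field(fg$stack, mode = "auto")
q
#>   coating day well field mode n_nuclei n_green n_red n_double n_myotubes
#> 1    <NA>  NA   NA    NA auto      120      72    47       21          4
#>   n_nuclei_in_myotubes
#> 1                   15

fg$truth
#> <ground_truth> 120 nuclei, 4 myotubes
#>   counts: green 72 red 47 double 21 fused 15

proliferation_index(q$n_double, q$n_green)   # 29.16667
fusion_index(q$n_nuclei_in_myotubes, q$n_nuclei)  # 12.5
```

Here the pipeline recovered all 120 nuclei, every marker call and all 4
myotubes exactly (compare `q` against `fg$truth`); the indices are then
plain ratios of the counts, in percent.

A full simulated study (coatings × days × wells × fields, TIFFs + manifest
on disk, pooled well indices, regression report) runs from one config:

```r
res <- run_pipeline(list(
  out_dir = "study",
  seed = 1,
  design = list(coatings = c("matrigel", "fibrin"), days = c(5, 9)),
  scene = list(n_nuclei = 150)))
res$summary                      # per coating x day mean (SD) over wells
res$contrasts                    # coating-vs-matrigel estimates per day
```

The same stages are scriptable from the shell via
`inst/cli/myoquant.R {simulate|quantify|indices|stats|validate|run-all}`.

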