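# vesiquant

Object-based colocalization and co-transport analysis for endosomal
vesicle imaging in R.

## The problem

Membrane markers such as EGFP-tagged Rab GTPases decorate the *surface*
of endosomes and image as rings; a lumenal cargo (for example an
mCherry-tagged viral envelope glycoprotein) fills the *inside* of the same
endosome. The two signals label one organelle while sharing almost no
pixels, so pixel-wise colocalization (Pearson, Manders) understates — or
inverts — the association. The right statistic is object-based: build a
filled region of interest (ROI) per marker-positive endosome, score the
cargo channel inside each ROI as above or below background, and report

    percent positive = 100 · (# cargo-positive endosomes) / (# endosomes),

with a Wilson 95% interval for the binomial uncertainty. Each object's
call compares its mean cargo intensity against a robust background
threshold, median + k·1.4826·MAD (k = 3 by default), estimated outside
the dilated ROI mask.

For time-lapse stacks the package also links detections into
trajectories, computes per-track mean squared displacement
MSD(τ), classifies motion from the log–log slope α (directed α ≥ 1.4,
diffusive 0.7 ≤ α < 1.4, confined α < 0.7; for diffusion MSD(τ) = 4Dτ),
and measures the fraction of cargo vesicles co-transported with attached
punctate particles.

Raw acquisitions of this kind are rarely deposited, so the package
includes a seeded synthetic microscopy generator (ring + lumen geometry,
Gaussian PSF, Poisson shot noise, Gaussian read noise, three motion
models) with complete per-vesicle and per-track ground truth; every
pipeline stage is validated against it.

## Worked example

```r
library(vesiquant)

cfg <- simulation_config(n_vesicles = 30, coloc_fraction = 0.5, seed = 7)
sim <- simulate_field(cfg)

marker <- get_frame(sim$stack, "marker")
cargo  <- get_frame(sim$stack, "cargo")

rois  <- detect_vesicles(marker)
bg    <- estimate_background(cargo, rois$label_map)
calls <- classify_objects(cargo, rois, bg, k = 3)
percent_positive(calls)
#> coloc_summary: 7 / 30 positive = 23.3% (95% CI 11.8-40.9)

mean(sim$truth$vesicles$is_cargo_positive)  # simulator ground truth
#> [1] 0.2333333

pixel_coloc(marker, cargo, rois$label_map > 0)
#> pixel_coloc over 2878 px: Pearson r = -0.113, M1 = 0.127, M2 = 0.946
```

The object-based estimate recovers the realized ground-truth fraction
exactly, while the masked Pearson coefficient is *negative* on the very
same vesicles — bright ring pixels are dim lumen pixels — which is the
whole argument for scoring per object.

End-to-end runs are driven by a YAML config:

```yaml
simulation:
  image_height: 256
  image_width: 256
  n_vesicles: 25
  coloc_fraction: 0.5
seed: 7
```

```sh
Rscript inst/cli/vesiquant.R run-rab-coloc --config demo.yaml --outdir out
# [vesiquant] detected 25 vesicle ROI(s)
# [vesiquant] 12 / 25 cargo-positive (48.0%)
```

which writes `per_object.csv`, `summary.csv` and a `provenance.yaml`;
reruns with the same config and seed are byte-identical. The subcommands
`simulate` and `run-cotransport` (tracking, MSD, motion classes,
co-transport fraction) work the same way.

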