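# rootpouch

High-throughput 2D root phenotyping from growth-pouch images, in R.

Seedlings grown in paper-based pouches are photographed as bright root
systems on a dark filter-paper background. Turning those images into
trait tables is corrupted by two artifacts: small bright particles
(root debris, dust, paper fibres) that a global threshold counts as
extra **root tips**, and — when imaging in air instead of submerged in
water — bright water menisci along root edges that inflate apparent
root width and length. `rootpouch` is for root biologists and
quantitative geneticists who need trait tables they can trust at
GWAS scale: it implements the background-cleaning segmentation
pipeline, the trait extraction, a synthetic-image generator with
analytic ground truth to validate the whole chain, and the statistics
that qualify such a platform for genetic mapping.

## What it computes

**Cleaning** (`clean_image`): RGB → CIELAB lightness → percentile
contrast stretch → global threshold (Otsu by default) → connected
components → reject components below an area cut-off or too far from
the image centre (rulers) → multiply the surviving mask with the image.

**Traits** (`measure_all`): from the cleaned mask and the pixel scale
(cm ruler, one shot per imaging session), via a pruned medial-axis
skeleton with a distance-transform radius at every pixel:

| morphological | architectural |
|---|---|
| TRL total root length (cm) = Σ lᵢ | TRW width (cm) |
| TSA surface area (cm²) = π Σ dᵢ lᵢ | TCA convex area (cm²) |
| TRV volume (cm³) = π/4 Σ dᵢ² lᵢ | SOL solidity = root area / TCA |
| DIM mean diameter (mm) = Σ dᵢ lᵢ / Σ lᵢ | COPM centre of projected mass (cm below junction) |
| TRT tip count (skeleton endpoints − collar) | RDI fraction of surface area in the lower ⅔ of rooting depth |
| TSA1, TSA3 surface area in the 0–0.5 / 1.0–1.5 mm diameter classes | |

**Synthetic validation** (`generate_model`, `render_scene`): parametric
tap-plus-laterals root systems with analytic truth traits, rendered
with configurable debris particles and meniscus halos.

**Statistics** (`r_squared`, `paired_t`, `heritability`,
`count_linkage_blocks`, `bonferroni_block_threshold`): tip-count
validation, air-vs-water comparisons, broad-sense heritability
H² = Vg/(Vg + Ve/r) from replicated genotypes, and linkage-block
Bonferroni thresholds −log10(α/B) for association scans.

## Worked example

Generate a synthetic pouch image with known truth, clean it, measure
it:

```r
library(rootpouch)

model <- generate_model(root_model_params(n_laterals = 60, seed = 3))
scene <- render_scene(model, scene_params(seed = 3, debris_count = 30))
cl    <- clean_image(scene$image, default_cleaning_config(50))
rec   <- measure_all(cl$cleaned_mask, pixels_per_cm = 50)

model$truth
#> TRL=96.1 TSA=14.9 DIM=0.495 TRV=0.216 TRT=61 TSA1=7.85 TSA3=1.77
#> TRW=4.36 TCA=66.2 RDI=0.589 SOL=0.0698 COPM=8.88
rec["TRT"]
#> TRT
#>  61
```

All 30 debris particles were removed by the cleaning stage — the tip
count matches truth exactly. On the *uncleaned* mask the same image
counts 92 tips, 31 of them false.

The self-contained validation experiment (16 images spanning the
observed tip-count range, each with 10–60 debris particles):

```r
cmd_validate(run_config(seed = 1))
#> <validation_result> n=16  R2 cleaned=1.000  uncleaned=0.759
```

Cleaning lifts the truth-vs-measured tip-count R² from ~0.76 to ~1.00
— the debris-driven gap this pipeline exists to close.

GWAS support, from the command line:

```sh
inst/scripts/rootpouch gwas-threshold --alpha 0.05 --blocks 212612
#> -log10 threshold = 6.6
```

Other subcommands: `synth`, `clean`, `measure`, `pipeline` (batch
directory → CSV), `validate-tips`, `herit`. Run `rootpouch` with no
arguments for usage.

## Further reading

`vignettes/rootpouch-methods.Rmd` documents the model assumptions, the
numerical choices (threshold behaviour on anti-aliased edges, skeleton
length estimation, diameter parity correction), what the synthetic
world does and does not emulate, and known limitations.
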