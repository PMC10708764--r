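---
title: "Methods: forest above-ground biomass inversion with forestagb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forest above-ground biomass inversion with forestagb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestagb)
```

## The estimation problem

Field inventories measure trees; carbon accounting needs wall-to-wall
biomass maps. `forestagb` implements the standard bridge between the two
for mixed temperate forest: per-tree above-ground biomass (AGB) from an
allometric model, aggregation to inventory plots, a catalogue of
co-registered remote-sensing predictors at the plot locations, correlation
screening, and competing regression models that are finally applied
pixelwise to the predictor rasters.

Three model families are compared throughout, because they bracket the
bias–flexibility trade-off practitioners face:

* a **stepwise linear regression** (forward entry / backward removal on
  F-test p-values, thresholds 0.05/0.10),
* a **single-hidden-layer neural network** (tanh hidden units, linear
  output) trained by **Levenberg–Marquardt** (LM) damped Gauss–Newton,
* the same network with weights first optimised by **particle swarm
  optimisation** (PSO), then LM fine-tuned.

## Allometric plot biomass

Per-tree biomass follows the power law

$$W = a\,D^{b}\,H^{c},$$

with $D$ the diameter at breast height (cm), $H$ tree height (m), and
defaults $a = 0.0470$, $b = 2.1181$, $c = 0.7088$, a published parameter
set for mixed temperate stands. The output unit is carried as an opaque
label (`"kg"` by default) and never converted: the source convention for
such equations is kilograms per tree with $D$ in cm and $H$ in m, but the
equation's printed form does not state units, so the package treats the
scale as metadata. Plot AGB is the sum over member trees; per-hectare
normalisation is available (`area_ha`) but off by default because plot
areas are rarely recorded in inventory extracts. `species_share()`
reproduces the usual composition summary (dominant oak near a quarter of
total biomass in the default simulation).

## The 86-variable predictor catalogue

Per plot the catalogue holds, by construction,
$6 + 7 + 48 + 2 + 20 + 3 = 86$ named variables:

* optical bands B2–B7 (surface reflectance in $[0,1]$);
* seven vegetation indices (NDVI, SAVI, DVI, RVI, ARVI, EVI, NDPI), with
  band roles BLUE = B2, RED = B4, NIR = B5, SWIR1 = B6 (the Landsat 8 OLI
  convention);
* 48 optical texture measures: 8 grey-level co-occurrence (GLCM) measures
  (mean, variance, homogeneity, contrast, dissimilarity, entropy, angular
  second moment, correlation) for each optical band;
* VV and VH backscatter (dB) and 20 SAR texture measures: the same list
  plus ASM, maximum probability and energy (10 per polarisation, with
  "second moment" and "ASM" treated as the single quantity they are —
  this is what makes the 48 + 20 split come out);
* altitude, slope and canopy closure.

Two indices are deliberately implemented in a non-textbook form, exactly
as the regression workflow this package mirrors printed them: EVI with
coefficient 7 (not 7.5) on the blue band, and ARVI with blue entering the
numerator negatively. The conventional forms are available via
`evi_standard = TRUE` / `arvi_standard = TRUE`; the defaults follow the
printed equations because intent should not be guessed. The "SVAI" label
that sometimes accompanies the soil-adjusted index is treated as a typo
for SAVI. NDPI uses the weighted red/SWIR mixture
$(\mathrm{NIR} - (0.74\,\mathrm{RED} + 0.26\,\mathrm{SWIR})) /
 (\mathrm{NIR} + (0.74\,\mathrm{RED} + 0.26\,\mathrm{SWIR}))$.

Texture is computed on a $7\times7$ window, 64 grey levels quantized over
the raster-wide band range, co-occurrences counted symmetrically and
averaged over the four principal offsets $(0,1)$, $(1,0)$, $(1,1)$,
$(1,-1)$. None of these values is canonical in the literature; they are
the package's defaults, all configurable, and models record them so that
mapping reuses the training configuration. Optical texture is computed on
quantized reflectance, SAR texture on quantized dB backscatter. For a
degenerate (constant) window the GLCM correlation is undefined; the
package reports 0 there, by convention and documented as such.

## Screening

Plot biomass is first cleaned by an **iterated mean ± 3 SD rule**: the
bounds are recomputed on the retained set until no plot moves. A
single-pass 3-SD rule can never remove more than about one ninth of a
sample (the outliers inflate the standard deviation they are judged
against), so iteration is the only way a rule of this family can cope
with heavy contamination; every removal is logged with its iteration and
bounds. The rule (multiplier, iteration) is configurable.

Each catalogue variable is then correlated with plot biomass (Pearson
$r$, two-sided $p$ from the exact t-transform with $n-2$ degrees of
freedom), tiered at $p<0.05$ and $p<0.01$, and the $p<0.01$ tier —
ordered by $|r|$ — feeds the models. No multiple-testing correction is
applied, matching the screening practice the package reproduces; the
table records the number of tests so users can judge for themselves.

## Models

**Stepwise regression** uses `stats::lm` sub-fits with `add1`/`drop1`
F-tests; entry at $p < 0.05$, removal at $p > 0.10$ (the usual defaults
of the workflow this mirrors, which never states them). The published
eight-term model is shipped frozen in `published_model()` — intercept
$-243.422$, terms Altitude $0.090$, CanopyClosure $125.943$, ARVI
$-156.917$, EVI $73.454$, RVI $148.340$, VVEntropy $34.447$, B6Mean
$24.306$, B6 $-245.049$ — because the inventory data behind it are
confidential and it cannot be refit; the fitter exists for synthetic and
user data. Predictions are not clipped at zero; negative values are
flagged, not altered.

**LM network.** Inputs and targets are min–max normalised to $[-1,1]$ on
the training subset. Each epoch solves
$(J^\top J + \lambda I)\,\delta = J^\top e$ with the per-sample backprop
Jacobian $J$; a step is accepted only if it strictly reduces training
SSE, whereupon $\lambda$ shrinks by a factor of 10 (it grows by the same
factor on rejection, with an overflow stop at $10^{10}$). Defaults
$\lambda_0 = 10^{-3}$, patience 6 epochs of non-improving validation MSE
(early stopping returns the best-validation weights), weight
initialisation uniform in $[-0.5, 0.5]$ scaled by fan-in, seeded. The
70/15/15 split uses floor sizes with the test set absorbing the
remainder, so 162 plots split 113/24/25. Three classical hidden-size
heuristics plus the trial range 5–20 are provided
(`hidden_size_candidates()`, `hidden_size_search()`); the second
heuristic is implemented as $\sqrt{n+m}+a$, $a \in [0,10]$ — its common
printed form drops the radical, and the literal un-rooted variant is
available behind `literal_sum = TRUE`.

**PSO network.** Particles encode the flattened weight vector; fitness is
training MSE on the normalised scale (validation data are reserved for
early stopping and selection, never fitness, to avoid leakage). The
update is the canonical
$v \leftarrow w v + c_1 r_1 (p_\text{best} - x) + c_2 r_2 (g_\text{best} - x)$
with $w$ linearly decreasing $0.9 \to 0.4$, $c_1 = c_2 = 1.49445$,
$N = 30$ particles, 200 iterations, velocity clamped to a quarter of the
box width and positions kept in bounds — standard values, supplied here
as package defaults because the six-step flow this implements prescribes
no numbers. "PSO-improved" is interpreted as PSO followed by LM
fine-tuning from the swarm optimum (the common hybrid); pure-PSO weights
are available with `fine_tune = FALSE`.

## Evaluation

`r_squared()` always exposes both quantities that get called $R^2$: the
squared Pearson correlation of predictions and observations (affine
invariant) and the coefficient of determination $1 - SS_{res}/SS_{tot}$
(penalises bias); reports label which is used — the pipeline ranks
models by the coefficient of determination. Relative errors are signed
percentages $100(\hat y - y)/y$; entries beyond $\pm 100\%$ are treated
as gross outliers and discarded before the mean absolute deviation is
computed (threshold configurable, `Inf` disables). "Mean deviation" is
the mean absolute relative error after that discard.

## The synthetic study conditions

The generator emulates a 354-plot continuous forest inventory paired with
an analysis-ready optical/SAR/terrain raster stack. Each plot has a
latent site-quality score $s \sim U(-1,1)$; clean biomass is
$2500 + 2000\,g(s)$ with
$g(s) = (s + \gamma \tanh 2s)/(1+\gamma)$, $\gamma$ the
`nonlinearity_strength`. Reflectance falls with $s$ in the visible/SWIR
bands and rises in the NIR; VV/VH backscatter rises; canopy closure and
altitude are positively linked with weaker coupling; slope is
independent. With $\gamma = 0$ and zero noise, biomass is exactly affine
in every generated feature (a property the tests exploit); with
$\gamma > 0$ the link saturates and a linear fit is provably
sub-optimal, which is how the package reproduces, as a testable
property, the qualitative finding that flexible models outrank linear
regression on this kind of data.

Trees are drawn per plot (count uniform 8–30, DBH uniform 5–45 cm,
height $1.1\,D^{0.7}$ with lognormal noise) and then rescaled so that
the allometric plot sum equals the plot's target biomass exactly — the
power-law form makes this a one-parameter rescaling, so tree and plot
tables are always mutually consistent.

A fraction $(354-162)/354$ of plots carries corrupted biomass,
emulating gross recording errors (unit mix-ups, transcription slips)
spanning orders of magnitude: corruption factors are log-uniformly
*spaced* over decades 1.5–5 and randomly assigned. Spacing rather than
iid sampling is deliberate: it keeps corrupted values separated from the
compact clean support *and from each other*, so the iterated 3-SD screen
removes exactly the planted set and the default run retains 162 of 354
plots — the calibration the study conditions demand. What the generator
does **not** emulate: radiative transfer, atmospheric or speckle effects,
spatial autocorrelation of the error field, species-specific allometry,
or geographic realism; passing tests therefore demonstrate correctness of
the machinery, not real-world accuracy.

The measured-biomass range reported for the real study
(0.56–430 "kg/hm²") is implausibly small for that unit and most likely
t/hm²; the package treats biomass units as opaque throughout and makes no
conversion.

## Rasters without a geospatial stack

No GeoTIFF library is a dependency: rasters are an in-memory
`rows × cols × bands` array with an affine geotransform, written as
multi-page 32-bit TIFF plus a JSON sidecar carrying band names, per-band
scale/offset, NA masks and georeferencing. Round trips are exact for NA
masks and accurate to 32-bit float precision for values. Pixelwise
inversion (`invert_raster()`) computes, per cell, exactly the features
the model needs with the training-time window and level settings, and is
bit-identical for any batch size; cells without a complete texture
window propagate to nodata.

## Problem sizes and determinism

Every stochastic component (generator, splits, weight initialisation,
swarm) is seeded, and each pipeline stage derives its seed from the
global one by fixed offsets, so stages are independently reproducible
and a rerun reproduces every numeric output exactly. The shipped tests
run the generator at full study scale (354 plots, 26 × 26 raster) for
the end-to-end checks and at 12–80 plots elsewhere; the model-ordering
property uses 10 seeded replicates at $\gamma = 3$ — sizes chosen to
exercise the full pipeline while keeping the suite quick on a single
CPU.

## Known limitations

* The iterated 3-SD screen is calibrated for gross, well-separated
  contamination; adversarial or clustered moderate outliers can stall
  it (robust alternatives such as median/MAD rules would be a natural
  extension, and the rule is pluggable).
* GLCM features are single-scale; no multi-window or rotation-invariant
  pooling beyond offset averaging.
* The LM trainer solves the full normal equations per epoch — fine for
  the intended network sizes (tens of inputs, 5–20 hidden units), not
  for large networks.
* Mapping assumes the predictor stack is already co-registered and
  resolution-harmonised; the package does no resampling (the optical
  and SAR sources it targets differ in native resolution, and that
  harmonisation is left to the user's preprocessing).
* `run_pipeline()` and the exported stage functions are the interface;
  there is no shell entry point.

## A worked example

```{r, eval = FALSE}
library(forestagb)
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "agb_run")
res$report          # three-model comparison on the held-out test plots
res$best_model
print(res$map)      # biomass surface, also written to agb_run/agb_map.tif
```
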