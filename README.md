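# icebg

Background modelling for X-ray diffraction images contaminated by ice
rings, for crystallographers and methods developers working on integration
pipelines.

Crystalline water ice in the sample mount adds sharp powder rings to the
diffraction background at characteristic d-spacings (hexagonal ice near
3.90, 3.67 and 3.44 Å; cubic/stacking-disordered ice near 3.67 Å).  The
constant or planar background models used by most integration programs
then bias summation-integrated intensities systematically: overestimated
on the rings (background under the peak too low), underestimated either
side (ring intruding into the background region).

`icebg` implements a global background model with per-reflection
maximum-likelihood scaling:

1. **Global model** — the masked per-pixel mean over the rotation series
   is regridded onto a polar (radius × azimuth) grid by count-conserving
   Sutherland–Hodgman polygon clipping, cleaned with a wrapped median
   filter along lines of constant resolution, completed by a Laplace
   (diffusion) fill over masked cells, and regridded back, giving a smooth
   per-pixel background shape *b*.
2. **Per-reflection fit** — for each reflection's background pixels with
   counts *cᵢ* ~ Poisson(*B bᵢ*), the maximum-likelihood scale is the
   closed form *B̂* = Σ*cᵢ* / Σ*bᵢ*, with a robust alternative on the
   Anscombe scale *y* = 2√(*x* + 3/8) using Huber weights
   *w* = min(1, *c*/|*r*|), *c* = 3, solved by IRLS.
3. **Summation integration** — *I* = Σ_fg *cⱼ* − *B̂* Σ_fg *bⱼ*, with
   variance Σ_fg *cⱼ* + var(*B̂*)(Σ_fg *bⱼ*)².

A simulator with exact ground truth (Poisson noise, radial background,
sharp/diffuse/drifting rings, Gaussian spots, detector gaps) and
diagnostics (intensity vs resolution, per-pixel index-of-dispersion
images, fourth moments of the normalised structure factors *E*) are
included, so every claim can be tested without external data.

## Worked example

Simulate a scan with a diffuse cubic-ice ring and 60 spots of true
intensity 400 placed across the ring band, build the model, and integrate
each reflection with both the global model and the classic flat baseline:

```r
library(icebg)
set.seed(1)
r <- runif(60, 440, 560); a <- runif(60, 60, 120) * pi/180
cfg <- default_presets("diffuse", n_images = 30, seed = 1,
  spots = data.frame(image = rep(1:30, each = 2), slow = 320 + r*cos(a),
                     fast = 20 + r*sin(a), intensity = 400, sigma = 1.5))
sim   <- simulate_stack(cfg)
model <- build_global_model(sim$stack, cfg$geometry)
model
#> Global background model: 640 x 640 px, range [5.171, 33.01] counts/px
#>   built from 30 images, min_images 10, median window 10
tab <- integrate_shoeboxes(sim$shoeboxes, model, cfg$geometry)
head(tab[, c("id", "image", "d", "B_global", "I_global", "I_flat")], 3)
#>   id image     d B_global I_global I_flat
#> 1  1     1 4.022   1.0192    387.7  370.0
#> 2  2     1 3.920   0.9903    383.9  345.6
#> 3  3     2 3.742   0.9816    405.5  414.2
mean(tab$I_global); mean(tab$I_flat)
#> [1] 403.6
#> [1] 392.4
```

`B_global` is the fitted scale of the global model for that shoebox
(≈ 1 here because the model already matches the per-image background);
`I_global`/`I_flat` are the summation intensities under each background
model.  Averaged over the 60 reflections the global model recovers the
true intensity (403.6 vs 400) while the flat baseline is biased low
(392.4) because the ring leaks into the background frames.  The same
comparison on the `"sharp"` preset reproduces the full spike-and-dips
signature (see `tests/testthat/test-acceptance.R` and the vignette).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/icebg.R diagnose --config run.yaml --out out/
```

with a YAML config holding the `geometry` block (`n_slow`, `n_fast`,
`pixel_size_mm`, `distance_mm`, `beam_centre_px`, `wavelength_A`) and
optional `model`, `fit` and `simulate` blocks; exit codes are 0 (ok),
2 (configuration error), 3 (data error).

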