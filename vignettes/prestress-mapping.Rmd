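---
title: "Prestress and modulus mapping from AFM force volumes: models, tip-shape optimization, and validation phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prestress and modulus mapping from AFM force volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prestressr)
```

## The measurement and the model

A force-volume (spectrum-image) acquisition indents a living cell on a
pixel grid until a force trigger is reached (3 nN for mapping, 1.5 nN for
gentler line profiles), recording at each pixel a post-contact
force-deformation curve f(d) and the contact height, which together give a
mechanical map and a topography map from the same data. Cells hold a
*tensegrity*: actomyosin-tensed fibers (tensile prestress, σ > 0) balanced
by compressed microtubule struts (σ < 0). When the tip presses on a tensed
element, the upward component of that pre-existing stress adds to the
elastic resistance; on a compressed element it subtracts, and in the
shallow range the total force can be negative — the strut bends away from
the tip. The HS model captures this as a prestress term added to Hertzian
sphere contact:

$$F = 4\pi R d\,\sigma\,\cos(\tan^{-1}\sqrt{2R/d})
    + \frac{4}{3}\,\frac{E}{1-\gamma^2}\,\sqrt{R}\,d^{3/2},$$

with the angle factor implemented as $\sqrt{d/(d+2R)}$ (the identity
$\cos(\tan^{-1}x) = 1/\sqrt{1+x^2}$; the factor is a pluggable function
argument so alternative groupings can be swapped in without touching the
fitter). Three standard alternatives are carried along for model
comparison: Hertz (sphere), Sneddon (cone, $F \propto d^2$), and the
cortical-shell-liquid-core model ($F$ linear in $d$, parametrized by a
cortical tension $T$ and the cell radius). The Poisson ratio is never
measured in such experiments; we default to $\gamma = 0.5$
(incompressible), configurable. The CSLC cell radius is likewise a user
input (default 10 µm), optionally estimated from the topography footprint.

On a cell, the *effective* tip geometry is not the nominal one: surface
slope changes the contact geometry, scanner/indenter synchronization error
couples the contact point to the topographic gradient along the scan
direction, and deeper contact engages more of the pyramid. All three are
absorbed into a linear tip-shape parametrization shared by all models,

$$R = r + a\,\partial z/\partial x + b\,\partial z/\partial y + c\,d,$$

(half-angle θ in place of R for the cone). The depth-dependent $R(d)$ is
substituted pointwise into the constant-R force expressions; no re-derived
contact solution is attempted, matching how the parametrization is used in
practice. A nonpositive effective radius (or an angle outside
$(0, \pi/2)$) at any sample is a *domain flag*: the pixel is excluded and
the event reported, never silently clamped.

## Fitting, objective, and model selection

With descriptors fixed, every model is linear in its material variates, so
each pixel is an ordinary least-squares fit of force on the model's basis
columns (`basis_functions()`); `fit_curve_linear()` imposes no positivity
constraint — a negative fitted modulus raises a flag instead, preserving
linearity and diagnosability. Degenerate designs (all depths equal,
geometry violations, curves left with fewer than 4 samples) are flagged and
masked, not errors.

`fit_map()` aggregates per-curve fitting errors (residual rms) map-wide.
Two objectives are provided:

* `"variance"` — the variance across pixels of the per-curve fitting
  error: the classic feedback quantity for descriptor search (descriptor
  errors are topography-coupled, so they inflate the *spatial
  inhomogeneity* of the misfit);
* `"sum"` — the accumulated squared residual over all curves.

`mcmc_optimize()` minimizes the chosen objective over $(r, a, b, c)$ with a
Metropolis chain: Gaussian proposals per parameter, acceptance
$\min\{1, e^{-(L'-L)/T}\}$, temperature set from the initial objective
value, both temperature and proposal scales annealed linearly (to 2% of
their starting values at 80% of the run), best-so-far descriptors tracked
and returned — a minimizer, not a posterior sampler. Defaults (10%
proposal scales with absolute floors; initial temperature $10^{-4}$ of the
initial objective) were set by probing the objective landscape: the map
objective has a long, shallow valley in which the constant radius term
trades off against the depth coupling $c$ (and, through the dome gradients,
against $a$ and $b$), so an effective search must be nearly greedy with
annealed steps; a hot chain wanders the valley and returns descriptors far
from the generating ones even when the map correlation is already high.
The same probing showed a genuine identifiability asymmetry between the two
objectives: under additive force noise the *sum* objective attains its
minimum at the generating descriptors (it is the maximum-likelihood
criterion for homoscedastic noise), whereas the minimum of the *variance*
objective can sit far along the valley — variance rewards spatially
homogeneous misfit, not small misfit. The package therefore keeps
`"variance"` as the default feedback (both objectives are always
computable and reported), but the validation experiments that score
descriptor recovery use `objective = "sum"`; users calibrating descriptors
on real maps should do the same.

Model selection never uses in-sample error: `split_train_test()` holds out
1/8 of the samples *within each curve* (one draw per consecutive
depth-block of eight samples, so test points span the depth range and every
pixel keeps enough training points to estimate its variates — a per-curve
holdout would leave test pixels with no variates at all, making the
prediction protocol impossible). `prediction_error()` fits on the training
points and scores the rms force error at held-out depths;
`compare_models()` runs the full per-model pipeline (descriptors are
optimized independently per model, since the cone's live in angle space)
and ranks ascending. On data generated by one model, that model wins; on
prestress-free data the HS model's σ fits to ≈ 0 and HS and Hertz tie at
the noise floor, both ahead of the cone and shell models.

## Depth windows, profiles, line scans

Depth-windowed maps re-fit each pixel on curves truncated to d ≤ d_max
(windows of 100 nm and 800 nm by convention: the shallow window reads the
actin cortex, the full depth the nucleoskeleton-dominated response), while
*reusing* the map-level descriptors — the tip shape is a property of the
acquisition, not of the analysis window. The full-depth window starts at
contact (0–800 nm), not at a cortex offset. `radial_profile()` bins
unmasked pixels in equal-width annuli around a chosen center (means per
bin; empty bins give NaN with count 0; normalization divides by the maximum
absolute value within range). `linescan_stats()` reduces repeated 1D scans
to the mean stress in a central window (5 µm default) and a height
statistic per repetition — the window maximum by default, configurable to
the mean.

## The virtual-cell phantom

All validation runs on `make_phantom()` / `simulate_spectrum_image()`
phantoms with exact ground truth:

* truncated-paraboloid dome topography (3 µm apex over a ~6 µm footprint:
  smooth, analytically differentiable gradients up to slope ≈ 1);
* stress fields in the tens-of-kPa range measured on living cells: tensile
  fiber segments (+40 kPa) over a compressive background (−5 kPa), with a
  base modulus of 20 kPa so the compressive background shows the shallow
  negative-force signature with a zero crossing near 300 nm (|σ|/E sets the
  crossover depth; |σ| ≥ E would keep the force negative over the whole
  measured range);
* true descriptors r = 100 nm, a = 30 nm, b = 50 nm (scan-direction
  coupling largest), c = 0.05 — a gold-coated contact-mode pyramid blunted
  to ~100 nm effective radius;
* optional scan-direction synchronization artifact (an extra b-like
  coupling injected only at simulation time, recoverable by the search);
* additive Gaussian force noise (30 pN rms, 1% of the 3 nN trigger, in the
  noisy experiments) and trigger truncation at the first sample reaching
  the threshold; curves that never trigger keep the full depth grid and are
  flagged.

Two-layer phantoms (cortex stress σ₁ above a 150 nm interface, deep stress
σ₂ below) use a *series-composite* forward curve: past the interface the
tip presses into the deep layer as a fresh contact with depth re-zeroed
there, $F(d) = F_1(t) + F_2(d-t)$, continuous by construction. This choice
was made after probing the alternative, offset-matched concatenation
$F_2(d) - F_2(t) + F_1(t)$: under that construction (and under a
depth-averaged-stress variant) the full-depth single-model refit returns
$\hat\sigma = \sigma_2 + M(\sigma_1-\sigma_2)$ with $M > 1$ for every tip
radius probed — the freely fitted modulus absorbs the deep-layer deficit
and σ lands *outside* the two layer values, destroying exactly the
cortex/nucleoskeleton discrimination the windows exist to show. The
series construction yields $M \approx 0.1\!-\!0.3$: the full-depth estimate
falls between the layers, closer to the deep one, while the 100 nm window
recovers the cortex stress. Two-layer control phantoms also use a
depth-independent sharp tip (r = 30 nm, c = 0) so layer structure is not
confounded with tip-shape depth coupling, and layer stresses of 4/3 kPa
over a 5 kPa modulus so the 3 nN trigger is not reached before the full
800 nm depth. Line-scan series are generated directly at the profile level
(dome profile, exponential stress relaxation to a plateau fraction,
optional monotone height trend) — they emulate the *statistics* of a
compression time course, not the per-curve physics.

What the phantoms deliberately do not emulate: viscoelastic
(rate-dependent) response, adhesion on retract, heteroscedastic
instrument noise, substrate bottom effects beyond the R(d) parametrization,
and drift between repetitions. Passing phantom tests therefore validates
the *inference machinery* — descriptor search, linear fits, ranking,
masking, export — on data whose generative model matches the fitted one; it
does not by itself establish accuracy on cells where those unmodeled
effects are present.

## Numerical choices and degenerate inputs

* The map fit is fully vectorized: all curves are packed into NA-padded
  depth/force matrices (one column per pixel), and the per-pixel 1- or
  2-variate OLS solutions are closed-form column reductions. One objective
  evaluation on a 32 × 32 × 81-sample map costs a few milliseconds, which
  is what makes 1000-iteration chains (and 10-seed validation sweeps)
  practical; the vectorized path is tested pixel-by-pixel against the
  reference per-curve fit.
* Validation experiments use 16 × 16 and 32 × 32 grids at 0.5–1 µm pitch
  with 0–800 nm depth grids in 10 nm steps — scaled-down stand-ins for a
  256 × 256 acquisition chosen to keep the full suite in the minutes
  range; nothing in the code depends on grid size.
* Singular designs are detected via the relative determinant of the 2 × 2
  normal matrix (tolerance 1e−12); geometry violations propagate as flags,
  and a proposal violating geometry on > 1% of samples scores an infinite
  objective. Bounds default to radius-space (r ≤ 10 µm, |a|, |b| ≤ 5 µm per
  unit slope, |c| ≤ 10) or angle-space equivalents.
* Contact detection for raw traces (baseline fit over the first 30%,
  trigger at 5 × MAD above baseline, deflection-corrected deformation) is
  an enum-dispatched method; phantoms emit f–d curves directly and bypass
  it.
* Containers are strict SI with units in field names; readers refuse to
  guess units and name the first offending field. CSV map export is
  full-precision text (`%.17g`, exact round-trip); the 32-bit float TIFF
  export is written by a minimal single-strip writer (no installed R
  package emits float TIFFs) and round-trip-verified against an
  independent reader. Missing pixels stay explicit (`NULL` curves, empty
  CSV cells, NaN TIFF samples, masked map entries).

## Known limitations

Beyond the phantom scope above: the depth-window refit inherits whatever
bias the single-layer model has on genuinely layered material (quantified
by the two-layer experiments); the Metropolis search is a point optimizer
and reports no descriptor uncertainty; the prediction protocol assumes
homoscedastic noise when comparing models; and the HS σ/E basis columns are
nearly collinear for depths below the tip radius, so per-pixel σ estimates
on very shallow windows carry large propagated noise — the noise-propagated
per-pixel bound (from the OLS covariance) is the right yardstick, and the
validation experiments use it.
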