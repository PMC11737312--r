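---
title: "Methods: dissection-based bite-force estimation and phylogenetic allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissection-based bite-force estimation and phylogenetic allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parrotbite)
```

## The biomechanical model and its assumptions

`parrotbite` estimates the maximal static bite force of a parrot from
measurements obtainable by dissection and scaled photography alone: each
jaw muscle's wet mass, its in-situ lateral surface area, its line of
action (LOA) and three moment arms, plus the skull's out-lever. The jaw
is a static third-class lever viewed in 2-D; cranial kinesis (movement
of the upper beak relative to the braincase) is deliberately outside the
model, as is any dynamic behaviour.

The per-muscle chain is:

1. **Volume** $V = m/\rho$ with $\rho = 1.06\times10^{-3}$ g/mm³
   (1.06 g/cm³, the standard density of vertebrate muscle; beware the
   occasional misprint "1060 g/mm³", which is the same number in
   mg/mm³ mislabelled).
2. **Thickness** $T = V/A$, using the lens-corrected area $A$. This is
   the depth of the muscle if its fascicles projected perpendicularly
   from the bone.
3. **Fascicle length** $l = T/\sin 45^\circ$. Dissection shows the
   fascicles packed at an angle to the bony origin rather than
   perpendicular; the 45° projection converts thickness to fascicle
   length. The angle is a `model_constants()` field, so sensitivity to
   it can be explored directly.
4. **PCSA** $= m\cos\theta/(\rho l)$ with $\theta$ the pennation angle.
   When $l$ comes from the same mass through steps 1–3, mass and density
   cancel and PCSA $= A\sin 45^\circ \cos\theta$ exactly; the test suite
   enforces this identity to $10^{-12}$ relative error, which also means
   the estimate is driven by the measured *areas*, not the masses.
5. **Force** $F = \sigma\,$PCSA with tetanic stress
   $\sigma = 0.3$ N/mm².
6. **Torque** $\tau = rF\sin(\mathrm{LOA})$, with $r$ the mean of the
   three moment arms measured at the start, middle and end of the LOA.

Bite force is $\mathrm{BF} = 2\sum_{\text{adductors}}\tau_i /
\text{out-lever}$. Only adductors enter the sum; the depressor
mandibulae is computed and reported with zero contribution. The factor 2
restores whole-jaw force from per-side muscle data; when both sides of a
head were dissected, per-muscle measurements are averaged across sides
first.

**Lens correction.** Digital distances differ from physical ones by a
linear lens-compression factor, estimated from a reference distance
measured both ways. Areas are corrected by the *squared* factor — the
dimensionally consistent choice; the linear alternative is available as
`area_scale_power = 1` for sensitivity checks, since sources are not
always explicit about the power. Moment arms are used as measured; the
correction is applied to areas only.

**Pennation.** Per-muscle pennation angles are rarely measurable in the
same dissection; the default is 0 rad ($\cos\theta = 1$), and nonzero
profiles can be supplied per muscle. A ±15° error changes PCSA by at
most $1-\cos 15^\circ \approx 3.4\%$, which is small against the other
measurement errors.

**Proxy areas.** The pterygoideus dorsalis is hidden in lateral view;
the palatine bone area stands in for it. The `area_is_proxy` flag
travels with the row so reports can annotate the approximation; the
numerical chain is unchanged.

## Phylogenetic regression

Species are not independent observations: closely related parrots
resemble each other. Log₁₀–log₁₀ trait relationships are therefore fit
by generalised least squares with residual covariance
$V(\lambda) = \lambda C$ off the diagonal and $\mathrm{diag}(C)$ on it,
where $C_{ij}$ is the branch length shared by tips $i$ and $j$ under
Brownian motion and $\lambda \in [0,1]$ is Pagel's λ: 0 recovers
ordinary least squares, 1 the full Brownian covariance. λ is profiled by
maximum likelihood with `stats::optimize`, with the boundary values
checked explicitly since the optimum often sits at 0 or 1. Two R²
flavours are reported: the generalized R² against the GLS intercept-only
model, and the OLS-style R² on the raw residuals (they coincide at
λ = 0); sources are not always explicit about which they print, so both
are available.

A variance-components formulation defines the phylogenetic signal as the
phylogenetic share of total residual variance. The branch-length
transform used here is the standard frequentist analogue of that ratio;
the two definitions agree at the boundaries and are close in between,
but are not identical — worth remembering when comparing λ values across
software.

Fitted exponents are tested against isometric expectations by one-sample
t-tests, $t = (b - b_0)/\mathrm{SE}(b)$: under geometric similarity a
force scales as mass^0.66 (the conventional two-decimal rendering of
2/3) and as length². Degrees of freedom follow the $n-1$ convention of
the comparative literature for these one-sample tests; p-values are
two-sided and uncorrected (a handful of planned tests, not a screen).

## Comparing calculated and measured bite forces

Whether dissection-based calculations agree with in-vivo transducer
measurements is a method-comparison question:
`phylo_ancova()` fits log₁₀ bite force against log₁₀ body mass × method
with species-level phylogenetic covariance expanded to observation level
(two observations of the same species are phylogenetically identical but
carry independent residuals: $V(\lambda) = \lambda C_{obs} +
(1-\lambda)I$ with $C_{obs}$ normalised to unit diagonal). The
interaction is tested first; if non-significant at α = 0.05 the additive
model is refit and the method main effect tested there — the usual
sequential simplification.

This is a maximum-likelihood replacement for a Bayesian phylogenetic
mixed model with the same inferential target (for reference, such
analyses typically run ~500,000 iterations, thinned every 500 after a
10,000-iteration burn-in, with parameter-expanded uninformative priors).
The ML route was chosen because it is deterministic, orders of magnitude
faster, and testable against closed-form GLS oracles; at these sample
sizes (≈ 20–60 observations) the two give practically identical
method-effect inferences, and the simulation tests show nominal type-I
error (≤ 0.08 at α = 0.05 over 500 null replicates) and good power
(≥ 0.8 for a 0.2 log-unit offset at 30 species).

## The scar predictor

The insertion of the adductor mandibulae externus leaves a measurable
scar on the mandible. `fit_scar_model()` fits
$\log_{10}\mathrm{BF} = a + b\log_{10}(\text{scar length})$ and reports
it as the power law $\mathrm{BF} = 10^a\,s^b$. Published coefficients
can be wrapped directly with `scar_power_law()`; the log base matters —
$10^{-0.026} = 0.94$ whereas $e^{-0.026} = 0.97$ — and base 10 is used
throughout, consistent with every other analysis in the pipeline
(an occasional "ln" label on such fits is a typo when the printed
power-law coefficient equals the base-10 back-transform, as it does
here). Prediction intervals from the residual variance are offered as a
clearly-marked extra; they ignore leverage and are diagnostic only.
`invert_prediction()` gives the scar length implied by a force; the
round trip is exact, and refitting the model on its own predictions
reproduces the coefficients, both enforced by tests.

## The synthetic-data generator

No public repository of parrot dissection tables exists, so the package
ships a generator that emulates the *statistical structure* the analyses
assume, making every stage testable end to end:

- **Tree**: pure-birth (Yule) tree rescaled to unit depth. Real parrot
  phylogenies are not Yule-shaped, but tree shape only perturbs the
  covariance structure; no attempt is made to mimic the true topology.
- **Body mass**: log₁₀ mass evolves by Brownian motion from a root of
  2.6 (≈ 400 g, mid-range for parrots) at rate σ² = 0.25 per unit
  depth, spanning roughly 30–1250 g across a tree — the span of real
  parrot species means.
- **Other traits**: per-trait allometric rules $a + b\log_{10}BM +
  N(0, sd)$ with defaults rounded from the log–log fits on the packaged
  19-species table (e.g. bite force: $a=-0.40$, $b=0.93$, sd 0.14).
- **Specimens**: one-side jaw muscle mass is split over six muscles (DM
  abductor; PTVL, AME, PSM, PTD, EM adductors; EM and AME dominant,
  fractions 0.28 and 0.26 — muscle-mass tables for parrots are scarce,
  so the profile is configuration, not a constant). Moment arms and the
  out-lever are fractions of skull length; corrected areas are then
  solved so that the forward model reproduces the species' bite force
  *exactly* (mass cancels in the PCSA chain, so areas are the free
  knob). Digital areas divide out the photo scale factor so the lens
  correction round-trips too. Optional log-normal measurement noise
  (multiplicative on masses and areas, the natural error model for
  weighing and tracing) breaks this exactness deliberately.
- **Measured forces**: $\log_{10}BF_{meas} = \log_{10}BF_{calc} +
  \delta + N(0, 0.05)$; δ = 0 is the null scenario in which the two
  methods agree.

What passing tests on synthetic data do *not* show: that real
photographed areas are unbiased, that the 45° fascicle projection is
anatomically right for every muscle, or that pennation defaults are
harmless in species with strongly pennate jaw muscles. The generator
validates the statistics and the software, not the anatomy.

## Numerical choices

- λ profiling: `optimize` on [0, 1] at tolerance 10⁻⁸ plus explicit
  boundary evaluation; singular covariances (e.g. duplicated species at
  λ = 1) score $-\infty$ and are never selected.
- GLS via Cholesky whitening, never explicit inversion (the explicit
  inverse appears only in test oracles).
- Zero-mass muscles short-circuit to zero force instead of dividing
  0/0.
- Species labels are matched to tree tips after space/underscore
  normalisation and case folding; unmatched species are dropped with a
  warning naming them.
- Angles are radians internally; CSV readers accept degrees (default)
  or radians, declared per call.
- Trees with a basal polytomy (including star trees) are treated as
  rooted at the polytomy — exactly what the Brownian covariance
  assumes — rather than rejected.

Problem sizes used by the simulation-based tests — 500 replicates of
50-tip trees for slope recovery, 500 null and 200 alternative
replicates at 30 species for the ANCOVA error rates — were chosen to
bound Monte-Carlo error on the assessed rates below about 2 percentage
points.

## Known limitations

- The model is static and 2-D: no gape-angle dependence, no cranial
  kinesis, no finite-element stress distribution. Calculated values are
  maximal isometric estimates.
- Published species-mean tables are not always internally consistent.
  Of the packaged parrot means, one printed bite-force:body-mass ratio
  (Psittacula eupatria) disagrees with its own numerator and
  denominator, and the printed jaw-muscle-mass regression (slope 0.715,
  intercept 1.538) cannot be recovered from the printed species means —
  the line it describes does not pass through the centroid of those 19
  points, which any least-squares fit must, so it was evidently fit on
  slightly different (likely unrounded or adductor-only) data. The
  package reports what the packaged means actually give (slope 0.778,
  intercept 1.720, R² 0.894); the R² matches the published 0.88, the
  coefficients do not, and the acceptance tests record that discrepancy
  rather than paper over it.
- The scar predictor is calibrated on parrots only; psittaciform jaw
  architecture (notably the ethmomandibularis) does not generalise, so
  applying it to other birds is unsupported.
- `pgls()` assumes an ultrametric tree for the "diagonal = depth"
  reading of λ; non-ultrametric trees are accepted but λ then rescales
  unequal tip variances too.
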