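# parrotbite

Parrots (Psittaciformes) have a reputation for ferocious bites, yet until
recently almost no bite-force data existed for them. `parrotbite`
implements a dissection-based pipeline for estimating bite force in
parrots and analysing how it scales with body size across species, for
comparative biomechanists and ornithologists who have jaw-muscle
dissection measurements (or only dry skulls) rather than live birds and
force transducers.

## The model

The jaw is treated as a static third-class lever in a 2-D lateral view,
with the base of the quadratojugal–quadrate complex as the fulcrum. For
each jaw muscle with wet mass *m* (g) and in-situ photographed surface
area *A* (mm², corrected for lens compression by the squared linear scale
factor between a physically and digitally measured reference distance):

- volume *V* = *m* / ρ, with muscle density ρ = 1.06 × 10⁻³ g/mm³,
- thickness *T* = *V* / *A*,
- fascicle length *l* = *T* / sin 45°, the fascicles leaving the bone at
  45° rather than projecting straight out,
- PCSA = *m* cos θ / (ρ *l*), with θ the pennation angle,
- force *F* = 0.3 N/mm² × PCSA (tetanic muscle stress),
- torque τ = *r* *F* sin(LOA), with *r* the mean of three moment-arm
  measurements along the line of action (LOA) and LOA its angle to the
  defined horizontal.

Bite force is the summed adductor torque (the depressor mandibulae, an
abductor, is reported but excluded), divided by the out-lever moment arm
and doubled for the two sides of the jaw:

BF = 2 · Σ τᵢ / out-lever  (N).

Species-level analyses fit log₁₀–log₁₀ regressions of bite force on body
mass, skull mass, skull length and jaw muscle mass by phylogenetically
controlled generalised least squares with Pagel's λ (profiled by maximum
likelihood on [0, 1]), test the fitted exponents against the isometric
expectations (0.66 for mass-like, 2.0 for length-like predictors), and
compare calculated against in-vivo measured bite forces with a
phylogenetic ANCOVA. A power-law model predicts bite force from the
length of the adductor mandibulae externus scar on the mandible — an
osteological proxy usable on museum skulls.

## Worked example

One specimen with three muscles (masses in g, areas in mm², arms in mm,
angles in radians):

```r
library(parrotbite)
m <- data.frame(
  muscle = c("DM", "AME", "EM"), role = c("abductor", "adductor", "adductor"),
  wet_mass = c(0.4, 0.9, 1.1), surface_area = c(60, 180, 210),
  pennation = 0, loa = c(60, 75, 90) * pi / 180,
  arm1 = c(5, 11, 13), arm2 = c(6, 12, 14), arm3 = c(7, 13, 15))
bite_force(m, list(out_lever = 39, physical_ref = 30, digital_ref = 28))
#> Bite force: 62.770 N (2 adductors, out-lever 39 mm, scale factor 1.071)
#>  muscle     role    pcsa  force mean_arm  torque
#>      DM abductor  48.704 14.611        6  75.922
#>     AME adductor 146.111 43.833       12 508.078
#>      EM adductor 170.463 51.139       14 715.946
```

The 62.8 N total is 2 × (508.1 + 715.9) N·mm divided by the 39 mm
out-lever; the abductor DM is listed but contributes nothing.

Allometry on the packaged 19-species table of parrot means:

```r
tt <- parrot_traits()
allometry_report(tt)[, c("predictor", "slope", "slope_se", "r_squared", "verdict")]
#>        predictor slope slope_se r_squared               verdict
#>        body_mass 0.929   0.0798     0.889 positively allometric
#>       skull_mass 0.829   0.0376     0.966 positively allometric
#>     skull_length 2.539   0.1817     0.920 positively allometric
#>  jaw_muscle_mass 0.778   0.0650     0.894             isometric
```

Bite force rises faster than the isometric expectation with body size
(big macaws bite disproportionately hard), but scales isometrically with
the jaw musculature itself. Predicting from a skull: a 20 mm adductor
scar and the published power law give

```r
predict(scar_power_law(-0.026, 2.195), 20)
#> [1] 675.7  # N
```

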