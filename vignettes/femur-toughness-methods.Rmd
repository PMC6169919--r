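---
title: "Methods: fracture toughness, morphometry and inference for notched mouse femurs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fracture toughness, morphometry and inference for notched mouse femurs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femurtough)
```

# The measurement model

## Idealized geometry

A notched femoral mid-diaphysis in three-point bending is modelled as a
thick-walled circular cylinder (mean radius $R_m$, wall thickness $t$)
carrying a symmetric circumferential through-wall crack of half angle
$\theta$. `cross_section()` holds this geometry; `fit_annulus()` produces it
from a segmented micro-CT section as the equivalent-area annulus
($R_o = \sqrt{\mathrm{Tt.Ar}/\pi}$, $R_i = \sqrt{\mathrm{Es.Ar}/\pi}$). The
real cross-section is elliptical and asymmetric, and the real crack front is
neither flat nor symmetric; the cylinder idealization is the standard
trade-off that makes a closed-form stress intensity available for hundreds of
specimens.

## From surface crack extension to crack angle

Imaging tracks the projected crack extension on the medial surface,
$\Delta a_{proj}$. `half_crack_angle()` converts it to the instantaneous half
crack angle by arc length at the mean radius,

$$\theta = \theta_0 + \Delta a_{proj} / R_m,$$

the conventional mapping for surface-measured circumferential crack growth.
An outer-surface mapping ($R_o$ in the denominator) would shrink all angles
by the ratio $R_m/R_o$ (about 11% for the default geometry); we fix the
mean-radius convention package-wide rather than expose a knob that silently
changes every downstream number. Angles are clipped just below $\pi$ with a
warning if a record claims more crack than the section can carry.

## Stress intensity and the geometry factor

At each analysis point,

$$K = F_b(\theta, R_m/t)\;\sigma_b\;\sqrt{\pi R_m \theta},\qquad
  \sigma_b = \frac{P S / 4}{\pi R_m^2 t},$$

with $P$ the instantaneous load and $S$ the span (default 8 mm). Inputs are
lab units (N, mm), $\sigma_b$ is in MPa, and $K$ is computed in
MPa$\sqrt{\text{mm}}$ then converted to MPa$\sqrt{\text{m}}$ (factor
$10^{-1.5}$); a test asserts this equals an all-SI evaluation to $10^{-9}$
relative.

`geometry_factor()` uses the polynomial form for a through-wall
circumferential crack in a cylinder under bending,

$$F_b = 1 + A(R_m/t)\left[4.5967\,(\theta/\pi)^{1.5}
        + 2.6422\,(\theta/\pi)^{4.24}\right],$$

with the amplitude $A$ stored in a versioned table by $R_m/t$ and linearly
interpolated between tabulated ratios. The published amplitude branches cover
$R_m/t \in [5, 20]$; murine diaphyses sit near $R_m/t \approx 3\text{–}4$, so
the table extends the low branch $A = (0.125\,R_m/t - 0.25)^{1/4}$ down to
2.5. This extension is a deliberate design choice: it preserves the limits
every boundary-correction factor must satisfy ($F_b \to 1$ as
$\theta \to 0$, $F_b \ge 1$, strictly increasing in $\theta$) and varies
smoothly across the thick-wall range, but it is an extrapolation, not a
published thick-wall solution; the table (`geometry_factor_table()`) is the
single place to swap in better coefficients. Supported windows — $\theta \in
(0, 0.6\pi]$, $R_m/t \in [2.5, 20]$ — are enforced with range errors rather
than silent extrapolation.

## Event detection

`detect_events()` works on the synchronized record: load is sampled densely
by the test frame, crack extension on the 5 Hz imaging clock, and load at
frame timestamps is obtained by linear interpolation.

* **Initiation**: first frame whose crack extension exceeds 5 pixels
  (11 µm at the default 2.2 µm/px) — at least twice the optical noise floor.
  Configurable via `init_threshold_px`.
* **Peak**: frame of maximum interpolated load (ties broken by the first
  maximum, which cannot occur for a strictly rising-then-falling trace).
* **Instability**: last frame before a between-frame load drop exceeding 10%
  of peak load, searched at or after the peak; if no such drop is recorded
  (the specimen failed between frames or the trace ends), the final frame
  with measurable crack extension is used. Configurable via `drop_frac`.

The ordering initiation ≤ peak ≤ instability is enforced. A record with no
crack extension or an all-zero load trace is an error, not a silent zero.

## Plastic-zone diagnostics

`plastic_zone_radius()` uses the Irwin estimate
$r_p = (K/\sigma_y)^2 / (6\pi)$ — the plane-strain constant, appropriate for
a thick section; plane stress ($1/(2\pi)$) is available by argument. With the
default yield strength of 160 MPa, $K = 3$ MPa$\sqrt{m}$ gives
$r_p \approx 18.7$ µm. `lefm_validity()` flags a toughness value valid when
$r_p \le t/10$ (the usual small-scale-yielding heuristic; cutoff
configurable) and always reports the ratio $r_p/t$. For a 0.2 mm murine
cortical wall this makes values below roughly 3 MPa$\sqrt{m}$ valid, so peak
and instability toughness typically carry a "not strictly valid" flag —
group comparisons remain meaningful, absolute values less so.

## Fracture angle

`fracture_angle()` measures the sagittal angle from the notch root to the
periosteal breakout point against the transverse plane:
$\alpha = \arctan(|\Delta_{long}| / |\Delta_{transverse}|)$, so 0° is a
perfectly transverse fracture and lower angles mean straighter, less
deflected cracks.

# Morphometry conventions

* Segmentation: pixels at or above the global threshold (default
  654 mg HA/cm³, inclusive); only the largest connected component is kept.
* Coordinates: pixel centres, lengths converted to mm; a 2D single slice at
  the notch plane stands in for the diaphyseal volume because the notch-plane
  section is what enters the toughness geometry (per-slice rows can be
  averaged when a stack is available).
* `Tt.Ar` is the filled periosteal boundary, so
  $\mathrm{Tt.Ar} = \mathrm{Ct.Ar} + \mathrm{Es.Ar}$ holds exactly by
  construction.
* Cortical thickness uses the local-thickness convention: twice the distance
  transform on the medial ridge of the mask, with a half-pixel centring
  correction; a radial-ray alternative (`method = "rays"`) is provided.
  Raster tests accept ±1 pixel.
* Principal moments come from the 2×2 inertia tensor about the centroid,
  including the per-pixel self moment $p^4/12$; a non-annular topology
  (no cavity, or multiple cavities) is an error for thickness and annulus
  fitting.

# Biochemistry conventions

The pentosidine standard curve is ordinary least squares of fluorescence on
quinine-sulfate concentration — linear, not four-parameter logistic, because
quinine-sulfate fluorescence is linear in the assay range. Inverse prediction
refuses (returns `NA` with a warning) readings beyond 120% of the top
standard rather than extrapolating. Collagen is hydroxyproline / 0.135.
Technical replicates are averaged with a CV flag at 15% — a QC annotation,
not an exclusion rule, since the emulated assay did not state one. nsAGE
readings have no technical replicates and are comparable only within a plate;
plate-batch modelling is out of scope and batches should travel as a column.

# The inference layer

* Per-time-point comparisons are equal-variance Student's t tests (a Welch
  flag exists), with percent change computed on group means. No
  multiple-testing correction is applied across time points or outcomes —
  this mirrors the emulated study's analysis and is a deliberate caveat, not
  an oversight.
* `ancova()` fits `value ~ group * time` and reports type-II effect tests
  (`car::Anova`), which match JMP-style effect tests on a balanced design.
  The common time slope is reported from the additive model; by the study's
  convention it is the quantity of interest when the interaction is not
  significant. On noiseless data the effect tests are degenerate and the p
  values are returned as `NA` while the coefficients remain exact.
* `anova_tukey()` is `aov()` + `TukeyHSD()`; `cohens_d()` uses the pooled-SD
  definition with the 0.2/0.5/0.8 size classes.

# What the synthetic generators emulate

`study_calibration()` loads a versioned YAML file in which every planted
value is tagged either `printed` (transcribed from the emulated study:
Sham instability toughness 5.5 MPa$\sqrt m$ with COV 0.14; −42% at week 0 and
−28% at week 12; −24% initiation and −45% peak toughness at week 0 with a
0.0377 MPa$\sqrt m$/week common initiation slope; −5% cortical area at week
12; devitalized paired effects −26/−26/−29%; ribosylation slopes and $R^2$;
the 4 × 5 Gy protocol with $\alpha/\beta$ = 2.8 Gy giving BED 55.7 Gy) or
`assumed` (anchors the study did not print — e.g. Sham means for initiation
and peak toughness, morphometry anchors and their COVs, intermediate-week
multipliers). Assumed anchors were chosen once from typical values for adult
female BALB/cJ femora and are not tuned.

Design choices:

* Outcome noise is normal with COV parameterization; at COV 0.14 the
  negative-value mass is negligible (≈10⁻¹²), so a lognormal switch was not
  made the default.
* The paired design uses a shared per-animal baseline carrying 70% of the
  variance (within-pair correlation 0.7 — unstated in the emulated study,
  flagged as assumed).
* Ribosylation outcomes follow `intercept + slope·day + ε` with the residual
  SD derived from the planted $R^2$ and the balanced day design's population
  variance (27.5 day² for days 0/3/7/14):
  $\sigma^2 = \beta^2\,\mathrm{var}(day)\,(1/R^2 - 1)$.
* `gen_bend_test()` is the exact forward model of the toughness chain: at
  every frame the load is solved so the stress intensity at that frame's
  crack angle equals the planted R-curve (K is linear in load, so the
  inversion is exact), and the load trace is sampled on a grid containing
  every frame timestamp. With zero load noise the round trip through
  `toughness_triplet()` is exact to numerical precision — this closure is the
  package's central correctness oracle. The generator refuses planted curves
  whose peak load would not fall on the peak event, rather than emitting a
  physically inconsistent record.
* `gen_section_mask()` rasterizes circular or elliptical annuli by
  pixel-centre inclusion and carries the continuous closed forms (areas,
  principal moments, wall thickness) as the oracle sidecar; an offset-wall
  mode produces constant-thickness elliptical sections.

What passing tests do **not** show about real data: the generators plant
clean normal cells, straight ribosylation lines, exact synchronization, flat
symmetric crack fronts and noise-free crack tracking. Real records have
measurement noise in $\Delta a_{proj}$, imperfect synchronization, elliptical
asymmetric sections and plate-batch effects. The tests establish that the
computational chain is correct and that the study's effects are recoverable
under its stated designs — not that the physical assumptions hold in any
particular specimen.

# Numerical choices and problem sizes

Linear interpolation is used for load-at-frame lookup and between tabulated
geometry-factor ratios; all angle work is in radians internally (degrees only
for the fracture angle, which is reported in degrees). Degenerate inputs
(zero loads, no crack, empty masks, broken pairs, zero collagen) raise typed
errors rather than propagating NaN.

The test suite uses raster sections of ~200×200 px (12 µm pixels on a 1 mm
bone), 2000 null simulations for the type-I calibration of the t test
(binomial three-sigma band around 5%), and 500 seeded replicates per
effect-recovery check (Monte-Carlo means compared at two Monte-Carlo standard
errors), with sub-seeds drawn from one declared master seed. The whole suite
runs in well under a minute on one core; `scripts/acceptance.R` re-derives
the headline quantities from scratch at any user seed.

# Known limitations

* The thick-wall geometry-factor amplitudes below $R_m/t = 5$ are a
  documented extrapolation of the published thin-wall branch.
* Elastic-plastic toughness (J-integral) is out of scope; the LEFM flags are
  diagnostics, not corrections.
* Crack tracking on real imagery is out of scope — the crack-extension
  series is consumed, not extracted from frames.
* Trabecular morphometry, scanner reconstruction and beam-hardening are out
  of scope; nsAGE values are plate-relative.
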