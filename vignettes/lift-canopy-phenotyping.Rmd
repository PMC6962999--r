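---
title: "Methods: canopy chlorophyll-fluorescence kinetics and modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy chlorophyll-fluorescence kinetics and modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftkin)
```

## The measurement and its statistics

A light-induced fluorescence transient (LIFT) instrument excites
chlorophyll fluorescence from a distance with sub-saturating flashlets.
One measurement consists of 427 flashlets: a fast-repetition-rate
excitation phase of 300 flashlets within 0.75 ms that cumulatively closes
PSII reaction centres and drives fluorescence from its minimum yield Fo to
its maximum Fm, followed by 127 flashlets fired at a decreasing repetition
rate over 200 ms that watch the fluorescence relax as electrons drain from
the reduced primary quinone acceptor (Qa-) towards the plastoquinone pool.

From each background-subtracted transient the package derives:

* **Fo** — yield of the first flashlet; **Fm** — mean yield of the 301st
  and 302nd flashlets (the last induction flashlet is avoided because
  quenching already develops during the excitation phase); **Fv = Fm − Fo**.
* **Fv/Fm** (dark) or **Fq'/Fm'** (light) — PSII quantum efficiency,
  `(Fm − Fo)/Fm`.
* **Fr1/Fv** and **Fr2/Fv** (primed in the light) — reoxidation
  efficiency statistics: the area between Fm and the actual fluorescence
  F(t), integrated over a relaxation window and normalised by the Fv area
  over the same window,

  `ratio = ∫ (Fm − F(t)) dt / (Fv · (t2 − t1))`.

  Window W1 = 0.8–1.47 ms captures the fast Qa-→Qb electron transfer
  phase (~0.2 ms time constant), W2 = 0.8–5.9 ms additionally covers
  Qb2-/plastoquinone exchange (~0.7 ms and 2–3 ms). Window times are
  measured from the first excitation flashlet, so W1 starts 0.05 ms into
  the relaxation phase — the only origin under which both windows sit
  inside the relaxation phase. A value of 0 means no relaxation,
  1 complete relaxation to Fo within the window.
* **SNR** — Fm divided by the standard deviation of the background
  channel samples. The instrument records background irradiance between
  flashlets; its spread is the natural noise reference for the
  species-specific discard thresholds (50 and 100).

Numerical choices: the area integral uses the trapezoidal rule over the
flashlet samples inside the window with linear interpolation at both
window edges. This is exact for piecewise-linear data and converges
quadratically with sampling density; at the instrument's 427-point
schedule it agrees with closed-form integrals of exponential relaxations
to better than 0.1% (tested), and the dominant error is the sparseness of
the schedule, not the rule. Flashlet ordinals are 1-based throughout.
A measurement counts as dark-adapted below 5 µmol photons m⁻² s⁻¹
ambient PPFD; the literature switches notation (Fv/Fm vs Fq'/Fm') without
naming a threshold, so one had to be fixed.

## Spectral processing

Raw spectrometer digital numbers (DN) are averaged onto the even 2-nm
grid from 400 to 800 nm; a native sample at wavelength w belongs to the
even bin c with c − 1 ≤ w < c + 1 (half-open bins; the convention had to
be chosen, any consistent assignment differs only at bin edges). The
dark current recorded the night before (latest dark scan before 04:00 of
the measurement day) is subtracted, clipping at zero.

Reflectance correction uses hourly scans of a grey calibration panel
reflecting 50% of incoming irradiance. Panel scans are keyed by the PPFD
of their minute, averaged in 10-µmol bins spanning 100–1350
µmol photons m⁻² s⁻¹, and stored as a look-up table; empty interior bins
borrow the nearest populated bin (ties toward the lower bin) and are
flagged. A canopy spectrum is corrected by the reference bin closest to
its PPFD: `R(λ) = DN(λ) / (DN_ref(λ)/0.5)`. Whether the original analysis
used the 0.5 algebra or a raw panel ratio is immaterial for all
normalized-difference indices, where the constant cancels. Below
100 µmol the correction is not attempted — pseudo-indices computed
directly from raw DN exist precisely because absolute correction is
fragile at low light.

Indices: NDVI = (R750−R706)/(R750+R706), NDVI_II = (R740−R680)/(R740+R680),
GNDVI = (R740−R540)/(R740+R540), MTCI = (R754−R710)/(R710+R680),
PRI = (R530−R570)/(R530+R570); pseudo-variants use the same bands on raw
DN. `reflectance_sum` totals raw DN over 450–800 nm. The signal at 685 nm
is read as the mean of the 684 and 686 nm bins since the grid holds only
even wavelengths. Each spectrum is paired with the fluorescence
measurement taken immediately before it in the same scan line.

## Quality control

Transients are discarded when SNR falls below 50 (maize, rapeseed,
soybean) or 100 (barley, wheat); when Fv/Fm or Fr1/Fv are negative; or
when Fr1/Fv exceeds 0.35 or Fr2/Fv exceeds 0.8. Bounds are strict as
stated ("lower than", "higher than"): equality survives. The rapeseed
threshold is carried although no rapeseed campaign is described.
Spectral indices are dropped below 30 µmol photons m⁻² s⁻¹ and, per
species and index, outside the Tukey fences (quartiles ± 1.5·IQR) — the
published wording about "1.5 times the second and third quantile" is
garbled, but the 1.5 factor together with two quartiles points to the
standard boxplot rule, which is what is implemented (whole rows are
dropped so that kept plus rejected always partitions the input). The
third measurement of every scan line is removed because the scanning
platform pauses at the line end and most likely measured the same spot.

## Linkage

Environmental records (PPFD, air temperature, relative humidity) are
logged once per minute; measurements join the record of the same minute
by truncation (not rounding), and multiple stations reporting in one
minute are averaged — the combination rule across stations had to be
chosen. Vapour pressure deficit uses the Magnus saturation formula
`es = 0.6108·exp(17.27·T/(T + 237.3))` kPa, `vpd = es·(1 − rh/100)`.
Days after sowing counts whole days with the sowing day as 0. "Daytime"
enters the models as the numeric hour of day; a categorical alternative
can be supplied through the covariate specification.

## Modelling

The genotype-by-environment model is `y = µ + Zu + ε` with the
coefficients penalised by the ℓ1 norm and the penalty scale λ chosen at
the minimum mean error of an internal 10-fold cross-validation (folds
assigned by a seeded shuffle; λ path logarithmic, 100 points spanning
four decades below the full-shrinkage value). Continuous covariates are
standardized on the training data and the constants are reused for
validation; categorical covariates (species, genotype, month, week) are
one-hot encoded with the reference level dropped. Solving is by
coordinate descent via glmnet. Prediction accuracy is the Pearson
correlation between predicted and measured values after averaging within
(genotype, day, hour) cells, computed per genotype. The half-days
training split assigns alternate calendar days deterministically (day
rank parity) so runs are reproducible; a seeded random variant and a
by-season split are available.

Explained variance is decomposed by sequential (Type-I) sums of squares
from an ordinary linear model, reported per factor as a percentage of
the total SS; the default factor order is temperature, month, crop,
hour, date, genotype, plot, DAS, √temperature. Sequential SS is
order-dependent by construction — the PSII-efficiency analysis instead
enters PPFD, √PPFD and PRI first, mirroring how that response is
analysed. Fully aliased factors (e.g. DAS after a date factor within a
single sowing) are absorbed with zero degrees of freedom and logged.
Response curves are ordinary least squares of a parameter on transformed
terms of one driver (√PPFD for the light response; √T and optionally T²
for the temperature response), fitted per group.

## The synthetic campaign generator

Every downstream stage is exercised on generated data, so the generator
is first-class, seeded code. It emulates:

* **Environment** — minute-resolution diurnal PPFD arcs (sunrise 06:00,
  sunset 20:00, clear-sky peak 1600 µmol m⁻² s⁻¹) modulated by smooth
  autoregressive cloudiness; temperature as a diurnal sinusoid (±6 °C,
  minimum 03:00) on a linear seasonal ramp (daily means 10→24 °C over the
  default 14 days, so the campaign spans roughly 4–30 °C); humidity
  anti-correlated with temperature and light, clipped to 20–100%.
* **Transients** — single-hit Poisson induction (per flashlet an open
  centre closes with probability `sigma_abs` = 0.03; PSII connectivity is
  deliberately ignored), relaxation as a three-exponential mixture with
  time constants 0.2 / 0.7 / 2.5 ms at the 20 °C reference and weights
  0.08 / 0.17 / 0.75. The slow-dominated weights are what places the
  statistics in their physically retained ranges (Fr1/Fv below 0.35,
  Fr2/Fv below 0.8 across 4–30 °C); an even mixture would relax far too
  completely within 5.9 ms. All time constants share an Arrhenius
  temperature factor with activation energy 45 kJ mol⁻¹, chosen so the
  5→30 °C span moves Fr2/Fv by roughly 0.3 — a strong but not saturating
  response. A genotype's cold tolerance c ∈ [0, 1] scales the activation
  energy to `(1 − c)·Ea`: tolerant electron transport is less
  temperature-sensitive. Quenching is Stern–Volmer with hyperbolic light
  dependence (`NPQ = 2.5·PPFD/(PPFD + 300)`); only Fm' is divided by
  1 + NPQ — quenching Fo' by the same factor would cancel out of every
  ratio and erase the light response of Fq'/Fm'.
* **Canopy optics** — each measurement carries a lognormal amplitude
  factor (leaf angle, sd 0.25 on the log scale) that cancels from all
  ratio statistics, and a lognormal light-penetration factor (sd 0.4)
  multiplying the PPFD the leaf actually experiences. The second factor
  is what makes PRI informative beyond station PPFD, as it is in real
  canopies where light penetration varies per measured spot.
* **Spectra** — broadband irradiance times a phenomenological vegetation
  reflectance (green bump at 550 nm, chlorophyll absorption trough at
  680 nm that fills in for chlorophyll-deficient genotypes, red edge to a
  0.45 NIR plateau, and a 531 nm xanthophyll dip deepening with NPQ —
  the PRI mechanism), plus dark current and shot noise. Grey-panel scans
  (flat 50% reflectance) and nightly dark scans accompany every campaign.
  With probability `soil_hit_rate` (default 0.03) a canopy spectrum
  instead sees flat bright soil — the outlier class the spectral fences
  exist for; transients are not soil-contaminated.
* **Noise** — additive Gaussian noise on flashlet yields (sd 2% of Fm'),
  a background channel proportional to ambient PPFD whose spread grows
  with light (4 + 0.01·PPFD DN), calibrated so the SNR thresholds of 50
  and 100 bite at high light but pass most measurements.
* **Geometry** — hourly scans of every plot, six combined measurements
  per 300-mm line taken 4 s apart (fluorescence first, spectrum 2 s
  later — the order the pairing rule relies on), line and position
  indices recorded so the repeated-spot rule is applicable.

The relaxation flashlet timing is not documented beyond "decreasing
repetition rate over 200 ms"; the schedule grows the gaps geometrically
from the induction spacing, with the growth ratio solved numerically so
the last flashlet lands exactly at 200.75 ms. This reproduces the dense
early sampling the 0.8–5.9 ms windows need (about 60 flashlets fall
inside W2) and is flagged as an assumption.

What the generator does *not* emulate: radiative canopy transfer, PSI
fluorescence, gas exchange, state transitions, photoinhibition, diurnal
hysteresis of quenching, and any correlation structure in the noise.
Passing tests therefore show that the processing and modelling chain
recovers what this generative model encodes — monotone temperature
kinetics, genotype contrasts, light-driven quenching — not that it would
behave identically on field data with those additional effects.

## Default study conditions and problem sizes

The demonstration campaign is two soybean genotypes contrasting in cold
tolerance (0.8 vs 0.2) in two replicate plots each — four plots, 14 days,
24 scans per day, 6 measurements per scan (8 064 transients and paired
spectra). These sizes keep a full pipeline run around a minute while
leaving roughly a hundred measurements in the 5 ± 0.5 °C band, enough
for the cold-contrast confidence intervals the tests check. Unit tests
use one- to two-day campaigns; the Lasso recovery benchmark uses
n = 2000 with one true driver and ten pure-noise covariates.

## Known limitations

* The additive genotype term in the Lasso model cannot express
  genotype-specific temperature slopes; predictions for a genotype whose
  response is much flatter than the population average are accordingly
  less accurate. Interaction covariates would lift this but are outside
  the published model form.
* Sequential variance shares depend on factor order; the package reports
  the order used and makes it explicit rather than attempting an
  order-free decomposition.
* Fm retrieval from flashlets 301–302 sits slightly below the kinetic
  asymptote (quenching during induction is the stated reason the 300th
  flashlet is avoided); composed statistics therefore deviate from ideal
  closed forms by up to ~2% on simulated traces, which the tests make
  explicit.
* The Tukey-fence reading of the garbled outlier sentence, the 5 µmol
  dark threshold, the geometric relaxation schedule, the station
  averaging rule and the 50%-panel algebra are documented choices where
  the source is silent; each is localised in one function should a
  different convention be needed.
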