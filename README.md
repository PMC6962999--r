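# liftkin

Processing and modelling pipeline for canopy chlorophyll-fluorescence
phenotyping with a scanning LIFT (light-induced fluorescence transient)
instrument, plus a seeded synthetic-campaign generator so the whole chain
is testable without instrument data.

## The scientific problem

Automated canopy scans acquire hundreds of thousands of fast-repetition-rate
(FRR) fluorescence transients and reflectance spectra per season under
fluctuating light and temperature. Two complementary parameters summarise
each transient:

* **Fv/Fm** (dark-adapted) and **Fq'/Fm'** (light-adapted) — the quantum
  efficiency of PSII charge separation, `(Fm − Fo)/Fm`, driven mainly by
  light intensity through non-photochemical quenching;
* **Fr1/Fv** and **Fr2/Fv** (primed in the light) — the efficiency of
  Qa⁻ reoxidation, i.e. electron transport beyond PSII, read from how
  completely fluorescence relaxes after the excitation flash:

  `Fr/Fv = ∫ₜ₁ᵗ² (Fm − F(t)) dt / (Fv · (t₂ − t₁))`

  over the windows 0.8–1.47 ms (Fr1, Qa⁻→Qb phase) and 0.8–5.9 ms
  (Fr2, including plastoquinone exchange). Fr2/Fv responds strongly to
  temperature and separates cold-tolerant from cold-sensitive genotypes
  at low temperature, where Fv/Fm shows no difference.

The package implements the full chain for one measurement campaign:
transient statistics (Fo = first flashlet, Fm = mean of flashlets
301–302, area-ratio integration), spectral binning to a 2-nm grid,
dark-current subtraction, PPFD-keyed grey-reference reflectance
correction and vegetation indices (NDVI, NDVI_II, GNDVI, MTCI, PRI and
their pseudo-variants), the campaign quality filters (species-specific
SNR, ratio bounds, low-light and Tukey-fence spectral outlier rules,
repeated-spot removal), minute-exact environmental linkage with Magnus
VPD, and the statistical layer: ℓ1-penalised (Lasso) genotype×environment
prediction with internal cross-validation and per-genotype Pearson
accuracy on (genotype, day, hour) cell means, sequential (Type-I)
sum-of-squares variance partitioning, and per-group response-curve fits.

## Worked example

A noiseless dark-adapted transient simulated at 5 °C and at 25 °C,
processed into its parameter set:

```r
library(liftkin)
kin <- kinetic_params()
tr5  <- simulate_transient(kin, temperature = 5,  ppfd = 0,
                           noise_sd_rel = 0, bg_noise_sd = 0)
process_transient(tr5)
#> # A tibble: 1 × 8
#>      fo    fm    fv  fvfm fr1_ratio fr2_ratio   snr adaptation_state
#>   <dbl> <dbl> <dbl> <dbl>     <dbl>     <dbl> <dbl> <chr>
#> 1  1000 4994. 3994. 0.800     0.109     0.411   Inf dark

tr25 <- simulate_transient(kin, temperature = 25, ppfd = 0,
                           noise_sd_rel = 0, bg_noise_sd = 0)
process_transient(tr25)
#> # A tibble: 1 × 8
#>      fo    fm    fv  fvfm fr1_ratio fr2_ratio   snr adaptation_state
#>   <dbl> <dbl> <dbl> <dbl>     <dbl>     <dbl> <dbl> <chr>
#> 1  1000 4979. 3979. 0.799     0.286     0.735   Inf dark
```

Fv/Fm is essentially unchanged (0.800 vs 0.799) while Fr2/Fv rises from
0.411 to 0.735: reoxidation is slower in the cold, and the area ratio
quantifies it. The `snr` is infinite because the background channel is
noiseless here; simulated campaigns carry a realistic background.

A complete campaign — generation, processing, QC, linkage, modelling,
with all tables and a reproducibility manifest written to `out/`:

```r
res <- run_pipeline(campaign_config(), out_dir = "out")
res$models$lasso$fr2$accuracy     # per-genotype Pearson r on held-out days
res$models$partitions$fr2         # Type-I variance partition
```

The same run is available from a shell:

```sh
Rscript inst/scripts/liftkin.R run --out out --seed 1 --days 14
```

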