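wl <- lift_wavelengths()

test_that("native spectra are averaged onto the even 2-nm grid", {
  native_wl <- seq(399.1, 800.9, by = 0.462)
  # constant signal: every bin is the constant
  out <- bin_wavelengths(native_wl, rep(100, length(native_wl)))
  expect_length(out$dn, 201)
  expect_equal(out$wavelengths, wl)
  expect_true(all(abs(out$dn - 100) < 1e-12))
  # ramp dn = lambda: bin means sit within 0.25 nm of the bin centre
  out <- bin_wavelengths(native_wl, native_wl)
  expect_true(all(abs(out$dn - out$wavelengths) <= 0.25))
  # a coverage gap raises a missing-band error
  gappy <- native_wl[native_wl < 500 | native_wl > 520]
  expect_error(bin_wavelengths(gappy, gappy), "missing band")
})

test_that("dark-current subtraction clips at zero and is idempotent", {
  expect_equal(subtract_dark_current(rep(500, 201), rep(40, 201)),
               rep(460, 201))
  d <- simulate_dark_spectrum(noise = FALSE)$dn
  expect_equal(subtract_dark_current(d, d), rep(0, 201))
  once <- subtract_dark_current(rep(500, 201), rep(40, 201))
  expect_equal(subtract_dark_current(once, rep(0, 201)), once)
  expect_error(subtract_dark_current(rep(1, 201), rep(0, 5)), "mismatch")
})

test_that("the prior-night dark is the latest one before 04:00", {
  darks <- tibble::tibble(
    timestamp = as.POSIXct(c("2017-04-02 01:10", "2017-04-03 01:10"),
                           tz = "UTC"),
    dn = list(rep(1, 201), rep(2, 201)))
  expect_error(prior_night_dark(darks, as.Date("2017-04-01")),
               "missing dark")
  expect_equal(prior_night_dark(darks, as.Date("2017-04-02")), rep(1, 201))
  expect_equal(prior_night_dark(darks, as.Date("2017-04-03")), rep(2, 201))
  expect_equal(prior_night_dark(darks, as.Date("2017-04-09")), rep(2, 201))
})

test_that("reference LUT bins grey scans by PPFD in 10-umol steps", {
  two <- tibble::tibble(ppfd = c(104, 107),
                        dn = list(rep(10, 201), rep(20, 201)))
  lut <- build_reference_lut(two)
  expect_equal(lut$spectra[1, ], rep(15, 201))  # same 100-110 bin, averaged
  expect_equal(lut$centers[1], 105)
  expect_equal(lut$centers[length(lut$centers)], 1345)
  # scans outside [100, 1350] are discarded
  expect_error(build_reference_lut(tibble::tibble(ppfd = 60,
                                                  dn = list(rep(1, 201)))),
               "empty LUT")
  mixed <- tibble::tibble(ppfd = c(60, 104), dn = list(rep(1, 201),
                                                       rep(7, 201)))
  expect_equal(build_reference_lut(mixed)$n_scans[1], 1L)
  # empty bins are filled from the nearest populated bin
  expect_true(all(build_reference_lut(mixed)$spectra == 7))
  expect_true(build_reference_lut(mixed)$filled[50])
})

test_that("reflectance normalisation uses the 50%-panel algebra", {
  ref <- tibble::tibble(ppfd = 500, dn = list(rep(800, 201)))
  lut <- build_reference_lut(ref)
  # the panel measures itself: R = 0.5 everywhere
  expect_equal(normalize_reflectance(rep(800, 201), 500, lut),
               rep(0.5, 201))
  expect_equal(normalize_reflectance(rep(1600, 201), 500, lut),
               rep(1, 201))
  # below the LUT range: uncorrectable
  expect_null(normalize_reflectance(rep(800, 201), 60, lut))
})

test_that("grey-scan round trip recovers 0.5 within noise across 450-800 nm", {
  set.seed(5)
  lutscans <- tibble::tibble(
    ppfd = rep(c(400, 600, 800), each = 8),
    dn = lapply(rep(c(400, 600, 800), each = 8), function(pp) {
      subtract_dark_current(simulate_gray_reference(pp)$dn,
                            dark_current_dn(lift_wavelengths()))
    }))
  lut <- build_reference_lut(lutscans)
  probe <- subtract_dark_current(simulate_gray_reference(600)$dn,
                                 dark_current_dn(wl))
  r <- normalize_reflectance(probe, 600, lut)
  band <- wl >= 450 & wl <= 800
  expect_true(all(abs(r[band] - 0.5) < 0.02))
})

test_that("generator reflectance survives the full correction round trip", {
  pp <- 700
  dark <- simulate_dark_spectrum(noise = FALSE)$dn
  ref <- subtract_dark_current(simulate_gray_reference(pp, noise = FALSE)$dn,
                               dark)
  lut <- build_reference_lut(tibble::tibble(ppfd = pp, dn = list(ref)))
  canopy <- simulate_spectrum(list(chlorophyll_level = 0.8), ppfd = pp,
                              npq_state = 1, noise = FALSE)
  r <- normalize_reflectance(subtract_dark_current(canopy$dn, dark), pp, lut)
  truth <- vegetation_reflectance(wl, chlorophyll_level = 0.8, npq_state = 1)
  expect_lt(median(abs(r - truth)), 0.02)
})

test_that("index formulas reproduce hand-computed values and bounds", {
  r <- rep(0.2, 201)
  set_band <- function(r, band, v) { r[match(band, wl)] <- v; r }
  r <- set_band(r, 750, 0.5); r <- set_band(r, 706, 0.1)
  r <- set_band(r, 754, 0.45); r <- set_band(r, 710, 0.15)
  r <- set_band(r, 680, 0.05)
  idx <- compute_indices(r, corrected = r)
  expect_equal(idx$ndvi, 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(idx$mtci, 0.30 / 0.20, tolerance = 1e-12)
  expect_equal(idx$pndvi, idx$ndvi)
  # symmetric bands give zero
  flat <- rep(0.3, 201)
  expect_equal(compute_indices(flat, flat)$ndvi, 0)
  # zero denominator flags NA
  z <- rep(0, 201)
  expect_true(is.na(compute_indices(z, z)$ndvi))
  # reflectance sum covers 450-800 inclusive; r685 interpolates the grid
  one <- rep(1, 201)
  expect_equal(compute_indices(one)$reflectance_sum, sum(wl >= 450))
  expect_equal(compute_indices(seq_along(wl))$r685,
               mean(c(match(684, wl), match(686, wl))))
  # normalized-difference indices stay within [-1, 1] on nonnegative spectra
  set.seed(9)
  for (k in 1:20) {
    v <- runif(201, 0, 10)
    ii <- compute_indices(v, v)
    expect_true(all(abs(c(ii$ndvi, ii$ndvi_ii, ii$gndvi, ii$pri,
                          ii$pndvi, ii$pndvi_ii, ii$pgndvi, ii$ppri)) <= 1))
  }
})

test_that("simulated spectra respond to chlorophyll, NPQ and darkness", {
  r_full <- vegetation_reflectance(wl, chlorophyll_level = 1)
  r_pale <- vegetation_reflectance(wl, chlorophyll_level = 0.4)
  expect_gt(r_pale[match(680, wl)], r_full[match(680, wl)])
  r_npq <- vegetation_reflectance(wl, npq_state = 2.5)
  expect_lt(r_npq[match(530, wl)], r_full[match(530, wl)])
  # night spectrum is dark current only
  night <- simulate_spectrum(list(chlorophyll_level = 1), ppfd = 0,
                             noise = FALSE)
  expect_equal(night$dn, dark_current_dn(wl))
})

test_that("pseudo and corrected NDVI rank canopies identically", {
  pp <- 600
  dark <- simulate_dark_spectrum(noise = FALSE)$dn
  ref <- subtract_dark_current(simulate_gray_reference(pp, noise = FALSE)$dn,
                               dark)
  lut <- build_reference_lut(tibble::tibble(ppfd = pp, dn = list(ref)))
  chl <- seq(0.3, 1, length.out = 8)
  both <- sapply(chl, function(cl) {
    sp <- simulate_spectrum(list(chlorophyll_level = cl), ppfd = pp,
                            noise = FALSE)
    dn <- subtract_dark_current(sp$dn, dark)
    ii <- compute_indices(dn, normalize_reflectance(dn, pp, lut))
    c(ii$ndvi, ii$pndvi)
  })
  expect_equal(cor(both[1, ], both[2, ], method = "spearman"), 1)
})

test_that("each spectrum pairs with the transient taken just before", {
  transients <- tibble::tibble(measurement_id = c(1L, 2L),
                               plot_id = "A", line_index = "L1",
                               time_s = c(0, 4))
  spectra <- tibble::tibble(spectrum_id = 1:3, plot_id = "A",
                            line_index = "L1", time_s = c(-1, 2, 6))
  paired <- pair_spectrum_to_transient(spectra, transients)
  # F1,S1,F2,S2 interleaving: S->preceding F; a spectrum before any
  # transient stays unpaired
  expect_equal(paired$measurement_id, c(NA_integer_, 1L, 2L))

  camp <- small_campaign()
  canopy <- camp$spectra[camp$spectra$target == "canopy", ]
  paired <- pair_spectrum_to_transient(canopy, camp$transients)
  expect_true(all(!is.na(paired$measurement_id)))
  one_line <- paired[paired$line_index == paired$line_index[1], ]
  expect_equal(nrow(one_line), 6)
})

test_that("process_spectra yields one indexed row per canopy spectrum", {
  camp <- small_campaign()
  idx <- process_spectra(camp$spectra, camp$references, camp$transients)
  expect_equal(nrow(idx), sum(camp$spectra$target == "canopy"))
  expect_true(all(c("pndvi", "ppri", "reflectance_sum", "r685",
                    "measurement_id", "corrected") %in% names(idx)))
  # corrected indices exist exactly where PPFD reaches the LUT range
  expect_true(all(idx$corrected == (idx$ppfd >= 100)))
  expect_true(all(is.na(idx$ndvi[!idx$corrected])))
})
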