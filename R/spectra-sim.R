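#' Even 2-nm wavelength grid of the spectral tables
#'
#' @return Numeric vector, 400 to 800 nm in 2 nm steps (201 bins).
#' @export
lift_wavelengths <- function() seq(400, 800, by = 2)

# broadband irradiance spectral shape (arbitrary units, ~1 mid-band)
irradiance_shape <- function(wl) exp(-0.5 * ((wl - 570) / 160)^2)

# detector gain: digital numbers per (PPFD unit x shape unit)
.SPEC_GAIN <- 2

# dark-current digital numbers of the detector
dark_current_dn <- function(wl) 120 + 0.01 * (wl - 400)

#' Synthetic vegetation reflectance spectrum
#'
#' Phenomenological canopy reflectance on the 2-nm grid: a low visible
#' baseline with a green bump near 550 nm, a chlorophyll absorption trough
#' around 680 nm that fills in as `chlorophyll_level` decreases (emulating
#' chlorophyll-deficient mutants), a red edge rising to a near-infrared
#' plateau (~0.45), and a xanthophyll-cycle dip at 531 nm that deepens with
#' the non-photochemical quenching state (the physiological basis of PRI).
#'
#' @param wl Wavelength grid (nm).
#' @param chlorophyll_level In `(0, 1]`.
#' @param npq_state Current NPQ (dimensionless, >= 0).
#' @return Reflectance in `[0, 1]` per wavelength.
#' @export
vegetation_reflectance <- function(wl = lift_wavelengths(),
                                   chlorophyll_level = 1, npq_state = 0) {
  0.04 +
    0.06 * exp(-((wl - 550) / 20)^2) +
    0.10 * (1 - chlorophyll_level) * exp(-((wl - 678) / 25)^2) +
    0.41 * stats::plogis((wl - 712) / 9) -
    0.04 * (npq_state / (1 + npq_state)) * exp(-((wl - 531) / 7)^2)
}

# flat-ish bright soil reflectance (spectral outlier target)
soil_reflectance <- function(wl) 0.15 + 0.00025 * (wl - 400)

#' Simulate one raw canopy (or soil) spectrum
#'
#' Digital numbers = gain x irradiance(PPFD, wavelength) x reflectance x
#' amplitude + dark current + shot noise. At night (`ppfd = 0`) only dark
#' current and noise remain. With probability `soil_hit_rate` the spectrum
#' targets bare soil instead of canopy (the outlier class the spectral QC
#' fences are designed to catch).
#'
#' @param profile A [genotype_profile()] (or a list with
#'   `chlorophyll_level`).
#' @param ppfd Ambient PPFD (>= 0).
#' @param npq_state NPQ of the target at measurement time.
#' @param amplitude_scale Per-measurement amplitude factor.
#' @param soil_hit_rate Probability of targeting soil.
#' @param noise Logical; FALSE gives a noiseless spectrum.
#' @return List with `wavelengths`, `dn` (201 digital numbers), `target`
#'   ("canopy"; soil hits keep target "canopy" — they are content outliers,
#'   not labelled calibration scans) and `soil_hit` (logical).
#' @export
simulate_spectrum <- function(profile, ppfd, npq_state = 0,
                              amplitude_scale = 1, soil_hit_rate = 0,
                              noise = TRUE) {
  stopifnot(ppfd >= 0, npq_state >= 0)
  wl <- lift_wavelengths()
  soil_hit <- soil_hit_rate > 0 && stats::runif(1) < soil_hit_rate
  refl <- if (soil_hit) soil_reflectance(wl) else {
    vegetation_reflectance(wl, profile$chlorophyll_level, npq_state)
  }
  signal <- .SPEC_GAIN * ppfd * irradiance_shape(wl) * refl * amplitude_scale
  dn <- signal + dark_current_dn(wl)
  if (noise) dn <- dn + stats::rnorm(length(wl), 0, 2 + 0.02 * sqrt(signal))
  list(wavelengths = wl, dn = dn, target = "canopy", soil_hit = soil_hit)
}

#' Simulate a grey-reference panel spectrum
#'
#' The calibration panel reflects 50% of incoming irradiance at every
#' wavelength; its spectrum under the current PPFD anchors the
#' reference look-up table used for reflectance correction.
#'
#' @param ppfd Ambient PPFD (>= 0).
#' @param noise Logical; FALSE gives a noiseless spectrum.
#' @return List with `wavelengths`, `dn`, `target = "gray_reference"`.
#' @export
simulate_gray_reference <- function(ppfd, noise = TRUE) {
  stopifnot(ppfd >= 0)
  wl <- lift_wavelengths()
  signal <- .SPEC_GAIN * ppfd * irradiance_shape(wl) * 0.5
  dn <- signal + dark_current_dn(wl)
  if (noise) dn <- dn + stats::rnorm(length(wl), 0, 2 + 0.02 * sqrt(signal))
  list(wavelengths = wl, dn = dn, target = "gray_reference")
}

#' Simulate a night-time dark-current spectrum
#'
#' @param noise Logical; FALSE gives the bare dark-current curve.
#' @return List with `wavelengths`, `dn`, `target = "dark"`.
#' @export
simulate_dark_spectrum <- function(noise = TRUE) {
  wl <- lift_wavelengths()
  dn <- dark_current_dn(wl)
  if (noise) dn <- dn + stats::rnorm(length(wl), 0, 2)
  list(wavelengths = wl, dn = dn, target = "dark")
}
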