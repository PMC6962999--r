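#' Bin a native-resolution spectrum to the even 2-nm grid
#'
#' The spectrometer samples at roughly 0.46 nm resolution; raw digital
#' numbers are averaged to one value per full even wavelength between 400
#' and 800 nm. A native sample at wavelength `w` is assigned to the even
#' bin centre `c` with `c - 1 <= w < c + 1` (half-open intervals).
#'
#' @param wavelength Native wavelengths (nm), covering 400-800.
#' @param dn Digital numbers, same length.
#' @return List with `wavelengths` (the 201-bin grid) and `dn` (bin means).
#' @export
bin_wavelengths <- function(wavelength, dn) {
  stopifnot(length(wavelength) == length(dn))
  centre <- 2 * floor((wavelength + 1) / 2)
  keep <- centre >= 400 & centre <= 800
  centre <- centre[keep]; dn <- dn[keep]
  grid <- lift_wavelengths()
  means <- vapply(split(dn, factor(centre, levels = grid)), mean, numeric(1))
  if (anyNA(means)) {
    stop("missing band: no native samples for bins ",
         paste(grid[is.na(means)][seq_len(min(5, sum(is.na(means))))],
               collapse = ", "), call. = FALSE)
  }
  list(wavelengths = grid, dn = unname(means))
}

#' Subtract the dark current from a binned spectrum
#'
#' @param dn Digital numbers on the 2-nm grid.
#' @param dark Dark-current digital numbers on the same grid (from the
#'   preceding night).
#' @return Corrected digital numbers, clipped at zero.
#' @export
subtract_dark_current <- function(dn, dark) {
  if (length(dn) != length(dark)) {
    stop("spectrum/dark length mismatch", call. = FALSE)
  }
  pmax(dn - dark, 0)
}

#' Find the prior-night dark spectrum for a measurement day
#'
#' The dark reference for a given day is the latest `target = "dark"`
#' record taken before 04:00 of that day.
#'
#' @param darks Tibble of dark spectra with `timestamp` and list-column
#'   `dn`.
#' @param date The measurement day (`Date`).
#' @return The dark `dn` vector.
#' @export
prior_night_dark <- function(darks, date) {
  cutoff <- as.POSIXct(date, tz = "UTC") + 4 * 3600
  cand <- darks[darks$timestamp < cutoff, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("missing dark: no dark-current spectrum before 04:00 of ",
         format(date), call. = FALSE)
  }
  cand$dn[[which.max(as.numeric(cand$timestamp))]]
}

#' Build the PPFD-keyed grey-reference look-up table
#'
#' Grey-panel scans are matched to the PPFD of the same minute, grouped
#' into 10 umol photons m^-2 s^-1 bins spanning 100-1350, and averaged per
#' bin. Scans outside that range are discarded. Empty interior bins are
#' filled from the nearest non-empty bin (ties toward the lower bin) and
#' flagged.
#'
#' @param gray_scans Tibble with columns `ppfd` and list-column `dn`
#'   (dark-current already subtracted).
#' @return A `reference_lut`: list with `centers` (105, 115, ..., 1345),
#'   `spectra` (matrix, one row per bin), `n_scans` and `filled` (logical:
#'   bin borrowed from a neighbour).
#' @export
build_reference_lut <- function(gray_scans) {
  usable <- gray_scans$ppfd >= 100 & gray_scans$ppfd <= 1350
  if (!any(usable)) {
    stop("empty LUT: no grey-reference scans with PPFD in [100, 1350]",
         call. = FALSE)
  }
  scans <- gray_scans[usable, , drop = FALSE]
  edges <- seq(100, 1340, by = 10)
  centers <- edges + 5
  bin <- pmin(findInterval(scans$ppfd, c(edges, 1350.000001)), length(edges))
  nwl <- length(scans$dn[[1]])
  spectra <- matrix(NA_real_, nrow = length(centers), ncol = nwl)
  n_scans <- integer(length(centers))
  for (b in unique(bin)) {
    mat <- do.call(rbind, scans$dn[bin == b])
    spectra[b, ] <- colMeans(mat)
    n_scans[b] <- nrow(mat)
  }
  filled <- n_scans == 0
  if (any(filled)) {
    nonempty <- which(!filled)
    for (b in which(filled)) {
      # nearest non-empty bin; which.min takes the first (= lower) on ties
      spectra[b, ] <- spectra[nonempty[which.min(abs(nonempty - b))], ]
    }
  }
  structure(list(centers = centers, spectra = spectra, n_scans = n_scans,
                 filled = filled, wavelengths = lift_wavelengths()),
            class = "reference_lut")
}

#' @export
print.reference_lut <- function(x, ...) {
  cat(sprintf("<reference_lut> %d PPFD bins (105-1345), %d populated, %d filled from neighbours\n",
              length(x$centers), sum(!x$filled), sum(x$filled)))
  invisible(x)
}

#' Normalise a canopy spectrum to reflectance via the reference LUT
#'
#' The grey panel reflects 50% of incoming irradiance, so with the
#' reference spectrum closest in PPFD to the measurement,
#' `R(lambda) = dn(lambda) / (dn_ref(lambda) / 0.5)`. Ties between two
#' equally close PPFD bins go to the lower bin. Measurements below the LUT
#' range (PPFD < 100) are uncorrectable and return `NULL`.
#'
#' @param dn Dark-current-subtracted digital numbers on the 2-nm grid.
#' @param ppfd PPFD at measurement time.
#' @param lut A [build_reference_lut()] result.
#' @return Reflectance vector, or `NULL` when uncorrectable.
#' @export
normalize_reflectance <- function(dn, ppfd, lut) {
  stopifnot(inherits(lut, "reference_lut"))
  if (!is.finite(ppfd) || ppfd < 100) return(NULL)
  b <- which.min(abs(lut$centers - ppfd))
  ref <- lut$spectra[b, ]
  dn / (ref / 0.5)
}

.INDEX_BANDS <- list(
  ndvi = c(750, 706), ndvi_ii = c(740, 680), gndvi = c(740, 540),
  pri = c(530, 570)
)

band_value <- function(values, wl, band) values[match(band, wl)]

norm_diff <- function(a, b) {
  d <- a + b
  if (!is.finite(d) || d == 0) return(NA_real_)
  (a - b) / d
}

#' Compute spectral indices from raw and corrected spectra
#'
#' Pseudo-indices (prefix `p`) are always computed from the raw digital
#' numbers; corrected indices only when a reflectance spectrum is
#' available. Formulas: NDVI = (R750-R706)/(R750+R706), NDVI_II =
#' (R740-R680)/(R740+R680), GNDVI = (R740-R540)/(R740+R540), MTCI =
#' (R754-R710)/(R710+R680), PRI = (R530-R570)/(R530+R570). `reflectance_sum`
#' is the sum of the raw digital numbers over 450-800 nm inclusive; `r685`
#' is the raw signal at 685 nm (mean of the 684 and 686 nm bins on the even
#' grid). Zero denominators yield `NA`.
#'
#' @param raw_dn Raw (dark-subtracted) digital numbers on the 2-nm grid.
#' @param corrected Reflectance spectrum from [normalize_reflectance()], or
#'   `NULL`.
#' @param wl Wavelength grid.
#' @return One-row tibble with `ndvi`, `ndvi_ii`, `gndvi`, `mtci`, `pri`
#'   (NA when uncorrected), `pndvi`, `pndvi_ii`, `pgndvi`, `pmtci`, `ppri`,
#'   `reflectance_sum`, `r685`, `corrected` (logical).
#' @export
compute_indices <- function(raw_dn, corrected = NULL,
                            wl = lift_wavelengths()) {
  idx <- function(values) {
    v <- lapply(.INDEX_BANDS, function(b) {
      norm_diff(band_value(values, wl, b[1]), band_value(values, wl, b[2]))
    })
    den <- band_value(values, wl, 710) + band_value(values, wl, 680)
    v$mtci <- if (!is.finite(den) || den == 0) NA_real_ else
      (band_value(values, wl, 754) - band_value(values, wl, 710)) / den
    v
  }
  p <- idx(raw_dn)
  cor_ok <- !is.null(corrected)
  cc <- if (cor_ok) idx(corrected) else
    list(ndvi = NA_real_, ndvi_ii = NA_real_, gndvi = NA_real_,
         pri = NA_real_, mtci = NA_real_)
  tibble::tibble(
    ndvi = cc$ndvi, ndvi_ii = cc$ndvi_ii, gndvi = cc$gndvi,
    mtci = cc$mtci, pri = cc$pri,
    pndvi = p$ndvi, pndvi_ii = p$ndvi_ii, pgndvi = p$gndvi,
    pmtci = p$mtci, ppri = p$pri,
    reflectance_sum = sum(raw_dn[wl >= 450 & wl <= 800]),
    r685 = (band_value(raw_dn, wl, 684) + band_value(raw_dn, wl, 686)) / 2,
    corrected = cor_ok
  )
}

#' Pair each spectrum with the fluorescence measurement taken just before
#'
#' During a scan every fluorescence transient is immediately followed by a
#' spectral measurement; each spectrum is therefore associated with the
#' latest preceding transient of the same plot and scan line. Spectra with
#' no preceding transient in their line stay unpaired (`NA`).
#'
#' @param spectra Tibble with `spectrum_id`, `plot_id`, `line_index`,
#'   `time_s`.
#' @param transients Tibble with `measurement_id`, `plot_id`, `line_index`,
#'   `time_s`.
#' @return `spectra` with a `measurement_id` column added.
#' @export
pair_spectrum_to_transient <- function(spectra, transients) {
  key_t <- paste(transients$plot_id, transients$line_index)
  key_s <- paste(spectra$plot_id, spectra$line_index)
  t_split <- split(seq_len(nrow(transients)), key_t)
  mid <- rep(NA_integer_, nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    cand <- t_split[[key_s[i]]]
    if (is.null(cand)) next
    before <- cand[transients$time_s[cand] < spectra$time_s[i]]
    if (length(before) == 0) next
    mid[i] <- transients$measurement_id[
      before[which.max(transients$time_s[before])]]
  }
  spectra$measurement_id <- mid
  spectra
}

#' Process a campaign spectra table into a spectral-index table
#'
#' Full spectral chain: prior-night dark-current subtraction for canopy and
#' grey-reference scans, reference-LUT construction from the grey scans,
#' reflectance normalisation of every canopy spectrum whose PPFD is inside
#' the LUT range, index computation (corrected where possible, pseudo
#' always), and pairing to the preceding fluorescence measurement.
#'
#' @param spectra Campaign spectra tibble (canopy rows plus `target =
#'   "dark"` rows).
#' @param references Grey-reference scan tibble.
#' @param transients Transient table used for pairing (may be `NULL` to
#'   skip pairing).
#' @param lut Optional pre-built [build_reference_lut()]; built from
#'   `references` when `NULL`.
#' @return Tibble with one row per canopy spectrum: identifiers, `ppfd`,
#'   the index columns of [compute_indices()] and `measurement_id`.
#' @export
process_spectra <- function(spectra, references, transients = NULL,
                            lut = NULL) {
  darks <- spectra[spectra$target == "dark", , drop = FALSE]
  canopy <- spectra[spectra$target == "canopy", , drop = FALSE]
  if (nrow(canopy) == 0) stop("no canopy spectra to process", call. = FALSE)

  dark_for_day <- function(date) prior_night_dark(darks, date)
  dark_cache <- new.env(parent = emptyenv())
  get_dark <- function(date) {
    k <- format(date)
    if (is.null(dark_cache[[k]])) dark_cache[[k]] <- dark_for_day(date)
    dark_cache[[k]]
  }

  if (is.null(lut)) {
    refs <- references
    refs$dn <- lapply(seq_len(nrow(refs)), function(i) {
      subtract_dark_current(refs$dn[[i]], get_dark(refs$date[i]))
    })
    lut <- build_reference_lut(refs)
  }

  rows <- vector("list", nrow(canopy))
  for (i in seq_len(nrow(canopy))) {
    dn <- subtract_dark_current(canopy$dn[[i]], get_dark(canopy$date[i]))
    refl <- normalize_reflectance(dn, canopy$ppfd[i], lut)
    rows[[i]] <- compute_indices(dn, refl)
  }
  out <- dplyr::bind_cols(
    canopy[, setdiff(names(canopy), "dn"), drop = FALSE],
    dplyr::bind_rows(rows)
  )
  if (!is.null(transients)) {
    out <- pair_spectrum_to_transient(out, transients)
  }
  attr(out, "lut") <- lut
  out
}
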