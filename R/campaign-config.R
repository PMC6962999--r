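#' Configuration of a synthetic semi-field campaign
#'
#' Defines the study conditions the generator emulates: plots of genotypes
#' measured hourly by a scanning fluorometer over a run of days in an
#' unheated glasshouse, with minute-resolution environmental logging. The
#' defaults describe a two-genotype cold-contrast trial: 14 days with a
#' seasonal warming trend (diurnal range about 4-30 degC over the campaign),
#' hourly scans of every plot, 6 combined fluorescence + spectral
#' measurements per 300 mm scan line.
#'
#' @param plots Tibble/data frame with one row per plot: columns `plot_id`,
#'   `genotype`, `species`, `replicate`, `cold_tolerance`,
#'   `chlorophyll_level`, `sowing_date`. See [demo_plots()].
#' @param n_days Number of campaign days (>= 1).
#' @param start_date First campaign day (`Date`).
#' @param scans_per_day Scan rounds per day (hourly = 24).
#' @param measurements_per_scan Combined measurements per scan line; the
#'   instrument geometry yields 5 to 7.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param noise_sd_rel Relative Gaussian noise on fluorescence yields.
#' @param leaf_angle_sd Log-scale standard deviation of the per-measurement
#'   amplitude factor (canopy / leaf-angle variation).
#' @param canopy_light_sd Log-scale standard deviation of the
#'   per-measurement light-penetration factor: the PPFD experienced by the
#'   measured leaf is the station PPFD times this lognormal factor
#'   (sunflecks and shading inside the canopy), so quenching-related
#'   quantities (Fq'/Fm', PRI) carry information beyond the station PPFD.
#' @param soil_hit_rate Probability a canopy spectrum actually targets soil
#'   (spectral outlier injection; transients are unaffected).
#' @param kin Baseline [kinetic_params()] shared by all plots (the genotype
#'   profile modulates temperature sensitivity and reflectance).
#' @param ppfd_max Clear-sky midday PPFD, umol photons m^-2 s^-1.
#' @param t_base Length-2 numeric: daily-mean temperature at campaign start
#'   and end (linear seasonal ramp between them), deg C.
#' @param t_amp Diurnal temperature half-amplitude, deg C.
#' @return A validated `campaign_config` object.
#' @export
campaign_config <- function(plots = demo_plots(),
                            n_days = 14,
                            start_date = as.Date("2017-04-01"),
                            scans_per_day = 24,
                            measurements_per_scan = 6,
                            seed = 1L,
                            noise_sd_rel = 0.02,
                            leaf_angle_sd = 0.25,
                            canopy_light_sd = 0.4,
                            soil_hit_rate = 0.03,
                            kin = kinetic_params(),
                            ppfd_max = 1600,
                            t_base = c(10, 24),
                            t_amp = 6) {
  plots <- tibble::as_tibble(plots)
  needed <- c("plot_id", "genotype", "species", "replicate",
              "cold_tolerance", "chlorophyll_level", "sowing_date")
  if (!all(needed %in% names(plots))) {
    stop("plots must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(plots$plot_id)) stop("plot_id must be unique",
                                         call. = FALSE)
  if (!is.numeric(n_days) || n_days < 1) {
    stop("configuration error: n_days must be >= 1", call. = FALSE)
  }
  if (!measurements_per_scan %in% 5:7) {
    stop("configuration error: measurements_per_scan must be 5, 6 or 7",
         call. = FALSE)
  }
  if (!scans_per_day %in% 1:24) {
    stop("configuration error: scans_per_day must be in 1..24", call. = FALSE)
  }
  stopifnot(inherits(start_date, "Date"), length(t_base) == 2,
            noise_sd_rel >= 0, leaf_angle_sd >= 0, canopy_light_sd >= 0,
            soil_hit_rate >= 0, soil_hit_rate <= 1, ppfd_max > 0, t_amp >= 0)
  if (!inherits(kin, "kinetic_params")) kin <- do.call(kinetic_params, kin)
  structure(
    list(plots = plots, n_days = as.integer(n_days), start_date = start_date,
         scans_per_day = as.integer(scans_per_day),
         measurements_per_scan = as.integer(measurements_per_scan),
         seed = as.integer(seed), noise_sd_rel = noise_sd_rel,
         leaf_angle_sd = leaf_angle_sd, canopy_light_sd = canopy_light_sd,
         soil_hit_rate = soil_hit_rate,
         kin = kin, ppfd_max = ppfd_max, t_base = t_base, t_amp = t_amp),
    class = "campaign_config"
  )
}

#' Default demonstration plot layout
#'
#' Two soybean genotypes contrasting in cold tolerance (as in breeding
#' panels where some lines are bred for cold: here `coldtol` at 0.8 and
#' `coldsens` at 0.2), two replicates each (4 plots), sown 20 days before
#' the campaign start.
#'
#' @param start_date Campaign start, used to set the sowing date.
#' @return Tibble suitable for [campaign_config()].
#' @export
demo_plots <- function(start_date = as.Date("2017-04-01")) {
  tibble::tibble(
    plot_id = c("P01", "P02", "P03", "P04"),
    genotype = c("coldtol", "coldtol", "coldsens", "coldsens"),
    species = "soybean",
    replicate = c(1L, 2L, 1L, 2L),
    cold_tolerance = c(0.8, 0.8, 0.2, 0.2),
    chlorophyll_level = 1,
    sowing_date = start_date - 20
  )
}

# Derive a per-stage RNG seed from the top-level seed (kept inside 32-bit
# integer range; fixed multiplier so a manifest seed reproduces every stage).
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stage) %% 2147483647)
}
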