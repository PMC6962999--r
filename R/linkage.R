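#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Magnus formula for saturation vapour pressure,
#' `es = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa, with
#' `vpd = es * (1 - rh / 100)`.
#'
#' @param temperature Air temperature, deg C.
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @return VPD in kPa (vectorised).
#' @examples
#' compute_vpd(25, 50)   # ~1.58 kPa
#' compute_vpd(25, 100)  # 0
#' @export
compute_vpd <- function(temperature, rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100)) {
    stop("rh must lie in [0, 100]", call. = FALSE)
  }
  es <- 0.6108 * exp(17.27 * temperature / (temperature + 237.3))
  es * (1 - rh / 100)
}

#' Link measurements to environmental records of the same minute
#'
#' Measurement timestamps are truncated (not rounded) to the minute and
#' joined exactly against the environment table. When several sensor
#' stations report in the same minute their values are averaged first.
#' Measurements with no environmental record in their minute are kept but
#' flagged (`env_linked = FALSE`); downstream modelling excludes them.
#'
#' @param measurements Tibble with a POSIXct `timestamp` column.
#' @param env Environment tibble with `timestamp`, `ppfd`, `temperature`,
#'   `rh` (and optionally `station`).
#' @return `measurements` with columns `ppfd`, `temperature`, `rh`, `vpd`
#'   and `env_linked` appended (existing columns of those names are
#'   replaced).
#' @export
link_environment <- function(measurements, env) {
  stopifnot(inherits(measurements$timestamp, "POSIXct"),
            inherits(env$timestamp, "POSIXct"))
  env_min <- env |>
    dplyr::mutate(timestamp = trunc_minute(.data$timestamp)) |>
    dplyr::summarise(ppfd = mean(.data$ppfd),
                     temperature = mean(.data$temperature),
                     rh = mean(.data$rh), .by = "timestamp") |>
    dplyr::mutate(vpd = compute_vpd(.data$temperature, .data$rh))
  out <- measurements[, setdiff(names(measurements),
                                c("ppfd", "temperature", "rh", "vpd")),
                      drop = FALSE]
  out$timestamp <- trunc_minute(out$timestamp)
  out <- dplyr::left_join(out, env_min, by = "timestamp")
  out$env_linked <- !is.na(out$ppfd)
  out
}

trunc_minute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60,
             origin = "1970-01-01", tz = attr(ts, "tzone") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the observation table feeding the models
#'
#' One row per quality-filtered fluorescence measurement, left-joined with
#' its paired spectral indices (absent indices allowed), linked to the
#' environmental record of the same minute, and completed with calendar
#' covariates: days after sowing (whole days, sowing day = 0), ISO week,
#' month and hour of day.
#'
#' @param fluor QC-kept fluorescence parameter tibble (must carry
#'   `measurement_id`, `plot_id`, `timestamp`).
#' @param indices QC-kept spectral index tibble with `measurement_id`
#'   pairing (may be `NULL`).
#' @param env Environment tibble.
#' @param metadata Plot table with `plot_id` and `sowing_date`.
#' @return Observation tibble; rows without an environmental record carry
#'   `env_linked = FALSE`.
#' @export
assemble_observations <- function(fluor, indices, env, metadata) {
  if (!"sowing_date" %in% names(metadata) ||
      anyNA(metadata$sowing_date)) {
    stop("configuration error: metadata must provide sowing_date per plot",
         call. = FALSE)
  }
  obs <- fluor
  if (!is.null(indices) && nrow(indices) > 0) {
    idx_cols <- c("measurement_id", "ndvi", "ndvi_ii", "gndvi", "mtci",
                  "pri", "pndvi", "pndvi_ii", "pgndvi", "pmtci", "ppri",
                  "reflectance_sum", "r685", "corrected")
    idx <- indices[!is.na(indices$measurement_id),
                   intersect(idx_cols, names(indices)), drop = FALSE]
    obs <- dplyr::left_join(obs, idx, by = "measurement_id")
  }
  obs <- link_environment(obs, env)
  meta <- metadata[, intersect(c("plot_id", "sowing_date"), names(metadata)),
                   drop = FALSE]
  obs <- dplyr::left_join(obs, meta, by = "plot_id")
  obs_date <- as.Date(obs$timestamp, tz = "UTC")
  obs$date <- obs_date
  obs$das <- as.integer(obs_date - obs$sowing_date)
  if (any(obs$das < 0, na.rm = TRUE)) {
    stop("configuration error: measurements before sowing date",
         call. = FALSE)
  }
  obs$week <- as.integer(strftime(obs_date, "%V"))
  obs$month <- as.integer(strftime(obs_date, "%m"))
  obs$hour_of_day <- as.integer(strftime(obs$timestamp, "%H", tz = "UTC"))
  obs
}
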