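#' Generate a minute-resolution environmental log
#'
#' Simulates the sensor-station record of a semi-field campaign: one row per
#' minute per day with PPFD, air temperature and relative humidity. PPFD
#' follows a smooth diurnal arc (sunrise 06:00, sunset 20:00, zero at
#' night) modulated by seeded cloud flecks (a smooth autoregressive
#' transmission factor), temperature a diurnal sinusoid (minimum near 03:00,
#' maximum near 15:00) riding on a linear seasonal ramp between the two
#' `t_base` values, and relative humidity moves opposite to temperature and
#' light, clipped to `[20, 100]` percent.
#'
#' @param config A [campaign_config()].
#' @return Tibble with columns `timestamp` (POSIXct, UTC, minute), `date`,
#'   `minute_of_day`, `ppfd`, `temperature`, `rh`, `station`.
#' @examples
#' env <- generate_environment(campaign_config(n_days = 1))
#' nrow(env)  # 1440
#' @export
generate_environment <- function(config) {
  if (!inherits(config, "campaign_config")) {
    stop("configuration error: expected a campaign_config", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 1L))
  n_days <- config$n_days
  m <- 0:1439

  # solar elevation proxy: 0 outside 06:00-20:00
  sun <- sin(pi * (m - 360) / 840)
  sun[m < 360 | m > 1200] <- 0
  sun <- pmax(sun, 0)

  out <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    # cloud transmission: logistic-squashed AR(1), in [0.25, 1]
    z <- as.numeric(stats::filter(stats::rnorm(1440, 0, 0.35), 0.98,
                                  method = "recursive"))
    cloud <- 0.25 + 0.75 * stats::plogis(z + 1.2)
    ppfd <- round(config$ppfd_max * sun * cloud, 1)

    base <- config$t_base[1] +
      (config$t_base[2] - config$t_base[1]) * (d - 1) / max(1, n_days - 1)
    temp <- base + config$t_amp * sin(2 * pi * (m - 540) / 1440) +
      stats::rnorm(1440, 0, 0.2)
    rh <- pmin(100, pmax(20, 85 - 1.8 * (temp - base) - 0.015 * ppfd +
                           stats::rnorm(1440, 0, 1.5)))
    date <- config$start_date + (d - 1)
    out[[d]] <- tibble::tibble(
      timestamp = as.POSIXct(date, tz = "UTC") + 60 * m,
      date = date,
      minute_of_day = m,
      ppfd = ppfd,
      temperature = round(temp, 2),
      rh = round(rh, 1),
      station = "S1"
    )
  }
  dplyr::bind_rows(out)
}
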