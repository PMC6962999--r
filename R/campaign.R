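#' Generate a full synthetic campaign dataset bundle
#'
#' Runs the whole measurement emulation: a minute-resolution environment
#' table, then for every scan hour and every plot a line of
#' `measurements_per_scan` combined measurements taken 4 s apart, each a
#' fluorescence transient immediately followed (2 s later) by a spectral
#' measurement — the order the pairing rule downstream relies on. Line and
#' position indices are recorded so the repeated-spot rule ("third
#' measurement of each line") can be applied later. Each scan round also
#' records a grey-panel reference spectrum tagged with the concurrent PPFD,
#' and each night a dark-current spectrum for dark subtraction.
#'
#' All randomness is driven by `config$seed`; the same seed reproduces the
#' bundle exactly.
#'
#' @param config A [campaign_config()].
#' @return A `lift_campaign` list with tibbles `transients` (list-columns
#'   `yields`, `background`), `spectra` (list-column `dn`; includes the
#'   night `target = "dark"` rows), `references` (grey-panel scans), `env`,
#'   `metadata` (the plot table), plus the `schedule` and `config` used.
#' @examples
#' cfg <- campaign_config(n_days = 1, scans_per_day = 4,
#'                        plots = demo_plots()[1, ])
#' camp <- generate_campaign(cfg)
#' nrow(camp$transients)  # 4 scans x 6 measurements
#' @export
generate_campaign <- function(config) {
  if (!inherits(config, "campaign_config")) {
    stop("configuration error: expected a campaign_config", call. = FALSE)
  }
  env <- generate_environment(config)
  schedule <- flash_schedule()
  set.seed(derive_seed(config$seed, 2L))

  plots <- config$plots
  n_plots <- nrow(plots)
  hours <- unique(floor(seq(0, 23, length.out = config$scans_per_day)))
  m_per <- config$measurements_per_scan
  n_meas <- config$n_days * length(hours) * n_plots * m_per

  # pre-allocated columns
  plot_id <- character(n_meas); species <- character(n_meas)
  genotype <- character(n_meas); replicate <- integer(n_meas)
  day <- integer(n_meas); hour <- integer(n_meas)
  line_index <- character(n_meas); position <- integer(n_meas)
  time_s <- numeric(n_meas); ppfd_t <- numeric(n_meas)
  temp_t <- numeric(n_meas); yields <- vector("list", n_meas)
  background <- vector("list", n_meas)
  sp_ppfd <- numeric(n_meas); sp_time_s <- numeric(n_meas)
  sp_soil <- logical(n_meas); dn <- vector("list", n_meas)

  ppfd_env <- env$ppfd; temp_env <- env$temperature
  env_at <- function(d, sec) (d - 1L) * 1440L + (sec %/% 60) + 1L
  kin <- config$kin

  i <- 0L
  for (d in seq_len(config$n_days)) {
    for (h in hours) {
      for (p in seq_len(n_plots)) {
        line <- sprintf("d%02dh%02d-%s", d, h, plots$plot_id[p])
        scan_start <- h * 3600 + (p - 1) * 30
        for (j in seq_len(m_per)) {
          i <- i + 1L
          sec_f <- scan_start + (j - 1) * 4
          sec_s <- sec_f + 2
          row_f <- env_at(d, sec_f); row_s <- env_at(d, sec_s)
          pf <- ppfd_env[row_f]; tf <- temp_env[row_f]
          amp <- exp(stats::rnorm(1, 0, config$leaf_angle_sd))
          # light actually reaching the measured leaf: station PPFD times a
          # lognormal canopy-penetration factor (sunflecks / shading)
          light_fac <- exp(stats::rnorm(1, 0, config$canopy_light_sd))
          tr <- simulate_transient(
            kin, temperature = tf, ppfd = pf * light_fac,
            schedule = schedule,
            amplitude_scale = amp, noise_sd_rel = config$noise_sd_rel,
            cold_tolerance = plots$cold_tolerance[p])
          ps <- ppfd_env[row_s]
          sp <- simulate_spectrum(
            list(chlorophyll_level = plots$chlorophyll_level[p]),
            ppfd = ps * light_fac,
            npq_state = npq_at_ppfd(kin, ps * light_fac),
            amplitude_scale = amp, soil_hit_rate = config$soil_hit_rate)

          plot_id[i] <- plots$plot_id[p]; species[i] <- plots$species[p]
          genotype[i] <- plots$genotype[p]; replicate[i] <- plots$replicate[p]
          day[i] <- d; hour[i] <- h
          line_index[i] <- line; position[i] <- j
          time_s[i] <- sec_f; ppfd_t[i] <- pf; temp_t[i] <- tf
          yields[[i]] <- tr$yields; background[[i]] <- tr$background
          sp_ppfd[i] <- ps; sp_time_s[i] <- sec_s; sp_soil[i] <- sp$soil_hit
          dn[[i]] <- sp$dn
        }
      }
    }
  }

  date <- config$start_date + (day - 1L)
  day_origin <- as.POSIXct(date, tz = "UTC")
  transients <- tibble::tibble(
    measurement_id = seq_len(n_meas),
    plot_id = plot_id, species = species, genotype = genotype,
    replicate = replicate, date = date, day = day, hour = hour,
    line_index = line_index, position_in_line = position,
    time_s = time_s,
    timestamp = day_origin + (time_s - time_s %% 60),
    ambient_ppfd = ppfd_t, temperature = temp_t,
    adaptation_state = ifelse(ppfd_t < .DARK_PPFD, "dark", "light"),
    yields = yields, background = background
  )
  spectra <- tibble::tibble(
    spectrum_id = seq_len(n_meas),
    plot_id = plot_id, line_index = line_index,
    position_in_line = position, date = date, day = day, hour = hour,
    time_s = sp_time_s,
    timestamp = day_origin + (sp_time_s - sp_time_s %% 60),
    target = "canopy", ppfd = sp_ppfd, soil_hit = sp_soil, dn = dn
  )

  # grey-panel reference scans, one per scan round
  refs <- tidyr::expand_grid(d = seq_len(config$n_days), h = hours)
  ref_sec <- refs$h * 3600 + n_plots * 30 + 10
  ref_row <- (refs$d - 1L) * 1440L + (ref_sec %/% 60) + 1L
  ref_ppfd <- ppfd_env[ref_row]
  ref_dn <- lapply(ref_ppfd, function(pp) simulate_gray_reference(pp)$dn)
  ref_date <- config$start_date + (refs$d - 1L)
  references <- tibble::tibble(
    ref_id = seq_along(ref_sec), date = ref_date, day = refs$d, hour = refs$h,
    time_s = ref_sec,
    timestamp = as.POSIXct(ref_date, tz = "UTC") + (ref_sec - ref_sec %% 60),
    target = "gray_reference", ppfd = ref_ppfd, dn = ref_dn
  )

  # nightly dark-current spectra at 01:10 of every day
  dark_date <- config$start_date + seq_len(config$n_days) - 1L
  darks <- tibble::tibble(
    spectrum_id = n_meas + seq_len(config$n_days),
    plot_id = NA_character_, line_index = NA_character_,
    position_in_line = NA_integer_, date = dark_date,
    day = seq_len(config$n_days), hour = 1L, time_s = 4200,
    timestamp = as.POSIXct(dark_date, tz = "UTC") + 4200,
    target = "dark", ppfd = 0, soil_hit = FALSE,
    dn = lapply(seq_len(config$n_days), function(d) simulate_dark_spectrum()$dn)
  )

  structure(
    list(transients = transients,
         spectra = dplyr::bind_rows(spectra, darks),
         references = references, env = env, metadata = plots,
         schedule = schedule, config = config),
    class = "lift_campaign"
  )
}

#' @export
print.lift_campaign <- function(x, ...) {
  cat(sprintf(
    "<lift_campaign> %d transients, %d spectra, %d reference scans, %d env minutes, %d plots\n",
    nrow(x$transients), nrow(x$spectra), nrow(x$references), nrow(x$env),
    nrow(x$metadata)))
  invisible(x)
}

pack_series <- function(x) {
  vapply(x, function(v) paste(sprintf("%.6g", v), collapse = ";"),
         character(1))
}

unpack_series <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), as.numeric)
}

#' Write a campaign bundle to delimited text files
#'
#' Writes `transients.csv`, `spectra.csv`, `references.csv`, `env.csv`,
#' `metadata.csv` and a `manifest.json` (seed, key configuration fields and
#' MD5 digests of every file) into `dir`. Array-valued cells (flashlet
#' yields, spectra) are packed as `;`-separated strings. With
#' `format = "arrow"` Feather files are written instead of CSV (requires
#' the arrow package).
#'
#' @param campaign A `lift_campaign` bundle.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (default) or `"arrow"`.
#' @return Invisibly, the manifest as a list.
#' @export
write_campaign <- function(campaign, dir, format = c("csv", "arrow")) {
  format <- match.arg(format)
  stopifnot(inherits(campaign, "lift_campaign"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  tr <- campaign$transients
  tr$yields <- pack_series(tr$yields)
  tr$background <- pack_series(tr$background)
  sp <- campaign$spectra
  sp$dn <- pack_series(sp$dn)
  rf <- campaign$references
  rf$dn <- pack_series(rf$dn)

  tabs <- list(transients = tr, spectra = sp, references = rf,
               env = campaign$env, metadata = campaign$metadata)
  ext <- if (format == "csv") ".csv" else ".feather"
  paths <- file.path(dir, paste0(names(tabs), ext))
  for (k in seq_along(tabs)) {
    if (format == "csv") {
      readr::write_csv(tabs[[k]], paths[k])
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("the arrow package is required for format = \"arrow\"",
             call. = FALSE)
      }
      arrow::write_feather(tabs[[k]], paths[k])
    }
  }
  manifest <- list(
    seed = campaign$config$seed,
    n_days = campaign$config$n_days,
    start_date = as.character(campaign$config$start_date),
    plots = campaign$metadata$plot_id,
    format = format,
    files = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a campaign bundle written by [write_campaign()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A `lift_campaign` bundle (config is not reconstructed; the
#'   manifest is attached as `manifest`).
#' @export
read_campaign <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  tr <- rd("transients.csv")
  tr$yields <- unpack_series(tr$yields)
  tr$background <- unpack_series(tr$background)
  sp <- rd("spectra.csv")
  sp$dn <- unpack_series(sp$dn)
  rf <- rd("references.csv")
  rf$dn <- unpack_series(rf$dn)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(
    list(transients = tr, spectra = sp, references = rf,
         env = rd("env.csv"), metadata = rd("metadata.csv"),
         schedule = flash_schedule(), config = NULL, manifest = manifest),
    class = "lift_campaign"
  )
}
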