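#' Campaign quality-control rules
#'
#' The discard rules applied to fluorescence parameters and spectral
#' indices. Defaults: transients are discarded when SNR is lower than 50
#' for maize, rapeseed and soybean or lower than 100 for barley and wheat;
#' when Fv/Fm (resp. Fq'/Fm') or Fr1/Fv (resp. Fr1'/Fq') are below zero; or
#' when Fr1/Fv exceeds 0.35 or Fr2/Fv exceeds 0.8. Spectral indices are
#' removed when PPFD at measurement time was below 30 umol photons m^-2
#' s^-1, and per-species per-index outliers outside the Tukey fences
#' (quartiles +/- 1.5 IQR) are removed. Boundary semantics are strict:
#' values exactly at a threshold survive.
#'
#' @param snr_min Named numeric vector mapping species to their minimum
#'   SNR.
#' @param fr1_max,fr2_max Upper bounds on the two reoxidation ratios.
#' @param ppfd_min_spectral Minimum PPFD for spectral indices.
#' @param iqr_factor Tukey fence factor.
#' @param drop_third_in_line Whether the repeated-spot rule (position 3 in
#'   each scan line) applies.
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(snr_min = c(maize = 50, rapeseed = 50, soybean = 50,
                                 barley = 100, wheat = 100),
                     fr1_max = 0.35, fr2_max = 0.8,
                     ppfd_min_spectral = 30, iqr_factor = 1.5,
                     drop_third_in_line = TRUE) {
  stopifnot(all(snr_min > 0), fr1_max > 0, fr2_max > 0,
            ppfd_min_spectral >= 0, iqr_factor > 0)
  structure(list(snr_min = snr_min, fr1_max = fr1_max, fr2_max = fr2_max,
                 ppfd_min_spectral = ppfd_min_spectral,
                 iqr_factor = iqr_factor,
                 drop_third_in_line = isTRUE(drop_third_in_line)),
            class = "qc_rules")
}

qc_log_row <- function(row_id, rule, value, threshold) {
  tibble::tibble(row_id = row_id, rule = rule, value = value,
                 threshold = threshold)
}

#' Quality-filter a fluorescence parameter table
#'
#' Applies the transient discard rules (see [qc_rules()]). The rules are
#' conjunctive, so the kept set does not depend on their order; the
#' rejection log records the first rule fired per dropped row in the fixed
#' order snr, fvfm_negative, fr1_negative, fr1_high, fr2_high.
#'
#' @param params Tibble with columns `species`, `snr`, `fvfm`,
#'   `fr1_ratio`, `fr2_ratio` (e.g. from [process_transients()]).
#' @param rules A [qc_rules()] object.
#' @return List with `kept` (filtered tibble) and `log` (tibble `row_id`,
#'   `rule`, `value`, `threshold`).
#' @export
qc_fluorescence <- function(params, rules = qc_rules()) {
  stopifnot(inherits(rules, "qc_rules"))
  if (!all(params$species %in% names(rules$snr_min))) {
    bad <- setdiff(unique(params$species), names(rules$snr_min))
    stop("configuration error: no SNR threshold for species ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  thr <- unname(rules$snr_min[params$species])
  checks <- list(
    snr = list(fail = params$snr < thr, value = params$snr, threshold = thr),
    fvfm_negative = list(fail = params$fvfm < 0, value = params$fvfm,
                         threshold = 0),
    fr1_negative = list(fail = params$fr1_ratio < 0,
                        value = params$fr1_ratio, threshold = 0),
    fr1_high = list(fail = params$fr1_ratio > rules$fr1_max,
                    value = params$fr1_ratio, threshold = rules$fr1_max),
    fr2_high = list(fail = params$fr2_ratio > rules$fr2_max,
                    value = params$fr2_ratio, threshold = rules$fr2_max)
  )
  row_id <- if ("measurement_id" %in% names(params)) params$measurement_id
            else seq_len(nrow(params))
  fired <- rep(NA_character_, nrow(params))
  logs <- list()
  for (nm in names(checks)) {
    ck <- checks[[nm]]
    new_fail <- which(ck$fail & is.na(fired))
    if (length(new_fail)) {
      fired[new_fail] <- nm
      logs[[nm]] <- qc_log_row(row_id[new_fail], nm, ck$value[new_fail],
                               if (length(ck$threshold) > 1)
                                 ck$threshold[new_fail] else ck$threshold)
    }
  }
  keep <- is.na(fired)
  list(kept = params[keep, , drop = FALSE],
       log = if (length(logs)) dplyr::bind_rows(logs) else qc_log_row(
         integer(0), character(0), numeric(0), numeric(0)))
}

#' Quality-filter a spectral-index table
#'
#' Two stages: rows whose linked PPFD is below the threshold are dropped;
#' then, per species and per index, rows whose value falls outside the
#' Tukey fences `[Q1 - f * IQR, Q3 + f * IQR]` of that species' values are
#' dropped (soil hits and similar targeting errors). Species groups with
#' fewer than 4 rows skip the fences (logged with rule `fences_skipped`).
#'
#' @param indices Tibble with columns `species`, `ppfd` and index columns.
#' @param rules A [qc_rules()] object.
#' @param index_cols Index columns fenced (default: the five pseudo-indices
#'   plus the five corrected indices where present).
#' @return List with `kept` and `log` as in [qc_fluorescence()].
#' @export
qc_spectral <- function(indices, rules = qc_rules(),
                        index_cols = c("pndvi", "pndvi_ii", "pgndvi",
                                       "pmtci", "ppri", "ndvi", "ndvi_ii",
                                       "gndvi", "mtci", "pri")) {
  stopifnot(inherits(rules, "qc_rules"), "ppfd" %in% names(indices))
  index_cols <- intersect(index_cols, names(indices))
  row_id <- if ("spectrum_id" %in% names(indices)) indices$spectrum_id
            else seq_len(nrow(indices))
  logs <- list()

  low <- indices$ppfd < rules$ppfd_min_spectral
  if (any(low)) {
    logs$ppfd <- qc_log_row(row_id[low], "ppfd_low", indices$ppfd[low],
                            rules$ppfd_min_spectral)
  }
  kept <- indices[!low, , drop = FALSE]
  kept_id <- row_id[!low]

  drop <- rep(FALSE, nrow(kept))
  for (sp in unique(kept$species)) {
    sel <- which(kept$species == sp)
    if (length(sel) < 4) {
      logs[[paste0("skip_", sp)]] <- qc_log_row(
        NA_integer_, "fences_skipped", length(sel), 4)
      next
    }
    for (col in index_cols) {
      v <- kept[[col]][sel]
      fin <- is.finite(v)
      if (sum(fin) < 4) next
      q <- stats::quantile(v[fin], c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      lo <- q[1] - rules$iqr_factor * iqr
      hi <- q[2] + rules$iqr_factor * iqr
      out <- which(fin & (v < lo | v > hi))
      if (length(out)) {
        idx <- sel[out]
        new <- idx[!drop[idx]]
        if (length(new)) {
          logs[[paste(sp, col, sep = "_")]] <- qc_log_row(
            kept_id[new], paste0("fence_", col), kept[[col]][new],
            ifelse(kept[[col]][new] < lo, lo, hi))
        }
        drop[idx] <- TRUE
      }
    }
  }
  list(kept = kept[!drop, , drop = FALSE],
       log = if (length(logs)) dplyr::bind_rows(logs) else qc_log_row(
         integer(0), character(0), numeric(0), numeric(0)))
}

#' Drop the repeated-spot measurement of each scan line
#'
#' The scanning platform pauses at the end of each 300 mm line, so the
#' third measurement of a line most likely hit the same spot as the second;
#' rows with `position_in_line == 3` (1-based) are removed.
#'
#' @param measurements Tibble with a `position_in_line` column.
#' @return The filtered tibble.
#' @export
drop_repeated_position <- function(measurements) {
  stopifnot("position_in_line" %in% names(measurements))
  measurements[is.na(measurements$position_in_line) |
                 measurements$position_in_line != 3, , drop = FALSE]
}
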