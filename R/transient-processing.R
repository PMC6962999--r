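#' Subtract the ambient background channel from a transient
#'
#' Under ambient light the instrument estimates background irradiation in
#' the detector band between flashlets; that estimate is subtracted from
#' every flashlet yield, clipping at zero. The background of the returned
#' trace is set to zero, so the operation is idempotent. The original
#' background vector is retained as `background_raw` (the noise reference
#' for [compute_snr()]).
#'
#' @param trace A `transient_trace`.
#' @return The corrected `transient_trace`.
#' @export
subtract_background <- function(trace) {
  stopifnot(inherits(trace, "transient_trace"))
  if (length(trace$background) != length(trace$yields)) {
    stop("malformed trace: background/yield length mismatch", call. = FALSE)
  }
  if (any(!is.finite(trace$background)) || any(trace$background < 0)) {
    stop("background must be finite and nonnegative", call. = FALSE)
  }
  if (is.null(trace$background_raw)) trace$background_raw <- trace$background
  trace$yields <- pmax(trace$yields - trace$background, 0)
  trace$background <- rep(0, length(trace$background))
  trace
}

#' Retrieve minimum and maximum fluorescence from a transient
#'
#' For the 0.75 ms fast-repetition-rate flash, the minimum yield Fo (F' in
#' the light) is the yield of the first flashlet and the maximum yield Fm
#' (Fm') is the mean of the 301st and 302nd flashlets — the first two
#' relaxation flashlets. The 300th (last induction) flashlet is not used
#' for Fm because quenching develops during the induction phase. Flashlet
#' ordinals are 1-based.
#'
#' @param trace A background-subtracted `transient_trace`.
#' @return Named numeric vector `c(fo = , fm = )`.
#' @export
extract_fo_fm <- function(trace) {
  stopifnot(inherits(trace, "transient_trace"))
  y <- trace$yields
  if (length(y) < 302) {
    stop("malformed trace: at least 302 flashlets required, got ",
         length(y), call. = FALSE)
  }
  c(fo = y[1], fm = (y[301] + y[302]) / 2)
}

#' PSII quantum efficiency from the minimum and maximum yield
#'
#' `(fm - fo) / fm`: the maximum PSII efficiency Fv/Fm for dark-adapted
#' measurements; the identical computation on a light-adapted trace yields
#' the operating efficiency Fq'/Fm'.
#'
#' @param fo,fm Minimum and maximum fluorescence yield; `fm` must be
#'   positive.
#' @return The efficiency ratio.
#' @export
compute_psii_efficiency <- function(fo, fm) {
  if (!is.finite(fm) || fm <= 0) {
    stop("degenerate trace: fm must be positive", call. = FALSE)
  }
  (fm - fo) / fm
}

#' Reoxidation (electron-transport) efficiency over a relaxation window
#'
#' The area between Fm and the actual fluorescence F(t) is integrated over
#' the window and normalised to the area of Fv over the same range:
#' `ratio = integral(fm - F(t)) dt / ((fm - fo) * (t_end - t_start))`.
#' A value of 0 means no relaxation (F stuck at Fm, reoxidation blocked),
#' 1 means complete relaxation to Fo within the window. With the standard
#' windows this yields Fr1/Fv (0.8-1.47 ms) and Fr2/Fv (0.8-5.9 ms) in the
#' dark, and Fr1'/Fq', Fr2'/Fq' in the light.
#'
#' Integration is trapezoidal over the flashlet samples inside the window,
#' with linear interpolation of F at both window edges (exact for
#' piecewise-linear data).
#'
#' @param trace A background-subtracted `transient_trace`.
#' @param fo,fm Minimum/maximum yield from [extract_fo_fm()]; `fm > fo`
#'   required.
#' @param window A [relaxation_window()].
#' @return The efficiency ratio (unitless).
#' @export
compute_reoxidation_efficiency <- function(trace, fo, fm, window) {
  stopifnot(inherits(trace, "transient_trace"),
            inherits(window, "relaxation_window"))
  if (!is.finite(fm) || !is.finite(fo) || fm <= fo) {
    stop("degenerate trace: fm must exceed fo", call. = FALSE)
  }
  t <- trace$schedule$times
  y <- trace$yields
  inside <- t > window$t_start & t < window$t_end
  if (sum(inside) < 1 || window$t_start < min(t) || window$t_end > max(t)) {
    stop("insufficient samples: window [", window$t_start, ", ",
         window$t_end, "] ms not covered by the schedule", call. = FALSE)
  }
  edge <- stats::approx(t, y, xout = c(window$t_start, window$t_end))$y
  tt <- c(window$t_start, t[inside], window$t_end)
  yy <- c(edge[1], y[inside], edge[2])
  area <- pracma::trapz(tt, fm - yy)
  area / ((fm - fo) * (window$t_end - window$t_start))
}

#' Signal-to-noise ratio of a transient
#'
#' Defined as the maximum fluorescence yield divided by the standard
#' deviation of the background-channel samples; a noiseless background
#' yields `Inf`. This makes the species-specific SNR discard thresholds
#' (50, 100) meaningful: weak fluorescence over a noisy ambient background
#' scores low.
#'
#' @param trace A `transient_trace` (background-subtracted or raw; the raw
#'   background channel is used as the noise reference).
#' @param fm Optional precomputed maximum yield; extracted from the trace
#'   when omitted.
#' @return The SNR (possibly `Inf`).
#' @export
compute_snr <- function(trace, fm = NULL) {
  stopifnot(inherits(trace, "transient_trace"))
  bg <- if (!is.null(trace$background_raw)) trace$background_raw else
    trace$background
  if (is.null(fm)) {
    fm <- extract_fo_fm(subtract_background(trace))[["fm"]]
  }
  s <- stats::sd(bg)
  if (!is.finite(s) || s == 0) return(Inf)
  fm / s
}

#' Process one transient into its fluorescence parameter set
#'
#' Composition of the processing chain: background subtraction, Fo/Fm
#' retrieval, PSII efficiency, the two reoxidation-efficiency statistics
#' (windows W1 = 0.8-1.47 ms and W2 = 0.8-5.9 ms), and SNR.
#'
#' @param trace A `transient_trace`.
#' @param windows List of two [relaxation_window()]s, `w1` and `w2`.
#' @return One-row tibble: `fo`, `fm`, `fv`, `fvfm`, `fr1_ratio`,
#'   `fr2_ratio`, `snr`, `adaptation_state`. In the dark the ratios are
#'   Fv/Fm, Fr1/Fv, Fr2/Fv; in the light Fq'/Fm', Fr1'/Fq', Fr2'/Fq'.
#' @export
process_transient <- function(trace, windows = relaxation_windows()) {
  trace <- subtract_background(trace)
  fofm <- extract_fo_fm(trace)
  fo <- fofm[["fo"]]; fm <- fofm[["fm"]]
  fvfm <- compute_psii_efficiency(fo, fm)
  fr1 <- compute_reoxidation_efficiency(trace, fo, fm, windows$w1)
  fr2 <- compute_reoxidation_efficiency(trace, fo, fm, windows$w2)
  tibble::tibble(
    fo = fo, fm = fm, fv = fm - fo, fvfm = fvfm,
    fr1_ratio = fr1, fr2_ratio = fr2,
    snr = compute_snr(trace, fm = fm),
    adaptation_state = trace$adaptation_state
  )
}

#' Process a campaign transient table into a parameter table
#'
#' Applies [process_transient()] to every row of a transients table (as
#' produced by [generate_campaign()] or read from disk), carrying the
#' measurement metadata through. Rows whose processing fails (e.g. flat
#' degenerate traces) are dropped with a message and listed in the
#' `failures` attribute.
#'
#' @param transients Tibble with list-columns `yields` and `background`
#'   plus metadata columns.
#' @param schedule The [flash_schedule()] the yields were sampled on.
#' @param windows Relaxation windows, see [relaxation_windows()].
#' @return Tibble with one row per successfully processed measurement:
#'   metadata columns followed by the `FluorescenceParams` fields.
#' @export
process_transients <- function(transients, schedule = flash_schedule(),
                               windows = relaxation_windows()) {
  # adaptation_state is recomputed per trace, so an incoming copy is dropped
  meta_cols <- setdiff(names(transients),
                       c("yields", "background", "adaptation_state"))
  n <- nrow(transients)
  out <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    tr <- new_transient_trace(
      schedule = schedule,
      yields = transients$yields[[i]],
      background = transients$background[[i]],
      ambient_ppfd = if ("ambient_ppfd" %in% meta_cols)
        transients$ambient_ppfd[i] else 0
    )
    res <- tryCatch(process_transient(tr, windows), error = function(e) e)
    if (inherits(res, "error")) next
    out[[i]] <- res
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no transient could be processed", call. = FALSE)
  params <- dplyr::bind_cols(
    transients[ok, meta_cols, drop = FALSE],
    dplyr::bind_rows(out[ok])
  )
  if (any(!ok)) {
    message(sum(!ok), " transient(s) failed processing and were dropped")
  }
  attr(params, "failures") <- which(!ok)
  params
}
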