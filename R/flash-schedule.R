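#' Flashlet timing schedule of a fast-repetition-rate measurement
#'
#' Builds the timing grid of one FRR measurement: a 0.75 ms excitation
#' (induction) phase of 300 uniformly spaced sub-saturating flashlets that
#' cumulatively closes PSII reaction centres, followed by a 200 ms relaxation
#' phase of 127 flashlets fired at a decreasing repetition rate so that the
#' early Qa- reoxidation kinetics (sub-millisecond to a few milliseconds) are
#' densely sampled while the tail is sparse.
#'
#' The relaxation gaps grow geometrically, starting from the induction
#' flashlet spacing; the growth ratio is solved numerically so the final
#' flashlet lands exactly at `induction_ms + relaxation_ms` after the first
#' flashlet. The instrument itself only guarantees "decreasing repetition
#' rate over 200 ms", so the geometric profile is a modelling choice (see the
#' package vignette).
#'
#' @param n_induction Number of excitation flashlets (default 300).
#' @param n_relaxation Number of relaxation flashlets (default 127).
#' @param induction_ms Duration of the excitation phase in ms (default 0.75).
#' @param relaxation_ms Duration of the relaxation phase in ms (default 200).
#' @return An object of class `flash_schedule`: a list with `times` (427
#'   strictly increasing flashlet times in ms, first at 0), `n_induction` and
#'   `n_relaxation`.
#' @examples
#' sched <- flash_schedule()
#' length(sched$times)       # 427
#' sched$times[300]          # 0.75
#' @export
flash_schedule <- function(n_induction = 300L, n_relaxation = 127L,
                           induction_ms = 0.75, relaxation_ms = 200) {
  stopifnot(n_induction >= 2, n_relaxation >= 2,
            induction_ms > 0, relaxation_ms > 0)
  t_ind <- seq(0, induction_ms, length.out = n_induction)
  d0 <- induction_ms / (n_induction - 1)

  # gap_k = d0 * r^k for k = 1..n_relaxation must sum to relaxation_ms
  gap_sum <- function(r) d0 * r * (r^n_relaxation - 1) / (r - 1) - relaxation_ms
  r <- stats::uniroot(gap_sum, c(1 + 1e-9, 4), tol = 1e-14)$root
  gaps <- d0 * r^seq_len(n_relaxation)
  t_rel <- induction_ms + cumsum(gaps)
  t_rel[n_relaxation] <- induction_ms + relaxation_ms  # pin the endpoint

  structure(
    list(times = c(t_ind, t_rel),
         n_induction = as.integer(n_induction),
         n_relaxation = as.integer(n_relaxation),
         gap_ratio = r),
    class = "flash_schedule"
  )
}

#' @export
print.flash_schedule <- function(x, ...) {
  cat(sprintf(
    "<flash_schedule> %d induction flashlets over %.3g ms + %d relaxation flashlets to %.4g ms (gap ratio %.5f)\n",
    x$n_induction, x$times[x$n_induction], x$n_relaxation,
    x$times[length(x$times)], x$gap_ratio))
  invisible(x)
}

#' Relaxation integration windows for the reoxidation-efficiency statistics
#'
#' The two time ranges over which fluorescence relaxation is integrated,
#' measured from the first excitation flashlet: W1 = 0.8-1.47 ms captures the
#' fast Qa- to Qb electron transfer phase (the "0.65 ms" statistic Fr1/Fv)
#' and W2 = 0.8-5.9 ms additionally covers Qb(2-)/plastoquinone exchange
#' (the "5 ms" statistic Fr2/Fv).
#'
#' @return Named list of two `relaxation_window` objects, `w1` and `w2`,
#'   each with `t_start`, `t_end` (ms) and `label`.
#' @export
relaxation_windows <- function() {
  list(
    w1 = relaxation_window(0.8, 1.47, "fr1"),
    w2 = relaxation_window(0.8, 5.9, "fr2")
  )
}

#' Construct a relaxation integration window
#'
#' @param t_start,t_end Window bounds in ms from the first excitation
#'   flashlet; must lie inside the relaxation phase (0.75, 200.75].
#' @param label Short name carried into outputs.
#' @return A `relaxation_window` object.
#' @export
relaxation_window <- function(t_start, t_end, label = "window") {
  stopifnot(is.numeric(t_start), is.numeric(t_end),
            t_start > 0.75, t_start < t_end, t_end <= 200.75)
  structure(list(t_start = t_start, t_end = t_end, label = label),
            class = "relaxation_window")
}
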