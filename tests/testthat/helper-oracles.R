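# Closed-form oracle for the area-ratio reoxidation statistic on a
# sum-of-exponentials relaxation F(t) = fo + (fm - fo) * sum(amp * exp(-(t - t0)/tau)):
# ratio = 1 - sum(amp_i * tau_i * (exp(-(t1-t0)/tau_i) - exp(-(t2-t0)/tau_i))) / (t2 - t1)
closed_form_ratio <- function(taus, amps, window, t0 = 0.75) {
  stopifnot(abs(sum(amps) - 1) < 1e-12)
  t1 <- window$t_start; t2 <- window$t_end
  1 - sum(amps * taus * (exp(-(t1 - t0) / taus) - exp(-(t2 - t0) / taus))) /
    (t2 - t1)
}

# independent fine-grid numeric quadrature of the same integral
quadrature_ratio <- function(taus, amps, window, t0 = 0.75, n = 200001) {
  tt <- seq(window$t_start, window$t_end, length.out = n)
  decay <- rowSums(sapply(seq_along(taus),
                          function(i) amps[i] * exp(-(tt - t0) / taus[i])))
  pracma::trapz(tt, 1 - decay) / (window$t_end - window$t_start)
}

# build a noiseless trace with an exact exponential-mixture relaxation;
# induction flashlets ramp from fo to fm so Fo/Fm retrieval stays exact
make_exp_trace <- function(fo, fm, taus, amps, schedule = flash_schedule()) {
  t <- schedule$times
  n_ind <- schedule$n_induction
  y <- numeric(length(t))
  y[seq_len(n_ind)] <- seq(fo, fm, length.out = n_ind)
  rel <- (n_ind + 1):length(t)
  decay <- rowSums(sapply(seq_along(taus),
                          function(i) amps[i] * exp(-(t[rel] - t[n_ind]) / taus[i])))
  y[rel] <- fo + (fm - fo) * decay
  new_transient_trace(schedule, yields = y, background = 0)
}

# uniform ultra-dense schedule for convergence checks
dense_schedule <- function(n_relaxation = 10000) {
  t_ind <- seq(0, 0.75, length.out = 300)
  t_rel <- seq(0.75, 200.75, length.out = n_relaxation + 1)[-1]
  structure(list(times = c(t_ind, t_rel), n_induction = 300L,
                 n_relaxation = as.integer(n_relaxation)),
            class = "flash_schedule")
}
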