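sched <- flash_schedule()

test_that("background subtraction is exact, clipped and idempotent", {
  tr <- new_transient_trace(sched, yields = rep(100, 427), background = 20)
  out <- subtract_background(tr)
  expect_equal(out$yields, rep(80, 427))
  expect_equal(out$background, rep(0, 427))
  # idempotent once the background is zeroed
  expect_equal(subtract_background(out)$yields, out$yields)
  # zero background is the identity
  tr0 <- new_transient_trace(sched, yields = rep(100, 427), background = 0)
  expect_equal(subtract_background(tr0)$yields, tr0$yields)
  # clipping at zero
  trc <- new_transient_trace(sched, yields = rep(10, 427), background = 25)
  expect_equal(subtract_background(trc)$yields, rep(0, 427))
  # malformed traces are refused
  bad <- tr; bad$background <- bad$background[1:10]
  expect_error(subtract_background(bad), "malformed")
})

test_that("Fo and Fm come from the defining flashlet ordinals", {
  y <- rep(2000, 427)
  y[1] <- 1000; y[300] <- 9999  # the 300th flashlet must never enter Fm
  y[301] <- 4000; y[302] <- 4100
  tr <- new_transient_trace(sched, yields = y, background = 0)
  expect_equal(extract_fo_fm(tr), c(fo = 1000, fm = 4050))

  flat <- new_transient_trace(sched, yields = rep(500, 427), background = 0)
  expect_equal(extract_fo_fm(flat), c(fo = 500, fm = 500))

  short <- structure(list(times = sched$times[1:200], n_induction = 300L,
                          n_relaxation = 127L), class = "flash_schedule")
  expect_error(extract_fo_fm(new_transient_trace(short, rep(1, 200))),
               "302")
})

test_that("PSII efficiency follows its defining arithmetic", {
  expect_equal(compute_psii_efficiency(1000, 5000), 0.8)
  expect_equal(compute_psii_efficiency(700, 700), 0)
  expect_equal(compute_psii_efficiency(0, 5000), 1)
  expect_error(compute_psii_efficiency(10, 0), "degenerate")
  expect_error(compute_psii_efficiency(10, -5), "degenerate")
})

test_that("reoxidation efficiency matches the closed-form integral", {
  w <- relaxation_windows()
  fo <- 1000; fm <- 5000

  # boundary cases: no relaxation and complete relaxation
  tr_fm <- new_transient_trace(sched, yields = rep(fm, 427), background = 0)
  expect_equal(compute_reoxidation_efficiency(tr_fm, fo, fm, w$w2), 0,
               tolerance = 1e-12)
  tr_fo <- new_transient_trace(sched, yields = rep(fo, 427), background = 0)
  expect_equal(compute_reoxidation_efficiency(tr_fo, fo, fm, w$w2), 1,
               tolerance = 1e-12)

  # single- and multi-exponential relaxations against the analytic oracle
  cases <- list(list(taus = 2, amps = 1),
                list(taus = 0.6, amps = 1),
                list(taus = c(0.2, 0.7, 2.5), amps = c(0.08, 0.17, 0.75)),
                list(taus = c(0.2, 3), amps = c(0.5, 0.5)))
  for (cs in cases) {
    tr <- make_exp_trace(fo, fm, cs$taus, cs$amps)
    for (win in w) {
      got <- compute_reoxidation_efficiency(tr, fo, fm, win)
      want <- closed_form_ratio(cs$taus, cs$amps, win)
      expect_equal(got, want, tolerance = 1e-3)
      # closed form itself cross-checked by independent quadrature
      expect_equal(want, quadrature_ratio(cs$taus, cs$amps, win),
                   tolerance = 1e-9)
    }
  }

  # frozen reference values for the canonical tau = 2 ms single exponential
  tr2 <- make_exp_trace(fo, fm, 2, 1)
  expect_equal(compute_reoxidation_efficiency(tr2, fo, fm, w$w2), 0.6474,
               tolerance = 1e-3)
  expect_equal(compute_reoxidation_efficiency(tr2, fo, fm, w$w1), 0.1712,
               tolerance = 1e-3)
})

test_that("trapezoid integration converges on dense uniform schedules", {
  # trapezoid error shrinks quadratically with the sampling interval
  # (worst case: the fast 0.2 ms phase inside the short fr1 window)
  w <- relaxation_windows()
  grids <- list(list(n = 10000, tol = 2e-4), list(n = 100000, tol = 2e-6))
  for (g in grids) {
    ds <- dense_schedule(g$n)
    for (cs in list(list(taus = 2, amps = 1),
                    list(taus = c(0.2, 0.7, 2.5),
                         amps = c(0.08, 0.17, 0.75)))) {
      tr <- make_exp_trace(1000, 5000, cs$taus, cs$amps, schedule = ds)
      for (win in w) {
        got <- compute_reoxidation_efficiency(tr, 1000, 5000, win)
        want <- closed_form_ratio(cs$taus, cs$amps, win)
        expect_lt(abs(got - want) / want, g$tol)
      }
    }
  }
})

test_that("fr2 decreases in every time constant; windows nest", {
  w <- relaxation_windows()
  base <- list(taus = c(0.2, 0.7, 2.5), amps = c(0.2, 0.3, 0.5))
  fr2_of <- function(taus) {
    tr <- make_exp_trace(1000, 5000, taus, base$amps)
    compute_reoxidation_efficiency(tr, 1000, 5000, w$w2)
  }
  for (i in 1:3) {
    slower <- base$taus; slower[i] <- slower[i] * 1.5
    expect_lt(fr2_of(slower), fr2_of(base$taus))
  }
  # fr1 <= fr2 on monotone relaxations
  for (tau in c(0.3, 1, 3, 10)) {
    tr <- make_exp_trace(1000, 5000, tau, 1)
    expect_lte(compute_reoxidation_efficiency(tr, 1000, 5000, w$w1),
               compute_reoxidation_efficiency(tr, 1000, 5000, w$w2))
  }
  expect_error(
    compute_reoxidation_efficiency(make_exp_trace(1000, 5000, 2, 1),
                                   fo = 5000, fm = 5000, w$w1),
    "degenerate")
})

test_that("SNR is Fm over the background spread", {
  tr <- new_transient_trace(sched, yields = rep(5000, 427),
                            background = rep(c(100, 200), length.out = 427))
  # fm given directly: definition arithmetic
  expect_equal(compute_snr(tr, fm = 5000), 5000 / sd(tr$background))
  tr0 <- new_transient_trace(sched, yields = rep(5000, 427), background = 50)
  expect_identical(compute_snr(tr0, fm = 5000), Inf)

  # Monte-Carlo: estimator lands near fm / bg_noise_sd
  set.seed(42)
  kin <- kinetic_params()
  snrs <- replicate(200, {
    tr <- simulate_transient(kin, 20, ppfd = 400, noise_sd_rel = 0.02,
                             bg_noise_sd = 10)
    compute_snr(tr)
  })
  fm_expected <- kin$fm_dark / (1 + npq_at_ppfd(kin, 400))
  expect_lt(abs(median(snrs) - fm_expected / 10) / (fm_expected / 10), 0.25)
})

test_that("process_transient composes the chain; batches preserve order", {
  kin <- kinetic_params()
  p <- process_transient(simulate_transient(kin, 20, 0, noise_sd_rel = 0,
                                            bg_noise_sd = 0))
  w <- relaxation_windows()
  taus <- tau_at_temperature(kin, 20)
  amps <- c(kin$amp_fast, kin$amp_mid, kin$amp_slow)
  # retrieved Fm (flashlets 301/302) sits just below the model asymptote,
  # so the composed ratios land within ~2% of the ideal closed forms
  expect_equal(p$fvfm, (kin$fm_dark - kin$f0_dark) / kin$fm_dark,
               tolerance = 2e-3)
  expect_equal(p$fr1_ratio, closed_form_ratio(taus, amps, w$w1),
               tolerance = 2e-2)
  expect_equal(p$fr2_ratio, closed_form_ratio(taus, amps, w$w2),
               tolerance = 2e-2)
  expect_equal(p$fv, p$fm - p$fo)

  flat <- new_transient_trace(sched, yields = rep(400, 427), background = 0)
  expect_error(process_transient(flat), "degenerate")

  camp <- small_campaign()
  batch <- camp$transients[1:12, ]
  params <- process_transients(batch, camp$schedule)
  expect_equal(nrow(params), 12)
  expect_equal(params$measurement_id, batch$measurement_id)
  expect_true(all(c("fo", "fm", "fvfm", "fr1_ratio", "fr2_ratio",
                    "snr", "adaptation_state") %in% names(params)))
})
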