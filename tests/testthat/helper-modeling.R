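# known-driver simulation for lasso support-recovery checks:
# y = beta * temperature + N(0, 1), plus 10 pure-noise covariates
sim_driver_data <- function(n = 2000, seed = 1, beta = 2) {
  set.seed(seed)
  d <- tibble::tibble(temperature = rnorm(n))
  for (k in 1:10) d[[paste0("noise", k)]] <- rnorm(n)
  d$y <- beta * d$temperature + rnorm(n)
  d
}

driver_covariates <- list(continuous = c("temperature", paste0("noise", 1:10)),
                          categorical = character(0))
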