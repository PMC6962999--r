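#' Kinetic parameter set for the transient simulator
#'
#' Parameters of the phenomenological PSII model used by the synthetic
#' campaign generator: basal and maximal fluorescence yield, a
#' three-exponential Qa- reoxidation mixture whose time constants follow the
#' canonical phases (about 0.2 ms for electron transfer to Qb, about 0.7 ms
#' for Qb- to Qb2-, and 2-3 ms for plastoquinone exchange at the Qb site),
#' an Arrhenius temperature sensitivity shared by all three phases,
#' Stern-Volmer non-photochemical quenching with hyperbolic light
#' dependence, and the per-flashlet excitation cross-section driving
#' induction.
#'
#' @param f0_dark Basal (dark, open-centre) fluorescence yield, instrument
#'   digital units.
#' @param fm_dark Maximal (all centres closed) yield, same units; must
#'   exceed `f0_dark`.
#' @param tau_fast,tau_mid,tau_slow Reoxidation time constants (ms) at the
#'   reference temperature.
#' @param amp_fast,amp_mid,amp_slow Nonnegative phase weights summing to 1.
#' @param e_act Activation energy (J mol^-1) scaling all time constants with
#'   temperature; 0 disables temperature sensitivity.
#' @param t_ref Reference temperature (deg C) at which the `tau_*` apply.
#' @param npq_max Maximal Stern-Volmer quenching (dimensionless).
#' @param k_npq Half-saturation PPFD of quenching (umol photons m^-2 s^-1).
#' @param sigma_abs Probability that one flashlet closes an open centre
#'   (single-hit Poisson induction, PSII connectivity ignored).
#' @return A validated `kinetic_params` object (list).
#' @examples
#' kin <- kinetic_params()
#' kin$tau_slow
#' @export
kinetic_params <- function(f0_dark = 1000, fm_dark = 5000,
                           tau_fast = 0.2, tau_mid = 0.7, tau_slow = 2.5,
                           amp_fast = 0.08, amp_mid = 0.17, amp_slow = 0.75,
                           e_act = 45000, t_ref = 20,
                           npq_max = 2.5, k_npq = 300,
                           sigma_abs = 0.03) {
  kin <- list(f0_dark = f0_dark, fm_dark = fm_dark,
              tau_fast = tau_fast, tau_mid = tau_mid, tau_slow = tau_slow,
              amp_fast = amp_fast, amp_mid = amp_mid, amp_slow = amp_slow,
              e_act = e_act, t_ref = t_ref,
              npq_max = npq_max, k_npq = k_npq, sigma_abs = sigma_abs)
  if (!all(vapply(kin, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("all kinetic parameters must be finite scalars", call. = FALSE)
  }
  if (any(c(tau_fast, tau_mid, tau_slow) <= 0)) {
    stop("time constants must be positive", call. = FALSE)
  }
  amps <- c(amp_fast, amp_mid, amp_slow)
  if (any(amps < 0) || abs(sum(amps) - 1) > 1e-9) {
    stop("phase amplitudes must be nonnegative and sum to 1", call. = FALSE)
  }
  if (fm_dark <= f0_dark) stop("fm_dark must exceed f0_dark", call. = FALSE)
  if (e_act < 0) stop("e_act must be nonnegative", call. = FALSE)
  if (sigma_abs <= 0 || sigma_abs >= 1) {
    stop("sigma_abs must lie in (0, 1)", call. = FALSE)
  }
  structure(kin, class = "kinetic_params")
}

#' Genotype profile for the synthetic campaign
#'
#' @param name Genotype identifier.
#' @param species One of barley, maize, soybean, wheat, arabidopsis.
#' @param cold_tolerance In `[0, 1]`; scales the activation energy of the
#'   reoxidation kinetics downward (1 = fully temperature-insensitive
#'   electron transport, i.e. most cold tolerant).
#' @param chlorophyll_level In `(0, 1]`; scales red absorption of the
#'   simulated canopy reflectance (values below 1 emulate
#'   chlorophyll-deficient mutants with a brighter red band).
#' @return A `genotype_profile` object.
#' @export
genotype_profile <- function(name, species = c("soybean", "barley", "maize",
                                               "wheat", "arabidopsis"),
                             cold_tolerance = 0.5, chlorophyll_level = 1) {
  species <- match.arg(species)
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(cold_tolerance) || cold_tolerance < 0 || cold_tolerance > 1) {
    stop("cold_tolerance must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(chlorophyll_level) || chlorophyll_level <= 0 ||
      chlorophyll_level > 1) {
    stop("chlorophyll_level must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, species = species,
                 cold_tolerance = cold_tolerance,
                 chlorophyll_level = chlorophyll_level),
            class = "genotype_profile")
}

# Universal gas constant, J mol^-1 K^-1
.R_GAS <- 8.314462618

#' Temperature-adjusted reoxidation time constants
#'
#' Arrhenius scaling of the three phase time constants: each tau is
#' multiplied by `exp(Ea_eff / R * (1/T - 1/T_ref))` on the Kelvin scale,
#' with `Ea_eff = e_act * (1 - cold_tolerance)`. Below the reference
#' temperature relaxation slows (larger tau); a fully cold-tolerant genotype
#' (`cold_tolerance = 1`) keeps its reference kinetics at any temperature.
#'
#' @param kin A [kinetic_params()] object.
#' @param temperature Leaf temperature, deg C.
#' @param cold_tolerance Genotype cold tolerance in `[0, 1]`.
#' @return Numeric vector `c(fast, mid, slow)` of time constants in ms.
#' @export
tau_at_temperature <- function(kin, temperature, cold_tolerance = 0) {
  t_k <- temperature + 273.15
  tref_k <- kin$t_ref + 273.15
  ea <- kin$e_act * (1 - cold_tolerance)
  fac <- exp(ea / .R_GAS * (1 / t_k - 1 / tref_k))
  c(kin$tau_fast, kin$tau_mid, kin$tau_slow) * fac
}

#' Stern-Volmer non-photochemical quenching at a given light level
#'
#' `NPQ = npq_max * ppfd / (ppfd + k_npq)`: zero in darkness, saturating
#' hyperbolically with PPFD. The light-adapted maximal yield is
#' `Fm' = Fm / (1 + NPQ)`.
#'
#' @param kin A [kinetic_params()] object.
#' @param ppfd Ambient PPFD, umol photons m^-2 s^-1.
#' @return NPQ value (dimensionless, >= 0).
#' @export
npq_at_ppfd <- function(kin, ppfd) {
  stopifnot(ppfd >= 0)
  if (ppfd == 0) return(0)
  kin$npq_max * ppfd / (ppfd + kin$k_npq)
}

#' Simulate one flashlet-resolved fluorescence transient
#'
#' Generates the 427 fluorescence yields of a single FRR measurement.
#' During induction, the closed-centre fraction `q` rises per flashlet by
#' `sigma_abs * (1 - q)` (single-hit Poisson, no connectivity); the yield is
#' `scale * (F0' + (Fm' - F0') * q)` with `Fm' = fm_dark / (1 + NPQ)`.
#' F0' is left unquenched: quenching both levels by the same factor would
#' cancel out of every ratio statistic and suppress the light response of
#' Fq'/Fm'. During relaxation `q` decays as the three-exponential mixture
#' with temperature-adjusted time constants. Gaussian noise with standard
#' deviation `noise_sd_rel * Fm' * amplitude_scale` is added to each yield,
#' and a background channel proportional to ambient PPFD (what the
#' instrument estimates between flashlets under ambient light) is added to
#' the yields and reported alongside them.
#'
#' @param kin A [kinetic_params()] object.
#' @param temperature Leaf temperature, deg C, in `[-10, 45]`.
#' @param ppfd Ambient PPFD, umol photons m^-2 s^-1 (>= 0).
#' @param schedule A [flash_schedule()].
#' @param amplitude_scale Multiplicative per-measurement amplitude (canopy /
#'   leaf-angle effect); 1 = nominal.
#' @param noise_sd_rel Relative Gaussian noise on yields (sd as a fraction
#'   of Fm'); 0 gives a noiseless trace.
#' @param cold_tolerance Genotype cold tolerance passed to
#'   [tau_at_temperature()].
#' @param bg_rate Background digital numbers per unit PPFD.
#' @param bg_noise_sd Standard deviation of the background channel; default
#'   `4 + 0.01 * ppfd` (detector noise grows with ambient light).
#' @param timestamp,plot_id,species,genotype,line_index,position_in_line
#'   Optional metadata carried on the trace.
#' @return A `transient_trace` object: list with `schedule`, `yields`,
#'   `background` (both length 427), `adaptation_state` ("dark" when PPFD
#'   is below 5 umol m^-2 s^-1, else "light"), `ambient_ppfd`,
#'   `temperature` and the metadata fields.
#' @examples
#' tr <- simulate_transient(kinetic_params(), temperature = 20, ppfd = 0,
#'                          noise_sd_rel = 0)
#' max(tr$yields)  # ~ fm_dark
#' @export
simulate_transient <- function(kin, temperature, ppfd,
                               schedule = flash_schedule(),
                               amplitude_scale = 1, noise_sd_rel = 0,
                               cold_tolerance = 0,
                               bg_rate = 0.5, bg_noise_sd = NULL,
                               timestamp = as.POSIXct(NA),
                               plot_id = NA_character_,
                               species = NA_character_,
                               genotype = NA_character_,
                               line_index = NA_character_,
                               position_in_line = NA_integer_) {
  if (!inherits(kin, "kinetic_params")) kin <- do.call(kinetic_params, kin)
  if (!is.finite(temperature) || temperature < -10 || temperature > 45) {
    stop("temperature must be finite and within [-10, 45] degC", call. = FALSE)
  }
  if (!is.finite(ppfd) || ppfd < 0) stop("ppfd must be finite and >= 0",
                                         call. = FALSE)
  if (!is.finite(amplitude_scale) || amplitude_scale <= 0) {
    stop("amplitude_scale must be positive and finite", call. = FALSE)
  }

  n_ind <- schedule$n_induction
  times <- schedule$times
  npq <- npq_at_ppfd(kin, ppfd)
  fm_p <- kin$fm_dark / (1 + npq)
  f0_p <- kin$f0_dark

  q_ind <- 1 - (1 - kin$sigma_abs)^(seq_len(n_ind) - 1)
  tau <- tau_at_temperature(kin, temperature, cold_tolerance)
  dt <- times[(n_ind + 1):length(times)] - times[n_ind]
  q_rel <- q_ind[n_ind] * (kin$amp_fast * exp(-dt / tau[1]) +
                           kin$amp_mid  * exp(-dt / tau[2]) +
                           kin$amp_slow * exp(-dt / tau[3]))
  q <- c(q_ind, q_rel)

  f <- amplitude_scale * (f0_p + (fm_p - f0_p) * q)
  n <- length(times)
  if (noise_sd_rel > 0) {
    f <- f + stats::rnorm(n, 0, noise_sd_rel * fm_p * amplitude_scale)
  }
  if (is.null(bg_noise_sd)) bg_noise_sd <- 4 + 0.01 * ppfd
  background <- pmax(bg_rate * ppfd + stats::rnorm(n, 0, bg_noise_sd), 0)

  new_transient_trace(
    schedule = schedule, yields = f + background, background = background,
    ambient_ppfd = ppfd, temperature = temperature,
    timestamp = timestamp, plot_id = plot_id, species = species,
    genotype = genotype, line_index = line_index,
    position_in_line = position_in_line
  )
}

# PPFD below which a measurement counts as dark-adapted (umol m^-2 s^-1).
# The notation switch (Fv/Fm vs Fq'/Fm') needs an explicit threshold.
.DARK_PPFD <- 5

#' Construct a transient trace
#'
#' Low-level constructor used by the simulator and by table readers; checks
#' the yield/background lengths against the schedule.
#'
#' @param schedule A [flash_schedule()].
#' @param yields Numeric vector of fluorescence yields, one per flashlet.
#' @param background Numeric vector (recycled if scalar) of background
#'   estimates, same units as yields, >= 0.
#' @param ambient_ppfd Ambient PPFD (>= 0); determines `adaptation_state`
#'   (dark below 5 umol m^-2 s^-1).
#' @param temperature Leaf/air temperature, deg C (may be NA).
#' @param timestamp,plot_id,species,genotype,line_index,position_in_line
#'   Metadata.
#' @return A `transient_trace` object.
#' @export
new_transient_trace <- function(schedule, yields, background = 0,
                                ambient_ppfd = 0, temperature = NA_real_,
                                timestamp = as.POSIXct(NA),
                                plot_id = NA_character_,
                                species = NA_character_,
                                genotype = NA_character_,
                                line_index = NA_character_,
                                position_in_line = NA_integer_) {
  n <- length(schedule$times)
  if (length(yields) != n) {
    stop("malformed trace: ", length(yields), " yields for ", n,
         " flashlets", call. = FALSE)
  }
  if (length(background) == 1) background <- rep(background, n)
  if (length(background) != n) {
    stop("malformed trace: background length must be 1 or match yields",
         call. = FALSE)
  }
  if (any(!is.finite(background)) || any(background < 0)) {
    stop("background must be finite and nonnegative", call. = FALSE)
  }
  if (!is.finite(ambient_ppfd) || ambient_ppfd < 0) {
    stop("ambient_ppfd must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(schedule = schedule, yields = as.numeric(yields),
         background = as.numeric(background),
         adaptation_state = if (ambient_ppfd < .DARK_PPFD) "dark" else "light",
         ambient_ppfd = ambient_ppfd, temperature = temperature,
         timestamp = timestamp, plot_id = plot_id, species = species,
         genotype = genotype, line_index = line_index,
         position_in_line = position_in_line),
    class = "transient_trace"
  )
}

#' @export
print.transient_trace <- function(x, ...) {
  cat(sprintf("<transient_trace> %d flashlets, %s-adapted, PPFD %.0f, plot %s\n",
              length(x$yields), x$adaptation_state, x$ambient_ppfd,
              x$plot_id))
  invisible(x)
}
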