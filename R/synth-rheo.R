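#' Ground-truth parameters for a synthetic gelation curve
#'
#' Describes a logistic (sigmoidal) storage-modulus trajectory
#' \eqn{G'(t) = g_0 + (g_{max} - g_0) / (1 + e^{-(t - t_{mid})/\tau})}
#' sampled on a regular grid with additive Gaussian noise. The defaults mirror
#' a typical 1.5 mg/mL collagen I gelation run: 30 s sampling over 40 min,
#' inflection at 10 min, plateau modulus 100 Pa, noise 2\% of the plateau.
#'
#' @param t_mid Inflection time in seconds.
#' @param tau Logistic time constant in seconds (must be > 0).
#' @param g0 Baseline modulus in Pa (>= 0).
#' @param gmax Plateau modulus in Pa (> `g0` unless the degenerate flat curve
#'   `gmax == g0` is wanted).
#' @param noise_sd Standard deviation of additive Gaussian noise, Pa.
#' @param dt Sampling interval in seconds.
#' @param duration Total sweep duration in seconds (>= 10 * `dt`).
#' @param seed Integer RNG seed; identical seeds reproduce identical curves.
#' @return An object of class `gelation_truth`.
#' @export
gelation_truth <- function(t_mid = 600, tau = 60, g0 = 1, gmax = 100,
                           noise_sd = 0.02 * gmax, dt = 30, duration = 2400,
                           seed = 1L) {
  check_that(tau > 0, "synth", "tau must be > 0")
  check_that(gmax >= g0 && g0 >= 0, "synth", "need gmax >= g0 >= 0")
  check_that(dt > 0, "synth", "dt must be > 0")
  check_that(duration >= 10 * dt, "synth", "duration must be >= 10 * dt")
  check_that(noise_sd >= 0, "synth", "noise_sd must be >= 0")
  structure(list(t_mid = t_mid, tau = tau, g0 = g0, gmax = gmax,
                 noise_sd = noise_sd, dt = dt, duration = duration,
                 seed = as.integer(seed)),
            class = "gelation_truth")
}

noiseless_logistic <- function(truth, t) {
  truth$g0 + (truth$gmax - truth$g0) / (1 + exp(-(t - truth$t_mid) / truth$tau))
}

#' Generate a synthetic gelation time sweep
#'
#' Samples the logistic storage modulus of a [gelation_truth()] at
#' `t_i = i * dt` and adds seeded Gaussian noise. The loss modulus is rendered
#' as a fixed fraction (default 0.15, gel-like G'' < G') of the noiseless G'
#' plus independent noise of the same standard deviation.
#'
#' @param truth A [gelation_truth()] object.
#' @param gdp_fraction G''/G' ratio used for the loss-modulus channel.
#' @return A `time_sweep`: data frame with columns `t` (s), `gprime` (Pa),
#'   `gdoubleprime` (Pa), with metadata attributes `strain_pct` and
#'   `osc_freq_hz`.
#' @export
gen_gelation_curve <- function(truth, gdp_fraction = 0.15) {
  check_that(inherits(truth, "gelation_truth"), "synth",
             "truth must be a gelation_truth object")
  t <- seq(0, truth$duration, by = truth$dt)
  base <- noiseless_logistic(truth, t)
  with_seed(truth$seed, {
    gp <- base + stats::rnorm(length(t), 0, truth$noise_sd)
    gdp <- gdp_fraction * base + stats::rnorm(length(t), 0, truth$noise_sd)
    time_sweep(t, gp, gdp)
  })
}

#' Construct a time-sweep object
#'
#' @param t Time in seconds, strictly increasing.
#' @param gprime Storage modulus G' in Pa.
#' @param gdoubleprime Loss modulus G'' in Pa.
#' @param strain_pct Oscillatory strain amplitude metadata (percent).
#' @param osc_freq_hz Oscillation frequency metadata (Hz).
#' @return A data frame of class `time_sweep`.
#' @export
time_sweep <- function(t, gprime, gdoubleprime, strain_pct = 1,
                       osc_freq_hz = 1) {
  check_that(length(t) == length(gprime) && length(t) == length(gdoubleprime),
             "rheo", "t, gprime, gdoubleprime must have equal length")
  check_that(length(t) >= 7, "rheo",
             "need at least 7 samples (5 baseline + 2 consecutive test points)")
  check_that(all(diff(t) > 0), "rheo", "t must be strictly increasing")
  check_that(all(is.finite(gprime)) && all(is.finite(gdoubleprime)), "rheo",
             "moduli must be finite")
  structure(data.frame(t = t, gprime = gprime, gdoubleprime = gdoubleprime),
            strain_pct = strain_pct, osc_freq_hz = osc_freq_hz,
            class = c("time_sweep", "data.frame"))
}

#' Construct a frequency-sweep object
#'
#' @param f Frequency in Hz, positive, sorted ascending.
#' @param gprime,gdoubleprime Moduli in Pa.
#' @return A data frame of class `frequency_sweep`.
#' @export
frequency_sweep <- function(f, gprime, gdoubleprime) {
  check_that(length(f) > 0, "rheo", "frequency list must be nonempty")
  check_that(all(f > 0), "rheo", "frequencies must be positive")
  check_that(length(f) == length(gprime) && length(f) == length(gdoubleprime),
             "rheo", "f, gprime, gdoubleprime must have equal length")
  check_that(!is.unsorted(f), "rheo", "f must be sorted ascending")
  structure(data.frame(f = f, gprime = gprime, gdoubleprime = gdoubleprime),
            class = c("frequency_sweep", "data.frame"))
}

#' Generate a synthetic endpoint frequency sweep
#'
#' Near-constant plateau moduli with seeded noise on a logarithmic frequency
#' grid, emulating an endpoint sweep of a fully gelled sample from 0.1 to
#' 10 Hz.
#'
#' @param plateau_gprime Plateau storage modulus, Pa.
#' @param plateau_gdoubleprime Plateau loss modulus, Pa.
#' @param freqs Frequency grid in Hz; default 21 log-spaced points 0.1-10 Hz.
#' @param noise_sd Additive noise standard deviation, Pa.
#' @param seed Integer RNG seed.
#' @return A `frequency_sweep`.
#' @export
gen_frequency_sweep <- function(plateau_gprime = 80, plateau_gdoubleprime = 12,
                                freqs = 10^seq(-1, 1, length.out = 21),
                                noise_sd = 0, seed = 1L) {
  check_that(length(freqs) > 0, "synth", "frequency list must be nonempty")
  check_that(all(freqs > 0), "synth", "frequencies must be positive")
  freqs <- sort(freqs)
  with_seed(seed, {
    gp <- plateau_gprime + stats::rnorm(length(freqs), 0, noise_sd)
    gdp <- plateau_gdoubleprime + stats::rnorm(length(freqs), 0, noise_sd)
    frequency_sweep(freqs, gp, gdp)
  })
}
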