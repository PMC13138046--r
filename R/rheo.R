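#' First derivative of the storage modulus
#'
#' Central differences at interior points, one-sided differences at the two
#' endpoints; same length as the input, units Pa/s. Central differencing
#' halves the truncation error relative to forward differences on a 30 s
#' sampling grid.
#'
#' @param sweep A [time_sweep()] (or any data frame with `t` and `gprime`).
#' @return Numeric vector of dG'/dt in Pa/s.
#' @export
rheo_derivative <- function(sweep) {
  t <- sweep$t
  g <- sweep$gprime
  n <- length(t)
  check_that(n >= 2, "rheo", "need at least 2 points for a derivative")
  d <- numeric(n)
  if (n > 2) {
    d[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  d[1] <- (g[2] - g[1]) / (t[2] - t[1])
  d[n] <- (g[n] - g[n - 1]) / (t[n] - t[n - 1])
  d
}

baseline_stats <- function(deriv, baseline_n) {
  b <- deriv[seq_len(baseline_n)]
  list(mean = mean(b), sd = stats::sd(b))
}

#' Detect the end of the nucleation (lag) phase
#'
#' The first `baseline_n` derivative values form a baseline; the nucleation
#' phase ends at the first point of the earliest run of `consecutive` points
#' that all strictly exceed `baseline_mean + k_sd * baseline_sd`.
#'
#' @param deriv Derivative series, Pa/s (see [rheo_derivative()]).
#' @param t Time vector, s, same length.
#' @param baseline_n Number of initial points defining the baseline.
#' @param k_sd Threshold multiplier on the baseline standard deviation.
#' @param consecutive Number of consecutive supra-threshold points required.
#' @return List with `time` (s, or `NA_real_` when no run qualifies),
#'   `index`, `baseline_mean`, `baseline_sd`, `threshold`.
#' @export
detect_nucleation_end <- function(deriv, t, baseline_n = 5, k_sd = 2,
                                  consecutive = 2) {
  check_that(length(deriv) == length(t), "rheo", "deriv and t lengths differ")
  check_that(length(deriv) >= baseline_n + consecutive, "rheo",
             "series too short: need at least baseline_n + consecutive = ",
             baseline_n + consecutive, " points, got ", length(deriv))
  bl <- baseline_stats(deriv, baseline_n)
  thr <- bl$mean + k_sd * bl$sd
  above <- deriv > thr
  idx <- NA_integer_
  if (consecutive >= 1) {
    run <- 0L
    for (i in seq_along(above)) {
      run <- if (above[i]) run + 1L else 0L
      if (run == consecutive) {
        idx <- i - consecutive + 1L
        break
      }
    }
  }
  list(time = if (is.na(idx)) NA_real_ else t[idx], index = idx,
       baseline_mean = bl$mean, baseline_sd = bl$sd, threshold = thr)
}

#' Peak growth rate of the storage modulus
#'
#' Maximum of the derivative series and its time; this coincides with the
#' inflection point of a sigmoidal gelation curve. Ties are broken by the
#' earliest time.
#'
#' @inheritParams detect_nucleation_end
#' @return List with `peak_rate` (Pa/s), `peak_t` (s), `index`.
#' @export
peak_growth_rate <- function(deriv, t) {
  check_that(length(deriv) >= 1, "rheo", "empty derivative series")
  check_that(length(deriv) == length(t), "rheo", "deriv and t lengths differ")
  i <- which.max(deriv)  # which.max returns the first maximum: earliest tie
  list(peak_rate = deriv[i], peak_t = t[i], index = i)
}

#' Detect the start of the plateau phase
#'
#' Symmetric counterpart of the nucleation rule: the first time after the
#' derivative peak at which the derivative falls to or below the nucleation
#' threshold and stays there for `consecutive` points. The gelation curve
#' names this phase but no consensus criterion exists; this fall-back rule is
#' this package's operational definition.
#'
#' @inheritParams detect_nucleation_end
#' @param peak_index Index of the derivative maximum (from
#'   [peak_growth_rate()]).
#' @param threshold Threshold in Pa/s (from [detect_nucleation_end()]).
#' @return List with `time` (s or `NA_real_`) and `index`.
#' @export
detect_plateau_start <- function(deriv, t, peak_index, threshold,
                                 consecutive = 2) {
  check_that(!is.null(peak_index) && !is.na(peak_index), "rheo",
             "plateau detection requires a detected peak")
  n <- length(deriv)
  idx <- NA_integer_
  if (peak_index < n) {
    below <- deriv <= threshold
    run <- 0L
    for (i in (peak_index + 1L):n) {
      run <- if (below[i]) run + 1L else 0L
      if (run == consecutive) {
        idx <- i - consecutive + 1L
        break
      }
    }
  }
  list(time = if (is.na(idx)) NA_real_ else t[idx], index = idx)
}

#' Endpoint moduli from a frequency sweep
#'
#' Arithmetic mean of G' and G'' over the samples falling inside the closed
#' frequency band, by default 0.16-2.5 Hz, the range over which plateau
#' moduli of collagen I gels are flat.
#'
#' @param sweep A [frequency_sweep()].
#' @param band Length-2 numeric, closed frequency band in Hz.
#' @return List of class `endpoint_moduli` with `gprime_end`,
#'   `gdoubleprime_end`, `band`, `n_points_in_band`.
#' @export
endpoint_moduli <- function(sweep, band = c(0.16, 2.5)) {
  check_that(length(band) == 2 && band[1] < band[2], "rheo",
             "band must be (lower, upper) with lower < upper")
  sel <- sweep$f >= band[1] & sweep$f <= band[2]
  check_that(any(sel), "rheo", "no samples inside the frequency band [",
             band[1], ", ", band[2], "] Hz")
  structure(list(gprime_end = mean(sweep$gprime[sel]),
                 gdoubleprime_end = mean(sweep$gdoubleprime[sel]),
                 band = band, n_points_in_band = sum(sel)),
            class = "endpoint_moduli")
}

#' Full gelation-curve phase analysis
#'
#' Orchestrates derivative computation, nucleation-end detection, peak growth
#' rate, plateau-start detection and (optionally) endpoint moduli into one
#' record per run, suitable for tabulation across replicates.
#'
#' @param sweep A [time_sweep()].
#' @param freq Optional [frequency_sweep()] for the endpoint moduli.
#' @param baseline_n,k_sd,consecutive Detection parameters, see
#'   [detect_nucleation_end()].
#' @param band Endpoint frequency band in Hz.
#' @return List of class `gelation_kinetics` with elements
#'   `nucleation_end_t`, `peak_rate`, `peak_t`, `plateau_start_t`,
#'   `baseline_mean`, `baseline_sd`, `threshold`, `derivative`, and, when a
#'   frequency sweep is supplied, `endpoint` (an `endpoint_moduli`).
#' @export
analyze_gelation <- function(sweep, freq = NULL, baseline_n = 5, k_sd = 2,
                             consecutive = 2, band = c(0.16, 2.5)) {
  d <- rheo_derivative(sweep)
  nuc <- detect_nucleation_end(d, sweep$t, baseline_n = baseline_n,
                               k_sd = k_sd, consecutive = consecutive)
  pk <- peak_growth_rate(d, sweep$t)
  plat <- if (!is.na(nuc$index)) {
    detect_plateau_start(d, sweep$t, pk$index, nuc$threshold,
                         consecutive = consecutive)
  } else {
    list(time = NA_real_, index = NA_integer_)
  }
  out <- list(nucleation_end_t = nuc$time, peak_rate = pk$peak_rate,
              peak_t = pk$peak_t, plateau_start_t = plat$time,
              baseline_mean = nuc$baseline_mean, baseline_sd = nuc$baseline_sd,
              threshold = nuc$threshold, derivative = d)
  if (!is.null(freq)) out$endpoint <- endpoint_moduli(freq, band = band)
  structure(out, class = "gelation_kinetics")
}

#' @export
print.gelation_kinetics <- function(x, ...) {
  cat("Gelation kinetics\n")
  cat(sprintf("  nucleation end : %s s\n",
              format(x$nucleation_end_t, digits = 4)))
  cat(sprintf("  peak growth    : %.4g Pa/s at t = %.4g s\n",
              x$peak_rate, x$peak_t))
  cat(sprintf("  plateau start  : %s s\n",
              format(x$plateau_start_t, digits = 4)))
  if (!is.null(x$endpoint)) {
    cat(sprintf("  endpoint G'/G'': %.4g / %.4g Pa (band %g-%g Hz, n = %d)\n",
                x$endpoint$gprime_end, x$endpoint$gdoubleprime_end,
                x$endpoint$band[1], x$endpoint$band[2],
                x$endpoint$n_points_in_band))
  }
  invisible(x)
}
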