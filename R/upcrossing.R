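# Rice's upcrossing formula and experiment-level derived quantities.

#' Rice's upcrossing rate
#'
#' For a stationary Gaussian process with mean `m`, standard deviation
#' `sigma_v` and rate-of-change standard deviation `sigma_vdot`, the rate of
#' positive-going crossings of a level `v_th` is
#' \deqn{r_{uc} = \frac{1}{2\pi}\frac{\sigma_{\dot v}}{\sigma_v}
#'   \exp\left(-\frac{(v_{th}-\langle v\rangle)^2}{2\sigma_v^2}\right).}
#' In the rare-event regime (threshold several sigma above the mean) this
#' approximates the firing rate of the same model with an integrate-and-fire
#' reset, because the effect of the previous reset has decayed by the time of
#' the next crossing.
#'
#' @param stats A [voltage_stats()].
#' @param v_th Threshold (mV above leak).
#' @return Upcrossing rate in kHz (1/ms).
#' @examples
#' st <- one_dendrite_stats(drive_params(mu = 4, sigma_s = 3, tau_s = 5), tau_v = 10)
#' khz <- rice_rate(st, v_th = 10)
#' 1000 * khz  # in Hz
#' @export
rice_rate <- function(stats, v_th) {
  stopifnot(inherits(stats, "voltage_stats"))
  if (stats$sigma_v <= 0 || stats$sigma_vdot <= 0)
    abort("degenerate voltage statistics: sigma_v and sigma_vdot must be positive",
          class = "ricecable_degenerate_stats")
  (stats$sigma_vdot / (2 * pi * stats$sigma_v)) *
    exp(-(v_th - stats$mean)^2 / (2 * stats$sigma_v^2))
}

#' Deterministic leaky integrate-and-fire rate
#'
#' Noise-free firing rate of a compact leaky integrate-and-fire unit whose
#' voltage relaxes towards `mean` with time constant `tau_v`: zero if
#' `mean <= v_th`, otherwise `1 / (tau_v log((mean - v_re)/(mean - v_th)))`.
#' Used as the suprathreshold reference curve in rate sweeps.
#'
#' @param mean Mean (asymptotic) voltage at the trigger point (mV).
#' @param tau_v Membrane time constant (ms).
#' @param v_th,v_re Threshold and reset (mV).
#' @return Rate in kHz. Vectorized over `mean`.
#' @export
deterministic_lif_rate <- function(mean, tau_v, v_th, v_re) {
  out <- numeric(length(mean))
  supra <- mean > v_th
  out[supra] <- 1 / (tau_v * log((mean[supra] - v_re) / (mean[supra] - v_th)))
  out
}

#' Voltage statistics at the trigger point of a morphology
#'
#' Routes to the closed forms where they exist -- sealed end of one dendrite
#' or nominal-soma junction of two, with the trigger at `x_th = 0` -- and to
#' the spectral quadrature engine ([stats_from_psd()]) for everything else
#' (axon and/or soma present, `n > 2`, trigger down the axon).
#'
#' @param morph A [morphology()].
#' @param drive A [drive_params()].
#' @param grid A [spectrum_grid()] for the spectral route.
#' @return A [voltage_stats()]; its `method` field records the route taken.
#' @export
trigger_stats <- function(morph, drive, grid = spectrum_grid()) {
  stopifnot(inherits(morph, "morphology"))
  closed <- is.null(morph$axon) && is.null(morph$soma) &&
    morph$threshold$x_th == 0 && morph$n_dendrites <= 2L
  if (closed) {
    if (morph$n_dendrites == 1L) one_dendrite_stats(drive, morph$dendrite$tau)
    else two_dendrite_stats(drive, morph$dendrite$tau)
  } else {
    stats_from_psd(morph, drive, grid)
  }
}

new_rate_result <- function(rate_khz, method, stats, uncertainty_hz = NA_real_,
                            params = NULL, seed = NA_integer_) {
  structure(list(rate_khz = rate_khz, rate_hz = khz_to_hz(rate_khz),
                 method = method, stats = stats,
                 uncertainty_hz = uncertainty_hz,
                 params = params, seed = seed),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> %.6g Hz [%s]%s\n", x$rate_hz, x$method,
              if (is.finite(x$uncertainty_hz))
                sprintf(" +/- %.3g Hz", x$uncertainty_hz) else ""))
  print(x$stats)
  invisible(x)
}

#' Analytic firing-rate estimate for a morphology
#'
#' Computes the trigger-point voltage statistics ([trigger_stats()]) and
#' applies Rice's formula at the morphology's threshold. The result records
#' which statistics engine (closed-form or spectral) produced the numbers.
#'
#' @param morph A [morphology()].
#' @param drive A [drive_params()].
#' @param grid A [spectrum_grid()].
#' @return A `rate_result`; see [tidy.rate_result()].
#' @examples
#' nm <- neuron_model(mu = 4, sigma_s = 3)
#' model_rate(nm$morph, nm$drive)$rate_hz
#' @export
model_rate <- function(morph, drive, grid = spectrum_grid()) {
  st <- trigger_stats(morph, drive, grid)
  new_rate_result(rate_khz = rice_rate(st, morph$threshold$v_th),
                  method = paste0("upcrossing/", st$method), stats = st,
                  params = list(morph = morph, drive = drive))
}

#' @rdname model_rate
#' @param neuron A [neuron_model()].
#' @export
firing_rate <- function(neuron, grid = spectrum_grid()) {
  stopifnot(inherits(neuron, "neuron_model"))
  model_rate(neuron$morph, neuron$drive, grid)
}

#' Calibrate the noise amplitude to a target rate
#'
#' Root-finds `sigma_s` such that the upcrossing rate of the model equals
#' `target_hz`. In the subthreshold regime the rate is strictly increasing in
#' `sigma_s` (both `sigma_v` and `sigma_vdot` scale linearly with it while
#' the threshold distance is fixed), so the root is unique; the initial
#' bracket is expanded geometrically if needed.
#'
#' @param morph A [morphology()].
#' @param drive A [drive_params()]; its `sigma_s` field is ignored.
#' @param target_hz Target rate (Hz).
#' @param bracket Initial `sigma_s` search interval (mV).
#' @param tol Relative tolerance on the achieved rate.
#' @return Calibrated `sigma_s` (mV).
#' @export
calibrate_sigma_s <- function(morph, drive, target_hz, bracket = c(0.1, 10),
                              tol = 1e-6) {
  rate_of <- function(sig) {
    d <- drive_params(mu = drive$mu, sigma_s = sig, tau_s = drive$tau_s,
                      E_L = drive$E_L, E_s = drive$E_s)
    model_rate(morph, d)$rate_hz
  }
  lo <- bracket[1]; hi <- bracket[2]
  f <- function(sig) log(rate_of(sig)) - log(target_hz)
  expand <- 0L
  while (f(lo) > 0 && expand < 20L) { lo <- lo / 2; expand <- expand + 1L }
  while (f(hi) < 0 && expand < 40L) { hi <- hi * 2; expand <- expand + 1L }
  if (f(lo) > 0 || f(hi) < 0)
    abort("target rate is not bracketed by any admissible sigma_s",
          class = "ricecable_bracket_failure")
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5)$root
  achieved <- rate_of(root)
  if (abs(achieved - target_hz) > tol * target_hz * 10)
    abort("calibration failed to reach the target rate",
          class = "ricecable_bracket_failure")
  root
}

# quadratic refinement of a grid argmax in log-x
refine_peak <- function(xg, yg) {
  i <- which.max(yg)
  if (i == 1L || i == length(xg)) return(list(x = xg[i], interior = FALSE))
  lx <- log(xg[(i - 1):(i + 1)])
  y <- yg[(i - 1):(i + 1)]
  d1 <- (y[3] - y[1]) / (lx[3] - lx[1])
  d2 <- ((y[3] - y[2]) / (lx[3] - lx[2]) - (y[2] - y[1]) / (lx[2] - lx[1])) /
    ((lx[3] - lx[1]) / 2)
  x_hat <- if (d2 < 0) exp(lx[2] - d1 / d2) else xg[i]
  list(x = min(max(x_hat, xg[i - 1]), xg[i + 1]), interior = TRUE)
}

#' Radius ratio maximizing the firing rate
#'
#' Scans the axon-to-dendrite radius ratio, rebuilding the axon for each
#' value (`lambda_alpha = lambda_1 sqrt(epsilon a_ratio)`, `tau_alpha =
#' epsilon tau_1`, and `rho_alpha` from `rho_1` when a soma is present), and
#' returns the location of the rate maximum with local quadratic refinement
#' in log-ratio. For a trigger at the junction (`x_th = 0`) the rate
#' decreases monotonically with the ratio and an error of class
#' `ricecable_monotone_profile` is signalled; an interior peak requires
#' `x_th > 0`, where the competition between axonal attenuation (favouring
#' large `lambda_alpha`) and conductance load (favouring small) creates one.
#'
#' @param neuron A [neuron_model()] serving as template (its `a_ratio` is
#'   swept; `x_th`, `mu`, `sigma_s`, soma, etc. are kept).
#' @param ratios Grid of radius ratios to scan.
#' @return A list with `ratio` (refined argmax), `rate_hz` at the grid
#'   maximum, and `table`, a tibble of the whole scan.
#' @export
peak_radius_ratio <- function(neuron,
                              ratios = exp(seq(log(0.02), log(1), length.out = 50))) {
  stopifnot(inherits(neuron, "neuron_model"))
  rate_at <- function(r) with_a_ratio(neuron, r)$rate_hz
  rates <- vapply(ratios, rate_at, numeric(1))
  pk <- refine_peak(ratios, rates)
  if (!pk$interior)
    abort("rate profile is monotone over the scanned ratios: no interior peak",
          class = "ricecable_monotone_profile")
  list(ratio = pk$x, rate_hz = max(rates),
       table = tibble(a_ratio = ratios, rate_hz = rates))
}

# rebuild the template neuron with a different radius ratio / dendrite count
with_a_ratio <- function(neuron, a_ratio, n = neuron$morph$n_dendrites) {
  d <- neuron$drive
  m <- neuron$morph
  nm <- neuron_model(mu = d$mu, sigma_s = d$sigma_s, n_dendrites = n,
                     a_ratio = if (a_ratio > 0) a_ratio else NULL,
                     rho_1 = if (is.null(m$soma)) NULL else m$soma$rho_1,
                     lambda_1 = m$dendrite$lambda, tau_1 = m$dendrite$tau,
                     tau_s = d$tau_s,
                     x_th = if (a_ratio > 0) m$threshold$x_th else 0,
                     v_th = m$threshold$v_th, v_re = m$threshold$v_re,
                     E_L = d$E_L, E_s = d$E_s,
                     tau_0 = if (is.null(m$soma)) NULL else m$soma$tau_0)
  firing_rate(nm)
}

#' Number of dendrites maximizing the firing rate
#'
#' Evaluates the upcrossing rate for each dendrite count in `n_range`
#' (identical dendrites, fixed axon/soma) and returns the maximizer, with
#' ties broken towards fewer dendrites. The optimum exists because each
#' added dendrite raises the mean towards its asymptote but dilutes every
#' dendrite's share of the input admittance, so the trigger-point variance
#' falls off as 1/n.
#'
#' @param neuron A [neuron_model()] template.
#' @param n_range Integer vector of dendrite counts to scan.
#' @return The optimal count (integer); the scan is attached as attribute
#'   `"table"`.
#' @export
n_max <- function(neuron, n_range = 1:12) {
  stopifnot(inherits(neuron, "neuron_model"))
  n_range <- sort(unique(as.integer(n_range)))
  a_ratio <- if (is.null(neuron$morph$axon)) 0 else neuron$morph$axon$radius_rel
  rates <- vapply(n_range, function(n)
    with_a_ratio(neuron, a_ratio, n = n)$rate_hz, numeric(1))
  best <- n_range[which.max(rates)]  # which.max takes the first maximum
  structure(best, table = tibble(n = n_range, rate_hz = rates))
}
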