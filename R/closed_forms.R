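# Closed-form voltage statistics for a sealed dendrite of length L and its
# two semi-infinite limits.
#
# The subthreshold model is the stochastic cable equation
#   tau_v dv/dt = mu - v + lambda^2 d^2v/dx^2 + s,
# with s an Ornstein-Uhlenbeck field, temporally filtered (tau_s) and
# spatially white, of amplitude sigma_s. For sealed (zero-gradient) ends the
# equal-time statistics follow from a cosine-mode decomposition. Two length
# scales appear: lambda itself and the shorter lambda/sqrt(kappa) with
# kappa = 1 + tau_v/tau_s.

#' Closed (sealed-end) dendrite specification
#'
#' @param L Dendrite length (um).
#' @param lambda Electrotonic length constant (um).
#' @param tau_v Membrane time constant (ms).
#' @param tau_s Synaptic time constant (ms).
#' @param sigma_s Synaptic noise amplitude (mV).
#' @return An object of class `closed_dendrite`; `kappa = 1 + tau_v/tau_s` is
#'   stored so all formulas share one definition site.
#' @export
closed_dendrite <- function(L, lambda, tau_v, tau_s, sigma_s) {
  check_scalar(L, "L"); check_scalar(lambda, "lambda")
  check_scalar(tau_v, "tau_v"); check_scalar(tau_s, "tau_s")
  check_scalar(sigma_s, "sigma_s", allow_zero = TRUE)
  structure(list(L = L, lambda = lambda, tau_v = tau_v, tau_s = tau_s,
                 sigma_s = sigma_s, kappa = 1 + tau_v / tau_s),
            class = "closed_dendrite")
}

#' Boundary kernel of the sealed dendrite
#'
#' The spatial kernel through which both voltage variances are expressed:
#' \deqn{C(x, \eta) = \frac{\cosh((L-x)\sqrt{\eta}/\lambda)\,
#'   \cosh(x\sqrt{\eta}/\lambda)}{\sqrt{\eta}\,\sinh(L\sqrt{\eta}/\lambda)}.}
#' It is symmetric about `L/2`, equals `coth(L sqrt(eta)/lambda)/sqrt(eta)`
#' at the ends, and tends to `1/sqrt(eta)` at a sealed end (and half that in
#' the bulk) as `L/lambda` grows. Evaluation is done with scaled
#' exponential-difference forms so that arbitrarily large `L sqrt(eta)/lambda`
#' neither overflows nor loses precision.
#'
#' @param x Position(s) along the dendrite, in `[0, L]` (um). Vectorized.
#' @param eta Positive dimensionless mode parameter (1 or kappa in the
#'   variance formulas).
#' @param spec A [closed_dendrite()].
#' @return Kernel values (dimensionless, units of 1/sqrt(eta)).
#' @export
boundary_kernel <- function(x, eta, spec) {
  stopifnot(inherits(spec, "closed_dendrite"))
  if (any(x < 0 | x > spec$L)) stop_invalid("`x` must lie in [0, L]")
  if (any(eta <= 0)) stop_invalid("`eta` must be positive")
  q <- sqrt(eta)
  a <- (spec$L - x) * q / spec$lambda
  b <- x * q / spec$lambda
  cc <- spec$L * q / spec$lambda
  # cosh(a) cosh(b) / sinh(c) with c = a + b, scaled by e^{-c}:
  # (1 + e^{-2a} + e^{-2b} + e^{-2c}) / (2 (1 - e^{-2c}))
  (1 + exp(-2 * a) + exp(-2 * b) + exp(-2 * cc)) / (2 * q * (1 - exp(-2 * cc)))
}

# scalar variance formulas shared by the profile table and the tests
sigma_v2_closed <- function(x, spec) {
  2 * spec$sigma_s^2 * (spec$tau_s / spec$tau_v) *
    (boundary_kernel(x, 1, spec) - boundary_kernel(x, spec$kappa, spec))
}

sigma_vdot2_closed <- function(x, spec) {
  (2 * spec$sigma_s^2 / (spec$tau_v * spec$tau_s)) *
    boundary_kernel(x, spec$kappa, spec)
}

#' Variance profile along a sealed dendrite
#'
#' Equal-time variance of the voltage and of its rate of change as a function
#' of position:
#' \deqn{\sigma_v^2(x) = 2\sigma_s^2 \frac{\tau_s}{\tau_v}
#'   \{C(x,1) - C(x,\kappa)\}, \qquad
#'   \sigma_{\dot v}^2(x) = \frac{2\sigma_s^2}{\tau_v \tau_s} C(x,\kappa),}
#' with the boundary kernel of [boundary_kernel()] and
#' `kappa = 1 + tau_v/tau_s`. The variance is elevated near the sealed ends
#' and decays towards the bulk over the length `lambda/sqrt(kappa)` for the
#' kappa-term and `lambda` for the leading term.
#'
#' @param spec A [closed_dendrite()].
#' @param x Positions (um); defaults to a 201-point grid over `[0, L]`.
#' @return A tibble with columns `x`, `variance` (mV^2) and `dvariance`
#'   (mV^2/ms^2).
#' @examples
#' cd <- closed_dendrite(L = 1000, lambda = 200, tau_v = 10, tau_s = 5, sigma_s = 1)
#' variance_profile(cd, x = c(0, 500))
#' @export
variance_profile <- function(spec, x = seq(0, spec$L, length.out = 201)) {
  stopifnot(inherits(spec, "closed_dendrite"))
  tibble(x = x,
         variance = sigma_v2_closed(x, spec),
         dvariance = sigma_vdot2_closed(x, spec))
}

#' Voltage statistics triple
#'
#' The sufficient statistics of the stationary Gaussian voltage at the
#' trigger point: mean, standard deviation and rate-of-change standard
#' deviation. These three numbers are the sole input to Rice's upcrossing
#' formula, [rice_rate()].
#'
#' @param mean Mean voltage (mV above leak).
#' @param sigma_v Voltage standard deviation (mV), > 0.
#' @param sigma_vdot Standard deviation of dv/dt (mV/ms), > 0.
#' @param method Provenance label (e.g. "closed-form", "spectral",
#'   "simulation").
#' @return An object of class `voltage_stats`.
#' @export
voltage_stats <- function(mean, sigma_v, sigma_vdot, method = "closed-form") {
  check_scalar(mean, "mean", positive = FALSE)
  check_scalar(sigma_v, "sigma_v")
  check_scalar(sigma_vdot, "sigma_vdot")
  structure(list(mean = mean, sigma_v = sigma_v, sigma_vdot = sigma_vdot,
                 method = method),
            class = "voltage_stats")
}

#' @export
print.voltage_stats <- function(x, ...) {
  cat(sprintf("<voltage_stats> mean = %.4g mV, sigma_v = %.4g mV, sigma_vdot = %.4g mV/ms [%s]\n",
              x$mean, x$sigma_v, x$sigma_vdot, x$method))
  invisible(x)
}

#' Sealed-end statistics of a single semi-infinite dendrite
#'
#' Limit of the closed-dendrite profile at a sealed end as `L/lambda` grows:
#' \deqn{\sigma_v^2 = 2\sigma_s^2 \frac{\tau_s}{\tau_v}
#'   \left(1 - \sqrt{\tau_s/(\tau_s+\tau_v)}\right), \qquad
#'   \sigma_{\dot v}^2 = \frac{2\sigma_s^2}{\tau_v\tau_s}
#'   \sqrt{\tau_s/(\tau_s+\tau_v)},}
#' and mean `mu`. Note the complete independence from `lambda`: once the
#' semi-infinite limit is taken no other quantity carries units of length, so
#' the firing rate of this model cannot depend on the electrotonic length.
#'
#' @param drive A [drive_params()].
#' @param tau_v Membrane time constant (ms).
#' @return A [voltage_stats()].
#' @export
one_dendrite_stats <- function(drive, tau_v) {
  stopifnot(inherits(drive, "drive_params"))
  check_scalar(tau_v, "tau_v")
  rt <- sqrt(drive$tau_s / (drive$tau_s + tau_v))  # = 1/sqrt(kappa)
  s2 <- 2 * drive$sigma_s^2 * (drive$tau_s / tau_v) * (1 - rt)
  sd2 <- (2 * drive$sigma_s^2 / (tau_v * drive$tau_s)) * rt
  voltage_stats(mean = drive$mu, sigma_v = sqrt(s2), sigma_vdot = sqrt(sd2),
                method = "closed-form")
}

#' Junction statistics of two semi-infinite dendrites
#'
#' Two statistically identical driven dendrites joined at a nominal soma,
#' with the trigger at the junction; equivalently the bulk (midpoint) limit
#' of the closed dendrite. Both variances are exactly half the one-dendrite
#' values and the mean is unchanged.
#'
#' @inheritParams one_dendrite_stats
#' @return A [voltage_stats()].
#' @export
two_dendrite_stats <- function(drive, tau_v) {
  s1 <- one_dendrite_stats(drive, tau_v)
  voltage_stats(mean = s1$mean,
                sigma_v = s1$sigma_v / sqrt(2),
                sigma_vdot = s1$sigma_vdot / sqrt(2),
                method = "closed-form")
}
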