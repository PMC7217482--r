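# Frequency-domain voltage statistics at the trigger point of composite
# morphologies (dendrites + axon, with nominal or lumped soma).
#
# The construction: a source element on a driven dendrite reaches the
# junction through the relative input admittance f(omega) of that dendrite
# within the whole neuron; integrating the squared transfer over the driven
# half-line shows that each dendrite contributes |f(omega)|^2 times the
# sealed-end spectrum of an isolated dendrite. Moving the trigger a distance
# x_th down the passive axon attenuates each frequency by
# exp(-x_th Re gamma_alpha / lambda_alpha), i.e. the spectrum by the square.
# Variances follow by quadrature of S and omega^2 S.

#' Cable frequency factor
#'
#' The dimensionless factor `gamma(omega) = sqrt(1 + i omega tau)` (principal
#' branch) through which a semi-infinite cable's input admittance
#' `G_lambda gamma(omega)` and attenuation `exp(-x gamma / lambda)` depend on
#' frequency. `Re gamma >= 1` with equality at DC.
#'
#' @param omega Angular frequency (rad/ms). Vectorized.
#' @param tau Membrane time constant (ms).
#' @return Complex vector.
#' @export
gamma_factor <- function(omega, tau) {
  if (tau <= 0) stop_invalid("`tau` must be positive")
  sqrt(1 + 1i * omega * tau)
}

# Relative admittance weights G_lambda_j ~ g_j^2 lambda_j^3 (per-area
# parameters fixed, radius ~ g lambda^2). Dendrite g_rel = epsilon, axon 1.
admittance_weights <- function(morph) {
  d <- morph$dendrite
  list(w1 = d$g_rel^2 * d$lambda^3,
       wa = if (is.null(morph$axon)) 0 else
         morph$axon$g_rel^2 * morph$axon$lambda^3)
}

#' Relative input admittance of one driven dendrite
#'
#' The complex, frequency-dependent fraction of the neuron's total input
#' admittance contributed by a single driven dendrite, evaluated at the
#' junction. With admittance weights `G_j ~ g_j^2 lambda_j^3` and
#' `gamma_j = sqrt(1 + i omega tau_j)`:
#' no soma: `f = G_1 gamma_1 / (n G_1 gamma_1 + G_a gamma_a)`;
#' lumped soma (dominance factors `rho_k = G_k/G_0`):
#' `f = rho_1 gamma_1 / (gamma_0^2 + n rho_1 gamma_1 + rho_a gamma_a)` with
#' `gamma_0^2 = 1 + i omega tau_0`. Satisfies `f(-omega) = Conj(f(omega))`,
#' `|f| <= 1`, and real `0 < f(0) <= 1` at DC.
#'
#' @param morph A [morphology()].
#' @param omega Angular frequency (rad/ms). Vectorized.
#' @return Complex vector of admittance fractions.
#' @export
rel_admittance <- function(morph, omega) {
  stopifnot(inherits(morph, "morphology"))
  w <- admittance_weights(morph)
  g1 <- gamma_factor(omega, morph$dendrite$tau)
  ga <- if (is.null(morph$axon)) 0 else gamma_factor(omega, morph$axon$tau)
  n <- morph$n_dendrites
  if (is.null(morph$soma)) {
    num <- w$w1 * g1
    den <- n * w$w1 * g1 + w$wa * ga
  } else {
    s <- morph$soma
    g02 <- 1 + 1i * omega * s$tau_0
    num <- s$rho_1 * g1
    den <- g02 + n * s$rho_1 * g1 + s$rho_alpha * ga
  }
  num / den
}

#' Voltage power spectrum at the sealed end of one driven dendrite
#'
#' Two-sided spectral density of the stationary voltage at the sealed end of
#' a single semi-infinite dendrite under distributed Ornstein-Uhlenbeck
#' drive:
#' \deqn{S_{\mathrm{end}}(\omega) = \frac{2\sigma_s^2\tau_s}
#'   {(1+\omega^2\tau_s^2)\sqrt{1+\omega^2\tau_v^2}\,
#'    \mathrm{Re}\,\gamma_v(\omega)},}
#' with `gamma_v` from [gamma_factor()]. Its moments
#' `(1/pi) * integral of S` and `(1/pi) * integral of omega^2 S` over
#' `[0, Inf)` reproduce the closed-form variances of
#' [one_dendrite_stats()]. The high-frequency tails decay as
#' `omega^(-7/2)` and `omega^(-3/2)` respectively, so the derivative
#' variance exists but converges slowly -- the quadrature in
#' [stats_from_psd()] maps the tail to a finite interval exactly rather than
#' truncating it.
#'
#' @param omega Angular frequency (rad/ms). Vectorized.
#' @param drive A [drive_params()].
#' @param tau_v Dendritic membrane time constant (ms).
#' @return Spectral density (mV^2 ms).
#' @export
sealed_end_psd <- function(omega, drive, tau_v) {
  stopifnot(inherits(drive, "drive_params"))
  re_g <- Re(gamma_factor(omega, tau_v))
  2 * drive$sigma_s^2 * drive$tau_s /
    ((1 + omega^2 * drive$tau_s^2) * sqrt(1 + omega^2 * tau_v^2) * re_g)
}

#' Voltage power spectrum at the trigger point
#'
#' Composes the sealed-end spectrum with the morphology:
#' `S(omega) = n |f(omega)|^2 exp(-2 x_th Re gamma_a / lambda_a) S_end(omega)`
#' where `f` is the relative input admittance of one driven dendrite
#' ([rel_admittance()]), `n` the number of (independently driven) dendrites,
#' and the exponential the spectral attenuation from the junction to the
#' trigger point on the passive axon.
#'
#' @param morph A [morphology()]; the trigger must sit at the junction
#'   (`x_th = 0`) or on the axon.
#' @param drive A [drive_params()].
#' @param omega Angular frequency (rad/ms). Vectorized.
#' @return Spectral density (mV^2 ms).
#' @export
trigger_psd <- function(morph, drive, omega) {
  stopifnot(inherits(morph, "morphology"))
  x_th <- morph$threshold$x_th
  if (morph$threshold$trigger == "dendrite" && x_th > 0)
    abort("trigger positions x_th > 0 on a driven dendrite are not supported",
          class = "ricecable_unsupported_morphology")
  S <- sealed_end_psd(omega, drive, morph$dendrite$tau)
  f2 <- Mod(rel_admittance(morph, omega))^2
  att <- 1
  if (x_th > 0) {
    ax <- morph$axon
    att <- exp(-2 * x_th * Re(gamma_factor(omega, ax$tau)) / ax$lambda)
  }
  morph$n_dendrites * f2 * att * S
}

#' Mean voltage at the trigger point
#'
#' For a single dendrite with no load the mean is simply `mu`. With an
#' axonal or somatic load the DC admittance fraction and the static axonal
#' attenuation apply, each of the `n` dendrites contributing linearly:
#' `n mu f(0) exp(-x_th/lambda_a)`.
#'
#' @param morph A [morphology()].
#' @param drive A [drive_params()].
#' @return Mean voltage (mV above leak).
#' @export
mean_at_trigger <- function(morph, drive) {
  stopifnot(inherits(morph, "morphology"), inherits(drive, "drive_params"))
  if (is.null(morph$axon) && is.null(morph$soma)) return(drive$mu)
  f0 <- Re(rel_admittance(morph, 0))
  att <- if (morph$threshold$x_th > 0)
    exp(-morph$threshold$x_th / morph$axon$lambda) else 1
  morph$n_dendrites * drive$mu * f0 * att
}

#' Quadrature grid descriptor for spectral moments
#'
#' Describes how [stats_from_psd()] integrates the voltage spectrum: an
#' adaptive panel on `[0, omega_split]` plus an exact algebraic change of
#' variable `omega = omega_split / t^2` that maps the remaining tail onto
#' `(0, 1]`, where the integrands of both moments are bounded and smooth.
#' Nothing is truncated, so the slowly converging derivative-variance moment
#' carries no systematic tail bias.
#'
#' @param rel_tol Relative tolerance passed to the adaptive quadrature.
#' @param omega_split Split frequency (rad/ms); `NULL` chooses
#'   `50 / min(tau)` from the model's time constants at evaluation time.
#' @return An object of class `spectrum_grid`.
#' @export
spectrum_grid <- function(rel_tol = 1e-10, omega_split = NULL) {
  check_scalar(rel_tol, "rel_tol")
  if (!is.null(omega_split)) check_scalar(omega_split, "omega_split")
  structure(list(rel_tol = rel_tol, omega_split = omega_split),
            class = "spectrum_grid")
}

# \int_0^Inf h(w) dw as [0, wc] + exact tail substitution w = wc/t^2.
integrate_spectrum <- function(h, omega_split, rel_tol) {
  head <- integrate(h, 0, omega_split, rel.tol = rel_tol, abs.tol = 0,
                    subdivisions = 400L, stop.on.error = FALSE)
  tail <- integrate(function(t) h(omega_split / t^2) * 2 * omega_split / t^3,
                    0, 1, rel.tol = rel_tol, abs.tol = 0,
                    subdivisions = 400L, stop.on.error = FALSE)
  if (head$message != "OK" || tail$message != "OK")
    abort("spectral quadrature failed to converge",
          class = "ricecable_non_convergence")
  list(value = head$value + tail$value,
       abs_error = head$abs.error + tail$abs.error)
}

#' Voltage statistics by quadrature of the trigger-point spectrum
#'
#' Computes `sigma_v^2 = (1/pi) * integral S(omega) domega` and
#' `sigma_vdot^2 = (1/pi) * integral omega^2 S(omega) domega` over
#' `[0, Inf)` from [trigger_psd()], and the mean from [mean_at_trigger()].
#' The achieved quadrature error bound is attached as attribute
#' `"quad_error"` (absolute, per moment); an error of class
#' `ricecable_non_convergence` is signalled if the estimated error exceeds
#' the grid tolerance.
#'
#' @param morph A [morphology()].
#' @param drive A [drive_params()].
#' @param grid A [spectrum_grid()].
#' @return A [voltage_stats()] with method `"spectral"`.
#' @examples
#' nm <- neuron_model(mu = 5, sigma_s = 3, a_ratio = 0.25, x_th = 30)
#' stats_from_psd(nm$morph, nm$drive)
#' @export
stats_from_psd <- function(morph, drive, grid = spectrum_grid()) {
  stopifnot(inherits(grid, "spectrum_grid"))
  taus <- c(drive$tau_s, morph$dendrite$tau,
            if (!is.null(morph$axon)) morph$axon$tau,
            if (!is.null(morph$soma)) morph$soma$tau_0)
  wc <- if (is.null(grid$omega_split)) 50 / min(taus) else grid$omega_split
  Sfun <- function(w) trigger_psd(morph, drive, w)
  m0 <- integrate_spectrum(Sfun, wc, grid$rel_tol)
  m2 <- integrate_spectrum(function(w) w^2 * Sfun(w), wc, grid$rel_tol)
  s2 <- m0$value / pi
  sd2 <- m2$value / pi
  err <- c(sigma_v2 = m0$abs_error / pi, sigma_vdot2 = m2$abs_error / pi)
  if (m0$abs_error > 1e4 * grid$rel_tol * m0$value ||
      m2$abs_error > 1e4 * grid$rel_tol * m2$value)
    abort("spectral quadrature error estimate exceeds tolerance",
          class = "ricecable_non_convergence")
  out <- voltage_stats(mean = mean_at_trigger(morph, drive),
                       sigma_v = sqrt(s2), sigma_vdot = sqrt(sd2),
                       method = "spectral")
  attr(out, "quad_error") <- err
  out
}

#' Tabulate the trigger-point spectrum
#'
#' Columnar export of the spectrum and the derivative-variance integrand for
#' inspection or plotting.
#'
#' @inheritParams stats_from_psd
#' @param omega Angular frequencies (rad/ms).
#' @return A tibble with columns `omega`, `S` and `omega2S`.
#' @export
spectrum_table <- function(morph, drive,
                           omega = seq(0, 10 / drive$tau_s, length.out = 256)) {
  S <- trigger_psd(morph, drive, omega)
  tibble(omega = omega, S = S, omega2S = omega^2 * S)
}
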