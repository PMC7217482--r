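# Parameter containers and derived-parameter relations.
#
# The analytic pipeline never sees absolute conductances or radii: every
# formula in the model depends only on the dimensionless ratios (epsilon,
# a_alpha/a_1, rho_1, rho_alpha) together with the per-neurite space and
# time constants (lambda, tau). Constructors validate strictly and refuse
# out-of-range values rather than clamping them, so that parameter sweeps
# stay honest.

stop_invalid <- function(msg) abort(msg, class = "ricecable_invalid_parameter")

check_scalar <- function(x, name, positive = TRUE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && (x < 0 || (!allow_zero && x == 0)))
    stop_invalid(sprintf("`%s` must be %s", name,
                         if (allow_zero) "non-negative" else "strictly positive"))
  invisible(x)
}

#' Effective synaptic drive parameters
#'
#' Bundles the effective description of distributed synaptic input to a
#' dendrite: the mean depolarization `mu` it produces above the leak
#' reversal, the noise amplitude `sigma_s` and time constant `tau_s` of the
#' Ornstein-Uhlenbeck synaptic fluctuation field, and the leak and synaptic
#' reversal potentials that fix the conductance ratio [derive_epsilon()].
#'
#' @param mu Effective resting potential above leak (mV); must satisfy
#'   `0 <= mu < E_s - E_L`.
#' @param sigma_s Synaptic noise amplitude (mV), non-negative.
#' @param tau_s Synaptic filter time constant (ms).
#' @param E_L,E_s Leak and synaptic reversal potentials (mV), `E_s > E_L`.
#' @return An object of class `drive_params`.
#' @examples
#' drive_params(mu = 5, sigma_s = 3, tau_s = 5)
#' @export
drive_params <- function(mu, sigma_s, tau_s, E_L = -70, E_s = 0) {
  check_scalar(mu, "mu", positive = TRUE, allow_zero = TRUE)
  check_scalar(sigma_s, "sigma_s", positive = TRUE, allow_zero = TRUE)
  check_scalar(tau_s, "tau_s")
  check_scalar(E_s - E_L, "E_s - E_L")
  if (mu >= E_s - E_L)
    stop_invalid("`mu` must be below the synaptic driving force E_s - E_L")
  structure(list(mu = mu, sigma_s = sigma_s, tau_s = tau_s,
                 E_L = E_L, E_s = E_s),
            class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat(sprintf("<drive_params> mu = %g mV, sigma_s = %g mV, tau_s = %g ms (E_L = %g, E_s = %g mV)\n",
              x$mu, x$sigma_s, x$tau_s, x$E_L, x$E_s))
  invisible(x)
}

#' Cable properties of a single neurite
#'
#' @param role `"driven-dendrite"` (receives distributed synaptic drive) or
#'   `"passive-axon"` (leak conductance only, no drive).
#' @param lambda Electrotonic length constant (um).
#' @param tau Membrane time constant (ms).
#' @param g_rel Membrane conductance per area relative to leak. For a driven
#'   dendrite under mean synaptic load this equals epsilon; a passive axon
#'   must have `g_rel = 1`.
#' @param radius_rel Radius relative to the reference dendrite.
#' @return An object of class `neurite_spec`.
#' @export
neurite_spec <- function(role = c("driven-dendrite", "passive-axon"),
                         lambda, tau, g_rel = 1, radius_rel = 1) {
  role <- match.arg(role)
  check_scalar(lambda, "lambda")
  check_scalar(tau, "tau")
  check_scalar(g_rel, "g_rel")
  check_scalar(radius_rel, "radius_rel", allow_zero = TRUE)
  if (g_rel < 1)
    stop_invalid("`g_rel` must be >= 1 (synaptic drive only adds conductance)")
  if (role == "passive-axon" && g_rel != 1)
    stop_invalid("a passive axon has no synaptic conductance: `g_rel` must be 1")
  structure(list(role = role, lambda = lambda, tau = tau,
                 g_rel = g_rel, radius_rel = radius_rel),
            class = "neurite_spec")
}

#' Lumped soma properties
#'
#' The soma is characterized by the dominance factors `rho_1 = G_lambda1/G_0`
#' and `rho_alpha = G_lambdaalpha/G_0` (ratios of the characteristic input
#' conductance of one electrotonic length of dendrite/axon to the somatic
#' conductance) and its membrane time constant `tau_0`.
#'
#' @param rho_1 Dendritic dominance factor (> 0; large values mean a small soma).
#' @param rho_alpha Axonal dominance factor (>= 0; zero when no axon).
#' @param tau_0 Somatic membrane time constant (ms).
#' @return An object of class `soma_spec`.
#' @export
soma_spec <- function(rho_1, rho_alpha = 0, tau_0) {
  check_scalar(rho_1, "rho_1")
  check_scalar(rho_alpha, "rho_alpha", allow_zero = TRUE)
  check_scalar(tau_0, "tau_0")
  structure(list(rho_1 = rho_1, rho_alpha = rho_alpha, tau_0 = tau_0),
            class = "soma_spec")
}

#' Spike trigger description
#'
#' The integrate-and-fire mechanism monitors the voltage at position `x_th`
#' along the trigger neurite; when it exceeds `v_th` the voltage of the whole
#' structure is reset to `v_re`.
#'
#' @param v_th Threshold voltage (mV, relative to leak).
#' @param v_re Reset voltage (mV); must be below `v_th`.
#' @param x_th Trigger position along the trigger neurite (um). `x_th = 0` is
#'   the sealed end / junction / soma.
#' @param trigger `"dendrite"` or `"axon"`. Trigger positions `x_th > 0` are
#'   supported on the axon only.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(v_th = 10, v_re = 0, x_th = 0,
                           trigger = c("dendrite", "axon")) {
  trigger <- match.arg(trigger)
  check_scalar(v_th, "v_th", positive = FALSE)
  check_scalar(v_re, "v_re", positive = FALSE)
  check_scalar(x_th, "x_th", allow_zero = TRUE)
  if (v_th <= v_re) stop_invalid("`v_th` must exceed `v_re`")
  structure(list(v_th = v_th, v_re = v_re, x_th = x_th, trigger = trigger),
            class = "threshold_spec")
}

#' Neuron morphology
#'
#' Assembles `n_dendrites` identical driven dendrites, an optional passive
#' axon and an optional lumped soma, all meeting at a single junction, plus
#' the spike-trigger description. With no axon and no soma the junction is a
#' sealed end (one dendrite) or a nominal soma (several dendrites).
#'
#' @param n_dendrites Number of identical driven dendrites (>= 1).
#' @param dendrite A [neurite_spec()] with role `"driven-dendrite"`.
#' @param axon Optional [neurite_spec()] with role `"passive-axon"`.
#' @param soma Optional [soma_spec()].
#' @param threshold A [threshold_spec()].
#' @param closed_length Optional finite dendrite length L (um); only used by
#'   the closed-dendrite variance profiles, all firing-rate models treat
#'   neurites as semi-infinite.
#' @return An object of class `morphology`.
#' @seealso [neuron_model()] for the high-level constructor that derives all
#'   coupled parameters from `mu` and the radius ratio.
#' @export
morphology <- function(n_dendrites = 1, dendrite, axon = NULL, soma = NULL,
                       threshold = threshold_spec(), closed_length = NULL) {
  if (!is.numeric(n_dendrites) || n_dendrites < 1 || n_dendrites != round(n_dendrites))
    stop_invalid("`n_dendrites` must be a positive integer")
  if (!inherits(dendrite, "neurite_spec") || dendrite$role != "driven-dendrite")
    stop_invalid("`dendrite` must be a neurite_spec with role 'driven-dendrite'")
  if (!is.null(axon) && (!inherits(axon, "neurite_spec") || axon$role != "passive-axon"))
    stop_invalid("`axon` must be NULL or a neurite_spec with role 'passive-axon'")
  if (!is.null(soma) && !inherits(soma, "soma_spec"))
    stop_invalid("`soma` must be NULL or a soma_spec")
  if (!inherits(threshold, "threshold_spec"))
    stop_invalid("`threshold` must be a threshold_spec")
  if (threshold$trigger == "axon" && is.null(axon))
    stop_invalid("trigger is on the axon but the morphology has no axon")
  if (threshold$trigger == "dendrite" && threshold$x_th > 0)
    abort("trigger positions x_th > 0 on a driven dendrite are not supported",
          class = "ricecable_unsupported_morphology")
  if (!is.null(soma) && (is.null(soma$rho_1) || (!is.null(axon) && soma$rho_alpha <= 0)))
    abort("soma present but dominance factors are unset",
          class = "ricecable_inconsistent_morphology")
  if (!is.null(closed_length)) check_scalar(closed_length, "closed_length")
  structure(list(n_dendrites = as.integer(n_dendrites), dendrite = dendrite,
                 axon = axon, soma = soma, threshold = threshold,
                 closed_length = closed_length),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d dendrite(s)%s%s; trigger %s @ x_th = %g um\n",
              x$n_dendrites,
              if (is.null(x$axon)) "" else
                sprintf(" + axon (lambda = %g um, tau = %g ms)", x$axon$lambda, x$axon$tau),
              if (is.null(x$soma)) "" else
                sprintf(" + soma (rho_1 = %g, rho_alpha = %g, tau_0 = %g ms)",
                        x$soma$rho_1, x$soma$rho_alpha, x$soma$tau_0),
              x$threshold$trigger, x$threshold$x_th))
  invisible(x)
}

#' Total-to-leak conductance ratio under mean synaptic load
#'
#' The tonic synaptic conductance raises the total membrane conductance g
#' above the leak value g_L by the factor
#' `epsilon = (E_L - E_s) / (E_L + mu - E_s)`, where `mu` is the effective
#' resting potential above leak produced by the drive. `epsilon >= 1`, with
#' equality when there is no mean drive.
#'
#' @param E_L,E_s Leak and synaptic reversal potentials (mV).
#' @param mu Effective resting potential above leak (mV). Vectorized.
#' @return The dimensionless ratio epsilon = g/g_L.
#' @examples
#' derive_epsilon(-70, 0, 5)   # 70/65
#' @export
derive_epsilon <- function(E_L, E_s, mu) {
  if (any(mu >= E_s - E_L) || any(mu < 0))
    stop_invalid("`mu` must lie in [0, E_s - E_L)")
  (E_L - E_s) / (E_L + mu - E_s)
}

#' Passive (axonal or somatic) time constant under dendritic load
#'
#' With identical per-area capacitance and leak conductance in all sections,
#' the only difference between the dendritic and axonal/somatic membrane time
#' constants is the tonic synaptic conductance on the dendrite, so
#' `tau_alpha = epsilon * tau_1`.
#'
#' @param epsilon Conductance ratio from [derive_epsilon()] (>= 1).
#' @param tau_1 Dendritic membrane time constant (ms).
#' @return Passive time constant (ms). Vectorized.
#' @export
axonal_time_constant <- function(epsilon, tau_1) {
  if (any(epsilon < 1)) stop_invalid("`epsilon` must be >= 1")
  if (any(tau_1 <= 0)) stop_invalid("`tau_1` must be positive")
  epsilon * tau_1
}

#' Axonal length constant from the radius ratio
#'
#' The radius ratio satisfies `a_alpha/a_1 = g_alpha lambda_alpha^2 /
#' (g_1 lambda_1^2)` and the dendrite/axon conductance ratio is
#' `g_1/g_alpha = epsilon` (the dendrite carries the mean synaptic
#' conductance, the axon leak only), hence
#' `lambda_alpha = lambda_1 * sqrt(epsilon * a_alpha/a_1)`.
#'
#' @param radius_ratio Axon-to-dendrite radius ratio `a_alpha/a_1` (>= 0).
#' @param lambda_1 Dendritic length constant (um).
#' @param epsilon Conductance ratio from [derive_epsilon()].
#' @return Axonal length constant (um). Vectorized.
#' @seealso [radius_ratio_from_lambda()] for the inverse map.
#' @export
lambda_from_radius_ratio <- function(radius_ratio, lambda_1, epsilon) {
  if (any(radius_ratio < 0)) stop_invalid("`radius_ratio` must be >= 0")
  lambda_1 * sqrt(epsilon * radius_ratio)
}

#' @rdname lambda_from_radius_ratio
#' @param lambda_alpha Axonal length constant (um).
#' @export
radius_ratio_from_lambda <- function(lambda_alpha, lambda_1, epsilon) {
  lambda_alpha^2 / (epsilon * lambda_1^2)
}

#' Axonal dominance factor from the dendritic one
#'
#' Given `rho_1 = G_lambda1/G_0`, the axonal factor follows from the ratio of
#' characteristic input conductances, `rho_alpha/rho_1 =
#' G_lambdaalpha/G_lambda1`, which with `G_lambda ~ g^2 lambda^3` (at fixed
#' per-area parameters, radius a ~ g lambda^2) and `g_1/g_alpha = epsilon`
#' gives `rho_alpha = rho_1 * lambda_alpha^3 / (lambda_1^3 * epsilon^2)`.
#'
#' @param rho_1 Dendritic dominance factor.
#' @param lambda_alpha,lambda_1 Length constants (um).
#' @param epsilon Conductance ratio from [derive_epsilon()].
#' @return Axonal dominance factor. Vectorized.
#' @export
rho_alpha_from_rho1 <- function(rho_1, lambda_alpha, lambda_1, epsilon) {
  if (any(rho_1 < 0)) stop_invalid("`rho_1` must be >= 0")
  rho_1 * lambda_alpha^3 / (lambda_1^3 * epsilon^2)
}

#' Total input conductance of a morphology, relative to one dendrite
#'
#' Evaluates `G_in = n * (2 pi a_1 lambda_1 g_1) + 2 pi a_alpha lambda_alpha
#' g_alpha` in units of the single-dendrite term for a reference dendritic
#' length constant. With the per-area parameters fixed, each term is
#' proportional to `g^2 lambda^3`. This supports the conductance-matched
#' rescaling `lambda_1(n) = lambda_1(1) / n^(1/3)` that keeps the total input
#' conductance equal to the single-dendrite value while adding dendrites.
#'
#' @param morph A [morphology()].
#' @param lambda_ref Reference dendritic length constant defining the unit
#'   (um); defaults to the morphology's own dendrite.
#' @return Dimensionless relative input conductance.
#' @export
relative_input_conductance <- function(morph, lambda_ref = morph$dendrite$lambda) {
  stopifnot(inherits(morph, "morphology"))
  d <- morph$dendrite
  unit <- d$g_rel^2 * lambda_ref^3
  g <- morph$n_dendrites * d$g_rel^2 * d$lambda^3
  if (!is.null(morph$axon)) {
    a <- morph$axon
    g <- g + a$g_rel^2 * a$lambda^3
  }
  g / unit
}

#' Microscopic synapse parameters
#'
#' Per-area membrane and synapse constants underlying the effective drive;
#' used only by the documented helper [effective_from_microscopic()], never
#' by the analytic pipeline, which is parametrized directly by
#' (mu, sigma_s, tau_s).
#'
#' @param c_m Membrane capacitance per area (uF/cm^2 or any consistent unit).
#' @param g_L Leak conductance per area.
#' @param gamma_s Conductance increment per synaptic event.
#' @param rho_dens Areal synapse density.
#' @param r_s Mean per-synapse arrival rate (1/ms).
#' @param r_a Axial resistivity.
#' @param a Neurite radius (um).
#' @return An object of class `microscopic_synapse_params`.
#' @export
microscopic_synapse_params <- function(c_m, g_L, gamma_s, rho_dens, r_s, r_a, a) {
  for (nm in c("c_m", "g_L", "gamma_s", "rho_dens", "r_a", "a"))
    check_scalar(get(nm), nm)
  check_scalar(r_s, "r_s", allow_zero = TRUE)
  structure(list(c_m = c_m, g_L = g_L, gamma_s = gamma_s, rho_dens = rho_dens,
                 r_s = r_s, r_a = r_a, a = a),
            class = "microscopic_synapse_params")
}

#' Effective drive from microscopic synaptic parameters
#'
#' Convenience helper mapping per-synapse quantities to the effective
#' parametrization. The mean synaptic conductance is
#' `<g_s> = tau_s * gamma_s * r_s * rho_dens`; the total conductance is
#' `g = g_L + <g_s>`; the mean depolarization is
#' `mu = <g_s> (E_s - E_L) / g`; and the noise amplitude is
#' `sigma_s = gamma_s (E_s - <V>) / (2 g) * sqrt(rho_dens r_s tau_s / (2 pi a lambda))`,
#' obtained by matching the diffusion limit of the shot-noise conductance to
#' the Ornstein-Uhlenbeck drive field. (The grouping of the prefactor is
#' ambiguous in some renderings of this expression; the form used here is the
#' one recovered by carrying the Gaussian approximation of the Poissonian
#' conductance through the rescaling to voltage units, and the main pipeline
#' never depends on it.)
#'
#' @param p A [microscopic_synapse_params()].
#' @param tau_s Synaptic time constant (ms).
#' @param E_L,E_s Reversal potentials (mV).
#' @param mean_V Mean voltage used for the effective driving force
#'   (mV; defaults to the self-consistent resting value E).
#' @return A list with the mean synaptic conductance per area `g_s_mean`, the
#'   conductance ratio `epsilon`, and a [drive_params()] with the implied
#'   (mu, sigma_s, tau_s).
#' @export
effective_from_microscopic <- function(p, tau_s, E_L = -70, E_s = 0, mean_V = NULL) {
  stopifnot(inherits(p, "microscopic_synapse_params"))
  check_scalar(tau_s, "tau_s")
  gs <- tau_s * p$gamma_s * p$r_s * p$rho_dens
  g <- p$g_L + gs
  mu <- gs * (E_s - E_L) / g
  if (is.null(mean_V)) mean_V <- E_L + mu
  lambda <- sqrt(p$a / (2 * g * p$r_a))
  sigma_s <- p$gamma_s * (E_s - mean_V) / (2 * g) *
    sqrt(p$rho_dens * p$r_s * tau_s / (2 * pi * p$a * lambda))
  list(g_s_mean = gs,
       epsilon = g / p$g_L,
       drive = drive_params(mu = mu, sigma_s = sigma_s, tau_s = tau_s,
                            E_L = E_L, E_s = E_s))
}

#' High-level neuron model constructor
#'
#' Builds a [morphology()] and [drive_params()] pair from the independent
#' parameters of the model, deriving all coupled quantities: `epsilon` from
#' `mu`, the dendritic conductance `g_rel = epsilon`, the axonal time
#' constant `tau_alpha = epsilon * tau_1`, the axonal length constant from
#' the radius ratio, and `rho_alpha` from `rho_1`. The dendritic radius is
#' implicitly adjusted with `mu` so that `lambda_1` stays fixed
#' (`a_1 ~ g_1(mu)` at constant lambda).
#'
#' @param mu Mean drive (mV above leak).
#' @param sigma_s Synaptic noise amplitude (mV).
#' @param n_dendrites Number of identical driven dendrites.
#' @param a_ratio Axon-to-dendrite radius ratio; `NULL` or `0` for no axon.
#' @param rho_1 Dendritic dominance factor; `NULL` for no (nominal) soma.
#' @param lambda_1 Dendritic length constant (um).
#' @param tau_1 Dendritic membrane time constant (ms).
#' @param tau_s Synaptic time constant (ms).
#' @param x_th Trigger position (um) along the axon (or 0 for the junction).
#' @param v_th,v_re Threshold and reset voltages (mV).
#' @param E_L,E_s Reversal potentials (mV).
#' @param tau_0 Somatic time constant (ms); defaults to `tau_alpha`.
#' @return An object of class `neuron_model`: a list with elements `morph`
#'   (a [morphology()]), `drive` (a [drive_params()]) and the derived scalars
#'   `epsilon`, `tau_alpha`, `lambda_alpha`, `rho_alpha`.
#' @examples
#' nm <- neuron_model(mu = 5, sigma_s = 3, a_ratio = 0.25, x_th = 30)
#' nm$epsilon            # 70/65
#' nm$morph$axon$lambda  # lambda_1 * sqrt(epsilon * a_ratio)
#' @export
neuron_model <- function(mu, sigma_s, n_dendrites = 1, a_ratio = NULL,
                         rho_1 = NULL, lambda_1 = 200, tau_1 = 10, tau_s = 5,
                         x_th = 0, v_th = 10, v_re = 0, E_L = -70, E_s = 0,
                         tau_0 = NULL) {
  drive <- drive_params(mu = mu, sigma_s = sigma_s, tau_s = tau_s,
                        E_L = E_L, E_s = E_s)
  eps <- derive_epsilon(E_L, E_s, mu)
  dend <- neurite_spec("driven-dendrite", lambda = lambda_1, tau = tau_1,
                       g_rel = eps)
  axon <- NULL
  lambda_alpha <- NA_real_
  tau_alpha <- axonal_time_constant(eps, tau_1)
  if (!is.null(a_ratio) && a_ratio > 0) {
    lambda_alpha <- lambda_from_radius_ratio(a_ratio, lambda_1, eps)
    axon <- neurite_spec("passive-axon", lambda = lambda_alpha,
                         tau = tau_alpha, g_rel = 1, radius_rel = a_ratio)
  }
  soma <- NULL
  rho_alpha <- NA_real_
  if (!is.null(rho_1)) {
    rho_alpha <- if (is.null(axon)) 0 else
      rho_alpha_from_rho1(rho_1, lambda_alpha, lambda_1, eps)
    soma <- soma_spec(rho_1 = rho_1, rho_alpha = rho_alpha,
                      tau_0 = if (is.null(tau_0)) tau_alpha else tau_0)
  }
  trigger <- if (is.null(axon)) "dendrite" else "axon"
  thr <- threshold_spec(v_th = v_th, v_re = v_re, x_th = x_th, trigger = trigger)
  morph <- morphology(n_dendrites = n_dendrites, dendrite = dend, axon = axon,
                      soma = soma, threshold = thr)
  structure(list(morph = morph, drive = drive, epsilon = eps,
                 tau_alpha = tau_alpha, lambda_alpha = lambda_alpha,
                 rho_alpha = rho_alpha),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  print(x$drive); print(x$morph)
  cat(sprintf("  derived: epsilon = %.4f, tau_alpha = %.4g ms\n",
              x$epsilon, x$tau_alpha))
  invisible(x)
}
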