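# Stochastic simulator of the threshold-reset cable model: R-side lattice
# construction, state bookkeeping and the wrappers around the compiled
# Euler-Maruyama stepping kernel.

#' Build the simulation lattice for a morphology
#'
#' Discretizes every neurite with spacing `dx`: voltage and synaptic-field
#' nodes at positions `(k + 1/2) dx`, derivative nodes at `k dx`.
#' Semi-infinite neurites are truncated at `L = max(1000, 10 lambda)` um with
#' sealed far ends, long enough that boundary effects at the junction are
#' negligible. Neurites are ordered dendrites first, axon last, all joined at
#' x = 0 (a sealed end for a single dendrite, otherwise a nominal or lumped
#' soma). The explicit scheme's stability bound
#' `dt <= 2 tau / (1 + 4 lambda^2/dx^2)` is verified per neurite (and for
#' the soma ODE), and the trigger position must coincide with a voltage node
#' (`x_th = 0` denotes the junction itself).
#'
#' @param morph A [morphology()].
#' @param dx Spatial step (um).
#' @param dt Time step (ms).
#' @param seed Optional integer seed stored with the lattice and applied by
#'   [run_simulation()].
#' @return An object of class `lattice_spec`.
#' @export
build_lattice <- function(morph, dx = 20, dt = 0.02, seed = NULL) {
  stopifnot(inherits(morph, "morphology"))
  check_scalar(dx, "dx"); check_scalar(dt, "dt")
  n <- morph$n_dendrites
  d <- morph$dendrite
  specs <- rep(list(d), n)
  if (!is.null(morph$axon)) specs <- c(specs, list(morph$axon))
  J <- length(specs)
  lengths <- vapply(specs, function(s) {
    L <- max(1000, 10 * s$lambda)
    ceiling(L / dx) * dx
  }, numeric(1))
  ncomp <- as.integer(lengths / dx)
  for (s in specs) {
    bound <- 2 * s$tau / (1 + 4 * s$lambda^2 / dx^2)
    if (dt > bound)
      abort(sprintf("dt = %g ms violates the stability bound %.4g ms for lambda = %g um",
                    dt, bound, s$lambda),
            class = "ricecable_stability_violation")
  }
  if (is.null(morph$soma)) {
    junction <- "nominal"
    # flux weights lambda_k G_k ~ g_k^2 lambda_k^4
    jweights <- vapply(specs, function(s) s$g_rel^2 * s$lambda^4, numeric(1))
    tau_0 <- 0
  } else {
    junction <- "lumped"
    rho <- c(rep(morph$soma$rho_1, n),
             if (!is.null(morph$axon)) morph$soma$rho_alpha)
    jweights <- rho * vapply(specs, function(s) s$lambda, numeric(1))
    tau_0 <- morph$soma$tau_0
    bound0 <- 2 * tau_0 / (1 + sum(jweights) * 2 / dx)
    if (dt > bound0)
      abort(sprintf("dt = %g ms violates the somatic stability bound %.4g ms",
                    dt, bound0),
            class = "ricecable_stability_violation")
  }
  x_th <- morph$threshold$x_th
  if (x_th == 0) {
    trig_neurite <- -1L; trig_node <- 0L
  } else {
    k <- round(x_th / dx - 0.5)
    if (k < 0 || abs((k + 0.5) * dx - x_th) > 1e-9)
      abort(sprintf("x_th = %g um does not coincide with a voltage node (nodes at (k+1/2)*%g um)",
                    x_th, dx),
            class = "ricecable_misaligned_trigger")
    trig_neurite <- if (morph$threshold$trigger == "axon") J - 1L else 0L
    trig_node <- as.integer(k)
    if (trig_node >= ncomp[trig_neurite + 1L])
      stop_invalid("trigger position beyond the truncated neurite")
  }
  structure(list(morph = morph, dx = dx, dt = dt, seed = seed,
                 n_neurites = J, ncomp = ncomp, lengths = lengths,
                 junction = junction, jweights = jweights, tau_0 = tau_0,
                 trig_neurite = trig_neurite, trig_node = trig_node),
            class = "lattice_spec")
}

neurite_params <- function(lattice, drive) {
  m <- lattice$morph
  n <- m$n_dendrites
  amp_d <- 2 * drive$sigma_s *
    sqrt(m$dendrite$lambda * drive$tau_s / (lattice$dx * lattice$dt))
  specs <- list()
  for (j in seq_len(n))
    specs[[j]] <- list(n = lattice$ncomp[j], tau = m$dendrite$tau,
                       lambda = m$dendrite$lambda, mu = drive$mu, amp = amp_d)
  if (!is.null(m$axon))
    specs[[n + 1]] <- list(n = lattice$ncomp[n + 1], tau = m$axon$tau,
                           lambda = m$axon$lambda, mu = 0, amp = 0)
  specs
}

#' Initial lattice state
#'
#' All fields start at zero (the leak potential); [run_simulation()] discards
#' an initial transient so the choice does not affect reported statistics.
#'
#' @param lattice A [build_lattice()] result.
#' @return An object of class `lattice_state` with per-neurite voltage `v`,
#'   synaptic field `s` and derivative field `dv`, the junction/soma voltage
#'   `v_junction`, and a `time_index`.
#' @export
lattice_state <- function(lattice) {
  stopifnot(inherits(lattice, "lattice_spec"))
  v <- lapply(lattice$ncomp, numeric)
  s <- lapply(lattice$ncomp, numeric)
  dv <- lapply(lattice$ncomp + 1L, numeric)
  structure(list(v = v, s = s, dv = dv, v_junction = 0, time_index = 0L),
            class = "lattice_state")
}

#' Apply boundary and junction conditions to a state
#'
#' Recomputes the derivative field and junction voltage from the voltage
#' field: sealed far ends impose a zero boundary derivative; a nominal soma
#' imposes the flux-balance junction voltage
#' `v_J = sum(w_k v_k(dx/2)) / sum(w_k)` with weights
#' `w_k = lambda_k G_k`, which makes the weighted derivative sum vanish
#' exactly; a lumped soma keeps its own dynamic voltage. Proximal derivative
#' nodes use the half spacing between the junction and the first voltage
#' node.
#'
#' @param state A [lattice_state()].
#' @param lattice A [build_lattice()] result.
#' @return The updated state.
#' @export
apply_boundaries <- function(state, lattice) {
  stopifnot(inherits(state, "lattice_state"))
  if (lattice$junction == "nominal") {
    first <- vapply(state$v, function(v) v[1], numeric(1))
    state$v_junction <- sum(lattice$jweights * first) / sum(lattice$jweights)
  }
  for (j in seq_len(lattice$n_neurites)) {
    v <- state$v[[j]]
    nk <- lattice$ncomp[j]
    dv <- numeric(nk + 1L)
    dv[1] <- (v[1] - state$v_junction) * 2 / lattice$dx
    if (nk > 1) dv[2:nk] <- diff(v) / lattice$dx
    dv[nk + 1L] <- 0
    state$dv[[j]] <- dv
  }
  state
}

#' Advance the lattice one Euler-Maruyama step
#'
#' Executes exactly one step of the staggered update (voltage from the
#' derivative field, derivative from the new voltage, Ornstein-Uhlenbeck
#' synaptic field with fresh Gaussian noise of amplitude
#' `2 sigma_s sqrt(lambda tau_s / (dx dt))` per driven site). No threshold
#' is applied; combine with [detect_and_reset()] for the integrate-and-fire
#' mechanism. Uses R's RNG stream.
#'
#' @param state A [lattice_state()].
#' @param lattice A [build_lattice()] result.
#' @param drive A [drive_params()].
#' @return The advanced state.
#' @export
em_step <- function(state, lattice, drive) {
  stopifnot(inherits(state, "lattice_state"), inherits(lattice, "lattice_spec"))
  res <- run_cable_cpp(neurite_params(lattice, drive),
                       lattice$dx, lattice$dt, drive$tau_s,
                       if (lattice$junction == "nominal") 0L else 1L,
                       lattice$jweights, lattice$tau_0,
                       lattice$trig_neurite, lattice$trig_node,
                       lattice$morph$threshold$v_th, lattice$morph$threshold$v_re,
                       0L, 1L, 0L,
                       state[c("v", "s", "v_junction")], FALSE)
  out <- res$state
  structure(list(v = out$v, s = out$s, dv = out$dv,
                 v_junction = out$v_junction,
                 time_index = state$time_index + 1L),
            class = "lattice_state")
}

#' Threshold detection and whole-cell reset
#'
#' If the voltage at the trigger node is at or above threshold, every voltage
#' node (including the junction/soma) is set to the reset value `v_re`; the
#' synaptic field is left untouched, since a somatic action potential does
#' not reset the state of the synapses.
#'
#' @param state A [lattice_state()].
#' @param lattice A [build_lattice()] result.
#' @param threshold A [threshold_spec()]; defaults to the morphology's own.
#' @return A list with the (possibly reset) `state` and logical `spike`.
#' @export
detect_and_reset <- function(state, lattice, threshold = lattice$morph$threshold) {
  vt <- trigger_voltage(state, lattice)
  if (vt >= threshold$v_th) {
    state$v <- lapply(state$v, function(v) rep(threshold$v_re, length(v)))
    state$v_junction <- threshold$v_re
    state <- apply_boundaries(state, lattice)
    list(state = state, spike = TRUE)
  } else {
    list(state = state, spike = FALSE)
  }
}

trigger_voltage <- function(state, lattice) {
  if (lattice$trig_neurite < 0) {
    if (lattice$junction == "nominal") {
      first <- vapply(state$v, function(v) v[1], numeric(1))
      sum(lattice$jweights * first) / sum(lattice$jweights)
    } else state$v_junction
  } else {
    state$v[[lattice$trig_neurite + 1L]][lattice$trig_node + 1L]
  }
}

#' Simulate the stochastic cable model
#'
#' Runs the compiled Euler-Maruyama kernel on the morphology for `duration`
#' ms, discarding an initial transient (default `10 * max(tau)`).
#' In `"reset"` mode the integrate-and-fire mechanism is active and the rate
#' is the spike count over the retained time; in `"no-reset"` mode
#' positive-going threshold crossings are counted instead (the upcrossing
#' rate); `"free"` applies no threshold. Voltage moments at the trigger node
#' and per-node means/variances are accumulated online; the rate uncertainty
#' is the Poisson-approximate standard error `sqrt(count)/time`.
#'
#' @param morph A [morphology()].
#' @param drive A [drive_params()].
#' @param duration Simulated time (ms), excluding nothing: the transient is
#'   part of it.
#' @param dx,dt Lattice steps (um, ms).
#' @param mode `"reset"`, `"no-reset"` or `"free"`.
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param transient Discarded initial time (ms).
#' @param record_trace If `TRUE`, keep the full trigger-voltage trace.
#' @param lattice Optionally a prebuilt [build_lattice()].
#' @return An object of class `cable_sim` with elements `spike_times`,
#'   `rate_hz`, `se_hz`, `n_events`, trigger moments (`mean_v`, `var_v`,
#'   `mean_vdot`, `var_vdot`), a `node_stats` tibble (per-node mean and
#'   variance at the sampled voltage nodes), and the run metadata.
#' @examples
#' \donttest{
#' nm <- neuron_model(mu = 4, sigma_s = 3)
#' sim <- run_simulation(nm$morph, nm$drive, duration = 2000, seed = 1)
#' sim$rate_hz
#' }
#' @export
run_simulation <- function(morph, drive, duration, dx = 20, dt = 0.02,
                           mode = c("reset", "no-reset", "free"), seed = NULL,
                           transient = NULL, record_trace = FALSE,
                           lattice = NULL) {
  mode <- match.arg(mode)
  if (is.null(lattice)) lattice <- build_lattice(morph, dx = dx, dt = dt, seed = seed)
  if (is.null(seed)) seed <- lattice$seed
  taus <- c(morph$dendrite$tau, drive$tau_s,
            if (!is.null(morph$axon)) morph$axon$tau,
            if (!is.null(morph$soma)) morph$soma$tau_0)
  if (is.null(transient)) transient <- 10 * max(taus)
  if (duration <= transient)
    stop_invalid("`duration` must exceed the discarded transient")
  n_steps <- ceiling(duration / lattice$dt)
  tr_steps <- ceiling(transient / lattice$dt)
  if (!is.null(seed)) set.seed(seed)
  mode_int <- c(free = 0L, `no-reset` = 1L, reset = 2L)[[mode]]
  res <- run_cable_cpp(neurite_params(lattice, drive),
                       lattice$dx, lattice$dt, drive$tau_s,
                       if (lattice$junction == "nominal") 0L else 1L,
                       lattice$jweights, lattice$tau_0,
                       lattice$trig_neurite, lattice$trig_node,
                       morph$threshold$v_th, morph$threshold$v_re,
                       mode_int, as.integer(n_steps), as.integer(tr_steps),
                       NULL, record_trace)
  t_obs <- (n_steps - tr_steps) * lattice$dt  # ms
  n_events <- if (mode == "reset") length(res$spike_times) else res$n_upcross
  rate_khz <- if (mode == "free") NA_real_ else n_events / t_obs
  se_khz <- if (mode == "free") NA_real_ else sqrt(max(n_events, 1)) / t_obs
  mean_v <- res$sum_v / res$n_samples
  var_v <- res$sum_v2 / res$n_samples - mean_v^2
  mean_vdot <- res$sum_vdot / res$n_dsamples
  var_vdot <- res$sum_vdot2 / res$n_dsamples - mean_vdot^2
  node_stats <- dplyr::bind_rows(lapply(seq_len(lattice$n_neurites), function(j) {
    m <- res$node_sum[[j]] / res$n_samples
    tibble(neurite = j,
           role = if (j <= morph$n_dendrites) "dendrite" else "axon",
           x = (seq_len(lattice$ncomp[j]) - 0.5) * lattice$dx,
           mean = m,
           variance = res$node_sum2[[j]] / res$n_samples - m^2)
  }))
  structure(list(
    spike_times = res$spike_times, n_events = n_events,
    rate_hz = khz_to_hz(rate_khz), se_hz = khz_to_hz(se_khz),
    mean_v = mean_v, var_v = var_v,
    mean_vdot = mean_vdot, var_vdot = var_vdot,
    node_stats = node_stats,
    trace = if (record_trace) res$trace else NULL,
    mode = mode, duration = duration, transient = transient,
    dt = lattice$dt, dx = lattice$dx, seed = seed,
    lattice = lattice, drive = drive),
    class = "cable_sim")
}

#' @export
print.cable_sim <- function(x, ...) {
  cat(sprintf("<cable_sim> mode = %s, %g ms simulated (transient %g ms), dx = %g um, dt = %g ms\n",
              x$mode, x$duration, x$transient, x$dx, x$dt))
  if (x$mode != "free")
    cat(sprintf("  events: %d, rate = %.4g +/- %.3g Hz\n",
                as.integer(x$n_events), x$rate_hz, x$se_hz))
  cat(sprintf("  trigger voltage: mean %.4g mV, var %.4g mV^2; vdot var %.4g mV^2/ms^2\n",
              x$mean_v, x$var_v, x$var_vdot))
  invisible(x)
}

#' Simulated rate as a rate_result
#'
#' @param sim A [run_simulation()] result (reset or no-reset mode).
#' @return A `rate_result` with method `"simulation"` and the Poisson
#'   standard error as uncertainty.
#' @export
sim_rate <- function(sim) {
  stopifnot(inherits(sim, "cable_sim"))
  if (sim$mode == "free")
    stop_invalid("free-mode simulations have no event rate")
  st <- voltage_stats(mean = sim$mean_v, sigma_v = sqrt(sim$var_v),
                      sigma_vdot = sqrt(sim$var_vdot), method = "simulation")
  new_rate_result(rate_khz = sim$rate_hz / 1000,
                  method = paste0(sim$mode, "/simulation"), stats = st,
                  uncertainty_hz = sim$se_hz, seed = sim$seed,
                  params = list(drive = sim$drive))
}
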