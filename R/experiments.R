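# Config-driven parameter sweeps and canned morphology experiments, with
# plain-CSV outputs and a JSON run manifest.

#' Experiment configuration
#'
#' @param name Experiment label (recorded in outputs).
#' @param grid Named list of parameter vectors (keys from the flat
#'   configuration vocabulary, see [read_neuron_config()]); the sweep is
#'   their cross product in deterministic row order.
#' @param engine `"analytic"`, `"simulation"` or `"both"`.
#' @param seed Base seed; simulation rows use `seed + row number`.
#' @param scale Fraction of the publication-scale simulated duration
#'   (100 s per grid point) to run, in (0, 1].
#' @param defaults Named list of fixed parameter values merged under each row.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(name, grid = list(),
                              engine = c("analytic", "simulation", "both"),
                              seed = 1L, scale = 0.1, defaults = list()) {
  engine <- match.arg(engine)
  bad <- setdiff(names(grid), config_keys)
  if (length(bad))
    stop_invalid(paste("unknown grid key(s):", paste(bad, collapse = ", ")))
  bad <- setdiff(names(defaults), config_keys)
  if (length(bad))
    stop_invalid(paste("unknown default key(s):", paste(bad, collapse = ", ")))
  if (scale <= 0 || scale > 1) stop_invalid("`scale` must be in (0, 1]")
  structure(list(name = name, grid = grid, engine = engine,
                 seed = as.integer(seed), scale = scale, defaults = defaults),
            class = "experiment_config")
}

sim_duration_ms <- function(scale) scale * 1e5  # publication scale: 100 s/point

#' Run a configured parameter sweep
#'
#' Evaluates the model on the cross product of the configured grid: one row
#' per point carrying the inputs, the trigger-point voltage statistics, the
#' upcrossing and deterministic rates, and (for simulation engines) the
#' simulated integrate-and-fire rate with its standard error and seed.
#' Failures are trapped per row into the `error` column and the sweep
#' continues. Analytic columns do not depend on the seed, and rerunning the
#' same configuration reproduces the table exactly.
#'
#' @param cfg An [experiment_config()].
#' @return A tibble, one row per grid point.
#' @examples
#' cfg <- experiment_config("demo", grid = list(mu = c(4, 6), sigma_s = c(1, 3)))
#' run_experiment(cfg)
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (length(cfg$grid) == 0L || any(lengths(cfg$grid) == 0L)) {
    return(tibble(row = integer(), mean = double(), sigma_v = double(),
                  sigma_vdot = double(), rate_hz = double(),
                  rate_deterministic_hz = double(), error = character()))
  }
  pts <- tidyr::expand_grid(!!!cfg$grid)
  one <- function(row, i) {
    params <- utils::modifyList(cfg$defaults, as.list(row))
    nm <- neuron_from_config(params)
    st <- trigger_stats(nm$morph, nm$drive)
    rr <- rice_rate(st, nm$morph$threshold$v_th)
    out <- tibble(mean = st$mean, sigma_v = st$sigma_v,
                  sigma_vdot = st$sigma_vdot,
                  rate_hz = khz_to_hz(rr),
                  rate_deterministic_hz = khz_to_hz(deterministic_lif_rate(
                    st$mean, nm$morph$dendrite$tau,
                    nm$morph$threshold$v_th, nm$morph$threshold$v_re)),
                  stats_method = st$method)
    if (cfg$engine %in% c("simulation", "both")) {
      sim <- run_simulation(nm$morph, nm$drive,
                            duration = sim_duration_ms(cfg$scale),
                            mode = "reset", seed = cfg$seed + i)
      out$sim_rate_hz <- sim$rate_hz
      out$sim_se_hz <- sim$se_hz
      out$sim_seed <- cfg$seed + i
    }
    out
  }
  res <- purrr::imap(seq_len(nrow(pts)), function(i, ...) {
    r <- purrr::safely(one)(pts[i, ], i)
    if (is.null(r$error)) dplyr::mutate(r$result, error = NA_character_)
    else tibble(error = conditionMessage(r$error))
  })
  dplyr::bind_cols(row = seq_len(nrow(pts)), pts,
                   dplyr::bind_rows(res))
}

write_manifest <- function(dir, name, cfg_like, seed, files) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) return(invisible(NULL))
  manifest <- list(
    experiment = name,
    package_version = as.character(utils::packageVersion("ricecable")),
    seed = seed,
    config = cfg_like,
    files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_panel <- function(tbl, dir, stem) {
  path <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(tbl, path, row.names = FALSE)
  path
}

#' Reproduce the package's canned morphology experiments
#'
#' Each experiment id maps to a standard sweep over one structural feature of
#' the model and writes the per-panel data tables as CSV (plus a JSON
#' manifest echoing the configuration):
#' \describe{
#'   \item{fig2}{sealed-dendrite variance profiles vs `lambda` (a) and,
#'     end-normalized, vs `tau_v` (b).}
#'   \item{fig3}{one- and two-dendrite upcrossing, deterministic and
#'     (optionally) simulated rates vs `mu` for `sigma_s` = 1, 2, 3 mV.}
#'   \item{fig4}{lambda-independence of the one-dendrite rate (a) and
#'     one/two-dendrite equivalence at matched voltage variance (b).}
#'   \item{fig5}{axonal load: relative rate vs radius ratio at the junction
#'     (a) and the non-monotonic rate vs radius ratio at `x_th` = 30 um (b).}
#'   \item{fig6}{dendrite number: rate vs `n` at fixed axon (a, b), the
#'     maximizing count over (`mu`, `a_ratio`) (c), and the
#'     conductance-matched rescaling `lambda_1(n) = lambda_1/n^(1/3)` (d).}
#'   \item{fig7}{lumped soma: rate vs `mu` per `rho_1` (a), axon-load ratio
#'     at 1 Hz-calibrated `sigma_s` (b), rate vs `n` per `rho_1` (c), and the
#'     maximizing count over (`mu`, `rho_1`) (d).}
#' }
#'
#' @param id One of `"fig2"` ... `"fig7"`.
#' @param dir Output directory (created if needed).
#' @param engine `"analytic"` or `"both"` (adds reset simulations where the
#'   experiment defines them).
#' @param seed Base seed for simulation engines.
#' @param scale Simulated-duration scale factor, see [experiment_config()].
#' @return Invisibly, the character vector of files written; the tables are
#'   attached as attribute `"tables"`.
#' @export
reproduce_figure <- function(id, dir = ".", engine = c("analytic", "both"),
                             seed = 1L, scale = 0.1) {
  engine <- match.arg(engine)
  id <- match.arg(id, c("fig2", "fig3", "fig4", "fig5", "fig6", "fig7"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- switch(id,
    fig2 = panels_fig2(), fig3 = panels_fig3(engine, seed, scale),
    fig4 = panels_fig4(), fig5 = panels_fig5(),
    fig6 = panels_fig6(), fig7 = panels_fig7())
  files <- vapply(names(tables), function(nm)
    write_panel(tables[[nm]], dir, paste0(id, nm)), character(1))
  write_manifest(dir, id, list(engine = engine, scale = scale), seed, files)
  invisible(structure(files, tables = tables))
}

panels_fig2 <- function() {
  x <- seq(0, 1000, by = 10)
  a <- dplyr::bind_rows(lapply(c(50, 100, 200, 400), function(l) {
    cd <- closed_dendrite(L = 1000, lambda = l, tau_v = 10, tau_s = 5, sigma_s = 1)
    dplyr::mutate(variance_profile(cd, x), lambda = l)
  }))
  b <- dplyr::bind_rows(lapply(c(2, 10, 50), function(tv) {
    cd <- closed_dendrite(L = 1000, lambda = 200, tau_v = tv, tau_s = 5, sigma_s = 1)
    p <- variance_profile(cd, x)
    dplyr::mutate(p, normalized = .data$variance / .data$variance[1], tau_v = tv)
  }))
  list(a = a, b = b)
}

panels_fig3 <- function(engine, seed, scale) {
  grid <- list(mu = seq(4, 12, by = 0.5), sigma_s = c(1, 2, 3))
  eng <- if (engine == "both") "both" else "analytic"
  one <- run_experiment(experiment_config("fig3_one", grid, engine = eng,
                                          seed = seed, scale = scale,
                                          defaults = list(n = 1)))
  two <- run_experiment(experiment_config("fig3_two", grid, engine = eng,
                                          seed = seed + 1000L, scale = scale,
                                          defaults = list(n = 2)))
  list(a = dplyr::mutate(one, model = "one-dendrite"),
       b = dplyr::mutate(two, model = "two-dendrite"))
}

panels_fig4 <- function() {
  mu <- seq(4, 12, by = 0.5)
  a <- run_experiment(experiment_config(
    "fig4a", list(mu = mu, lambda_1 = c(100, 400)),
    defaults = list(sigma_s = 1)))
  b1 <- run_experiment(experiment_config(
    "fig4b_one", list(mu = mu), defaults = list(sigma_s = 1, n = 1)))
  b2 <- run_experiment(experiment_config(
    "fig4b_two", list(mu = mu), defaults = list(sigma_s = sqrt(2), n = 2)))
  list(a = a,
       b = dplyr::bind_rows(dplyr::mutate(b1, model = "one-dendrite"),
                            dplyr::mutate(b2, model = "two-dendrite, sigma_s*sqrt(2)")))
}

panels_fig5 <- function() {
  ratios <- seq(0.02, 1, by = 0.02)
  sealed <- firing_rate(neuron_model(mu = 5, sigma_s = 3))$rate_hz
  a <- tibble(a_ratio = c(0, ratios),
              rate_hz = c(sealed, vapply(ratios, function(r)
                firing_rate(neuron_model(mu = 5, sigma_s = 3, a_ratio = r,
                                         x_th = 0))$rate_hz, numeric(1))),
              relative_rate = .data$rate_hz / sealed)
  b <- dplyr::bind_rows(lapply(4:8, function(mu)
    dplyr::mutate(peak_radius_ratio(neuron_model(mu = mu, sigma_s = 3,
                                                 a_ratio = 0.25, x_th = 30),
                                    ratios)$table, mu = mu)))
  list(a = a, b = b)
}

panels_fig6 <- function() {
  mus <- 8:11; ns <- 1:8
  rate_n <- function(mu, n, lambda_alpha, lambda_1 = 200) {
    eps <- derive_epsilon(-70, 0, mu)
    a_ratio <- radius_ratio_from_lambda(lambda_alpha, lambda_1, eps)
    firing_rate(neuron_model(mu = mu, sigma_s = 3, n_dendrites = n,
                             a_ratio = a_ratio, lambda_1 = lambda_1,
                             x_th = 30))$rate_hz
  }
  sweep_n <- function(lambda_alpha) {
    tidyr::expand_grid(mu = mus, n = ns) |>
      dplyr::mutate(rate_hz = purrr::map2_dbl(.data$mu, .data$n, rate_n,
                                              lambda_alpha = lambda_alpha),
                    lambda_alpha = lambda_alpha)
  }
  cgrid <- tidyr::expand_grid(mu = mus, a_ratio = seq(0.1, 0.6, by = 0.05))
  c_tbl <- dplyr::mutate(cgrid, n_max = purrr::map2_int(
    .data$mu, .data$a_ratio, function(mu, r) {
      as.integer(n_max(neuron_model(mu = mu, sigma_s = 3, a_ratio = r,
                                    x_th = 30), n_range = 1:12))
    }))
  d_tbl <- tidyr::expand_grid(mu = mus, n = ns) |>
    dplyr::mutate(rate_hz = purrr::map2_dbl(.data$mu, .data$n, function(mu, n)
      rate_n(mu, n, lambda_alpha = 100, lambda_1 = 200 / n^(1 / 3))),
      rescaling = "conductance-matched")
  list(a = sweep_n(100), b = sweep_n(150), c = c_tbl, d = d_tbl)
}

panels_fig7 <- function() {
  rhos <- c(1, 4, 16)
  lam_alpha_ratio <- function(mu) {
    eps <- derive_epsilon(-70, 0, mu)
    radius_ratio_from_lambda(100, 200, eps)
  }
  a <- tidyr::expand_grid(mu = seq(8, 12, by = 0.5), rho_1 = rhos) |>
    dplyr::mutate(rate_hz = purrr::map2_dbl(.data$mu, .data$rho_1, function(mu, rho)
      firing_rate(neuron_model(mu = mu, sigma_s = 3,
                               a_ratio = lam_alpha_ratio(mu), rho_1 = rho,
                               x_th = 30))$rate_hz))
  b <- relative_axon_load_curve(mu = 8, rho_1 = rhos,
                                ratios = seq(0.05, 1, by = 0.05))
  cc <- tidyr::expand_grid(n = 1:8, rho_1 = rhos) |>
    dplyr::mutate(rate_hz = purrr::map2_dbl(.data$n, .data$rho_1, function(n, rho)
      firing_rate(neuron_model(mu = 12, sigma_s = 3, n_dendrites = n,
                               a_ratio = lam_alpha_ratio(12), rho_1 = rho,
                               x_th = 30))$rate_hz))
  d <- tidyr::expand_grid(mu = 8:12, rho_1 = c(1, 2, 4, 8, 16)) |>
    dplyr::mutate(n_max = purrr::map2_int(.data$mu, .data$rho_1, function(mu, rho)
      as.integer(n_max(neuron_model(mu = mu, sigma_s = 3,
                                    a_ratio = lam_alpha_ratio(mu), rho_1 = rho,
                                    x_th = 30), n_range = 1:16))))
  list(a = a, b = b, c = cc, d = d)
}

#' Relative effect of the axonal load in the presence of a soma
#'
#' For each dendritic dominance factor, calibrates `sigma_s` so that the
#' axon-free (dendrite + soma) model fires at `target_hz`, then sweeps the
#' axon-to-dendrite radius ratio with the trigger at the junction and reports
#' the rate relative to the axon-free value. The decline is steeper for
#' larger `rho_1` (smaller soma), because a large somatic admittance masks
#' the added axonal load.
#'
#' @param mu Mean drive (mV); must leave the axon-free model subthreshold at
#'   the junction (`n mu rho_1/(1 + n rho_1) < v_th`), so the default sits at
#'   the lower end of the usual drive range.
#' @param rho_1 Vector of dendritic dominance factors.
#' @param ratios Radius-ratio grid.
#' @param target_hz Calibration target for the axon-free rate.
#' @return A tibble with columns `rho_1`, `a_ratio`, `sigma_s`, `rate_hz`,
#'   `relative_rate`.
#' @export
relative_axon_load_curve <- function(mu = 8, rho_1 = c(1, 4, 16),
                                     ratios = seq(0.05, 1, by = 0.05),
                                     target_hz = 1) {
  dplyr::bind_rows(lapply(rho_1, function(rho) {
    base <- neuron_model(mu = mu, sigma_s = 1, rho_1 = rho, x_th = 0)
    sig <- calibrate_sigma_s(base$morph, base$drive, target_hz)
    r0 <- firing_rate(neuron_model(mu = mu, sigma_s = sig, rho_1 = rho,
                                   x_th = 0))$rate_hz
    tibble(rho_1 = rho, a_ratio = ratios, sigma_s = sig,
           rate_hz = vapply(ratios, function(r)
             firing_rate(neuron_model(mu = mu, sigma_s = sig, a_ratio = r,
                                      rho_1 = rho, x_th = 0))$rate_hz,
             numeric(1)),
           relative_rate = .data$rate_hz / r0)
  }))
}
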