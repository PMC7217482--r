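# broom-style tidiers so results drop straight into dplyr pipelines.

#' Tidy a voltage_stats object
#'
#' @param x A [voltage_stats()].
#' @param ... Unused.
#' @return One-row tibble with `mean`, `sigma_v`, `sigma_vdot`, `method`.
#' @export
tidy.voltage_stats <- function(x, ...) {
  tibble(mean = x$mean, sigma_v = x$sigma_v, sigma_vdot = x$sigma_vdot,
         method = x$method)
}

#' Tidy and summarize rate results
#'
#' `tidy()` returns the rate together with the voltage statistics behind it;
#' `glance()` returns the one-row summary only.
#'
#' @param x A `rate_result` from [model_rate()] or [sim_rate()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.rate_result <- function(x, ...) {
  tibble(rate_hz = x$rate_hz, method = x$method,
         mean = x$stats$mean, sigma_v = x$stats$sigma_v,
         sigma_vdot = x$stats$sigma_vdot,
         uncertainty_hz = x$uncertainty_hz, seed = x$seed)
}

#' @rdname tidy.rate_result
#' @export
glance.rate_result <- function(x, ...) {
  tibble(rate_hz = x$rate_hz, uncertainty_hz = x$uncertainty_hz,
         method = x$method)
}

#' Tidy and summarize simulations
#'
#' `tidy()` returns the spike (or crossing-epoch) times, one row per event;
#' `glance()` the run-level summary.
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cable_sim <- function(x, ...) {
  tibble(time = as.numeric(x$spike_times))
}

#' @rdname tidy.cable_sim
#' @export
glance.cable_sim <- function(x, ...) {
  tibble(mode = x$mode, n_events = as.integer(x$n_events),
         rate_hz = x$rate_hz, se_hz = x$se_hz,
         mean_v = x$mean_v, var_v = x$var_v, var_vdot = x$var_vdot,
         duration = x$duration, transient = x$transient,
         dx = x$dx, dt = x$dt,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Serialize a rate result to a JSON-style record
#'
#' @param x A `rate_result`.
#' @return A nested list (method, rate, stats, provenance) suitable for
#'   `jsonlite::toJSON()`.
#' @export
as_record <- function(x) {
  stopifnot(inherits(x, "rate_result"))
  drv <- x$params$drive
  list(rate_hz = x$rate_hz, method = x$method,
       uncertainty_hz = x$uncertainty_hz,
       stats = list(mean = x$stats$mean, sigma_v = x$stats$sigma_v,
                    sigma_vdot = x$stats$sigma_vdot),
       provenance = list(
         seed = x$seed,
         drive = if (is.null(drv)) NULL else
           drv[c("mu", "sigma_s", "tau_s", "E_L", "E_s")]))
}
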