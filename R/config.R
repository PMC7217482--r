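# Flat key = value configuration documents.
#
# Keys use the standard symbols of the model: E_L, E_s, mu, tau_1, tau_s,
# lambda_1, lambda_alpha, a_ratio, rho_1, sigma_s, v_th, v_re, x_th, n.
# Either a_ratio or lambda_alpha may be given for the axon (they are related
# through epsilon); rho_1 switches on the lumped soma.

config_keys <- c("E_L", "E_s", "mu", "tau_1", "tau_s", "lambda_1",
                 "lambda_alpha", "a_ratio", "rho_1", "sigma_s",
                 "v_th", "v_re", "x_th", "n", "tau_0")

#' Read or write a flat key = value model configuration
#'
#' `read_neuron_config()` parses a plain-text document of `key = value`
#' lines (`#` starts a comment) into a named list; `write_neuron_config()`
#' performs the inverse. `neuron_from_config()` builds a [neuron_model()]
#' from such a document or list.
#'
#' @param path File path.
#' @return `read_neuron_config()`: a named list of numeric values.
#' @export
read_neuron_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop_invalid(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% config_keys)
      stop_invalid(sprintf("unknown configuration key '%s'", key))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop_invalid(sprintf("non-numeric value for '%s'", key))
    out[[key]] <- num
  }
  out
}

#' @rdname read_neuron_config
#' @param config Named list of configuration values.
#' @export
write_neuron_config <- function(config, path) {
  bad <- setdiff(names(config), config_keys)
  if (length(bad))
    stop_invalid(paste("unknown configuration key(s):", paste(bad, collapse = ", ")))
  writeLines(sprintf("%s = %.17g", names(config), as.numeric(config)), path)
  invisible(path)
}

#' @rdname read_neuron_config
#' @export
neuron_from_config <- function(config) {
  if (is.character(config)) config <- read_neuron_config(config)
  get_or <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  E_L <- get_or("E_L", -70); E_s <- get_or("E_s", 0)
  mu <- get_or("mu", 0)
  a_ratio <- config[["a_ratio"]]
  if (is.null(a_ratio) && !is.null(config[["lambda_alpha"]])) {
    eps <- derive_epsilon(E_L, E_s, mu)
    a_ratio <- radius_ratio_from_lambda(config[["lambda_alpha"]],
                                        get_or("lambda_1", 200), eps)
  }
  neuron_model(mu = mu,
               sigma_s = get_or("sigma_s", 1),
               n_dendrites = get_or("n", 1),
               a_ratio = a_ratio,
               rho_1 = config[["rho_1"]],
               lambda_1 = get_or("lambda_1", 200),
               tau_1 = get_or("tau_1", 10),
               tau_s = get_or("tau_s", 5),
               x_th = get_or("x_th", 0),
               v_th = get_or("v_th", 10),
               v_re = get_or("v_re", 0),
               E_L = E_L, E_s = E_s,
               tau_0 = config[["tau_0"]])
}
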