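# Shared fixtures: the standard drive (sigma_s = 1, tau_s = 5, tau_v = 10)
# and closed-form reference values derived independently of the package
# (mode-integral results for the semi-infinite sealed dendrite).

std_drive <- function(mu = 0, sigma_s = 1, tau_s = 5) {
  drive_params(mu = mu, sigma_s = sigma_s, tau_s = tau_s)
}

# kappa = 1 + tau_v/tau_s = 3 for the standard constants; independent
# closed forms: sv2 = 2 sigma_s^2 (tau_s/tau_v)(1 - 1/sqrt(kappa)),
#               svd2 = (2 sigma_s^2/(tau_v tau_s)) / sqrt(kappa)
ref_sv2_one <- function(sigma_s = 1, tau_s = 5, tau_v = 10) {
  k <- 1 + tau_v / tau_s
  2 * sigma_s^2 * (tau_s / tau_v) * (1 - 1 / sqrt(k))
}
ref_svd2_one <- function(sigma_s = 1, tau_s = 5, tau_v = 10) {
  k <- 1 + tau_v / tau_s
  (2 * sigma_s^2 / (tau_v * tau_s)) / sqrt(k)
}

# Rice rate (Hz) from the one-dendrite closed forms, written out directly
ref_rate_one_hz <- function(mu, sigma_s = 3, tau_s = 5, tau_v = 10, v_th = 10) {
  s2 <- ref_sv2_one(sigma_s, tau_s, tau_v)
  sd2 <- ref_svd2_one(sigma_s, tau_s, tau_v)
  1000 * sqrt(sd2 / s2) / (2 * pi) * exp(-(v_th - mu)^2 / (2 * s2))
}

eps_of <- function(mu) (-70 - 0) / (-70 + mu - 0)
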