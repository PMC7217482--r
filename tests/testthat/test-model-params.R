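test_that("epsilon follows the conductance-ratio formula and is monotone in mu", {
  expect_equal(derive_epsilon(-70, 0, 0), 1)
  expect_equal(derive_epsilon(-70, 0, 5), 70 / 65)
  expect_equal(derive_epsilon(-70, 0, 8), 70 / 62)
  mu <- seq(0, 69, length.out = 200)
  expect_true(all(diff(derive_epsilon(-70, 0, mu)) > 0))
  expect_error(derive_epsilon(-70, 0, 70), class = "ricecable_invalid_parameter")
  expect_error(derive_epsilon(-70, 0, 80), class = "ricecable_invalid_parameter")
})

test_that("passive time constant scales the dendritic one by epsilon", {
  expect_equal(axonal_time_constant(1, 10), 10)
  expect_equal(signif(axonal_time_constant(derive_epsilon(-70, 0, 5), 10), 3), 10.8)
  expect_equal(signif(axonal_time_constant(derive_epsilon(-70, 0, 8), 10), 3), 11.3)
  expect_error(axonal_time_constant(0.9, 10), class = "ricecable_invalid_parameter")
})

test_that("radius ratio and axonal length constant round-trip", {
  eps <- derive_epsilon(-70, 0, 5)
  expect_equal(lambda_from_radius_ratio(0, 200, eps), 0)
  expect_equal(lambda_from_radius_ratio(1 / eps, 200, eps), 200)
  expect_equal(lambda_from_radius_ratio(0.25, 200, eps), 200 * sqrt(0.25 * eps))
  for (r in c(1e-3, 0.1, 0.25, 0.7, 1)) {
    la <- lambda_from_radius_ratio(r, 200, eps)
    expect_equal(radius_ratio_from_lambda(la, 200, eps), r, tolerance = 1e-14)
  }
})

test_that("axonal dominance factor is consistent with the admittance ratio", {
  eps5 <- derive_epsilon(-70, 0, 5)
  expect_equal(rho_alpha_from_rho1(3, 150, 150, 1), 3)
  expect_equal(rho_alpha_from_rho1(16, 100, 200, eps5), 16 * 0.125 / eps5^2)
  expect_equal(rho_alpha_from_rho1(0, 100, 200, eps5), 0)
  # degree-1 homogeneity in rho_1
  expect_equal(rho_alpha_from_rho1(8, 120, 200, eps5),
               4 * rho_alpha_from_rho1(2, 120, 200, eps5))
  # cross-check against G_lambda_alpha/G_lambda_1 * rho_1 with
  # G ~ g^2 lambda^3 and g_1/g_alpha = epsilon, over a parameter grid
  for (mu in c(0, 4, 8, 12)) {
    eps <- derive_epsilon(-70, 0, mu)
    for (la in c(50, 100, 250)) for (rho in c(0.5, 4, 16)) {
      direct <- rho * (1 * la^3) / (eps^2 * 200^3)
      expect_equal(rho_alpha_from_rho1(rho, la, 200, eps), direct,
                   tolerance = 1e-12)
    }
  }
})

test_that("relative input conductance counts dendrites and supports the n^(1/3) rescaling", {
  m1 <- neuron_model(mu = 5, sigma_s = 1)$morph
  expect_equal(relative_input_conductance(m1), 1)
  m2 <- neuron_model(mu = 5, sigma_s = 1, n_dendrites = 2)$morph
  expect_equal(relative_input_conductance(m2), 2)
  # 4 dendrites thinned so lambda_1 -> lambda_1/4^(1/3), same fixed axon:
  # total equals the single-dendrite morphology's value
  a_ratio <- 0.25
  ref <- neuron_model(mu = 5, sigma_s = 1, a_ratio = a_ratio, x_th = 30)
  eps <- ref$epsilon
  resc <- neuron_model(mu = 5, sigma_s = 1, n_dendrites = 4,
                       lambda_1 = 200 / 4^(1 / 3),
                       a_ratio = radius_ratio_from_lambda(ref$lambda_alpha,
                                                          200 / 4^(1 / 3), eps),
                       x_th = 30)
  expect_equal(relative_input_conductance(resc$morph, lambda_ref = 200),
               relative_input_conductance(ref$morph, lambda_ref = 200),
               tolerance = 1e-12)
})

test_that("microscopic-parameter helper reproduces the effective drive scalings", {
  p0 <- microscopic_synapse_params(c_m = 1, g_L = 0.05, gamma_s = 0.01,
                                   rho_dens = 0.1, r_s = 0, r_a = 150e-6, a = 1)
  z <- effective_from_microscopic(p0, tau_s = 5)
  expect_equal(z$g_s_mean, 0)
  expect_equal(z$drive$mu, 0)
  expect_equal(z$drive$sigma_s, 0)
  p1 <- microscopic_synapse_params(c_m = 1, g_L = 0.05, gamma_s = 0.01,
                                   rho_dens = 0.1, r_s = 0.002, r_a = 150e-6, a = 1)
  p2 <- microscopic_synapse_params(c_m = 1, g_L = 0.05, gamma_s = 0.01,
                                   rho_dens = 0.1, r_s = 0.004, r_a = 150e-6, a = 1)
  expect_equal(effective_from_microscopic(p2, 5)$g_s_mean,
               2 * effective_from_microscopic(p1, 5)$g_s_mean)
  # sigma_s ~ sqrt(rho_dens r_s) at fixed total conductance g (g_L adjusted)
  z1 <- effective_from_microscopic(p1, 5)
  gs1 <- z1$g_s_mean
  p4 <- microscopic_synapse_params(c_m = 1, g_L = 0.05 + gs1 - 4 * gs1,
                                   gamma_s = 0.01, rho_dens = 0.4,
                                   r_s = 0.002, r_a = 150e-6, a = 1)
  z4 <- effective_from_microscopic(p4, 5, mean_V = -60)
  z1b <- effective_from_microscopic(p1, 5, mean_V = -60)
  expect_equal(z4$drive$sigma_s / z1b$drive$sigma_s, 2, tolerance = 1e-12)
})

test_that("constructors validate strictly instead of clamping", {
  expect_error(drive_params(mu = -1, sigma_s = 1, tau_s = 5),
               class = "ricecable_invalid_parameter")
  expect_error(drive_params(mu = 75, sigma_s = 1, tau_s = 5),
               class = "ricecable_invalid_parameter")
  expect_error(neurite_spec("passive-axon", lambda = 100, tau = 10, g_rel = 1.2),
               class = "ricecable_invalid_parameter")
  expect_error(threshold_spec(v_th = 0, v_re = 0),
               class = "ricecable_invalid_parameter")
  d <- neurite_spec("driven-dendrite", lambda = 200, tau = 10, g_rel = 1.1)
  expect_error(
    morphology(dendrite = d,
               threshold = threshold_spec(x_th = 30, trigger = "axon")),
    class = "ricecable_invalid_parameter")
  expect_error(
    morphology(dendrite = d,
               threshold = threshold_spec(x_th = 30, trigger = "dendrite")),
    class = "ricecable_unsupported_morphology")
})

test_that("flat key=value configs round-trip and build models", {
  cfg <- list(mu = 5, sigma_s = 3, tau_s = 5, lambda_1 = 200, tau_1 = 10,
              a_ratio = 0.25, x_th = 30, v_th = 10, v_re = 0, n = 1)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_neuron_config(cfg, path)
  back <- read_neuron_config(path)
  expect_equal(back[order(names(back))], cfg[order(names(cfg))])
  nm <- neuron_from_config(path)
  expect_s3_class(nm, "neuron_model")
  expect_equal(nm$morph$axon$lambda, 200 * sqrt(nm$epsilon * 0.25))
  # lambda_alpha may be given instead of a_ratio
  nm2 <- neuron_from_config(list(mu = 5, sigma_s = 3, lambda_alpha = nm$morph$axon$lambda,
                                 x_th = 30))
  expect_equal(nm2$morph$axon$lambda, nm$morph$axon$lambda, tolerance = 1e-12)
  expect_error(read_neuron_config(withr::local_tempfile(lines = "bogus = 1")),
               class = "ricecable_invalid_parameter")
})
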