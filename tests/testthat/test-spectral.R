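test_that("gamma factor: principal branch identities", {
  w <- c(0, 0.1, 1, 10, 250)
  g <- gamma_factor(w, 10)
  expect_equal(g[1], 1 + 0i)
  expect_equal(Mod(g)^2, sqrt(1 + w^2 * 100), tolerance = 1e-14)
  expect_equal(Re(g), sqrt((sqrt(1 + w^2 * 100) + 1) / 2), tolerance = 1e-14)
  expect_true(all(Re(g) >= 1))
})

test_that("relative admittance: symmetry, bounds and completeness", {
  w <- seq(-40, 40, length.out = 81)
  nm <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, x_th = 30)
  f <- rel_admittance(nm$morph, w)
  expect_lt(max(Mod(rel_admittance(nm$morph, -w) - Conj(f))), 1e-13)
  expect_true(all(Mod(f) <= 1 + 1e-12))
  # one neurite, no load: unity at all frequencies
  plain <- neuron_model(mu = 5, sigma_s = 1)$morph
  expect_equal(rel_admittance(plain, w), rep(1 + 0i, length(w)))
  # passive axon identical to the (undriven) dendrite: exactly 1/2
  d <- neurite_spec("driven-dendrite", lambda = 200, tau = 10, g_rel = 1)
  a <- neurite_spec("passive-axon", lambda = 200, tau = 10, g_rel = 1)
  twin <- morphology(dendrite = d, axon = a,
                     threshold = threshold_spec(trigger = "axon"))
  expect_lt(max(Mod(rel_admittance(twin, w) - 0.5)), 1e-13)
  # admittance-fraction completeness at every frequency (no soma):
  # n * f + axon share = 1 with the same denominator
  m <- neuron_model(mu = 7, sigma_s = 1, n_dendrites = 3, a_ratio = 0.4, x_th = 30)$morph
  g1 <- gamma_factor(w, m$dendrite$tau)
  ga <- gamma_factor(w, m$axon$tau)
  w1 <- m$dendrite$g_rel^2 * m$dendrite$lambda^3
  wa <- m$axon$lambda^3
  axon_share <- wa * ga / (3 * w1 * g1 + wa * ga)
  expect_lt(max(Mod(3 * rel_admittance(m, w) + axon_share - 1)), 1e-12)
  # randomized parameter draws keep |f| <= 1 and f(0) in (0, 1]
  set.seed(42)
  for (i in 1:20) {
    mm <- neuron_model(mu = runif(1, 0, 12), sigma_s = 1,
                       n_dendrites = sample(1:6, 1),
                       a_ratio = runif(1, 0.05, 1),
                       rho_1 = if (runif(1) < 0.5) NULL else 2^runif(1, 0, 4),
                       x_th = 30)
    ww <- 10^runif(15, -2, 2.5)
    ff <- rel_admittance(mm$morph, ww)
    expect_true(all(Mod(ff) <= 1 + 1e-12))
    f0 <- rel_admittance(mm$morph, 0)
    expect_equal(Im(f0), 0)
    expect_true(Re(f0) > 0 && Re(f0) <= 1)
  }
})

test_that("soma model collapses to the nominal-soma model as rho_1 grows", {
  w <- c(0, 0.3, 3)
  withsoma <- function(rho) neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25,
                                         rho_1 = rho, x_th = 30)$morph
  nosoma <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, x_th = 30)$morph
  expect_lt(max(Mod(rel_admittance(withsoma(1e8), w) -
                      rel_admittance(nosoma, w))), 1e-6)
  # DC value of the soma model
  m <- withsoma(4)
  s <- m$soma
  expect_equal(Re(rel_admittance(m, 0)), s$rho_1 / (1 + s$rho_1 + s$rho_alpha),
               tolerance = 1e-14)
})

test_that("sealed-end spectrum has the right DC value, tail and moments", {
  d <- std_drive(sigma_s = 1.5)
  expect_equal(sealed_end_psd(0, d, 10), 2 * 1.5^2 * 5)
  # tail ~ omega^(-7/2)
  expect_equal(sealed_end_psd(4e3, d, 10) / sealed_end_psd(2e3, d, 10),
               2^-3.5, tolerance = 1e-3)
  # moments against the closed forms (independent quadrature)
  m0 <- integrate(function(w) sealed_end_psd(w, d, 10) / pi, 0, Inf,
                  rel.tol = 1e-12)$value
  m2 <- integrate(function(w) w^2 * sealed_end_psd(w, d, 10) / pi, 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(m0, ref_sv2_one(sigma_s = 1.5), tolerance = 1e-8)
  expect_equal(m2, ref_svd2_one(sigma_s = 1.5), tolerance = 1e-6)
})

test_that("trigger spectrum composes admittance, attenuation and dendrite count", {
  w <- c(0, 0.05, 0.5, 5)
  d <- std_drive(mu = 0)
  plain <- neuron_model(mu = 0, sigma_s = 1)$morph
  expect_equal(trigger_psd(plain, d, w), sealed_end_psd(w, d, 10))
  # two identical driven dendrites: half the sealed-end spectrum
  m2 <- neuron_model(mu = 0, sigma_s = 1, n_dendrites = 2)$morph
  expect_equal(trigger_psd(m2, d, w), sealed_end_psd(w, d, 10) / 2,
               tolerance = 1e-14)
  # passive twin axon at the junction: a quarter
  dd <- neurite_spec("driven-dendrite", lambda = 200, tau = 10, g_rel = 1)
  aa <- neurite_spec("passive-axon", lambda = 200, tau = 10, g_rel = 1)
  twin <- morphology(dendrite = dd, axon = aa,
                     threshold = threshold_spec(trigger = "axon"))
  expect_equal(trigger_psd(twin, d, w), sealed_end_psd(w, d, 10) / 4,
               tolerance = 1e-14)
})

test_that("spectral quadrature reproduces the closed forms to 1e-8", {
  d <- std_drive(mu = 1)
  s1 <- stats_from_psd(neuron_model(mu = 1, sigma_s = 1)$morph, d)
  c1 <- one_dendrite_stats(d, 10)
  expect_equal(s1$sigma_v^2, c1$sigma_v^2, tolerance = 1e-8)
  expect_equal(s1$sigma_vdot^2, c1$sigma_vdot^2, tolerance = 1e-8)
  s2 <- stats_from_psd(neuron_model(mu = 1, sigma_s = 1, n_dendrites = 2)$morph, d)
  c2 <- two_dendrite_stats(d, 10)
  expect_equal(s2$sigma_v^2, c2$sigma_v^2, tolerance = 1e-8)
  expect_equal(s2$sigma_vdot^2, c2$sigma_vdot^2, tolerance = 1e-8)
  expect_lt(max(attr(s1, "quad_error") /
                  c(s1$sigma_v^2, s1$sigma_vdot^2)), 1e-8)
})

test_that("trigger statistics obey the structural limit chain", {
  d5 <- drive_params(5, 1, 5)
  # vanishing axon -> one-dendrite statistics
  tiny <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 1e-10, x_th = 0)
  st <- stats_from_psd(tiny$morph, tiny$drive)
  c1 <- one_dendrite_stats(d5, 10)
  expect_equal(st$sigma_v, c1$sigma_v, tolerance = 1e-6)
  expect_equal(st$sigma_vdot, c1$sigma_vdot, tolerance = 1e-6)
  expect_equal(st$mean, c1$mean, tolerance = 1e-6)
  # enormous soma dominance -> nominal-soma model
  big <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, rho_1 = 1e8, x_th = 30)
  ref <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, x_th = 30)
  sb <- stats_from_psd(big$morph, big$drive)
  sr <- stats_from_psd(ref$morph, ref$drive)
  expect_equal(sb$sigma_v, sr$sigma_v, tolerance = 1e-6)
  expect_equal(sb$mean, sr$mean, tolerance = 1e-6)
})

test_that("variance attenuates monotonically along the axon and scales as 1/n", {
  vars <- vapply(c(10, 30, 50, 90, 150), function(x) {
    nm <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, x_th = x)
    stats_from_psd(nm$morph, nm$drive)$sigma_v^2
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
  v_n <- function(n) stats_from_psd(
    neuron_model(mu = 5, sigma_s = 1, n_dendrites = n, a_ratio = 0.25,
                 x_th = 30)$morph, drive_params(5, 1, 5))$sigma_v^2
  expect_equal(32 * v_n(32), 64 * v_n(64), tolerance = 0.05)
})

test_that("mean at the trigger follows DC admittance and axonal decay", {
  expect_equal(mean_at_trigger(neuron_model(mu = 5, sigma_s = 1)$morph,
                               drive_params(5, 1, 5)), 5)
  eps <- eps_of(5)
  nm <- neuron_model(mu = 5, sigma_s = 1,
                     a_ratio = radius_ratio_from_lambda(100, 200, eps),
                     x_th = 30)
  f0 <- 1 / (1 + 100^3 / (eps^2 * 200^3))
  expect_equal(mean_at_trigger(nm$morph, nm$drive), 5 * f0 * exp(-0.3),
               tolerance = 1e-12)
  # n -> large: mean approaches mu * exp(-x_th/lambda_alpha) from below
  m_n <- function(n) mean_at_trigger(
    neuron_model(mu = 5, sigma_s = 1, n_dendrites = n,
                 a_ratio = radius_ratio_from_lambda(100, 200, eps),
                 x_th = 30)$morph, drive_params(5, 1, 5))
  expect_true(m_n(4) < m_n(64))
  expect_equal(m_n(512), 5 * exp(-0.3), tolerance = 1e-2)
  expect_lt(m_n(512), 5 * exp(-0.3))
})

test_that("spectrum table export is columnar and consistent", {
  nm <- neuron_model(mu = 5, sigma_s = 2, a_ratio = 0.25, x_th = 30)
  tb <- spectrum_table(nm$morph, nm$drive, omega = c(0, 0.5, 2))
  expect_named(tb, c("omega", "S", "omega2S"))
  expect_equal(tb$omega2S, tb$omega^2 * tb$S)
  expect_equal(tb$S, trigger_psd(nm$morph, nm$drive, tb$omega))
})
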