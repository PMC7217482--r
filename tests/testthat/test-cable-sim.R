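# Unit-level checks of the lattice, the stepping kernel and the
# integrate-and-fire bookkeeping. Statistical checks use short runs with
# generous (>= 3 sigma) bands; the long-run convergence checks live in the
# acceptance suite.

test_that("lattice construction: sizes, trigger mapping and guard rails", {
  nm <- neuron_model(mu = 0, sigma_s = 1, lambda_1 = 100)
  lat <- build_lattice(nm$morph, dx = 20, dt = 0.02)
  expect_equal(lat$ncomp, 50L)          # L = 1000 um at lambda = 100 um
  expect_equal(lat$lengths, 1000)
  lat2 <- build_lattice(neuron_model(mu = 0, sigma_s = 1)$morph)
  expect_equal(lat2$lengths, 2000)      # 10 lambda at lambda = 200 um
  ax <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, x_th = 30)
  lax <- build_lattice(ax$morph)
  expect_equal(lax$trig_neurite, 1L)    # axon is the last neurite (0-based)
  expect_equal(lax$trig_node, 1L)       # node centred at 30 um
  expect_equal(lat$trig_neurite, -1L)   # x_th = 0 is the junction/end node
  expect_error(build_lattice(ax$morph, dt = 0.2),
               class = "ricecable_stability_violation")
  bad <- neuron_model(mu = 5, sigma_s = 1, a_ratio = 0.25, x_th = 20)
  expect_error(build_lattice(bad$morph),
               class = "ricecable_misaligned_trigger")
  # accepted reference configuration
  expect_s3_class(build_lattice(nm$morph, dx = 20, dt = 0.02), "lattice_spec")
})

test_that("a uniform voltage with no drive decays by (1 - dt/tau) per step", {
  nm <- neuron_model(mu = 0, sigma_s = 0, lambda_1 = 100)
  lat <- build_lattice(nm$morph)
  st <- lattice_state(lat)
  st$v[[1]][] <- 2
  st$v_junction <- 2
  st <- apply_boundaries(st, lat)
  expect_equal(max(abs(st$dv[[1]])), 0)
  st1 <- em_step(st, lat, nm$drive)
  expect_equal(st1$v[[1]], rep(2 * (1 - 0.02 / 10), 50), tolerance = 1e-14)
  expect_equal(st1$time_index, 1L)
})

test_that("mirror-symmetric dendrites at a nominal soma carry zero junction flux", {
  nm <- neuron_model(mu = 0, sigma_s = 1, n_dendrites = 2, lambda_1 = 100)
  lat <- build_lattice(nm$morph)
  st <- lattice_state(lat)
  set.seed(1)
  prof <- cumsum(rnorm(50, sd = 0.1))
  st$v[[1]] <- prof; st$v[[2]] <- prof
  st <- apply_boundaries(st, lat)
  expect_equal(st$v_junction, prof[1])
  flux <- sum(lat$jweights * c(st$dv[[1]][1], st$dv[[2]][1]))
  expect_equal(flux, 0)
  # asymmetric states put the junction at the weighted balance point
  st$v[[2]] <- prof + 1
  st <- apply_boundaries(st, lat)
  expect_equal(st$v_junction, prof[1] + 0.5)
})

test_that("the synaptic field relaxes to its discrete stationary variance", {
  nm <- neuron_model(mu = 0, sigma_s = 1, lambda_1 = 100)
  lat <- build_lattice(nm$morph, dx = 20, dt = 0.05)
  st <- lattice_state(lat)
  set.seed(99)
  burn <- 1000L; keep <- 3000L
  samples <- numeric(0)
  for (i in seq_len(burn + keep)) {
    st <- em_step(st, lat, nm$drive)
    if (i > burn && i %% 10 == 0) samples <- c(samples, st$s[[1]])
  }
  # exact stationary variance of the discrete Ornstein-Uhlenbeck update:
  # (2 sigma_s^2 lambda / dx) / (1 - dt/(2 tau_s)); continuum value 10 mV^2
  expected <- (2 * 100 / 20) / (1 - 0.05 / 10)
  expect_equal(var(samples), expected, tolerance = 0.15)
})

test_that("threshold reset clears every voltage node but leaves the synaptic field", {
  nm <- neuron_model(mu = 8, sigma_s = 3, n_dendrites = 2, lambda_1 = 100)
  lat <- build_lattice(nm$morph)
  st <- lattice_state(lat)
  st$s[[1]][] <- 1.5
  st$v[[1]][] <- 5; st$v[[2]][] <- 5
  st <- apply_boundaries(st, lat)
  below <- detect_and_reset(st, lat)
  expect_false(below$spike)
  expect_equal(below$state$v[[1]], st$v[[1]])
  st$v[[1]][1] <- 11  # drives the junction voltage over threshold? no:
  st <- apply_boundaries(st, lat)  # junction = mean(11, 5) = 8 < 10
  expect_false(detect_and_reset(st, lat)$spike)
  st$v[[2]][1] <- 11
  st <- apply_boundaries(st, lat)  # junction = 11 >= 10
  fired <- detect_and_reset(st, lat)
  expect_true(fired$spike)
  expect_equal(unique(unlist(fired$state$v)), 0)
  expect_equal(fired$state$v_junction, 0)
  expect_equal(fired$state$s[[1]], st$s[[1]])
})

test_that("reset and no-reset trajectories share the noise stream and split at the first spike", {
  nm <- neuron_model(mu = 8, sigma_s = 3, lambda_1 = 100)
  no <- run_simulation(nm$morph, nm$drive, duration = 1500, mode = "no-reset",
                       seed = 5, transient = 100, record_trace = TRUE)
  re <- run_simulation(nm$morph, nm$drive, duration = 1500, mode = "reset",
                       seed = 5, transient = 100, record_trace = TRUE)
  first <- which(no$trace >= 10)[1]
  expect_false(is.na(first))
  expect_equal(re$trace[seq_len(first)], no$trace[seq_len(first)])
  expect_lt(re$trace[first + 1], no$trace[first + 1])  # reset bites
  # and identical seeds reproduce runs exactly
  re2 <- run_simulation(nm$morph, nm$drive, duration = 1500, mode = "reset",
                        seed = 5, transient = 100, record_trace = TRUE)
  expect_identical(re$trace, re2$trace)
  expect_identical(re$spike_times, re2$spike_times)
})

test_that("no noise and subthreshold drive produce no spikes", {
  nm <- neuron_model(mu = 8, sigma_s = 0, lambda_1 = 100)
  sim <- run_simulation(nm$morph, nm$drive, duration = 500, mode = "reset",
                        seed = 1, transient = 200)
  expect_equal(length(sim$spike_times), 0L)
  expect_equal(sim$rate_hz, 0)
  # the mean settles at mu
  expect_equal(sim$mean_v, 8, tolerance = 1e-3)
})

test_that("the simulated mean decays along the axon as exp(-x/lambda_alpha)", {
  eps <- eps_of(8)
  nm <- neuron_model(mu = 8, sigma_s = 1, lambda_1 = 100,
                     a_ratio = radius_ratio_from_lambda(100, 100, eps), x_th = 30)
  sim <- run_simulation(nm$morph, nm$drive, duration = 12000, mode = "free",
                        seed = 3)
  ax <- dplyr::filter(sim$node_stats, .data$role == "axon", .data$x <= 300)
  fit <- stats::lm(log(mean) ~ x, data = ax)
  expect_equal(unname(stats::coef(fit)[2]), -1 / 100, tolerance = 0.05)
  # and the trigger-node mean agrees with the analytic DC transfer
  expect_equal(sim$mean_v, mean_at_trigger(nm$morph, nm$drive), tolerance = 0.05)
})

test_that("halving the grid steps leaves the sealed-end variance unchanged within error", {
  nm <- neuron_model(mu = 0, sigma_s = 1, lambda_1 = 100)
  coarse <- run_simulation(nm$morph, nm$drive, duration = 40000, mode = "free",
                           seed = 11, dx = 20, dt = 0.02)
  fine <- run_simulation(nm$morph, nm$drive, duration = 20000, mode = "free",
                         seed = 12, dx = 10, dt = 0.005)
  # ~3 sigma for the combined Monte-Carlo error of the two estimates
  expect_equal(fine$var_v / coarse$var_v, 1, tolerance = 0.15)
})
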