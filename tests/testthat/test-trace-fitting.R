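test_that("exact-model single-exponential data are recovered to six
           significant digits", {
  tr <- make_single_exp_trace(k = 12.4)
  f <- fit_single_exponential(tr, "decay")
  expect_true(f$converged)
  expect_equal(f$estimates[["k"]], 12.4, tolerance = 1e-7)
  expect_equal(f$estimates[["A"]], 0.05, tolerance = 1e-7)
  expect_equal(f$estimates[["y_inf"]], 0.10, tolerance = 1e-7)
})

test_that("a constant trace yields no detected transition", {
  flat <- new_trace(seq(0, 5, by = 0.01), rep(0.1, 501), "mant",
                    noise_sd = 0.003)
  f <- fit_single_exponential(flat, "decay")
  expect_false(f$converged)
  expect_match(f$message, "no transition")
})

test_that("double-exponential fit recovers both wild-type rise phases
           from exact-model data", {
  tr <- make_double_exp_trace(3528, 717)
  f <- fit_double_exponential(tr)
  expect_equal(f$estimates[["k_fast"]], 3528, tolerance = 1e-5)
  expect_equal(f$estimates[["k_slow"]], 717, tolerance = 1e-5)
  expect_gte(f$estimates[["k_fast"]], f$estimates[["k_slow"]])
})

test_that("sodium-buffer simulations (no dimerization) lose the slow
           rise phase", {
  p_na <- cycle_parameters(3896, 0.6, k_dim = 0, k_hyd = 0, k_diss = 0,
                           label = "wt-NaCl")
  # enzyme in excess so that the binding phase is cleanly first-order
  g_na <- generate_traces(p_na, "mant", e0 = 10, t0 = 0.5,
                          duration = 0.5, dt = 0.002, noise_sd = 0,
                          n_replicates = 1, seed = 1)
  f_na <- fit_single_exponential(g_na$noiseless, "rise")
  # a single exponential fully describes the NaCl trace ...
  expect_lt(f_na$residual_sd / abs(f_na$estimates[["A"]]), 0.01)
  # ... and no residual slow component: either the biphasic fit
  # degenerates (near-equal rates) or its slow-phase amplitude vanishes
  fd <- suppressWarnings(fit_double_exponential(g_na$noiseless))
  if (fd$model == "double_exponential") {
    slow_ok <- fd$estimates[["k_fast"]] / fd$estimates[["k_slow"]] < 3 ||
      abs(fd$estimates[["A_slow"]] / fd$estimates[["A_fast"]]) < 0.02
    expect_true(slow_ok)
  }
  # the potassium-buffer counterpart is genuinely biphasic: a single
  # exponential leaves structured misfit
  p_k <- cycle_parameters(3896, 0.6, k_dim = 717, k_hyd = 0, k_diss = 0)
  g_k <- generate_traces(p_k, "mant", e0 = 10, t0 = 0.5, duration = 0.5,
                         dt = 0.002, noise_sd = 0, n_replicates = 1,
                         seed = 1)
  f_k <- fit_single_exponential(g_k$noiseless, "rise")
  expect_gt(f_k$residual_sd / abs(f_k$estimates[["A"]]),
            10 * f_na$residual_sd / abs(f_na$estimates[["A"]]))
})

test_that("equal generating rates trigger the degeneracy warning path", {
  tr <- make_double_exp_trace(300, 300, A1 = 0.05, A2 = 0.05)
  expect_warning(fit_double_exponential(tr), "poorly separable")
})

test_that("double exponential with one zero amplitude agrees with the
           single-exponential fit", {
  tr <- make_double_exp_trace(717, 5, A1 = 0.15, A2 = 0, duration = 0.5)
  fd <- suppressWarnings(fit_double_exponential(tr))
  fs <- fit_single_exponential(tr, "rise")
  k_d <- if (fd$model == "double_exponential")
    fd$estimates[["k_fast"]] else fd$estimates[["k"]]
  expect_equal(k_d, fs$estimates[["k"]], tolerance = 1e-6)
  expect_equal(k_d, 717, tolerance = 1e-4)
})

test_that("one-phase decay fit recovers exact-model quench data and
           flags pathological inputs", {
  q <- make_quench_points(k = 201)
  f <- fit_one_phase_decay(q)
  expect_true(f$converged)
  expect_equal(f$estimates[["k"]], 201, tolerance = 1e-5)
  # increasing data
  up <- new_trace(c(0, 1, 2, 4, 8, 12), c(10, 20, 40, 60, 80, 90),
                  "quench")
  fu <- fit_one_phase_decay(up)
  expect_false(fu$converged)
  expect_match(fu$message, "increasing")
  # no hydrolysis: flat at 100 percent
  p0 <- cycle_parameters(3896, 0.6, 717, 0, 12.4)
  q0 <- generate_quench_flow(p0, noise_frac = 0, seed = 1)
  f0 <- fit_one_phase_decay(q0)
  expect_false(f0$converged)
  expect_match(f0$message, "no transition")
  expect_error(fit_one_phase_decay(q[1:3, ]), ">= 5")
})

test_that("noisy quench recovery stays within the generating rate's
           experimental uncertainty", {
  ks <- vapply(1:10, function(s) {
    q <- generate_quench_flow(wt, seed = 1000 + s)
    fit_one_phase_decay(q)$estimates[["k"]]
  }, 0)
  expect_lt(abs(stats::median(ks) - 201) / 201, 0.05)
})

test_that("hyperbolic titration fit recovers exact parameters and
           validates the design", {
  ti <- generate_kobs_titration(wt, "binding", noise_frac = 0, seed = 1)
  f <- fit_hyperbolic(ti)
  expect_equal(f$estimates[["k_max"]], 3896, tolerance = 1e-8)
  expect_equal(f$estimates[["K_D"]], 0.60, tolerance = 1e-8)
  # prediction at [E] = K_D is half-maximal by construction
  kd <- f$estimates[["K_D"]]
  expect_equal(f$estimates[["k_max"]] * kd / (kd + kd),
               f$estimates[["k_max"]] / 2)
  expect_error(fit_hyperbolic(data.frame(conc = c(1, 2, 5),
                                         k_obs = c(10, 20, 30))),
               ">= 4")
  expect_warning(
    fit_hyperbolic(data.frame(conc = c(20, 30, 40, 50),
                              k_obs = 3896 * c(20, 30, 40, 50) /
                                (0.6 + c(20, 30, 40, 50)))),
    "poorly constrained")
})

test_that("wild-type lag phase is about 0.6 s and shortens with faster
           hydrolysis", {
  pp <- cycle_parameters_from_profile("wt")
  g <- generate_traces(pp, "mant", 2.5, 2.5, duration = 17,
                       noise_sd = 0.003, n_replicates = 6, seed = 5)
  lag <- detect_lag(g$average)
  expect_gt(lag, 0.4)
  expect_lt(lag, 0.8)
  # 10x vs 100x hydrolysis-to-dissociation separation: lag decreases
  lag10 <- detect_lag(generate_traces(
    cycle_parameters(3896, 0.6, 717, 124, 12.4), "mant", 2.5, 2.5,
    duration = 17, noise_sd = 0, n_replicates = 1,
    seed = 1)$noiseless, noise_sd = 0.003 / sqrt(6))
  lag100 <- detect_lag(generate_traces(
    cycle_parameters(3896, 0.6, 717, 1240, 12.4), "mant", 2.5, 2.5,
    duration = 17, noise_sd = 0, n_replicates = 1,
    seed = 1)$noiseless, noise_sd = 0.003 / sqrt(6))
  expect_lt(lag100, lag10)
  # no hydrolysis: the signal never decays
  p0 <- cycle_parameters(3896, 0.6, 717, 0, 12.4)
  g0 <- generate_traces(p0, "mant", 2.5, 2.5, duration = 17,
                        noise_sd = 0, n_replicates = 1, seed = 1)
  expect_error(detect_lag(g0$noiseless, noise_sd = 0.003), "no decay")
})

test_that("amplitude retention reproduces the printed Pi-retention
           percentages", {
  expect_equal(amplitude_retention(7.7, 10), 23)
  expect_equal(amplitude_retention(2.12, 10), 78.8)
  expect_equal(amplitude_retention(5, 5), 0)
  expect_error(amplitude_retention(-1, 10), "non-negative")
})

test_that("median fitted rate is within 2 percent of the generating rate
           for every wild-type step at default noise", {
  n_seeds <- 100
  # binding and dimerization from exact biphasic traces
  k_fast <- k_slow <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    tr <- make_double_exp_trace(3528, 717, noise_sd = 0.003,
                                seed = 5000 + s)
    f <- suppressWarnings(fit_double_exponential(tr))
    k_fast[s] <- f$estimates[["k_fast"]]
    k_slow[s] <- f$estimates[["k_slow"]]
  }
  expect_lt(abs(stats::median(k_fast) - 3528) / 3528, 0.02)
  expect_lt(abs(stats::median(k_slow) - 717) / 717, 0.02)
  # hydrolysis from exact one-phase quench points with 2 percent noise
  k3 <- vapply(seq_len(n_seeds), function(s) {
    q <- make_quench_points(201)
    y <- q$signal * (1 + withr::with_seed(6000 + s,
      stats::rnorm(nrow(q), sd = 0.02)))
    fit_one_phase_decay(new_trace(q$time, y, "quench",
                                  noise_sd = 2))$estimates[["k"]]
  }, 0)
  expect_lt(abs(stats::median(k3) - 201) / 201, 0.02)
  # dissociation from exact single-exponential traces
  k4 <- vapply(seq_len(n_seeds), function(s) {
    tr <- make_single_exp_trace(12.4, noise_sd = 0.003, seed = 7000 + s)
    fit_single_exponential(tr, "decay")$estimates[["k"]]
  }, 0)
  expect_lt(abs(stats::median(k4) - 12.4) / 12.4, 0.02)
})
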