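test_that("bateman chain matches closed-form landmarks", {
  # two-step chain (2, 1) min^-1: intermediate peaks at t* = ln 2 min
  tt <- seq(0, 4, by = 1e-4) * 60
  occ <- bateman_chain(c(2, 1), tt)
  expect_equal(tt[which.max(occ[, "S1"])] / 60, log(2), tolerance = 1e-3)
  # t = 0 is all mass in the first state
  expect_equal(unname(bateman_chain(c(2, 1), 0)[1, ]), c(1, 0, 0))
  # occupancies sum to 1 at every time
  expect_equal(rowSums(occ), rep(1, length(tt)), tolerance = 1e-12)
  # single step is a plain exponential
  expect_equal(bateman_chain(60, 60)[1, "S0"], exp(-60), ignore_attr = TRUE)
})

test_that("degenerate bateman rates error or perturb", {
  expect_error(bateman_chain(c(5, 5), 1), "degenerate")
  expect_warning(occ <- bateman_chain(c(5, 5), 30, degenerate = "perturb"),
                 "perturbed")
  # perturbed solution approximates the k^2 t e^{-kt} limit
  expect_equal(occ[1, "S1"], (5 * 0.5) * exp(-5 * 0.5),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(bateman_chain(c(1, -2), 1), "positive")
})

test_that("numeric integration equals the Bateman solution under
           pseudo-first-order conditions", {
  tg <- seq(0, 17, by = 0.01)
  st <- simulate_cycle(wt, e0 = 50, t0 = 0.01, t_grid = tg)
  keff <- effective_binding_rate(wt, 50)
  occ <- bateman_chain(c(keff, wt$k_dim, wt$k_hyd, wt$k_diss), tg)
  num <- cbind(st$T_free, st$E_T, st$D_T, st$D_P, st$E_D) / 0.01
  expect_lt(max(abs(num - occ)), 1e-6)
  # at 0.1 uM substrate the second-order depletion of free enzyme leaves
  # a slightly larger (still tiny) residual
  st2 <- simulate_cycle(wt, e0 = 50, t0 = 0.1, t_grid = tg)
  num2 <- cbind(st2$T_free, st2$E_T, st2$D_T, st2$D_P, st2$E_D) / 0.1
  expect_lt(max(abs(num2 - occ)), 1e-5)
  # spot rates (201, 12.4) at t = 0.6 s against a plain two-step chain
  st3 <- simulate_cycle(cycle_parameters(1e7, 1e-4, 1e7, 201, 12.4),
                        e0 = 50, t0 = 0.01,
                        t_grid = seq(0, 0.6, by = 0.01))
  occ3 <- bateman_chain(c(201, 12.4), 0.6)
  expect_equal(st3$D_P[nrow(st3)] / 0.01, occ3[1, "S1"],
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("enzyme and phosphate mass are conserved", {
  for (inh in list(inhibitor_context(),
                   inhibitor_context(gdp_conc = 50),
                   inhibitor_context(pi_conc = 5000))) {
    st <- simulate_cycle(wt, e0 = 2.5, t0 = 2.5, inhibitors = inh,
                         t_grid = seq(0, 17, by = 0.05))
    enz <- st$E_apo + st$E_I + st$E_T + st$D_T + st$D_P + st$E_D
    expect_lt(max(abs(enz - 2.5)) / 2.5, 1e-6)
    phos <- 3 * (st$T_free + st$E_T + st$D_T + st$D_P) +
      2 * (st$E_D + st$GDP_free) + st$Pi_free
    expect_lt(max(abs(phos - 3 * 2.5)) / (3 * 2.5), 1e-6)
  }
  # finite Pi-release variant conserves mass too
  pf <- cycle_parameters(3896, 0.6, 717, 201, 12.4, k_pi_rel = 1.6)
  st <- simulate_cycle(pf, 2.5, 2.5, t_grid = seq(0, 17, by = 0.05))
  enz <- st$E_apo + st$E_I + st$E_T + st$D_T + st$D_P + st$E_D
  expect_lt(max(abs(enz - 2.5)) / 2.5, 1e-6)
})

test_that("wild-type mant projection rises to ~0.15 and decays toward 0.10", {
  st <- simulate_cycle(wt, e0 = 2.5, t0 = 2.5,
                       t_grid = seq(0, 17, by = 0.01))
  tr <- project_observable(st, "mant")
  peak <- max(tr$signal)
  expect_gt(peak, 0.14)
  expect_lt(peak, 0.155)
  expect_lt(tr$time[which.max(tr$signal)], 0.8)
  # end of the 17 s run has decayed most of the way to the 0.10 level
  expect_lt(tr$signal[nrow(tr)], 0.105)
  expect_gt(tr$signal[nrow(tr)], 0.095)
})

test_that("without hydrolysis the closed dimer accumulates and nothing
           decays", {
  p0 <- cycle_parameters(3896, 0.6, 717, 0, 12.4, label = "no-hyd")
  st <- simulate_cycle(p0, 2.5, 2.5, t_grid = seq(0, 17, by = 0.01))
  expect_gt(st$D_T[nrow(st)], 2.4)      # plateau near full conversion
  expect_equal(max(st$D_P), 0, tolerance = 1e-12)
  q <- project_observable(st, "quench")
  expect_equal(q$signal[nrow(q)], 100, tolerance = 1e-6)
})

test_that("projection channels respect their defining monotonicities", {
  st <- simulate_cycle(wt, e0 = 2.5, t0 = 2.5,
                       t_grid = seq(0, 17, by = 0.02))
  q <- project_observable(st, "quench")
  expect_true(all(diff(q$signal) <= 1e-9))
  pb <- project_observable(st, "pbp")
  expect_true(all(diff(pb$signal) >= -1e-9))
  # all-apo initial point projects to the mant baseline
  m <- project_observable(st, "mant")
  expect_equal(m$signal[1L], 0, tolerance = 1e-12)
  expect_error(observable_map("bogus"))
})

test_that("hydrolysis is fluorescence-silent with default mant
           coefficients", {
  # D_T and D_P carry the same coefficient, so a pure D_T -> D_P
  # interconversion leaves the projected signal constant
  map <- observable_map("mant")
  expect_equal(map$coefficients[["D_T"]], map$coefficients[["D_P"]])
  frac <- seq(0, 1, by = 0.1)
  sig <- 0.15 * frac + 0.15 * (1 - frac)
  expect_equal(diff(range(sig)), 0)
})

test_that("effective binding rate follows the titration hyperbola", {
  expect_equal(effective_binding_rate(wt, wt$kd_bind), wt$k_max_bind / 2)
  expect_equal(effective_binding_rate(wt, 2.5), 3896 * 2.5 / 3.1,
               tolerance = 1e-12)
  expect_equal(effective_binding_rate(wt, 2.5), 3141.9, tolerance = 1e-4)
  ctx <- inhibitor_context()
  expect_equal(effective_binding_rate(wt, 2.5, gdp_conc = ctx$ki_e_gdp),
               effective_binding_rate(wt, 2.5) / 2)
})

test_that("steady-state rate law reduces correctly", {
  # no inhibitor: plain Michaelis-Menten for either model
  v_c <- steady_state_rate(0.23, 60, 19.5, s = 10, i = 0, "competitive",
                           ki_e = 41.2)
  v_m <- steady_state_rate(0.23, 60, 19.5, s = 10, i = 0, "mixed",
                           ki_e = 41.2, ki_es = 100)
  expect_equal(v_c, 0.23 * 60 * 10 / 29.5)
  expect_equal(v_c, v_m)
  # half-saturation at s = Km
  expect_equal(steady_state_rate(0.23, 60, 19.5, s = 19.5, i = 0,
                                 "competitive", ki_e = 41.2),
               0.23 * 60 / 2)
  # mixed rate vanishes monotonically as i -> infinity
  iseq <- 10^(0:8)
  v <- steady_state_rate(0.23, 60, 19.5, s = 19.5, i = iseq, "mixed",
                         ki_e = 41.2, ki_es = 5800)
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-4)
  expect_error(steady_state_rate(0.23, 60, 19.5, 10, 0, "bogus", 41.2))
})

test_that("competitor chase releases mGDP at a concentration-independent
           rate with concentration-dependent amplitude", {
  tg <- seq(0, 120, by = 0.01)
  fits <- lapply(c(0.8, 80, 800), function(cc) {
    tr <- simulate_chase(wt, competitor_conc = cc, t_add = 60, t_grid = tg)
    post <- tr[tr$time >= 60, ]
    fit_single_exponential(new_trace(post$time, post$signal, "fret"),
                           "decay")
  })
  rates <- vapply(fits, function(f) f$estimates[["k"]], 0)
  amps <- vapply(fits, function(f) abs(f$estimates[["A"]]), 0)
  expect_equal(rates[3], 300, tolerance = 1e-6)
  expect_lt(max(abs(rates - rates[1])) / rates[1], 0.05)
  expect_true(all(diff(amps) > 0))
  # no competitor, no fluorescence change
  flat <- simulate_chase(wt, competitor_conc = 0, t_add = 60, t_grid = tg)
  expect_equal(diff(range(flat$signal)), 0)
  expect_error(simulate_chase(wt, -1, 60, tg), ">= 0")
  expect_error(simulate_chase(wt, 800, 500, tg), "within")
})

test_that("time units convert exactly once between seconds and minutes", {
  # a pure 60 min^-1 step observed for 1 s must decay by exactly e^-1
  expect_equal(bateman_chain(60, 1)[1, "S0"], exp(-60 / 60),
               ignore_attr = TRUE)
  p <- cycle_parameters(1e7, 1e-4, 1e7, 1e7, 60)
  st <- simulate_cycle(p, 50, 0.01, t_grid = c(0, 1))
  expect_equal(st$E_D[2] / 0.01, 1 - exp(-1), tolerance = 1e-4)
})

test_that("simulation inputs are validated", {
  expect_error(simulate_cycle(wt, 0, 2.5, t_grid = c(0, 1)), "e0")
  expect_error(simulate_cycle(wt, 2.5, 2.5, t_grid = c(1, 2)),
               "starting at 0")
  expect_error(simulate_cycle(wt, 2.5, 2.5, t_grid = c(0, 2, 1)),
               "increasing")
  expect_error(cycle_parameters(-1, 0.6, 717, 201, 12.4), "k_max_bind")
  expect_error(cycle_parameters(3896, 0, 717, 201, 12.4), "kd_bind")
})
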