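# shared fixtures: wild-type constants and small exact-model generators

wt <- wt_parameters()

# exact single-exponential trace (no ODE): y = y_inf + A exp(-k t)
make_single_exp_trace <- function(k, A = 0.05, y_inf = 0.10,
                                  duration = 17, dt = 0.01,
                                  noise_sd = 0, seed = NULL,
                                  channel = "mant") {
  t <- seq(0, duration, by = dt)
  y <- y_inf + A * exp(-k * t / 60)
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  }
  new_trace(t, y, channel, noise_sd = noise_sd)
}

# exact biphasic rise: y = y0 + A1 (1 - e^-k1 t) + A2 (1 - e^-k2 t)
make_double_exp_trace <- function(k1, k2, A1 = 0.095, A2 = 0.055,
                                  y0 = 0, duration = 0.5, dt = 0.002,
                                  noise_sd = 0, seed = NULL) {
  t <- seq(0, duration, by = dt)
  y <- y0 + A1 * (1 - exp(-k1 * t / 60)) + A2 * (1 - exp(-k2 * t / 60))
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  }
  new_trace(t, y, "mant", noise_sd = noise_sd)
}

# exact one-phase quench decay points
make_quench_points <- function(k, plateau = 0,
                               t = c(0, 10^seq(log10(0.02), log10(12),
                                               length.out = 11))) {
  y <- plateau + (100 - plateau) * exp(-k * t / 60)
  new_trace(t, y, "quench", noise_sd = 0)
}

table3_gdp <- data.frame(
  inhibitor_conc = c(0, 10, 50, 80, 100),
  kcat = c(0.23, 0.27, 0.30, 0.32, 0.35),
  Km = c(19.5, 38.8, 57.4, 65.6, 77.6))

table3_pi <- data.frame(
  inhibitor_conc = c(0, 500, 2000, 5000, 10000),
  kcat = c(0.41, 0.37, 0.19, 0.20, 0.14),
  Km = c(8.7, 14.3, 17.8, 34.3, 60.8))
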