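# Seeded synthetic-data generators emulating the statistical structure of
# the single-turnover experiments: stopped-flow optical traces sampled at
# 10 ms and averaged over >= 6 replicates, quench-flow percent-uncleaved
# time points, hyperbolic k_obs titrations and initial-rate inhibition
# grids.  Noise is additive i.i.d. Gaussian; replicate r of a call with
# seed s draws with seed s + r, so one integer seed fixes everything.

#' Construct a kinetic trace
#'
#' One instrument channel's signal versus time, with noise and replicate
#' metadata carried as attributes.
#'
#' @param time time points in seconds, strictly increasing.
#' @param signal signal values (relative fluorescence, or percent
#'   uncleaved GTP for the quench channel).
#' @param channel one of `"mant"`, `"fret"`, `"pbp"`, `"quench"`.
#' @param noise_sd Gaussian noise standard deviation of this trace
#'   (signal units; an averaged trace carries the post-averaging value).
#' @param n_replicates number of replicates averaged into this trace.
#' @param seed integer seed used to generate it, or `NA`.
#' @param label construct name.
#' @return an object of class `kin_trace` (a data frame with columns
#'   `time`, `signal`).
#' @export
new_trace <- function(time, signal, channel, noise_sd = 0,
                      n_replicates = 1L, seed = NA_integer_, label = "") {
  if (length(time) != length(signal)) {
    stop("'time' and 'signal' must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("'time' must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time, signal = signal),
            channel = channel, noise_sd = noise_sd,
            n_replicates = as.integer(n_replicates),
            seed = seed, label = label,
            class = c("kin_trace", "data.frame"))
}

#' @export
print.kin_trace <- function(x, ...) {
  cat(sprintf(
    "kinetic trace [%s] channel=%s, %d points over %.3g s, noise_sd=%g, n_rep=%d\n",
    attr(x, "label"), attr(x, "channel"), nrow(x), max(x$time),
    attr(x, "noise_sd"), attr(x, "n_replicates")))
  invisible(x)
}

.add_noise <- function(trace, noise_sd, seed) {
  noisy <- trace
  noisy$signal <- trace$signal +
    .with_seed(seed, stats::rnorm(nrow(trace), sd = noise_sd))
  attr(noisy, "noise_sd") <- noise_sd
  attr(noisy, "seed") <- as.integer(seed)
  noisy
}

#' Generate replicated noisy stopped-flow traces
#'
#' Simulates the cycle, projects the requested optical channel, discards
#' the instrument dead time, and adds i.i.d. Gaussian noise to each of
#' `n_replicates` replicates (replicate r uses seed `seed + r`).  The
#' replicate average mimics the trace a stopped-flow experiment reports.
#'
#' @param params a [cycle_parameters()] object.
#' @param channel `"mant"`, `"fret"` or `"pbp"`.
#' @param e0,t0 post-mix enzyme and nucleotide concentrations (uM).
#' @param duration trace length (s).
#' @param dt sampling interval (s); default 10 ms.
#' @param noise_sd per-replicate Gaussian noise SD (signal units).
#' @param n_replicates number of replicates (>= 1); experiments average
#'   at least six.
#' @param seed integer seed.
#' @param inhibitors an [inhibitor_context()].
#' @param dead_time initial interval discarded from the optical trace (s).
#' @return list with elements `replicates` (list of `kin_trace`),
#'   `average` (`kin_trace`, noise_sd recorded as `noise_sd/sqrt(n)`) and
#'   `noiseless` (the projection itself).
#' @export
#' @examples
#' g <- generate_traces(wt_parameters(), "mant", e0 = 2.5, t0 = 2.5,
#'                      duration = 2, noise_sd = 0.003, n_replicates = 3,
#'                      seed = 1)
#' g$average
generate_traces <- function(params, channel = c("mant", "fret", "pbp"),
                            e0, t0, duration, dt = 0.01,
                            noise_sd = 0.003, n_replicates = 6L, seed,
                            inhibitors = inhibitor_context(),
                            dead_time = 0.002) {
  channel <- match.arg(channel)
  .assert_scalar_num(dt, "dt", positive = TRUE)
  if (duration < 10 * dt) stop("grid too coarse: duration < 10 * dt",
                               call. = FALSE)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  .assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  .assert_scalar_num(seed, "seed")

  t_grid <- unique(c(0, seq(0, duration, by = dt)))
  states <- simulate_cycle(params, e0 = e0, t0 = t0,
                           inhibitors = inhibitors, t_grid = t_grid)
  noiseless <- project_observable(states, observable_map(channel))
  noiseless <- noiseless[noiseless$time >= dead_time, , drop = FALSE]
  noiseless <- new_trace(noiseless$time, noiseless$signal, channel,
                         noise_sd = 0, n_replicates = 1L,
                         label = params$label)

  reps <- lapply(seq_len(n_replicates), function(r) {
    .add_noise(noiseless, noise_sd, seed + r)
  })
  avg_signal <- rowMeans(vapply(reps, function(tr) tr$signal,
                                numeric(nrow(noiseless))))
  average <- new_trace(noiseless$time, avg_signal, channel,
                       noise_sd = noise_sd / sqrt(n_replicates),
                       n_replicates = n_replicates, seed = seed,
                       label = params$label)
  list(replicates = reps, average = average, noiseless = noiseless)
}

#' Generate a synthetic quench-flow time course
#'
#' Percent uncleaved GTP at discrete quench times, as produced by mixing
#' 100 uM protein 1:1 with 100 uM GTP (50 uM each post-mix), quenching at
#' time points spread over 12 s, and quantifying remaining GTP.  Noise is
#' Gaussian, proportional to the signal (relative SD `noise_frac`).
#'
#' @param params a [cycle_parameters()] object.
#' @param e0,t0 post-mix concentrations (uM); default 50.
#' @param timepoints quench times (s); default `t = 0` plus 11 log-spaced
#'   points from 20 ms to 12 s (12 points total).
#' @param noise_frac relative noise SD per point (default 2 percent).
#' @param n_replicates replicates averaged (replicate r uses seed
#'   `seed + r`).
#' @param seed integer seed.
#' @param inhibitors an [inhibitor_context()].
#' @return a `kin_trace` on the quench channel (the replicate average,
#'   with per-replicate signals in `attr(, "replicate_signals")`).
#' @export
generate_quench_flow <- function(params, e0 = 50, t0 = 50,
                                 timepoints = NULL, noise_frac = 0.02,
                                 n_replicates = 3L, seed,
                                 inhibitors = inhibitor_context()) {
  stopifnot(inherits(params, "cycle_parameters"))
  if (is.null(timepoints)) {
    timepoints <- c(0, 10^seq(log10(0.02), log10(12), length.out = 11))
  }
  if (any(diff(timepoints) <= 0) || timepoints[1L] != 0) {
    stop("'timepoints' must be strictly increasing and start at 0",
         call. = FALSE)
  }
  .assert_scalar_num(noise_frac, "noise_frac", nonneg = TRUE)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  .assert_scalar_num(seed, "seed")

  states <- simulate_cycle(params, e0 = e0, t0 = t0,
                           inhibitors = inhibitors, t_grid = timepoints)
  clean <- project_observable(states, observable_map("quench"))
  sig <- vapply(seq_len(n_replicates), function(r) {
    clean$signal +
      .with_seed(seed + r,
                 stats::rnorm(nrow(clean), sd = noise_frac * clean$signal))
  }, numeric(nrow(clean)))
  avg <- rowMeans(sig)
  out <- new_trace(timepoints, avg, "quench",
                   noise_sd = noise_frac * 100 / sqrt(n_replicates),
                   n_replicates = n_replicates, seed = seed,
                   label = params$label)
  attr(out, "replicate_signals") <- sig
  out
}

#' Generate a synthetic k_obs-versus-concentration titration
#'
#' Observed rate constants for one step of the cycle at a series of
#' enzyme concentrations, drawn from the hyperbolic saturation law
#' `k_obs = k_step_max [E] / (K_D + [E])` with multiplicative Gaussian
#' noise.  `k_step_max` is `k_max_bind`, `k_dim` or `k_diss` according to
#' `step`; the binding K_D is used for all steps.
#'
#' @param params a [cycle_parameters()] object.
#' @param step `"binding"`, `"dimerization"` or `"dissociation"`.
#' @param e_concs enzyme concentrations (uM), >= 4 distinct values;
#'   default 8 values spanning 0.5-50 uM.
#' @param noise_frac relative noise SD (default 5 percent).
#' @param seed integer seed.
#' @return a `kobs_titration` data frame with columns `conc`, `k_obs`.
#' @export
generate_kobs_titration <- function(params,
                                    step = c("binding", "dimerization",
                                             "dissociation"),
                                    e_concs = c(0.5, 1, 2, 5, 10, 20,
                                                35, 50),
                                    noise_frac = 0.05, seed) {
  step <- match.arg(step)
  stopifnot(inherits(params, "cycle_parameters"))
  if (length(unique(e_concs)) < 4L || any(e_concs <= 0)) {
    stop("degenerate design: need >= 4 distinct positive concentrations",
         call. = FALSE)
  }
  .assert_scalar_num(noise_frac, "noise_frac", nonneg = TRUE)
  .assert_scalar_num(seed, "seed")
  k_step <- switch(step, binding = params$k_max_bind,
                   dimerization = params$k_dim,
                   dissociation = params$k_diss)
  k_true <- k_step * e_concs / (params$kd_bind + e_concs)
  k_obs <- k_true *
    (1 + .with_seed(seed, stats::rnorm(length(e_concs), sd = noise_frac)))
  structure(data.frame(conc = e_concs, k_obs = k_obs),
            step = step, seed = seed, label = params$label,
            class = c("kobs_titration", "data.frame"))
}

#' Generate a synthetic initial-rate inhibition grid
#'
#' Rectangular grid of initial rates over substrate x inhibitor
#' concentrations drawn from the steady-state rate law (competitive for
#' GDP, mixed for Pi, overridable) with multiplicative Gaussian noise.
#'
#' @param kcat turnover number (min^-1).
#' @param e0 enzyme concentration (uM).
#' @param Km Michaelis constant (uM).
#' @param inhibitor `"GDP"` or `"Pi"`.
#' @param ki_e inhibition constant toward free enzyme (uM).
#' @param ki_es inhibition constant toward the enzyme-substrate complex
#'   (uM); required for the mixed model.
#' @param s_list substrate concentrations (uM), >= 3 levels.
#' @param i_list inhibitor concentrations (uM), >= 3 levels.
#' @param noise_frac relative noise SD (default 3 percent); must be >= 0.
#' @param seed integer seed.
#' @param model rate-law override (`"competitive"` or `"mixed"`).
#' @return an `inhibition_grid` data frame with columns `substrate_uM`,
#'   `inhibitor_uM`, `rate`.
#' @export
generate_inhibition_grid <- function(kcat, e0, Km,
                                     inhibitor = c("GDP", "Pi"),
                                     ki_e, ki_es = NULL, s_list, i_list,
                                     noise_frac = 0.03, seed,
                                     model = NULL) {
  inhibitor <- match.arg(inhibitor)
  if (is.null(model)) {
    model <- if (inhibitor == "GDP") "competitive" else "mixed"
  }
  if (length(unique(s_list)) < 3L || length(unique(i_list)) < 3L) {
    stop("need >= 3 substrate levels and >= 3 inhibitor levels",
         call. = FALSE)
  }
  if (!is.numeric(noise_frac) || noise_frac < 0) {
    stop("'noise_frac' must be >= 0", call. = FALSE)
  }
  .assert_scalar_num(seed, "seed")
  g <- expand.grid(substrate_uM = sort(s_list), inhibitor_uM = sort(i_list))
  v <- steady_state_rate(kcat, e0, Km, s = g$substrate_uM,
                         i = g$inhibitor_uM, model = model,
                         ki_e = ki_e, ki_es = ki_es)
  g$rate <- v * (1 + .with_seed(seed,
                                stats::rnorm(nrow(g), sd = noise_frac)))
  structure(g, inhibitor = inhibitor, model = model, seed = seed,
            class = c("inhibition_grid", "data.frame"))
}

#' Single-turnover kinetic constants of the MnmE mutant panel
#'
#' The wild type plus 13 G-domain variants with their per-step rate
#' constants (min^-1) from single-turnover assays, tRNA-modification
#' activity (percent of wild type) and hydrolase class (`fast`: hydrolysis
#' above 30 min^-1; `slow`: below 13 min^-1).  Rows where hydrolysis was
#' too slow for the downstream steps to be measured carry `NA`.
#'
#' @return data frame with columns `label`, `k_bind`, `k_dim`, `k_hyd`,
#'   `k_diss`, `k_pi_rel`, `modification_activity`, `hydrolase_class`;
#'   row names are the construct labels.
#' @export
#' @examples
#' mutant_panel()["T250S", "k_diss"]  # 2.6
mutant_panel <- function() {
  path <- system.file("extdata", "mutant_panel.json",
                      package = "mnmekinetics", mustWork = TRUE)
  panel <- jsonlite::fromJSON(path)
  stopifnot(!anyDuplicated(panel$label))
  rownames(panel) <- panel$label
  panel
}

#' Look up one construct in the mutant panel
#'
#' @param label construct name, e.g. `"wt"` or `"T250S"`.
#' @return one-row list of the panel entry.
#' @export
mutant_profile <- function(label) {
  panel <- mutant_panel()
  if (!label %in% rownames(panel)) {
    stop("unknown construct '", label, "'; valid labels: ",
         paste(rownames(panel), collapse = ", "), call. = FALSE)
  }
  as.list(panel[label, ])
}

#' Cycle parameters for a panel construct
#'
#' Builds [cycle_parameters()] from a mutant-panel row.  Panel rate
#' constants are the rates observed at the 2.5 uM reference mixing
#' condition, so the binding maximum rate is back-solved from the
#' hyperbola: `k_max_bind = k1 (K_D + c) / c` with `c = at_conc`, making
#' the simulated binding rate at the reference concentration equal the
#' tabulated `k1`.
#'
#' @param label construct name in the panel.
#' @param kd_bind binding K_D (uM); the panel variants show no appreciable
#'   change in nucleotide affinity, so the wild-type 0.60 uM is used.
#' @param at_conc reference enzyme concentration (uM) at which the panel
#'   rates were observed.
#' @return a [cycle_parameters()] object.
#' @export
cycle_parameters_from_profile <- function(label, kd_bind = 0.60,
                                          at_conc = 2.5) {
  pr <- mutant_profile(label)
  if (is.na(pr$k_hyd) || is.na(pr$k_diss)) {
    stop("construct '", label, "' has no measured post-hydrolysis rates",
         call. = FALSE)
  }
  k_pi <- if (is.na(pr$k_pi_rel)) Inf else pr$k_pi_rel
  # treat near-dissociation-limited Pi release as instantaneous
  if (is.finite(k_pi) && k_pi >= 0.75 * pr$k_diss) k_pi <- Inf
  cycle_parameters(
    k_max_bind = pr$k_bind * (kd_bind + at_conc) / at_conc,
    kd_bind = kd_bind,
    k_dim = pr$k_dim, k_hyd = pr$k_hyd, k_diss = pr$k_diss,
    k_pi_rel = k_pi, label = label
  )
}
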