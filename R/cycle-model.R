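# Mechanistic model of the five-step MnmE GTPase cycle.
#
# State vector (uM), integrated in minutes by deSolve::lsoda:
#   Tp   free GTP/mGTP pool
#   E    apo enzyme (open, nucleotide-free G-domain pair), including the
#        fraction transiently sequestered by dead-end GDP/Pi binding
#   ET   open, GTP-bound
#   DT   closed G-domain dimer, GTP
#   DP   closed dimer, GDP.Pi (post-hydrolysis)
#   EDP  open, GDP-bound, Pi still retained (only populated when Pi
#        release is finite)
#   ED   open, GDP-bound, Pi released
#   Pi   free inorganic phosphate
#
# Binding is a rapid-equilibrium encounter (K_D) followed by isomerization
# at k_max, integrated as a genuinely bimolecular flux
#   v_bind = k_max * [E_avail] / (K_D + [E_avail]) * [T]
# which reduces to the hyperbolic pseudo-first-order law when enzyme is in
# excess and remains valid for equimolar mixing.  Dead-end GDP binding
# scales the available enzyme by 1/(1 + [GDP]/K_IE_gdp); Pi scales
# availability by 1/(1 + [Pi]/K_IE_pi) and hydrolysis by
# 1/(1 + [Pi]/K_IES_pi).  Free Pi produced during the run feeds back into
# the inhibition terms.

.cycle_rhs <- function(t, y, p) {
  pi_tot <- p$pi0 + y[["Pi"]]
  f_gdp <- 1 / (1 + p$gdp0 / p$ki_e_gdp)
  f_pi_bind <- 1 / (1 + pi_tot / p$ki_e_pi)
  f_pi_hyd <- 1 / (1 + pi_tot / p$ki_es_pi)

  e_avail <- y[["E"]] * f_gdp * f_pi_bind
  v_bind <- p$k_max_bind * e_avail / (p$kd_bind + e_avail) * y[["Tp"]]
  v_dim <- p$k_dim * y[["ET"]]
  v_hyd <- p$k_hyd * f_pi_hyd * y[["DT"]]
  v_diss <- p$k_diss * y[["DP"]]
  if (is.infinite(p$k_pi_rel)) {
    v_rel <- v_diss  # Pi leaves with the dissociating dimer
    dEDP <- 0
    dED <- v_diss
  } else {
    v_rel <- p$k_pi_rel * y[["EDP"]]
    dEDP <- v_diss - v_rel
    dED <- v_rel
  }
  list(c(
    Tp = -v_bind,
    E = -v_bind,
    ET = v_bind - v_dim,
    DT = v_dim - v_hyd,
    DP = v_hyd - v_diss,
    EDP = dEDP,
    ED = dED,
    Pi = v_rel
  ))
}

#' Simulate the five-step MnmE GTPase cycle
#'
#' Integrates the cycle GTP binding -> G-domain dimerization -> GTP
#' hydrolysis -> G-domain dissociation -> Pi release for a single-turnover
#' mixing experiment, with optional GDP/Pi product inhibition.  GDP
#' produced by the run remains enzyme-bound (its affinity, ~0.5 uM, far
#' exceeds the micromolar concentrations used here); release under
#' competitor chase is modelled separately by [simulate_chase()].
#'
#' @param params a [cycle_parameters()] object.
#' @param e0 total enzyme concentration after mixing (uM).
#' @param t0 total GTP/mGTP concentration after mixing (uM).
#' @param inhibitors an [inhibitor_context()]; defaults to no inhibitor.
#' @param t_grid strictly increasing time grid in seconds starting at 0.
#' @param rtol,atol integrator tolerances passed to [deSolve::lsoda()].
#' @return a `species_timeseries` data frame with columns `time` (s) and
#'   the species concentrations (uM) `T_free`, `E_apo`, `E_T`, `D_T`,
#'   `D_P`, `E_D`, `Pi_free`, `GDP_free`, `E_I`.  `E_D` pools the open
#'   GDP-bound states with and without retained Pi; `E_I` is the dead-end
#'   inhibited fraction of the apo pool.
#' @export
#' @examples
#' st <- simulate_cycle(wt_parameters(), e0 = 2.5, t0 = 2.5,
#'                      t_grid = seq(0, 17, by = 0.01))
#' max(st$D_T + st$D_P)  # closed-dimer peak
simulate_cycle <- function(params, e0, t0,
                           inhibitors = inhibitor_context(),
                           t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "cycle_parameters"),
            inherits(inhibitors, "inhibitor_context"))
  .assert_scalar_num(e0, "e0", positive = TRUE)
  .assert_scalar_num(t0, "t0", positive = TRUE)
  if (length(t_grid) < 2L || t_grid[1L] != 0 || any(diff(t_grid) <= 0)) {
    stop("'t_grid' must be a strictly increasing grid starting at 0",
         call. = FALSE)
  }

  p <- c(params[c("k_max_bind", "kd_bind", "k_dim", "k_hyd", "k_diss",
                  "k_pi_rel")],
         list(gdp0 = inhibitors$gdp_conc, pi0 = inhibitors$pi_conc,
              ki_e_gdp = inhibitors$ki_e_gdp, ki_e_pi = inhibitors$ki_e_pi,
              ki_es_pi = inhibitors$ki_es_pi))
  y0 <- c(Tp = t0, E = e0, ET = 0, DT = 0, DP = 0, EDP = 0, ED = 0, Pi = 0)

  sol <- deSolve::lsoda(y = y0, times = .sec_to_min(t_grid),
                        func = .cycle_rhs, parms = p,
                        rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0) {
    stop("stiff integration failed (lsoda istate = ", diagn[1L],
         "); consider loosening tolerances or shortening the grid",
         call. = FALSE)
  }
  sol <- as.data.frame(sol)

  # instantaneous dead-end partition of the apo pool
  pi_tot <- inhibitors$pi_conc + sol$Pi
  f_free <- 1 / (1 + inhibitors$gdp_conc / inhibitors$ki_e_gdp) /
    (1 + pi_tot / inhibitors$ki_e_pi)
  out <- data.frame(
    time = t_grid,
    T_free = sol$Tp,
    E_apo = sol$E * f_free,
    E_T = sol$ET,
    D_T = sol$DT,
    D_P = sol$DP,
    E_D = sol$ED + sol$EDP,
    Pi_free = sol$Pi,
    GDP_free = 0,
    E_I = sol$E * (1 - f_free)
  )
  structure(out, e0 = e0, t0 = t0, params = params,
            inhibitors = inhibitors,
            class = c("species_timeseries", "data.frame"))
}

#' Closed-form occupancies of a sequential first-order chain
#'
#' Analytic (Bateman) solution of the irreversible linear chain
#' `S0 -> S1 -> ... -> Sn` with per-step rate constants `rates`
#' (min^-1), starting from all mass in `S0`.  Used as the independent
#' oracle for the numeric integrator under pseudo-first-order conditions.
#'
#' @param rates vector of n positive, pairwise-distinct rate constants
#'   (min^-1).
#' @param t time points in seconds.
#' @param degenerate what to do when two rates coincide within 1e-9
#'   relative: `"error"` (default) or `"perturb"`, which separates the
#'   duplicates by a 1e-6 relative perturbation with a warning.
#' @return matrix of occupancy fractions, `length(t)` rows and `n + 1`
#'   state columns; rows sum to 1.
#' @export
#' @examples
#' # two-step chain: intermediate peaks at ln(2) min when rates are (2, 1)
#' tt <- seq(0, 5, by = 0.001) * 60
#' occ <- bateman_chain(c(2, 1), tt)
#' tt[which.max(occ[, 2])] / 60  # ~ log(2)
bateman_chain <- function(rates, t, degenerate = c("error", "perturb")) {
  degenerate <- match.arg(degenerate)
  if (length(rates) < 1L || any(!is.finite(rates)) || any(rates <= 0)) {
    stop("'rates' must be positive and finite", call. = FALSE)
  }
  n <- length(rates)
  dup <- FALSE
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      rel <- abs(rates[i] - rates[(i + 1L):n]) / rates[i]
      if (any(rel < 1e-9)) dup <- TRUE
    }
  }
  if (dup) {
    if (degenerate == "error") {
      stop("duplicate rates (within 1e-9 relative); use the ",
           "degenerate = \"perturb\" branch or perturb the rates yourself",
           call. = FALSE)
    }
    warning("duplicate rates perturbed by 1e-6 relative", call. = FALSE)
    rates <- rates * (1 + 1e-6 * (seq_len(n) - 1L))
  }

  tm <- .sec_to_min(t)
  # augment with the absorbing terminal state (rate 0)
  k <- c(rates, 0)
  occ <- matrix(0, nrow = length(t), ncol = n + 1L)
  for (j in seq_len(n + 1L)) {         # state S_{j-1}
    idx <- seq_len(j)                  # rates k_1..k_j feed/leave it
    pref <- prod(rates[seq_len(j - 1L)])
    acc <- 0
    for (i in idx) {
      denom <- prod(k[setdiff(idx, i)] - k[i])
      acc <- acc + exp(-k[i] * tm) / denom
    }
    occ[, j] <- pref * acc
  }
  colnames(occ) <- paste0("S", seq_len(n + 1L) - 1L)
  occ
}

#' Project mechanistic species onto an instrument channel
#'
#' @param states a `species_timeseries` from [simulate_cycle()].
#' @param map an [observable_map()], or a channel name.
#' @return a noiseless `kin_trace` (see [new_trace()]): for `mant`/`fret`
#'   a linear combination of enzyme-species fractions; for `quench` the
#'   percentage of uncleaved GTP (non-increasing); for `pbp` a signal
#'   proportional to free Pi.
#' @export
project_observable <- function(states, map = observable_map("mant")) {
  stopifnot(inherits(states, "species_timeseries"))
  if (is.character(map)) map <- observable_map(map)
  stopifnot(inherits(map, "observable_map"))
  e0 <- attr(states, "e0")
  t0 <- attr(states, "t0")
  cf <- map$coefficients
  m <- as.matrix(states[, .species_names, drop = FALSE])
  signal <- switch(map$channel,
    mant = ,
    fret = drop(m %*% cf) / e0,
    pbp = drop(m %*% cf) / t0,
    quench = 100 * drop(m %*% cf) / t0
  ) + map$baseline
  new_trace(time = states$time, signal = signal, channel = map$channel,
            noise_sd = 0, n_replicates = 1L,
            label = attr(states, "params")$label)
}

#' Observed GTP-binding rate at a given enzyme concentration
#'
#' Hyperbolic concentration dependence of the binding step,
#' `k_obs = k_max [E] / (K_D + [E])`, scaled by the competitive dead-end
#' GDP factor `1 / (1 + [GDP]/K_IE)`.
#'
#' @param params a [cycle_parameters()] object.
#' @param e_conc enzyme concentration (uM).
#' @param gdp_conc GDP concentration (uM).
#' @param ctx an [inhibitor_context()] supplying `ki_e_gdp`.
#' @return observed binding rate constant (min^-1).
#' @export
#' @examples
#' effective_binding_rate(wt_parameters(), e_conc = 2.5)  # ~3141 min^-1
effective_binding_rate <- function(params, e_conc, gdp_conc = 0,
                                   ctx = inhibitor_context()) {
  stopifnot(inherits(params, "cycle_parameters"))
  .assert_scalar_num(e_conc, "e_conc", nonneg = TRUE)
  .assert_scalar_num(gdp_conc, "gdp_conc", nonneg = TRUE)
  params$k_max_bind * e_conc / (params$kd_bind + e_conc) /
    (1 + gdp_conc / ctx$ki_e_gdp)
}

#' Steady-state rate under competitive or mixed inhibition
#'
#' Initial-velocity law used for the multi-turnover inhibition analysis:
#' competitive, `v = kcat e0 s / (Km (1 + i/ki_e) + s)`; mixed,
#' `v = kcat e0 s / (Km (1 + i/ki_e) + s (1 + i/ki_es))`.
#'
#' @param kcat turnover number (min^-1).
#' @param e0 enzyme concentration (uM).
#' @param Km Michaelis constant (uM).
#' @param s substrate concentration(s) (uM).
#' @param i inhibitor concentration(s) (uM).
#' @param model `"competitive"` or `"mixed"`.
#' @param ki_e inhibition constant toward free enzyme (uM).
#' @param ki_es inhibition constant toward the enzyme-substrate complex
#'   (uM); required for the mixed model.
#' @return rate(s) in uM min^-1.
#' @export
steady_state_rate <- function(kcat, e0, Km, s, i = 0,
                              model = c("competitive", "mixed"),
                              ki_e, ki_es = NULL) {
  model <- match.arg(model)
  .assert_scalar_num(kcat, "kcat", positive = TRUE)
  .assert_scalar_num(e0, "e0", positive = TRUE)
  .assert_scalar_num(Km, "Km", positive = TRUE)
  .assert_scalar_num(ki_e, "ki_e", positive = TRUE)
  if (any(s < 0) || any(i < 0)) stop("concentrations must be >= 0",
                                     call. = FALSE)
  vmax <- kcat * e0
  if (model == "competitive") {
    vmax * s / (Km * (1 + i / ki_e) + s)
  } else {
    .assert_scalar_num(ki_es, "ki_es", positive = TRUE)
    vmax * s / (Km * (1 + i / ki_e) + s * (1 + i / ki_es))
  }
}

#' Simulate a FRET competitor-chase experiment
#'
#' After single-turnover hydrolysis the product mGDP stays enzyme-bound
#' and the FRET signal sits at a plateau.  Adding unlabelled competitor
#' GTP at `t_add` opens an exit: each exchange event releases mGDP with
#' probability `comp / (comp + rebind_weight)` (competition between
#' competitor and rebinding of the released mGDP, whose affinities are
#' comparable), so the fluorescence loss is single-exponential with rate
#' `k_gdp_off` independent of the competitor concentration, while its
#' amplitude grows with it.
#'
#' @param params a [cycle_parameters()] object (supplies `k_gdp_off`).
#' @param competitor_conc unlabelled GTP concentration (uM).
#' @param t_add addition time (s), strictly inside `t_grid`.
#' @param t_grid strictly increasing time grid (s).
#' @param e0 enzyme = mGDP concentration at the plateau (uM); the
#'   rebinding weight.
#' @param plateau FRET plateau level (relative fluorescence).
#' @return a noiseless `kin_trace` on the `fret` channel.
#' @export
#' @examples
#' tr <- simulate_chase(wt_parameters(), competitor_conc = 800,
#'                      t_add = 60, t_grid = seq(0, 120, by = 0.01))
simulate_chase <- function(params, competitor_conc, t_add, t_grid,
                           e0 = 2, plateau = 0.10) {
  stopifnot(inherits(params, "cycle_parameters"))
  if (competitor_conc < 0) stop("'competitor_conc' must be >= 0",
                                call. = FALSE)
  .assert_scalar_num(e0, "e0", positive = TRUE)
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing",
                                   call. = FALSE)
  if (t_add < min(t_grid) || t_add > max(t_grid)) {
    stop("'t_add' must lie within 't_grid'", call. = FALSE)
  }
  frac <- competitor_conc / (competitor_conc + e0)
  signal <- rep(plateau, length(t_grid))
  post <- t_grid >= t_add
  dt_min <- .sec_to_min(t_grid[post] - t_add)
  signal[post] <- plateau -
    plateau * frac * (1 - exp(-params$k_gdp_off * dt_min))
  new_trace(time = t_grid, signal = signal, channel = "fret",
            noise_sd = 0, n_replicates = 1L, label = params$label)
}
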