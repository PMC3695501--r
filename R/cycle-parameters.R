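# Parameter containers for the five-step MnmE GTPase cycle.
#
# The cycle is modelled as
#   E_apo + GTP -> E.T -> D.T -> D.P -> E.D (+ Pi)
# i.e. binding, G-domain dimerization (k2), GTP hydrolysis (k3), G-domain
# dissociation (k4) and Pi release (k5).  Binding is a rapid-equilibrium
# encounter (dissociation constant `kd_bind`) followed by an isomerization
# with maximum rate `k_max_bind`, which reproduces the hyperbolic
# concentration dependence k_obs = k_max [E] / (K_D + [E]).

#' Rate and affinity constants of the MnmE GTPase cycle
#'
#' Container for the kinetic constants of one MnmE construct.  All rate
#' constants are in min^-1 (the convention used throughout the package),
#' all concentrations in micromolar.
#'
#' @param k_max_bind maximum rate of the GTP-binding step (min^-1); the
#'   `k_max` of the hyperbolic titration law.
#' @param kd_bind dissociation constant of the binding encounter (uM).
#' @param k_dim G-domain dimerization rate `k2` (min^-1).
#' @param k_hyd GTP hydrolysis rate `k3` (min^-1).
#' @param k_diss G-domain dissociation rate `k4` (min^-1).
#' @param k_pi_rel Pi release rate `k5` (min^-1), or `Inf` for release
#'   that is instantaneous upon G-domain dissociation (the wild-type
#'   behaviour; finite values describe variants with retarded release).
#' @param k_gdp_off exchange-limited GDP/mGDP off-rate (min^-1); about
#'   300 for wild type.
#' @param kd_gdp equilibrium dissociation constant for GDP (uM), about 0.5.
#' @param label construct name.
#' @return an object of class `cycle_parameters`.
#' @seealso [wt_parameters()], [cycle_parameters_from_profile()]
#' @export
#' @examples
#' cycle_parameters(k_max_bind = 3896, kd_bind = 0.60, k_dim = 717,
#'                  k_hyd = 201, k_diss = 12.4)
cycle_parameters <- function(k_max_bind, kd_bind, k_dim, k_hyd, k_diss,
                             k_pi_rel = Inf, k_gdp_off = 300, kd_gdp = 0.5,
                             label = "construct") {
  .assert_scalar_num(k_max_bind, "k_max_bind", nonneg = TRUE)
  .assert_scalar_num(kd_bind, "kd_bind", positive = TRUE)
  .assert_scalar_num(k_dim, "k_dim", nonneg = TRUE)
  .assert_scalar_num(k_hyd, "k_hyd", nonneg = TRUE)
  .assert_scalar_num(k_diss, "k_diss", nonneg = TRUE)
  if (!(is.numeric(k_pi_rel) && length(k_pi_rel) == 1L &&
        !is.na(k_pi_rel) && k_pi_rel >= 0)) {
    stop("'k_pi_rel' must be a non-negative rate or Inf", call. = FALSE)
  }
  .assert_scalar_num(k_gdp_off, "k_gdp_off", nonneg = TRUE)
  .assert_scalar_num(kd_gdp, "kd_gdp", positive = TRUE)
  structure(
    list(k_max_bind = k_max_bind, kd_bind = kd_bind, k_dim = k_dim,
         k_hyd = k_hyd, k_diss = k_diss, k_pi_rel = k_pi_rel,
         k_gdp_off = k_gdp_off, kd_gdp = kd_gdp,
         label = as.character(label)[1L]),
    class = "cycle_parameters"
  )
}

#' @export
print.cycle_parameters <- function(x, ...) {
  cat(sprintf("MnmE GTPase cycle parameters [%s]\n", x$label))
  cat(sprintf("  binding      : k_max %.4g min^-1, K_D %.3g uM\n",
              x$k_max_bind, x$kd_bind))
  cat(sprintf("  dimerization : k2 %.4g min^-1\n", x$k_dim))
  cat(sprintf("  hydrolysis   : k3 %.4g min^-1\n", x$k_hyd))
  cat(sprintf("  dissociation : k4 %.4g min^-1\n", x$k_diss))
  cat(sprintf("  Pi release   : k5 %s\n",
              if (is.infinite(x$k_pi_rel)) "instantaneous"
              else sprintf("%.4g min^-1", x$k_pi_rel)))
  cat(sprintf("  GDP off-rate %.4g min^-1, K_D(GDP) %.3g uM\n",
              x$k_gdp_off, x$kd_gdp))
  invisible(x)
}

#' Wild-type MnmE kinetic constants
#'
#' Single-turnover constants of the full-length wild-type protein:
#' binding hyperbola (k_max 3896 min^-1, K_D 0.60 uM), dimerization
#' 717 min^-1, hydrolysis 201 min^-1, dissociation 12.4 min^-1,
#' instantaneous Pi release, GDP off-rate 300 min^-1, K_D(GDP) 0.5 uM.
#'
#' @param k_pi_rel Pi release rate; default `Inf` (instantaneous upon
#'   G-domain dissociation).
#' @return a [cycle_parameters()] object.
#' @export
wt_parameters <- function(k_pi_rel = Inf) {
  cycle_parameters(k_max_bind = 3896, kd_bind = 0.60, k_dim = 717,
                   k_hyd = 201, k_diss = 12.4, k_pi_rel = k_pi_rel,
                   k_gdp_off = 300, kd_gdp = 0.5, label = "wt")
}

#' Product-inhibition context
#'
#' Concentrations of the reaction products GDP and Pi present at mixing,
#' together with the inhibition constants through which they act: GDP is a
#' competitive dead-end inhibitor of GTP binding (K_IE 41.2 uM); Pi acts
#' on the free enzyme (K_IE 670 uM) and on the enzyme-substrate complex,
#' i.e. on transition-state stabilization (K_IES 5800 uM).
#'
#' @param gdp_conc GDP concentration (uM).
#' @param pi_conc Pi concentration (uM).
#' @param ki_e_gdp competitive inhibition constant of GDP (uM).
#' @param ki_e_pi inhibition constant of Pi toward free enzyme (uM).
#' @param ki_es_pi inhibition constant of Pi toward the enzyme-substrate
#'   complex (uM).
#' @return an object of class `inhibitor_context`.
#' @export
inhibitor_context <- function(gdp_conc = 0, pi_conc = 0,
                              ki_e_gdp = 41.2, ki_e_pi = 670,
                              ki_es_pi = 5800) {
  .assert_scalar_num(gdp_conc, "gdp_conc", nonneg = TRUE)
  .assert_scalar_num(pi_conc, "pi_conc", nonneg = TRUE)
  .assert_scalar_num(ki_e_gdp, "ki_e_gdp", positive = TRUE)
  .assert_scalar_num(ki_e_pi, "ki_e_pi", positive = TRUE)
  .assert_scalar_num(ki_es_pi, "ki_es_pi", positive = TRUE)
  structure(
    list(gdp_conc = gdp_conc, pi_conc = pi_conc, ki_e_gdp = ki_e_gdp,
         ki_e_pi = ki_e_pi, ki_es_pi = ki_es_pi),
    class = "inhibitor_context"
  )
}

#' Cellular nucleotide and phosphate concentrations
#'
#' Steady-state concentrations in E. coli used for the IC50 and
#' fraction-inhibited calculations: GTP 5 mM, GDP 0.7 mM, Pi 10 mM
#' (all in uM here).
#'
#' @param gtp_cellular,gdp_cellular,pi_cellular concentrations in uM.
#' @return an object of class `cellular_context`.
#' @export
cellular_context <- function(gtp_cellular = 5000, gdp_cellular = 700,
                             pi_cellular = 10000) {
  .assert_scalar_num(gtp_cellular, "gtp_cellular", positive = TRUE)
  .assert_scalar_num(gdp_cellular, "gdp_cellular", positive = TRUE)
  .assert_scalar_num(pi_cellular, "pi_cellular", positive = TRUE)
  structure(
    list(gtp_cellular = gtp_cellular, gdp_cellular = gdp_cellular,
         pi_cellular = pi_cellular),
    class = "cellular_context"
  )
}

# species tracked by the simulator, in output order
.species_names <- c("T_free", "E_apo", "E_T", "D_T", "D_P", "E_D",
                    "Pi_free", "GDP_free", "E_I")

#' Observable projection map
#'
#' Defines how mechanistic species are projected onto one instrument
#' channel.  For the optical channels (`mant`, `fret`) the signal is a
#' linear combination of enzyme-species fractions (species concentration
#' divided by total enzyme); the default mant coefficients are 0 for apo
#' enzyme and free nucleotide, 0.095 for the open GTP-bound state, 0.15
#' for the closed dimer before and after hydrolysis, and 0.10 for the
#' open GDP-bound state, so hydrolysis itself produces no fluorescence
#' change and the decay reports G-domain dissociation only.  The `quench`
#' channel is the percentage of uncleaved GTP, `100 (T_free + E_T + D_T) /
#' t0`; the `pbp` channel is proportional to free Pi (MDCC-PBP sensor
#' binding treated as instantaneous and non-depleting).
#'
#' @param channel one of `"mant"`, `"fret"`, `"pbp"`, `"quench"`.
#' @param coefficients optional named numeric vector of per-species signal
#'   coefficients overriding the channel defaults (names from
#'   `T_free, E_apo, E_T, D_T, D_P, E_D, Pi_free, GDP_free, E_I`).
#' @param baseline additive baseline offset (signal units).
#' @return an object of class `observable_map`.
#' @export
observable_map <- function(channel = c("mant", "fret", "pbp", "quench"),
                           coefficients = NULL, baseline = 0) {
  channel <- match.arg(channel)
  coefs <- switch(channel,
    mant = c(T_free = 0, E_apo = 0, E_T = 0.095, D_T = 0.15, D_P = 0.15,
             E_D = 0.10, Pi_free = 0, GDP_free = 0, E_I = 0),
    # FRET from G-domain tryptophans to any bound mant nucleotide: equal
    # contribution from all nucleotide-occupied enzyme states.
    fret = c(T_free = 0, E_apo = 0, E_T = 0.10, D_T = 0.10, D_P = 0.10,
             E_D = 0.10, Pi_free = 0, GDP_free = 0, E_I = 0),
    pbp = c(T_free = 0, E_apo = 0, E_T = 0, D_T = 0, D_P = 0, E_D = 0,
            Pi_free = 1, GDP_free = 0, E_I = 0),
    quench = c(T_free = 1, E_apo = 0, E_T = 1, D_T = 1, D_P = 0, E_D = 0,
               Pi_free = 0, GDP_free = 0, E_I = 0)
  )
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% .species_names)) {
      stop("'coefficients' must be named after model species: ",
           paste(.species_names, collapse = ", "), call. = FALSE)
    }
    coefs[names(coefficients)] <- coefficients
  }
  if (!all(is.finite(coefs))) stop("signal coefficients must be finite",
                                   call. = FALSE)
  .assert_scalar_num(baseline, "baseline")
  structure(list(channel = channel, coefficients = coefs,
                 baseline = baseline),
            class = "observable_map")
}
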