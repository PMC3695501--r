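# Product-inhibition inference: Michaelis-Menten fits under inhibitor,
# Dixon (1/v vs [I]) and Cornish-Bowden ([S]/v vs [I]) inhibition
# constants, inhibition-type classification, IC50 formulas and the
# fraction of enzyme inhibited at cellular metabolite concentrations.
#
# For the competitive rate law the Dixon lines at different substrate
# levels intersect exactly at [I] = -K_IE; for the mixed law the [S]/v
# lines intersect exactly at [I] = -K_IES.  The intersection is computed
# as the least-squares common point of all fitted lines rather than read
# graphically.

# least-squares common intersection of lines y = a_j + b_j x: for each x
# the best common y is the mean, so minimize sum_j ((a_j - abar) +
# (b_j - bbar) x)^2, a quadratic with closed-form minimizer.
.common_intersection <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  x <- -sum(da * db) / sum(db^2)
  y <- mean(a + b * x)
  resid <- sqrt(mean((a + b * x - y)^2))
  list(x = x, y = y, resid = resid)
}

.grid_lines <- function(grid, transform) {
  stopifnot(is.data.frame(grid),
            all(c("substrate_uM", "inhibitor_uM", "rate") %in% names(grid)))
  s_levels <- sort(unique(grid$substrate_uM))
  if (length(s_levels) < 2L) stop("need >= 2 substrate levels",
                                  call. = FALSE)
  if (length(unique(grid$inhibitor_uM)) < 3L) {
    stop("need >= 3 inhibitor levels", call. = FALSE)
  }
  coefs <- t(vapply(s_levels, function(s) {
    d <- grid[grid$substrate_uM == s, ]
    f <- stats::lm(transform(d) ~ d$inhibitor_uM)
    cf <- stats::coef(f)
    # noiseless model-generated grids fit the lines exactly
    se <- tryCatch(
      withCallingHandlers(
        summary(f)$coefficients[2L, "Std. Error"],
        warning = function(w) {
          if (grepl("essentially perfect fit", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NA_real_)
    c(cf, se)
  }, numeric(3L)))
  list(s_levels = s_levels, a = coefs[, 1L], b = coefs[, 2L],
       b_se = coefs[, 3L])
}

# Slope-pattern diagnosis.  Lines with slopes identical to numerical
# precision are the signature of the uncompetitive Dixon / competitive
# [S]/v rate laws, whose lines share one slope exactly: that is an error
# (no intersection exists).  A mixed law with Km/K_IE >> s/K_IES
# produces slope spreads of only a few percent that are nonetheless
# real, so small-but-noisy spreads must not abort estimation; when even
# the largest pairwise slope difference is within one joint standard
# error the intersection is merely flagged as poorly determined.
.slope_pattern <- function(b, b_se) {
  spread <- diff(range(b))
  if (spread <= 1e-6 * max(abs(b), 1e-300)) return("parallel")
  z_max <- 0
  n <- length(b)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sqrt(b_se[i]^2 + b_se[j]^2)
      z <- if (!is.finite(denom) || denom == 0) Inf else
        abs(b[i] - b[j]) / denom
      z_max <- max(z_max, z)
    }
  }
  if (is.finite(z_max) && z_max < 1) "indistinct" else "distinct"
}

#' Dixon analysis: competitive inhibition constant
#'
#' Fits straight lines `1/v` versus inhibitor concentration at each
#' substrate level and returns `K_IE = -[I]` at their least-squares
#' common intersection.  A global nonlinear fit of the competitive rate
#' law is reported alongside as a cross-check.
#'
#' @param grid an `inhibition_grid` (columns `substrate_uM`,
#'   `inhibitor_uM`, `rate`) with >= 2 substrate and >= 3 inhibitor
#'   levels.
#' @return list with `ki_e` (uM, from the intersection), `ki_e_global`
#'   (uM, from the nonlinear competitive fit), `intersection`
#'   (`x`, `y`, `resid`) and the per-substrate line coefficients.
#' @export
dixon_fit <- function(grid) {
  gl <- .grid_lines(grid, function(d) 1 / d$rate)
  pat <- .slope_pattern(gl$b, gl$b_se)
  if (pat == "parallel") {
    stop("no intersection: uncompetitive-like pattern (Dixon lines ",
         "near-parallel)", call. = FALSE)
  }
  if (pat == "indistinct") {
    warning("Dixon slopes statistically indistinguishable; K_IE poorly ",
            "determined", call. = FALSE)
  }
  inter <- .common_intersection(gl$a, gl$b)
  # global nonlinear cross-check with the competitive law
  start <- list(vmax = max(grid$rate) * 1.5,
                km = stats::median(grid$substrate_uM),
                ki = abs(inter$x))
  gfit <- .nls_safe(
    rate ~ vmax * substrate_uM / (km * (1 + inhibitor_uM / ki) +
                                    substrate_uM),
    grid, start = start, lower = c(vmax = 0, km = 0, ki = 0))
  ki_g <- if (is.null(gfit)) NA_real_ else stats::coef(gfit)[["ki"]]
  list(ki_e = -inter$x, ki_e_global = ki_g, intersection = inter,
       lines = data.frame(substrate_uM = gl$s_levels, intercept = gl$a,
                          slope = gl$b))
}

#' Cornish-Bowden analysis: enzyme-substrate inhibition constant
#'
#' Fits straight lines `[S]/v` versus inhibitor concentration at each
#' substrate level; for a purely competitive pattern these lines are
#' parallel and the constant is unbounded.  Their common intersection
#' sits at `[I] = -K_IES`, but reading the constant off the intersection
#' is attenuation-biased whenever the slope differences are comparable
#' to their noise (the mixed law's `Km/K_IE` term dominates all slopes),
#' so the reported `ki_es` comes from a global fit of the mixed rate law
#' in log space (the maximum-likelihood estimate under the proportional
#' error of initial-rate data).  The intersection estimate is returned
#' alongside; on noiseless model-generated grids the two coincide with
#' the generating constant exactly.
#'
#' @inheritParams dixon_fit
#' @return list with `ki_es` (uM, global rate-law fit),
#'   `ki_es_intersection` (uM), `ki_e_global` (uM, from the same global
#'   fit), `intersection` (`x`, `y`, `resid`) and the per-substrate line
#'   coefficients.
#' @export
cornish_bowden_fit <- function(grid) {
  gl <- .grid_lines(grid, function(d) d$substrate_uM / d$rate)
  pat <- .slope_pattern(gl$b, gl$b_se)
  if (pat == "parallel") {
    stop("competitive pattern: K_IES unbounded ([S]/v lines ",
         "near-parallel)", call. = FALSE)
  }
  if (pat == "indistinct") {
    warning("[S]/v slopes statistically indistinguishable; K_IES poorly ",
            "determined", call. = FALSE)
  }
  inter <- .common_intersection(gl$a, gl$b)
  ki0 <- max(abs(inter$x), min(grid$inhibitor_uM[grid$inhibitor_uM > 0]))
  gfit <- .nls_safe(
    log(rate) ~ log(vmax * substrate_uM /
                      (km * (1 + inhibitor_uM / kie) +
                         substrate_uM * (1 + inhibitor_uM / kies))),
    grid,
    start = list(vmax = max(grid$rate) * 1.5,
                 km = stats::median(grid$substrate_uM),
                 kie = ki0, kies = ki0),
    lower = c(vmax = 1e-9, km = 1e-9, kie = 1e-9, kies = 1e-9))
  if (is.null(gfit)) {
    ki_es <- -inter$x
    ki_e_g <- NA_real_
  } else {
    ki_es <- stats::coef(gfit)[["kies"]]
    ki_e_g <- stats::coef(gfit)[["kie"]]
  }
  list(ki_es = ki_es, ki_es_intersection = -inter$x,
       ki_e_global = ki_e_g, intersection = inter,
       lines = data.frame(substrate_uM = gl$s_levels, intercept = gl$a,
                          slope = gl$b))
}

#' Fit the Michaelis-Menten law at one inhibitor level
#'
#' Nonlinear fit of `v = Vmax s / (Km_app + s)`; `kcat = Vmax / e0`.
#'
#' @param s substrate concentrations (uM), >= 3 distinct levels.
#' @param v initial rates (uM min^-1, or min^-1 for rate-constant data
#'   with `e0 = 1`).
#' @param e0 enzyme concentration (uM).
#' @param inhibitor,inhibitor_conc optional metadata recorded in the
#'   result.
#' @return list of class `mm_fit` with `kcat`, `Km`, `Vmax`, standard
#'   errors, and the metadata.  Warns when the design does not reach
#'   saturation (`max(s) < Km_app`).
#' @export
fit_michaelis_menten <- function(s, v, e0 = 1, inhibitor = NA_character_,
                                 inhibitor_conc = NA_real_) {
  if (length(unique(s)) < 3L) stop("need >= 3 substrate levels",
                                   call. = FALSE)
  .assert_scalar_num(e0, "e0", positive = TRUE)
  lin <- stats::coef(stats::lm(I(1 / v) ~ I(1 / s)))
  vmax0 <- unname(if (lin[1L] > 0) 1 / lin[1L] else max(v) * 1.2)
  km0 <- unname(max(abs(lin[2L]) * vmax0, min(s) / 10))
  fit <- .nls_safe(v ~ vmax * s / (km + s), data.frame(s = s, v = v),
                   start = list(vmax = vmax0, km = km0),
                   lower = c(vmax = 0, km = 0))
  if (is.null(fit)) stop("Michaelis-Menten fit did not converge",
                         call. = FALSE)
  fs <- .fit_summary(fit)
  km <- unname(fs$est["km"])
  vmax <- unname(fs$est["vmax"])
  if (max(s) < km) warning("non-saturating design: max substrate below ",
                           "apparent Km", call. = FALSE)
  structure(list(kcat = vmax / e0, Km = km, Vmax = vmax,
                 se = c(kcat = unname(fs$se["vmax"]) / e0,
                        Km = unname(fs$se["km"]),
                        Vmax = unname(fs$se["vmax"])),
                 residual_sd = fs$sigma, inhibitor = inhibitor,
                 inhibitor_conc = inhibitor_conc),
            class = "mm_fit")
}

#' Classify the inhibition pattern from a Michaelis-Menten series
#'
#' Given fits across increasing inhibitor levels (including zero):
#' competitive if the apparent Km rises monotonically while kcat does not
#' fall appreciably; mixed if Km rises and kcat falls by more than the
#' `kcat_drop` fraction; `"none"` otherwise.  (A competitive inhibitor
#' leaves kcat invariant; upward drift in kcat is treated as unchanged.)
#'
#' @param mm_fits list of `mm_fit` objects ordered by inhibitor
#'   concentration, or a data frame with columns `inhibitor_conc`,
#'   `kcat`, `Km`.
#' @param kcat_drop fractional kcat decrease separating mixed from
#'   competitive (default 0.25).
#' @return `"competitive"`, `"mixed"` or `"none"`.
#' @export
#' @examples
#' gdp <- data.frame(inhibitor_conc = c(0, 10, 50, 80, 100),
#'                   kcat = c(0.23, 0.27, 0.30, 0.32, 0.35),
#'                   Km = c(19.5, 38.8, 57.4, 65.6, 77.6))
#' classify_inhibition(gdp)  # "competitive"
classify_inhibition <- function(mm_fits, kcat_drop = 0.25) {
  if (is.list(mm_fits) && !is.data.frame(mm_fits)) {
    mm_fits <- data.frame(
      inhibitor_conc = vapply(mm_fits, `[[`, 0, "inhibitor_conc"),
      kcat = vapply(mm_fits, `[[`, 0, "kcat"),
      Km = vapply(mm_fits, `[[`, 0, "Km"))
  }
  stopifnot(all(c("inhibitor_conc", "kcat", "Km") %in% names(mm_fits)))
  if (nrow(mm_fits) < 3L || min(mm_fits$inhibitor_conc) != 0) {
    stop("need >= 3 inhibitor levels including 0", call. = FALSE)
  }
  if (is.unsorted(mm_fits$inhibitor_conc, strictly = TRUE)) {
    stop("inhibitor levels must be strictly increasing", call. = FALSE)
  }
  km_up <- all(diff(rank(mm_fits$Km)) > 0) && all(diff(mm_fits$Km) > 0)
  kcat0 <- mm_fits$kcat[1L]
  kcat_end <- mm_fits$kcat[nrow(mm_fits)]
  rel_change <- (kcat_end - kcat0) / kcat0
  if (km_up && rel_change < -kcat_drop) return("mixed")
  if (km_up) return("competitive")
  "none"
}

#' IC50 of a competitive inhibitor at the cellular substrate level
#'
#' Literal evaluation of `IC50 = K_IE (1 + s_cell / Km)`.
#'
#' @param ki_e competitive inhibition constant (uM).
#' @param Km Michaelis constant (uM).
#' @param s_cell cellular substrate concentration (uM); may be 0, giving
#'   `K_IE` back.
#' @return IC50 in uM.
#' @export
#' @examples
#' ic50_competitive(41.2, 710, 5000)  # 331.3 uM
ic50_competitive <- function(ki_e, Km, s_cell) {
  .assert_scalar_num(ki_e, "ki_e", positive = TRUE)
  .assert_scalar_num(Km, "Km", positive = TRUE)
  .assert_scalar_num(s_cell, "s_cell", nonneg = TRUE)
  ki_e * (1 + s_cell / Km)
}

#' IC50 of a mixed inhibitor at the cellular substrate level
#'
#' Evaluates `IC50 = K_IE / ((Km / s_cell) + (K_IE / K_IES))` (the
#' bracketed reading of the conventional shorthand) and, for comparison,
#' the textbook mixed-inhibition formula
#' `IC50 = (s_cell + Km) / (Km / K_IE + s_cell / K_IES)`.
#'
#' @param ki_e,ki_es inhibition constants toward free enzyme and the
#'   enzyme-substrate complex (uM).
#' @param Km Michaelis constant (uM).
#' @param s_cell cellular substrate concentration (uM).
#' @return list with `ic50` (bracketed reading) and `ic50_textbook`, uM.
#' @export
#' @examples
#' ic50_mixed(670, 5800, 710, 5000)
ic50_mixed <- function(ki_e, ki_es, Km, s_cell) {
  .assert_scalar_num(ki_e, "ki_e", positive = TRUE)
  .assert_scalar_num(ki_es, "ki_es", positive = TRUE)
  .assert_scalar_num(Km, "Km", positive = TRUE)
  .assert_scalar_num(s_cell, "s_cell", positive = TRUE)
  list(ic50 = ki_e / ((Km / s_cell) + (ki_e / ki_es)),
       ic50_textbook = (s_cell + Km) / (Km / ki_e + s_cell / ki_es))
}

#' Fraction of enzyme inhibited at given inhibitor/substrate levels
#'
#' Competitive model: the equilibrium fraction of enzyme sequestered in
#' the dead-end inhibitor complex,
#' `(i/K_IE) / (1 + i/K_IE + s/Km)`.  Mixed model: the fractional rate
#' reduction `1 - v(i)/v(0)` under the mixed rate law.
#'
#' @param model `"competitive"` or `"mixed"`.
#' @param i inhibitor concentration (uM).
#' @param s substrate concentration (uM).
#' @param Km Michaelis constant (uM).
#' @param ki_e inhibition constant toward free enzyme (uM).
#' @param ki_es enzyme-substrate inhibition constant (uM), mixed model
#'   only.
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' fraction_inhibited("competitive", i = 700, s = 5000, Km = 710,
#'                    ki_e = 41.2)  # ~0.679
fraction_inhibited <- function(model = c("competitive", "mixed"), i, s,
                               Km, ki_e, ki_es = NULL) {
  model <- match.arg(model)
  .assert_scalar_num(i, "i", nonneg = TRUE)
  .assert_scalar_num(s, "s", nonneg = TRUE)
  .assert_scalar_num(Km, "Km", positive = TRUE)
  .assert_scalar_num(ki_e, "ki_e", positive = TRUE)
  if (model == "competitive") {
    (i / ki_e) / (1 + i / ki_e + s / Km)
  } else {
    .assert_scalar_num(ki_es, "ki_es", positive = TRUE)
    v0 <- s / (Km + s)
    vi <- s / (Km * (1 + i / ki_e) + s * (1 + i / ki_es))
    1 - vi / v0
  }
}

#' Full inhibition analysis of an initial-rate grid
#'
#' Runs the complete inference on one substrate x inhibitor grid:
#' Michaelis-Menten fits at each inhibitor level, classification of the
#' inhibition type from the Km/kcat trends, the matching
#' inhibition-constant analyses (Dixon for K_IE; Cornish-Bowden
#' additionally for K_IES under mixed inhibition), the IC50 at the
#' cellular substrate concentration, and the fraction of enzyme
#' inhibited at the cellular concentration of the inhibitor.
#'
#' @param grid an `inhibition_grid` (columns `substrate_uM`,
#'   `inhibitor_uM`, `rate`); the `inhibitor` attribute ("GDP" or "Pi"),
#'   when present, selects the cellular inhibitor concentration.
#' @param e0 enzyme concentration (uM) used to convert Vmax to kcat.
#' @param cellular a [cellular_context()].
#' @param Km_cellular Michaelis constant (uM) used in the IC50 and
#'   cellular-fraction arithmetic; defaults to the uninhibited fitted
#'   Km.  The multi-turnover Km (710 uM for wild type) differs from the
#'   single-turnover grid Km, so pass it explicitly when reproducing
#'   cellular-inhibition numbers.
#' @return list of class `inhibition_result` with elements `model`,
#'   `ki_e`, `ki_es` (NA for competitive), `ic50`,
#'   `fraction_inhibited_at_cellular`, `mm_fits` (per-level data frame)
#'   and the underlying analyses.
#' @seealso [write_inhibition_result()]
#' @export
analyze_inhibition_grid <- function(grid, e0 = 1,
                                    cellular = cellular_context(),
                                    Km_cellular = NULL) {
  stopifnot(all(c("substrate_uM", "inhibitor_uM", "rate") %in%
                  names(grid)))
  inhibitor <- attr(grid, "inhibitor") %||% "GDP"
  levels <- sort(unique(grid$inhibitor_uM))
  mm <- do.call(rbind, lapply(levels, function(i0) {
    d <- grid[grid$inhibitor_uM == i0, ]
    f <- fit_michaelis_menten(d$substrate_uM, d$rate, e0 = e0,
                              inhibitor = inhibitor, inhibitor_conc = i0)
    data.frame(inhibitor_conc = i0, kcat = f$kcat, Km = f$Km)
  }))
  model <- classify_inhibition(mm)
  dx <- tryCatch(suppressWarnings(dixon_fit(grid)),
                 error = function(e) NULL)
  ki_e <- if (is.null(dx)) NA_real_ else dx$ki_e
  cb <- if (model == "mixed") {
    tryCatch(suppressWarnings(cornish_bowden_fit(grid)),
             error = function(e) NULL)
  } else NULL
  ki_es <- if (is.null(cb)) NA_real_ else cb$ki_es

  km_cell <- Km_cellular %||% mm$Km[1L]
  i_cell <- if (inhibitor == "Pi") cellular$pi_cellular else
    cellular$gdp_cellular
  ic50 <- if (model == "mixed" && is.finite(ki_es)) {
    ic50_mixed(ki_e, ki_es, km_cell, cellular$gtp_cellular)$ic50
  } else if (is.finite(ki_e)) {
    ic50_competitive(ki_e, km_cell, cellular$gtp_cellular)
  } else NA_real_
  frac <- if (model == "mixed" && is.finite(ki_es)) {
    fraction_inhibited("mixed", i_cell, cellular$gtp_cellular, km_cell,
                       ki_e, ki_es)
  } else if (is.finite(ki_e)) {
    fraction_inhibited("competitive", i_cell, cellular$gtp_cellular,
                       km_cell, ki_e)
  } else NA_real_

  structure(list(inhibitor = inhibitor, model = model, ki_e = ki_e,
                 ki_es = ki_es, ic50 = ic50,
                 fraction_inhibited_at_cellular = frac, mm_fits = mm,
                 dixon = dx, cornish_bowden = cb),
            class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("inhibition analysis [%s]: %s\n", x$inhibitor, x$model))
  cat(sprintf("  K_IE  %.4g uM\n", x$ki_e))
  if (is.finite(x$ki_es)) cat(sprintf("  K_IES %.4g uM\n", x$ki_es))
  cat(sprintf("  IC50 at cellular GTP: %.4g uM\n", x$ic50))
  cat(sprintf("  fraction inhibited at cellular [%s]: %.3f\n",
              x$inhibitor, x$fraction_inhibited_at_cellular))
  invisible(x)
}

#' Write an inhibition result as JSON
#'
#' @param result an `inhibition_result` from [analyze_inhibition_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_inhibition_result <- function(result, path) {
  stopifnot(inherits(result, "inhibition_result"))
  out <- result[c("inhibitor", "model", "ki_e", "ki_es", "ic50",
                  "fraction_inhibited_at_cellular")]
  out$mm_fits <- result$mm_fits
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Express a rate constant relative to a reference
#'
#' Reporting arithmetic for the construct and inhibition tables:
#' `percent_of_reference = round(100 k/k_ref)` and `percent_inhibition =
#' round(100 (1 - k/k_ref))`, both rounded half away from zero to
#' integers.
#'
#' @param k_test,k_ref rate constants (min^-1); `k_ref` must be > 0,
#'   `k_test` >= 0.
#' @return named list with `percent_of_reference` and
#'   `percent_inhibition`.
#' @export
#' @examples
#' rate_percentages(201, 301)  # 67 percent of reference
#' rate_percentages(48, 201)   # 76 percent inhibition
rate_percentages <- function(k_test, k_ref) {
  if (k_test < 0 || k_ref <= 0) {
    stop("rates must be non-negative and the reference positive",
         call. = FALSE)
  }
  list(percent_of_reference = round_half_out(100 * k_test / k_ref),
       percent_inhibition = round_half_out(100 * (1 - k_test / k_ref)))
}
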