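# Trace-level inference: exponential fits (single, double, one-phase
# quench decay), the hyperbolic k_obs titration fit, lag-phase detection
# and amplitude-based Pi-retention.  All rates are reported in min^-1;
# trace time axes are in seconds and converted once at the fitter
# boundary.  Nonlinear fits are initialized by a log-spaced grid search
# over rates (1e-1 to 1e5 min^-1) with the linear parameters profiled
# out, then polished with Levenberg-Marquardt (minpack.lm::nlsLM).

.k_grid <- function(n = 61) 10^seq(-1, 5, length.out = n)

#' Fit result container
#'
#' @param model model label.
#' @param estimates named numeric vector of parameter estimates (rates in
#'   min^-1, amplitudes/offsets in signal units).
#' @param se named numeric vector of standard errors (same names).
#' @param residual_sd residual standard deviation.
#' @param converged logical; if `FALSE` the estimates are unusable.
#' @param n number of data points fitted.
#' @param message optional diagnostic message.
#' @param lag optional lag duration (seconds).
#' @return an object of class `kin_fit`.
#' @export
new_fit_result <- function(model, estimates, se, residual_sd, converged,
                           n, message = NULL, lag = NULL) {
  structure(list(model = model, estimates = estimates, se = se,
                 residual_sd = residual_sd, converged = converged,
                 n = n, message = message, lag = lag),
            class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("fit [%s]%s\n", x$model,
              if (x$converged) "" else "  ** not converged **"))
  est <- rbind(estimate = x$estimates, se = x$se[names(x$estimates)])
  print(signif(est, 6))
  cat(sprintf("residual SD %.4g over %d points\n", x$residual_sd, x$n))
  if (!is.null(x$message)) cat("note:", x$message, "\n")
  invisible(x)
}

# profile the linear coefficients out for a fixed set of exponential
# rates: y ~ X(k) beta, returns RSS and beta (rss = Inf for rate
# candidates whose regressors underflow to collinearity)
.profiled_lm <- function(y, X) {
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(rss = Inf, beta = NULL))
  }
  list(rss = sum(fit$residuals^2), beta = fit$coefficients)
}

.nls_safe <- function(formula, data, start, lower = NULL) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  tryCatch({
    if (is.null(lower)) {
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctl)
    } else {
      minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                        control = ctl)
    }
  }, error = function(e) NULL)
}

# weighted variant; the weight vector is injected as a data column so
# that nls's non-standard evaluation of `weights` can resolve it
.nls_safe2 <- function(formula, data, start, lower, weights) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  data$.w <- weights
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      weights = .w, control = ctl),
    error = function(e) NULL)
}

.fit_summary <- function(fit) {
  # noiseless exact-model refits legitimately reach machine precision
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(est = stats::coef(fit), se = s$coefficients[, "Std. Error"],
       sigma = s$sigma)
}

#' Fit a single-exponential transition
#'
#' Fits `y = y_inf + A exp(-k t)` to one trace (or a time window of it),
#' the model used for the G-domain dissociation phase.  The rate `k` is
#' in min^-1.  A grid of candidate rates initializes the fit.
#'
#' @param trace a `kin_trace`.
#' @param direction `"decay"` (signal falls to `y_inf`, A > 0) or
#'   `"rise"` (A < 0); used for the no-transition check only, the sign of
#'   `A` is fitted freely.
#' @param window optional `c(t_min, t_max)` in seconds restricting the
#'   fit; the dissociation phase of a mant trace is conventionally fitted
#'   on 0.5-17 s.
#' @return a `kin_fit` with estimates `k`, `A`, `y_inf`.  If the fitted
#'   amplitude is below 3x the trace noise SD the result is flagged
#'   "no transition detected".
#' @export
fit_single_exponential <- function(trace, direction = c("decay", "rise"),
                                   window = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(trace, "kin_trace"))
  d <- trace
  if (!is.null(window)) {
    d <- d[d$time >= window[1] & d$time <= window[2], , drop = FALSE]
  }
  if (nrow(d) < 20L) stop("need >= 20 points in the fit window",
                          call. = FALSE)
  tm <- .sec_to_min(d$time - d$time[1L])
  y <- d$signal

  best <- NULL
  for (k in .k_grid()) {
    X <- cbind(1, exp(-k * tm))
    pl <- .profiled_lm(y, X)
    if (is.finite(pl$rss) && (is.null(best) || pl$rss < best$rss)) {
      best <- list(rss = pl$rss, k = k, beta = pl$beta)
    }
  }
  dat <- data.frame(tm = tm, y = y)
  fit <- .nls_safe(y ~ yinf + A * exp(-k * tm), dat,
                   start = list(yinf = unname(best$beta[1L]),
                                A = unname(best$beta[2L]), k = best$k),
                   lower = c(yinf = -Inf, A = -Inf, k = 0))
  if (is.null(fit)) {
    # fall back on the grid-search solution (flat traces defeat the
    # Levenberg-Marquardt polish but still need the amplitude check)
    est <- c(k = best$k, A = unname(best$beta[2L]),
             y_inf = unname(best$beta[1L]))
    na <- c(k = NA_real_, A = NA_real_, y_inf = NA_real_)
    res <- new_fit_result("single_exponential", est, na,
                          sqrt(best$rss / nrow(d)), converged = FALSE,
                          n = nrow(d),
                          message = "nonlinear fit did not converge")
  } else {
    fs <- .fit_summary(fit)
    est <- c(k = unname(fs$est["k"]), A = unname(fs$est["A"]),
             y_inf = unname(fs$est["yinf"]))
    se <- c(k = unname(fs$se["k"]), A = unname(fs$se["A"]),
            y_inf = unname(fs$se["yinf"]))
    res <- new_fit_result("single_exponential", est, se, fs$sigma,
                          converged = TRUE, n = nrow(d))
  }
  noise_sd <- attr(trace, "noise_sd")
  if (is.null(noise_sd)) noise_sd <- 0
  thresh <- 3 * max(noise_sd, res$residual_sd,
                    1e-12 * max(abs(y), 1), na.rm = TRUE)
  if (is.finite(est[["A"]]) && abs(est[["A"]]) < thresh) {
    res$converged <- FALSE
    res$message <- "no transition detected"
  }
  res
}

#' Fit a double-exponential rise
#'
#' Fits `y = y0 + A1 (1 - exp(-k_fast t)) + A2 (1 - exp(-k_slow t))`, the
#' model for the biphasic fluorescence increase (GTP binding then
#' G-domain dimerization) in the first half second.  Phases are labelled
#' by rate magnitude (`k_fast >= k_slow`).  If the two fitted rates are
#' within a factor of 3 the phases are poorly separable: a warning is
#' raised and the fit is compared against a single exponential by AIC,
#' falling back to the single-exponential result when that wins.
#'
#' @param trace a `kin_trace`.
#' @param window fit window in seconds (default `c(0, 0.5)`).
#' @return a `kin_fit` with estimates `k_fast`, `k_slow`, `A_fast`,
#'   `A_slow`, `y0` (or a single-exponential fallback result).
#' @export
fit_double_exponential <- function(trace, window = c(0, 0.5)) {
  stopifnot(inherits(trace, "kin_trace"))
  d <- trace[trace$time >= window[1] & trace$time <= window[2], ,
             drop = FALSE]
  if (nrow(d) < 40L) stop("need >= 40 points in the fit window",
                          call. = FALSE)
  tm <- .sec_to_min(d$time - d$time[1L])
  y <- d$signal

  kg <- .k_grid(31)
  best <- NULL
  for (i in seq_along(kg)) {
    for (j in seq_len(i - 1L)) {        # kg[i] > kg[j]
      X <- cbind(1, 1 - exp(-kg[i] * tm), 1 - exp(-kg[j] * tm))
      pl <- .profiled_lm(y, X)
      if (is.finite(pl$rss) && (is.null(best) || pl$rss < best$rss)) {
        best <- list(rss = pl$rss, k1 = kg[i], k2 = kg[j], beta = pl$beta)
      }
    }
  }
  dat <- data.frame(tm = tm, y = y)
  fit <- .nls_safe(
    y ~ y0 + A1 * (1 - exp(-k1 * tm)) + A2 * (1 - exp(-k2 * tm)), dat,
    start = list(y0 = unname(best$beta[1L]), A1 = unname(best$beta[2L]),
                 A2 = unname(best$beta[3L]), k1 = best$k1, k2 = best$k2),
    lower = c(y0 = -Inf, A1 = -Inf, A2 = -Inf, k1 = 0, k2 = 0))
  if (is.null(fit)) {
    nm <- c("k_fast", "k_slow", "A_fast", "A_slow", "y0")
    na <- stats::setNames(rep(NA_real_, 5L), nm)
    return(new_fit_result("double_exponential", na, na, NA_real_,
                          converged = FALSE, n = nrow(d),
                          message = "nonlinear fit did not converge"))
  }
  fs <- .fit_summary(fit)
  ord <- order(c(fs$est[["k1"]], fs$est[["k2"]]), decreasing = TRUE)
  kk <- c(fs$est[["k1"]], fs$est[["k2"]])[ord]
  aa <- c(fs$est[["A1"]], fs$est[["A2"]])[ord]
  kse <- c(fs$se[["k1"]], fs$se[["k2"]])[ord]
  ase <- c(fs$se[["A1"]], fs$se[["A2"]])[ord]
  est <- c(k_fast = kk[1L], k_slow = kk[2L], A_fast = aa[1L],
           A_slow = aa[2L], y0 = unname(fs$est[["y0"]]))
  se <- c(k_fast = kse[1L], k_slow = kse[2L], A_fast = ase[1L],
          A_slow = ase[2L], y0 = unname(fs$se[["y0"]]))
  res <- new_fit_result("double_exponential", est, se, fs$sigma,
                        converged = TRUE, n = nrow(d))

  if (is.finite(kk[2L]) && kk[2L] > 0 && kk[1L] / kk[2L] < 3) {
    warning("phases poorly separable (rate ratio < 3); ",
            "comparing against a single exponential", call. = FALSE)
    single <- fit_single_exponential(trace, direction = "rise",
                                     window = window)
    n <- nrow(d)
    aic_d <- n * log(fs$sigma^2 * (n - 5L) / n) + 2 * 5
    aic_s <- n * log(single$residual_sd^2 * (n - 3L) / n) + 2 * 3
    if (single$converged && aic_s < aic_d) {
      single$message <- "double-exponential phases degenerate; single exponential preferred by AIC"
      return(single)
    }
    res$message <- "phases poorly separable (rate ratio < 3)"
  }
  res
}

#' Fit a one-phase exponential decay to quench-flow data
#'
#' Fits `pct = plateau + (100 - plateau) exp(-k max(t - t0, 0))` to
#' percent-uncleaved GTP time points; the rate `k` estimates the
#' single-turnover GTP hydrolysis rate constant.  Two refinements of the
#' plain one-phase decay reflect how these data arise: a short fitted
#' onset delay `t0` absorbs the burst during which GTP binding and
#' G-domain dimerization are still loading the hydrolysis-competent
#' dimer ("plateau followed by one-phase decay"); and because the
#' chromatographic quantification error is proportional to the measured
#' amount, the fit is iteratively reweighted with variances proportional
#' to the squared fitted signal.  Both can be disabled.
#'
#' @param points a quench-channel `kin_trace` (must include t = 0).
#' @param delay fit the onset delay `t0` (default `TRUE`); with `FALSE`
#'   the classic `plateau + (100 - plateau) exp(-k t)` form is used.
#' @param weighting `"relative"` (default, proportional-error model) or
#'   `"none"` for ordinary least squares.
#' @param weight_floor signal floor (percent units) limiting the weight
#'   of near-zero points under relative weighting.
#' @return a `kin_fit` with estimates `k` (min^-1), `plateau` and (when
#'   `delay`) `t0` (minutes).
#' @export
fit_one_phase_decay <- function(points, delay = TRUE,
                                weighting = c("relative", "none"),
                                weight_floor = 0.5) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(points, "kin_trace"))
  if (nrow(points) < 5L) stop("need >= 5 time points", call. = FALSE)
  if (min(points$time) > 1e-9) stop("t = 0 point required", call. = FALSE)
  tm <- .sec_to_min(points$time)
  y <- points$signal
  if (stats::coef(stats::lm(y ~ tm))[2L] > 0) {
    est <- c(k = NA_real_, plateau = NA_real_)
    return(new_fit_result("one_phase_decay", est, est, NA_real_,
                          converged = FALSE, n = length(y),
                          message = "increasing data: not a decay"))
  }

  best <- NULL
  for (k in .k_grid()) {
    e <- exp(-k * tm)
    u <- 1 - e
    denom <- sum(u^2)
    plateau <- if (denom < 1e-12) 0 else sum((y - 100 * e) * u) / denom
    rss <- sum((plateau + (100 - plateau) * e - y)^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss)) {
      best <- list(rss = rss, k = k, plateau = plateau)
    }
  }
  fml <- if (delay) {
    y ~ plateau + (100 - plateau) * exp(-k * pmax(tm - t0, 0))
  } else {
    y ~ plateau + (100 - plateau) * exp(-k * tm)
  }
  start <- list(plateau = best$plateau, k = best$k)
  lower <- c(plateau = -Inf, k = 0)
  if (delay) {
    start$t0 <- .sec_to_min(stats::median(diff(points$time)) / 10)
    lower <- c(lower, t0 = 0)
  }
  w <- rep(1, length(y))
  fit <- NULL
  n_iter <- if (weighting == "relative") 6L else 1L
  for (it in seq_len(n_iter)) {
    dat <- data.frame(tm = tm, y = y, w = w)
    fit <- .nls_safe2(fml, dat, start = start, lower = lower, weights = w)
    if (is.null(fit)) break
    cf <- stats::coef(fit)
    start <- as.list(cf)
    if (weighting == "relative") {
      w <- 1 / pmax(stats::predict(fit), weight_floor)^2
    }
  }
  if (is.null(fit)) {
    # grid-search fallback so flat traces still get the amplitude check
    est <- c(k = best$k, plateau = best$plateau)
    na <- c(k = NA_real_, plateau = NA_real_)
    res <- new_fit_result("one_phase_decay", est, na,
                          sqrt(best$rss / length(y)), converged = FALSE,
                          n = length(y),
                          message = "nonlinear fit did not converge")
  } else {
    fs <- .fit_summary(fit)
    est <- c(k = unname(fs$est["k"]), plateau = unname(fs$est["plateau"]))
    se <- c(k = unname(fs$se["k"]), plateau = unname(fs$se["plateau"]))
    if (delay) {
      est <- c(est, t0 = unname(fs$est["t0"]))
      se <- c(se, t0 = unname(fs$se["t0"]))
    }
    res <- new_fit_result("one_phase_decay", est, se, fs$sigma,
                          converged = TRUE, n = length(y))
  }
  noise_sd <- attr(points, "noise_sd")
  if (is.null(noise_sd)) noise_sd <- 0
  thresh <- 3 * max(noise_sd, res$residual_sd, 1e-10, na.rm = TRUE)
  if (is.finite(est[["plateau"]]) &&
      abs(100 - est[["plateau"]]) < thresh) {
    res$converged <- FALSE
    res$message <- "no transition detected"
  }
  res
}

#' Fit the hyperbolic k_obs titration
#'
#' Fits `k_obs = k_max [E] / (K_D + [E])` to an observed-rate-versus-
#' enzyme-concentration titration.
#'
#' @param titration a `kobs_titration` (or data frame with columns
#'   `conc`, `k_obs`) with >= 4 distinct concentrations.
#' @return a `kin_fit` with estimates `k_max` (min^-1) and `K_D` (uM).
#'   Warns "K_D poorly constrained" when all concentrations lie well
#'   above the fitted K_D.
#' @export
fit_hyperbolic <- function(titration) {
  stopifnot(is.data.frame(titration),
            all(c("conc", "k_obs") %in% names(titration)))
  if (length(unique(titration$conc)) < 4L) {
    stop("need >= 4 distinct concentrations", call. = FALSE)
  }
  e <- titration$conc
  k <- titration$k_obs
  # linearized start: 1/k = 1/kmax + (KD/kmax) (1/e)
  pos <- k > 0
  lin <- stats::coef(stats::lm(I(1 / k[pos]) ~ I(1 / e[pos])))
  kmax0 <- unname(if (lin[1L] > 0) 1 / lin[1L] else max(k) * 1.2)
  kd0 <- unname(max(lin[2L] * kmax0, min(e) / 10))
  fit <- .nls_safe(k_obs ~ kmax * conc / (kd + conc),
                   data.frame(conc = e, k_obs = k),
                   start = list(kmax = kmax0, kd = kd0),
                   lower = c(kmax = 0, kd = 0))
  if (is.null(fit)) {
    est <- c(k_max = NA_real_, K_D = NA_real_)
    return(new_fit_result("hyperbolic", est, est, NA_real_,
                          converged = FALSE, n = length(e),
                          message = "nonlinear fit did not converge"))
  }
  fs <- .fit_summary(fit)
  est <- c(k_max = unname(fs$est["kmax"]), K_D = unname(fs$est["kd"]))
  se <- c(k_max = unname(fs$se["kmax"]), K_D = unname(fs$se["kd"]))
  if (min(e) > 10 * est[["K_D"]]) {
    warning("K_D poorly constrained: all concentrations far above the ",
            "fitted K_D", call. = FALSE)
  }
  new_fit_result("hyperbolic", est, se, fs$sigma, converged = TRUE,
                 n = length(e))
}

#' Detect the post-dimerization lag phase
#'
#' Measures the delay between completion of the fluorescence rise (the
#' signal peak, where the closed dimer has formed) and the onset of the
#' dissociation decay: the lag ends when the (smoothed) signal first
#' falls more than `3 * noise_sd` below the plateau mean.  On wild-type
#' traces this interval covers the silent hydrolysis step, about 0.6 s.
#'
#' @param trace a `kin_trace` containing the peak plateau.
#' @param plateau_window length (s) of the window after the peak averaged
#'   to define the plateau level.
#' @param smooth_width width (s) of the running-mean smoother applied
#'   before peak and threshold detection (noise robustness; has no effect
#'   on noiseless traces).
#' @param noise_sd noise SD used for the 3-sigma threshold; defaults to
#'   the trace attribute, or to the residual SD about the plateau when
#'   the trace is noiseless.
#' @return lag duration in seconds (0 if the decay is immediate).
#' @export
detect_lag <- function(trace, plateau_window = 0.2, smooth_width = 0.1,
                       noise_sd = NULL) {
  stopifnot(inherits(trace, "kin_trace"))
  t <- trace$time
  y <- trace$signal
  dt <- stats::median(diff(t))
  w <- max(1L, round(smooth_width / dt))
  ys <- if (w > 1L) stats::filter(y, rep(1 / w, w), sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  i_peak <- which.max(ys)
  in_win <- t >= t[i_peak] & t <= t[i_peak] + plateau_window
  plateau <- mean(ys[in_win])
  if (is.null(noise_sd)) {
    noise_sd <- attr(trace, "noise_sd")
    if (is.null(noise_sd) || noise_sd == 0) {
      noise_sd <- max(stats::sd(y[in_win] - ys[in_win]), 1e-6)
    }
  }
  thresh <- plateau - 3 * noise_sd
  after <- seq(i_peak, length(t))
  below <- after[ys[after] < thresh]
  if (length(below) == 0L) stop("no decay within trace", call. = FALSE)
  t[below[1L]] - t[i_peak]
}

#' Percent of signal amplitude lost relative to a reference
#'
#' Used for Pi-retention: the fraction of molecules retaining Pi is read
#' from the reduction of the Pi-sensor amplitude relative to the
#' reference construct, `100 (1 - A_variant / A_reference)`, reported to
#' one decimal place (half away from zero).
#'
#' @param amp_variant,amp_reference signal amplitudes (same units);
#'   both must be >= 0 and the reference > 0.
#' @return percent retained.
#' @export
#' @examples
#' amplitude_retention(7.7, 10)   # 23
#' amplitude_retention(2.12, 10)  # 78.8
amplitude_retention <- function(amp_variant, amp_reference) {
  if (amp_variant < 0 || amp_reference <= 0) {
    stop("amplitudes must be non-negative and the reference positive",
         call. = FALSE)
  }
  round_half_out(100 * (1 - amp_variant / amp_reference), digits = 1)
}
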