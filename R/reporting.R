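# File I/O, configuration, tRNA-modification arithmetic and the
# end-to-end mutant-panel pipeline.
#
# Trace CSV dialect: comma-separated, '.' decimal, leading '#' comment
# lines carrying key=value metadata, then a header
# time_s,signal,replicate_id (replicate_id optional; legacy files without
# it are read as a single replicate).  Times are always seconds, rates
# always min^-1 in outputs.

#' Write a kinetic trace to CSV
#'
#' @param trace a `kin_trace`, or a list of replicate `kin_trace`s
#'   sharing one time grid (written in long format with `replicate_id`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "kin_trace")) trace <- list(trace)
  stopifnot(all(vapply(trace, inherits, TRUE, "kin_trace")))
  meta <- c(
    sprintf("# channel=%s", attr(trace[[1L]], "channel")),
    sprintf("# construct=%s", attr(trace[[1L]], "label")),
    sprintf("# noise_sd=%.17g", attr(trace[[1L]], "noise_sd")),
    sprintf("# n_replicates=%d", length(trace)),
    sprintf("# seed=%s", attr(trace[[1L]], "seed"))
  )
  rows <- do.call(rbind, lapply(seq_along(trace), function(r) {
    data.frame(time_s = trace[[r]]$time, signal = trace[[r]]$signal,
               replicate_id = r)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_s,signal,replicate_id", con)
  writeLines(sprintf("%.17g,%.17g,%d", rows$time_s, rows$signal,
                     rows$replicate_id), con)
  invisible(path)
}

#' Read a kinetic trace from CSV
#'
#' @param path CSV file as written by [write_trace()] (or any file with
#'   columns `time_s`, `signal` and optional `replicate_id`; '#' lines
#'   are metadata).
#' @return a single `kin_trace` if the file holds one replicate,
#'   otherwise a list with `replicates` and their `average`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  body <- lines[!grepl("^#", lines)]
  d <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("time_s", "signal")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate_id" %in% names(d)) d$replicate_id <- 1L
  channel <- meta$channel %||% "mant"
  noise_sd <- as.numeric(meta$noise_sd %||% 0)
  label <- meta$construct %||% ""
  seed <- suppressWarnings(as.integer(meta$seed %||% NA))

  reps <- lapply(split(d, d$replicate_id), function(dd) {
    if (any(diff(dd$time_s) <= 0)) {
      stop("time must be strictly increasing within a replicate",
           call. = FALSE)
    }
    new_trace(dd$time_s, dd$signal, channel, noise_sd = noise_sd,
              n_replicates = 1L, seed = seed, label = label)
  })
  if (length(reps) == 1L) return(reps[[1L]])
  sig <- vapply(reps, function(tr) tr$signal, numeric(nrow(reps[[1L]])))
  avg <- new_trace(reps[[1L]]$time, rowMeans(sig), channel,
                   noise_sd = noise_sd / sqrt(length(reps)),
                   n_replicates = length(reps), seed = seed, label = label)
  list(replicates = unname(reps), average = avg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an initial-rate inhibition grid CSV
#'
#' Columns `substrate_uM`, `inhibitor_uM`, `rate`.
#'
#' @param grid an `inhibition_grid` data frame.
#' @param path CSV file.
#' @return `path` (write) or an `inhibition_grid` (read).
#' @export
write_inhibition_grid <- function(grid, path) {
  stopifnot(all(c("substrate_uM", "inhibitor_uM", "rate") %in%
                  names(grid)))
  utils::write.csv(grid[, c("substrate_uM", "inhibitor_uM", "rate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inhibition_grid
#' @export
read_inhibition_grid <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(c("substrate_uM", "inhibitor_uM", "rate"), names(d))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(d, class = c("inhibition_grid", "data.frame"))
}

#' tRNA-modification activity from nucleoside absorbance ratios
#'
#' The modified-uridine content is quantified by the mnm5s2U/s4U
#' absorbance ratio at 314 nm; activity is the ratio relative to the
#' wild-type reference, as an integer percentage (half away from zero).
#'
#' @param ratio mnm5s2U/s4U absorbance ratio of the test strain (>= 0).
#' @param reference wild-type ratio (> 0).
#' @return percent activity (integer-valued).
#' @export
#' @examples
#' modification_activity(0.007, 0.037)  # 19
modification_activity <- function(ratio, reference) {
  if (any(ratio < 0)) stop("'ratio' must be >= 0", call. = FALSE)
  .assert_scalar_num(reference, "reference", positive = TRUE)
  round_half_out(100 * ratio / reference)
}

#' Pipeline configuration
#'
#' Settings for the end-to-end simulate/generate/fit pipeline.  All
#' randomness is controlled by the explicit `seed`.
#'
#' @param constructs character vector of panel labels.
#' @param e0,t0 stopped-flow post-mix concentrations (uM).
#' @param duration,dt mant trace length and sampling interval (s).
#' @param noise_sd per-replicate optical noise SD.
#' @param n_replicates optical replicates.
#' @param quench_e0 quench-flow post-mix concentration (uM).
#' @param quench_noise_frac relative quench noise.
#' @param rise_window,decay_window fitting windows (s) for the biphasic
#'   rise and the dissociation decay.
#' @param pbp_duration Pi-sensor trace length (s).
#' @param inhibition_scan optional named list describing an inhibition
#'   scan (`inhibitor`, `kcat`, `Km`, `ki_e`, optionally `ki_es`,
#'   `s_list`, `i_list`, `noise_frac`, `Km_cellular`): a seeded grid is
#'   generated and run through [analyze_inhibition_grid()].
#' @param seed integer seed.
#' @param out_dir optional output directory; when given, the report
#'   bundle is written there as CSV/JSON plus a run log.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(constructs = "wt", e0 = 2.5, t0 = 2.5,
                            duration = 17, dt = 0.01, noise_sd = 0.003,
                            n_replicates = 6L, quench_e0 = 50,
                            quench_noise_frac = 0.02,
                            rise_window = c(0, 0.5),
                            decay_window = c(0.5, 17),
                            pbp_duration = 60, inhibition_scan = NULL,
                            seed, out_dir = NULL) {
  .assert_scalar_num(e0, "e0", positive = TRUE)
  .assert_scalar_num(t0, "t0", positive = TRUE)
  .assert_scalar_num(quench_e0, "quench_e0", positive = TRUE)
  .assert_scalar_num(duration, "duration", positive = TRUE)
  .assert_scalar_num(dt, "dt", positive = TRUE)
  if (missing(seed)) stop("'seed' must be given explicitly", call. = FALSE)
  .assert_scalar_num(seed, "seed")
  structure(list(constructs = constructs, e0 = e0, t0 = t0,
                 duration = duration, dt = dt, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 quench_e0 = quench_e0,
                 quench_noise_frac = quench_noise_frac,
                 rise_window = rise_window, decay_window = decay_window,
                 pbp_duration = pbp_duration,
                 inhibition_scan = inhibition_scan,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file holds named [pipeline_config()] arguments; the seed must be
#' present (no implicit randomness).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated [pipeline_config()].
#' @export
pipeline_config_from_file <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, fields)
}

.fit_construct <- function(label, cfg, seed_offset) {
  params <- cycle_parameters_from_profile(label)
  seed <- cfg$seed + seed_offset

  mant <- generate_traces(params, "mant", e0 = cfg$e0, t0 = cfg$t0,
                          duration = cfg$duration, dt = cfg$dt,
                          noise_sd = cfg$noise_sd,
                          n_replicates = cfg$n_replicates, seed = seed)
  rise <- suppressWarnings(
    fit_double_exponential(mant$average, window = cfg$rise_window))
  decay <- fit_single_exponential(mant$average, "decay",
                                  window = cfg$decay_window)
  quench <- generate_quench_flow(params, e0 = cfg$quench_e0,
                                 t0 = cfg$quench_e0,
                                 noise_frac = cfg$quench_noise_frac,
                                 seed = seed + 1000L)
  hyd <- fit_one_phase_decay(quench)
  pbp <- generate_traces(params, "pbp", e0 = cfg$e0, t0 = cfg$t0,
                         duration = cfg$pbp_duration, dt = cfg$dt,
                         noise_sd = cfg$noise_sd,
                         n_replicates = cfg$n_replicates,
                         seed = seed + 2000L)
  rel <- fit_single_exponential(pbp$average, "rise")

  k1 <- if (rise$model == "double_exponential")
    rise$estimates[["k_fast"]] else rise$estimates[["k"]]
  k2 <- if (rise$model == "double_exponential")
    rise$estimates[["k_slow"]] else NA_real_
  data.frame(
    construct = label,
    k_bind = k1, k_dim = k2,
    k_hyd = hyd$estimates[["k"]],
    k_diss = decay$estimates[["k"]],
    k_pi_rel = rel$estimates[["k"]],
    composite_decay = params$k_hyd < 3 * params$k_diss
  )
}

#' Run the end-to-end panel pipeline
#'
#' For each requested construct: simulate the cycle, generate seeded
#' noisy stopped-flow, quench-flow and Pi-sensor data, fit all steps
#' (biphasic rise for binding/dimerization, single-exponential decay for
#' dissociation, one-phase quench decay for hydrolysis, single
#' exponential for Pi release) and assemble a summary table with each
#' rate expressed as a percentage of the wild-type reference.  Constructs
#' whose hydrolysis rate is below 3x the dissociation rate have their
#' dissociation phase flagged as a composite of hydrolysis and
#' dissociation.  Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `summary` (data frame of fitted rates and
#'   percentages) and `config`; written to `config$out_dir` as
#'   `panel_summary.csv`, `panel_summary.json` and `run_log.txt` when an
#'   output directory is configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  panel <- mutant_panel()
  unknown <- setdiff(config$constructs, rownames(panel))
  if (length(unknown) > 0L) {
    stop("unknown construct(s) ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(rownames(panel), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_along(config$constructs), function(i) {
    .fit_construct(config$constructs[i], config, seed_offset = 10000L * i)
  })
  summary <- do.call(rbind, rows)

  ref <- summary[summary$construct == "wt", , drop = FALSE]
  if (nrow(ref) == 0L) {
    ref <- .fit_construct("wt", config, seed_offset = 0L)
  }
  for (col in c("k_bind", "k_dim", "k_hyd", "k_diss")) {
    summary[[paste0(col, "_pct")]] <- vapply(seq_len(nrow(summary)),
      function(i) {
        k <- summary[[col]][i]
        if (is.na(k) || is.na(ref[[col]][1L])) return(NA_real_)
        rate_percentages(k, ref[[col]][1L])$percent_of_reference
      }, numeric(1L))
  }

  inhibition <- NULL
  if (!is.null(config$inhibition_scan)) {
    sc <- config$inhibition_scan
    g <- generate_inhibition_grid(
      kcat = sc$kcat, e0 = sc$e0 %||% 1, Km = sc$Km,
      inhibitor = sc$inhibitor, ki_e = sc$ki_e, ki_es = sc$ki_es,
      s_list = sc$s_list, i_list = sc$i_list,
      noise_frac = sc$noise_frac %||% 0.03,
      seed = config$seed + 500000L)
    inhibition <- analyze_inhibition_grid(
      g, e0 = sc$e0 %||% 1, Km_cellular = sc$Km_cellular)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary,
                     file.path(config$out_dir, "panel_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "panel_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    writeLines(c(
      sprintf("mnmekinetics run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      sprintf("seed=%d", config$seed),
      sprintf("constructs=%s", paste(config$constructs, collapse = ",")),
      sprintf("e0=%g t0=%g duration=%g dt=%g noise_sd=%g n_replicates=%d",
              config$e0, config$t0, config$duration, config$dt,
              config$noise_sd, config$n_replicates)
    ), file.path(config$out_dir, "run_log.txt"))
    if (!is.null(inhibition)) {
      write_inhibition_result(
        inhibition, file.path(config$out_dir, "inhibition_result.json"))
    }
  }
  list(summary = summary, inhibition = inhibition, config = config)
}
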