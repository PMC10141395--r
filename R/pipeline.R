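#' Analyse a set of replicate recordings
#'
#' Runs the full per-replicate analysis (analysis-window extraction, MFDFA,
#' singularity spectrum, summary descriptors) on a set of recordings sharing
#' one condition, then aggregates across replicates: pointwise mean and
#' sample standard deviation (denominator n - 1) of H(q) over the q grid, and
#' mean/sd of both spectrum-width conventions and of the left-endpoint
#' coordinates. With a single successful replicate the standard deviations
#' are `NA`, not 0. Replicates whose analysis fails are excluded and counted.
#'
#' @param recordings list of [recording()]s sharing condition and voltage.
#' @param condition condition label for the set; default taken from the
#'   first recording.
#' @param window `TRUE` to apply [extract_analysis_window()] with the
#'   arguments in `window_args`; `FALSE` to analyse the full trace.
#' @param window_args list of arguments for [extract_analysis_window()].
#' @param ... further arguments passed to [mfdfa()] (q grid, scales, order,
#'   fit range).
#' @return an object of class `"replicate_set"`: a list with per-replicate
#'   fits (`fits`, `spectra`, `summaries`), the H(q) matrix
#'   (`hq`, replicates by q), aggregates (`mean_H`, `sd_H`, data frame
#'   `aggregate` of width/endpoint statistics), `n_replicates`, `n_failed`,
#'   `failures`, `condition`, `voltage_mV`.
#' @export
analyze_replicates <- function(recordings, condition = NULL,
                               window = TRUE, window_args = list(), ...) {
  if (!length(recordings)) stop("no recordings supplied", call. = FALSE)
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  stopifnot(all(vapply(recordings, inherits, logical(1), "recording")))
  if (is.null(condition)) condition <- recordings[[1L]]$condition
  fits <- list(); spectra <- list(); summaries <- list(); failures <- list()
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    res <- tryCatch({
      x <- if (window) {
        do.call(extract_analysis_window, c(list(r), window_args))
      } else {
        r$current
      }
      fit <- mfdfa(x, ...)
      spec <- singularity_spectrum(fit)
      list(fit = fit, spec = spec, summ = spectrum_summary(spec))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(replicate = r$replicate, message = conditionMessage(res))
    } else {
      k <- length(fits) + 1L
      fits[[k]] <- res$fit
      spectra[[k]] <- res$spec
      summaries[[k]] <- res$summ
    }
  }
  if (!length(fits)) {
    stop("no replicate completed analysis for condition '", condition, "'",
         call. = FALSE)
  }
  qgrid <- fits[[1L]]$q
  hq <- do.call(rbind, lapply(fits, function(f) f$hurst$H))
  colnames(hq) <- format(qgrid, trim = TRUE)
  n_ok <- nrow(hq)
  sd_or_na <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
  metrics <- vapply(summaries, function(s) {
    c(width_alpha = s$width_alpha, width_H = s$width_H,
      endpoint_alpha = s$endpoint_alpha, endpoint_f = s$endpoint_f)
  }, numeric(4))
  aggregate <- data.frame(
    metric = rownames(metrics),
    mean = rowMeans(metrics),
    sd = apply(metrics, 1L, sd_or_na),
    row.names = NULL
  )
  structure(
    list(condition = condition,
         voltage_mV = recordings[[1L]]$voltage_mV,
         q = qgrid,
         fits = fits, spectra = spectra, summaries = summaries,
         hq = hq,
         mean_H = colMeans(hq),
         sd_H = if (n_ok > 1L) apply(hq, 2L, stats::sd) else
           stats::setNames(rep(NA_real_, ncol(hq)), colnames(hq)),
         aggregate = aggregate,
         n_replicates = n_ok,
         n_failed = length(failures),
         failures = failures),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set '%s' (U = %s mV): %d replicate(s) analysed",
              x$condition, format(x$voltage_mV), x$n_replicates))
  if (x$n_failed > 0) cat(sprintf(", %d failed", x$n_failed))
  cat("\n")
  print(format(x$aggregate, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Condition summary tables
#'
#' Collapses a list of replicate sets into the two summary tables used to
#' compare conditions: (a) a width table with the mean and sample standard
#' deviation of both spectrum-width conventions per condition, and (b) an
#' endpoint table with the mean coordinates of the left-hand final point of
#' the singularity spectrum. Rows keep the input order; a condition with a
#' single replicate reports `NA` standard deviations.
#'
#' @param sets list of `"replicate_set"` objects.
#' @return an object of class `"condition_tables"`: list of data frames
#'   `width` (condition, n, mean_width_H, sd_width_H, mean_width_alpha,
#'   sd_width_alpha) and `endpoint` (condition, endpoint_alpha, endpoint_f).
#' @export
build_condition_tables <- function(sets) {
  if (inherits(sets, "replicate_set")) sets <- list(sets)
  if (!length(sets)) stop("no replicate sets supplied", call. = FALSE)
  stopifnot(all(vapply(sets, inherits, logical(1), "replicate_set")))
  get_stat <- function(s, metric, col) {
    s$aggregate[s$aggregate$metric == metric, col]
  }
  width <- data.frame(
    condition = vapply(sets, function(s) as.character(s$condition), ""),
    n = vapply(sets, function(s) s$n_replicates, 0L),
    mean_width_H = vapply(sets, get_stat, 0, "width_H", "mean"),
    sd_width_H = vapply(sets, get_stat, 0, "width_H", "sd"),
    mean_width_alpha = vapply(sets, get_stat, 0, "width_alpha", "mean"),
    sd_width_alpha = vapply(sets, get_stat, 0, "width_alpha", "sd")
  )
  endpoint <- data.frame(
    condition = width$condition,
    endpoint_alpha = vapply(sets, get_stat, 0, "endpoint_alpha", "mean"),
    endpoint_f = vapply(sets, get_stat, 0, "endpoint_f", "mean")
  )
  structure(list(width = width, endpoint = endpoint),
            class = "condition_tables")
}

#' @export
print.condition_tables <- function(x, ...) {
  cat("Singularity spectrum width by condition (mean / sd over replicates):\n")
  print(format(x$width, digits = 4), row.names = FALSE)
  cat("\nLeft-hand final point of the singularity spectrum:\n")
  print(format(x$endpoint, digits = 4), row.names = FALSE)
  invisible(x)
}

# Plausible voltage dependence for a fast-activating vacuolar channel:
# nearly silent at the -40 mV holding potential, increasingly active at
# large potentials of either polarity, current sign following the voltage.
default_gating_for_voltage <- function(voltage_mV, dt = 5e-5) {
  gating_spec(
    open_rate = 8 * exp(abs(voltage_mV) / 45),
    close_rate = 220,
    unitary_current = sign(voltage_mV) * 1e-12,
    baseline_current = 0,
    noise_sd = 0.2e-12,
    n_channels = 2L,
    dt = dt
  )
}

# Simulate one protocol sweep for a condition. `memory_a` injects long-range
# correlated, multifractal structure by modulating the Gaussian noise with
# binomial-cascade weights (branch-shuffled, normalised to unit RMS): the
# noise becomes noise_sd * w_t * z_t, whose multifractal spectrum widens as
# `a` moves away from 0.5.
simulate_condition_recording <- function(p, g_test, replicate, condition,
                                         incubation_min = NA_real_,
                                         memory_a = NULL, seed = NULL) {
  g_hold <- default_gating_for_voltage(p$holding_voltage, dt = p$dt)
  if (is.null(memory_a)) {
    return(assemble_protocol_recording(p, g_hold, g_test,
                                       replicate = replicate,
                                       condition = condition,
                                       incubation_min = incubation_min,
                                       seed = seed))
  }
  with_seed(seed, {
    g_test_quiet <- g_test
    g_test_quiet$noise_sd <- 0
    g_hold_quiet <- g_hold
    g_hold_quiet$noise_sd <- 0
    r <- assemble_protocol_recording(p, g_hold_quiet, g_test_quiet,
                                     replicate = replicate,
                                     condition = condition,
                                     incubation_min = incubation_min,
                                     seed = NULL)
    n <- length(r$current)
    k <- ceiling(log2(n))
    w <- simulate_cascade(memory_a, k, shuffle = TRUE, seed = NULL)[seq_len(n)]
    w <- w / sqrt(mean(w^2))
    r$current <- r$current + g_test$noise_sd * w * stats::rnorm(n)
    r
  })
}

#' Run the full voltage- or incubation-series study on simulated recordings
#'
#' End-to-end protocol analysis on freshly simulated recordings: for every
#' condition, simulate `n_replicates` voltage-step sweeps, extract the
#' analysis window, run MFDFA and the singularity spectrum per replicate,
#' aggregate mean/sd curves, and build the condition summary tables. A single
#' `master_seed` determines every simulated sample and hence every output
#' number. Two study designs are built in:
#'
#' * `arm = "voltage"`: one condition per test potential (default the six
#'   potentials of the protocol set), gating kinetics following a plausible
#'   voltage dependence;
#' * `arm = "incubation"`: all conditions at one test potential (default
#'   -100 mV), one condition per incubation label; `memory_a` (one value per
#'   condition) injects a condition-dependent multifractal noise component.
#'
#' @param arm study design (see above).
#' @param voltages test potentials for the voltage arm.
#' @param incubation_min incubation labels (minutes) for the incubation arm;
#'   `NA` denotes the control bath.
#' @param test_voltage test potential used by the incubation arm.
#' @param n_replicates sweeps per condition.
#' @param master_seed integer seed controlling all simulations.
#' @param memory_a optional numeric vector (one per condition) of
#'   cascade-asymmetry parameters injecting multifractal noise; `NA` entries
#'   leave the plain Gaussian noise.
#' @param gating optional function `(voltage_mV, dt)` returning the
#'   test-phase [gating_spec()] per condition, replacing the built-in
#'   voltage dependence.
#' @param dt sampling interval, seconds.
#' @param out_dir optional directory: when given, curves, tables and a JSON
#'   run manifest are written as tab-separated text via
#'   [write_result_bundle()].
#' @param ... further arguments passed to [analyze_replicates()] (and on to
#'   [mfdfa()]).
#' @return an object of class `"protocol_study"`: list with `sets` (one
#'   `"replicate_set"` per condition), `tables` (a `"condition_tables"`),
#'   and `config` (every parameter and derived seed).
#' @examples
#' \donttest{
#' study <- run_protocol_study(arm = "voltage", voltages = c(-100, 100),
#'                             n_replicates = 2, master_seed = 1,
#'                             n_min = 16, n_scales = 12)
#' study$tables
#' }
#' @export
run_protocol_study <- function(arm = c("voltage", "incubation"),
                               voltages = c(-100, -80, -60, 60, 80, 100),
                               incubation_min = c(NA, 0, 5, 10, 15, 20, 25, 30),
                               test_voltage = -100,
                               n_replicates = 5L,
                               master_seed = 1L,
                               memory_a = NULL,
                               gating = NULL,
                               dt = 5e-5,
                               out_dir = NULL,
                               ...) {
  arm <- match.arg(arm)
  if (is.null(gating)) gating <- default_gating_for_voltage
  conditions <- if (arm == "voltage") {
    data.frame(label = paste0(voltages, " mV"), voltage = voltages,
               incubation = NA_real_)
  } else {
    data.frame(
      label = ifelse(is.na(incubation_min), "control",
                     paste0("IAA ", incubation_min, " min")),
      voltage = test_voltage,
      incubation = incubation_min
    )
  }
  if (!is.null(memory_a) && length(memory_a) != nrow(conditions)) {
    stop("`memory_a` must have one entry per condition", call. = FALSE)
  }
  sets <- vector("list", nrow(conditions))
  seeds <- matrix(NA_integer_, nrow(conditions), n_replicates)
  for (ci in seq_len(nrow(conditions))) {
    voltage <- conditions$voltage[ci]
    p <- protocol_spec(test_voltage = voltage, dt = dt,
                       n_replicates = n_replicates)
    g_test <- gating(voltage, dt)
    mem <- if (!is.null(memory_a) && !is.na(memory_a[ci])) memory_a[ci]
    recs <- vector("list", n_replicates)
    for (ri in seq_len(n_replicates)) {
      seeds[ci, ri] <- derive_seed(master_seed, ci, ri)
      recs[[ri]] <- simulate_condition_recording(
        p, g_test, replicate = ri, condition = conditions$label[ci],
        incubation_min = conditions$incubation[ci],
        memory_a = mem, seed = seeds[ci, ri]
      )
    }
    sets[[ci]] <- analyze_replicates(recs, condition = conditions$label[ci],
                                     ...)
  }
  tables <- build_condition_tables(sets)
  config <- list(arm = arm, conditions = conditions,
                 n_replicates = n_replicates, master_seed = master_seed,
                 memory_a = memory_a, dt = dt, seeds = seeds,
                 mfdfa_args = list(...))
  study <- structure(list(sets = sets, tables = tables, config = config),
                     class = "protocol_study")
  if (!is.null(out_dir)) write_result_bundle(study, out_dir)
  study
}

#' @export
print.protocol_study <- function(x, ...) {
  cat(sprintf("Protocol study (%s arm): %d condition(s) x %d replicate(s)\n\n",
              x$config$arm, length(x$sets), x$config$n_replicates))
  print(x$tables)
  invisible(x)
}
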