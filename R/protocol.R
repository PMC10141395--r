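#' Voltage-step protocol parameters
#'
#' Describes the voltage-step acquisition protocol: a holding phase at the
#' holding potential followed by a step to one test potential. The defaults
#' match a 0.5 s hold at -40 mV followed by 3.5 s at the test potential,
#' sampled every 5e-5 s, which gives exactly 80,000 samples per sweep, with
#' five replicate sweeps per test potential.
#'
#' @param test_voltage test-phase potential, millivolts; must belong to
#'   `voltage_set` when protocol checking is on.
#' @param holding_voltage holding potential, millivolts.
#' @param holding_duration holding-phase duration, seconds.
#' @param test_duration test-phase duration, seconds.
#' @param dt sampling interval, seconds.
#' @param n_replicates replicate sweeps per condition.
#' @param voltage_set admissible test potentials, millivolts; set to `NULL`
#'   to disable the membership check.
#' @return an object of class `"protocol_spec"`.
#' @examples
#' p <- protocol_spec(test_voltage = -100)
#' p$n_samples  # 80000
#' @export
protocol_spec <- function(test_voltage,
                          holding_voltage = -40,
                          holding_duration = 0.5,
                          test_duration = 3.5,
                          dt = 5e-5,
                          n_replicates = 5L,
                          voltage_set = c(-100, -80, -60, 60, 80, 100)) {
  if (holding_duration < 0 || test_duration <= 0 || dt <= 0) {
    stop("durations must be non-negative and `dt` > 0", call. = FALSE)
  }
  if (!is.null(voltage_set) && !(test_voltage %in% voltage_set)) {
    stop("`test_voltage` ", test_voltage, " mV is not in the protocol set {",
         paste(voltage_set, collapse = ", "), "}", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  n_hold <- as.integer(round(holding_duration / dt))
  n_test <- as.integer(round(test_duration / dt))
  structure(
    list(test_voltage = test_voltage, holding_voltage = holding_voltage,
         holding_duration = holding_duration, test_duration = test_duration,
         dt = dt, n_replicates = as.integer(n_replicates),
         voltage_set = voltage_set,
         n_holding = n_hold, n_test = n_test, n_samples = n_hold + n_test),
    class = "protocol_spec"
  )
}

#' Assemble a protocol-shaped recording from gating simulations
#'
#' Concatenates a holding-phase current and a test-phase current, each drawn
#' from its own two-state gating model, into a single voltage-step sweep with
#' full metadata. With the default protocol the result has exactly 80,000
#' samples (4.0 s at 5e-5 s).
#'
#' @param p a [protocol_spec()].
#' @param g_holding,g_test [gating_spec()]s for the holding and test phases;
#'   both must share `dt` with the protocol.
#' @param replicate replicate identifier stored in the metadata.
#' @param condition condition label stored in the metadata.
#' @param incubation_min incubation time (minutes) stored in the metadata.
#' @param seed integer seed; one seed determines the whole sweep.
#' @return a [recording()].
#' @examples
#' p <- protocol_spec(test_voltage = 100)
#' g_hold <- gating_spec(open_rate = 2, close_rate = 400)
#' g_test <- gating_spec(open_rate = 80, close_rate = 160)
#' r <- assemble_protocol_recording(p, g_hold, g_test, replicate = 1, seed = 1)
#' length(r$current)
#' @export
assemble_protocol_recording <- function(p, g_holding, g_test,
                                        replicate = 1L,
                                        condition = "control",
                                        incubation_min = NA_real_,
                                        seed = NULL) {
  stopifnot(inherits(p, "protocol_spec"),
            inherits(g_holding, "gating_spec"),
            inherits(g_test, "gating_spec"))
  if (g_holding$dt != p$dt || g_test$dt != p$dt) {
    stop("gating specs must share `dt` with the protocol (", p$dt, " s)",
         call. = FALSE)
  }
  current <- with_seed(seed, {
    hold <- if (p$n_holding > 0) {
      simulate_channel_current(g_holding, p$n_holding)
    } else {
      numeric(0)
    }
    test <- simulate_channel_current(g_test, p$n_test)
    c(hold, test)
  })
  recording(current, dt = p$dt, voltage_mV = p$test_voltage,
            replicate = replicate, condition = condition,
            incubation_min = incubation_min,
            extra = list(holding_voltage_mV = p$holding_voltage,
                         holding_duration_s = p$holding_duration,
                         test_duration_s = p$test_duration))
}
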