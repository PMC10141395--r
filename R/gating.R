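#' Parameters of a two-state channel-gating simulator
#'
#' Bundles the kinetic and amplitude parameters of a closed/open two-state
#' Markov gating model for one or more identical, independent channels in a
#' patch. Defaults are order-of-magnitude plausible for single-channel
#' recordings: unitary current 1 pA and baseline noise 0.2 pA over a 5e-5 s
#' sampling interval.
#'
#' @param open_rate closed -> open transition rate, per second (>= 0).
#' @param close_rate open -> closed transition rate, per second (> 0).
#' @param unitary_current current carried by one open channel, amperes.
#' @param baseline_current patch baseline (leak) current, amperes.
#' @param noise_sd standard deviation of additive Gaussian recording noise,
#'   amperes (>= 0).
#' @param n_channels number of independent channels in the patch.
#' @param dt sampling interval, seconds.
#' @return an object of class `"gating_spec"` (a named list).
#' @examples
#' g <- gating_spec(open_rate = 50, close_rate = 150)
#' g$open_rate / (g$open_rate + g$close_rate)  # stationary open probability
#' @export
gating_spec <- function(open_rate, close_rate,
                        unitary_current = 1e-12,
                        baseline_current = 0,
                        noise_sd = 0.2e-12,
                        n_channels = 1L,
                        dt = 5e-5) {
  if (!is.numeric(open_rate) || open_rate < 0) {
    stop("`open_rate` must be >= 0 (per second)", call. = FALSE)
  }
  if (!is.numeric(close_rate) || close_rate <= 0) {
    stop("`close_rate` must be > 0 (per second)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_channels < 1 || n_channels != round(n_channels)) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be > 0 (seconds)", call. = FALSE)
  structure(
    list(open_rate = open_rate, close_rate = close_rate,
         unitary_current = unitary_current,
         baseline_current = baseline_current,
         noise_sd = noise_sd, n_channels = as.integer(n_channels), dt = dt),
    class = "gating_spec"
  )
}

# One channel's 0/1 state sequence, built dwell-by-dwell. Per-sample switching
# probabilities 1 - exp(-rate * dt) make discrete dwells geometric; the chain
# is unconditionally stable for any dt but biased when dt * rate is large.
simulate_gating_states <- function(open_rate, close_rate, dt, n_samples) {
  p_open <- 1 - exp(-open_rate * dt)   # closed -> open per step
  p_close <- 1 - exp(-close_rate * dt) # open -> closed per step
  p_stat <- open_rate / (open_rate + close_rate)
  state <- as.integer(stats::runif(1) < p_stat)
  lengths <- integer(0)
  values <- integer(0)
  total <- 0L
  while (total < n_samples) {
    p_leave <- if (state == 1L) p_close else p_open
    if (p_leave <= 0) {
      dwell <- n_samples - total  # absorbing state
    } else {
      dwell <- 1L + stats::rgeom(1L, p_leave)
    }
    dwell <- min(dwell, n_samples - total)
    lengths <- c(lengths, dwell)
    values <- c(values, state)
    total <- total + dwell
    state <- 1L - state
  }
  inverse.rle(list(lengths = lengths, values = values))
}

#' Simulate a single-channel patch-clamp current trace
#'
#' Samples `n_channels` independent two-state (closed/open) continuous-time
#' Markov channels at interval `dt` and returns the summed patch current:
#' baseline + (number open) x unitary current + Gaussian recording noise.
#' Per-sample transition probabilities are `1 - exp(-rate * dt)`, so discrete
#' dwell times are geometric approximations of the exponential dwell-time
#' distributions of the continuous-time chain.
#'
#' @param g a [gating_spec()].
#' @param n_samples number of current samples to generate (>= 1).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return numeric vector of `n_samples` current values (amperes).
#' @examples
#' g <- gating_spec(open_rate = 50, close_rate = 150)
#' i <- simulate_channel_current(g, n_samples = 2000, seed = 1)
#' mean(i) / g$unitary_current  # ~ stationary open probability
#' @export
simulate_channel_current <- function(g, n_samples, seed = NULL) {
  stopifnot(inherits(g, "gating_spec"))
  if (!is.numeric(n_samples) || n_samples < 1 || n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (g$dt * max(g$open_rate, g$close_rate) > 0.1) {
    warning("dt * rate exceeds 0.1; discrete-time gating is biased at this ",
            "resolution", call. = FALSE)
  }
  with_seed(seed, {
    n_open <- integer(n_samples)
    for (ch in seq_len(g$n_channels)) {
      n_open <- n_open +
        simulate_gating_states(g$open_rate, g$close_rate, g$dt, n_samples)
    }
    current <- g$baseline_current + n_open * g$unitary_current
    if (g$noise_sd > 0) {
      current <- current + stats::rnorm(n_samples, sd = g$noise_sd)
    }
    current
  })
}
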