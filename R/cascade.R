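#' Simulate a binomial multiplicative cascade
#'
#' Builds the deterministic binomial measure on 2^k cells: starting from unit
#' mass, each interval is split in two, the left half receiving fraction `a`
#' of the mass and the right half `1 - a`, repeated `k` levels. For
#' `a != 0.5` the result is the textbook multifractal benchmark, with the
#' closed-form generalised Hurst exponent of [cascade_hurst()]. With
#' `shuffle = TRUE` the left/right assignment of each individual split is
#' randomised; this changes the spatial arrangement but not the multiset of
#' cell masses, so H(q) is invariant.
#'
#' @param a mass fraction assigned to the left child, in (0, 1).
#' @param k number of splitting levels (>= 1); output length is `2^k`.
#' @param shuffle randomise the branch orientation of each split.
#' @param seed integer seed for the shuffled variant; ignored when
#'   `shuffle = FALSE` (the canonical cascade is deterministic).
#' @return numeric vector of length `2^k`, positive, summing to 1.
#' @examples
#' w <- simulate_cascade(a = 0.75, k = 10)
#' sum(w)  # mass is conserved
#' @export
simulate_cascade <- function(a, k, shuffle = FALSE, seed = NULL) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1) {
    stop("`a` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  build <- function() {
    w <- 1
    for (level in seq_len(k)) {
      len <- length(w)
      left <- if (shuffle) stats::runif(len) < 0.5 else rep(TRUE, len)
      mult_left <- ifelse(left, a, 1 - a)
      out <- numeric(2L * len)
      out[seq(1L, 2L * len, by = 2L)] <- mult_left * w
      out[seq(2L, 2L * len, by = 2L)] <- (1 - mult_left) * w
      w <- out
    }
    w
  }
  if (shuffle) with_seed(seed, build()) else build()
}

#' Closed-form generalised Hurst exponent of the binomial cascade
#'
#' For the binomial multiplicative cascade with parameter `a`, the generalised
#' Hurst exponent is
#' \deqn{H(q) = \frac{1}{q} - \frac{\log_2(a^q + (1-a)^q)}{q}, \quad q \ne 0,}
#' with the continuous limit \eqn{H(0) = -(\log_2 a + \log_2(1-a))/2}.
#' This is the analytic oracle against which MFDFA estimates are validated.
#'
#' @param q numeric vector of moment orders.
#' @param a cascade parameter in (0, 1).
#' @return numeric vector H(q).
#' @seealso [cascade_alpha()] for the analytic Hoelder exponent.
#' @export
cascade_hurst <- function(q, a) {
  stopifnot(a > 0, a < 1)
  h <- numeric(length(q))
  nz <- q != 0
  h[nz] <- (1 - log2(a^q[nz] + (1 - a)^q[nz])) / q[nz]
  h[!nz] <- -(log2(a) + log2(1 - a)) / 2
  h
}

#' Closed-form Hoelder exponent of the binomial cascade
#'
#' Analytic \eqn{\alpha(q) = H(q) + q\,dH/dq} for the binomial cascade:
#' \deqn{\alpha(q) = -\frac{a^q \ln a + (1-a)^q \ln(1-a)}{(a^q + (1-a)^q)\ln 2}.}
#'
#' @inheritParams cascade_hurst
#' @return numeric vector alpha(q).
#' @export
cascade_alpha <- function(q, a) {
  stopifnot(a > 0, a < 1)
  -(a^q * log(a) + (1 - a)^q * log(1 - a)) / ((a^q + (1 - a)^q) * log(2))
}
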