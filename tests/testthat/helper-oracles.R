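# Independent oracles used across the suite.
#
# naive_* is a deliberately plain MFDFA written with explicit loops over
# segments, scales and moment orders, fitting each segment trend with
# lm.fit. It shares no code with the package internals and serves as the
# brute-force reference the optimised implementation must agree with.

naive_segment_f2 <- function(Y, n, order) {
  N <- length(Y)
  M <- N %/% n
  f2 <- numeric(2 * M)
  X <- outer(seq_len(n), 0:order, `^`)
  for (v in seq_len(M)) {
    idx <- ((v - 1) * n + 1):(v * n)
    r <- lm.fit(X, Y[idx])$residuals
    f2[v] <- sum(r^2) / n
  }
  for (v in seq_len(M)) {
    idx <- (N - v * n + 1):(N - (v - 1) * n)
    r <- lm.fit(X, Y[idx])$residuals
    f2[M + v] <- sum(r^2) / n
  }
  f2
}

naive_fq_matrix <- function(x, q, scales, order) {
  Y <- cumsum(x - mean(x))
  fq <- matrix(NA_real_, length(q), length(scales))
  for (s in seq_along(scales)) {
    f2 <- naive_segment_f2(Y, scales[s], order)
    for (k in seq_along(q)) {
      qi <- q[k]
      if (qi == 0) {
        fq[k, s] <- exp(0.5 * mean(log(f2[f2 > 0])))
      } else if (qi < 0) {
        fq[k, s] <- mean(f2[f2 > 0]^(qi / 2))^(1 / qi)
      } else {
        fq[k, s] <- mean(f2^(qi / 2))^(1 / qi)
      }
    }
  }
  fq
}

# Frozen closed-form values for the binomial cascade, evaluated by hand from
# H(q) = [1 - log2(a^q + (1-a)^q)]/q and alpha(q) = -(a^q ln a +
# (1-a)^q ln(1-a)) / ((a^q + (1-a)^q) ln 2) at a = 0.75:
#   H(2)      = 0.5 - log2(0.625)/2          = 0.8390360
#   alpha(0)  = -(log2(0.75) + log2(0.25))/2 = 1.2075187
#   alpha(-6) - alpha(6)                     = 1.5806187
CASCADE75_H2 <- 0.8390360
CASCADE75_ALPHA0 <- 1.2075187
CASCADE75_DALPHA_Q6 <- 1.5806187

# H(q) width over the default grid from a fitted mfdfa object.
hq_width <- function(fit) {
  h <- coef(fit)
  max(h) - min(h)
}
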