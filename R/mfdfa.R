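#' Integrated signal profile
#'
#' Cumulative sum of the mean-subtracted series,
#' \eqn{Y_j = \sum_{i \le j} (x_i - \langle x \rangle)}. Detrended
#' fluctuation analysis always operates on this profile rather than on the
#' raw series; by construction the last profile value is zero up to rounding.
#'
#' @param x numeric vector of at least 2 finite samples, or a [recording()].
#' @return numeric vector of profile values, same length as the input.
#' @examples
#' compute_profile(c(1, 2, 3))  # -1 -1 0
#' @export
compute_profile <- function(x) {
  if (inherits(x, "recording")) x <- x$current
  if (!is.numeric(x) || length(x) < 2L) {
    stop("input series must be numeric with length >= 2", call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad)) {
    stop("non-finite sample at index ", bad[1L], call. = FALSE)
  }
  cumsum(x - mean(x))
}

#' Build a logarithmic grid of segment lengths
#'
#' Returns approximately `n_scales` unique integer scales, logarithmically
#' spaced over `[n_min, n_max]`. At each scale `n` the profile is divided
#' into `floor(N/n)` disjoint segments from the start and the same number
#' from the end, giving `2 * floor(N/n)` segments in total. The default
#' maximum `floor(N/4)` keeps at least four forward segments at the largest
#' scale; the minimum must exceed the number of detrending parameters.
#'
#' @param N series length.
#' @param n_min smallest scale (>= `order + 2`).
#' @param n_max largest scale; default `floor(N/4)`.
#' @param n_scales requested number of scales.
#' @param order detrending polynomial order (used only to validate `n_min`).
#' @return integer vector of strictly increasing scales.
#' @export
build_scale_grid <- function(N, n_min = 16L, n_max = NULL, n_scales = 30L,
                             order = 1L) {
  if (is.null(n_max)) n_max <- floor(N / 4)
  if (n_min < order + 2) {
    stop("`n_min` must be >= order + 2 = ", order + 2,
         " (detrending needs more points than parameters)", call. = FALSE)
  }
  if (n_max > N) stop("`n_max` exceeds the series length", call. = FALSE)
  if (n_min >= n_max) {
    stop("`n_min` must be smaller than `n_max` (N = ", N,
         " may be too short)", call. = FALSE)
  }
  scales <- unique(round(exp(seq(log(n_min), log(n_max),
                                 length.out = n_scales))))
  as.integer(scales)
}

# Residual-variance of every segment at one scale: QR-detrend all forward and
# backward segments at once. Column order: forward segments 1..M from the
# start, then backward segments numbered from the series end inward.
segment_variances_at_scale <- function(Y, n, order) {
  N <- length(Y)
  M <- N %/% n
  fwd <- matrix(Y[seq_len(M * n)], nrow = n)
  bwd <- matrix(Y[seq.int(N - M * n + 1L, N)], nrow = n)
  bwd <- bwd[, rev(seq_len(M)), drop = FALSE]  # numbered from the end
  X <- outer(seq_len(n), 0:order, `^`)
  qr_x <- qr(X)
  res <- qr.resid(qr_x, cbind(fwd, bwd))
  colMeans(res^2)
}

#' Detrended variance of the profile segments at one scale
#'
#' Fits a least-squares polynomial of order `order` to each length-`n`
#' segment of the profile (forward segments from the start, backward segments
#' from the end) and returns the mean squared residual of every segment.
#'
#' @param profile numeric profile, as returned by [compute_profile()].
#' @param n segment length (scale); must satisfy `n > order + 1`.
#' @param order detrending polynomial order (>= 0).
#' @return numeric vector of `2 * floor(N/n)` segment variances; forward
#'   segments first, then backward segments ordered from the series end.
#' @examples
#' segment_variances(c(0, 1, 0), n = 3, order = 1)  # 2/9 twice
#' @export
segment_variances <- function(profile, n, order = 1L) {
  N <- length(profile)
  if (n <= order + 1) {
    stop("scale n = ", n, " cannot support order-", order,
         " detrending (need n > order + 1)", call. = FALSE)
  }
  if (n > N) stop("scale n = ", n, " exceeds the profile length", call. = FALSE)
  segment_variances_at_scale(profile, as.integer(n), as.integer(order))
}

#' q-th-order fluctuation function at one scale
#'
#' Collapses the segment variances at one scale into the fluctuation
#' function:
#' \deqn{F_q(n) = \left\{\frac{1}{2M_n}\sum_\nu [F^2(\nu,n)]^{q/2}\right\}^{1/q},
#' \quad q \ne 0,}
#' and for \eqn{q = 0} the logarithmic average
#' \eqn{F_0(n) = \exp\{\tfrac{1}{4M_n}\sum_\nu \ln F^2(\nu,n)\}}.
#' Segments with exactly zero variance would make non-positive moments
#' infinite; they are excluded from the average for `q <= 0` and their count
#' is reported via the `"n_zero_excluded"` attribute.
#'
#' @param f2 numeric vector of segment variances (all >= 0).
#' @param q numeric vector of moment orders (may include 0).
#' @return numeric vector `F_q(n)`, one value per `q`, with attribute
#'   `"n_zero_excluded"`.
#' @examples
#' fluctuation_function(c(1, 4), q = c(-2, 0, 2))
#' @export
fluctuation_function <- function(f2, q) {
  if (any(f2 < 0)) stop("segment variances must be >= 0", call. = FALSE)
  pos <- f2 > 0
  if (!any(pos)) {
    stop("series is locally deterministic at this scale: ",
         "all segment variances are zero", call. = FALSE)
  }
  n_zero <- sum(!pos)
  out <- vapply(q, function(qi) {
    if (qi == 0) {
      exp(0.5 * mean(log(f2[pos])))
    } else if (qi < 0) {
      mean(f2[pos]^(qi / 2))^(1 / qi)
    } else {
      mean(f2^(qi / 2))^(1 / qi)
    }
  }, numeric(1))
  attr(out, "n_zero_excluded") <- n_zero
  out
}

#' Fit the generalised Hurst exponent from the fluctuation matrix
#'
#' For each moment order q, regresses `log F_q(n)` on `log n` by ordinary
#' least squares over the fitting scale range; the slope is the generalised
#' Hurst exponent H(q) and the coefficient of determination diagnoses how
#' well the fluctuations follow a power law.
#'
#' @param fq numeric matrix of fluctuation values, `length(q)` rows by
#'   `length(scales)` columns.
#' @param scales integer vector of scales (columns of `fq`).
#' @param q numeric vector of moment orders (rows of `fq`).
#' @param fit_range optional `c(min, max)` restricting the scales used in the
#'   fit; default uses every scale.
#' @return data frame with columns `q`, `H`, `intercept`, `r_squared`.
#' @export
estimate_hurst <- function(fq, scales, q, fit_range = NULL) {
  fq <- matrix(fq, nrow = length(q))
  use <- rep(TRUE, length(scales))
  if (!is.null(fit_range)) {
    use <- scales >= fit_range[1L] & scales <= fit_range[2L]
  }
  if (sum(use) < 3L) {
    stop("fewer than 3 scales in the fitting range", call. = FALSE)
  }
  if (any(!is.finite(fq[, use])) || any(fq[, use] <= 0)) {
    stop("fluctuation values must be finite and positive in the fitting range",
         call. = FALSE)
  }
  lx <- log(scales[use])
  lx_c <- lx - mean(lx)
  denom <- sum(lx_c^2)
  fit_one <- function(ly) {
    slope <- sum(lx_c * (ly - mean(ly))) / denom
    intercept <- mean(ly) - slope * mean(lx)
    ss_res <- sum((ly - intercept - slope * lx)^2)
    ss_tot <- sum((ly - mean(ly))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    c(slope, intercept, r2)
  }
  coefs <- t(apply(log(fq[, use, drop = FALSE]), 1L, fit_one))
  data.frame(q = q, H = coefs[, 1L], intercept = coefs[, 2L],
             r_squared = coefs[, 3L])
}

#' Multifractal detrended fluctuation analysis
#'
#' Runs the complete MFDFA estimator on a time series: integrated profile,
#' bidirectional segmentation at each scale, polynomial detrending, q-th-order
#' fluctuation functions and the log-log power-law fit giving the generalised
#' Hurst exponent H(q). For a monofractal series H(q) is constant in q; a
#' q-dependent H(q) signals multifractality, quantified further by the
#' singularity spectrum ([singularity_spectrum()]).
#'
#' @param x numeric series (length >= 2, finite) or a [recording()].
#' @param q moment orders; the default grid -6..6 in steps of 0.25 includes
#'   q = 0, which is handled by logarithmic averaging.
#' @param scales integer scale grid; default built by [build_scale_grid()].
#' @param n_min,n_max,n_scales passed to [build_scale_grid()] when `scales`
#'   is `NULL`.
#' @param order detrending polynomial order; 1 (linear detrending) is
#'   standard practice.
#' @param fit_range optional `c(min, max)` scale range for the H(q) fit;
#'   inspect `r_squared` per q to decide whether to restrict it.
#' @return an object of class `"mfdfa"`: a list with elements
#'   `hurst` (data frame `q`, `H`, `intercept`, `r_squared`),
#'   `fq` (fluctuation matrix, q by scale), `scales`, `q`,
#'   `segments` (2 M_n per scale), `zero_excluded` (zero-variance segments
#'   dropped per scale for q <= 0), `order`, `fit_range`, `N` and `call`.
#'   Methods: [print.mfdfa()], [summary.mfdfa()], [coef.mfdfa()],
#'   [plot.mfdfa()], [residuals.mfdfa()].
#' @examples
#' x <- simulate_fgn(hurst = 0.7, n = 4096, seed = 1)
#' fit <- mfdfa(x, n_min = 16, n_scales = 20)
#' coef(fit)[c("-2", "0", "2")]
#' @export
mfdfa <- function(x, q = seq(-6, 6, by = 0.25), scales = NULL,
                  n_min = 16L, n_max = NULL, n_scales = 30L,
                  order = 1L, fit_range = NULL) {
  cl <- match.call()
  if (inherits(x, "recording")) x <- x$current
  if (length(q) < 1L || is.unsorted(q, strictly = TRUE)) {
    stop("`q` must be a non-empty strictly increasing vector", call. = FALSE)
  }
  profile <- compute_profile(x)
  N <- length(profile)
  if (is.null(scales)) {
    scales <- build_scale_grid(N, n_min = n_min, n_max = n_max,
                               n_scales = n_scales, order = order)
  } else {
    scales <- as.integer(scales)
    if (is.unsorted(scales, strictly = TRUE) || scales[1L] <= order + 1 ||
        scales[length(scales)] > N) {
      stop("`scales` must be strictly increasing, > order + 1 and <= N",
           call. = FALSE)
    }
  }
  fq <- matrix(NA_real_, nrow = length(q), ncol = length(scales),
               dimnames = list(format(q, trim = TRUE), scales))
  zero_excluded <- integer(length(scales))
  segments <- integer(length(scales))
  for (s in seq_along(scales)) {
    f2 <- segment_variances_at_scale(profile, scales[s], order)
    segments[s] <- length(f2)
    fqs <- tryCatch(
      fluctuation_function(f2, q),
      error = function(e) {
        stop("fluctuation stage failed at scale n = ", scales[s], ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    zero_excluded[s] <- attr(fqs, "n_zero_excluded")
    fq[, s] <- fqs
  }
  if (any(zero_excluded > 0)) {
    warning(sum(zero_excluded), " zero-variance segment(s) excluded from ",
            "q <= 0 averages across ", sum(zero_excluded > 0), " scale(s)",
            call. = FALSE)
  }
  hurst <- estimate_hurst(fq, scales, q, fit_range = fit_range)
  structure(
    list(hurst = hurst, fq = fq, scales = scales, q = q,
         segments = segments, zero_excluded = zero_excluded,
         order = as.integer(order),
         fit_range = if (is.null(fit_range)) range(scales) else fit_range,
         N = N, call = cl),
    class = "mfdfa"
  )
}

#' @describeIn mfdfa generalised Hurst exponents as a named vector
#'   (names are the q values).
#' @param object,... method arguments.
#' @export
coef.mfdfa <- function(object, ...) {
  stats::setNames(object$hurst$H, format(object$hurst$q, trim = TRUE))
}

#' @describeIn mfdfa residuals of the per-q log-log power-law fits
#'   (matrix, q by scale).
#' @export
residuals.mfdfa <- function(object, ...) {
  use <- object$scales >= object$fit_range[1L] &
    object$scales <= object$fit_range[2L]
  lx <- log(object$scales[use])
  pred <- outer(object$hurst$H, lx) + object$hurst$intercept
  res <- log(object$fq[, use, drop = FALSE]) - pred
  dimnames(res) <- list(format(object$q), object$scales[use])
  res
}

#' @export
print.mfdfa <- function(x, ...) {
  cat("Multifractal detrended fluctuation analysis\n")
  cat(sprintf("  N = %d samples, %d scales in [%d, %d], detrending order %d\n",
              x$N, length(x$scales), min(x$scales), max(x$scales), x$order))
  h <- x$hurst
  h2 <- h$H[which.min(abs(h$q - 2))]
  cat(sprintf("  q grid: [%g, %g] (%d values)\n",
              min(x$q), max(x$q), length(x$q)))
  cat(sprintf("  H(2) = %.4f | H(q) range = [%.4f, %.4f] (width %.4f)\n",
              h2, min(h$H), max(h$H), max(h$H) - min(h$H)))
  if (any(x$zero_excluded > 0)) {
    cat(sprintf("  note: %d zero-variance segment(s) excluded for q <= 0\n",
                sum(x$zero_excluded)))
  }
  invisible(x)
}

#' @param x,object an `"mfdfa"` object.
#' @describeIn mfdfa prints H(q) at selected q, the H(q) width, and fit
#'   diagnostics; returns the summary invisibly.
#' @export
summary.mfdfa <- function(object, ...) {
  h <- object$hurst
  out <- list(
    hurst = h,
    width_H = max(h$H) - min(h$H),
    min_r_squared = min(h$r_squared),
    zero_excluded = sum(object$zero_excluded),
    N = object$N
  )
  class(out) <- "summary.mfdfa"
  out
}

#' @export
print.summary.mfdfa <- function(x, ...) {
  cat("MFDFA fit over", nrow(x$hurst), "moment orders, N =", x$N, "\n\n")
  show_q <- c(-6, -2, 0, 2, 6)
  rows <- x$hurst[x$hurst$q %in% show_q, ]
  print(format(rows, digits = 4), row.names = FALSE)
  cat(sprintf("\nH(q) width (max - min): %.4f\n", x$width_H))
  cat(sprintf("worst power-law fit R^2: %.4f\n", x$min_r_squared))
  if (x$zero_excluded > 0) {
    cat("zero-variance segments excluded:", x$zero_excluded, "\n")
  }
  invisible(x)
}

#' Plot an MFDFA fit
#'
#' `type = "fluctuation"` draws the log-log fluctuation functions
#' `F_q(n)` against scale for a spread of q values with the fitted power
#' laws; `type = "hurst"` draws the generalised Hurst exponent H(q).
#'
#' @param x an `"mfdfa"` object.
#' @param type which panel to draw.
#' @param ... passed to the underlying plotting functions.
#' @return the object, invisibly.
#' @export
plot.mfdfa <- function(x, type = c("fluctuation", "hurst"), ...) {
  type <- match.arg(type)
  if (type == "fluctuation") {
    pick <- unique(round(seq(1, length(x$q), length.out = 5)))
    cols <- grDevices::hcl.colors(length(pick), "Dark 3")
    graphics::matplot(x$scales, t(x$fq[pick, , drop = FALSE]),
                      log = "xy", type = "p", pch = 1, col = cols,
                      xlab = "scale n", ylab = expression(F[q](n)), ...)
    for (i in seq_along(pick)) {
      graphics::curve(exp(x$hurst$intercept[pick[i]]) * t^x$hurst$H[pick[i]],
                      from = min(x$scales), to = max(x$scales),
                      xname = "t", add = TRUE, col = cols[i])
    }
    graphics::legend("topleft", legend = paste("q =", x$q[pick]),
                     col = cols, pch = 1, bty = "n")
  } else {
    graphics::plot(x$hurst$q, x$hurst$H, type = "b", pch = 16,
                   xlab = "q", ylab = "H(q)", ...)
  }
  invisible(x)
}
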