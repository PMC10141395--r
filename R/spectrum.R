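#' Singularity spectrum by Legendre transform of H(q)
#'
#' Converts the generalised Hurst exponent into the singularity (multifractal)
#' spectrum of Hoelder exponents:
#' \deqn{\alpha(q) = H(q) + q\,\frac{\partial H}{\partial q}, \qquad
#'       f(\alpha) = q\,[\alpha(q) - H(q)] + 1.}
#' The derivative is taken by central finite differences on the q grid
#' (one-sided at the two ends); no smoothing is applied. For a monofractal
#' series the spectrum degenerates to the single point
#' \eqn{(\alpha, f) = (H, 1)}; the width of the \eqn{\alpha} support measures
#' the strength of multifractality. At q = 0, \eqn{f(\alpha) = 1} exactly by
#' construction.
#'
#' @param h an `"mfdfa"` fit, or a data frame with columns `q` and `H`
#'   (>= 3 rows).
#' @return an object of class `"singularity_spectrum"`: a data frame with
#'   columns `q`, `H`, `alpha`, `f_alpha`, carrying the source fit (if any)
#'   in attribute `"source"`.
#' @examples
#' h <- data.frame(q = seq(-6, 6, 0.25), H = cascade_hurst(seq(-6, 6, 0.25), 0.75))
#' s <- singularity_spectrum(h)
#' range(s$alpha)
#' @export
singularity_spectrum <- function(h) {
  src <- NULL
  if (inherits(h, "mfdfa")) {
    src <- h$call
    h <- h$hurst
  }
  if (!is.data.frame(h) || !all(c("q", "H") %in% names(h))) {
    stop("`h` must be an mfdfa fit or a data frame with columns q and H",
         call. = FALSE)
  }
  q <- h$q
  H <- h$H
  m <- length(q)
  if (m < 3L) stop("need H(q) on at least 3 grid points", call. = FALSE)
  dH <- numeric(m)
  dH[1L] <- (H[2L] - H[1L]) / (q[2L] - q[1L])
  dH[m] <- (H[m] - H[m - 1L]) / (q[m] - q[m - 1L])
  if (m > 2L) {
    i <- 2:(m - 1L)
    dH[i] <- (H[i + 1L] - H[i - 1L]) / (q[i + 1L] - q[i - 1L])
  }
  alpha <- H + q * dH
  f_alpha <- q * (alpha - H) + 1
  out <- data.frame(q = q, H = H, alpha = alpha, f_alpha = f_alpha)
  attr(out, "source") <- src
  class(out) <- c("singularity_spectrum", "data.frame")
  out
}

#' Summary descriptors of a singularity spectrum
#'
#' Computes the descriptors used to compare conditions:
#'
#' * `width_alpha`: support width of the spectrum,
#'   `max(alpha) - min(alpha)`;
#' * `width_H`: `max(H(q)) - min(H(q))`, the width convention labelled
#'   max(Hq) - min(Hq) in condition summary tables;
#' * `endpoint_alpha`, `endpoint_f`: coordinates of the left-hand (small
#'   alpha, largest q) final point of the spectrum curve.
#'
#' Both width conventions are reported because they answer slightly different
#' questions (spread of local regularity vs spread of scaling exponents);
#' they coincide at zero for a monofractal.
#'
#' @param s a `"singularity_spectrum"`.
#' @return an object of class `"spectrum_summary"` (a named list with fields
#'   `width_alpha`, `width_H`, `endpoint_alpha`, `endpoint_f`, `q_range`).
#' @export
spectrum_summary <- function(s) {
  stopifnot(inherits(s, "singularity_spectrum"))
  if (nrow(s) == 0L) stop("empty spectrum", call. = FALSE)
  i_end <- which.max(s$q)
  structure(
    list(width_alpha = max(s$alpha) - min(s$alpha),
         width_H = max(s$H) - min(s$H),
         endpoint_alpha = s$alpha[i_end],
         endpoint_f = s$f_alpha[i_end],
         q_range = range(s$q)),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Singularity spectrum summary\n")
  cat(sprintf("  width (alpha support)     : %.4f\n", x$width_alpha))
  cat(sprintf("  width (max H - min H)     : %.4f\n", x$width_H))
  cat(sprintf("  left endpoint (alpha, f)  : (%.4f, %.4f)\n",
              x$endpoint_alpha, x$endpoint_f))
  cat(sprintf("  over q in [%g, %g]\n", x$q_range[1L], x$q_range[2L]))
  invisible(x)
}

#' @export
print.singularity_spectrum <- function(x, ...) {
  cat(sprintf("Singularity spectrum on %d q values in [%g, %g]\n",
              nrow(x), min(x$q), max(x$q)))
  cat(sprintf("  alpha in [%.4f, %.4f] (width %.4f)\n",
              min(x$alpha), max(x$alpha), max(x$alpha) - min(x$alpha)))
  cat(sprintf("  f(alpha) in [%.4f, %.4f]\n", min(x$f_alpha), max(x$f_alpha)))
  invisible(x)
}

#' Plot a singularity spectrum
#'
#' Draws f(alpha) against alpha; the apex sits at q = 0 where f = 1, the
#' left branch (small alpha) corresponds to large positive q and the right
#' branch to large negative q.
#'
#' @param x a `"singularity_spectrum"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.singularity_spectrum <- function(x, ...) {
  graphics::plot(x$alpha, x$f_alpha, type = "b", pch = 16,
                 xlab = expression(alpha), ylab = expression(f(alpha)), ...)
  invisible(x)
}
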