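# Noise-scale estimation and the minimax shrinkage threshold used by the
# state discrimination model.

#' Robust noise scale of wavelet packet coefficients
#'
#' Median-absolute-deviation estimator of the noise standard deviation,
#' \code{sigma = median(|u|) / 0.6745}.  The constant 0.6745 is the upper
#' quartile of the standard normal, making the estimator unbiased for
#' Gaussian noise and insensitive to a sparse set of large oscillation
#' coefficients.  The estimator is scale-equivariant:
#' \code{estimate_sigma(c * u) == c * estimate_sigma(u)} for \code{c > 0}.
#'
#' @param u Numeric coefficient vector (non-empty).
#' @return Estimated noise standard deviation (>= 0).
#' @export
#' @examples
#' estimate_sigma(c(-0.6745, 0.6745, 0.6745))  # 1
estimate_sigma <- function(u) {
  if (length(u) == 0) stop("empty coefficient window", call. = FALSE)
  stats::median(abs(u)) / 0.6745
}

#' Minimax threshold for synchronization discrimination
#'
#' The minimax wavelet shrinkage threshold
#' \code{T = sigma * (0.396 + 0.1829 * log2(N))}, with \code{sigma}
#' estimated by \code{\link{estimate_sigma}} from the \code{N} coefficients
#' of the window.  It is preferred over the universal threshold for short
#' coefficient windows because of its lower estimation variance.  \code{T}
#' is non-decreasing in \code{N} for fixed \code{sigma}.
#'
#' @param u Numeric coefficient vector with \code{N = length(u) >= 2}.
#' @param span_s Optional extent of the window in seconds, recorded in the
#'   result for provenance.
#' @return Object of class \code{threshold_estimate}: list with the
#'   threshold \code{T}, the noise scale \code{sigma}, the coefficient
#'   count \code{N}, and \code{span_s}.
#' @export
#' @examples
#' u <- rep(0.6745, 1024)
#' minimaxi_threshold(u)$T  # 0.396 + 0.1829 * 10 = 2.225
minimaxi_threshold <- function(u, span_s = NA_real_) {
  N <- length(u)
  if (N < 2) stop("at least 2 coefficients are required", call. = FALSE)
  sigma <- estimate_sigma(u)
  structure(list(T = sigma * .minimaxi_factor(N), sigma = sigma, N = N,
                 span_s = span_s),
            class = "threshold_estimate")
}

.minimaxi_factor <- function(N) 0.396 + 0.1829 * log2(N)

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Minimax threshold: T = %.6g (sigma = %.6g, N = %d%s)\n",
              x$T, x$sigma, x$N,
              if (is.na(x$span_s)) "" else sprintf(", span %.3g s", x$span_s)))
  invisible(x)
}
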