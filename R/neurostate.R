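#' Identify dynamic neural states in a deep-brain LFP signal
#'
#' The main fitting function of the package.  Runs the full state
#' identification pipeline on a 384 Hz analysis-ready signal: for each
#' requested oscillation band the signal is sparsely represented by a
#' running-window wavelet packet transform
#' (\code{\link{windowed_decompose}}), synchronization states are
#' discriminated with the adaptive minimax threshold and the n1/n2
#' confirmation rule (\code{\link{detect_states}}), and, when both theta
#' and alpha are analysed, the per-step joint neural state is binary
#' encoded (\code{\link{encode_joint}}).
#'
#' @param x Numeric signal at 384 Hz, or an \code{lfp_recording} (see
#'   \code{\link{preprocess}} for producing one from a raw recording).
#' @param fs Sampling rate in Hz; must be 384 so that theta (6-9 Hz) and
#'   alpha (9-12 Hz) align with level-6 wavelet packet nodes.
#' @param bands Bands to analyse, subset of \code{c("theta", "alpha")}.
#' @param config A \code{\link{detector_config}}.
#' @return Object of class \code{neurostate}: list with \code{bands} (one
#'   \code{binary_states} per band, with threshold traces), \code{joint}
#'   (a \code{joint_states} series, or \code{NULL}), the coefficient
#'   series in \code{coefs}, the \code{config}, \code{fs} and \code{call}.
#' @export
#' @examples
#' trial <- generate_trial(simulation_spec("theta", snr_db = -9,
#'                                         duration_s = 20, seed = 1))
#' fit <- neurostate(trial$signal, bands = "theta")
#' print(fit)
neurostate <- function(x, fs = 384, bands = c("theta", "alpha"),
                       config = detector_config()) {
  cl <- match.call()
  if (inherits(x, "lfp_recording")) { fs <- x$fs; x <- x$samples }
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (abs(fs - 384) > 1e-9)
    stop("neurostate() expects a 384 Hz signal; run preprocess() first",
         call. = FALSE)
  bands <- match.arg(bands, c("theta", "alpha"), several.ok = TRUE)
  coefs <- list(); fits <- list()
  for (b in bands) {
    basis <- if (b %in% names(config$basis)) config$basis[[b]] else .band_basis(b)
    cs <- windowed_decompose(x, basis, .band_node(b),
                             L_running = config$L_running, step = config$step,
                             level = config$level, fs = fs)
    st <- detect_states(cs, config)
    st$band <- b
    coefs[[b]] <- cs; fits[[b]] <- st
  }
  joint <- if (all(c("theta", "alpha") %in% bands))
    encode_joint(fits$theta, fits$alpha) else NULL
  structure(list(bands = fits, joint = joint, coefs = coefs,
                 config = config, fs = fs, n_samples = length(x), call = cl),
            class = "neurostate")
}

#' @export
print.neurostate <- function(x, ...) {
  cat("Dynamic neural state identification\n")
  cat(sprintf("  signal: %d samples at %g Hz (%.1f s)\n",
              x$n_samples, x$fs, x$n_samples / x$fs))
  for (b in names(x$bands)) {
    st <- x$bands[[b]]
    cat(sprintf("  %s: %.1f%% synchronization over %d steps\n",
                b, 100 * mean(st$states), length(st$states)))
  }
  if (!is.null(x$joint)) {
    tab <- occurrence_frequency(x$joint)
    cat("  joint states (%):",
        paste(sprintf("%s %.1f", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.neurostate <- function(object, ...) {
  occ <- if (!is.null(object$joint)) state_occurrence(object$joint)
         else vapply(object$bands, function(s) 100 * mean(s$states), numeric(1))
  thr <- vapply(object$bands, function(s) {
    stats::median(s$threshold[is.finite(s$threshold) & !s$warmup])
  }, numeric(1))
  out <- list(occurrence = occ, median_threshold = thr,
              n_steps = length(object$bands[[1]]$states),
              warmup_steps = sum(object$bands[[1]]$warmup),
              config = object$config)
  class(out) <- "summary.neurostate"
  out
}

#' @export
print.summary.neurostate <- function(x, ...) {
  cat("Neural state summary\n")
  cat(sprintf("  %d steps (%d warmup)\n", x$n_steps, x$warmup_steps))
  cat("  occurrence (%):\n")
  for (nm in names(x$occurrence))
    cat(sprintf("    %-5s %6.2f\n", nm, x$occurrence[nm]))
  cat("  median adaptive threshold:",
      paste(sprintf("%s %.3g", names(x$median_threshold), x$median_threshold),
            collapse = ", "), "\n")
  print(x$config)
  invisible(x)
}

#' Plot a fitted neural state identification
#'
#' One panel per band showing the largest coefficient magnitude of each
#' running window, the adaptive threshold trace, and the discriminated
#' synchronization state (shaded).
#'
#' @param x A \code{neurostate} object.
#' @param bands Bands to plot (default: all fitted).
#' @param ... Passed to \code{plot.default}.
#' @export
plot.neurostate <- function(x, bands = names(x$bands), ...) {
  old <- graphics::par(mfrow = c(length(bands), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (b in bands) {
    st <- x$bands[[b]]
    cs <- x$coefs[[b]]
    amp <- apply(abs(cs$u), 2, max)
    tt <- st$time_s
    ylim <- range(0, amp, st$threshold[is.finite(st$threshold)])
    graphics::plot(tt, amp, type = "l", col = "grey40",
                   xlab = "time (s)", ylab = "|coefficient|",
                   main = sprintf("%s (%s)", b, cs$basis), ylim = ylim, ...)
    on_runs <- rle(st$states)
    ends <- cumsum(on_runs$lengths)
    starts <- ends - on_runs$lengths + 1L
    for (i in which(on_runs$values == 1L))
      graphics::rect(tt[starts[i]], ylim[1], tt[ends[i]], ylim[2],
                     col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
    graphics::lines(tt, st$threshold, col = "firebrick", lwd = 1.2)
  }
  invisible(x)
}
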