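# Benchmark signal generator: trapezoid-modulated sinusoids in white
# Gaussian noise with ground-truth synchronization labels, plus the
# threshold-based SNR estimator.

#' Specification of a simulated oscillation trial
#'
#' Describes a benchmark signal: a sinusoidal carrier at the centre
#' frequency of the band (7.5 Hz for theta, 10.5 Hz for alpha, values in
#' [-1, 1]) multiplied by a periodic trapezoidal envelope (period 2 s,
#' duty cycle 0.5, amplitude 0 to 1) plus white Gaussian noise scaled to a
#' target SNR.
#'
#' The envelope's high phase (\code{duty_cycle * envelope_period_s}) is
#' split into a linear rise, a plateau, and a linear fall;
#' \code{ramp_fraction} is the fraction of the high phase spent ramping
#' (both ramps together).  The default 0.5 gives, at the default geometry,
#' a 0.25 s rise, 0.5 s plateau, 0.25 s fall and 1 s silence per period.
#' \code{ramp_fraction = 0} yields a square envelope, useful for
#' closed-form checks.
#'
#' @param band \code{"theta"} or \code{"alpha"}; sets the default carrier.
#' @param carrier_hz Carrier frequency (Hz); default per band.
#' @param fs Sampling rate (Hz), default 384.
#' @param envelope_period_s Envelope period in seconds.
#' @param duty_cycle Fraction of the period with non-zero envelope.
#' @param ramp_fraction Fraction of the high phase spent ramping.
#' @param snr_db Target signal-to-noise ratio in dB, defined over the whole
#'   trial as \code{10*log10(P_clean / P_noise)}; \code{Inf} disables noise.
#' @param duration_s Trial duration in seconds (at least one envelope
#'   period).
#' @param seed Integer seed for the noise generator.
#' @return Object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(band = c("theta", "alpha"), carrier_hz = NULL,
                            fs = 384, envelope_period_s = 2, duty_cycle = 0.5,
                            ramp_fraction = 0.5, snr_db = -9, duration_s = 60,
                            seed = 0L) {
  band <- match.arg(band)
  if (is.null(carrier_hz))
    carrier_hz <- switch(band, theta = 7.5, alpha = 10.5)
  if (duty_cycle <= 0 || duty_cycle >= 1) stop("duty_cycle must be in (0, 1)", call. = FALSE)
  if (ramp_fraction < 0 || ramp_fraction > 1) stop("ramp_fraction must be in [0, 1]", call. = FALSE)
  if (duration_s < envelope_period_s)
    stop("duration must cover at least one envelope period", call. = FALSE)
  if (carrier_hz >= fs / 2) stop("carrier above Nyquist", call. = FALSE)
  structure(list(band = band, carrier_hz = carrier_hz, fs = fs,
                 envelope_period_s = envelope_period_s,
                 duty_cycle = duty_cycle, ramp_fraction = ramp_fraction,
                 snr_db = snr_db, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Periodic trapezoidal envelope
#'
#' @param t Time points in seconds.
#' @param period_s Envelope period.
#' @param duty_cycle Fraction of the period with non-zero envelope.
#' @param ramp_fraction Fraction of the high phase spent ramping (both
#'   ramps together); 0 gives a square envelope.
#' @return Envelope values in [0, 1].
#' @export
trapezoid_envelope <- function(t, period_s = 2, duty_cycle = 0.5,
                               ramp_fraction = 0.5) {
  high <- duty_cycle * period_s
  ramp <- ramp_fraction * high / 2
  ph <- t %% period_s
  env <- numeric(length(t))
  if (ramp > 0) {
    rising <- ph < ramp
    env[rising] <- ph[rising] / ramp
    falling <- ph >= high - ramp & ph < high
    env[falling] <- (high - ph[falling]) / ramp
    env[ph >= ramp & ph < high - ramp] <- 1
  } else {
    env[ph < high] <- 1
  }
  env
}

#' Generate a simulated oscillation trial
#'
#' Builds the clean amplitude-modulated sinusoid, adds white Gaussian
#' noise scaled so that the realized whole-trial SNR equals
#' \code{spec$snr_db} exactly, and records the envelope for ground-truth
#' labelling.  Identical specs (including seed) give identical trials.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @return Object of class \code{simulated_trial}: list with
#'   \code{signal}, \code{clean}, \code{noise}, \code{envelope},
#'   \code{time_s} and \code{spec}; \code{signal == clean + noise}
#'   exactly.
#' @export
generate_trial <- function(spec) {
  if (!inherits(spec, "simulation_spec")) stop("spec must be a simulation_spec", call. = FALSE)
  n <- round(spec$duration_s * spec$fs)
  if (n < 2) stop("degenerate duration", call. = FALSE)
  t <- (seq_len(n) - 1L) / spec$fs
  env <- trapezoid_envelope(t, spec$envelope_period_s, spec$duty_cycle,
                            spec$ramp_fraction)
  clean <- env * sin(2 * pi * spec$carrier_hz * t)
  if (is.infinite(spec$snr_db) && spec$snr_db > 0) {
    noise <- numeric(n)
  } else {
    p_clean <- mean(clean^2)
    p_noise <- p_clean / 10^(spec$snr_db / 10)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed)
    eps <- stats::rnorm(n)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    noise <- eps * sqrt(p_noise / mean(eps^2))
  }
  structure(list(signal = clean + noise, clean = clean, noise = noise,
                 envelope = env, time_s = t, spec = spec),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  s <- x$spec
  snr <- if (all(x$noise == 0)) Inf else
    10 * log10(mean(x$clean^2) / mean(x$noise^2))
  cat(sprintf(
    "Simulated %s trial: %.4g Hz carrier, %.3g s at %g Hz, SNR %.4g dB (seed %d)\n",
    s$band, s$carrier_hz, s$duration_s, s$fs, snr, s$seed))
  invisible(x)
}

#' Ground-truth synchronization states of a simulated trial
#'
#' The true state at a detector step is synchronization (1) iff the
#' envelope strictly exceeds 0.5 at the step's reference time.  The
#' reference defaults to the running-window midpoint, since the
#' coefficients of a frame summarize the whole window and their energy is
#' centred there; \code{reference = "start"} labels by the window start
#' instead.  Truth labels depend only on the envelope, never on the
#' noise.
#'
#' @param trial A \code{simulated_trial} (or a numeric envelope sampled on
#'   the signal grid, with \code{fs} supplied).
#' @param starts 0-based window start samples, e.g. from a
#'   \code{wp_coef_series}; defaults to the grid of the default detector
#'   (128-sample window, 8-sample step).
#' @param L_running Window length used for the midpoint reference.
#' @param step Step in samples for the default grid.
#' @param reference \code{"midpoint"} (default) or \code{"start"}.
#' @param fs Sampling rate when \code{trial} is a plain envelope.
#' @return A \code{binary_states} series on the detector's step grid.
#' @export
truth_states <- function(trial, starts = NULL, L_running = 128L, step = 8L,
                         reference = c("midpoint", "start"), fs = 384) {
  reference <- match.arg(reference)
  if (inherits(trial, "simulated_trial")) {
    env <- trial$envelope; fs <- trial$spec$fs
  } else env <- trial
  if (is.null(starts)) starts <- seq(0L, length(env) - L_running, by = as.integer(step))
  ref <- if (reference == "start") starts else starts + L_running %/% 2L
  binary_states(as.integer(env[ref + 1L] > 0.5), step_s = step / fs,
                t0_s = starts[1] / fs, band = "truth")
}

#' Estimate the SNR of an oscillation by wavelet packet thresholding
#'
#' Separates the oscillation from the background by thresholding the
#' wavelet packet coefficients of its band node: the signal is decomposed
#' over the full level-6 tree, a minimax threshold is computed from the
#' band node's coefficients, the supra-threshold coefficients are
#' reconstructed as the oscillation component, and everything else
#' (sub-threshold band coefficients plus all other nodes) counts as
#' noise.  The estimate is
#' \code{10*log10(P_oscillation / P_noise)} over the reconstructed
#' components.
#'
#' @param x Signal (at least several envelope periods; 6-s segments are
#'   typical), length a multiple of \code{2^level}.
#' @param band \code{"theta"} or \code{"alpha"} (selects node and default
#'   basis at 384 Hz / level 6).
#' @param basis Wavelet basis (default per band).
#' @param fs Sampling rate.
#' @param level Tree depth.
#' @return SNR estimate in dB.  If no coefficient exceeds the threshold
#'   the estimate is \code{-Inf} with attribute \code{no_oscillation =
#'   TRUE}.
#' @export
estimate_snr <- function(x, band = c("theta", "alpha"), basis = NULL,
                         fs = 384, level = 6L) {
  band <- match.arg(band)
  if (inherits(x, "lfp_recording")) { fs <- x$fs; x <- x$samples }
  if (is.null(basis)) basis <- .band_basis(band)
  node <- .band_node(band)
  d <- wp_decompose(x, basis, level)
  u <- d$coef[, node + 1L]
  thr <- minimaxi_threshold(u)
  keep <- abs(u) > thr$T
  if (!any(keep)) {
    out <- -Inf
    attr(out, "no_oscillation") <- TRUE
    return(out)
  }
  osc <- wp_reconstruct_node(d, node, coef = ifelse(keep, u, 0))
  noise <- x - osc
  10 * log10(mean(osc^2) / mean(noise^2))
}
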