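# Preprocessing chain turning a raw deep-brain LFP recording into the
# 384 Hz analysis-ready signal whose theta and alpha bands align with
# level-6 wavelet packet nodes.

#' Construct an LFP recording
#'
#' Lightweight container for a single-channel LFP time series with its
#' sampling rate and recording metadata.
#'
#' @param samples Numeric amplitude series (arbitrary units, typically uV);
#'   must be finite and non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param nucleus Recording site: \code{"PVAG"}, \code{"VPL"} or
#'   \code{"OTHER"}.
#' @param contact_pair,subject_id Free-text metadata.
#' @param provenance Character vector of processing steps already applied.
#' @return Object of class \code{lfp_recording}.
#' @export
lfp_recording <- function(samples, fs, nucleus = "OTHER", contact_pair = NA,
                          subject_id = NA, provenance = character()) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("empty recording", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples contain non-finite values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive number", call. = FALSE)
  nucleus <- match.arg(nucleus, c("PVAG", "VPL", "OTHER"))
  structure(list(samples = samples, fs = fs, nucleus = nucleus,
                 contact_pair = contact_pair, subject_id = subject_id,
                 provenance = provenance),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d samples at %g Hz (%.1f s), nucleus %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$nucleus))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Preprocessing configuration
#'
#' Parameters of the filter chain applied by \code{\link{preprocess}}:
#' 90 Hz low-pass (Chebyshev type I, order 10), down-sampling to 500 Hz,
#' 50 Hz notch, 2 Hz high-pass (Chebyshev type I, order 5), and rational
#' resampling to 384 Hz.  The 384 Hz target is fixed by the node
#' alignment of the level-6 wavelet packet tree and should not normally
#' be changed.
#'
#' @param lowpass_hz,lowpass_order Low-pass cutoff and order.
#' @param ripple_db Chebyshev type I passband ripple (dB).
#' @param intermediate_fs Intermediate rate after the first down-sampling.
#' @param notch_hz Mains interference frequency.
#' @param notch_q Quality factor of the second-order IIR notch.
#' @param highpass_hz,highpass_order High-pass cutoff and order.
#' @param target_fs Final sampling rate.
#' @return Object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(lowpass_hz = 90, lowpass_order = 10,
                              ripple_db = 0.5, intermediate_fs = 500,
                              notch_hz = 50, notch_q = 30,
                              highpass_hz = 2, highpass_order = 5,
                              target_fs = 384) {
  stopifnot(lowpass_hz > 0, intermediate_fs > 0, notch_hz > 0,
            highpass_hz > 0, target_fs > 0)
  structure(list(lowpass_hz = lowpass_hz, lowpass_order = lowpass_order,
                 ripple_db = ripple_db, intermediate_fs = intermediate_fs,
                 notch_hz = notch_hz, notch_q = notch_q,
                 highpass_hz = highpass_hz, highpass_order = highpass_order,
                 target_fs = target_fs),
            class = "preprocess_config")
}

# Second-order IIR notch (constrained biquad): unit gain away from
# notch_hz, null at notch_hz, bandwidth notch_hz / q.
.notch_coefficients <- function(notch_hz, fs, q) {
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

.apply_filter <- function(x, b, a, zero_phase) {
  if (zero_phase) as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x))
  else as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

.resample_to <- function(x, fs_from, fs_to) {
  if (abs(fs_from - fs_to) < 1e-9) return(x)
  ratio <- fs_from / fs_to
  if (abs(ratio - round(ratio)) < 1e-9) {
    # integer decimation; the preceding low-pass already band-limits
    x[seq(1, length(x), by = round(ratio))]
  } else {
    frac <- MASS::fractions(fs_to / fs_from)
    pq <- as.integer(strsplit(attr(frac, "fracs"), "/")[[1]])
    if (length(pq) == 1L) pq <- c(pq, 1L)
    as.numeric(signal::resample(x, pq[1], pq[2]))
  }
}

#' Preprocess a raw LFP recording to 384 Hz
#'
#' Applies the standard chain, in order: 90 Hz Chebyshev-I low-pass
#' (order 10), down-sampling to 500 Hz, 50 Hz IIR notch, 2 Hz Chebyshev-I
#' high-pass (order 5), and polyphase rational resampling to 384 Hz.
#' Filtering is causal (forward-only) by default to honour the streaming
#' use case; \code{zero_phase = TRUE} switches every filter to
#' forward-backward filtering for offline analysis.  Every step is
#' recorded in the output's provenance.
#'
#' @param rec An \code{lfp_recording} (or numeric vector with \code{fs}
#'   supplied).
#' @param config A \code{\link{preprocess_config}}.
#' @param zero_phase Use zero-phase (filtfilt) filtering.
#' @param fs Sampling rate when \code{rec} is a plain vector.
#' @return An \code{lfp_recording} at 384 Hz with populated provenance.
#' @export
preprocess <- function(rec, config = preprocess_config(), zero_phase = FALSE,
                       fs = NULL) {
  if (!inherits(rec, "lfp_recording")) {
    if (is.null(fs)) stop("fs must be given for a plain numeric signal", call. = FALSE)
    rec <- lfp_recording(rec, fs)
  }
  cfg <- config
  if (rec$fs < 2 * cfg$lowpass_hz)
    stop("sampling rate too low for the ", cfg$lowpass_hz, " Hz low-pass",
         call. = FALSE)
  if (!all(is.finite(rec$samples))) stop("non-finite samples", call. = FALSE)
  prov <- rec$provenance
  mode <- if (zero_phase) "zero-phase" else "causal"
  x <- rec$samples
  fs0 <- rec$fs

  lp <- signal::cheby1(cfg$lowpass_order, cfg$ripple_db,
                       cfg$lowpass_hz / (fs0 / 2), type = "low")
  x <- .apply_filter(x, lp$b, lp$a, zero_phase)
  prov <- c(prov, sprintf("lowpass cheby1 order %d, %g Hz, ripple %g dB (%s)",
                          cfg$lowpass_order, cfg$lowpass_hz, cfg$ripple_db, mode))

  x <- .resample_to(x, fs0, cfg$intermediate_fs)
  prov <- c(prov, sprintf("resample %g -> %g Hz", fs0, cfg$intermediate_fs))
  fs1 <- cfg$intermediate_fs

  nc <- .notch_coefficients(cfg$notch_hz, fs1, cfg$notch_q)
  x <- .apply_filter(x, nc$b, nc$a, zero_phase)
  prov <- c(prov, sprintf("notch %g Hz, Q %g (%s)", cfg$notch_hz, cfg$notch_q, mode))

  hp <- signal::cheby1(cfg$highpass_order, cfg$ripple_db,
                       cfg$highpass_hz / (fs1 / 2), type = "high")
  x <- .apply_filter(x, hp$b, hp$a, zero_phase)
  prov <- c(prov, sprintf("highpass cheby1 order %d, %g Hz, ripple %g dB (%s)",
                          cfg$highpass_order, cfg$highpass_hz, cfg$ripple_db, mode))

  x <- .resample_to(x, fs1, cfg$target_fs)
  prov <- c(prov, sprintf("resample %g -> %g Hz", fs1, cfg$target_fs))

  lfp_recording(x, cfg$target_fs, nucleus = rec$nucleus,
                contact_pair = rec$contact_pair, subject_id = rec$subject_id,
                provenance = prov)
}
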