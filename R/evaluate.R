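# Scoring detections against ground truth, the fixed-threshold baseline,
# the parameter sweeps over the simulation benchmark, and the clinical
# correlation utilities.

#' Score a detected state series against ground truth
#'
#' Duration-based sensitivity and specificity:
#' \code{sensitivity = ts / Ts} and \code{specificity = td / Td}, where
#' \code{Ts}/\code{Td} are the total durations of true synchronization /
#' de-synchronization and \code{ts}/\code{td} the durations correctly
#' identified as such.  Warmup steps of the detected series are excluded
#' from both numerator and denominator.  If the truth contains no
#' synchronization (or no de-synchronization) time, the undefined metric
#' is reported as \code{NA}.
#'
#' @param identified,truth Aligned \code{binary_states} series of equal
#'   length.
#' @return Object of class \code{performance_result}: list with
#'   \code{sensitivity}, \code{specificity} (fractions in [0, 1]) and the
#'   durations \code{Ts}, \code{Td}, \code{ts}, \code{td} in seconds.
#' @export
score_detection <- function(identified, truth) {
  if (!inherits(identified, "binary_states") || !inherits(truth, "binary_states"))
    stop("both series must be binary_states", call. = FALSE)
  if (length(identified$states) != length(truth$states))
    stop("series lengths differ", call. = FALSE)
  keep <- !identified$warmup
  id <- identified$states[keep]
  tr <- truth$states[keep]
  dt <- identified$step_s
  Ts <- sum(tr == 1L) * dt
  Td <- sum(tr == 0L) * dt
  ts <- sum(id == 1L & tr == 1L) * dt
  td <- sum(id == 0L & tr == 0L) * dt
  structure(list(sensitivity = if (Ts > 0) ts / Ts else NA_real_,
                 specificity = if (Td > 0) td / Td else NA_real_,
                 Ts = Ts, Td = Td, ts = ts, td = td),
            class = "performance_result")
}

#' @export
print.performance_result <- function(x, ...) {
  cat(sprintf("Sensitivity %.3f (ts %.2f / Ts %.2f s), specificity %.3f (td %.2f / Td %.2f s)\n",
              x$sensitivity, x$ts, x$Ts, x$specificity, x$td, x$Td))
  invisible(x)
}

#' Identification delays at state transitions
#'
#' Measures, for every truth transition, how much later the detector's
#' decision became available in the streaming view.  A confirmed state
#' flip is stamped at the first frame of its confirming run, but online
#' the label is only emitted once the look-ahead run is complete, i.e.
#' \code{n1} (or \code{n2}) steps later; the identification delay of a
#' truth transition is the emission time of the matching identified
#' transition minus the truth transition time.  Each truth transition is
#' matched to the identified transition of the same direction whose
#' emission time is nearest, within \code{match_window_s}; unmatched
#' transitions are counted as misses and excluded from the statistics.
#'
#' @param identified,truth Aligned \code{binary_states} series.
#' @param match_window_s Maximum matching distance in seconds (half an
#'   envelope period by default).
#' @param lookahead Steps of look-ahead per transition kind,
#'   \code{c(sync, desync)}; defaults to the n1/n2 values stored in the
#'   identified series' configuration (0 if none).
#' @return Object of class \code{delay_stats}: vectors of delays (ms) per
#'   transition kind and miss counts.
#' @export
transition_delays <- function(identified, truth, match_window_s = 1,
                              lookahead = NULL) {
  if (length(identified$states) != length(truth$states))
    stop("series lengths differ", call. = FALSE)
  dt <- identified$step_s
  if (is.null(lookahead)) {
    cfg <- identified$config
    lookahead <- if (!is.null(cfg) && identical(cfg$strategy, "hysteresis"))
      c(cfg$n1, cfg$n2) else c(0L, 0L)
  }
  trans <- function(s, from, to) which(s[-1] == to & s[-length(s)] == from) + 1L
  match_delays <- function(kind_from, kind_to, la) {
    tt <- trans(truth$states, kind_from, kind_to)
    ii <- trans(identified$states, kind_from, kind_to) + la
    tt <- tt[!identified$warmup[tt]]
    delays <- numeric(0); missed <- 0L
    for (t0 in tt) {
      if (length(ii) == 0) { missed <- missed + 1L; next }
      k <- which.min(abs(ii - t0))
      if (abs(ii[k] - t0) * dt <= match_window_s)
        delays <- c(delays, (ii[k] - t0) * dt * 1000)
      else missed <- missed + 1L
    }
    list(delays = delays, missed = missed)
  }
  if (sum(abs(diff(truth$states))) < 1) {
    res <- structure(list(sync_onset = numeric(0), desync_onset = numeric(0),
                          sync_missed = 0L, desync_missed = 0L,
                          no_transitions = TRUE),
                     class = "delay_stats")
    return(res)
  }
  s <- match_delays(0L, 1L, lookahead[1])
  d <- match_delays(1L, 0L, lookahead[2])
  structure(list(sync_onset = s$delays, desync_onset = d$delays,
                 sync_missed = s$missed, desync_missed = d$missed,
                 no_transitions = FALSE),
            class = "delay_stats")
}

#' @export
print.delay_stats <- function(x, ...) {
  if (isTRUE(x$no_transitions)) {
    cat("Delay statistics: no transitions in truth\n")
    return(invisible(x))
  }
  cat(sprintf("Sync onset delay: %.1f +/- %.1f ms (n=%d, missed %d)\n",
              mean(x$sync_onset), stats::sd(x$sync_onset),
              length(x$sync_onset), x$sync_missed))
  cat(sprintf("De-sync onset delay: %.1f +/- %.1f ms (n=%d, missed %d)\n",
              mean(x$desync_onset), stats::sd(x$desync_onset),
              length(x$desync_onset), x$desync_missed))
  invisible(x)
}

#' Global fixed-threshold baseline
#'
#' The offline comparator for the adaptive detector: a single minimax
#' threshold for the whole recording, with each frame labelled
#' synchronization iff any of its coefficient magnitudes exceeds it.  The
#' noise scale \code{sigma} is estimated from the node's running-window
#' coefficient series (so the threshold lives on the node's amplitude
#' scale), while \code{N} counts all wavelet packet coefficients of the
#' entire signal -- the size of the full packet decomposition, equal to
#' the signal's sample count.  By default no n1/n2 hysteresis is applied
#' (pure per-frame thresholding); \code{hysteresis = TRUE} applies the
#' confirmation rule of \code{config} on top.
#'
#' @param coefs A \code{wp_coef_series}.
#' @param truth Ground-truth \code{binary_states} aligned with
#'   \code{coefs}.
#' @param n_total Total wavelet packet coefficient count of the signal;
#'   defaults to the sample count implied by the coefficient series.
#' @param hysteresis Apply the n1/n2 rule to the fixed-threshold
#'   exceedances.
#' @param config Detector configuration (used only when
#'   \code{hysteresis = TRUE}).
#' @return A \code{performance_result} with the fixed \code{threshold}
#'   estimate and the identified \code{states} attached.
#' @export
fixed_threshold_baseline <- function(coefs, truth, n_total = NULL,
                                     hysteresis = FALSE,
                                     config = detector_config()) {
  if (!inherits(coefs, "wp_coef_series"))
    stop("coefs must be a wp_coef_series", call. = FALSE)
  if (is.null(n_total))
    n_total <- max(coefs$starts) + coefs$L_running
  sigma <- estimate_sigma(as.vector(coefs$u))
  est <- structure(list(T = sigma * .minimaxi_factor(n_total), sigma = sigma,
                        N = n_total, span_s = n_total / coefs$fs),
                   class = "threshold_estimate")
  cond <- apply(abs(coefs$u) > est$T, 2, any)
  states <- if (hysteresis)
    .state_automaton(cond, config$n1, config$n2, config$counting)
  else as.integer(cond)
  id <- binary_states(states, step_s = coefs$step / coefs$fs,
                      t0_s = coefs$starts[1] / coefs$fs, band = "fixed")
  res <- score_detection(id, truth)
  res$threshold <- est
  res$states <- id
  res
}

# --- simulation benchmark ---------------------------------------------------

# Coefficients and truth labels for one simulated trial.
.benchmark_trial <- function(band, snr_db, duration_s, seed, config,
                             ramp_fraction = 0.5) {
  spec <- simulation_spec(band, snr_db = snr_db, duration_s = duration_s,
                          seed = seed, ramp_fraction = ramp_fraction)
  trial <- generate_trial(spec)
  basis <- if (band %in% names(config$basis)) config$basis[[band]] else .band_basis(band)
  coefs <- windowed_decompose(trial$signal, basis, .band_node(band),
                              L_running = config$L_running, step = config$step,
                              level = config$level, fs = spec$fs)
  truth <- truth_states(trial, starts = coefs$starts)
  list(coefs = coefs, truth = truth)
}

.default_snr <- function(band) switch(band, theta = -9, alpha = -11)

#' Run the simulation benchmark for one condition
#'
#' Generates replicate simulated trials of one band at one SNR, runs the
#' requested detectors on each, and scores them against the envelope
#' ground truth.  The \code{"adaptive"} detector is the full approach
#' (adaptive threshold plus n1/n2 rule), \code{"simple"} drops the n1/n2
#' rule (per-window thresholding with the adaptive threshold), and
#' \code{"fixed"} is the global fixed-threshold baseline.
#'
#' @param band \code{"theta"} or \code{"alpha"}.
#' @param snr_db Signal-to-noise ratio in dB (default -9 for theta, -11
#'   for alpha, the SNR levels typical of deep-brain LFP oscillations).
#' @param reps Number of replicate trials.
#' @param duration_s Trial duration in seconds.
#' @param seeds Integer vector of noise seeds, one per trial (default
#'   \code{0:(reps-1)}).
#' @param config A \code{\link{detector_config}}.
#' @param detectors Subset of \code{c("adaptive", "simple", "fixed")}.
#' @param delays Also collect transition delay statistics for the
#'   adaptive detector.
#' @param ramp_fraction Envelope ramp fraction passed to the generator.
#' @return Object of class \code{benchmark_result}: data frame with one
#'   row per (trial, detector) and columns \code{seed}, \code{detector},
#'   \code{sensitivity}, \code{specificity}; pooled delay vectors are
#'   attached as attribute \code{"delays"} when requested.
#' @export
benchmark_detection <- function(band = c("theta", "alpha"), snr_db = NULL,
                                reps = 50, duration_s = 60, seeds = NULL,
                                config = detector_config(),
                                detectors = "adaptive", delays = FALSE,
                                ramp_fraction = 0.5) {
  band <- match.arg(band)
  if (is.null(snr_db)) snr_db <- .default_snr(band)
  if (is.null(seeds)) seeds <- seq_len(reps) - 1L
  detectors <- match.arg(detectors, c("adaptive", "simple", "fixed"),
                         several.ok = TRUE)
  rows <- list()
  dly_sync <- numeric(0); dly_desync <- numeric(0)
  simple_cfg <- config; simple_cfg$strategy <- "simple"
  for (seed in seeds) {
    bt <- .benchmark_trial(band, snr_db, duration_s, seed, config, ramp_fraction)
    for (det in detectors) {
      perf <- switch(det,
        adaptive = {
          st <- detect_states(bt$coefs, config)
          if (delays) {
            ds <- transition_delays(st, bt$truth,
                                    match_window_s = 2)
            dly_sync <- c(dly_sync, ds$sync_onset)
            dly_desync <- c(dly_desync, ds$desync_onset)
          }
          score_detection(st, bt$truth)
        },
        simple = score_detection(detect_states(bt$coefs, simple_cfg), bt$truth),
        fixed = fixed_threshold_baseline(bt$coefs, bt$truth))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, detector = det,
        sensitivity = perf$sensitivity, specificity = perf$specificity)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "band") <- band
  attr(res, "snr_db") <- snr_db
  attr(res, "duration_s") <- duration_s
  if (delays) attr(res, "delays") <- list(sync_onset = dly_sync,
                                          desync_onset = dly_desync)
  class(res) <- c("benchmark_result", "data.frame")
  res
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Simulation benchmark: %s band, SNR %g dB, %d trials of %g s\n",
              attr(x, "band"), attr(x, "snr_db"),
              length(unique(x$seed)), attr(x, "duration_s")))
  agg <- stats::aggregate(cbind(sensitivity, specificity) ~ detector,
                          data = x, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

# Mean metrics per detector from a benchmark_result.
.benchmark_means <- function(res, detector = "adaptive") {
  sub <- res[res$detector == detector, , drop = FALSE]
  c(sensitivity = mean(sub$sensitivity), specificity = mean(sub$specificity))
}

#' Sweep the a-priori window length
#'
#' Runs the simulation benchmark with the per-window discrimination rule
#' (no n1/n2 hysteresis, the rule in force while this parameter is
#' selected) for several a-priori window lengths, reusing the same trials
#' across lengths.
#'
#' @inheritParams benchmark_detection
#' @param lengths A-priori window lengths in seconds.
#' @return Object of class \code{sweep_result}: data frame with
#'   \code{L_priori}, mean \code{sensitivity} and \code{specificity};
#'   per-trial values in attribute \code{"trials"}.
#' @export
sweep_priori_length <- function(band = c("theta", "alpha"),
                                lengths = c(1, 2, 4, 6, 8), snr_db = NULL,
                                reps = 50, duration_s = 60, seeds = NULL,
                                config = detector_config(),
                                ramp_fraction = 0.5) {
  band <- match.arg(band)
  if (is.null(snr_db)) snr_db <- .default_snr(band)
  if (is.null(seeds)) seeds <- seq_len(reps) - 1L
  trials <- list()
  for (seed in seeds)
    trials[[as.character(seed)]] <-
      .benchmark_trial(band, snr_db, duration_s, seed, config, ramp_fraction)
  rows <- list()
  for (L in lengths) {
    cfg <- config; cfg$L_priori <- L; cfg$strategy <- "simple"
    perf <- vapply(trials, function(bt) {
      p <- score_detection(detect_states(bt$coefs, cfg), bt$truth)
      c(p$sensitivity, p$specificity)
    }, numeric(2))
    rows[[length(rows) + 1L]] <- data.frame(
      L_priori = L, sensitivity = mean(perf[1, ]), specificity = mean(perf[2, ]))
  }
  res <- do.call(rbind, rows)
  attr(res, "band") <- band; attr(res, "snr_db") <- snr_db
  attr(res, "reps") <- length(seeds); attr(res, "seeds") <- seeds
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Sweep the n1/n2 confirmation parameters
#'
#' Evaluates the hysteresis rule over a grid of (n1, n2) values.  The
#' adaptive thresholds do not depend on n1/n2, so they are computed once
#' per trial and only the confirmation automaton is re-run per cell.
#'
#' @inheritParams benchmark_detection
#' @param n1,n2 Integer grids (default 1..6 each).
#' @return A \code{sweep_result} data frame with columns \code{n1},
#'   \code{n2}, mean \code{sensitivity} and \code{specificity}.
#' @export
sweep_n1_n2 <- function(band = c("theta", "alpha"), n1 = 1:6, n2 = 1:6,
                        snr_db = NULL, reps = 50, duration_s = 60,
                        seeds = NULL, config = detector_config(),
                        ramp_fraction = 0.5) {
  band <- match.arg(band)
  if (is.null(snr_db)) snr_db <- .default_snr(band)
  if (is.null(seeds)) seeds <- seq_len(reps) - 1L
  grid <- expand.grid(n1 = n1, n2 = n2)
  sens <- matrix(0, nrow(grid), length(seeds))
  spc <- matrix(0, nrow(grid), length(seeds))
  for (si in seq_along(seeds)) {
    bt <- .benchmark_trial(band, snr_db, duration_s, seeds[si], config,
                           ramp_fraction)
    thr <- .adaptive_thresholds(bt$coefs$u, config, bt$coefs$fs)
    cond <- colSums(abs(bt$coefs$u) > rep(thr$T, each = nrow(bt$coefs$u))) > 0
    for (gi in seq_len(nrow(grid))) {
      st <- .state_automaton(cond, grid$n1[gi], grid$n2[gi], config$counting)
      id <- binary_states(st, step_s = bt$coefs$step / bt$coefs$fs,
                          warmup = thr$warmup)
      p <- score_detection(id, bt$truth)
      sens[gi, si] <- p$sensitivity
      spc[gi, si] <- p$specificity
    }
  }
  res <- data.frame(grid, sensitivity = rowMeans(sens),
                    specificity = rowMeans(spc))
  attr(res, "band") <- band; attr(res, "snr_db") <- snr_db
  attr(res, "reps") <- length(seeds); attr(res, "seeds") <- seeds
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Sweep the simulation SNR
#'
#' Full adaptive detector performance across noise levels.
#'
#' @inheritParams benchmark_detection
#' @param snr_values SNR grid in dB (default -4 to -14 for theta, -6 to
#'   -16 for alpha).
#' @return A \code{sweep_result} data frame with columns \code{snr_db},
#'   mean \code{sensitivity} and \code{specificity}.
#' @export
sweep_snr <- function(band = c("theta", "alpha"), snr_values = NULL,
                      reps = 50, duration_s = 60, seeds = NULL,
                      config = detector_config(), ramp_fraction = 0.5) {
  band <- match.arg(band)
  if (is.null(snr_values))
    snr_values <- if (band == "theta") seq(-4, -14, by = -2) else seq(-6, -16, by = -2)
  rows <- lapply(snr_values, function(snr) {
    res <- benchmark_detection(band, snr_db = snr, reps = reps,
                               duration_s = duration_s, seeds = seeds,
                               config = config, ramp_fraction = ramp_fraction)
    m <- .benchmark_means(res)
    data.frame(snr_db = snr, sensitivity = m["sensitivity"],
               specificity = m["specificity"])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "band") <- band; attr(res, "reps") <- reps
  class(res) <- c("sweep_result", "data.frame")
  res
}

# --- clinical correlation ---------------------------------------------------

#' Percentage pain relief from VAS scores
#'
#' \code{relief = (vas_pre - vas_post) / vas_pre * 100}, the post-operative
#' percentage change of the visual analog scale score against the
#' pre-operative score.
#'
#' @param vas_pre,vas_post VAS scores (0-10); \code{vas_pre} must be
#'   positive.  Vectorized.
#' @return Relief in percent.
#' @export
#' @examples
#' pain_relief(9.8, 3)  # 69.4
pain_relief <- function(vas_pre, vas_post) {
  if (any(vas_pre <= 0)) stop("vas_pre must be positive", call. = FALSE)
  if (any(vas_pre > 10 | vas_post > 10 | vas_post < 0))
    stop("VAS scores must lie in [0, 10]", call. = FALSE)
  (vas_pre - vas_post) / vas_pre * 100
}

# All permutations of 1..n as a matrix (n! rows); used for the exact
# Spearman null at small n.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation between state occurrence and clinical outcome
#'
#' Spearman rank correlation with average ranks for ties.  The two-sided
#' p-value is computed by exhaustive permutation of one variable for
#' \code{n < 10} and by the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} otherwise.
#'
#' @param occurrences Numeric vector of per-recording state occurrence
#'   frequencies (percent).
#' @param outcomes Numeric vector of outcomes (e.g. percentage pain
#'   relief), same length, at least 3 pairs.
#' @return Object of class \code{correlation_result}: list with
#'   \code{rho}, \code{p}, \code{n} and \code{method}.
#' @export
correlate_states_with_outcome <- function(occurrences, outcomes) {
  n <- length(occurrences)
  if (length(outcomes) != n) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("at least 3 paired observations are required", call. = FALSE)
  rx <- rank(occurrences); ry <- rank(outcomes)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}
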