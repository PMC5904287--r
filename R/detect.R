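# Adaptive synchronization-state discrimination: per-step minimax
# thresholds from a trailing a-priori window of coefficients, and the
# n1/n2 consecutive-window confirmation rule.

#' Detector configuration
#'
#' Bundles the tunable parameters of the state identification approach.
#' Defaults are the optimized operating point for theta/alpha LFP
#' oscillations at 384 Hz: 128-sample running window, 8-sample (nominally
#' 20 ms) step, 2-s a-priori window, \code{n1 = 1}, \code{n2 = 6}, basis
#' \code{rbio3.7} for theta and \code{bior3.7} for alpha.
#'
#' @param L_running Running-window length in samples (multiple of
#'   \code{2^level}).
#' @param step Window advance in samples.
#' @param L_priori A-priori window length in seconds; must cover at least
#'   one running window.
#' @param n1 Consecutive confirming windows required to switch to
#'   synchronization (1-6).
#' @param n2 Consecutive confirming windows required to switch to
#'   de-synchronization (1-6).
#' @param basis Named character vector mapping band to wavelet basis.
#' @param level Wavelet packet tree depth.
#' @param counting How the confirming run is counted.  \code{"additional"}
#'   (default): the current window plus the next \code{n} windows must all
#'   agree (run of \code{n + 1}).  \code{"total"}: a run of \code{n}
#'   windows including the current one.
#' @param priori Content of the a-priori window.  \code{"all"} (default):
#'   every overlapping running-window frame of the trailing
#'   \code{L_priori} seconds (192 coefficients at defaults), matching the
#'   coefficient buffer that the sliding window maintains online.
#'   \code{"tiled"}: only the non-overlapping frames tiling the trailing
#'   window (12 coefficients at defaults), so each sample enters once.
#' @param strategy \code{"hysteresis"} applies the n1/n2 rule;
#'   \code{"simple"} labels each window independently (synchronization iff
#'   any coefficient exceeds the threshold), the rule used while selecting
#'   the a-priori window length.
#' @return Object of class \code{detector_config}.
#' @export
detector_config <- function(L_running = 128L, step = 8L, L_priori = 2,
                            n1 = 1L, n2 = 6L,
                            basis = c(theta = "rbio3.7", alpha = "bior3.7"),
                            level = 6L,
                            counting = c("additional", "total"),
                            priori = c("all", "tiled"),
                            strategy = c("hysteresis", "simple")) {
  counting <- match.arg(counting)
  priori <- match.arg(priori)
  strategy <- match.arg(strategy)
  if (n1 < 1 || n1 > 6 || n2 < 1 || n2 > 6)
    stop("n1 and n2 must lie in 1..6", call. = FALSE)
  if (L_running %% 2^level != 0)
    stop("L_running must be a multiple of 2^level", call. = FALSE)
  structure(list(L_running = as.integer(L_running), step = as.integer(step),
                 L_priori = L_priori, n1 = as.integer(n1), n2 = as.integer(n2),
                 basis = basis, level = as.integer(level),
                 counting = counting, priori = priori, strategy = strategy),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "Detector config: L_running=%d, step=%d, L_priori=%g s, n1=%d, n2=%d (%s, %s priori, %s)\n",
    x$L_running, x$step, x$L_priori, x$n1, x$n2, x$counting, x$priori, x$strategy))
  cat("  bases:", paste(names(x$basis), x$basis, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Per-step adaptive thresholds from the trailing a-priori window of
# coefficients (current frame excluded, so the threshold is predictive).
# Until a full a-priori window has elapsed, all coefficients seen so far
# are used (minimum one earlier frame); those steps are flagged as warmup.
# Steps with no usable history get T = Inf (nothing can exceed it).
.adaptive_thresholds <- function(u, cfg, fs) {
  W <- ncol(u)
  Tvec <- rep(Inf, W)
  sig <- rep(NA_real_, W)
  stride <- cfg$L_running %/% cfg$step
  if (cfg$priori == "tiled") {
    nback <- max(1L, as.integer(floor(cfg$L_priori * fs / cfg$L_running)))
    offs <- stride * seq_len(nback)
  } else {
    nback <- max(1L, as.integer(floor(cfg$L_priori * fs / cfg$step)))
    offs <- seq_len(nback)
  }
  warmup <- seq_len(W) <= max(offs)
  for (t in 2:W) {
    idx <- t - offs
    idx <- idx[idx >= 1L]
    if (length(idx) == 0L) idx <- seq_len(t - 1L)      # bootstrap: everything so far
    uw <- u[, idx, drop = FALSE]
    if (length(uw) < 2L) next
    est <- minimaxi_threshold(as.vector(uw))
    Tvec[t] <- est$T
    sig[t] <- est$sigma
  }
  list(T = Tvec, sigma = sig, warmup = warmup)
}

# The n1/n2 confirmation automaton over the per-step exceedance indicator.
# cond[t] is TRUE when any coefficient of frame t exceeds the threshold.
# With run lengths r1 = n1 + 1 ("additional") or n1 ("total"), the state
# becomes 1 when cond holds for r1 consecutive frames starting at t, 0 when
# !cond holds for r2 consecutive frames starting at t, and otherwise
# carries over.  Runs are truncated at the end of the series.  Initial
# state is de-synchronization (0).
.state_automaton <- function(cond, n1, n2, counting = "additional") {
  W <- length(cond)
  r1 <- if (counting == "additional") n1 + 1L else n1
  r2 <- if (counting == "additional") n2 + 1L else n2
  run_true <- integer(W)
  run_false <- integer(W)
  rt <- 0L; rf <- 0L
  for (t in W:1) {
    if (cond[t]) { rt <- rt + 1L; rf <- 0L } else { rf <- rf + 1L; rt <- 0L }
    run_true[t] <- rt; run_false[t] <- rf
  }
  remaining <- W - seq_len(W) + 1L
  go1 <- run_true >= pmin(r1, remaining)   # truncated look-ahead at the tail
  go0 <- run_false >= pmin(r2, remaining)
  states <- integer(W)
  s <- 0L
  for (t in seq_len(W)) {
    if (go1[t]) s <- 1L else if (go0[t]) s <- 0L
    states[t] <- s
  }
  states
}

#' Discriminate synchronization states from a coefficient series
#'
#' For each running-window frame the minimax threshold is estimated from
#' the trailing a-priori window of coefficients (excluding the current
#' frame) and the frame is a synchronization candidate when at least one
#' coefficient magnitude strictly exceeds the threshold.  Under the
#' default hysteresis strategy a state switch to synchronization requires
#' the candidate condition to hold for the current and the next \code{n1}
#' consecutive frames, and a switch to de-synchronization requires its
#' absence for the current and the next \code{n2} frames; otherwise the
#' previous state carries over.  The confirmed transition is stamped at
#' the first frame of the confirming run (in a streaming setting the label
#' is available after the look-ahead, which is the identification delay).
#'
#' @param coefs A \code{wp_coef_series} from \code{\link{windowed_decompose}}.
#' @param config A \code{\link{detector_config}}.
#' @return Object of class \code{binary_states}: list with integer
#'   \code{states} (0 = de-synchronization, 1 = synchronization), window
#'   start \code{time_s}, \code{step_s}, \code{warmup} flags (steps before
#'   the first full a-priori window), the per-step \code{threshold} and
#'   \code{sigma} traces, the exceedance indicator \code{cond}, and the
#'   \code{band} when known.
#' @export
detect_states <- function(coefs, config = detector_config()) {
  if (!inherits(coefs, "wp_coef_series"))
    stop("coefs must be a wp_coef_series", call. = FALSE)
  cfg <- config
  fs <- coefs$fs
  W <- ncol(coefs$u)
  need <- max(2L, cfg$L_running %/% cfg$step + 1L)
  if (W < need)
    stop("coefficient series shorter than one a-priori window bootstrap", call. = FALSE)
  if (cfg$L_priori * fs < cfg$L_running)
    stop("a-priori window shorter than the running window", call. = FALSE)
  thr <- .adaptive_thresholds(coefs$u, cfg, fs)
  cond <- colSums(abs(coefs$u) > rep(thr$T, each = nrow(coefs$u))) > 0
  states <- if (cfg$strategy == "simple") as.integer(cond)
            else .state_automaton(cond, cfg$n1, cfg$n2, cfg$counting)
  band <- names(cfg$basis)[match(coefs$basis, cfg$basis)]
  structure(list(states = states,
                 time_s = coefs$starts / fs,
                 step_s = coefs$step / fs,
                 t0_s = coefs$starts[1] / fs,
                 warmup = thr$warmup,
                 threshold = thr$T, sigma = thr$sigma, cond = cond,
                 band = if (length(band) == 1 && !is.na(band)) band else NA_character_,
                 config = cfg),
            class = "binary_states")
}

# Plain constructor used for ground-truth and toy series.
binary_states <- function(states, step_s, t0_s = 0, band = NA_character_,
                          warmup = NULL) {
  states <- as.integer(states)
  if (!all(states %in% c(0L, 1L))) stop("states must be 0/1", call. = FALSE)
  structure(list(states = states,
                 time_s = t0_s + step_s * (seq_along(states) - 1L),
                 step_s = step_s, t0_s = t0_s,
                 warmup = if (is.null(warmup)) rep(FALSE, length(states)) else warmup,
                 threshold = NULL, sigma = NULL, cond = NULL,
                 band = band, config = NULL),
            class = "binary_states")
}

#' @export
print.binary_states <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("Binary state series%s: %d steps of %.4g ms, %.1f%% synchronization\n",
              if (is.na(x$band)) "" else paste0(" (", x$band, ")"),
              n, 1000 * x$step_s, 100 * mean(x$states)))
  if (any(x$warmup))
    cat(sprintf("  %d warmup steps before the first full a-priori window\n",
                sum(x$warmup)))
  invisible(x)
}

#' Combine two binary state series into the joint neural state
#'
#' Binary encoding of the joint alpha-theta state: each step is labelled
#' with one of the four symbols \code{a0t0}, \code{a0t1}, \code{a1t0},
#' \code{a1t1}, where \code{a}/\code{t} carry the alpha/theta
#' synchronization bit (e.g. \code{a0t1} is alpha de-synchronized, theta
#' synchronized).  The two series must be aligned step for step.
#'
#' @param theta,alpha \code{binary_states} series of equal length, step and
#'   origin.
#' @return Object of class \code{joint_states}: list with the factor
#'   \code{states} (levels \code{a0t0}, \code{a0t1}, \code{a1t0},
#'   \code{a1t1}), \code{step_s}, \code{t0_s}, \code{warmup} (union), and
#'   the two marginal series.
#' @export
encode_joint <- function(theta, alpha) {
  if (!inherits(theta, "binary_states") || !inherits(alpha, "binary_states"))
    stop("inputs must be binary_states", call. = FALSE)
  if (length(theta$states) != length(alpha$states) ||
      abs(theta$step_s - alpha$step_s) > 1e-12 ||
      abs(theta$t0_s - alpha$t0_s) > 1e-9)
    stop("theta and alpha series are not aligned", call. = FALSE)
  lev <- c("a0t0", "a0t1", "a1t0", "a1t1")
  sym <- lev[1L + theta$states + 2L * alpha$states]
  structure(list(states = factor(sym, levels = lev),
                 step_s = theta$step_s, t0_s = theta$t0_s,
                 warmup = theta$warmup | alpha$warmup,
                 theta = theta, alpha = alpha),
            class = "joint_states")
}

#' @export
print.joint_states <- function(x, ...) {
  cat(sprintf("Joint neural state series: %d steps of %.4g ms\n",
              length(x$states), 1000 * x$step_s))
  tab <- 100 * table(x$states) / length(x$states)
  cat("  occurrence (%):", paste(sprintf("%s %.1f", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Occurrence frequency of a state
#'
#' Percentage of steps spent in a given state symbol,
#' \code{f = t_state / t_total * 100}.  For a \code{binary_states} series
#' the symbol is 0 or 1; for a \code{joint_states} series one of
#' \code{"a0t0"}, \code{"a0t1"}, \code{"a1t0"}, \code{"a1t1"}.  With
#' \code{symbol = NULL} the full occurrence table is returned (the four
#' joint frequencies sum to 100).
#'
#' @param states A \code{binary_states} or \code{joint_states} series.
#' @param symbol State symbol, or \code{NULL} for the full table.
#' @return Percentage (0-100), or a named vector of percentages.
#' @export
occurrence_frequency <- function(states, symbol = NULL) {
  if (inherits(states, "binary_states")) {
    s <- states$states
    if (length(s) == 0) stop("empty state series", call. = FALSE)
    if (is.null(symbol))
      return(c(`0` = 100 * mean(s == 0L), `1` = 100 * mean(s == 1L)))
    return(100 * mean(s == as.integer(symbol)))
  }
  if (inherits(states, "joint_states")) {
    s <- states$states
    if (length(s) == 0) stop("empty state series", call. = FALSE)
    tab <- 100 * table(s) / length(s)
    if (is.null(symbol)) return(c(tab))
    if (!symbol %in% levels(s)) stop("unknown state symbol '", symbol, "'", call. = FALSE)
    return(unname(tab[symbol]))
  }
  stop("states must be a binary_states or joint_states series", call. = FALSE)
}

#' Six-state occurrence report
#'
#' Occurrence frequencies of the six encoded states used to characterize a
#' recording: the marginal synchronization of each oscillation
#' (\code{a1}, \code{t1}) and the four joint states.  By construction
#' \code{t1 = a0t1 + a1t1} and \code{a1 = a1t0 + a1t1}.
#'
#' @param joint A \code{joint_states} series.
#' @return Named numeric vector of percentages
#'   (\code{a1, t1, a0t0, a0t1, a1t0, a1t1}).
#' @export
state_occurrence <- function(joint) {
  if (!inherits(joint, "joint_states"))
    stop("joint must be a joint_states series", call. = FALSE)
  tab <- occurrence_frequency(joint)
  c(a1 = unname(tab["a1t0"] + tab["a1t1"]),
    t1 = unname(tab["a0t1"] + tab["a1t1"]),
    tab)
}
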