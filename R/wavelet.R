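# Wavelet packet transform with periodized (circular) boundary handling.
#
# The two-channel analysis step computes, for a filter f of even length m,
#   a[k] = sum_j f[j] * x[(2k + m/2 - j) mod n],        k = 0 .. n/2-1
# and the synthesis step
#   x[t] = sum_j rec[j] * up[(t - j + m/2 - 1) mod n],  t = 0 .. n-1
# where up is the zero-upsampled coefficient vector.  With the built-in
# biorthogonal filter pairs this convention is perfectly reconstructing for
# any even signal length; filters longer than the signal are folded
# circularly, which preserves the reconstruction identity.

.wp_ana_step <- function(x, f) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n %% 2L != 0L) stop("signal length must be even", call. = FALSE)
  m <- length(f)
  k2 <- seq(0L, n - 2L, by = 2L)
  if (is.matrix(x)) {
    a <- matrix(0, n %/% 2L, ncol(x))
    for (j in seq_len(m) - 1L)
      a <- a + f[j + 1L] * x[((k2 + m %/% 2L - j) %% n) + 1L, , drop = FALSE]
  } else {
    a <- numeric(n %/% 2L)
    for (j in seq_len(m) - 1L)
      a <- a + f[j + 1L] * x[((k2 + m %/% 2L - j) %% n) + 1L]
  }
  a
}

.wp_syn_step <- function(a, d, flo, fhi) {
  mat <- is.matrix(a)
  nh <- if (mat) nrow(a) else length(a)
  n <- 2L * nh
  m <- length(flo)
  t0 <- 0:(n - 1L)
  if (mat) {
    ua <- matrix(0, n, ncol(a)); ud <- ua
    ua[seq(1L, n, by = 2L), ] <- a
    ud[seq(1L, n, by = 2L), ] <- d
    x <- matrix(0, n, ncol(a))
    for (j in seq_len(m) - 1L) {
      idx <- ((t0 - j + m %/% 2L - 1L) %% n) + 1L
      x <- x + flo[j + 1L] * ua[idx, , drop = FALSE] +
        fhi[j + 1L] * ud[idx, , drop = FALSE]
    }
  } else {
    ua <- numeric(n); ud <- numeric(n)
    ua[seq(1L, n, by = 2L)] <- a
    ud[seq(1L, n, by = 2L)] <- d
    x <- numeric(n)
    for (j in seq_len(m) - 1L) {
      idx <- ((t0 - j + m %/% 2L - 1L) %% n) + 1L
      x <- x + flo[j + 1L] * ua[idx] + fhi[j + 1L] * ud[idx]
    }
  }
  x
}

# Gray-code maps between natural (Paley) and frequency node orderings.
# The high-pass branch of each split mirrors the frequency axis, so the
# natural index of the node at frequency rank f is the binary-reflected
# Gray code of f.
.gray <- function(f) bitwXor(f, f %/% 2L)

.gray_inverse <- function(g) {
  f <- 0L
  while (g > 0L) {
    f <- bitwXor(f, g)
    g <- bitwShiftR(g, 1L)
  }
  f
}

#' Full wavelet packet decomposition
#'
#' Decomposes a signal down to a given level of the full wavelet packet
#' binary tree, producing one coefficient vector per terminal node.  Nodes
#' are returned in frequency order, so column \code{i} holds the band
#' \code{[(i-1), i) * fs/2^(level+1)}.  Boundaries are handled by circular
#' periodization, which keeps the transform perfectly reconstructing
#' (\code{\link{wp_reconstruct}}) and the coefficient count equal to the
#' signal length.
#'
#' @param x Numeric signal; its length must be divisible by \code{2^level}.
#' @param basis Wavelet basis name, one of \code{\link{wp_bases}()}.
#' @param level Decomposition depth (default 6, giving 64 bands).
#' @return An object of class \code{wp_decomposition}: a list with the
#'   coefficient matrix \code{coef} (\code{length(x)/2^level} rows, one
#'   column per frequency-ordered node), and the \code{basis}, \code{level}
#'   and original length \code{n}.
#' @export
#' @examples
#' x <- sin(2 * pi * 7.5 * (0:2303) / 384)
#' d <- wp_decompose(x, "rbio3.7", level = 6)
#' # energy concentrates in the 6-9 Hz node (frequency index 2)
#' which.max(colSums(d$coef^2)) - 1L
wp_decompose <- function(x, basis, level = 6L) {
  filt <- wp_filters(basis)
  n <- length(x)
  if (n < 2^level || n %% 2^level != 0)
    stop("signal length must be a positive multiple of 2^level", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  nodes <- list(x)  # natural order at current depth
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nxt[[2L * i - 1L]] <- .wp_ana_step(nodes[[i]], filt$dec_lo)
      nxt[[2L * i]] <- .wp_ana_step(nodes[[i]], filt$dec_hi)
    }
    nodes <- nxt
  }
  nn <- 2L^level
  coef <- matrix(0, n %/% nn, nn)
  for (f in 0:(nn - 1L)) coef[, f + 1L] <- nodes[[.gray(f) + 1L]]
  structure(list(coef = coef, basis = basis, level = level, n = n),
            class = "wp_decomposition")
}

#' Invert a full wavelet packet decomposition
#'
#' @param d A \code{wp_decomposition}, or a coefficient matrix in frequency
#'   order (then \code{basis} and \code{level} must be given).
#' @param basis,level Used only when \code{d} is a plain matrix.
#' @return The reconstructed signal.
#' @export
wp_reconstruct <- function(d, basis = NULL, level = NULL) {
  if (inherits(d, "wp_decomposition")) {
    coef <- d$coef; basis <- d$basis; level <- d$level
  } else coef <- d
  filt <- wp_filters(basis)
  nn <- 2L^level
  if (ncol(coef) != nn) stop("coefficient matrix has wrong number of nodes", call. = FALSE)
  nodes <- vector("list", nn)
  for (f in 0:(nn - 1L)) nodes[[.gray(f) + 1L]] <- coef[, f + 1L]
  for (l in seq_len(level)) {
    half <- length(nodes) %/% 2L
    nxt <- vector("list", half)
    for (i in seq_len(half))
      nxt[[i]] <- .wp_syn_step(nodes[[2L * i - 1L]], nodes[[2L * i]],
                               filt$rec_lo, filt$rec_hi)
    nodes <- nxt
  }
  nodes[[1L]]
}

#' Reconstruct the contribution of a single wavelet packet node
#'
#' Zeroes every node except the requested one and inverts the transform,
#' yielding the band-limited component of the signal.
#'
#' @param d A \code{wp_decomposition} (or coefficient matrix with
#'   \code{basis}/\code{level} supplied).
#' @param node Frequency-ordered node index, 0-based (0 = lowest band).
#' @param coef Optional replacement coefficients for the node (defaults to
#'   the node's own coefficients); length must match the node size.
#' @inheritParams wp_reconstruct
#' @return Band-limited signal of the original length.
#' @export
wp_reconstruct_node <- function(d, node, coef = NULL, basis = NULL, level = NULL) {
  if (inherits(d, "wp_decomposition")) {
    mat <- d$coef; basis <- d$basis; level <- d$level
  } else mat <- d
  if (node < 0 || node >= ncol(mat)) stop("node index out of range", call. = FALSE)
  u <- if (is.null(coef)) mat[, node + 1L] else coef
  if (length(u) != nrow(mat))
    stop("coefficient length does not match node size", call. = FALSE)
  z <- matrix(0, nrow(mat), ncol(mat))
  z[, node + 1L] <- u
  wp_reconstruct(z, basis = basis, level = level)
}

#' Frequency band of a wavelet packet node
#'
#' At level \code{L} the packet tree tiles \code{[0, fs/2)} into \code{2^L}
#' equal bands of width \code{fs/2^(L+1)}.  At the canonical 384 Hz / level
#' 6 configuration each band is 3 Hz wide; theta (6-9 Hz) is frequency
#' index 2 and alpha (9-12 Hz) is index 3.
#'
#' @param node Frequency-ordered node index (0-based).
#' @param fs Sampling rate in Hz.
#' @param level Tree depth.
#' @return List with \code{f_low}, \code{f_high} (Hz), the frequency
#'   \code{node} index, and the conventional tree \code{label} (natural
#'   ordering, e.g. \code{"[6 3]"} for 6-9 Hz at 384 Hz).
#' @export
#' @examples
#' band_for_node(2, fs = 384, level = 6)  # theta, labelled [6 3]
band_for_node <- function(node, fs, level = 6L) {
  nn <- 2L^level
  if (node < 0 || node >= nn) stop("node index out of range", call. = FALSE)
  w <- fs / 2 / nn
  list(f_low = node * w, f_high = (node + 1) * w, node = as.integer(node),
       label = wp_node_label(node, level))
}

#' @rdname band_for_node
#' @param f_low,f_high Band edges in Hz; must align exactly with the node
#'   grid, otherwise an error is raised.
#' @export
node_for_band <- function(f_low, f_high, fs, level = 6L) {
  w <- fs / 2 / 2^level
  node <- f_low / w
  if (abs(node - round(node)) > 1e-9 || abs((f_high - f_low) - w) > 1e-9)
    stop("band [", f_low, ", ", f_high, ") is not aligned to the ",
         w, " Hz node grid", call. = FALSE)
  band_for_node(round(node), fs, level)
}

#' @rdname band_for_node
#' @export
wp_node_label <- function(node, level = 6L) {
  sprintf("[%d %d]", as.integer(level), .gray(as.integer(node)))
}

# Frequency index of the canonical theta / alpha bands at fs=384, level 6.
.band_node <- function(band) {
  switch(match.arg(band, c("theta", "alpha")), theta = 2L, alpha = 3L)
}

# Default extraction basis per band.
.band_basis <- function(band) {
  switch(match.arg(band, c("theta", "alpha")),
         theta = "rbio3.7", alpha = "bior3.7")
}

# --- windowed (running) transform -------------------------------------------

# Linear operator mapping a running window of length L to the coefficients
# of one frequency-ordered node (rows = L/2^level coefficients).  Built by
# pushing the identity matrix through the analysis path; cached per
# (basis, level, node, L).
.op_cache <- new.env(parent = emptyenv())

.wp_node_operator <- function(basis, level, node, L) {
  key <- paste(basis, level, node, L, sep = "|")
  op <- .op_cache[[key]]
  if (!is.null(op)) return(op)
  filt <- wp_filters(basis)
  natural <- .gray(as.integer(node))
  x <- diag(L)
  for (l in seq_len(level)) {
    bit <- bitwAnd(bitwShiftR(natural, level - l), 1L)
    f <- if (bit == 0L) filt$dec_lo else filt$dec_hi
    x <- .wp_ana_step(x, f)
  }
  .op_cache[[key]] <- x
  x
}

# Inverse operator: node coefficients (length L/2^level) -> window signal.
.wp_node_recon_operator <- function(basis, level, node, L) {
  key <- paste("R", basis, level, node, L, sep = "|")
  op <- .op_cache[[key]]
  if (!is.null(op)) return(op)
  filt <- wp_filters(basis)
  natural <- .gray(as.integer(node))
  nc <- L %/% 2L^level
  x <- diag(nc)
  for (l in rev(seq_len(level))) {
    bit <- bitwAnd(bitwShiftR(natural, level - l), 1L)
    z <- matrix(0, nrow(x), ncol(x))
    x <- if (bit == 0L) .wp_syn_step(x, z, filt$rec_lo, filt$rec_hi)
         else .wp_syn_step(z, x, filt$rec_lo, filt$rec_hi)
  }
  .op_cache[[key]] <- x
  x
}

#' Running-window wavelet packet coefficients of one node
#'
#' Slides a short analysis window along the signal and computes, for each
#' position, the wavelet packet coefficients of a single frequency node.
#' This is the streaming-compatible front end of the oscillation extraction
#' model: the frame at window start \code{t} depends only on the samples in
#' \code{[t, t + L_running)}.
#'
#' The nominal 20 ms update interval quantizes to 8 samples (20.83 ms) at
#' 384 Hz, which is the default step.
#'
#' @param x Numeric signal (or an \code{lfp_recording}).
#' @param basis Wavelet basis name.
#' @param node Frequency-ordered node index (0-based); see
#'   \code{\link{node_for_band}}.
#' @param L_running Window length in samples; must be a multiple of
#'   \code{2^level}.  Default 128 (2 coefficients per frame at level 6).
#' @param step Window advance in samples (default 8).
#' @param level Tree depth (default 6).
#' @param fs Sampling rate, taken from \code{x} when it is a recording.
#' @return Object of class \code{wp_coef_series}: list with \code{u}
#'   (coefficient matrix, one column per frame), \code{starts} (0-based
#'   window start samples), \code{step}, \code{fs}, \code{node},
#'   \code{basis}, \code{level}, \code{L_running}.
#' @export
windowed_decompose <- function(x, basis, node, L_running = 128L, step = 8L,
                               level = 6L, fs = 384) {
  if (inherits(x, "lfp_recording")) { fs <- x$fs; x <- x$samples }
  if (L_running %% 2^level != 0)
    stop("L_running must be a multiple of 2^level", call. = FALSE)
  n <- length(x)
  if (n < L_running) stop("signal shorter than the running window", call. = FALSE)
  starts <- seq(0L, n - L_running, by = as.integer(step))
  W <- matrix(x[outer(1:L_running, starts, `+`)], nrow = L_running)
  op <- .wp_node_operator(basis, level, node, L_running)
  structure(list(u = op %*% W, starts = starts, step = as.integer(step),
                 fs = fs, node = as.integer(node), basis = basis,
                 level = as.integer(level), L_running = as.integer(L_running)),
            class = "wp_coef_series")
}

#' @export
print.wp_coef_series <- function(x, ...) {
  cat("Running-window WP coefficient series\n")
  cat(sprintf("  basis %s, node %d (%s, %.1f-%.1f Hz), %d frames of %d coefficients\n",
              x$basis, x$node, wp_node_label(x$node, x$level),
              band_for_node(x$node, x$fs, x$level)$f_low,
              band_for_node(x$node, x$fs, x$level)$f_high,
              ncol(x$u), nrow(x$u)))
  cat(sprintf("  window %d samples, step %d samples (%.2f ms at %g Hz)\n",
              x$L_running, x$step, 1000 * x$step / x$fs, x$fs))
  invisible(x)
}

# --- basis selection --------------------------------------------------------

#' Shannon entropy of a wavelet coefficient vector
#'
#' Measures how sparsely a basis represents a signal: the squared
#' coefficients are normalized to an energy distribution \code{p} and
#' \code{H = -sum(p * log(p))} (natural log) is returned.  A basis matched
#' to the oscillation concentrates energy in few coefficients and yields a
#' low entropy; \code{H} attains its maximum \code{log(K)} for a uniform
#' spread over \code{K} coefficients and 0 for a one-hot vector.
#'
#' @param u Numeric coefficient vector; must contain non-zero energy.
#' @return Entropy in nats.
#' @export
#' @examples
#' basis_entropy(rep(1, 64))  # log(64)
#' basis_entropy(c(1, 0, 0))  # 0
basis_entropy <- function(u) {
  if (length(u) == 0) stop("empty coefficient vector", call. = FALSE)
  e <- u^2
  s <- sum(e)
  if (s == 0) stop("all-zero coefficients: energy distribution undefined", call. = FALSE)
  p <- e / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Rank wavelet packet bases by coefficient entropy
#'
#' Decomposes the signal with each candidate basis and ranks the bases by
#' the Shannon entropy of the coefficients of the target node, ascending
#' (sparsest first).  Ties keep the candidate-list order.  Candidates not
#' in the built-in filter bank are skipped with a warning.
#'
#' @param x Signal (length a multiple of \code{2^level}).
#' @param candidates Character vector of basis names; defaults to the full
#'   candidate set in \code{\link{wp_bases}()}.
#' @param node Frequency-ordered node index of the oscillation band.
#' @param level Tree depth.
#' @return Data frame with columns \code{basis} and \code{entropy}, sorted
#'   ascending by entropy.
#' @export
select_basis <- function(x, candidates = wp_bases(), node, level = 6L) {
  if (length(candidates) < 1) stop("no candidate bases", call. = FALSE)
  known <- candidates %in% wp_bases()
  if (any(!known)) {
    warning("skipping unknown bases: ", paste(candidates[!known], collapse = ", "))
    candidates <- candidates[known]
  }
  H <- vapply(candidates, function(b) {
    d <- wp_decompose(x, b, level)
    basis_entropy(d$coef[, node + 1L])
  }, numeric(1))
  res <- data.frame(basis = candidates, entropy = unname(H),
                    stringsAsFactors = FALSE)
  res[order(res$entropy), , drop = FALSE]
}

# --- running window length selection ----------------------------------------

#' Percentage root-mean-square deviation between two signals
#'
#' \code{e = 100 * sqrt(mean((y - x)^2)) / c} where the normalizer \code{c}
#' is the mean of the reference signal (\code{normalize = "mean"}) or its
#' RMS (\code{normalize = "rms"}).  Band-limited oscillations are
#' essentially zero-mean, so mean normalization is refused when
#' \code{|mean(x)|} is negligible relative to the signal scale; use the RMS
#' variant there.
#'
#' @param x_ref Reference signal.
#' @param y_exp Experimental signal, same length.
#' @param normalize \code{"mean"} or \code{"rms"}.
#' @return Relative error in percent (0 iff the signals are identical).
#' @export
#' @examples
#' relative_error(rep(1, 10), rep(1.1, 10))  # 10
relative_error <- function(x_ref, y_exp, normalize = c("mean", "rms")) {
  normalize <- match.arg(normalize)
  if (length(x_ref) != length(y_exp)) stop("length mismatch", call. = FALSE)
  if (length(x_ref) == 0) stop("empty signals", call. = FALSE)
  rmsd <- sqrt(mean((y_exp - x_ref)^2))
  if (normalize == "mean") {
    xbar <- mean(x_ref)
    if (abs(xbar) < 1e-3 * max(1e-300, sqrt(mean(x_ref^2))))
      stop("reference mean is near zero relative to its RMS; ",
           "use normalize = \"rms\"", call. = FALSE)
    100 * rmsd / abs(xbar)
  } else {
    xr <- sqrt(mean(x_ref^2))
    if (xr == 0) stop("reference signal is identically zero", call. = FALSE)
    100 * rmsd / xr
  }
}

# Windowed node reconstruction used by the window-length sweep: consecutive
# non-overlapping windows of length L, each zero-padded up to the next
# multiple of 2^level when needed, decomposed along the node path and
# reconstructed; the concatenation is truncated to the tiled length.
.windowed_node_recon <- function(x, basis, node, L, level = 6L) {
  nn <- 2L^level
  Lp <- as.integer(ceiling(L / nn) * nn)
  nwin <- length(x) %/% L
  if (nwin < 1) stop("signal shorter than the window", call. = FALSE)
  xt <- x[seq_len(nwin * L)]
  W <- matrix(0, Lp, nwin)
  W[seq_len(L), ] <- matrix(xt, nrow = L)
  op <- .wp_node_operator(basis, level, node, Lp)
  rop <- .wp_node_recon_operator(basis, level, node, Lp)
  Y <- rop %*% (op %*% W)
  as.vector(Y[seq_len(L), ])
}

#' Sweep the running-window length and measure representation error
#'
#' For each candidate window length, the oscillation of one node is
#' reconstructed from windowed coefficients (consecutive non-overlapping
#' windows) and compared, via \code{\link{relative_error}} with RMS
#' normalization, against the reconstruction from a single whole-signal
#' transform.  Window lengths that are multiples of \code{2^level} align
#' with the coefficient grid and show local error minima.
#'
#' @param signals A numeric vector or list of numeric vectors (e.g. 6-s
#'   segments).
#' @param basis Wavelet basis.
#' @param node Frequency-ordered node index.
#' @param lengths Candidate window lengths in samples (default 32 to 200).
#' @param level Tree depth.
#' @return Object of class \code{wp_window_sweep}: data frame with
#'   \code{length} and mean \code{error} (percent), plus the per-signal
#'   error matrix as attribute \code{"errors"}.
#' @export
sweep_window_length <- function(signals, basis, node,
                                lengths = seq(32L, 200L, by = 8L), level = 6L) {
  if (!is.list(signals)) signals <- list(signals)
  if (any(lengths < 2)) stop("window lengths must be >= 2 samples", call. = FALSE)
  errs <- matrix(NA_real_, length(lengths), length(signals))
  for (si in seq_along(signals)) {
    x <- signals[[si]]
    ref_full <- wp_reconstruct_node(wp_decompose(x, basis, level), node)
    for (li in seq_along(lengths)) {
      L <- lengths[li]
      y <- .windowed_node_recon(x, basis, node, L, level)
      errs[li, si] <- relative_error(ref_full[seq_along(y)], y, normalize = "rms")
    }
  }
  res <- data.frame(length = as.integer(lengths), error = rowMeans(errs))
  attr(res, "errors") <- errs
  class(res) <- c("wp_window_sweep", "data.frame")
  res
}
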