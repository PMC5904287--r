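# Independent oracles coded directly from the rule definitions, kept
# deliberately naive and separate from the package internals.

# Literal simulation of the n1/n2 discrimination rule: at each step look
# ahead explicitly and re-evaluate the run conditions with plain loops.
oracle_automaton <- function(cond, n1, n2, counting = "additional") {
  W <- length(cond)
  r1 <- if (counting == "additional") n1 + 1L else n1
  r2 <- if (counting == "additional") n2 + 1L else n2
  states <- integer(W)
  prev <- 0L
  for (t in seq_len(W)) {
    hi <- min(W, t + r1 - 1L)
    sync_run <- TRUE
    for (j in t:hi) if (!cond[j]) { sync_run <- FALSE; break }
    hi2 <- min(W, t + r2 - 1L)
    quiet_run <- TRUE
    for (j in t:hi2) if (cond[j]) { quiet_run <- FALSE; break }
    if (sync_run) prev <- 1L else if (quiet_run) prev <- 0L
    states[t] <- prev
  }
  states
}

# Per-step confusion counting for duration-based sensitivity/specificity.
oracle_confusion <- function(id, truth, dt, warmup = rep(FALSE, length(id))) {
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(id)) {
    if (warmup[i]) next
    if (truth[i] == 1L) {
      if (id[i] == 1L) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (id[i] == 0L) tn <- tn + 1L else fp <- fp + 1L
    }
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       Ts = (tp + fn) * dt, Td = (tn + fp) * dt, ts = tp * dt, td = tn * dt)
}

# Spearman rho via the defining Pearson correlation of average ranks,
# written out elementwise.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Exhaustive two-sided permutation p-value for Spearman rho.
oracle_spearman_p <- function(x, y) {
  obs <- abs(oracle_spearman_rho(x, y))
  perms <- .perm_list(length(y))
  hits <- 0L
  for (p in perms)
    if (abs(oracle_spearman_rho(x, y[p])) >= obs - 1e-12) hits <- hits + 1L
  hits / length(perms)
}

.perm_list <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n))
    for (p in .perm_list(n - 1L))
      out[[length(out) + 1L]] <- c(k, ifelse(p >= k, p + 1L, p))
  out
}

# Literal percentage-RMSD formula.
oracle_relative_error <- function(x, y, norm) {
  s <- 0
  for (k in seq_along(x)) s <- s + (y[k] - x[k])^2
  100 * sqrt(s / length(x)) / norm
}

# Small deterministic theta-burst fixture: a 7.5 Hz tone gated by a square
# envelope, with light noise from a fixed seed.
theta_burst_fixture <- function(duration_s = 6, snr_db = Inf, seed = 42) {
  generate_trial(simulation_spec("theta", snr_db = snr_db,
                                 duration_s = duration_s, seed = seed))
}
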