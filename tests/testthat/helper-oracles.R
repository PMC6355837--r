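# Independent brute-force oracles used to check the package implementations.
# Each is deliberately written from first principles, not by calling the
# code path it validates.

# naive exact two-sided Spearman permutation p: loop over every permutation
# of y and call cor() on average ranks
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  perms <- oracle_perms(n)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- cor(rx, ry)
  count <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(cor(rx, ry[perms[i, ]])) >= abs(rho_obs) - 1e-12) count <- count + 1L
  }
  count / nrow(perms)
}

oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    s <- sub
    s[s >= i] <- s[s >= i] + 1L
    out <- rbind(out, cbind(i, s))
  }
  out
}

# brute-force variable-CpG classification: sort, keep central band by
# type-7 quantiles, compare the range to the cutoff
oracle_classify_variable <- function(v, trim = 0.10, min_range = 0.05) {
  v <- sort(v[!is.na(v)])
  lo <- quantile(v, trim, type = 7, names = FALSE)
  hi <- quantile(v, 1 - trim, type = 7, names = FALSE)
  kept <- v[v >= lo & v <= hi]
  if (!length(kept)) return(FALSE)
  (kept[length(kept)] - kept[1]) >= min_range
}

# independent greedy matrix cleaner: recompute fractions from scratch every
# iteration, remove the worst row (preferring rows on ties, then the
# lexicographically smallest name)
oracle_greedycut <- function(m, stop_fraction) {
  removed <- data.frame(type = character(0), id = character(0), stringsAsFactors = FALSE)
  repeat {
    if (nrow(m) == 0 || ncol(m) == 0) break
    rf <- apply(m, 1, mean)
    cf <- apply(m, 2, mean)
    if (max(c(rf, cf)) <= stop_fraction) break
    if (max(rf) >= max(cf)) {
      id <- min(names(rf)[rf == max(rf)])
      removed <- rbind(removed, data.frame(type = "probe", id = id))
      m <- m[rownames(m) != id, , drop = FALSE]
    } else {
      id <- min(names(cf)[cf == max(cf)])
      removed <- rbind(removed, data.frame(type = "sample", id = id))
      m <- m[, colnames(m) != id, drop = FALSE]
    }
  }
  list(removed = removed, final = m)
}

# two-pass Pearson correlation from the definitional formula
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# closed-form simple OLS via the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept)
}

# Monte-Carlo oracle for the generator's latent correlation model: simulate
# the variance components directly (shared subject effect + independent
# noise) and measure the mean per-probe Spearman correlation
oracle_mean_spearman <- function(target_rho, noise_sd, n_subjects, n_probes, seed) {
  set.seed(seed)
  subj_sd <- sqrt(target_rho / (1 - target_rho)) * noise_sd
  rho <- numeric(n_probes)
  u <- matrix(rnorm(n_subjects * n_probes, 0, subj_sd), n_subjects)
  e1 <- matrix(rnorm(n_subjects * n_probes, 0, noise_sd), n_subjects)
  e2 <- matrix(rnorm(n_subjects * n_probes, 0, noise_sd), n_subjects)
  for (j in seq_len(n_probes)) {
    rho[j] <- cor(rank(u[, j] + e1[, j]), rank(u[, j] + e2[, j]))
  }
  mean(rho)
}

# exhaustive simplex grid search for the constrained least-squares objective
oracle_simplex_grid <- function(R, y, resolution = 0.01) {
  K <- ncol(R)
  stopifnot(K %in% c(2, 3))
  grid <- seq(0, 1, by = resolution)
  best <- Inf
  best_w <- NULL
  if (K == 2) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      obj <- sum((R %*% w - y)^2)
      if (obj < best) { best <- obj; best_w <- w }
    }
  } else {
    for (w1 in grid) for (w2 in grid[grid <= 1 - w1 + 1e-12]) {
      w <- c(w1, w2, 1 - w1 - w2)
      obj <- sum((R %*% w - y)^2)
      if (obj < best) { best <- obj; best_w <- w }
    }
  }
  list(objective = best, w = best_w)
}
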