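# Reference-based cell-type composition estimation and adjustment.
#
# Proportions are estimated per sample by least squares onto the reference
# cell-type beta profiles under simplex constraints (weights nonnegative,
# summing to one). Adjustment residualizes each probe on the estimated
# proportions and re-centers at the probe mean, reporting the share of
# variance the composition model explains.

#' Construct reference cell-type beta profiles
#'
#' @param profiles matrix of mean beta values, cell types x probes, with
#'   cell-type row names and probe column names
#' @return `ReferenceProfiles` object (validated matrix)
#' @export
reference_profiles <- function(profiles) {
  if (!is.matrix(profiles) || nrow(profiles) < 2) {
    stop("reference must be a matrix with >= 2 cell-type rows", call. = FALSE)
  }
  if (any(profiles < 0 | profiles > 1)) {
    stop("reference betas must lie in [0,1]", call. = FALSE)
  }
  if (is.null(rownames(profiles)) || is.null(colnames(profiles))) {
    stop("reference needs cell-type row names and probe column names", call. = FALSE)
  }
  class(profiles) <- c("ReferenceProfiles", class(profiles))
  profiles
}

# exact simplex-constrained least squares: min ||R w - y||^2, w >= 0,
# sum(w) = 1. The optimum's support is one of the 2^K - 1 cell-type subsets;
# each candidate is solved through its equality-constrained KKT system and
# the feasible solution with the smallest objective is returned. Exact for
# the small K typical of tissue deconvolution.
simplex_lsq <- function(R, y) {
  K <- ncol(R)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^K - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    Rs <- R[, S, drop = FALSE]
    G <- crossprod(Rs)
    kkt <- rbind(cbind(2 * G, rep(1, length(S))),
                 c(rep(1, length(S)), 0))
    rhs <- c(2 * crossprod(Rs, y), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_along(S)]
    if (any(w < -1e-9)) next
    w[w < 0] <- 0
    w <- w / sum(w)
    obj <- sum((Rs %*% w - y)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- numeric(K)
      best[S] <- w
    }
  }
  list(w = best, objective = best_obj)
}

#' Estimate cell-type proportions per sample
#'
#' Constrained least squares of each sample's beta profile onto the
#' reference cell-type profiles, with weights nonnegative and summing to 1.
#'
#' @param sample_betas probe x sample beta matrix
#' @param reference [reference_profiles()] matrix (cell types x probes)
#' @param min_shared minimum number of probes shared between sample and
#'   reference (default 50)
#' @return `ProportionEstimate` list: `proportions` (sample x cell type),
#'   `residual_norm` per sample, `n_probes_used`
#' @export
estimate_proportions <- function(sample_betas, reference, min_shared = 50) {
  shared <- intersect(rownames(sample_betas), colnames(reference))
  if (length(shared) < min_shared) {
    stop(sprintf("only %d probes shared between samples and reference (need >= %d)",
                 length(shared), min_shared), call. = FALSE)
  }
  R <- t(unclass(reference)[, shared, drop = FALSE])   # probes x cell types
  if (qr(R)$rank < ncol(R)) {
    stop("reference profiles are rank-deficient on the shared probes", call. = FALSE)
  }
  Y <- sample_betas[shared, , drop = FALSE]
  n_s <- ncol(Y)
  K <- ncol(R)
  W <- matrix(NA_real_, n_s, K, dimnames = list(colnames(Y), colnames(R)))
  resid_norm <- numeric(n_s)
  for (j in seq_len(n_s)) {
    fit <- simplex_lsq(R, Y[, j])
    W[j, ] <- fit$w
    resid_norm[j] <- sqrt(fit$objective)
  }
  out <- list(proportions = W, residual_norm = resid_norm,
              n_probes_used = length(shared))
  class(out) <- "ProportionEstimate"
  out
}

#' Adjust beta values for cell-type composition
#'
#' Per probe, ordinary least squares of beta on the estimated cell-type
#' proportions (one column dropped to remove the sum-to-one collinearity);
#' the adjusted value is the residual plus the probe mean, clipped to
#' \[0,1\]. The per-probe R-squared of the composition model quantifies how
#' much methylation variation composition explains.
#'
#' @param betas probe x sample beta matrix
#' @param proportions a [estimate_proportions()] result or a sample x
#'   cell-type weight matrix covering every sample
#' @return list: `adjusted` (same shape as `betas`), `r_squared` per probe,
#'   `n_clipped` count of entries clipped to \[0,1\]
#' @export
adjust_for_composition <- function(betas, proportions) {
  W <- if (inherits(proportions, "ProportionEstimate")) proportions$proportions else proportions
  if (!all(colnames(betas) %in% rownames(W))) {
    stop("proportions missing for some samples", call. = FALSE)
  }
  W <- W[colnames(betas), , drop = FALSE]
  n_s <- ncol(betas)
  if (ncol(W) > n_s) stop("more cell types than samples", call. = FALSE)
  X <- cbind(1, W[, -1, drop = FALSE])           # drop one column: sum-to-one
  # pivoted QR tolerates rank deficiency (e.g. constant proportions, where
  # the model reduces to the intercept and adjustment is a no-op)
  qx <- qr(X)
  resid <- t(qr.resid(qx, t(betas)))
  mu <- rowMeans(betas)
  adjusted <- resid + mu
  n_clipped <- sum(adjusted < 0 | adjusted > 1)
  adjusted <- pmin(pmax(adjusted, 0), 1)
  sst <- rowSums((betas - mu)^2)
  sse <- rowSums(resid^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  list(adjusted = adjusted, r_squared = r2, n_clipped = n_clipped)
}

#' Compare concordance before and after composition adjustment
#'
#' @param records_raw,records_adjusted within-subject correlation tables
#'   over the same probe set
#' @param p_nominal nominal significance level for the proportion deltas
#' @return list: `per_probe` (probe_id, rho_raw, rho_adjusted, delta_rho),
#'   `delta_mean_rho`, `delta_prop_nominal`
#' @export
compare_adjusted_concordance <- function(records_raw, records_adjusted,
                                         p_nominal = 0.05) {
  sym_diff <- length(setdiff(records_raw$probe_id, records_adjusted$probe_id)) +
    length(setdiff(records_adjusted$probe_id, records_raw$probe_id))
  if (sym_diff > 0) {
    stop(sprintf("probe sets differ (symmetric difference: %d probes)", sym_diff),
         call. = FALSE)
  }
  i <- match(records_raw$probe_id, records_adjusted$probe_id)
  adj <- records_adjusted[i, , drop = FALSE]
  per_probe <- data.frame(
    probe_id = records_raw$probe_id,
    rho_raw = records_raw$rho,
    rho_adjusted = adj$rho,
    delta_rho = adj$rho - records_raw$rho,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(records_raw$rho) & !is.na(adj$rho)
  okp <- !is.na(records_raw$p) & !is.na(adj$p)
  list(
    per_probe = per_probe,
    delta_mean_rho = mean(adj$rho[ok]) - mean(records_raw$rho[ok]),
    delta_prop_nominal = mean(adj$p[okp] < p_nominal) - mean(records_raw$p[okp] < p_nominal)
  )
}
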