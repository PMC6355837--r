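# Cross-tissue concordance: across-subject Pearson correlation of averaged
# methylation profiles, per-CpG within-subject Spearman correlation with
# exact permutation p-values at small n, the interpercentile-range
# variability classifier, Bonferroni family-wise thresholds, and the
# covariance-corrected comparison of dependent overlapping correlations.

#' Per-probe mean methylation profile
#'
#' Arithmetic mean over non-missing samples for each probe; a probe with all
#' values missing yields NA.
#'
#' @param betas probe x sample beta matrix
#' @return named numeric vector of per-probe means
#' @export
mean_profile <- function(betas) {
  if (is.null(dim(betas))) betas <- cbind(betas)
  if (ncol(betas) < 1) stop("need >= 1 sample", call. = FALSE)
  m <- rowMeans(betas, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Across-subject correlation of two tissue profiles
#'
#' Pearson correlation, over probes, between two subject-averaged methylation
#' profiles. Subsetting to location- or annotation-defined probe sets yields
#' the stratified versions of the same analysis.
#'
#' @param profile_a,profile_b named per-probe mean vectors
#' @param probe_subset optional probe ids (or indices) to restrict to
#' @return list with `rho` (Pearson r) and `n` (probes used)
#' @export
across_subject_correlation <- function(profile_a, profile_b, probe_subset = NULL) {
  if (!is.null(probe_subset)) {
    profile_a <- profile_a[probe_subset]
    profile_b <- profile_b[probe_subset]
  }
  ok <- !is.na(profile_a) & !is.na(profile_b)
  a <- profile_a[ok]
  b <- profile_b[ok]
  if (length(a) < 3) stop("need >= 3 probes after subsetting/missing removal", call. = FALSE)
  if (stats::sd(a) == 0) stop("zero variance in profile_a", call. = FALSE)
  if (stats::sd(b) == 0) stop("zero variance in profile_b", call. = FALSE)
  list(rho = stats::cor(a, b), n = length(a))
}

# ---- exact Spearman permutation machinery ---------------------------------

# all permutations of 1..n as an n! x n matrix (n <= 7 in practice)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    s <- sub
    s[s >= i] <- s[s >= i] + 1L
    cbind(rep(i, nrow(s)), s)
  }))
}

.spearman_cache <- new.env(parent = emptyenv())

# null |rho| values over all permutations of untied ranks 1..n (cached)
spearman_null_abs <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  P <- all_perms(n)
  r <- seq_len(n)
  rc <- r - mean(r)
  ss <- sum(rc^2)
  rho <- as.numeric((P %*% rc) - mean(r) * sum(rc)) / ss
  .spearman_cache[[key]] <- abs(rho)
  abs(rho)
}

# exact two-sided permutation p-value for Spearman's rho given the two
# observed (possibly tied, average-rank) rank vectors
spearman_exact_p <- function(rank_a, rank_b) {
  n <- length(rank_a)
  rho_obs <- stats::cor(rank_a, rank_b)
  if (is.na(rho_obs)) return(NA_real_)
  if (!any(duplicated(rank_a)) && !any(duplicated(rank_b))) {
    null_abs <- spearman_null_abs(n)
    return(mean(null_abs >= abs(rho_obs) - 1e-12))
  }
  P <- all_perms(n)
  Yp <- matrix(rank_b[P], nrow(P), n)
  ac <- rank_a - mean(rank_a)
  ssy <- sum((rank_b - mean(rank_b))^2)
  ssa <- sum(ac^2)
  if (ssa == 0 || ssy == 0) return(NA_real_)
  rho_all <- as.numeric(Yp %*% ac) / sqrt(ssa * ssy)
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# two-sided p from the t approximation with df = n - 2
spearman_approx_p <- function(rho, n) {
  rho2 <- pmin(rho^2, 1)
  tval <- abs(rho) * sqrt((n - 2) / pmax(1 - rho2, .Machine$double.eps))
  p <- 2 * stats::pt(-tval, df = n - 2)
  p[rho2 >= 1] <- 0
  pmin(p, 1)
}

# collapse a probe x sample matrix to probe x subject means
collapse_to_subjects <- function(betas, sample_sheet) {
  samples <- colnames(betas)
  subj <- sample_sheet$subject[match(samples, sample_sheet$sample)]
  if (anyNA(subj)) stop("samples missing from sample_sheet: ",
                        paste(samples[is.na(subj)], collapse = ", "), call. = FALSE)
  us <- unique(subj)
  out <- matrix(NA_real_, nrow(betas), length(us),
                dimnames = list(rownames(betas), us))
  for (s in us) {
    cols <- which(subj == s)
    out[, s] <- if (length(cols) == 1) betas[, cols] else
      rowMeans(betas[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-CpG within-subject Spearman correlations between two tissues
#'
#' For each probe, computes Spearman's rank correlation across subjects
#' between paired measurements in the two tissues (pairwise-complete
#' subjects; duplicate samples per subject-tissue are averaged first).
#' Two-sided p-values use exhaustive permutation enumeration when the number
#' of complete pairs is at most `exact_cutoff` and the t approximation with
#' df = n - 2 otherwise. Probes with fewer than `min_pairs` complete pairs or
#' zero variance yield NA rho/p with the pair count recorded.
#'
#' @param betas_a,betas_b probe x sample beta matrices for the two tissues
#'   (tissue a is conventionally the reference/brain tissue)
#' @param sample_sheet data.frame with `sample` and `subject` columns
#' @param min_pairs minimum complete subject pairs to report a correlation
#' @param exact_cutoff largest n for exact permutation p-values (default 7)
#' @param trim,min_range passed to [classify_variable()] for the per-tissue
#'   variability flags attached to each record
#' @return data.frame with columns `probe_id`, `rho`, `p`, `n_pairs`,
#'   `variable_a`, `variable_b`
#' @export
within_subject_correlations <- function(betas_a, betas_b, sample_sheet,
                                        min_pairs = 5, exact_cutoff = 7,
                                        trim = 0.10, min_range = 0.05) {
  A <- collapse_to_subjects(betas_a, sample_sheet)
  B <- collapse_to_subjects(betas_b, sample_sheet)
  common <- intersect(colnames(A), colnames(B))
  if (length(common) < min_pairs) {
    stop(sprintf("only %d subjects present in both tissues (min_pairs = %d)",
                 length(common), min_pairs), call. = FALSE)
  }
  probes <- rownames(betas_a)
  if (is.null(probes)) probes <- sprintf("p%06d", seq_len(nrow(betas_a)))
  A <- A[, common, drop = FALSE]
  B <- B[, common, drop = FALSE]
  n_probes <- nrow(A)

  var_a <- classify_variable(A, trim = trim, min_range = min_range)
  var_b <- classify_variable(B, trim = trim, min_range = min_range)

  rho <- rep(NA_real_, n_probes)
  pval <- rep(NA_real_, n_probes)
  n_pairs <- integer(n_probes)

  complete <- !is.na(A) & !is.na(B)
  n_pairs <- rowSums(complete)
  full <- n_pairs == length(common)

  if (any(full)) {
    idx <- which(full)
    RA <- t(apply(A[idx, , drop = FALSE], 1, rank))
    RB <- t(apply(B[idx, , drop = FALSE], 1, rank))
    RAc <- RA - rowMeans(RA)
    RBc <- RB - rowMeans(RB)
    ssa <- rowSums(RAc^2)
    ssb <- rowSums(RBc^2)
    ok <- ssa > 0 & ssb > 0
    r <- rep(NA_real_, length(idx))
    r[ok] <- rowSums(RAc * RBc)[ok] / sqrt(ssa[ok] * ssb[ok])
    r <- pmin(pmax(r, -1), 1)
    rho[idx] <- r
    n <- length(common)
    if (n > exact_cutoff) {
      pv <- rep(NA_real_, length(idx))
      pv[ok] <- spearman_approx_p(r[ok], n)
      pval[idx] <- pv
    } else {
      for (j in seq_along(idx)) {
        if (ok[j]) pval[idx[j]] <- spearman_exact_p(RA[j, ], RB[j, ])
      }
    }
  }

  partial <- which(!full & n_pairs >= min_pairs)
  for (i in partial) {
    keep <- complete[i, ]
    a <- A[i, keep]
    b <- B[i, keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ra <- rank(a); rb <- rank(b)
    rho[i] <- stats::cor(ra, rb)
    pval[i] <- if (length(a) <= exact_cutoff) spearman_exact_p(ra, rb) else
      spearman_approx_p(rho[i], length(a))
  }

  data.frame(probe_id = probes, rho = rho, p = pval, n_pairs = as.integer(n_pairs),
             variable_a = var_a, variable_b = var_b,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify variable CpGs by interpercentile range
#'
#' Discards each probe's values outside the central interpercentile band
#' (by default the 10th-90th percentile, type-7 quantiles), then flags the
#' probe as variable when the remaining values still span at least
#' `min_range` on the beta scale (boundary inclusive, "at least").
#'
#' @param betas probe x sample beta matrix (or a single numeric vector)
#' @param trim one-sided trimming fraction, in \[0, 0.5)
#' @param min_range minimum post-trim range on the beta scale
#' @return logical vector per probe (NA when fewer than 3 non-missing values)
#' @export
classify_variable <- function(betas, trim = 0.10, min_range = 0.05) {
  if (trim < 0 || trim >= 0.5) {
    stop("invalid `trim`: must lie in [0, 0.5)", call. = FALSE)
  }
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  apply(betas, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA)
    q <- stats::quantile(v, c(trim, 1 - trim), type = 7, names = FALSE)
    kept <- v[v >= q[1] & v <= q[2]]
    if (length(kept) == 0) return(FALSE)
    (max(kept) - min(kept)) >= min_range
  })
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha family-wise error rate, in (0,1)
#' @param m number of tests (>= 1)
#' @return the per-test threshold alpha / m
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("invalid `alpha`: must lie in (0,1)", call. = FALSE)
  if (m < 1) stop("invalid `m`: must be >= 1", call. = FALSE)
  alpha / m
}

#' Summarize a within-subject correlation table
#'
#' Reports, over evaluable records (non-missing rho and p), the fraction
#' nominally significant, the fraction with moderately strong correlation,
#' mean and median rho, and the count surviving Bonferroni correction.
#' `restrict_variable` reproduces the variable-CpG analyses: "peripheral"
#' keeps probes variable in tissue b, "brain" those variable in tissue a,
#' "both" their intersection.
#'
#' @param records output of [within_subject_correlations()]
#' @param restrict_variable one of "none", "peripheral", "brain", "both"
#' @param p_nominal nominal significance level (default 0.05)
#' @param rho_moderate threshold for "moderately strong" rho (default 0.5)
#' @param bonferroni_alpha,bonferroni_m family-wise level and family size for
#'   the Bonferroni count; `bonferroni_m` defaults to the total record count
#' @param profile_a,profile_b optional subject-averaged profiles; when given,
#'   the across-subject Pearson correlation over the summarized probe set is
#'   included
#' @param tissue_pair optional character pair of tissue labels
#' @return a `ConcordanceSummary` list
#' @export
summarize_concordance <- function(records, restrict_variable = "none",
                                  p_nominal = 0.05, rho_moderate = 0.5,
                                  bonferroni_alpha = 0.05, bonferroni_m = NULL,
                                  profile_a = NULL, profile_b = NULL,
                                  tissue_pair = c("a", "b")) {
  if (nrow(records) == 0) stop("empty record list", call. = FALSE)
  restrict_variable <- match.arg(restrict_variable, c("none", "peripheral", "brain", "both"))
  if (is.null(bonferroni_m)) bonferroni_m <- nrow(records)
  keep <- switch(restrict_variable,
    none = rep(TRUE, nrow(records)),
    peripheral = records$variable_b %in% TRUE,
    brain = records$variable_a %in% TRUE,
    both = (records$variable_a %in% TRUE) & (records$variable_b %in% TRUE)
  )
  rec <- records[keep, , drop = FALSE]
  eval_ok <- !is.na(rec$rho) & !is.na(rec$p)
  n_eval <- sum(eval_ok)
  if (n_eval == 0) stop("zero evaluable records after restriction", call. = FALSE)
  rec <- rec[eval_ok, , drop = FALSE]
  thr <- bonferroni_threshold(bonferroni_alpha, bonferroni_m)
  across <- NULL
  if (!is.null(profile_a) && !is.null(profile_b)) {
    across <- across_subject_correlation(profile_a, profile_b, rec$probe_id)$rho
  }
  out <- list(
    tissue_pair = tissue_pair,
    across_subject_rho = across,
    n_cpgs = nrow(rec),
    n_null = sum(!eval_ok),
    prop_nominal = mean(rec$p < p_nominal),
    prop_moderate = mean(rec$rho > rho_moderate),
    mean_rho = mean(rec$rho),
    median_rho = stats::median(rec$rho),
    n_bonferroni = sum(rec$p < thr),
    bonferroni_threshold = thr,
    restricted_to_variable = restrict_variable
  )
  class(out) <- "ConcordanceSummary"
  out
}

#' @export
print.ConcordanceSummary <- function(x, ...) {
  cat(sprintf("ConcordanceSummary [%s vs %s]%s\n", x$tissue_pair[1], x$tissue_pair[2],
              if (x$restricted_to_variable != "none")
                sprintf(" (variable: %s)", x$restricted_to_variable) else ""))
  if (!is.null(x$across_subject_rho))
    cat(sprintf("  across-subject Pearson r : %.3f\n", x$across_subject_rho))
  cat(sprintf("  CpGs evaluated           : %d (+%d null)\n", x$n_cpgs, x$n_null))
  cat(sprintf("  nominally correlated     : %.1f%%\n", 100 * x$prop_nominal))
  cat(sprintf("  moderately correlated    : %.1f%%\n", 100 * x$prop_moderate))
  cat(sprintf("  mean / median rho        : %.3f / %.3f\n", x$mean_rho, x$median_rho))
  cat(sprintf("  Bonferroni survivors     : %d (p < %.3g)\n",
              x$n_bonferroni, x$bonferroni_threshold))
  invisible(x)
}

#' Compare two dependent overlapping correlations
#'
#' Tests whether two correlations sharing a common variable (e.g. the
#' brain-saliva and brain-blood correlations, which share brain) differ,
#' using Fisher z transforms with the Meng-Rosenthal-Rubin covariance
#' correction for overlapping dependent correlations (the Steiger-style Z).
#'
#' @param r_common_a correlation of the common variable with variable a
#' @param r_common_b correlation of the common variable with variable b
#' @param r_ab correlation between variables a and b
#' @param n sample size (>= 4)
#' @return list with `z`, two-sided normal `p` (floored at the smallest
#'   positive double, with `p_underflow = TRUE` when the true value is
#'   smaller), and the inputs
#' @export
compare_dependent_correlations <- function(r_common_a, r_common_b, r_ab, n) {
  for (r in c(r_common_a, r_common_b, r_ab)) {
    if (abs(r) >= 1) stop("correlations must satisfy |r| < 1 (Fisher z undefined at 1)",
                          call. = FALSE)
  }
  if (n < 4) stop("need n >= 4", call. = FALSE)
  rbar2 <- (r_common_a^2 + r_common_b^2) / 2
  f <- (1 - r_ab) / (2 * (1 - rbar2))
  f <- min(f, 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_common_a) - atanh(r_common_b)) *
    sqrt((n - 3) / (2 * (1 - r_ab) * h))
  p <- 2 * stats::pnorm(-abs(z))
  underflow <- p < .Machine$double.xmin
  list(z = z, p = max(p, .Machine$double.xmin), p_underflow = underflow,
       r_common_a = r_common_a, r_common_b = r_common_b, r_ab = r_ab, n = n)
}
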