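# Sample-level structure: distance matrices, classical (Torgerson) MDS,
# per-subject cross-tissue concordance, and the paired distance-versus-
# correlation regression.

#' Pairwise sample distances on beta profiles
#'
#' @param betas probe x sample beta matrix combining all tissues
#' @param probe_subset optional probe ids/indices to restrict to
#' @param metric `"euclidean"` (default) or `"one_minus_r"`
#'   (1 - Pearson correlation between sample profiles)
#' @return symmetric distance matrix with zero diagonal, class
#'   `DistanceMatrix` with the metric recorded as an attribute
#' @export
sample_distances <- function(betas, probe_subset = NULL,
                             metric = c("euclidean", "one_minus_r")) {
  metric <- match.arg(metric)
  if (!is.null(probe_subset)) betas <- betas[probe_subset, , drop = FALSE]
  if (ncol(betas) < 2) stop("need >= 2 samples", call. = FALSE)
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(t(betas))),
    one_minus_r = 1 - stats::cor(betas, use = "pairwise.complete.obs")
  )
  diag(D) <- 0
  D <- (D + t(D)) / 2
  class(D) <- c("DistanceMatrix", class(D))
  attr(D, "metric") <- metric
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and embeds samples in the top-k
#' eigenvector space scaled by the square roots of the eigenvalues (via
#' [stats::cmdscale()]). Axis signs are fixed by forcing each axis's
#' largest-magnitude loading positive, so plots are reproducible.
#' Goodness of fit is the retained share of positive eigenvalue mass.
#'
#' @param D distance matrix (as from [sample_distances()])
#' @param k embedding dimension (>= 1 and at most the number of strictly
#'   positive eigenvalues)
#' @return `MDSResult` list: `coordinates` (sample x k), `eigenvalues`
#'   (descending), `goodness_of_fit`, `k`
#' @export
classical_mds <- function(D, k = 2) {
  D <- unclass(D)
  n <- nrow(D)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of samples", call. = FALSE)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-10
  n_pos <- sum(eig > tol)
  if (k > n_pos) {
    stop(sprintf("k = %d exceeds the %d positive eigenvalues; attainable k: 1..%d",
                 k, n_pos, n_pos), call. = FALSE)
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("MDS", seq_len(k))
  res <- list(
    coordinates = coords,
    eigenvalues = sort(eig, decreasing = TRUE),
    goodness_of_fit = sum(eig[seq_len(k)]) / sum(eig[eig > tol]),
    k = k
  )
  class(res) <- "MDSResult"
  res
}

#' @export
print.MDSResult <- function(x, ...) {
  cat(sprintf("MDSResult: %d samples embedded in %d dims, GOF %.3f\n",
              nrow(x$coordinates), x$k, x$goodness_of_fit))
  invisible(x)
}

#' Per-subject cross-tissue concordance
#'
#' For each subject with a sample in both tissues, the Spearman correlation
#' across all probes between that subject's two tissue profiles (duplicate
#' samples per subject-tissue averaged first). Subjects missing either
#' tissue are omitted and listed in the `omitted` attribute with a warning.
#'
#' @param betas_a,betas_b probe x sample beta matrices
#' @param sample_sheet data.frame with `sample` and `subject`
#' @param method correlation method (default `"spearman"`)
#' @return data.frame with `subject` and `rho`
#' @export
per_subject_concordance <- function(betas_a, betas_b, sample_sheet,
                                    method = "spearman") {
  A <- collapse_to_subjects(betas_a, sample_sheet)
  B <- collapse_to_subjects(betas_b, sample_sheet)
  common <- intersect(colnames(A), colnames(B))
  omitted <- setdiff(union(colnames(A), colnames(B)), common)
  if (length(omitted)) {
    warning("subjects missing a tissue, omitted: ", paste(omitted, collapse = ", "))
  }
  if (length(common) == 0) stop("no subjects with both tissues", call. = FALSE)
  rho <- vapply(common, function(s) {
    ok <- !is.na(A[, s]) & !is.na(B[, s])
    suppressWarnings(stats::cor(A[ok, s], B[ok, s], method = method))
  }, numeric(1))
  out <- data.frame(subject = common, rho = unname(rho), stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  out
}

#' Regression of per-subject correlation on paired sample distance
#'
#' Ordinary least squares of each subject's cross-tissue correlation on the
#' distance between that subject's two tissue samples (taken from the full
#' distance matrix, i.e. the full-rank embedding, not a k-dimensional
#' projection). Reports slope, intercept, r-squared, the F statistic on
#' (1, n-2) df and its two-sided p-value.
#'
#' @param distances sample x sample distance matrix
#' @param sample_sheet data.frame with `sample`, `subject`, `tissue`
#' @param per_subject_rho data.frame with `subject` and `rho` (as from
#'   [per_subject_concordance()])
#' @param tissue_a,tissue_b the two tissue labels whose paired distances are
#'   used (one sample per subject per tissue; duplicates use the first)
#' @return list: `slope`, `intercept`, `r_squared`, `f_statistic`, `p`, `n`,
#'   `data` (per-subject distance and rho)
#' @export
paired_distance_vs_correlation <- function(distances, sample_sheet,
                                           per_subject_rho,
                                           tissue_a, tissue_b) {
  subj <- per_subject_rho$subject
  d <- vapply(subj, function(s) {
    sa <- sample_sheet$sample[sample_sheet$subject == s & sample_sheet$tissue == tissue_a]
    sb <- sample_sheet$sample[sample_sheet$subject == s & sample_sheet$tissue == tissue_b]
    sa <- intersect(sa, rownames(distances))
    sb <- intersect(sb, rownames(distances))
    if (length(sa) == 0 || length(sb) == 0) return(NA_real_)
    distances[sa[1], sb[1]]
  }, numeric(1))
  ok <- !is.na(d) & !is.na(per_subject_rho$rho)
  if (sum(ok) < 3) stop("need >= 3 subjects with both distance and correlation", call. = FALSE)
  x <- d[ok]
  y <- per_subject_rho$rho[ok]
  if (stats::sd(x) == 0) stop("zero-variance predictor (all paired distances equal)",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    f_statistic = unname(fstat[1]),
    p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    n = sum(ok),
    data = data.frame(subject = subj[ok], distance = x, rho = y,
                      stringsAsFactors = FALSE)
  )
}
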