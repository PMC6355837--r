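# Cell-composition estimation (simplex-constrained least squares) and
# per-probe residualization adjustment.

make_reference <- function(n_probes = 80, K = 3, seed = 1) {
  set.seed(seed)
  R <- matrix(runif(K * n_probes), K, n_probes,
              dimnames = list(paste0("ct", 1:K), sprintf("cg%05d", 1:n_probes)))
  reference_profiles(R)
}

mix_samples <- function(reference, W, noise_sd = 0, seed = 2) {
  set.seed(seed)
  Y <- t(unclass(reference)) %*% t(W)    # probes x samples
  if (noise_sd > 0) {
    Y <- stats::plogis(stats::qlogis(pmin(pmax(Y, 1e-6), 1 - 1e-6)) +
                         matrix(rnorm(length(Y), 0, noise_sd), nrow(Y)))
  }
  colnames(Y) <- paste0("s", seq_len(ncol(Y)))
  Y
}

test_that("proportion estimation recovers pure and exact mixtures", {
  ref <- make_reference()
  Y <- mix_samples(ref, rbind(c(1, 0, 0), c(0.3, 0.7, 0), c(0.2, 0.3, 0.5)))
  est <- estimate_proportions(Y, ref)
  expect_equal(unname(est$proportions[1, ]), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(unname(est$proportions[2, ]), c(0.3, 0.7, 0), tolerance = 1e-6)
  expect_equal(unname(est$proportions[3, ]), c(0.2, 0.3, 0.5), tolerance = 1e-6)
  expect_equal(est$residual_norm, rep(0, 3), tolerance = 1e-6)
})

test_that("estimated proportions satisfy the simplex constraints and beat every vertex", {
  ref <- make_reference(n_probes = 60, K = 3, seed = 3)
  set.seed(4)
  W <- methconcord:::rdirichlet(6, c(2, 2, 2))
  Y <- mix_samples(ref, W, noise_sd = 0.3, seed = 5)
  est <- estimate_proportions(Y, ref)
  expect_true(all(est$proportions >= 0))
  expect_equal(unname(rowSums(est$proportions)), rep(1, 6), tolerance = 1e-9)
  R <- t(unclass(ref))
  for (j in 1:6) {
    obj <- sum((R %*% est$proportions[j, ] - Y[, j])^2)
    grid <- oracle_simplex_grid(R, Y[, j], resolution = 0.01)
    expect_lte(obj, grid$objective + 1e-9)
  }
})

test_that("rank-deficient references and insufficient overlap are rejected", {
  ref <- make_reference(K = 2)
  bad <- unclass(ref)
  bad[2, ] <- bad[1, ]
  expect_error(estimate_proportions(mix_samples(ref, rbind(c(0.5, 0.5))),
                                    reference_profiles(bad)), "rank-deficient")
  expect_error(estimate_proportions(mix_samples(ref, rbind(c(0.5, 0.5)))[1:10, ], ref),
               "shared")
  expect_error(reference_profiles(matrix(2, 2, 5)), "\\[0,1\\]")
})

test_that("noisy mixture recovery has small mean absolute error", {
  ref <- make_reference(n_probes = 200, K = 3, seed = 6)
  set.seed(7)
  W <- methconcord:::rdirichlet(100, c(3, 3, 3))
  Y <- mix_samples(ref, W, noise_sd = 0.1, seed = 8)
  est <- estimate_proportions(Y, ref)
  mae <- mean(abs(est$proportions - W))
  expect_lt(mae, 0.05)
})

test_that("recovery error decreases monotonically with noise", {
  ref <- make_reference(n_probes = 150, K = 3, seed = 9)
  set.seed(10)
  W <- methconcord:::rdirichlet(40, c(3, 3, 3))
  maes <- vapply(c(0.2, 0.1, 0.05, 0.01), function(ns) {
    Y <- mix_samples(ref, W, noise_sd = ns, seed = 11)
    mean(abs(estimate_proportions(Y, ref)$proportions - W))
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
})

test_that("adjustment is a no-op when composition is constant", {
  set.seed(12)
  Y <- matrix(runif(30 * 8), 30, 8,
              dimnames = list(sprintf("p%02d", 1:30), paste0("s", 1:8)))
  W <- matrix(rep(c(0.6, 0.4), each = 8), 8, 2,
              dimnames = list(paste0("s", 1:8), c("ct1", "ct2")))
  adj <- adjust_for_composition(Y, W)
  expect_equal(adj$adjusted, Y, tolerance = 1e-10)
  expect_equal(unname(adj$r_squared), rep(0, 30), tolerance = 1e-10)
})

test_that("composition-driven variation is removed and means preserved", {
  ref <- make_reference(n_probes = 60, K = 2, seed = 13)
  set.seed(14)
  W <- cbind(ct1 = runif(12, 0.2, 0.8))
  W <- cbind(W, ct2 = 1 - W[, 1])
  rownames(W) <- paste0("s", 1:12)
  Y <- mix_samples(ref, W, noise_sd = 0)   # variation purely compositional
  colnames(Y) <- rownames(W)
  adj <- adjust_for_composition(Y, W)
  expect_lt(max(apply(adj$adjusted, 1, var)), 1e-10)
  # per-probe means preserved (no clipping can occur here)
  expect_equal(rowMeans(adj$adjusted), rowMeans(Y), tolerance = 1e-10)
  expect_true(all(adj$r_squared > 0.999))
  expect_error(adjust_for_composition(Y[, 1, drop = FALSE], W), "more cell types")
})

test_that("adjusted betas are essentially unexplained by composition", {
  ref <- make_reference(n_probes = 120, K = 3, seed = 15)
  set.seed(16)
  W <- methconcord:::rdirichlet(20, c(3, 3, 3))
  rownames(W) <- paste0("s", 1:20)
  colnames(W) <- paste0("ct", 1:3)
  Y <- mix_samples(ref, W, noise_sd = 0.05, seed = 17)
  colnames(Y) <- rownames(W)
  adj <- adjust_for_composition(Y, W)
  readj <- adjust_for_composition(adj$adjusted, W)
  expect_gte(mean(readj$r_squared <= 0.01), 0.95)
})

test_that("adjusted concordance comparison reports deltas and guards probe sets", {
  rec <- toy_records(rho = runif(10), p = runif(10))
  cmp0 <- compare_adjusted_concordance(rec, rec)
  expect_equal(cmp0$delta_mean_rho, 0)
  expect_equal(cmp0$delta_prop_nominal, 0)
  expect_true(all(cmp0$per_probe$delta_rho == 0))

  rec2 <- rec
  rec2$rho[1] <- rec2$rho[1] + 0.1
  expect_equal(compare_adjusted_concordance(rec, rec2)$delta_mean_rho,
               0.1 / 10, tolerance = 1e-12)
  expect_error(compare_adjusted_concordance(rec, rec[-1, ]), "symmetric difference")
})

test_that("subject-effect-driven concordance survives composition adjustment", {
  # correlation comes from the shared subject effect, not composition
  b <- generate_cohort(synth_config(
    n_probes = 300, seed = 31,
    tissues = c("brain", "blood"),
    cell_types = c("leukocyte", "epithelial"),
    tissue_mixture_params = list(brain = c(leukocyte = 30, epithelial = 20),
                                 blood = c(leukocyte = 45, epithelial = 5))
  ))
  ref <- reference_profiles(stats::plogis(b$truth$cell_profiles))
  est_a <- estimate_proportions(b$betas$brain, ref)
  est_b <- estimate_proportions(b$betas$blood, ref)
  adj_a <- adjust_for_composition(b$betas$brain, est_a)
  adj_b <- adjust_for_composition(b$betas$blood, est_b)
  rec_raw <- within_subject_correlations(b$betas$brain, b$betas$blood, b$sample_sheet)
  rec_adj <- within_subject_correlations(adj_a$adjusted, adj_b$adjusted, b$sample_sheet)
  cmp <- compare_adjusted_concordance(rec_raw, rec_adj)
  expect_lt(abs(cmp$delta_mean_rho), 0.05)
})
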