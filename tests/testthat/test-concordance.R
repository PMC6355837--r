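# Concordance core: profiles, both correlation frameworks, the variability
# classifier, Bonferroni thresholds, summaries, and the dependent-
# correlation comparison.

test_that("mean profiles average non-missing samples per probe", {
  m <- rbind(a = c(0.2, 0.4, 0.6), b = c(0.2, NA, 0.6), c = c(NA, NA, NA))
  p <- mean_profile(m)
  expect_equal(unname(p), c(0.4, 0.4, NA))
  one <- matrix(c(0.1, 0.9), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(mean_profile(one), c(a = 0.1, b = 0.9))
})

test_that("across-subject correlation matches the definitional Pearson formula", {
  a <- c(x = 0.1, y = 0.4, z = 0.5, w = 0.9)
  b <- c(x = 0.2, y = 0.3, z = 0.7, w = 0.8)
  expect_equal(across_subject_correlation(a, a)$rho, 1)
  expect_equal(across_subject_correlation(c(a = .1, b = .2, c = .3),
                                          c(a = .3, b = .2, c = .1))$rho, -1)
  expect_equal(across_subject_correlation(a, b)$rho, oracle_pearson(a, b),
               tolerance = 1e-12)
  # subsetting restricts the computation
  expect_equal(across_subject_correlation(a, b, c("x", "y", "z"))$rho,
               oracle_pearson(a[1:3], b[1:3]), tolerance = 1e-12)
  expect_error(across_subject_correlation(c(1, 1, 1) / 2, c(.1, .2, .3)), "profile_a")
  expect_error(across_subject_correlation(c(.1, .2, .3), c(1, 1, 1) / 2), "profile_b")
  expect_error(across_subject_correlation(a[1:2], b[1:2]), ">= 3")
})

test_that("exact Spearman p equals exhaustive enumeration", {
  # perfectly monotone, n = 6: only identity and reversal reach |rho| = 1
  expect_equal(methconcord:::spearman_exact_p(rank(1:6), rank(c(2, 3, 5, 7, 8, 9))),
               2 / 720, tolerance = 1e-15)
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    x <- runif(n)
    y <- runif(n)
    expect_equal(methconcord:::spearman_exact_p(rank(x), rank(y)),
                 oracle_spearman_exact_p(x, y), tolerance = 1e-12)
  }
  # tied values go through the generic enumeration path
  x <- c(1, 2, 2, 3, 4)
  y <- c(2, 1, 3, 3, 5)
  expect_equal(methconcord:::spearman_exact_p(rank(x), rank(y)),
               oracle_spearman_exact_p(x, y), tolerance = 1e-12)
})

test_that("within-subject correlations handle degeneracy and missingness", {
  set.seed(1)
  n_probes <- 20
  subj <- sprintf("S%02d", 1:8)
  sheet <- data.frame(sample = c(paste0(subj, "_a"), paste0(subj, "_b")),
                      subject = rep(subj, 2), stringsAsFactors = FALSE)
  A <- matrix(runif(n_probes * 8), n_probes, 8,
              dimnames = list(sprintf("p%02d", 1:n_probes), paste0(subj, "_a")))
  B <- matrix(runif(n_probes * 8), n_probes, 8,
              dimnames = list(sprintf("p%02d", 1:n_probes), paste0(subj, "_b")))
  A[1, ] <- 0.5                       # constant probe -> null record
  B[2, 1:5] <- NA                     # only 3 pairs -> below min_pairs
  rec <- within_subject_correlations(A, B, sheet, min_pairs = 5)
  expect_true(is.na(rec$rho[1]) && is.na(rec$p[1]))
  expect_true(is.na(rec$rho[2]))
  expect_equal(rec$n_pairs[2], 3L)
  expect_equal(rec$n_pairs[3], 8L)
  # n = 8 > exact cutoff: t-approximation, all p in [0,1]
  expect_true(all(rec$p[-c(1, 2)] >= 0 & rec$p[-c(1, 2)] <= 1))

  # exact path: n = 7 fixture matches the naive enumeration oracle
  rec7 <- within_subject_correlations(A[, 1:7], B[, 1:7], sheet, min_pairs = 5,
                                      exact_cutoff = 7)
  i <- 4
  expect_equal(rec7$p[i], oracle_spearman_exact_p(A[i, 1:7], B[i, 1:7]),
               tolerance = 1e-12)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(7)
  subj <- sprintf("S%02d", 1:10)
  sheet <- data.frame(sample = c(paste0(subj, "_a"), paste0(subj, "_b")),
                      subject = rep(subj, 2), stringsAsFactors = FALSE)
  A <- matrix(runif(50 * 10), 50, 10, dimnames = list(NULL, paste0(subj, "_a")))
  B <- matrix(runif(50 * 10), 50, 10, dimnames = list(NULL, paste0(subj, "_b")))
  r1 <- within_subject_correlations(A, B, sheet)
  r2 <- within_subject_correlations(A^3, pmin(pmax(exp(B) / 3, 0), 1), sheet)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("approximate p tracks the exact decision at small n", {
  # the exact enumeration is authoritative for n <= 7; the t-approximation
  # (used only above the cutoff) should still reach the same alpha = 0.05
  # decision on the large majority of small-n fixtures
  set.seed(11)
  agree <- 0L
  n_fix <- 200L
  for (i in seq_len(n_fix)) {
    n <- sample(5:7, 1)
    x <- rank(runif(n))
    y <- rank(runif(n))
    pe <- methconcord:::spearman_exact_p(x, y)
    pa <- methconcord:::spearman_approx_p(cor(x, y), n)
    agree <- agree + ((pe < 0.05) == (pa < 0.05))
  }
  expect_gte(agree / n_fix, 0.95)
})

test_that("variability classification matches the sort-trim-range oracle", {
  expect_false(classify_variable(rep(0.4, 21)))
  expect_true(classify_variable(seq(0, 1, length.out = 21)))
  expect_error(classify_variable(runif(21), trim = 0.5), "trim")

  # exactly representable boundary: post-trim range exactly 1/16, inclusive
  v <- c(0.1, 0.2, 0.25, seq(0.26, 0.30, length.out = 15), 0.3125, 0.4, 0.5)
  expect_equal(sort(v)[3], 0.25)
  expect_equal(sort(v)[19], 0.3125)
  expect_true(classify_variable(v, min_range = 0.0625))
  expect_identical(classify_variable(v, min_range = 0.0625),
                   oracle_classify_variable(v, min_range = 0.0625))

  set.seed(5)
  for (i in 1:100) {
    v <- runif(21, 0, ifelse(i %% 2, 0.12, 1))
    expect_identical(classify_variable(v), oracle_classify_variable(v))
  }
})

test_that("variability classification is monotone in its parameters", {
  set.seed(6)
  for (i in 1:20) {
    v <- runif(21)
    f_strict <- classify_variable(v, min_range = 0.3)
    f_loose <- classify_variable(v, min_range = 0.05)
    expect_true(!f_strict || f_loose)   # lowering min_range never unsets
    r_narrow <- diff(range(v[v >= quantile(v, .2, type = 7) & v <= quantile(v, .8, type = 7)]))
    r_wide <- diff(range(v[v >= quantile(v, .1, type = 7) & v <= quantile(v, .9, type = 7)]))
    expect_lte(r_narrow, r_wide + 1e-12)
  }
})

test_that("Bonferroni thresholds are alpha over m", {
  expect_equal(signif(bonferroni_threshold(0.05, 822996), 2), 6.1e-8)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 450000), 2), 1.1e-7)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("summaries report the right proportions and respect restrictions", {
  rec <- toy_records(rho = rep(0, 10), p = rep(1, 10))
  s <- summarize_concordance(rec)
  expect_equal(s$prop_nominal, 0)
  expect_equal(s$prop_moderate, 0)
  expect_equal(s$mean_rho, 0)

  rec2 <- toy_records(rho = seq(0.1, 1, by = 0.1),
                      p = c(0.01, 0.02, 0.03, rep(0.5, 7)))
  expect_equal(summarize_concordance(rec2)$prop_nominal, 0.3)
  # order invariance
  perm <- sample(nrow(rec2))
  expect_equal(summarize_concordance(rec2[perm, ])$prop_nominal, 0.3)

  # variable restriction recount against brute force
  rec3 <- toy_records(rho = runif(20), p = runif(20),
                      variable_a = rep(c(TRUE, FALSE), 10),
                      variable_b = rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  s3 <- summarize_concordance(rec3, restrict_variable = "both")
  keep <- rec3$variable_a & rec3$variable_b
  expect_equal(s3$n_cpgs, sum(keep))
  expect_equal(s3$prop_nominal, mean(rec3$p[keep] < 0.05))
  expect_error(summarize_concordance(rec3[0, ]), "empty")
})

test_that("dependent-correlation comparison behaves at its edges and on printed values", {
  r0 <- compare_dependent_correlations(0.5, 0.5, 0.3, 100)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)

  # published comparison: saliva-brain vs blood-brain over ~823k CpGs
  r <- compare_dependent_correlations(0.90, 0.86, 0.97, 822996)
  expect_lt(r$p, 2.2e-16)
  expect_true(r$p_underflow)
  expect_gt(r$z, 0)

  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 10), "Fisher z")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 3), "n >= 4")
})

test_that("the dependent-correlation test is calibrated under the null", {
  set.seed(21)
  n <- 50
  reps <- 4000
  rho0 <- 0.3
  rej <- 0L
  L <- chol(matrix(c(1, rho0, rho0, rho0, 1, rho0, rho0, rho0, 1), 3))
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(n * 3), n, 3) %*% L
    cc <- cor(X)
    out <- compare_dependent_correlations(cc[1, 2], cc[1, 3], cc[2, 3], n)
    rej <- rej + (out$p < 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 0.01)
})
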