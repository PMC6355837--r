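# Stratification by annotation groupings, gene sets, and the region query.

make_strat_fixture <- function(n = 12, seed = 3) {
  set.seed(seed)
  ann <- toy_annotation(n)
  rec <- toy_records(rho = runif(n, -1, 1), p = runif(n))
  list(ann = ann, rec = rec)
}

test_that("a single all-probe group reproduces the overall summary", {
  fx <- make_strat_fixture()
  ann <- fx$ann
  ann$genic_class <- "genic"
  res <- stratified_concordance(fx$rec, ann, "genic_class")
  g <- res[[which(vapply(res, function(x) x$group_label, "") == "genic")]]
  overall <- summarize_concordance(fx$rec)
  expect_equal(g$summary$prop_nominal, overall$prop_nominal)
  expect_equal(g$summary$mean_rho, overall$mean_rho)
  expect_equal(g$group_size, nrow(fx$rec))
})

test_that("constructed groups separate perfectly and counts partition", {
  ann <- toy_annotation(12)
  ann$genic_class <- rep(c("promoter", "genic"), each = 6)
  rec <- toy_records(rho = runif(12),
                     p = c(rep(0.001, 6), rep(0.9, 6)))
  res <- stratified_concordance(rec, ann, "genic_class")
  labs <- vapply(res, function(x) x$group_label, "")
  expect_equal(res[[which(labs == "promoter")]]$summary$prop_nominal, 1.0)
  expect_equal(res[[which(labs == "genic")]]$summary$prop_nominal, 0.0)
  expect_null(res[[which(labs == "intergenic")]]$summary)

  # random partition: per-group nominal counts sum to the overall count
  set.seed(9)
  ann$genic_class <- sample(c("promoter", "genic", "intergenic"), 12, replace = TRUE)
  rec <- toy_records(rho = runif(12), p = runif(12))
  res <- stratified_concordance(rec, ann, "genic_class")
  sizes <- vapply(res, function(x) x$group_size, numeric(1))
  expect_equal(sum(sizes), nrow(rec))
  nom <- vapply(res, function(x) {
    ids <- ann$probe_id[ann$genic_class == x$group_label]
    sum(rec$p[rec$probe_id %in% ids] < 0.05)   # brute-force recount
  }, numeric(1))
  expect_equal(sum(nom), sum(rec$p < 0.05))
})

test_that("mQTL split with all flags false puts everything in the non-mQTL stratum", {
  fx <- make_strat_fixture()
  ann <- fx$ann
  ann$mqtl <- FALSE
  res <- stratified_concordance(fx$rec, ann, "mqtl")
  labs <- vapply(res, function(x) x$group_label, "")
  expect_equal(res[[which(labs == "mqtl")]]$group_size, 0)
  expect_null(res[[which(labs == "mqtl")]]$summary)
  non <- res[[which(labs == "non_mqtl")]]
  expect_equal(non$group_size, nrow(fx$rec))
  expect_equal(non$summary$prop_nominal, summarize_concordance(fx$rec)$prop_nominal)
})

test_that("unknown grouping keys and uncovered probes raise errors", {
  fx <- make_strat_fixture()
  expect_error(stratified_concordance(fx$rec, fx$ann, "bogus"), "unknown grouping")
  expect_error(stratified_concordance(fx$rec, fx$ann[-1, ], "mqtl"), "annotation missing")
})

test_that("gene-set concordance restricts, tabulates per gene, and reports unmatched", {
  ann <- toy_annotation(12)
  rec <- toy_records(rho = c(0.9, rep(0.1, 11)),
                     p = c(0.001, rep(0.8, 11)))
  # gene GA is on probes 1,4,7,10; only probe 1 nominal
  gs <- gene_set_concordance(rec, ann, "GA")
  expect_equal(gs$per_gene$n_cpgs, 4)
  expect_equal(gs$per_gene$n_nominal, 1)
  expect_equal(gs$per_gene$max_abs_rho, 0.9)
  expect_equal(gs$n_genes_nominal, 1)

  # covering all annotated genes reproduces the summary over gene probes
  gs_all <- gene_set_concordance(rec, ann, c("GA", "GB"))
  in_genes <- ann$probe_id[ann$genes != ""]
  expect_equal(gs_all$summary$n_cpgs, length(in_genes))

  # case-insensitive matching; unmatched names reported in the error
  expect_equal(gene_set_concordance(rec, ann, "ga")$per_gene$n_cpgs, 4)
  expect_error(gene_set_concordance(rec, ann, c("NOPE1", "NOPE2")), "NOPE1")
})

test_that("gene recovery: high-correlation genes dominate the nominal count", {
  # synthetic cohort where 10 of 50 genes carry strongly correlated probes
  set.seed(14)
  n_probes <- 250
  subj <- sprintf("S%02d", 1:21)
  sheet <- data.frame(sample = c(paste0(subj, "_a"), paste0(subj, "_b")),
                      subject = rep(subj, 2), stringsAsFactors = FALSE)
  genes <- paste0("G", formatC(rep(1:50, each = 5), width = 2, flag = "0"))
  hot <- genes %in% paste0("G", formatC(1:10, width = 2, flag = "0"))
  u <- matrix(rnorm(n_probes * 21), n_probes)
  A <- stats::plogis(u + matrix(rnorm(n_probes * 21, 0, 0.2), n_probes))
  noise_b <- matrix(rnorm(n_probes * 21, 0, 0.2), n_probes)
  noise_b[!hot, ] <- matrix(rnorm(sum(!hot) * 21, 0, 5), sum(!hot))
  B <- stats::plogis(u + noise_b)
  dimnames(A) <- list(sprintf("cg%07d", 1:n_probes), paste0(subj, "_a"))
  dimnames(B) <- list(sprintf("cg%07d", 1:n_probes), paste0(subj, "_b"))
  ann <- toy_annotation(n_probes)
  ann$genes <- genes
  rec <- within_subject_correlations(A, B, sheet)
  gs <- gene_set_concordance(rec, ann, unique(genes))
  hot_nominal <- gs$per_gene$n_nominal[gs$per_gene$gene %in%
                                         paste0("G", formatC(1:10, width = 2, flag = "0"))]
  expect_gte(sum(hot_nominal >= 1), 9)
})

test_that("region queries respect boundaries and compose over intervals", {
  ann <- toy_annotation(12)   # positions 100, 150, ..., 650 alternating chr1/chr2
  rec <- list(brain_vs_blood = toy_records(rho = runif(12), p = runif(12)))

  q1 <- region_query(rec, ann, probes = ann$probe_id[3])
  expect_equal(nrow(q1), 1)
  expect_equal(q1$probe_id, ann$probe_id[3])

  # 1-based inclusive: chr1:100-200 hits pos 100 and 200 on chr1, not 201
  q2 <- region_query(rec, ann, interval = "chr1:100-200")
  expect_setequal(q2$pos, ann$pos[ann$chrom == "chr1" & ann$pos <= 200])
  q3 <- region_query(rec, ann, interval = "chr1:100-199")
  expect_false(200 %in% q3$pos)

  # union of disjoint intervals equals concatenation of the two queries
  qa <- region_query(rec, ann, interval = "chr1:100-200")
  qb <- region_query(rec, ann, interval = "chr1:300-400")
  qu <- region_query(rec, ann, interval = c("chr1:100-200", "chr1:300-400"))
  expect_setequal(qu$probe_id, c(qa$probe_id, qb$probe_id))

  expect_warning(qe <- region_query(rec, ann, gene = "ABSENT"), "no probes")
  expect_equal(nrow(qe), 0)
  expect_error(region_query(rec, ann, interval = "chr1:300-200"), "start > end")
  expect_error(region_query(rec, ann), "exactly one")
})

test_that("BED intervals convert from 0-based half-open on read", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", bed)
  iv <- read_bed(bed)
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 200L)
})
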