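# Shared fixture builders for the test suite.

# single-cell-type two-tissue config: the latent correlation structure is
# then unobscured by mixture-weight variation
pure_config <- function(n_subjects = 21, n_probes = 500, seed = 1L,
                        subject_effect_sd = 0.5, noise_sd = 0.5,
                        target_rho = NULL, tissues = c("brain", "blood")) {
  synth_config(
    n_subjects = n_subjects, n_probes = n_probes, seed = seed,
    tissues = tissues, cell_types = "bulk",
    tissue_mixture_params = stats::setNames(
      replicate(length(tissues), c(bulk = 1), simplify = FALSE), tissues),
    subject_effect_sd = subject_effect_sd, noise_sd = noise_sd,
    target_rho = target_rho
  )
}

# small default 4-tissue cohort
small_cohort <- function(n_probes = 300, seed = 1L, ...) {
  generate_cohort(synth_config(n_probes = n_probes, seed = seed, ...))
}

# deterministic toy annotation for stratification tests
toy_annotation <- function(n = 12) {
  data.frame(
    probe_id = sprintf("cg%07d", seq_len(n)),
    chrom = rep(c("chr1", "chr2"), length.out = n),
    pos = seq(100, by = 50, length.out = n),
    genes = rep(c("GA", "GB", ""), length.out = n),
    genic_class = rep(c("promoter", "genic", "intergenic"), length.out = n),
    tfbs = rep(c(TRUE, FALSE), length.out = n),
    enhancer = FALSE,
    open_chromatin = rep(c(FALSE, TRUE), length.out = n),
    mqtl = rep(c(TRUE, FALSE, FALSE), length.out = n),
    snp_within_5bp = FALSE,
    context_specific = FALSE,
    stringsAsFactors = FALSE
  )
}

# correlation-record table with chosen rho/p values
toy_records <- function(rho, p, probe_id = sprintf("cg%07d", seq_along(rho)),
                        variable_a = TRUE, variable_b = TRUE) {
  data.frame(probe_id = probe_id, rho = rho, p = p,
             n_pairs = 21L, variable_a = variable_a, variable_b = variable_b,
             stringsAsFactors = FALSE)
}
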