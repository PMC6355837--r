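# Synthetic multi-tissue methylation cohort generator.
#
# The generator emulates the structure of a paired-tissue methylation study:
# several tissues sampled from the same subjects, each tissue a bulk mixture
# of latent cell types, with cross-tissue correlation at each CpG induced by
# a subject-level random effect shared across tissues. Cell-type mixing is
# performed on the beta scale (bulk methylation is a linear mixture of cell
# methylomes); subject effects and measurement noise act on the logit scale
# and are back-transformed.

#' Configuration for a synthetic multi-tissue cohort
#'
#' Defaults describe the emulated study: 21 subjects, four tissues
#' (brain, blood, saliva, buccal) built from four latent cell types, with
#' saliva a roughly 70/30 leukocyte/epithelial mixture, buccal predominantly
#' epithelial, blood nearly pure leukocyte and brain a neuron/glia mixture.
#'
#' @param n_subjects number of subjects (>= 2)
#' @param n_probes number of CpG probes (>= 1)
#' @param tissues character vector of tissue labels
#' @param cell_types character vector of latent cell-type labels
#' @param tissue_mixture_params named list (one entry per tissue) of Dirichlet
#'   concentration vectors over `cell_types`; all concentrations > 0
#' @param subject_effect_sd SD of the subject-level random effect on the logit
#'   scale (ignored when `target_rho` is given)
#' @param noise_sd per-tissue measurement noise SD on the logit scale
#' @param target_rho optional target per-probe cross-tissue latent correlation
#'   in \[0,1\]; converted to a subject-effect variance via
#'   rho = s2_subj / (s2_subj + s2_noise)
#' @param variable_fraction fraction of probes given wide between-subject
#'   spread (mid-range methylation); the remainder sit near the 0/1 extremes
#' @param seed integer root RNG seed
#' @return a `SynthConfig` list
#' @export
synth_config <- function(n_subjects = 21,
                         n_probes = 1000,
                         tissues = c("brain", "blood", "saliva", "buccal"),
                         cell_types = c("neuron", "glia", "leukocyte", "epithelial"),
                         tissue_mixture_params = NULL,
                         subject_effect_sd = 0.5,
                         noise_sd = 0.5,
                         target_rho = NULL,
                         variable_fraction = 0.25,
                         seed = 1L) {
  if (is.null(tissue_mixture_params)) {
    if (!setequal(tissues, c("brain", "blood", "saliva", "buccal")) ||
        !setequal(cell_types, c("neuron", "glia", "leukocyte", "epithelial"))) {
      stop("tissue_mixture_params must be supplied for non-default tissues/cell_types",
           call. = FALSE)
    }
    # concentrations chosen so Dirichlet means match the emulated compositions
    # (saliva ~70% leukocyte / 30% epithelial; buccal 20/80; blood ~pure
    # leukocyte; brain neuron/glia) with realistic sample-to-sample spread
    tissue_mixture_params <- list(
      brain  = c(neuron = 40,  glia = 60,  leukocyte = 0.05, epithelial = 0.05),
      blood  = c(neuron = 0.05, glia = 0.05, leukocyte = 100, epithelial = 0.5),
      saliva = c(neuron = 0.05, glia = 0.05, leukocyte = 35,  epithelial = 15),
      buccal = c(neuron = 0.05, glia = 0.05, leukocyte = 10,  epithelial = 40)
    )
    tissue_mixture_params <- lapply(tissue_mixture_params, function(a) a[cell_types])
    names(tissue_mixture_params) <- tissues[match(names(tissue_mixture_params), tissues)]
    tissue_mixture_params <- tissue_mixture_params[tissues]
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_probes = as.integer(n_probes),
    tissues = as.character(tissues),
    cell_types = as.character(cell_types),
    tissue_mixture_params = tissue_mixture_params,
    subject_effect_sd = subject_effect_sd,
    noise_sd = noise_sd,
    target_rho = target_rho,
    variable_fraction = variable_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "SynthConfig"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  assert_field(cfg$n_subjects >= 2, "n_subjects", "must be >= 2")
  assert_field(cfg$n_probes >= 1, "n_probes", "must be >= 1")
  assert_field(length(cfg$tissues) >= 1 && !anyDuplicated(cfg$tissues),
               "tissues", "must be non-empty and unique")
  assert_field(length(cfg$cell_types) >= 1 && !anyDuplicated(cfg$cell_types),
               "cell_types", "must be non-empty and unique")
  assert_field(cfg$subject_effect_sd >= 0, "subject_effect_sd", "must be >= 0")
  assert_field(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  assert_field(is.list(cfg$tissue_mixture_params) &&
                 setequal(names(cfg$tissue_mixture_params), cfg$tissues),
               "tissue_mixture_params", "must be a named list with one entry per tissue")
  for (t in cfg$tissues) {
    a <- cfg$tissue_mixture_params[[t]]
    assert_field(length(a) == length(cfg$cell_types) && all(a > 0),
                 "tissue_mixture_params",
                 sprintf("concentrations for tissue '%s' must be positive and match cell_types", t))
  }
  if (!is.null(cfg$target_rho)) {
    assert_field(all(cfg$target_rho >= 0 & cfg$target_rho <= 1),
                 "target_rho", "must lie in [0,1]")
    if (any(cfg$target_rho == 1) && cfg$noise_sd > 0) {
      stop("invalid `target_rho`: rho = 1 is unattainable with noise_sd > 0", call. = FALSE)
    }
    if (any(cfg$target_rho < 1) && cfg$noise_sd == 0) {
      stop("invalid `target_rho`: rho < 1 is unattainable with noise_sd = 0", call. = FALSE)
    }
  }
  assert_field(cfg$variable_fraction >= 0 && cfg$variable_fraction <= 1,
               "variable_fraction", "must lie in [0,1]")
  invisible(cfg)
}

# Convert the requested latent cross-tissue correlation to a subject-effect SD
# given the noise SD: rho = s2_u / (s2_u + s2_e)  =>  s2_u = rho/(1-rho) * s2_e.
rho_to_subject_sd <- function(rho, noise_sd) {
  ifelse(rho >= 1, Inf, sqrt(rho / (1 - rho)) * noise_sd)
}

#' Simulate one bulk-tissue beta profile from cell-type profiles
#'
#' Bulk methylation is the proportion-weighted mixture, on the beta scale, of
#' the cell-type methylomes. Measurement noise acts on the logit scale (one
#' shared draw per probe across cell types) before back-transformation.
#'
#' @param cell_profiles matrix of logit-scale cell-type means,
#'   cell types in rows, probes in columns
#' @param proportions nonnegative weights summing to 1, one per cell type
#' @param noise_sd logit-scale noise SD
#' @param seed optional seed for the noise draw
#' @return beta vector of length `ncol(cell_profiles)`, values in \[0,1\]
#' @export
simulate_mixture_sample <- function(cell_profiles, proportions, noise_sd = 0, seed = NULL) {
  if (!is.matrix(cell_profiles)) cell_profiles <- rbind(cell_profiles)
  k <- nrow(cell_profiles)
  p <- ncol(cell_profiles)
  assert_field(length(proportions) == k, "proportions",
               "length must equal the number of cell-type profiles")
  assert_field(all(proportions >= 0), "proportions", "must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("invalid `proportions`: must sum to 1 within 1e-9", call. = FALSE)
  }
  assert_field(noise_sd >= 0, "noise_sd", "must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  e <- if (noise_sd > 0) stats::rnorm(p, 0, noise_sd) else numeric(p)
  betas <- inv_logit(sweep(cell_profiles, 2, e, `+`))
  out <- as.numeric(crossprod(betas, proportions))
  clip_beta(out, 0)  # mixture of [0,1] values stays in [0,1]; guard fp error
}

#' Generate trimodal SNP-probe betas with subject-consistent genotypes
#'
#' Genotypes are drawn once per subject under Hardy-Weinberg equilibrium and
#' reused for every sample of that subject, so same-subject samples share a
#' near-identical SNP fingerprint (the basis of sample-identity checks).
#' Beta values sit at genotype/2 (0, 0.5, 1) plus truncated noise.
#'
#' @param n_subjects number of subjects
#' @param n_probes number of SNP probes (default 65)
#' @param maf minor-allele frequency, in (0, 0.5]
#' @param noise_sd beta-scale noise SD
#' @param seed RNG seed
#' @param subjects optional character vector giving the subject of each
#'   sample; defaults to one sample per subject
#' @return list with `betas` (probes x samples) and `genotypes`
#'   (probes x subjects, minor-allele counts 0/1/2)
#' @export
spike_snp_probes <- function(n_subjects, n_probes = 65, maf = 0.3, noise_sd = 0.02,
                             seed = 1L, subjects = NULL) {
  assert_field(maf > 0 && maf <= 0.5, "maf", "must lie in (0, 0.5]")
  assert_field(noise_sd >= 0, "noise_sd", "must be >= 0")
  subject_ids <- sprintf("S%02d", seq_len(n_subjects))
  if (is.null(subjects)) subjects <- subject_ids
  assert_field(all(subjects %in% subject_ids), "subjects",
               "must reference subjects 1..n_subjects (labels S01, S02, ...)")
  set.seed(derive_seed(seed, 7001))
  geno <- matrix(stats::rbinom(n_probes * n_subjects, 2, maf),
                 nrow = n_probes, ncol = n_subjects,
                 dimnames = list(sprintf("rs%04d", seq_len(n_probes)), subject_ids))
  idx <- match(subjects, subject_ids)
  betas <- geno[, idx, drop = FALSE] / 2
  if (noise_sd > 0) {
    betas <- betas + matrix(stats::rnorm(length(betas), 0, noise_sd), nrow = n_probes)
    betas <- pmin(pmax(betas, 0), 1)
  }
  colnames(betas) <- if (!is.null(names(subjects))) names(subjects) else subjects
  list(betas = betas, genotypes = geno)
}

#' Generate a detection p-value matrix
#'
#' Passing entries are uniform on (0, 0.005); failing entries uniform on
#' (0.02, 1), so the 0.01 filtering threshold separates them cleanly and the
#' expected failing fraction equals `fail_rate`.
#'
#' @param n_probes,n_samples matrix shape
#' @param fail_rate probability an entry fails, in \[0,1\]
#' @param seed RNG seed
#' @return numeric matrix of detection p-values in \[0,1\]
#' @export
generate_detection_p <- function(n_probes, n_samples, fail_rate = 0.002, seed = 1L) {
  assert_field(fail_rate >= 0 && fail_rate <= 1, "fail_rate", "must lie in [0,1]")
  set.seed(derive_seed(seed, 7002))
  n <- n_probes * n_samples
  fail <- stats::runif(n) < fail_rate
  p <- stats::runif(n, 0, 0.005)
  p[fail] <- stats::runif(sum(fail), 0.02, 1)
  matrix(p, nrow = n_probes, ncol = n_samples)
}

# Probe annotation with plausible marginal frequencies for genic class,
# regulatory features and QC flags. Probes are assigned to synthetic gene
# symbols (~20 probes per gene); intergenic probes carry no gene.
generate_annotation <- function(n_probes, seed) {
  set.seed(derive_seed(seed, 7003))
  probe_id <- sprintf("cg%07d", seq_len(n_probes))
  chrom <- paste0("chr", sample(1:22, n_probes, replace = TRUE))
  pos <- integer(n_probes)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    pos[i] <- sort(sample.int(1e8, sum(i)))
  }
  genic_class <- sample(c("promoter", "genic", "intergenic"), n_probes,
                        replace = TRUE, prob = c(0.25, 0.45, 0.30))
  n_genes <- max(1L, ceiling(n_probes / 20))
  genes <- paste0("GENE", formatC(sample.int(n_genes, n_probes, replace = TRUE),
                                  width = 5, flag = "0"))
  genes[genic_class == "intergenic"] <- ""
  data.frame(
    probe_id = probe_id,
    chrom = chrom,
    pos = pos,
    genes = genes,
    genic_class = genic_class,
    tfbs = stats::runif(n_probes) < 0.15,
    enhancer = stats::runif(n_probes) < 0.10,
    open_chromatin = stats::runif(n_probes) < 0.15,
    mqtl = stats::runif(n_probes) < 0.10,
    snp_within_5bp = stats::runif(n_probes) < 0.02,
    context_specific = stats::runif(n_probes) < 0.005,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic multi-tissue cohort
#'
#' Draws, per probe, logit-scale cell-type means; per subject, a random effect
#' shared across all tissues; and per sample, independent logit-scale noise.
#' Each sample's beta values are the Dirichlet-weighted beta-scale mixture of
#' its tissue's cell-type methylomes. The shared subject effect is the sole
#' source of cross-tissue correlation, so the latent per-probe correlation is
#' s2_subj / (s2_subj + s2_noise); supplying `target_rho` solves for the
#' subject-effect SD. Probes are generated in fixed-size blocks with
#' deterministic sub-seeds, so enlarging `n_probes` leaves earlier probes'
#' draws untouched.
#'
#' @param config a [synth_config()] object
#' @return a `CohortBundle` list: `betas` (named list of probe x sample
#'   matrices, one per tissue), `sample_sheet`, `annotation`, `detection_p`
#'   (named list), `snp_betas`, `snp_genotypes`, and `truth` (`SynthTruth`:
#'   cell profiles, mixture proportions, subject effects, realized latent
#'   correlation per probe, variable-probe flags, seed)
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  n_s <- config$n_subjects
  n_p <- config$n_probes
  tissues <- config$tissues
  cts <- config$cell_types
  n_k <- length(cts)
  noise_sd <- config$noise_sd
  subj_sd <- if (!is.null(config$target_rho)) {
    rho_to_subject_sd(config$target_rho, noise_sd)
  } else config$subject_effect_sd
  if (!is.null(config$target_rho) && any(config$target_rho == 1)) {
    subj_sd <- config$subject_effect_sd
    if (subj_sd <= 0) subj_sd <- 0.5
  }
  subj_sd <- rep_len(subj_sd, n_p)

  subject_ids <- sprintf("S%02d", seq_len(n_s))
  probe_ids <- sprintf("cg%07d", seq_len(n_p))

  # samples: one per subject x tissue
  sample_sheet <- expand.grid(subject = subject_ids, tissue = tissues,
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sample_sheet$sample <- paste(sample_sheet$subject, sample_sheet$tissue, sep = "_")
  sample_sheet$day_offset <- ifelse(sample_sheet$tissue %in% c("saliva", "buccal"), 2L, 0L)
  sample_sheet <- sample_sheet[, c("sample", "subject", "tissue", "day_offset")]

  # per-sample mixture proportions (one Dirichlet draw per sample)
  set.seed(derive_seed(config$seed, 0, 99))
  props <- matrix(NA_real_, nrow(sample_sheet), n_k,
                  dimnames = list(sample_sheet$sample, cts))
  for (t in tissues) {
    i <- which(sample_sheet$tissue == t)
    props[i, ] <- rdirichlet(length(i), config$tissue_mixture_params[[t]])
  }

  betas <- lapply(tissues, function(t) {
    matrix(NA_real_, n_p, n_s, dimnames = list(probe_ids, paste(subject_ids, t, sep = "_")))
  })
  names(betas) <- tissues

  block_size <- 1000L
  n_blocks <- ceiling(n_p / block_size)
  cell_profiles <- matrix(NA_real_, n_k, n_p, dimnames = list(cts, probe_ids))
  subject_effects <- matrix(NA_real_, n_s, n_p, dimnames = list(subject_ids, probe_ids))
  variable_flag <- logical(n_p)
  realized_rho <- rep(NA_real_, n_p)

  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):min(b * block_size, n_p)
    m <- length(idx)
    # every stream draws a full block's worth of variates and keeps the
    # first m, so a partial final block today matches a full block after
    # n_probes grows

    # stream 1: profiles and variability flags
    set.seed(derive_seed(config$seed, 1, b))
    vflag_full <- stats::runif(block_size) < config$variable_fraction
    base_full <- numeric(block_size)
    base_full[vflag_full] <- stats::rnorm(sum(vflag_full), 0, 1)
    n_nv <- sum(!vflag_full)
    if (n_nv > 0) {
      # extreme methylation: low slope of the inverse logit keeps spread small
      base_full[!vflag_full] <- sample(c(-1, 1), n_nv, replace = TRUE) *
        (3.2 + abs(stats::rnorm(n_nv, 0, 0.5)))
    }
    off <- matrix(stats::rnorm(n_k * block_size, 0, 1.5), n_k, block_size)
    off[, !vflag_full] <- off[, !vflag_full, drop = FALSE] * 0.3
    prof <- sweep(off, 2, base_full, `+`)[, seq_len(m), drop = FALSE]
    vflag <- vflag_full[seq_len(m)]

    # stream 2: subject effects (shared across tissues)
    set.seed(derive_seed(config$seed, 2, b))
    u <- matrix(stats::rnorm(n_s * block_size), n_s, block_size)[, seq_len(m), drop = FALSE]
    u <- sweep(u, 2, subj_sd[idx], `*`)

    # streams 3..: per-tissue noise
    noise <- vector("list", length(tissues))
    for (ti in seq_along(tissues)) {
      set.seed(derive_seed(config$seed, 3 + ti, b))
      noise[[ti]] <- if (noise_sd > 0) {
        matrix(stats::rnorm(n_s * block_size, 0, noise_sd),
               n_s, block_size)[, seq_len(m), drop = FALSE]
      } else matrix(0, n_s, m)
    }

    for (ti in seq_along(tissues)) {
      t <- tissues[ti]
      x <- u + noise[[ti]]                      # subjects x probes latent
      w <- props[paste(subject_ids, t, sep = "_"), , drop = FALSE]
      bb <- matrix(0, m, n_s)
      for (k in seq_len(n_k)) {
        # invlogit(mu_kp + x_sp): probes x subjects
        lk <- inv_logit(matrix(prof[k, ], m, n_s) + t(x))
        bb <- bb + sweep(lk, 2, w[, k], `*`)
      }
      betas[[t]][idx, ] <- clip_beta(bb)
    }

    cell_profiles[, idx] <- prof
    subject_effects[, idx] <- u
    variable_flag[idx] <- vflag
    # realized latent correlation between the first two tissues
    if (length(tissues) >= 2 && n_s >= 3) {
      x1 <- u + noise[[1]]
      x2 <- u + noise[[2]]
      num <- colSums(scale(x1, scale = FALSE) * scale(x2, scale = FALSE))
      den <- sqrt(colSums(scale(x1, scale = FALSE)^2) * colSums(scale(x2, scale = FALSE)^2))
      realized_rho[idx] <- ifelse(den > 0, num / den, NA_real_)
    }
  }

  detection_p <- lapply(seq_along(tissues), function(ti) {
    dp <- generate_detection_p(n_p, n_s, fail_rate = 0.002,
                               seed = derive_seed(config$seed, 5, ti))
    dimnames(dp) <- dimnames(betas[[ti]])
    dp
  })
  names(detection_p) <- tissues

  snp <- spike_snp_probes(
    n_subjects = n_s, n_probes = 65, maf = 0.3, noise_sd = 0.02,
    seed = derive_seed(config$seed, 6),
    subjects = stats::setNames(sample_sheet$subject, sample_sheet$sample)
  )

  annotation <- generate_annotation(n_p, config$seed)

  truth <- list(
    cell_profiles = cell_profiles,
    mixture_proportions = props,
    subject_effects = subject_effects,
    realized_rho = realized_rho,
    variable_flag = variable_flag,
    subject_sd = subj_sd,
    noise_sd = noise_sd,
    seed = config$seed
  )
  class(truth) <- "SynthTruth"

  bundle <- list(
    betas = betas,
    sample_sheet = sample_sheet,
    annotation = annotation,
    detection_p = detection_p,
    snp_betas = snp$betas,
    snp_genotypes = snp$genotypes,
    truth = truth,
    config = config
  )
  class(bundle) <- "CohortBundle"
  bundle
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat(sprintf("CohortBundle: %d probes x %d subjects x %d tissues (%s)\n",
              nrow(x$betas[[1]]), x$config$n_subjects,
              length(x$betas), paste(names(x$betas), collapse = ", ")))
  invisible(x)
}
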