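# End-to-end orchestration: QC -> identity check -> concordance (both
# frameworks, all configured tissue pairs) -> stratification -> MDS and
# per-subject analysis -> optional composition adjustment and re-analysis.

#' Build a pipeline run configuration
#'
#' All analysis thresholds are surfaced here with their standard defaults:
#' detection p 0.01, greedy-cut stop fraction 0.05, 10% interpercentile trim
#' with a 0.05 beta-range variability cutoff, 0.05 nominal level, 0.5
#' moderate-correlation cutoff.
#'
#' @param tissue_pairs list of length-2 character vectors; at least one pair
#'   must include the reference tissue
#' @param reference_tissue the common tissue of the surrogacy comparisons
#'   (default `"brain"`)
#' @param input_dir optional directory of bundle TSVs (see [read_bundle()])
#' @param out_dir optional output directory; when given, all result tables
#'   are written beneath it
#' @param detection_threshold,greedycut_stop,qc_rules probe QC settings
#' @param trim,min_range variability classifier settings
#' @param p_nominal,rho_moderate,bonferroni_alpha summary thresholds
#' @param min_pairs,exact_cutoff within-subject correlation settings
#' @param groupings annotation groupings to stratify by
#' @param gene_sets named list of gene-symbol vectors (or file paths)
#' @param mds_metric `"euclidean"` or `"one_minus_r"`
#' @param adjust logical: estimate cell proportions (reference profiles
#'   required) and re-run the reference-pair concordance on adjusted data
#' @param reference_profiles optional [reference_profiles()] matrix for the
#'   adjustment stage
#' @param seed integer seed for any stochastic step
#' @return validated `RunConfig` list
#' @export
run_config <- function(tissue_pairs,
                       reference_tissue = "brain",
                       input_dir = NULL,
                       out_dir = NULL,
                       detection_threshold = 0.01,
                       greedycut_stop = 0.05,
                       qc_rules = QC_RULES,
                       trim = 0.10,
                       min_range = 0.05,
                       p_nominal = 0.05,
                       rho_moderate = 0.5,
                       bonferroni_alpha = 0.05,
                       min_pairs = 5,
                       exact_cutoff = 7,
                       groupings = c("genic_class", "regulatory_any", "mqtl"),
                       gene_sets = NULL,
                       mds_metric = "euclidean",
                       adjust = FALSE,
                       reference_profiles = NULL,
                       seed = 1L) {
  if (length(tissue_pairs) == 0) stop("config lists zero tissue pairs", call. = FALSE)
  if (!is.list(tissue_pairs)) tissue_pairs <- list(tissue_pairs)
  ok_ref <- any(vapply(tissue_pairs, function(p) reference_tissue %in% p, logical(1)))
  if (!ok_ref) {
    stop(sprintf("no tissue pair includes the reference tissue '%s'", reference_tissue),
         call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop(sprintf("input_dir does not exist: %s", input_dir), call. = FALSE)
  }
  cfg <- list(tissue_pairs = tissue_pairs, reference_tissue = reference_tissue,
              input_dir = input_dir, out_dir = out_dir,
              detection_threshold = detection_threshold,
              greedycut_stop = greedycut_stop, qc_rules = qc_rules,
              trim = trim, min_range = min_range, p_nominal = p_nominal,
              rho_moderate = rho_moderate, bonferroni_alpha = bonferroni_alpha,
              min_pairs = min_pairs, exact_cutoff = exact_cutoff,
              groupings = groupings, gene_sets = gene_sets,
              mds_metric = mds_metric, adjust = adjust,
              reference_profiles = reference_profiles, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the [run_config()] arguments
#' @return `RunConfig`
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tissue_pairs)) {
    y$tissue_pairs <- lapply(y$tissue_pairs, unlist)
  }
  do.call(run_config, y)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, sprintf(...)))
}

#' Run the full concordance pipeline
#'
#' Executes probe QC (detection-p flagging, greedy-cut, annotation filters),
#' SNP-probe identity verification, both correlation frameworks for every
#' configured tissue pair, annotation-based stratification, MDS with the
#' per-subject distance-versus-correlation regression, and (optionally)
#' cell-composition adjustment with re-analysis of the reference pair.
#' Reruns with identical config and inputs are deterministic.
#'
#' @param config a [run_config()] object
#' @param bundle optional in-memory cohort (as from [generate_cohort()] or
#'   [read_bundle()]); when NULL, read from `config$input_dir`
#' @return report list: `qc`, `identity`, `concordance` (per pair:
#'   `records`, `summary_all`, `summary_variable`, `across_rho`),
#'   `correlation_matrix` (all-pairs across-subject r, overall and
#'   variable-restricted), `stratified`, `mds`, `per_subject`,
#'   `distance_regression`, `adjusted`, `manifest`
#' @export
run_pipeline <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(bundle)) {
    if (is.null(config$input_dir)) stop("no bundle and no input_dir", call. = FALSE)
    bundle <- read_bundle(config$input_dir)
  }
  tissues <- names(bundle$betas)
  for (pair in config$tissue_pairs) {
    if (!all(pair %in% tissues)) {
      stop(sprintf("tissue pair (%s) not present in the bundle", paste(pair, collapse = ", ")),
           call. = FALSE)
    }
  }
  probe_sets <- lapply(bundle$betas, rownames)
  if (!all(vapply(probe_sets, identical, logical(1), y = probe_sets[[1]]))) {
    stop("mismatched probe sets across tissues", call. = FALSE)
  }

  # ---- QC ----
  stage_log("qc", "start: %d probes x %d tissues", nrow(bundle$betas[[1]]), length(tissues))
  unreliable_cols <- lapply(tissues, function(t) {
    if (is.null(bundle$detection_p[[t]])) return(NULL)
    flag_unreliable(bundle$detection_p[[t]], config$detection_threshold)
  })
  names(unreliable_cols) <- tissues
  have_detp <- !vapply(unreliable_cols, is.null, logical(1))
  gc_res <- NULL
  unreliable_probes <- character(0)
  removed_samples <- character(0)
  if (any(have_detp)) {
    combined <- do.call(cbind, unreliable_cols[have_detp])
    gc_res <- greedycut(combined, config$greedycut_stop)
    unreliable_probes <- gc_res$removed_probes
    removed_samples <- gc_res$removed_samples
    # probes with any unreliable entry surviving greedy-cut are also dropped
    kept <- combined[gc_res$kept_probes, gc_res$kept_samples, drop = FALSE]
    unreliable_probes <- union(unreliable_probes, rownames(kept)[rowSums(kept) > 0])
  }
  filt <- filter_probes(bundle$annotation, unreliable_probes, config$qc_rules)
  filt$samples_removed <- removed_samples
  keep_probes <- filt$kept_probes
  betas <- lapply(bundle$betas, function(m) {
    m <- m[keep_probes, , drop = FALSE]
    m[, setdiff(colnames(m), removed_samples), drop = FALSE]
  })
  stage_log("qc", "done: %d probes kept, %d removed, %d samples removed",
            length(keep_probes), nrow(filt$removed_probes), length(removed_samples))

  # ---- identity ----
  identity <- NULL
  if (!is.null(bundle$snp_betas)) {
    identity <- verify_sample_identity(bundle$snp_betas, bundle$sample_sheet)
    stage_log("identity", "%d mismatch pair(s) flagged", nrow(identity$flagged_mismatches))
  }

  # ---- concordance ----
  profiles <- lapply(betas, mean_profile)
  conc <- list()
  for (pair in config$tissue_pairs) {
    key <- paste(pair, collapse = "_vs_")
    stage_log("concordance", "pair %s", key)
    rec <- within_subject_correlations(
      betas[[pair[1]]], betas[[pair[2]]], bundle$sample_sheet,
      min_pairs = config$min_pairs, exact_cutoff = config$exact_cutoff,
      trim = config$trim, min_range = config$min_range
    )
    sm_all <- summarize_concordance(
      rec, p_nominal = config$p_nominal, rho_moderate = config$rho_moderate,
      bonferroni_alpha = config$bonferroni_alpha,
      profile_a = profiles[[pair[1]]], profile_b = profiles[[pair[2]]],
      tissue_pair = pair
    )
    sm_var <- summarize_concordance(
      rec, restrict_variable = "peripheral",
      p_nominal = config$p_nominal, rho_moderate = config$rho_moderate,
      bonferroni_alpha = config$bonferroni_alpha,
      profile_a = profiles[[pair[1]]], profile_b = profiles[[pair[2]]],
      tissue_pair = pair
    )
    conc[[key]] <- list(pair = pair, records = rec,
                        summary_all = sm_all, summary_variable = sm_var,
                        across_rho = sm_all$across_subject_rho)
  }

  # all-pairs across-subject correlation matrix (Table-1 style)
  all_pairs <- utils::combn(tissues, 2, simplify = FALSE)
  cormat <- do.call(rbind, lapply(all_pairs, function(pr) {
    overall <- across_subject_correlation(profiles[[pr[1]]], profiles[[pr[2]]])$rho
    vb <- classify_variable(collapse_to_subjects(betas[[pr[2]]], bundle$sample_sheet),
                            trim = config$trim, min_range = config$min_range)
    vids <- rownames(betas[[pr[2]]])[vb %in% TRUE]
    var_r <- if (length(vids) >= 3)
      across_subject_correlation(profiles[[pr[1]]], profiles[[pr[2]]], vids)$rho else NA_real_
    data.frame(tissue_a = pr[1], tissue_b = pr[2],
               overall_r = overall, variable_r = var_r, stringsAsFactors = FALSE)
  }))

  # ---- stratification ----
  strat <- list()
  ref_pairs <- Filter(function(p) config$reference_tissue %in% p, config$tissue_pairs)
  for (pair in ref_pairs) {
    key <- paste(pair, collapse = "_vs_")
    strat[[key]] <- lapply(config$groupings, function(g) {
      stratified_concordance(conc[[key]]$records, bundle$annotation, g,
                             profile_a = profiles[[pair[1]]],
                             profile_b = profiles[[pair[2]]])
    })
    names(strat[[key]]) <- config$groupings
    if (!is.null(config$gene_sets)) {
      strat[[key]]$gene_sets <- lapply(config$gene_sets, function(gs) {
        if (is.character(gs) && length(gs) == 1 && file.exists(gs)) gs <- read_gene_set(gs)
        gene_set_concordance(conc[[key]]$records, bundle$annotation, gs,
                             p_nominal = config$p_nominal)
      })
    }
  }
  stage_log("stratify", "%d reference pair(s) x %d grouping(s)",
            length(ref_pairs), length(config$groupings))

  # ---- structure ----
  combined_betas <- do.call(cbind, betas)
  D <- sample_distances(combined_betas, metric = config$mds_metric)
  mds <- classical_mds(D, k = 2)
  per_subject <- list()
  dist_reg <- list()
  for (pair in ref_pairs) {
    key <- paste(pair, collapse = "_vs_")
    psc <- per_subject_concordance(betas[[pair[1]]], betas[[pair[2]]], bundle$sample_sheet)
    per_subject[[key]] <- psc
    dist_reg[[key]] <- tryCatch(
      paired_distance_vs_correlation(D, bundle$sample_sheet, psc, pair[1], pair[2]),
      error = function(e) list(error = conditionMessage(e))
    )
  }
  stage_log("structure", "MDS GOF %.3f over %d samples", mds$goodness_of_fit, nrow(D))

  # ---- adjustment ----
  adjusted <- NULL
  if (isTRUE(config$adjust)) {
    if (is.null(config$reference_profiles)) {
      stop("stage adjustment failed: reference_profiles required when adjust = TRUE",
           call. = FALSE)
    }
    pair <- ref_pairs[[1]]
    key <- paste(pair, collapse = "_vs_")
    adj_betas <- lapply(pair, function(t) {
      est <- estimate_proportions(betas[[t]], config$reference_profiles)
      adjust_for_composition(betas[[t]], est)
    })
    names(adj_betas) <- pair
    rec_adj <- within_subject_correlations(
      adj_betas[[1]]$adjusted, adj_betas[[2]]$adjusted, bundle$sample_sheet,
      min_pairs = config$min_pairs, exact_cutoff = config$exact_cutoff,
      trim = config$trim, min_range = config$min_range
    )
    adjusted <- list(
      pair = pair,
      records = rec_adj,
      summary_all = summarize_concordance(rec_adj, tissue_pair = pair),
      comparison = compare_adjusted_concordance(conc[[key]]$records, rec_adj,
                                                config$p_nominal),
      r_squared = lapply(adj_betas, `[[`, "r_squared")
    )
    stage_log("adjust", "delta mean rho %.4f", adjusted$comparison$delta_mean_rho)
  }

  manifest <- list(
    parameters = config[setdiff(names(config), c("reference_profiles"))],
    n_probes_input = nrow(bundle$betas[[1]]),
    n_probes_kept = length(keep_probes),
    tissues = tissues,
    package_version = as.character(utils::packageVersion("methconcord"))
  )

  report <- list(qc = filt, greedycut = gc_res, identity = identity,
                 concordance = conc, correlation_matrix = cormat,
                 stratified = strat, mds = mds, distances = D,
                 per_subject = per_subject, distance_regression = dist_reg,
                 adjusted = adjusted, manifest = manifest)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# write the machine-readable report artifacts under out_dir
write_report <- function(report, out_dir) {
  dirs <- file.path(out_dir, c("qc", "concordance", "stratified", "mds", "report"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(counts_removed_per_rule = as.list(report$qc$counts_removed_per_rule),
         n_kept = length(report$qc$kept_probes),
         samples_removed = report$qc$samples_removed),
    file.path(out_dir, "qc", "filter_report.json"), auto_unbox = TRUE, digits = NA)
  for (key in names(report$concordance)) {
    rec <- report$concordance[[key]]$records
    data.table::fwrite(rec, file.path(out_dir, "concordance", paste0(key, ".tsv")), sep = "\t")
  }
  data.table::fwrite(report$correlation_matrix,
                     file.path(out_dir, "concordance", "correlation_matrix.tsv"), sep = "\t")
  coords <- data.frame(sample = rownames(report$mds$coordinates),
                       report$mds$coordinates, stringsAsFactors = FALSE)
  data.table::fwrite(coords, file.path(out_dir, "mds", "coordinates.tsv"), sep = "\t")
  summaries <- lapply(report$concordance, function(x) {
    list(all = unclass(x$summary_all), variable = unclass(x$summary_variable))
  })
  jsonlite::write_json(list(summaries = summaries,
                            manifest = report$manifest),
                       file.path(out_dir, "report", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
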