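# Probe-level quality control: detection-p flagging, greedy-cut removal of
# unreliable probes/samples, annotation-based exclusion rules, and SNP-probe
# sample-identity verification.

# canonical rule order for attribution of removed probes
QC_RULES <- c("snp_within_5bp", "unreliable", "context_specific")

#' Flag unreliable measurements from detection p-values
#'
#' An entry is unreliable when its detection p-value strictly exceeds the
#' threshold (default 0.01); a value exactly at the threshold passes.
#'
#' @param detection_p numeric matrix of detection p-values in \[0,1\]
#' @param threshold detection p cutoff, in (0,1)
#' @return logical matrix of the same shape, TRUE = unreliable
#' @export
flag_unreliable <- function(detection_p, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) {
    stop("invalid `threshold`: must lie in (0,1)", call. = FALSE)
  }
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    stop("invalid `detection_p`: entries must lie in [0,1]", call. = FALSE)
  }
  detection_p > threshold
}

#' Iterative greedy removal of unreliable probes and samples
#'
#' Repeatedly removes the single row (probe) or column (sample) with the
#' highest fraction of unreliable entries until no remaining row or column
#' exceeds `stop_fraction`. Ties are broken in favour of rows, then by
#' lexicographic identifier. This is a documented surrogate for the
#' iterative "greedycut" style of matrix cleaning used in array QC
#' pipelines, not a clone of any particular implementation.
#'
#' @param unreliable logical probe x sample matrix (TRUE = unreliable)
#' @param stop_fraction stop once the max row/column unreliable fraction is
#'   <= this value (default 0.05)
#' @return list with `removed_probes`, `removed_samples`, `trace`
#'   (data.frame: step, type, id, fraction), `kept_probes`, `kept_samples`
#' @export
greedycut <- function(unreliable, stop_fraction = 0.05) {
  if (!is.matrix(unreliable) || length(unreliable) == 0) {
    stop("`unreliable` must be a nonempty matrix", call. = FALSE)
  }
  if (stop_fraction < 0 || stop_fraction > 1) {
    stop("invalid `stop_fraction`: must lie in [0,1]", call. = FALSE)
  }
  m <- unreliable
  if (is.null(rownames(m))) rownames(m) <- sprintf("row%05d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("col%05d", seq_len(ncol(m)))
  mode(m) <- "logical"

  trace <- list()
  removed_rows <- character(0)
  removed_cols <- character(0)
  step <- 0L
  repeat {
    if (nrow(m) == 0 || ncol(m) == 0) break
    rf <- rowMeans(m)
    cf <- colMeans(m)
    max_r <- max(rf)
    max_c <- max(cf)
    if (max(max_r, max_c) <= stop_fraction) break
    step <- step + 1L
    if (max_r >= max_c) {
      cand <- names(rf)[rf == max_r]
      id <- sort(cand)[1]
      trace[[step]] <- data.frame(step = step, type = "probe", id = id,
                                  fraction = max_r, stringsAsFactors = FALSE)
      removed_rows <- c(removed_rows, id)
      m <- m[setdiff(rownames(m), id), , drop = FALSE]
    } else {
      cand <- names(cf)[cf == max_c]
      id <- sort(cand)[1]
      trace[[step]] <- data.frame(step = step, type = "sample", id = id,
                                  fraction = max_c, stringsAsFactors = FALSE)
      removed_cols <- c(removed_cols, id)
      m <- m[, setdiff(colnames(m), id), drop = FALSE]
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), type = character(0), id = character(0),
               fraction = numeric(0), stringsAsFactors = FALSE)
  list(removed_probes = removed_rows, removed_samples = removed_cols,
       trace = trace, kept_probes = rownames(m), kept_samples = colnames(m))
}

#' Apply annotation-based probe exclusion rules
#'
#' Removes probes failing any of the requested rules: proximity to a SNP
#' (`snp_within_5bp`), membership in the unreliable set from detection-p /
#' greedy-cut QC (`unreliable`), or context-specific (non-CpG) status
#' (`context_specific`). A probe failing several rules is attributed to the
#' first rule it fails in the canonical order above, so per-rule counts sum
#' to the number of removed probes.
#'
#' @param annotation probe annotation data.frame with `probe_id` and logical
#'   `snp_within_5bp`, `context_specific` columns
#' @param unreliable_rows character vector of probe ids flagged unreliable
#' @param rules character vector of rules to apply (subset of
#'   `snp_within_5bp`, `unreliable`, `context_specific`)
#' @return a `FilterReport` list: `counts_removed_per_rule`, `kept_probes`,
#'   `removed_probes` (data.frame probe_id, rule), `samples_removed`
#' @export
filter_probes <- function(annotation,
                          unreliable_rows = character(0),
                          rules = QC_RULES) {
  unknown <- setdiff(rules, QC_RULES)
  if (length(unknown)) {
    stop(sprintf("unknown rule(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  probes <- annotation$probe_id
  fails <- list(
    snp_within_5bp = if ("snp_within_5bp" %in% rules)
      as.logical(annotation$snp_within_5bp) else rep(FALSE, length(probes)),
    unreliable = if ("unreliable" %in% rules)
      probes %in% unreliable_rows else rep(FALSE, length(probes)),
    context_specific = if ("context_specific" %in% rules)
      as.logical(annotation$context_specific) else rep(FALSE, length(probes))
  )
  # first-failing-rule attribution in canonical order
  attributed <- rep(NA_character_, length(probes))
  for (r in QC_RULES) {
    hit <- fails[[r]] & is.na(attributed)
    attributed[hit] <- r
  }
  removed <- !is.na(attributed)
  counts <- vapply(QC_RULES, function(r) sum(attributed == r, na.rm = TRUE), integer(1))
  report <- list(
    counts_removed_per_rule = counts,
    kept_probes = probes[!removed],
    removed_probes = data.frame(probe_id = probes[removed],
                                rule = attributed[removed],
                                stringsAsFactors = FALSE),
    samples_removed = character(0)
  )
  class(report) <- "FilterReport"
  report
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", length(x$kept_probes), "probes kept,",
      nrow(x$removed_probes), "removed\n")
  for (r in names(x$counts_removed_per_rule)) {
    cat(sprintf("  %-18s %d\n", r, x$counts_removed_per_rule[[r]]))
  }
  invisible(x)
}

#' Verify same-subject sample identity from SNP probes
#'
#' Computes the sample-by-sample Pearson correlation over the SNP probes.
#' Same-subject pairs below `same_threshold` and different-subject pairs
#' above `diff_threshold` are flagged as possible labelling errors. A sample
#' whose SNP vector has zero variance is reported as unevaluable rather than
#' raising an error.
#'
#' @param snp_betas SNP-probe beta matrix (probes x samples)
#' @param sample_sheet data.frame with `sample` and `subject` columns
#' @param same_threshold minimum similarity expected for same-subject pairs
#' @param diff_threshold maximum similarity expected across subjects
#' @return an `IdentityReport` list: `pairwise_similarity`,
#'   `expected_same_subject_pairs`, `flagged_mismatches`, `unevaluable`
#' @export
verify_sample_identity <- function(snp_betas, sample_sheet,
                                   same_threshold = 0.9, diff_threshold = 0.8) {
  if (ncol(snp_betas) < 2) stop("need >= 2 samples", call. = FALSE)
  if (nrow(snp_betas) < 10) stop("need >= 10 SNP probes", call. = FALSE)
  samples <- colnames(snp_betas)
  if (is.null(samples)) stop("snp_betas must have sample column names", call. = FALSE)
  sds <- apply(snp_betas, 2, stats::sd)
  unevaluable <- samples[sds == 0 | is.na(sds)]
  sim <- suppressWarnings(stats::cor(snp_betas))
  diag(sim) <- 1
  subj <- sample_sheet$subject[match(samples, sample_sheet$sample)]

  pairs <- utils::combn(seq_along(samples), 2)
  same_subject <- subj[pairs[1, ]] == subj[pairs[2, ]]
  pair_df <- data.frame(
    sample_a = samples[pairs[1, ]],
    sample_b = samples[pairs[2, ]],
    similarity = sim[cbind(pairs[1, ], pairs[2, ])],
    same_subject = same_subject,
    stringsAsFactors = FALSE
  )
  evaluable <- !(pair_df$sample_a %in% unevaluable | pair_df$sample_b %in% unevaluable)
  flagged <- pair_df[evaluable & !is.na(pair_df$similarity) &
                       ((pair_df$same_subject & pair_df$similarity < same_threshold) |
                          (!pair_df$same_subject & pair_df$similarity > diff_threshold)), ]
  report <- list(
    pairwise_similarity = sim,
    expected_same_subject_pairs = pair_df[pair_df$same_subject,
                                          c("sample_a", "sample_b", "similarity")],
    flagged_mismatches = flagged,
    unevaluable = unevaluable
  )
  class(report) <- "IdentityReport"
  report
}

#' @export
print.IdentityReport <- function(x, ...) {
  cat(sprintf("IdentityReport: %d samples, %d same-subject pairs, %d flagged, %d unevaluable\n",
              ncol(x$pairwise_similarity), nrow(x$expected_same_subject_pairs),
              nrow(x$flagged_mismatches), length(x$unevaluable)))
  invisible(x)
}
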