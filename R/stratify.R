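# Stratification of concordance results by genomic context, regulatory
# features, mQTL status and gene sets, plus a local region/gene/probe query.

# split a "genes" annotation field (possibly ";"-separated) into symbols
split_genes <- function(genes) {
  strsplit(ifelse(is.na(genes), "", genes), ";", fixed = TRUE)
}

# group membership lists for each supported grouping
build_groups <- function(annotation, grouping, gene_list = NULL) {
  p <- annotation$probe_id
  switch(grouping,
    genic_class = {
      lv <- c("promoter", "genic", "intergenic")
      stats::setNames(lapply(lv, function(g) p[annotation$genic_class == g]), lv)
    },
    regulatory_any = {
      reg <- annotation$tfbs | annotation$enhancer | annotation$open_chromatin
      list(regulatory = p[reg], non_regulatory = p[!reg])
    },
    regulatory_feature = list(
      tfbs = p[annotation$tfbs],
      enhancer = p[annotation$enhancer],
      open_chromatin = p[annotation$open_chromatin]
    ),
    mqtl = list(mqtl = p[annotation$mqtl], non_mqtl = p[!annotation$mqtl]),
    gene_set = {
      if (is.null(gene_list)) stop("grouping 'gene_set' requires `gene_list`", call. = FALSE)
      hits <- probes_for_genes(annotation, gene_list)
      list(in_set = hits, out_of_set = setdiff(p, hits))
    },
    stop(sprintf("unknown grouping key '%s'", grouping), call. = FALSE)
  )
}

# probe ids annotated to any gene in gene_list (exact symbol, case-insensitive)
probes_for_genes <- function(annotation, gene_list) {
  wanted <- toupper(trimws(gene_list))
  syms <- split_genes(annotation$genes)
  hit <- vapply(syms, function(g) any(toupper(g) %in% wanted), logical(1))
  annotation$probe_id[hit]
}

#' Stratified concordance summaries
#'
#' Recomputes the concordance summary (and, when profiles are supplied, the
#' across-subject Pearson correlation) separately for each group of probes
#' defined by the chosen annotation grouping. Groups with fewer than 3
#' record probes yield a NULL summary with the group size reported.
#'
#' @param records within-subject correlation table
#' @param annotation probe annotation covering all record probes
#' @param grouping one of `genic_class`, `regulatory_any`,
#'   `regulatory_feature`, `mqtl`, `gene_set`
#' @param gene_list character vector of gene symbols (for `gene_set`)
#' @param profile_a,profile_b optional tissue mean profiles
#' @param ... further arguments passed to [summarize_concordance()]
#' @return list of per-group entries: `group_label`, `group_size`, `summary`
#' @export
stratified_concordance <- function(records, annotation, grouping,
                                   gene_list = NULL,
                                   profile_a = NULL, profile_b = NULL, ...) {
  missing_ann <- setdiff(records$probe_id, annotation$probe_id)
  if (length(missing_ann)) {
    stop(sprintf("annotation missing %d record probes", length(missing_ann)), call. = FALSE)
  }
  groups <- build_groups(annotation, grouping, gene_list)
  lapply(names(groups), function(g) {
    ids <- intersect(groups[[g]], records$probe_id)
    rec <- records[records$probe_id %in% ids, , drop = FALSE]
    s <- if (nrow(rec) < 3) NULL else
      summarize_concordance(rec, profile_a = profile_a, profile_b = profile_b, ...)
    list(group_label = g, group_size = nrow(rec), summary = s)
  })
}

#' Gene-set concordance with a per-gene breakdown
#'
#' Restricts the correlation table to probes annotated to the listed genes
#' (exact symbol match, case-insensitive), optionally further restricted to
#' probes variable in the named tissues, and reports both the overall
#' summary and a per-gene table (CpG count, nominally correlated count,
#' max |rho|).
#'
#' @param records within-subject correlation table
#' @param annotation probe annotation
#' @param gene_list nonempty character vector of gene symbols
#' @param require_variable_in subset of `c("brain", "peripheral")`: restrict
#'   to probes variable in those tissues (both = intersection)
#' @param p_nominal nominal significance level
#' @param ... passed to [summarize_concordance()]
#' @return list with `summary`, `per_gene` (data.frame), `n_genes_nominal`
#'   (genes with at least one nominally correlated CpG), `unmatched_genes`
#' @export
gene_set_concordance <- function(records, annotation, gene_list,
                                 require_variable_in = NULL,
                                 p_nominal = 0.05, ...) {
  if (length(gene_list) == 0) stop("`gene_list` must be nonempty", call. = FALSE)
  wanted <- toupper(trimws(gene_list))
  syms <- split_genes(annotation$genes)
  upper_syms <- lapply(syms, toupper)
  hit <- vapply(upper_syms, function(g) any(g %in% wanted), logical(1))
  matched_symbols <- unique(unlist(upper_syms[hit]))
  unmatched <- setdiff(wanted, matched_symbols)
  ids <- annotation$probe_id[hit]
  rec <- records[records$probe_id %in% ids, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("no probes map to the gene list; unmatched genes: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  if (!is.null(require_variable_in)) {
    keep <- rep(TRUE, nrow(rec))
    if ("brain" %in% require_variable_in) keep <- keep & (rec$variable_a %in% TRUE)
    if ("peripheral" %in% require_variable_in) keep <- keep & (rec$variable_b %in% TRUE)
    rec <- rec[keep, , drop = FALSE]
  }
  overall <- summarize_concordance(rec, ...)

  # per-gene table over the matched probes
  ann_hit <- annotation[hit, , drop = FALSE]
  probe_gene <- data.frame(
    probe_id = rep(ann_hit$probe_id, lengths(upper_syms[hit])),
    gene = unlist(upper_syms[hit]),
    stringsAsFactors = FALSE
  )
  probe_gene <- probe_gene[probe_gene$gene %in% wanted, , drop = FALSE]
  probe_gene <- merge(probe_gene, rec[, c("probe_id", "rho", "p")], by = "probe_id")
  per_gene <- do.call(rbind, lapply(split(probe_gene, probe_gene$gene), function(d) {
    data.frame(gene = d$gene[1],
               n_cpgs = nrow(d),
               n_nominal = sum(d$p < p_nominal, na.rm = TRUE),
               max_abs_rho = if (all(is.na(d$rho))) NA_real_ else max(abs(d$rho), na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(summary = overall,
       per_gene = per_gene,
       n_genes_nominal = sum(per_gene$n_nominal >= 1),
       unmatched_genes = unmatched)
}

# parse "chr1:100-200" into list(chrom, start, end); 1-based inclusive
parse_interval <- function(q) {
  m <- regmatches(q, regexec("^([^:]+):([0-9]+)-([0-9]+)$", q))[[1]]
  if (length(m) != 4) stop(sprintf("malformed interval '%s'", q), call. = FALSE)
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (start > end) stop(sprintf("malformed interval '%s': start > end", q), call. = FALSE)
  list(chrom = m[2], start = start, end = end)
}

#' Read a BED file of intervals
#'
#' BED coordinates are 0-based half-open; they are converted on read to the
#' 1-based inclusive convention used by [region_query()].
#'
#' @param path BED file path (first three columns used)
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
             stringsAsFactors = FALSE)
}

#' Query concordance results by probe, gene or genomic interval
#'
#' Local lookup over the analysed probes: given probe ids, a gene symbol, or
#' a 1-based inclusive interval string `chr:start-end`, returns each matching
#' probe's position, per-tissue mean beta, and the within-subject rho and p
#' from each supplied correlation table, with variability flags.
#'
#' @param records named list of within-subject correlation tables (one per
#'   tissue pair), or a single table
#' @param annotation probe annotation
#' @param betas named list of probe x sample beta matrices (one per tissue)
#' @param probes,gene,interval exactly one of: probe id vector, gene symbol,
#'   or interval string(s) `chr:start-end`
#' @return data.frame (zero rows, with a warning, when nothing matches)
#' @export
region_query <- function(records, annotation, betas = NULL,
                         probes = NULL, gene = NULL, interval = NULL) {
  n_args <- sum(!is.null(probes), !is.null(gene), !is.null(interval))
  if (n_args != 1) stop("supply exactly one of `probes`, `gene`, `interval`", call. = FALSE)
  if (is.data.frame(records)) records <- list(pair = records)

  ids <- if (!is.null(probes)) {
    intersect(probes, annotation$probe_id)
  } else if (!is.null(gene)) {
    probes_for_genes(annotation, gene)
  } else {
    hits <- character(0)
    for (q in interval) {
      iv <- if (is.list(q)) q else parse_interval(q)
      sel <- annotation$chrom == iv$chrom &
        annotation$pos >= iv$start & annotation$pos <= iv$end
      hits <- c(hits, annotation$probe_id[sel])
    }
    unique(hits)
  }

  if (length(ids) == 0) {
    warning("query matched no probes")
    out <- data.frame(probe_id = character(0), chrom = character(0),
                      pos = integer(0), stringsAsFactors = FALSE)
    attr(out, "status") <- "no_matches"
    return(out)
  }
  ann <- annotation[match(ids, annotation$probe_id),
                    c("probe_id", "chrom", "pos", "genes", "genic_class")]
  out <- ann
  if (!is.null(betas)) {
    for (t in names(betas)) {
      out[[paste0("mean_beta_", t)]] <- mean_profile(betas[[t]])[ids]
    }
  }
  for (pair in names(records)) {
    rec <- records[[pair]]
    i <- match(ids, rec$probe_id)
    out[[paste0("rho_", pair)]] <- rec$rho[i]
    out[[paste0("p_", pair)]] <- rec$p[i]
    out[[paste0("variable_a_", pair)]] <- rec$variable_a[i]
    out[[paste0("variable_b_", pair)]] <- rec$variable_b[i]
  }
  rownames(out) <- NULL
  attr(out, "status") <- "ok"
  out
}
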