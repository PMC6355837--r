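# TSV/JSON input and output for cohort bundles and results.

#' Write a beta-style matrix as TSV
#'
#' Probe ids in the first column (`probe_id`), one column per sample.
#'
#' @param m probe x sample numeric matrix with dimnames
#' @param path output path
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a beta-style TSV matrix
#'
#' @param path TSV with a `probe_id` first column
#' @return probe x sample numeric matrix
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write a synthetic cohort bundle to a directory
#'
#' Emits `betas_<tissue>.tsv`, `detection_p_<tissue>.tsv`,
#' `sample_sheet.tsv`, `annotation.tsv`, `snp_probes.tsv` and
#' `truth.json` (scalar truth parameters; full matrices stay in memory).
#'
#' @param bundle a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(bundle$betas)) {
    write_matrix_tsv(bundle$betas[[t]], file.path(dir, sprintf("betas_%s.tsv", t)))
    write_matrix_tsv(bundle$detection_p[[t]], file.path(dir, sprintf("detection_p_%s.tsv", t)))
  }
  data.table::fwrite(bundle$sample_sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t")
  data.table::fwrite(bundle$annotation, file.path(dir, "annotation.tsv"), sep = "\t")
  write_matrix_tsv(bundle$snp_betas, file.path(dir, "snp_probes.tsv"))
  truth <- list(seed = bundle$truth$seed,
                noise_sd = bundle$truth$noise_sd,
                subject_sd = unname(bundle$truth$subject_sd[1]),
                n_variable = sum(bundle$truth$variable_flag))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort bundle from a directory written by [write_bundle()]
#'
#' @param dir directory containing the bundle TSVs
#' @param tissues tissue labels to read (default: inferred from file names)
#' @return list with `betas`, `detection_p`, `sample_sheet`, `annotation`,
#'   `snp_betas`
#' @export
read_bundle <- function(dir, tissues = NULL) {
  if (is.null(tissues)) {
    f <- list.files(dir, pattern = "^betas_.*\\.tsv$")
    tissues <- sub("^betas_(.*)\\.tsv$", "\\1", f)
  }
  betas <- lapply(tissues, function(t) read_matrix_tsv(file.path(dir, sprintf("betas_%s.tsv", t))))
  names(betas) <- tissues
  detp <- lapply(tissues, function(t) {
    p <- file.path(dir, sprintf("detection_p_%s.tsv", t))
    if (file.exists(p)) read_matrix_tsv(p) else NULL
  })
  names(detp) <- tissues
  list(
    betas = betas,
    detection_p = detp,
    sample_sheet = as.data.frame(data.table::fread(file.path(dir, "sample_sheet.tsv"))),
    annotation = as.data.frame(data.table::fread(file.path(dir, "annotation.tsv"))),
    snp_betas = {
      p <- file.path(dir, "snp_probes.tsv")
      if (file.exists(p)) read_matrix_tsv(p) else NULL
    }
  )
}

#' Read a gene set from a one-symbol-per-line text file
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored
#' @return character vector of symbols
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
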