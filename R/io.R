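## Readers and writers for the pipeline's plain-text formats:
## Beta matrices and covariates as TSV, annotation as TSV, feature tracks as
## BED (0-based half-open), CpG sets as one id per line, mQTL tables as TSV.

#' Read a Beta matrix from TSV
#'
#' Expects a header row of sample ids and a first column of CpG ids; `NA` and
#' empty cells become missing values. Duplicate CpG ids or non-numeric cells
#' raise an error naming the offender.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, CpGs x samples.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort(paste0("Duplicate CpG ids: ", paste(head(dup, 5), collapse = ", ")))
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- apply(vals, 2, as.numeric))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("Non-numeric cell at row %d (CpG %s), column %s.",
                  bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  num
}

#' Write a Beta matrix as TSV
#' @param beta Numeric matrix with CpG rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- as_tibble(beta, rownames = "cpg")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample covariate table (TSV: sample_id, age, sex)
#' @param path File path.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character()
  ), progress = FALSE)
}

#' @rdname read_covariates
#' @param covariates Tibble with `sample_id` and optional `age`, `sex`.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, progress = FALSE)
  invisible(path)
}

#' Read / write probe annotation (TSV: cpg, chrom, pos, reliable)
#'
#' Positions are 1-based. A missing `reliable` column defaults to `TRUE`.
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    cpg = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), reliable = readr::col_logical()
  ), progress = FALSE)
  if (!"reliable" %in% names(ann)) ann$reliable <- TRUE
  ann
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Read / write a BED interval track (0-based, half-open)
#'
#' Backed by `rtracklayer`; only the first three columns (plus an optional
#' name) are used.
#' @param path File path.
#' @return A tibble `(chrom, start, end)` with `start` 0-based.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' @rdname read_bed
#' @param intervals Tibble `(chrom, start, end)`, BED convention.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L, intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write single-base CpG calls as BED
#'
#' Each CpG becomes a single-base interval `[pos - 1, pos)` named by its id.
#' @param cpgs Character vector of ids.
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @export
write_cpg_bed <- function(cpgs, annotation, path) {
  ann <- annotation[match(cpgs, annotation$cpg), ]
  gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$pos, ann$pos))
  names(gr) <- ann$cpg
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a CpG-id set (one id per line)
#' @param path File path.
#' @return Character vector.
#' @export
read_cpg_set <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_cpg_set
#' @param ids Character vector of ids.
#' @export
write_cpg_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read / write an mQTL summary table (TSV: cpg, snp, beta, maf, kind, p)
#' @param path File path.
#' @param cis_p,trans_p Optional significance thresholds applied as row
#'   filters on cis / trans records (`NULL` keeps everything).
#' @return A tibble of mQTL records.
#' @export
read_mqtl_table <- function(path, cis_p = NULL, trans_p = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    cpg = readr::col_character(), snp = readr::col_character(),
    beta = readr::col_double(), maf = readr::col_double(),
    kind = readr::col_character(), p = readr::col_double()
  ), progress = FALSE)
  if (!is.null(cis_p)) tab <- filter(tab, .data$kind != "cis" | .data$p < cis_p)
  if (!is.null(trans_p)) tab <- filter(tab, .data$kind != "trans" | .data$p < trans_p)
  tab
}

#' @rdname read_mqtl_table
#' @param records Tibble of mQTL records.
#' @export
write_mqtl_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a complete methylation dataset from disk
#'
#' @param beta_path Beta matrix TSV.
#' @param dataset_id Dataset label.
#' @param covariates_path Optional covariate TSV.
#' @param detection_p_path Optional detection p-value TSV (same layout as the
#'   Beta matrix).
#' @param tissue,ethnicity Optional labels.
#' @return A [meth_dataset()].
#' @export
read_meth_dataset <- function(beta_path, dataset_id,
                              covariates_path = NULL,
                              detection_p_path = NULL,
                              tissue = NA_character_, ethnicity = NA_character_) {
  beta <- read_beta_matrix(beta_path)
  cov <- if (!is.null(covariates_path)) read_covariates(covariates_path) else NULL
  det <- if (!is.null(detection_p_path)) read_beta_matrix(detection_p_path) else NULL
  meth_dataset(beta, dataset_id = dataset_id, covariates = cov,
               detection_p = det, tissue = tissue, ethnicity = ethnicity)
}

#' Read a fetal multi-tissue study from disk
#'
#' Expects one Beta TSV per tissue slot per group plus an individual mapping;
#' the simplest on-disk layout is the one produced by [write_fetal_study()].
#'
#' @param dir Directory written by [write_fetal_study()].
#' @return A `fetal_study`.
#' @export
read_fetal_study <- function(dir) {
  groups <- list()
  for (g in c("endo_meso", "endo_ecto", "meso_ecto")) {
    ta <- read_beta_matrix(file.path(dir, paste0(g, "_tissueA.tsv")))
    tb <- read_beta_matrix(file.path(dir, paste0(g, "_tissueB.tsv")))
    groups[[g]] <- list(tissue_a = ta, tissue_b = tb, individuals = colnames(ta))
  }
  structure(list(groups = groups, truth = NULL, seed = NA_integer_),
            class = "fetal_study")
}

#' @rdname read_fetal_study
#' @param study A `fetal_study`.
#' @export
write_fetal_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(study$groups)) {
    write_beta_matrix(study$groups[[g]]$tissue_a,
                      file.path(dir, paste0(g, "_tissueA.tsv")))
    write_beta_matrix(study$groups[[g]]$tissue_b,
                      file.path(dir, paste0(g, "_tissueB.tsv")))
  }
  invisible(dir)
}
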