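#' Methylation dataset container
#'
#' Bundles one study's CpG-by-sample Beta matrix with its sample covariates
#' and (optionally) a detection p-value matrix of the same shape. Beta values
#' are proportions in \[0, 1\]; missing values are allowed and propagate
#' through the probe filters.
#'
#' @param beta Numeric matrix, CpGs in rows (rownames = CpG ids), samples in
#'   columns (colnames = sample ids), values in \[0, 1\] or `NA`.
#' @param dataset_id Single string naming the dataset.
#' @param covariates Optional tibble/data frame with columns `sample_id` and
#'   any of `age` (years) and `sex` (`"male"`/`"female"`). Rows are matched to
#'   `colnames(beta)`.
#' @param detection_p Optional numeric matrix aligned to `beta` (same
#'   dimnames) holding per-call detection p-values.
#' @param tissue,ethnicity Optional labels carried through reports.
#'
#' @return An object of class `meth_dataset`.
#' @export
meth_dataset <- function(beta, dataset_id, covariates = NULL,
                         detection_p = NULL, tissue = NA_character_,
                         ethnicity = NA_character_) {
  if (!is.matrix(beta) || !is.numeric(beta)) abort("`beta` must be a numeric matrix.")
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort("`beta` must have CpG rownames and sample colnames.")
  }
  if (anyDuplicated(colnames(beta))) abort("Sample ids must be unique.")
  if (anyDuplicated(rownames(beta))) abort("CpG ids must be unique.")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("Beta values must lie in [0, 1].")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)) ||
        !identical(dimnames(detection_p), dimnames(beta))) {
      abort("`detection_p` must be aligned to `beta` (same dimnames).")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (!"sample_id" %in% names(covariates)) abort("`covariates` needs a `sample_id` column.")
    missing <- setdiff(colnames(beta), covariates$sample_id)
    if (length(missing)) abort("`covariates` missing samples: ", paste(head(missing, 5), collapse = ", "))
    covariates <- covariates[match(colnames(beta), covariates$sample_id), , drop = FALSE]
  }
  structure(
    list(beta = beta, dataset_id = dataset_id, covariates = covariates,
         detection_p = detection_p, tissue = tissue, ethnicity = ethnicity),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(sprintf("<meth_dataset> %s: %d CpGs x %d samples", x$dataset_id,
              nrow(x$beta), ncol(x$beta)))
  if (!is.na(x$tissue)) cat(sprintf(" [%s]", x$tissue))
  cat("\n")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(setdiff(names(x$covariates), "sample_id"), collapse = ", "), "\n")
  }
  if (!is.null(x$detection_p)) cat("  detection p-values present\n")
  invisible(x)
}

#' @export
dim.meth_dataset <- function(x) dim(x$beta)

# Fast internal constructor for generator output whose invariants hold by
# construction (skips the per-cell validation pass).
new_meth_dataset <- function(beta, dataset_id, covariates = NULL,
                             detection_p = NULL, tissue = NA_character_,
                             ethnicity = NA_character_) {
  structure(
    list(beta = beta, dataset_id = dataset_id, covariates = covariates,
         detection_p = detection_p, tissue = tissue, ethnicity = ethnicity),
    class = "meth_dataset"
  )
}
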