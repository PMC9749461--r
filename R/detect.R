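#' Per-CpG Beta variance for one dataset
#'
#' Unbiased sample variance of each probe's Beta values, with missing values
#' excluded probe-wise. Probes with fewer than two observed values get `NA`
#' and are excluded from downstream ranking.
#'
#' @param dataset A (preprocessed) [meth_dataset()].
#' @return Named numeric vector of variances (Beta-squared units).
#' @export
dataset_variances <- function(dataset) {
  stopifnot(inherits(dataset, "meth_dataset"))
  setNames(row_vars(dataset$beta), rownames(dataset$beta))
}

#' Flag the top-variance probes of one dataset
#'
#' A probe is flagged when its variance lies within the top `top_pct` percent
#' of the dataset's retained (non-missing-variance) probes. The cutoff is the
#' `floor(n * top_pct / 100)`-th largest variance, and ties with the cutoff
#' value are all included, so with all-equal variances every probe is flagged.
#'
#' @param variances Named variance vector from [dataset_variances()].
#' @param top_pct Percentage threshold `i`, in (0, 100\] (default 5).
#' @return Named logical vector over the retained probes.
#' @export
top_variance_flags <- function(variances, top_pct = 5) {
  if (!length(variances)) abort("`variances` is empty.")
  if (top_pct <= 0 || top_pct > 100) abort("`top_pct` must be in (0, 100].")
  v <- variances[!is.na(variances)]
  if (!length(v)) abort("No probe has a defined variance.")
  k <- max(1L, floor(length(v) * top_pct / 100 + 1e-9))
  cutoff <- sort(v, decreasing = TRUE)[k]
  setNames(v >= cutoff, names(v))
}

#' Identify hypervariable CpGs across datasets
#'
#' Combines per-dataset top-variance flags: a CpG is called hypervariable
#' (hvCpG) when it is covered (retained after filtering) in at least
#' `min_datasets` datasets and flagged in at least `min_fraction_pct`% of the
#' datasets covering it. Counts are reported for every CpG seen in any
#' dataset; the ids covered in `>= min_datasets` datasets form the array
#' background, attached as the `array_background` attribute.
#'
#' @param flags List of named logical vectors from [top_variance_flags()],
#'   one per dataset; each vector's names define that dataset's retained CpGs.
#' @param min_fraction_pct Threshold `j`: minimum percentage of covering
#'   datasets in which the CpG must be flagged (default 65; the comparison is
#'   `>=`).
#' @param min_datasets Minimum number of covering datasets (default 15).
#' @return A tibble of class `hvcpg_result` with columns `cpg`, `n_covered`,
#'   `n_hypervariable`, `fraction`, `is_hvcpg`.
#' @export
identify_hvcpgs <- function(flags, min_fraction_pct = 65, min_datasets = 15) {
  if (!length(flags)) abort("`flags` is empty.")
  min_datasets <- assert_count(min_datasets, "min_datasets", 1L)
  all_ids <- sort(unique(unlist(lapply(flags, names), use.names = FALSE)))
  n_cov <- integer(length(all_ids))
  n_hv <- integer(length(all_ids))
  names(n_cov) <- names(n_hv) <- all_ids
  for (f in flags) {
    n_cov[names(f)] <- n_cov[names(f)] + 1L
    hit <- names(f)[f]
    n_hv[hit] <- n_hv[hit] + 1L
  }
  frac <- n_hv / n_cov
  res <- tibble(
    cpg = all_ids,
    n_covered = unname(n_cov),
    n_hypervariable = unname(n_hv),
    fraction = unname(frac),
    is_hvcpg = unname(n_cov >= min_datasets & frac >= min_fraction_pct / 100)
  )
  structure(res,
            class = c("hvcpg_result", class(res)),
            params = list(min_fraction_pct = min_fraction_pct,
                          min_datasets = min_datasets,
                          n_datasets = length(flags)),
            array_background = all_ids[n_cov >= min_datasets])
}

#' Extract the called hvCpG ids
#' @param result An `hvcpg_result`.
#' @return Character vector of hvCpG ids.
#' @export
hvcpg_ids <- function(result) {
  stopifnot(inherits(result, "hvcpg_result"))
  result$cpg[result$is_hvcpg]
}

#' Threshold-sensitivity grid of hvCpG counts
#'
#' Recomputes the hvCpG call over a grid of variance-percentage thresholds
#' `i` and dataset-fraction thresholds `j`, returning the count of CpGs
#' called at each `(i, j)`. Counts are non-decreasing in `i` and
#' non-increasing in `j` because the flag sets are nested.
#'
#' @param variances List of named variance vectors (one per dataset).
#' @param i_values Variance-percentage thresholds (default `1:20`).
#' @param j_values Dataset-fraction thresholds in percent
#'   (default `seq(5, 100, by = 5)`).
#' @param min_datasets Coverage threshold (default 15).
#' @return An integer matrix of class `hvcpg_grid` (rows = `i`, columns =
#'   `j`).
#' @export
threshold_grid <- function(variances, i_values = 1:20,
                           j_values = seq(5, 100, by = 5),
                           min_datasets = 15) {
  # per dataset, the descending percentile rank of each retained CpG
  ranks <- lapply(variances, function(v) {
    v <- v[!is.na(v)]
    setNames(rank(-v, ties.method = "max") / length(v), names(v))
  })
  all_ids <- sort(unique(unlist(lapply(ranks, names), use.names = FALSE)))
  n_cov <- integer(length(all_ids))
  names(n_cov) <- all_ids
  for (r in ranks) n_cov[names(r)] <- n_cov[names(r)] + 1L
  eligible <- n_cov >= min_datasets

  grid <- matrix(0L, length(i_values), length(j_values),
                 dimnames = list(i = i_values, j = j_values))
  for (ii in seq_along(i_values)) {
    i <- i_values[ii]
    n_hv <- integer(length(all_ids))
    names(n_hv) <- all_ids
    for (d in seq_along(ranks)) {
      r <- ranks[[d]]
      v <- variances[[d]]
      v <- v[!is.na(v)]
      k <- max(1L, floor(length(v) * i / 100 + 1e-9))
      cutoff <- sort(v, decreasing = TRUE)[k]
      hit <- names(v)[v >= cutoff]
      n_hv[hit] <- n_hv[hit] + 1L
    }
    frac <- n_hv / n_cov
    for (jj in seq_along(j_values)) {
      grid[ii, jj] <- sum(eligible & frac >= j_values[jj] / 100)
    }
  }
  structure(grid, class = c("hvcpg_grid", class(grid)))
}

#' Drop technically unreliable probes from an hvCpG call
#'
#' Removes probes on the unreliable list (e.g. low intra-class correlation in
#' technical-replicate screens) from the called set; coverage counts are kept
#' so the result remains a full report.
#'
#' @param result An `hvcpg_result`.
#' @param unreliable Character vector of unreliable CpG ids.
#' @return The updated `hvcpg_result`; the number of calls removed is in the
#'   `n_unreliable_removed` attribute.
#' @export
apply_reliability_filter <- function(result, unreliable) {
  stopifnot(inherits(result, "hvcpg_result"))
  removed <- sum(result$is_hvcpg & result$cpg %in% unreliable)
  result$is_hvcpg <- result$is_hvcpg & !result$cpg %in% unreliable
  attr(result, "n_unreliable_removed") <- removed
  result
}

#' @export
print.hvcpg_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<hvcpg_result> %d hvCpGs of %d background CpGs (flagged in >= %s%% of >= %d covering datasets)\n",
              sum(x$is_hvcpg), length(attr(x, "array_background")),
              p$min_fraction_pct, p$min_datasets))
  NextMethod()
}
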