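## Matched-control construction and mQTL variance-explained summaries.

# Scaled KS statistic sqrt(nm/(n+m)) * D; the asymptotic two-sided p-value is
# strictly decreasing in this quantity, so ranking candidates by it ascending
# ranks them by p descending.
ks_lambda <- function(d, n, m) sqrt(n * m / (n + m)) * d

#' Distribution-matched control CpGs by Kolmogorov-Smirnov search
#'
#' For each target CpG (processed in sorted-id order), searches the remaining
#' background pool for the probe whose Beta distribution in the reference
#' dataset is least distinguishable by a two-sided KS test, selects it when
#' its KS p-value exceeds `min_p`, and removes it from the pool (matching
#' without replacement, so no control serves two targets). Targets with no
#' qualifying candidate are reported unmatched.
#'
#' The full candidate scan uses a vectorised KS-statistic computation; the
#' exact `stats::ks.test` p-value is then evaluated on the leading candidates
#' (ranked by asymptotic p, which is monotone in the statistic at equal
#' sample sizes) and the candidate with the greatest exact p is selected,
#' ties broken by id.
#'
#' @param hvcpgs Character vector of target CpG ids.
#' @param background Character vector of candidate ids (must exclude the
#'   targets; unreliable probes should already be removed).
#' @param reference_dataset Preprocessed [meth_dataset()] providing the Beta
#'   distributions.
#' @param min_p Minimum acceptable KS p-value (default 0.1).
#' @param n_exact Number of leading candidates on which the exact test is
#'   evaluated (default 20).
#' @return A list of class `control_match`: `matches` tibble
#'   `(hvcpg, control, ks_p)` and `unmatched` character vector.
#' @export
ks_match_controls <- function(hvcpgs, background, reference_dataset,
                              min_p = 0.1, n_exact = 20) {
  stopifnot(inherits(reference_dataset, "meth_dataset"))
  if (!length(background)) abort("`background` is empty.")
  if (length(intersect(hvcpgs, background))) {
    abort("`background` must not contain target CpGs.")
  }
  beta <- reference_dataset$beta
  hv <- sort(intersect(hvcpgs, rownames(beta)))
  pool <- intersect(background, rownames(beta))
  skipped <- setdiff(hvcpgs, hv)
  pool_beta <- beta[pool, , drop = FALSE]
  # presort every candidate once (padded columns, NA dropped)
  pool_n <- as.integer(rowSums(!is.na(pool_beta)))
  pool_sorted <- matrix(Inf, ncol(pool_beta), length(pool))
  for (k in seq_along(pool)) {
    v <- sort(pool_beta[k, ])   # sort() drops NA
    if (length(v)) pool_sorted[seq_along(v), k] <- v
  }
  alive <- rep(TRUE, length(pool))

  matches <- vector("list", length(hv))
  unmatched <- character(0)
  for (i in seq_along(hv)) {
    x <- beta[hv[i], ]
    x <- sort(x[!is.na(x)])
    idx <- which(alive)
    if (!length(idx)) { unmatched <- c(unmatched, hv[i]); next }
    d <- ks_stat_sorted_cpp(x, pool_sorted, pool_n, idx - 1L)
    lambda <- ks_lambda(d, length(x), pool_n[idx])
    ord <- order(lambda, pool[idx])
    top <- head(ord, n_exact)
    best_p <- -1; best_j <- NA_integer_
    for (j in top) {
      y <- pool_beta[idx[j], ]
      p <- suppressWarnings(ks.test(x, y[!is.na(y)])$p.value)
      if (p > best_p + 1e-15) { best_p <- p; best_j <- idx[j] }
    }
    if (!is.na(best_j) && best_p > min_p) {
      matches[[i]] <- tibble(hvcpg = hv[i], control = pool[best_j], ks_p = best_p)
      alive[best_j] <- FALSE
    } else {
      unmatched <- c(unmatched, hv[i])
    }
  }
  structure(list(matches = bind_rows(matches),
                 unmatched = sort(c(unmatched, skipped)),
                 min_p = min_p),
            class = "control_match")
}

#' @export
print.control_match <- function(x, ...) {
  cat(sprintf("<control_match> %d matched, %d unmatched\n",
              nrow(x$matches), length(x$unmatched)))
  invisible(x)
}

#' Methylation variance explained by one mQTL
#'
#' `2 * beta^2 * maf * (1 - maf)` — the variance of an additive per-allele
#' effect `beta` at a Hardy-Weinberg locus with minor allele frequency `maf`.
#' Interpreting the result as a *fraction* of methylation variance assumes
#' `beta` is on the standardized-methylation scale.
#'
#' @param beta Per-allele effect size(s).
#' @param maf Minor allele frequency(ies) in (0, 0.5\].
#' @return Numeric vector of variance-explained values.
#' @export
mqtl_variance_explained <- function(beta, maf) {
  if (any(is.na(maf)) || any(maf <= 0 | maf > 0.5)) {
    abort("`maf` must lie in (0, 0.5].")
  }
  2 * beta^2 * maf * (1 - maf)
}

#' Per-CpG mean variance explained across its mQTLs
#'
#' @param records Tibble of mQTL records with columns `cpg`, `beta`, `maf`.
#' @return Tibble `(cpg, n_assoc, mean_var_explained)`.
#' @export
mean_variance_explained <- function(records) {
  stopifnot(all(c("cpg", "beta", "maf") %in% names(records)))
  records |>
    mutate(ve = mqtl_variance_explained(.data$beta, .data$maf)) |>
    group_by(.data$cpg) |>
    summarise(n_assoc = n(), mean_var_explained = mean(.data$ve), .groups = "drop")
}

#' mQTL-matched control CpGs
#'
#' Matches each target CpG (in sorted-id order, without replacement) to a
#' candidate with (i) exactly the same number of mQTL associations, (ii) the
#' nearest mean variance explained within `tolerance`, and (iii) coverage in
#' at least as many datasets as the target.
#'
#' @param hvcpgs Character vector of target ids.
#' @param mqtl_summary Tibble with columns `cpg`, `n_assoc`,
#'   `mean_var_explained`, `n_datasets_covered`, covering both targets and
#'   candidates.
#' @param tolerance Maximum allowed |difference| in mean variance explained
#'   (default 0.005).
#' @return A `control_match` (as for [ks_match_controls()], with `delta_ve`
#'   instead of `ks_p`).
#' @export
mqtl_match_controls <- function(hvcpgs, mqtl_summary, tolerance = 0.005) {
  need <- c("cpg", "n_assoc", "mean_var_explained", "n_datasets_covered")
  stopifnot(all(need %in% names(mqtl_summary)))
  hv <- sort(intersect(hvcpgs, mqtl_summary$cpg))
  skipped <- setdiff(hvcpgs, hv)
  cand <- mqtl_summary |>
    filter(!.data$cpg %in% hvcpgs) |>
    arrange(.data$cpg)
  alive <- rep(TRUE, nrow(cand))
  s <- mqtl_summary[match(hv, mqtl_summary$cpg), ]
  matches <- vector("list", length(hv))
  unmatched <- character(0)
  for (i in seq_along(hv)) {
    ok <- alive &
      cand$n_assoc == s$n_assoc[i] &
      cand$n_datasets_covered >= s$n_datasets_covered[i]
    if (!any(ok)) { unmatched <- c(unmatched, hv[i]); next }
    delta <- abs(cand$mean_var_explained - s$mean_var_explained[i])
    delta[!ok] <- Inf
    j <- which.min(delta)
    if (delta[j] <= tolerance) {
      matches[[i]] <- tibble(hvcpg = hv[i], control = cand$cpg[j], delta_ve = delta[j])
      alive[j] <- FALSE
    } else {
      unmatched <- c(unmatched, hv[i])
    }
  }
  structure(list(matches = bind_rows(matches),
                 unmatched = sort(c(unmatched, skipped)),
                 tolerance = tolerance),
            class = "control_match")
}
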