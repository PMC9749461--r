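#' Mean inter-germ-layer correlation per CpG
#'
#' For each CpG, computes the Pearson correlation between the two tissues'
#' Beta values across the individuals of each germ-layer-pair group, then
#' averages the three group correlations with equal weight. Groups where the
#' correlation is undefined (zero variance in either tissue, or fewer than 3
#' individuals with complete data) are excluded from the average and counted.
#'
#' @param study A `fetal_study` from [simulate_fetal_multitissue()] or
#'   [read_fetal_study()].
#' @param cpgs Optional character vector restricting the CpGs (default: all).
#' @return A tibble `(cpg, mean_r, n_groups)`; `mean_r` is `NA` when all
#'   three groups were undefined.
#' @export
inter_germlayer_correlation <- function(study, cpgs = NULL) {
  stopifnot(inherits(study, "fetal_study"))
  ids <- rownames(study$groups[[1]]$tissue_a)
  if (!is.null(cpgs)) ids <- intersect(ids, cpgs)
  rs <- vapply(study$groups, function(g) {
    row_cors(g$tissue_a[ids, , drop = FALSE], g$tissue_b[ids, , drop = FALSE])
  }, numeric(length(ids)))
  if (is.null(dim(rs))) rs <- matrix(rs, nrow = 1)
  n_groups <- rowSums(!is.na(rs))
  tibble(cpg = ids,
         mean_r = ifelse(n_groups > 0, rowMeans(rs, na.rm = TRUE), NA_real_),
         n_groups = as.integer(n_groups))
}

#' Interindividual variation across tissues
#'
#' For every individual, takes the mean of the two tissue Beta values at each
#' CpG; the CpG's interindividual variation is the range (max minus min) of
#' these per-individual means over all available individuals.
#'
#' @inheritParams inter_germlayer_correlation
#' @return A tibble `(cpg, range, n_individuals)`.
#' @export
interindividual_variation <- function(study, cpgs = NULL) {
  stopifnot(inherits(study, "fetal_study"))
  ids <- rownames(study$groups[[1]]$tissue_a)
  if (!is.null(cpgs)) ids <- intersect(ids, cpgs)
  means <- do.call(cbind, lapply(study$groups, function(g) {
    (g$tissue_a[ids, , drop = FALSE] + g$tissue_b[ids, , drop = FALSE]) / 2
  }))
  rng <- apply(means, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    max(v) - min(v)
  })
  tibble(cpg = ids, range = unname(rng), n_individuals = ncol(means))
}

#' Predicate defining systemic interindividual variation (SIV)
#'
#' @param range_threshold Minimum range of per-individual cross-tissue mean
#'   Beta values (default 0.2).
#' @param corr_threshold Optional minimum pairwise inter-tissue Pearson
#'   correlation; `NULL` disables the correlation component. The published
#'   SIV screens' correlation component is not fixed here, so it is supplied
#'   by the user.
#' @param require_all_pairs When a correlation threshold is set, require it
#'   of every tissue pair (`TRUE`, default) or only of the pairwise average.
#' @return A list of class `siv_predicate_spec`.
#' @export
siv_predicate_spec <- function(range_threshold = 0.2, corr_threshold = NULL,
                               require_all_pairs = TRUE) {
  if (range_threshold < 0) abort("`range_threshold` must be >= 0.")
  structure(list(range_threshold = range_threshold,
                 corr_threshold = corr_threshold,
                 require_all_pairs = isTRUE(require_all_pairs)),
            class = "siv_predicate_spec")
}

#' Evaluate the SIV predicate on one sampled cohort
#'
#' @param sample Numeric matrix, individuals in rows and tissues in columns
#'   (Beta values).
#' @param predicate A [siv_predicate_spec()].
#' @return `TRUE`/`FALSE`. When a correlation threshold is set and any tissue
#'   has zero variance, the predicate is `FALSE` (attribute
#'   `degenerate = TRUE`).
#' @export
siv_predicate <- function(sample, predicate = siv_predicate_spec()) {
  stopifnot(is.matrix(sample), nrow(sample) >= 2)
  rng <- diff(range(rowMeans(sample)))
  ok <- rng >= predicate$range_threshold
  if (!is.null(predicate$corr_threshold)) {
    sds <- apply(sample, 2, sd)
    if (any(sds == 0)) {
      out <- FALSE
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    cm <- cor(sample)
    rs <- cm[upper.tri(cm)]
    corr_ok <- if (predicate$require_all_pairs) all(rs >= predicate$corr_threshold)
               else mean(rs) >= predicate$corr_threshold
    ok <- ok && corr_ok
  }
  ok
}

#' Power to detect SIV by multivariate-normal simulation
#'
#' For each CpG, repeatedly draws `n_individuals` independent tissue triplets
#' from a multivariate normal with the CpG's tissue mean vector and
#' cross-tissue covariance, clips the draws to the Beta domain \[0, 1\]
#' (disable with `clip = FALSE` for oracle comparisons), evaluates the SIV
#' predicate, and reports the passing fraction as the power estimate with its
#' Monte-Carlo standard error `sqrt(p * (1 - p) / n_reps)`.
#'
#' Covariance matrices are repaired to positive semidefinite by clipping
#' negative eigenvalues at zero when they exceed `-psd_tol`; more negative
#' eigenvalues raise an error.
#'
#' @param mu List of (or single) length-3 tissue mean vectors, or a CpG x 3
#'   matrix.
#' @param sigma List of (or single) 3 x 3 covariance matrices.
#' @param n_individuals Simulated cohort size per replicate (default 4).
#' @param n_reps Number of replicates (default 1000).
#' @param predicate A [siv_predicate_spec()].
#' @param seed Integer seed.
#' @param clip Clip draws to \[0, 1\] (default `TRUE`).
#' @param psd_tol Tolerance for negative eigenvalues (default 1e-10).
#' @param cpg Optional CpG ids for the output.
#' @return A tibble of class `siv_power` with columns `cpg`, `power`, `se`.
#' @export
siv_power <- function(mu, sigma, n_individuals = 4, n_reps = 1000,
                      predicate = siv_predicate_spec(), seed = 1L,
                      clip = TRUE, psd_tol = 1e-10, cpg = NULL) {
  if (is.matrix(mu)) mu <- asplit(mu, 1)
  if (is.numeric(mu) && !is.list(mu)) mu <- list(mu)
  if (is.matrix(sigma) && !is.list(sigma)) sigma <- list(sigma)
  if (length(sigma) == 1) sigma <- rep(sigma, length(mu))
  stopifnot(length(mu) == length(sigma))
  n_individuals <- assert_count(n_individuals, "n_individuals", 2L)
  n_reps <- assert_count(n_reps, "n_reps", 1L)
  if (is.null(cpg)) cpg <- cpg_ids(length(mu))

  set.seed(seed)
  power <- numeric(length(mu))
  for (i in seq_along(mu)) {
    m <- as.numeric(mu[[i]])
    s <- as.matrix(sigma[[i]])
    stopifnot(length(m) == ncol(s), nrow(s) == ncol(s))
    s <- (s + t(s)) / 2
    ev <- eigen(s, symmetric = TRUE)
    if (min(ev$values) < -psd_tol * max(1, abs(max(ev$values)))) {
      abort(sprintf("Covariance for CpG %s is not positive semidefinite.", cpg[i]))
    }
    vals <- pmax(ev$values, 0)
    rt <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))   # symmetric square root
    z <- matrix(rnorm(n_individuals * n_reps * length(m)), ncol = length(m))
    draws <- z %*% rt
    draws <- sweep(draws, 2, m, "+")
    if (clip) draws <- pmin(pmax(draws, 0), 1)
    ind_means <- rowMeans(draws)
    rep_idx <- rep(seq_len(n_reps), each = n_individuals)
    if (is.null(predicate$corr_threshold)) {
      rng <- tapply(ind_means, rep_idx, function(v) max(v) - min(v))
      power[i] <- mean(rng >= predicate$range_threshold)
    } else {
      pass <- vapply(seq_len(n_reps), function(r) {
        isTRUE(siv_predicate(draws[rep_idx == r, , drop = FALSE], predicate))
      }, logical(1))
      power[i] <- mean(pass)
    }
  }
  res <- tibble(cpg = cpg, power = power,
                se = sqrt(power * (1 - power) / n_reps))
  structure(res, class = c("siv_power", class(res)),
            params = list(n_individuals = n_individuals, n_reps = n_reps,
                          predicate = predicate, clip = clip, seed = seed))
}

#' Estimate per-CpG tissue means and cross-tissue covariance from samples
#'
#' Builds the inputs for [siv_power()] from an individuals x tissues Beta
#' matrix per CpG, using the unbiased covariance estimator.
#'
#' @param beta_by_tissue List (per CpG) of individuals x 3 Beta matrices, or
#'   a single such matrix.
#' @return A list with `mu` and `sigma` lists aligned by CpG.
#' @export
estimate_power_inputs <- function(beta_by_tissue) {
  if (is.matrix(beta_by_tissue)) beta_by_tissue <- list(beta_by_tissue)
  mu <- lapply(beta_by_tissue, colMeans)
  sigma <- lapply(beta_by_tissue, stats::cov)
  list(mu = mu, sigma = sigma)
}
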