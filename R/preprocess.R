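#' Probe filtering rules
#'
#' @param detection_p_threshold Detection p-value above which a call is
#'   considered failed (default 0.01).
#' @param detection_sample_fraction A probe is removed when more than this
#'   fraction of its samples fail detection (default 0.05). The detection
#'   filter is skipped when the dataset carries no detection p-values.
#' @param multimap_list,xy_list,snp_list Character vectors of CpG ids to
#'   exclude (multi-mapping probes, X/Y probes, SNP-affected probes). May be
#'   empty.
#' @param drop_any_missing Remove a probe that has a missing Beta in any
#'   sample of the dataset (default `TRUE`).
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(detection_p_threshold = 0.01,
                         detection_sample_fraction = 0.05,
                         multimap_list = character(),
                         xy_list = character(),
                         snp_list = character(),
                         drop_any_missing = TRUE) {
  assert_fraction(detection_p_threshold, "detection_p_threshold", 0, 1, TRUE, TRUE)
  assert_fraction(detection_sample_fraction, "detection_sample_fraction", 0, 1, TRUE, TRUE)
  structure(list(detection_p_threshold = detection_p_threshold,
                 detection_sample_fraction = detection_sample_fraction,
                 multimap_list = as.character(multimap_list),
                 xy_list = as.character(xy_list),
                 snp_list = as.character(snp_list),
                 drop_any_missing = isTRUE(drop_any_missing)),
            class = "filter_rules")
}

#' Apply probe filters to one dataset
#'
#' Removes probes failing any rule: detection p-value above threshold in more
#' than the allowed fraction of samples (only when detection p-values are
#' present), membership in any exclusion list, or a missing Beta value in any
#' sample (when `drop_any_missing`). The sample axis is untouched. Applying
#' the same rules twice is a no-op.
#'
#' @param dataset A [meth_dataset()].
#' @param rules A [filter_rules()].
#' @return The filtered `meth_dataset`; the per-rule removal counts are
#'   attached as the `filter_report` attribute (a tibble).
#' @export
filter_probes <- function(dataset, rules = filter_rules()) {
  stopifnot(inherits(dataset, "meth_dataset"), inherits(rules, "filter_rules"))
  beta <- dataset$beta
  ids <- rownames(beta)
  drop_detect <- rep(FALSE, nrow(beta))
  if (!is.null(dataset$detection_p)) {
    frac_fail <- rowMeans(dataset$detection_p > rules$detection_p_threshold, na.rm = TRUE)
    drop_detect <- frac_fail > rules$detection_sample_fraction
  }
  drop_list <- ids %in% c(rules$multimap_list, rules$xy_list, rules$snp_list)
  drop_missing <- if (rules$drop_any_missing) rowSums(is.na(beta)) > 0 else rep(FALSE, nrow(beta))
  keep <- !(drop_detect | drop_list | drop_missing)

  report <- tibble(
    rule = c("detection_p", "exclusion_list", "missing_value", "retained"),
    n = c(sum(drop_detect), sum(drop_list & !drop_detect),
          sum(drop_missing & !drop_detect & !drop_list), sum(keep))
  )
  out <- dataset
  out$beta <- beta[keep, , drop = FALSE]
  if (!is.null(dataset$detection_p)) {
    out$detection_p <- dataset$detection_p[keep, , drop = FALSE]
  }
  attr(out, "filter_report") <- report
  out
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`. Values at exactly 0 or 1 are clamped to
#' `eps`/`1 - eps` first so the logit is finite; the number of clamped values
#' is attached as the `n_clamped` attribute.
#'
#' @param beta Numeric vector/matrix of Beta values in \[0, 1\].
#' @param eps Clamping bound (default 1e-6).
#' @return M-values with the shape of `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  n_clamped <- sum(beta <= 0 | beta >= 1, na.rm = TRUE)
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(m) <- dim(beta)
  dimnames(m) <- dimnames(beta)
  attr(m, "n_clamped") <- n_clamped
  m
}

#' M-value to Beta back-transform
#'
#' The default `"base2"` mode inverts [beta_to_m()] exactly:
#' `2^M / (1 + 2^M)`. Mode `"natural"` applies the natural-exponential form
#' `exp(M) / (1 + exp(M))` instead; the two differ because the logit is base 2
#' while the natural form is base e, and only the base-2 mode round-trips.
#'
#' @param m Numeric vector/matrix of M-values.
#' @param mode `"base2"` (default) or `"natural"`.
#' @return Beta values strictly inside (0, 1).
#' @export
m_to_beta <- function(m, mode = c("base2", "natural")) {
  mode <- match.arg(mode)
  out <- if (mode == "base2") plogis(m * log(2)) else plogis(m)
  dimnames(out) <- dimnames(m)
  attr(out, "n_clamped") <- NULL
  out
}

#' Adjustment specification for principal-component / covariate regression
#'
#' @param n_pcs Number of principal components of the M-value matrix to
#'   regress out (default 10; must be smaller than the sample count).
#' @param use_age,use_sex Include age/sex as regressors when available and
#'   non-constant.
#' @param add_back_fitted_mean Add each CpG's fitted intercept back onto its
#'   residuals before the back-transform, preserving the methylation level
#'   (default `TRUE`).
#' @param back_transform Back-transform mode passed to [m_to_beta()].
#' @return A list of class `adjustment_spec`.
#' @export
adjustment_spec <- function(n_pcs = 10, use_age = TRUE, use_sex = TRUE,
                            add_back_fitted_mean = TRUE,
                            back_transform = c("base2", "natural")) {
  structure(list(n_pcs = assert_count(n_pcs, "n_pcs"),
                 use_age = isTRUE(use_age), use_sex = isTRUE(use_sex),
                 add_back_fitted_mean = isTRUE(add_back_fitted_mean),
                 back_transform = match.arg(back_transform)),
            class = "adjustment_spec")
}

#' Residual-adjust a dataset for principal components, age and sex
#'
#' Transforms Beta to M-values, computes the sample scores of the first
#' `n_pcs` principal components of the centred M matrix (samples as
#' observations), regresses each CpG's M-values on those scores plus age and
#' sex in a single linear model, and back-transforms the residuals (plus the
#' CpG's fitted intercept, by default) to Beta. Constant covariates are
#' dropped with a warning. Requires complete Beta values — run
#' [filter_probes()] with `drop_any_missing = TRUE` first.
#'
#' @param dataset A [meth_dataset()] without missing Beta values.
#' @param spec An [adjustment_spec()].
#' @return The adjusted `meth_dataset`; the regressors used are recorded in
#'   the `adjustment_report` attribute.
#' @export
adjust_covariates <- function(dataset, spec = adjustment_spec()) {
  stopifnot(inherits(dataset, "meth_dataset"), inherits(spec, "adjustment_spec"))
  beta <- dataset$beta
  if (anyNA(beta)) abort("`adjust_covariates()` requires complete Beta values; filter missing probes first.")
  ns <- ncol(beta)
  if (spec$n_pcs >= ns) abort("`n_pcs` must be smaller than the number of samples.")
  m <- beta_to_m(beta)
  mt <- t(m)                                   # samples x CpGs

  terms <- "(intercept)"
  x <- matrix(1, ns, 1)
  if (spec$n_pcs > 0) {
    pca <- prcomp(mt, center = TRUE, scale. = FALSE)
    k <- min(spec$n_pcs, ncol(pca$x))
    x <- cbind(x, pca$x[, seq_len(k), drop = FALSE])
    terms <- c(terms, paste0("PC", seq_len(k)))
  }
  cov <- dataset$covariates
  add_covariate <- function(x, v, label) {
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(sprintf("Covariate `%s` is constant; dropped from the adjustment.", label))
      return(x)
    }
    if (anyNA(v)) {
      warn(sprintf("Covariate `%s` has missing values; dropped from the adjustment.", label))
      return(x)
    }
    terms <<- c(terms, label)
    cbind(x, v)
  }
  if (spec$use_age && !is.null(cov) && "age" %in% names(cov)) {
    x <- add_covariate(x, as.numeric(cov$age), "age")
  }
  if (spec$use_sex && !is.null(cov) && "sex" %in% names(cov)) {
    x <- add_covariate(x, as.numeric(factor(cov$sex)), "sex")
  }

  qx <- qr(x)
  coefs <- qr.coef(qx, mt)
  resid <- qr.resid(qx, mt)
  adj_m <- t(resid)
  if (spec$add_back_fitted_mean) adj_m <- adj_m + coefs[1, ]
  out <- dataset
  out$beta <- m_to_beta(adj_m, mode = spec$back_transform)
  attr(out, "adjustment_report") <- tibble(term = terms)
  out
}

#' Tukey outer-fence outlier mask
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]`, where Q1/Q3 are the
#' 25th/75th percentiles by linear-interpolation quantiles and
#' `IQR = Q3 - Q1`. The default `k = 3` gives Tukey's outer fences. Missing
#' values are never flagged.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @param k Fence multiplier (default 3).
#' @return Logical vector: `TRUE` marks an outlier.
#' @export
tukey_outlier_mask <- function(values, k = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 4) abort("`values` needs at least 4 non-missing entries.")
  if (k <= 0) abort("`k` must be positive.")
  q <- quantile(values[ok], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  mask <- values < q[1] - k * iqr | values > q[2] + k * iqr
  mask[is.na(mask)] <- FALSE
  mask
}

#' Remove per-probe outlier Beta values
#'
#' Applies [tukey_outlier_mask()] to every probe and sets flagged values to
#' missing. Probes with fewer than 4 observed values are left untouched.
#'
#' @param dataset A [meth_dataset()].
#' @param k Fence multiplier (default 3, Tukey's outer fences).
#' @return The dataset with outliers set to `NA`; the number of masked values
#'   is in the `n_outliers_removed` attribute.
#' @export
remove_outliers <- function(dataset, k = 3) {
  stopifnot(inherits(dataset, "meth_dataset"))
  beta <- dataset$beta
  n_masked <- 0L
  for (i in seq_len(nrow(beta))) {
    v <- beta[i, ]
    if (sum(!is.na(v)) < 4) next
    mask <- tukey_outlier_mask(v, k = k)
    if (any(mask)) {
      beta[i, mask] <- NA_real_
      n_masked <- n_masked + sum(mask)
    }
  }
  out <- dataset
  out$beta <- beta
  attr(out, "n_outliers_removed") <- n_masked
  out
}

#' Run the full per-dataset preprocessing chain
#'
#' Convenience wrapper: [filter_probes()], [adjust_covariates()], then
#' [remove_outliers()], in the order the variance analysis expects.
#'
#' @inheritParams filter_probes
#' @inheritParams adjust_covariates
#' @param tukey_k Outer-fence multiplier (default 3).
#' @return The preprocessed `meth_dataset` with the stage reports attached.
#' @export
preprocess_dataset <- function(dataset, rules = filter_rules(),
                               spec = adjustment_spec(), tukey_k = 3) {
  filtered <- filter_probes(dataset, rules)
  adjusted <- adjust_covariates(filtered, spec)
  out <- remove_outliers(adjusted, k = tukey_k)
  attr(out, "filter_report") <- attr(filtered, "filter_report")
  attr(out, "adjustment_report") <- attr(adjusted, "adjustment_report")
  out
}
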