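#' Fisher's-exact set enrichment of a target versus a comparator
#'
#' Builds the 2x2 table (rows target/comparator, columns in-feature/not),
#' computes the two-sided Fisher's exact p-value and the conditional-MLE odds
#' ratio from [stats::fisher.test()], alongside the sample (cross-product)
#' odds ratio with a Haldane-Anscombe 0.5 correction when a zero cell occurs,
#' and the fold enrichment as the ratio of in-feature proportions.
#'
#' @param target,comparator Disjoint character vectors of CpG ids.
#' @param feature Character vector of ids defining the feature set.
#' @param B Bootstrap replicates for a percentile CI on the sample odds ratio
#'   (resampling CpGs within each of target and comparator); `0` (default)
#'   skips the CI.
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble of class `enrichment_result` with the table
#'   counts, `odds_ratio` (conditional MLE), `sample_or`, `fold`, `p`,
#'   `ci_low`, `ci_high`.
#' @export
fisher_enrichment <- function(target, comparator, feature, B = 0, seed = 1L) {
  if (!length(target)) abort("`target` is empty.")
  if (!length(comparator)) abort("`comparator` is empty.")
  if (length(intersect(target, comparator))) {
    abort("`target` and `comparator` must be disjoint.")
  }
  tab <- enrichment_table(target, comparator, feature)
  enrichment_from_table(tab, B = B, seed = seed,
                        target = target, comparator = comparator,
                        feature = feature)
}

enrichment_table <- function(target, comparator, feature) {
  a <- sum(target %in% feature)
  c_ <- sum(comparator %in% feature)
  matrix(c(a, length(target) - a, c_, length(comparator) - c_),
         2, 2, byrow = TRUE,
         dimnames = list(set = c("target", "comparator"),
                         feature = c("in", "out")))
}

enrichment_from_table <- function(tab, B = 0, seed = 1L,
                                  target = NULL, comparator = NULL,
                                  feature = NULL) {
  ft <- fisher.test(tab)
  sample_or <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) / ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  p_t <- tab[1, 1] / sum(tab[1, ])
  p_c <- tab[2, 1] / sum(tab[2, ])
  fold <- if (p_c > 0) p_t / p_c else Inf
  ci <- c(NA_real_, NA_real_)
  if (B > 0 && !is.null(target)) {
    stat <- function(ids_t, ids_c) {
      tt <- enrichment_table(ids_t, ids_c, feature)
      ((tt[1, 1] + 0.5) * (tt[2, 2] + 0.5)) / ((tt[1, 2] + 0.5) * (tt[2, 1] + 0.5))
    }
    set.seed(seed)
    reps <- vapply(seq_len(B), function(b) {
      stat(sample(target, length(target), replace = TRUE),
           sample(comparator, length(comparator), replace = TRUE))
    }, numeric(1))
    ci <- unname(quantile(reps, c(0.025, 0.975), names = FALSE))
  }
  res <- tibble(
    n_target_in = tab[1, 1], n_target_out = tab[1, 2],
    n_comparator_in = tab[2, 1], n_comparator_out = tab[2, 2],
    odds_ratio = unname(ft$estimate), sample_or = sample_or,
    fold = fold, p = ft$p.value, ci_low = ci[1], ci_high = ci[2]
  )
  structure(res, class = c("enrichment_result", class(res)), table = tab)
}

#' Interval-proximity enrichment at multiple distance thresholds
#'
#' A CpG is proximal at threshold `x` when its position lies within `x` bp of
#' any interval (distance 0 inside an interval). Distances are computed
#' between the 1-based CpG position and 0-based half-open BED intervals.
#' Returns the proximity proportions in target and comparator plus
#' [fisher_enrichment()] at each threshold; proportions are non-decreasing in
#' the threshold.
#'
#' @param cpgs,comparator Disjoint CpG-id sets.
#' @param annotation Probe annotation tibble (`cpg`, `chrom`, `pos`,
#'   1-based).
#' @param intervals Tibble `(chrom, start, end)` in BED convention (0-based,
#'   half-open), e.g. from [read_bed()] or [simulate_annotation_tracks()].
#' @param distances Numeric vector of distance thresholds in bp.
#' @return A tibble: one row per threshold with `distance_bp`, `prop_target`,
#'   `prop_comparator` and the `enrichment_result` columns.
#' @export
proximity_enrichment <- function(cpgs, comparator, annotation, intervals,
                                 distances = c(0, 1000, 5000, 10000)) {
  ids <- union(cpgs, comparator)
  ann <- annotation[match(ids, annotation$cpg), ]
  if (anyNA(ann$cpg)) abort("Some CpGs are missing from the annotation.")
  if (nrow(intervals)) {
    missing_chr <- setdiff(intervals$chrom, unique(annotation$chrom))
    if (length(missing_chr)) {
      abort(paste0("Interval chromosomes absent from the annotation: ",
                   paste(head(missing_chr, 5), collapse = ", ")))
    }
  }
  d <- cpg_interval_distance(ann, intervals)
  names(d) <- ann$cpg
  out <- map(distances, function(x) {
    feature <- names(d)[!is.na(d) & d <= x]
    res <- fisher_enrichment(cpgs, comparator, feature)
    mutate(as_tibble(res),
           distance_bp = x,
           prop_target = .data$n_target_in / (.data$n_target_in + .data$n_target_out),
           prop_comparator = .data$n_comparator_in /
             (.data$n_comparator_in + .data$n_comparator_out),
           .before = 1)
  })
  bind_rows(out)
}

# Distance from each annotated CpG (1-based pos) to its nearest interval
# (0-based half-open); 0 inside an interval, NA when there are no intervals.
cpg_interval_distance <- function(ann, intervals) {
  if (!nrow(intervals)) return(rep(NA_real_, nrow(ann)))
  cpg_gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$pos, ann$pos))
  iv_gr <- GenomicRanges::GRanges(intervals$chrom,
                                  IRanges::IRanges(intervals$start + 1, intervals$end))
  d <- rep(NA_real_, nrow(ann))
  hits <- GenomicRanges::distanceToNearest(cpg_gr, iv_gr)
  idx <- S4Vectors::queryHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  # GRanges gap distance counts positions strictly between the ranges;
  # the bp distance used here is gap + 1 outside, 0 on/inside an interval.
  inside <- GenomicRanges::countOverlaps(cpg_gr, iv_gr) > 0
  d[idx] <- ifelse(inside[idx], 0, gap + 1)
  d
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the units of `data` (vector elements, or rows of a data frame)
#' with replacement `B` times, evaluates `statistic` on each resample, and
#' returns the percentile interval. A constant statistic yields a zero-width
#' interval (flagged via the `degenerate` attribute).
#'
#' @param statistic Function of one resample.
#' @param data Vector or data frame of analysis units (typically CpGs).
#' @param B Number of bootstrap resamples (default 1000; at least 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, level = 0.95, seed = 1L) {
  B <- assert_count(B, "B", 100L)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    as.numeric(statistic(take(sample.int(n, n, replace = TRUE))))
  }, numeric(1))
  alpha <- (1 - level) / 2
  out <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  out <- setNames(out, c("low", "high"))
  if (isTRUE(all.equal(out[["low"]], out[["high"]]))) attr(out, "degenerate") <- TRUE
  out
}

#' Sex-split stability of hypervariability flags
#'
#' Splits each qualifying dataset (both sexes present, near-balanced, more
#' than `min_n` samples) into male-only and female-only sub-datasets,
#' recomputes the top-variance flags in each, and reports the proportion of
#' the given hvCpGs flagged in at least one sub-dataset. CpGs whose pooled
#' bimodality is purely sex-driven lose their flag in both sub-datasets.
#'
#' @param datasets List of [meth_dataset()] objects with a `sex` covariate.
#' @param hvcpgs Character vector of hvCpG ids.
#' @param min_n Minimum dataset size (default 80; the comparison is `>`).
#' @param top_pct Variance percentage used for the flags (default 5).
#' @param balance_min Minimum sex proportion for "approximately equal"
#'   (default 0.4).
#' @return A list: `proportion` (of hvCpGs covered by >= 1 qualifying
#'   sub-dataset that are flagged in >= 1), `detail` tibble per dataset, and
#'   `n_qualifying`.
#' @export
sex_split_stability <- function(datasets, hvcpgs, min_n = 80, top_pct = 5,
                                balance_min = 0.4) {
  if (!length(hvcpgs)) {
    return(list(proportion = NA_real_, detail = tibble(), n_qualifying = 0L))
  }
  flagged <- character(0)
  covered <- character(0)
  detail <- list()
  n_q <- 0L
  for (d in datasets) {
    cov <- d$covariates
    if (is.null(cov) || !"sex" %in% names(cov)) next
    sexes <- cov$sex
    n <- ncol(d$beta)
    prop_m <- mean(sexes == "male", na.rm = TRUE)
    if (n <= min_n || min(prop_m, 1 - prop_m) < balance_min) next
    n_q <- n_q + 1L
    hits <- character(0)
    for (sx in c("male", "female")) {
      sub <- d$beta[, which(sexes == sx), drop = FALSE]
      v <- row_vars(sub)
      names(v) <- rownames(sub)
      fl <- top_variance_flags(v, top_pct)
      hits <- union(hits, names(fl)[fl])
    }
    covered <- union(covered, rownames(d$beta))
    flagged <- union(flagged, hits)
    detail[[length(detail) + 1L]] <- tibble(
      dataset_id = d$dataset_id, n_samples = n,
      n_hv_flagged = sum(hvcpgs %in% hits),
      n_hv_covered = sum(hvcpgs %in% rownames(d$beta))
    )
  }
  if (n_q == 0L) abort("No dataset qualifies for the sex-split check.")
  hv_cov <- intersect(hvcpgs, covered)
  prop <- if (length(hv_cov)) mean(hv_cov %in% flagged) else NA_real_
  list(proportion = prop, detail = bind_rows(detail), n_qualifying = n_q)
}

#' Enrichment report over published CpG sets
#'
#' Restricts each published set to the array background (when given), drops
#' sets overlapping fewer than `trait_min_fraction` of the target, computes
#' [fisher_enrichment()] of target versus comparator for the remainder, and
#' appends Benjamini-Hochberg q-values across the tested sets.
#'
#' @param target Character vector of target CpG ids.
#' @param published_sets Named list of CpG-id vectors.
#' @param comparator Character vector of comparator ids (disjoint from
#'   target).
#' @param trait_min_fraction Minimum overlap fraction of the target required
#'   to test a set (default 0.01).
#' @param background Optional array-background ids the published sets are
#'   intersected with first.
#' @return A tibble with one row per tested set (`set`, overlap counts, the
#'   enrichment columns, `q`).
#' @export
set_overlap_report <- function(target, published_sets, comparator,
                               trait_min_fraction = 0.01, background = NULL) {
  stopifnot(is.list(published_sets), !is.null(names(published_sets)))
  rows <- imap(published_sets, function(ids, nm) {
    if (!is.null(background)) ids <- intersect(ids, background)
    frac <- mean(target %in% ids)
    if (frac < trait_min_fraction) return(NULL)
    res <- fisher_enrichment(target, comparator, ids)
    mutate(as_tibble(res), set = nm, target_overlap_fraction = frac, .before = 1)
  })
  out <- bind_rows(rows)
  if (nrow(out)) out$q <- p.adjust(out$p, method = "BH")
  out
}
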