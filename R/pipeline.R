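#' Run the hvCpG discovery pipeline end to end
#'
#' Chains the stages in the order the method prescribes: per-dataset probe
#' filtering, principal-component/covariate adjustment, outer-fence outlier
#' removal, per-dataset Beta variance, the cross-dataset top-variance
#' intersection call, reliability filtering, distribution-matched control
#' selection, and gap-based clustering with de-clustering. All outputs are
#' written as plain-text files into `out_dir` together with a JSON manifest
#' recording the parameters, seed and output file hashes; re-running with an
#' identical configuration reproduces identical files.
#'
#' @param datasets List of [meth_dataset()] objects.
#' @param annotation Probe annotation tibble (`cpg`, `chrom`, `pos`,
#'   `reliable`).
#' @param out_dir Output directory (created if needed).
#' @param rules [filter_rules()] applied to every dataset.
#' @param spec [adjustment_spec()] applied to every dataset.
#' @param top_pct,min_fraction_pct,min_datasets hvCpG thresholds (defaults
#'   5, 65, 15).
#' @param tukey_k Outer-fence multiplier (default 3).
#' @param gap Cluster gap in bp (default 4000).
#' @param ks_min_p Minimum KS p-value for distribution matching (default
#'   0.1).
#' @param reference_dataset_id Dataset used for distribution matching
#'   (default: the largest preprocessed dataset).
#' @param seed Seed for the de-clustering draw.
#' @param adjust Run the adjustment stage (`TRUE` by default; turn off for
#'   pre-adjusted input).
#' @return A list with the in-memory stage results (`result`, `controls`,
#'   `clusters`, `declustered`, `variances`, `manifest`), invisibly.
#' @export
run_hvcpg_pipeline <- function(datasets, annotation, out_dir,
                               rules = filter_rules(),
                               spec = adjustment_spec(),
                               top_pct = 5, min_fraction_pct = 65,
                               min_datasets = 15, tukey_k = 3, gap = 4000,
                               ks_min_p = 0.1, reference_dataset_id = NULL,
                               seed = 1L, adjust = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pre <- map(datasets, function(d) {
    f <- filter_probes(d, rules)
    a <- if (adjust) adjust_covariates(f, spec) else f
    remove_outliers(a, k = tukey_k)
  })
  variances <- map(pre, dataset_variances)
  names(variances) <- vapply(pre, function(d) d$dataset_id, character(1))
  flags <- map(variances, top_variance_flags, top_pct = top_pct)
  result <- identify_hvcpgs(flags, min_fraction_pct = min_fraction_pct,
                            min_datasets = min_datasets)
  unreliable <- annotation$cpg[!annotation$reliable]
  result <- apply_reliability_filter(result, unreliable)
  hv <- hvcpg_ids(result)

  readr::write_tsv(as_tibble(result), file.path(out_dir, "hvcpg_report.tsv"),
                   progress = FALSE)
  if (length(hv)) write_cpg_bed(hv, annotation, file.path(out_dir, "hvcpgs.bed"))

  controls <- NULL
  if (length(hv)) {
    ref_id <- reference_dataset_id %||%
      pre[[which.max(vapply(pre, function(d) ncol(d$beta), integer(1)))]]$dataset_id
    ref <- pre[[match(ref_id, names(variances))]]
    background <- setdiff(attr(result, "array_background"), c(hv, unreliable))
    controls <- ks_match_controls(hv, background, ref, min_p = ks_min_p)
    readr::write_tsv(controls$matches, file.path(out_dir, "matched_controls.tsv"),
                     progress = FALSE)
  }

  clusters <- NULL
  declustered <- character(0)
  if (length(hv)) {
    clusters <- build_clusters(hv, annotation, gap = gap)
    declustered <- decluster(clusters, seed = seed)
    readr::write_tsv(clusters$membership, file.path(out_dir, "cluster_membership.tsv"),
                     progress = FALSE)
    write_cpg_set(declustered, file.path(out_dir, "declustered_hvcpgs.txt"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    parameters = list(top_pct = top_pct, min_fraction_pct = min_fraction_pct,
                      min_datasets = min_datasets, tukey_k = tukey_k, gap = gap,
                      ks_min_p = ks_min_p, seed = seed, adjust = adjust,
                      n_pcs = spec$n_pcs),
    datasets = names(variances),
    n_hvcpgs = length(hv),
    n_unreliable_removed = attr(result, "n_unreliable_removed"),
    outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(result = result, controls = controls, clusters = clusters,
                 declustered = declustered, variances = variances,
                 manifest = manifest))
}
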