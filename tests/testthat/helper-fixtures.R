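# Small fixtures shared across tests; everything is generated in code.

small_sim <- function(seed = 11, ...) {
  args <- modifyList(list(
    n_datasets = 4, n_samples_per_dataset = 30, n_cpgs = 400,
    n_planted_shared_hv = 10, n_planted_dataset_specific = 4,
    n_planted_mqtl = 5, n_planted_clusters = 2, cluster_size = 4,
    seed = seed
  ), list(...))
  simulate_study(do.call(sim_config, args))
}

# A bare dataset built from an explicit Beta matrix.
toy_dataset <- function(beta, id = "toy", covariates = NULL, detection_p = NULL) {
  if (is.null(rownames(beta))) rownames(beta) <- sprintf("cg%08d", seq_len(nrow(beta)))
  if (is.null(colnames(beta))) colnames(beta) <- sprintf("S%03d", seq_len(ncol(beta)))
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(beta)
  meth_dataset(beta, dataset_id = id, covariates = covariates,
               detection_p = detection_p)
}

# Flags list builder: one named logical vector per dataset.
flags_from_spec <- function(cpg, n_covered, n_flagged, n_datasets) {
  lapply(seq_len(n_datasets), function(d) {
    if (d <= n_covered) setNames(d <= n_flagged, cpg) else setNames(logical(0), character(0))
  })
}
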