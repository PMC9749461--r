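#' Configuration for the multi-dataset methylation simulator
#'
#' Captures the study conditions emulated by [simulate_study()]: many disjoint
#' cohorts typed on a methylation array, a planted subset of CpGs that is
#' hypervariable in every dataset (intermediate-methylation mixtures), CpGs
#' hypervariable in exactly one dataset, CpGs driven additively by a cis/trans
#' mQTL (Hardy-Weinberg genotypes), low-rank batch components, optional sex and
#' age effects on small CpG subsets, and spatially clustered co-methylated CpGs
#' whose correlation decays with genomic distance.
#'
#' Baseline methylation is generated on the M scale (Gaussian) and mapped to
#' Beta through the base-2 inverse logit, so Beta values are guaranteed to lie
#' in (0, 1) without clipping. Per-CpG baseline means are drawn independently
#' in each dataset, which makes per-dataset variance ranks exchangeable across
#' datasets in the absence of planted signal — the null regime under which the
#' cross-dataset intersection rule is expected to call nothing.
#'
#' @param n_datasets Number of independent datasets (cohorts).
#' @param n_samples_per_dataset Samples per dataset (scalar or vector of
#'   length `n_datasets`).
#' @param n_cpgs Number of CpGs on the simulated array.
#' @param n_planted_shared_hv CpGs hypervariable in every dataset.
#' @param n_planted_dataset_specific CpGs hypervariable in exactly one dataset
#'   (assigned round-robin).
#' @param n_planted_mqtl CpGs with an additive genotype effect on M-values.
#' @param n_planted_clusters,cluster_size Number and size of planted
#'   co-methylated CpG clusters.
#' @param hv_variance_multiplier Controls the spread of the hypervariable
#'   mixture components; the Beta-scale variance of a planted CpG scales
#'   roughly linearly with this multiplier relative to a typical null CpG.
#' @param mqtl_maf Minor allele frequency used for Hardy-Weinberg genotype
#'   draws, in (0, 0.5].
#' @param mqtl_effect_m_scale Per-allele genotype effect in M-value units.
#' @param n_batch_components Rank of the additive batch/technical component
#'   per dataset (sample scores x CpG loadings on the M scale).
#' @param cluster_gap_bp Maximum genomic gap used when placing planted cluster
#'   members (bp).
#' @param cluster_span_bp Genomic span over which one cluster's members are
#'   scattered (bp).
#' @param cluster_decay_bp Length scale of the planted co-methylation decay:
#'   member correlation is `exp(-d / cluster_decay_bp)`.
#' @param cluster_latent_sd SD (M units) of the shared spatial latent field.
#' @param interglayer_rho_planted Default cross-germ-layer correlation handed
#'   to [simulate_fetal_multitissue()].
#' @param sex_effect_frac,age_effect_frac Fractions of null CpGs receiving a
#'   sex offset (delta M = 1) or an age slope (0.02 M/year).
#' @param missing_rate Fraction of Beta cells set to missing.
#' @param detection_fail_rate Fraction of detection p-values drawn above the
#'   usual 0.01 threshold (a detection matrix is attached only when > 0).
#' @param unreliable_frac Fraction of probes flagged technically unreliable in
#'   the annotation.
#' @param baseline_m_sd SD of per-CpG baseline means on the M scale.
#' @param noise_m_sd Residual SD on the M scale.
#' @param batch_loading_sd SD of batch-component CpG loadings.
#' @param seed Integer seed; fully determines all outputs.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 30,
                       n_samples_per_dataset = 100,
                       n_cpgs = 20000,
                       n_planted_shared_hv = 200,
                       n_planted_dataset_specific = 100,
                       n_planted_mqtl = 100,
                       n_planted_clusters = 0,
                       cluster_size = 8,
                       hv_variance_multiplier = 5,
                       mqtl_maf = 0.2,
                       mqtl_effect_m_scale = 1,
                       n_batch_components = 2,
                       cluster_gap_bp = 4000,
                       cluster_span_bp = 4000,
                       cluster_decay_bp = 2000,
                       cluster_latent_sd = 0.8,
                       interglayer_rho_planted = 0.7,
                       sex_effect_frac = 0,
                       age_effect_frac = 0,
                       missing_rate = 0,
                       detection_fail_rate = 0,
                       unreliable_frac = 0,
                       baseline_m_sd = 1.5,
                       noise_m_sd = 0.35,
                       batch_loading_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_datasets = assert_count(n_datasets, "n_datasets", 1L),
    n_samples_per_dataset = n_samples_per_dataset,
    n_cpgs = assert_count(n_cpgs, "n_cpgs", 1L),
    n_planted_shared_hv = assert_count(n_planted_shared_hv, "n_planted_shared_hv"),
    n_planted_dataset_specific = assert_count(n_planted_dataset_specific, "n_planted_dataset_specific"),
    n_planted_mqtl = assert_count(n_planted_mqtl, "n_planted_mqtl"),
    n_planted_clusters = assert_count(n_planted_clusters, "n_planted_clusters"),
    cluster_size = assert_count(cluster_size, "cluster_size", 2L),
    hv_variance_multiplier = hv_variance_multiplier,
    mqtl_maf = assert_fraction(mqtl_maf, "mqtl_maf", 0, 0.5, open_lo = TRUE),
    mqtl_effect_m_scale = mqtl_effect_m_scale,
    n_batch_components = assert_count(n_batch_components, "n_batch_components"),
    cluster_gap_bp = assert_count(cluster_gap_bp, "cluster_gap_bp", 1L),
    cluster_span_bp = assert_count(cluster_span_bp, "cluster_span_bp", 1L),
    cluster_decay_bp = assert_count(cluster_decay_bp, "cluster_decay_bp", 1L),
    cluster_latent_sd = cluster_latent_sd,
    interglayer_rho_planted = assert_fraction(interglayer_rho_planted, "interglayer_rho_planted", -1, 1),
    sex_effect_frac = assert_fraction(sex_effect_frac, "sex_effect_frac"),
    age_effect_frac = assert_fraction(age_effect_frac, "age_effect_frac"),
    missing_rate = assert_fraction(missing_rate, "missing_rate"),
    detection_fail_rate = assert_fraction(detection_fail_rate, "detection_fail_rate"),
    unreliable_frac = assert_fraction(unreliable_frac, "unreliable_frac"),
    baseline_m_sd = baseline_m_sd,
    noise_m_sd = noise_m_sd,
    batch_loading_sd = batch_loading_sd,
    seed = assert_count(seed, "seed")
  )
  if (hv_variance_multiplier <= 0) abort("`hv_variance_multiplier` must be positive.")
  ns <- rep_len(cfg$n_samples_per_dataset, cfg$n_datasets)
  if (any(ns < 4)) abort("Each dataset needs at least 4 samples.")
  cfg$n_samples_per_dataset <- as.integer(ns)
  n_cluster_cpgs <- cfg$n_planted_clusters * cfg$cluster_size
  planted <- cfg$n_planted_shared_hv + cfg$n_planted_dataset_specific +
    cfg$n_planted_mqtl + n_cluster_cpgs
  if (planted > cfg$n_cpgs) abort("Planted-category counts exceed `n_cpgs`.")
  structure(cfg, class = "sim_config")
}

# Mixture component M-levels for hypervariable CpGs: 2-3 components centred
# at intermediate Beta, spread scaled by the variance multiplier.
hv_mixture_levels <- function(n, multiplier) {
  k <- sample(2:3, n, replace = TRUE)
  centre <- runif(n, 0.4, 0.6)
  delta <- pmin(0.3, 0.06 * sqrt(multiplier))
  lapply(seq_len(n), function(i) {
    b <- if (k[i] == 2) c(centre[i] - delta, centre[i] + delta)
         else centre[i] + c(-delta, 0, delta)
    log2(b / (1 - b))
  })
}

place_annotation <- function(cfg, category) {
  n <- cfg$n_cpgs
  ids <- cpg_ids(n)
  chroms <- paste0("chr", 1:22)
  is_cluster <- category == "cluster_member"
  chrom <- character(n)
  pos <- integer(n)
  # background CpGs: per-chromosome cumulative exponential gaps
  bg <- which(!is_cluster)
  chrom[bg] <- sample(chroms, length(bg), replace = TRUE)
  for (ch in chroms) {
    idx <- bg[chrom[bg] == ch]
    if (!length(idx)) next
    gaps <- 500L + as.integer(rexp(length(idx), rate = 1 / 6000))
    pos[idx] <- cumsum(gaps)
  }
  # cluster members: contiguous blocks in a reserved coordinate range so they
  # never interleave with background probes or other clusters
  if (cfg$n_planted_clusters > 0) {
    cl_idx <- which(is_cluster)
    blocks <- split(cl_idx, rep(seq_len(cfg$n_planted_clusters), each = cfg$cluster_size))
    for (b in seq_along(blocks)) {
      members <- blocks[[b]]
      ch <- chroms[((b - 1) %% length(chroms)) + 1]
      start <- 5e7 + (b - 1) %/% length(chroms) * 1e6
      offs <- sort(c(0, sample(seq_len(cfg$cluster_span_bp - 1),
                               cfg$cluster_size - 1)))
      chrom[members] <- ch
      pos[members] <- as.integer(start + offs)
    }
  }
  reliable <- rep(TRUE, n)
  if (cfg$unreliable_frac > 0) {
    reliable[sample.int(n, round(cfg$unreliable_frac * n))] <- FALSE
  }
  tibble(cpg = ids, chrom = chrom, pos = pos, reliable = reliable)
}

#' Simulate a multi-dataset methylation study with known ground truth
#'
#' Generates `n_datasets` independent cohorts sharing one CpG annotation, with
#' the planted structure described in [sim_config()]. Identical configurations
#' (including the seed) produce identical output.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `hvcpg_sim` with elements
#'   * `datasets`: list of [meth_dataset()] objects,
#'   * `annotation`: tibble `(cpg, chrom, pos, reliable)`,
#'   * `truth`: tibble `(cpg, category, cluster, hv_dataset)` where `category`
#'     is one of `shared_hv`, `dataset_specific_hv`, `mqtl_driven`,
#'     `cluster_member`, `null` (sex/age-affected CpGs stay `null` but are
#'     marked in `sex_affected`/`age_affected`),
#'   * `mqtl_truth`: tibble of planted SNP-CpG effects (empty when none),
#'   * `genotypes`: per-dataset genotype dosage matrices at the planted mQTL
#'     CpGs (`NULL` entries when none), kept so planted effects can be
#'     re-estimated.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cpgs
  ids <- cpg_ids(n)

  n_cl <- cfg$n_planted_clusters * cfg$cluster_size
  category <- rep("null", n)
  i0 <- 0L
  take <- function(k) if (k > 0) (i0 + 1L):(i0 + k) else integer(0)
  hv_idx <- take(cfg$n_planted_shared_hv); i0 <- i0 + cfg$n_planted_shared_hv
  ds_idx <- take(cfg$n_planted_dataset_specific); i0 <- i0 + cfg$n_planted_dataset_specific
  mq_idx <- take(cfg$n_planted_mqtl); i0 <- i0 + cfg$n_planted_mqtl
  cl_idx <- take(n_cl); i0 <- i0 + n_cl
  category[hv_idx] <- "shared_hv"
  category[ds_idx] <- "dataset_specific_hv"
  category[mq_idx] <- "mqtl_driven"
  category[cl_idx] <- "cluster_member"

  annotation <- place_annotation(cfg, category)

  # shared (cross-dataset) parameters
  hv_levels <- hv_mixture_levels(length(hv_idx), cfg$hv_variance_multiplier)
  ds_levels <- hv_mixture_levels(length(ds_idx), cfg$hv_variance_multiplier)
  ds_assign <- if (length(ds_idx)) ((seq_along(ds_idx) - 1L) %% cfg$n_datasets) + 1L else integer(0)
  mq_effect <- if (length(mq_idx)) cfg$mqtl_effect_m_scale * sample(c(-1, 1), length(mq_idx), replace = TRUE) else numeric(0)

  null_pool <- which(category == "null")
  n_sex <- round(cfg$sex_effect_frac * n)
  n_age <- round(cfg$age_effect_frac * n)
  sex_idx <- if (n_sex > 0) sample(null_pool, min(n_sex, length(null_pool))) else integer(0)
  age_pool <- setdiff(null_pool, sex_idx)
  age_idx <- if (n_age > 0) sample(age_pool, min(n_age, length(age_pool))) else integer(0)

  cluster_of <- rep(NA_integer_, n)
  if (n_cl > 0) cluster_of[cl_idx] <- rep(seq_len(cfg$n_planted_clusters), each = cfg$cluster_size)
  cl_chol <- list()
  if (n_cl > 0) {
    for (b in seq_len(cfg$n_planted_clusters)) {
      members <- cl_idx[cluster_of[cl_idx] == b]
      d <- abs(outer(annotation$pos[members], annotation$pos[members], "-"))
      cl_chol[[b]] <- chol(exp(-d / cfg$cluster_decay_bp))
    }
  }

  tissues <- c("blood", "saliva", "brain", "liver", "kidney", "skin", "colon", "lung")
  ethnicities <- c("EUR", "AFR", "EAS", "SAS", "AMR")
  dataset_tissue <- sample(tissues, cfg$n_datasets, replace = TRUE)
  dataset_eth <- sample(ethnicities, cfg$n_datasets, replace = TRUE)

  datasets <- vector("list", cfg$n_datasets)
  genotypes <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    ns <- cfg$n_samples_per_dataset[d]
    sample_id <- sprintf("D%02d_S%03d", d, seq_len(ns))
    age <- round(runif(ns, 20, 70), 1)
    sex <- rep_len(c("female", "male"), ns)[sample.int(ns)]

    m <- rnorm(n, 0, cfg$baseline_m_sd) +
      matrix(rnorm(n * ns, 0, cfg$noise_m_sd), n, ns)
    if (cfg$n_batch_components > 0) {
      loadings <- matrix(rnorm(n * cfg$n_batch_components, 0, cfg$batch_loading_sd),
                         n, cfg$n_batch_components)
      scores <- matrix(rnorm(cfg$n_batch_components * ns), cfg$n_batch_components, ns)
      m <- m + loadings %*% scores
    }
    for (i in seq_along(hv_idx)) {
      lev <- hv_levels[[i]]
      m[hv_idx[i], ] <- lev[sample.int(length(lev), ns, replace = TRUE)] +
        rnorm(ns, 0, cfg$noise_m_sd)
    }
    for (i in seq_along(ds_idx)) {
      if (ds_assign[i] != d) next
      lev <- ds_levels[[i]]
      m[ds_idx[i], ] <- lev[sample.int(length(lev), ns, replace = TRUE)] +
        rnorm(ns, 0, cfg$noise_m_sd)
    }
    geno <- NULL
    if (length(mq_idx)) {
      geno <- matrix(rbinom(length(mq_idx) * ns, 2, cfg$mqtl_maf), length(mq_idx), ns,
                     dimnames = list(ids[mq_idx], sample_id))
      m[mq_idx, ] <- m[mq_idx, ] + mq_effect * geno
    }
    if (n_cl > 0) {
      for (b in seq_len(cfg$n_planted_clusters)) {
        members <- cl_idx[cluster_of[cl_idx] == b]
        z <- matrix(rnorm(length(members) * ns), length(members), ns)
        m[members, ] <- m[members, ] +
          cfg$cluster_latent_sd * crossprod(cl_chol[[b]], z)
      }
    }
    if (length(sex_idx)) m[sex_idx, sex == "male"] <- m[sex_idx, sex == "male"] + 1
    if (length(age_idx)) {
      m[age_idx, ] <- m[age_idx, ] + outer(rep(0.02, length(age_idx)), age - 45)
    }

    beta <- inv_logit2(m)
    dimnames(beta) <- list(ids, sample_id)
    if (cfg$missing_rate > 0) {
      beta[sample.int(length(beta), round(cfg$missing_rate * length(beta)))] <- NA_real_
    }
    detection_p <- NULL
    if (cfg$detection_fail_rate > 0) {
      detection_p <- matrix(runif(n * ns, 0, 0.005), n, ns, dimnames = dimnames(beta))
      fail <- sample.int(length(detection_p), round(cfg$detection_fail_rate * length(detection_p)))
      detection_p[fail] <- runif(length(fail), 0.011, 0.5)
    }
    genotypes[[d]] <- geno
    datasets[[d]] <- new_meth_dataset(
      beta, dataset_id = sprintf("sim%02d", d),
      covariates = tibble(sample_id = sample_id, age = age, sex = sex),
      detection_p = detection_p,
      tissue = dataset_tissue[d], ethnicity = dataset_eth[d]
    )
  }

  truth <- tibble(
    cpg = ids, category = category, cluster = cluster_of,
    hv_dataset = NA_integer_,
    sex_affected = seq_len(n) %in% sex_idx,
    age_affected = seq_len(n) %in% age_idx
  )
  truth$hv_dataset[ds_idx] <- ds_assign

  mqtl_truth <- if (length(mq_idx)) {
    cpg_ann <- annotation[mq_idx, ]
    cis <- runif(length(mq_idx)) < 0.8
    snp_chrom <- ifelse(cis, cpg_ann$chrom,
                        paste0("chr", ((match(cpg_ann$chrom, paste0("chr", 1:22)) + 10) %% 22) + 1))
    snp_pos <- ifelse(cis,
                      pmax(1L, cpg_ann$pos + sample(c(-1, 1), length(mq_idx), TRUE) *
                             sample.int(5e5, length(mq_idx))),
                      cpg_ann$pos + 5e6)
    tibble(
      cpg = ids[mq_idx], snp = sprintf("rs%07d", seq_along(mq_idx)),
      beta_effect = mq_effect, maf = cfg$mqtl_maf,
      snp_chrom = snp_chrom, snp_pos = as.integer(snp_pos)
    )
  } else {
    tibble(cpg = character(), snp = character(), beta_effect = numeric(),
           maf = numeric(), snp_chrom = character(), snp_pos = integer())
  }

  structure(list(datasets = datasets, annotation = annotation, truth = truth,
                 mqtl_truth = mqtl_truth, genotypes = genotypes, config = cfg),
            class = "hvcpg_sim")
}

#' @export
print.hvcpg_sim <- function(x, ...) {
  cat(sprintf("<hvcpg_sim> %d datasets x %d CpGs (seed %d)\n",
              length(x$datasets), nrow(x$annotation), x$config$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Build the mQTL summary table for a simulated study
#'
#' One row per planted SNP-CpG association, in the column layout consumed by
#' the controls module: `cpg, snp, beta, maf, kind, p`. The cis/trans label is
#' assigned by the 1 Mb same-chromosome distance rule, and the
#' variance-explained field is `2 * beta^2 * maf * (1 - maf)` (which assumes
#' `beta` is on the standardized-methylation scale).
#'
#' @param sim An `hvcpg_sim` from [simulate_study()].
#' @param cis_max_bp SNP-CpG distance at or below which an association is
#'   labelled `cis` (default 1 Mb).
#' @return A tibble of mQTL records (zero rows when nothing was planted).
#' @export
simulate_mqtl_table <- function(sim, cis_max_bp = 1e6) {
  stopifnot(inherits(sim, "hvcpg_sim"))
  mt <- sim$mqtl_truth
  if (nrow(mt) == 0) {
    return(tibble(cpg = character(), snp = character(), beta = numeric(),
                  maf = numeric(), kind = character(), p = numeric()))
  }
  ann <- sim$annotation[match(mt$cpg, sim$annotation$cpg), ]
  kind <- ifelse(mt$snp_chrom == ann$chrom & abs(mt$snp_pos - ann$pos) <= cis_max_bp,
                 "cis", "trans")
  set.seed(sim$config$seed + 1L)
  tibble(cpg = mt$cpg, snp = mt$snp, beta = mt$beta_effect, maf = mt$maf,
         kind = kind, p = 10^(-runif(nrow(mt), 9, 30)))
}

#' Simulate a fetal multi-tissue study
#'
#' Emulates a cohort in which each individual contributes methylation from two
#' tissues derived from different germ layers, split into three germ-layer-pair
#' groups (endoderm-mesoderm, endoderm-ectoderm, mesoderm-ectoderm). Planted
#' CpGs share a per-individual latent methylation level across both tissues
#' with correlation `rho_planted`; remaining CpGs are independent across
#' tissues. Values are generated on the Beta scale around intermediate means
#' and clipped to \[0, 1\] (clipping is negligible at the default SDs).
#'
#' @param n_individuals_per_pair Integer vector of length 3 giving the group
#'   sizes for (endo-meso, endo-ecto, meso-ecto); default `c(9, 10, 8)`,
#'   totalling 27 individuals.
#' @param n_cpgs Number of CpGs.
#' @param rho_planted Cross-tissue correlation of planted CpGs, in \[-1, 1\].
#' @param seed Integer seed.
#' @param n_planted Number of planted CpGs (first `n_planted` ids); defaults
#'   to all of them.
#' @param between_sd Between-individual SD of Beta values.
#' @param noise_sd Additional independent per-tissue measurement noise SD
#'   (default 0).
#' @return A list of class `fetal_study` with `groups` (each holding
#'   `tissue_a`/`tissue_b` CpG x individual matrices) and a `truth` tibble.
#' @export
simulate_fetal_multitissue <- function(n_individuals_per_pair = c(9L, 10L, 8L),
                                       n_cpgs = 10000,
                                       rho_planted = 0.7,
                                       seed = 1L,
                                       n_planted = n_cpgs,
                                       between_sd = 0.1,
                                       noise_sd = 0) {
  if (length(n_individuals_per_pair) == 1) {
    n_individuals_per_pair <- rep(n_individuals_per_pair, 3)
  }
  stopifnot(length(n_individuals_per_pair) == 3)
  n_individuals_per_pair <- vapply(n_individuals_per_pair, assert_count,
                                   integer(1), name = "n_individuals_per_pair", min = 2L)
  n_cpgs <- assert_count(n_cpgs, "n_cpgs", 1L)
  rho_planted <- assert_fraction(rho_planted, "rho_planted", -1, 1)
  n_planted <- assert_count(n_planted, "n_planted")
  if (n_planted > n_cpgs) abort("`n_planted` cannot exceed `n_cpgs`.")
  set.seed(seed)
  ids <- cpg_ids(n_cpgs)
  planted <- seq_len(n_cpgs) <= n_planted
  mu <- runif(n_cpgs, 0.3, 0.7)
  group_names <- c("endo_meso", "endo_ecto", "meso_ecto")
  rho <- ifelse(planted, rho_planted, 0)
  groups <- list()
  for (g in 1:3) {
    k <- n_individuals_per_pair[g]
    # bivariate normal deviations with per-CpG correlation rho
    z1 <- matrix(rnorm(n_cpgs * k), n_cpgs, k)
    z2 <- matrix(rnorm(n_cpgs * k), n_cpgs, k)
    a <- between_sd * z1
    b <- between_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    ta <- mu + a
    tb <- mu + b
    if (noise_sd > 0) {
      ta <- ta + matrix(rnorm(n_cpgs * k, 0, noise_sd), n_cpgs, k)
      tb <- tb + matrix(rnorm(n_cpgs * k, 0, noise_sd), n_cpgs, k)
    }
    ta <- pmin(pmax(ta, 0), 1)
    tb <- pmin(pmax(tb, 0), 1)
    ind <- sprintf("%s_I%02d", group_names[g], seq_len(k))
    dimnames(ta) <- dimnames(tb) <- list(ids, ind)
    groups[[group_names[g]]] <- list(tissue_a = ta, tissue_b = tb, individuals = ind)
  }
  structure(list(groups = groups,
                 truth = tibble(cpg = ids, planted = planted, rho = rho),
                 seed = seed),
            class = "fetal_study")
}

#' @export
print.fetal_study <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$individuals), integer(1))
  cat(sprintf("<fetal_study> %d CpGs; individuals per germ-layer pair: %s (total %d)\n",
              nrow(x$groups[[1]]$tissue_a),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
              sum(sizes)))
  invisible(x)
}

#' Simulate a genomic feature track enriched near a chosen CpG set
#'
#' Places `n_intervals` short intervals on the simulated genome so that CpGs
#' in `enriched_cpgs` fall within `window` bp of an interval at roughly `fold`
#' times the background rate (in expectation); `fold = 1` places intervals
#' uniformly over CpG neighbourhoods.
#'
#' @param annotation Probe annotation tibble (`cpg`, `chrom`, `pos`).
#' @param n_intervals Number of intervals to place.
#' @param enriched_cpgs Character vector of CpG ids to enrich near.
#' @param fold Target proximity rate ratio (>= 1).
#' @param seed Integer seed.
#' @param width Interval width in bp.
#' @param window Proximity window the enrichment is calibrated for, in bp.
#' @return A tibble of intervals `(chrom, start, end)` in 0-based half-open
#'   BED convention.
#' @export
simulate_annotation_tracks <- function(annotation, n_intervals,
                                       enriched_cpgs = character(),
                                       fold = 1, seed = 1L,
                                       width = 200, window = 10000) {
  n_intervals <- assert_count(n_intervals, "n_intervals")
  if (fold < 1) abort("`fold` must be >= 1.")
  set.seed(seed)
  if (n_intervals == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  is_enr <- annotation$cpg %in% enriched_cpgs
  n_e <- sum(is_enr); n_b <- sum(!is_enr)
  k_e <- if (n_e > 0) round(n_intervals * fold * n_e / (fold * n_e + n_b)) else 0L
  k_b <- n_intervals - k_e
  anchor <- c(
    if (k_e > 0) sample(which(is_enr), k_e, replace = k_e > n_e),
    if (k_b > 0) sample(which(!is_enr), k_b, replace = k_b > n_b)
  )
  centre <- annotation$pos[anchor] +
    round(runif(length(anchor), -(window - width) / 2, (window - width) / 2))
  start <- pmax(0L, as.integer(centre - width / 2))
  tibble(chrom = annotation$chrom[anchor], start = start,
         end = start + as.integer(width)) |>
    arrange(.data$chrom, .data$start)
}
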