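test_that("identical configuration reproduces bitwise-identical output", {
  a <- small_sim(seed = 5)
  b <- small_sim(seed = 5)
  expect_identical(a$datasets[[1]]$beta, b$datasets[[1]]$beta)
  expect_identical(a$datasets[[3]]$beta, b$datasets[[3]]$beta)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 6)
  expect_false(identical(a$datasets[[1]]$beta, c$datasets[[1]]$beta))
})

test_that("without planted signal all CpGs are null and variances homogeneous across datasets", {
  sim <- simulate_study(sim_config(
    n_datasets = 3, n_samples_per_dataset = 50, n_cpgs = 2000,
    n_planted_shared_hv = 0, n_planted_dataset_specific = 0,
    n_planted_mqtl = 0, n_planted_clusters = 0,
    hv_variance_multiplier = 1, seed = 2
  ))
  expect_true(all(sim$truth$category == "null"))
  # per-dataset variance distributions should be mutually consistent (same
  # generative law): compare medians across datasets
  meds <- vapply(sim$datasets, function(d) median(dataset_variances(d)), numeric(1))
  expect_lt(diff(range(meds)) / mean(meds), 0.2)
  # Beta stays in [0, 1] without clipping
  rng <- range(sim$datasets[[1]]$beta)
  expect_gt(rng[1], 0); expect_lt(rng[2], 1)
})

test_that("planted-category invariants hold: disjoint categories, counts respected", {
  sim <- small_sim(seed = 9)
  tab <- table(sim$truth$category)
  expect_equal(unname(tab["shared_hv"]), 10)
  expect_equal(unname(tab["dataset_specific_hv"]), 4)
  expect_equal(unname(tab["mqtl_driven"]), 5)
  expect_equal(unname(tab["cluster_member"]), 8)
  expect_equal(sum(tab), 400)  # every CpG has exactly one primary label
  expect_error(sim_config(n_cpgs = 10, n_planted_shared_hv = 20), "exceed")
  expect_error(sim_config(mqtl_maf = 0.7), "maf")
})

test_that("zero mQTL effect size yields near-zero genotype-methylation slopes", {
  sim <- simulate_study(sim_config(
    n_datasets = 2, n_samples_per_dataset = 100, n_cpgs = 300,
    n_planted_shared_hv = 0, n_planted_dataset_specific = 0,
    n_planted_mqtl = 20, mqtl_effect_m_scale = 0, seed = 4
  ))
  d <- sim$datasets[[1]]
  g <- sim$genotypes[[1]]
  m <- beta_to_m(d$beta)
  for (cg in rownames(g)) {
    fit <- summary(lm(m[cg, ] ~ g[cg, ]))$coefficients
    expect_lt(abs(fit[2, 1]), 3 * fit[2, 2])
  }
})

test_that("planted mQTL effects are recovered by per-CpG regression within 3 SE", {
  sim <- simulate_study(sim_config(
    n_datasets = 1, n_samples_per_dataset = 250, n_cpgs = 200,
    n_planted_shared_hv = 0, n_planted_dataset_specific = 0,
    n_planted_mqtl = 15, mqtl_effect_m_scale = 0.8, seed = 8
  ))
  m <- beta_to_m(sim$datasets[[1]]$beta)
  g <- sim$genotypes[[1]]
  truth <- sim$mqtl_truth
  for (i in seq_len(nrow(truth))) {
    cg <- truth$cpg[i]
    fit <- summary(lm(m[cg, ] ~ g[cg, ]))$coefficients
    expect_lt(abs(fit[2, 1] - truth$beta_effect[i]), 3 * fit[2, 2])
  }
})

test_that("mQTL table carries the planted truth and round-trips through TSV", {
  sim <- small_sim(seed = 3)
  tab <- simulate_mqtl_table(sim)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$cpg, sim$truth$cpg[sim$truth$category == "mqtl_driven"])
  # variance explained is the closed form of the planted effect and MAF
  expect_equal(mqtl_variance_explained(tab$beta, tab$maf),
               2 * tab$beta^2 * tab$maf * (1 - tab$maf))
  expect_true(all(tab$kind %in% c("cis", "trans")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mqtl_table(tab, path)
  expect_equal(as.data.frame(read_mqtl_table(path)), as.data.frame(tab))
  # no planted mQTLs -> empty table
  sim0 <- simulate_study(sim_config(n_datasets = 2, n_samples_per_dataset = 10,
                                    n_cpgs = 50, n_planted_shared_hv = 0,
                                    n_planted_dataset_specific = 0,
                                    n_planted_mqtl = 0, seed = 1))
  expect_equal(nrow(simulate_mqtl_table(sim0)), 0)
})

test_that("fetal study matches the three-group design and correlation limits", {
  fs <- simulate_fetal_multitissue(c(9, 10, 8), n_cpgs = 50, rho_planted = 0.7, seed = 1)
  sizes <- vapply(fs$groups, function(g) length(g$individuals), integer(1))
  expect_equal(unname(sizes), c(9, 10, 8))
  expect_equal(sum(sizes), 27)

  # perfect covariation: rho = 1 with no extra noise gives r exactly 1
  fs1 <- simulate_fetal_multitissue(c(4, 4, 4), n_cpgs = 20, rho_planted = 1,
                                    seed = 2, noise_sd = 0)
  r1 <- inter_germlayer_correlation(fs1)
  expect_true(all(abs(r1$mean_r - 1) < 1e-12))

  # independence: rho = 0 has mean r near 0 over many CpGs
  fs0 <- simulate_fetal_multitissue(c(9, 10, 8), n_cpgs = 1500, rho_planted = 0, seed = 3)
  r0 <- inter_germlayer_correlation(fs0)
  expect_lt(abs(mean(r0$mean_r)), 0.1)

  expect_error(simulate_fetal_multitissue(rho_planted = 1.5), "rho_planted")
})

test_that("annotation tracks respect the zero-interval and enrichment-fold contracts", {
  sim <- small_sim(seed = 13)
  empty <- simulate_annotation_tracks(sim$annotation, n_intervals = 0)
  expect_equal(nrow(empty), 0)
  prox <- proximity_enrichment(
    cpgs = sim$truth$cpg[1:50], comparator = sim$truth$cpg[51:100],
    annotation = sim$annotation, intervals = empty, distances = c(1000, 10000)
  )
  expect_true(all(prox$prop_target == 0))
  expect_error(simulate_annotation_tracks(sim$annotation, 10, fold = 0.5), "fold")

  # strong planting near the shared-hv CpGs is detected as enrichment
  hv <- sim$truth$cpg[sim$truth$category == "shared_hv"]
  nulls <- sim$truth$cpg[sim$truth$category == "null"]
  track <- simulate_annotation_tracks(sim$annotation, n_intervals = 60,
                                      enriched_cpgs = hv, fold = 8, seed = 5)
  res <- proximity_enrichment(hv, nulls, sim$annotation, track, distances = 10000)
  expect_gt(res$sample_or, 1)
  expect_lt(res$p, 0.05)
})
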