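test_that("Beta/M transforms match their closed forms and round-trip", {
  expect_equal(beta_to_m(0.5), 0, ignore_attr = TRUE)
  expect_equal(beta_to_m(0.8), 2, ignore_attr = TRUE)
  for (x in c(0.1, 0.37, 0.9)) {
    expect_equal(m_to_beta(beta_to_m(x)), x, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(m_to_beta(0), 0.5, ignore_attr = TRUE)
  expect_equal(m_to_beta(2), 0.8, ignore_attr = TRUE)
  # natural-exponential mode reproduces exp(M)/(1 + exp(M))
  expect_equal(m_to_beta(2, mode = "natural"), exp(2) / (1 + exp(2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # clamping keeps the logit finite and is counted
  m <- beta_to_m(c(0, 0.5, 1))
  expect_true(all(is.finite(m)))
  expect_equal(attr(m, "n_clamped"), 2)
  # back-transform output strictly inside (0, 1)
  b <- m_to_beta(c(-50, 0, 50))
  expect_true(all(b > 0 & b < 1))
})

test_that("probe filters implement the detection, exclusion and missingness rules", {
  set.seed(1)
  beta <- matrix(runif(5 * 20, 0.2, 0.8), 5, 20,
                 dimnames = list(sprintf("cg%02d", 1:5), sprintf("S%03d", 1:20)))
  det <- matrix(0.001, 5, 20)
  det[2, 1:2] <- 0.02                      # 2 of 20 = 10% > 5% -> removed
  det[3, 1] <- 0.02                        # 1 of 20 = 5%, not > 5% -> kept
  ds <- toy_dataset(beta, detection_p = det)
  out <- filter_probes(ds, filter_rules())
  expect_setequal(rownames(out$beta), rownames(beta)[-2])

  # empty exclusion lists + complete data: identity
  ds2 <- toy_dataset(beta)
  out2 <- filter_probes(ds2, filter_rules())
  expect_identical(out2$beta, ds2$beta)

  # a probe with any missing Beta is removed under drop_any_missing
  beta_na <- beta; beta_na[4, 7] <- NA
  out3 <- filter_probes(toy_dataset(beta_na), filter_rules())
  expect_false(rownames(beta)[4] %in% rownames(out3$beta))
  out3b <- filter_probes(toy_dataset(beta_na),
                         filter_rules(drop_any_missing = FALSE))
  expect_true(rownames(beta)[4] %in% rownames(out3b$beta))

  # exclusion lists and idempotence
  rules <- filter_rules(xy_list = rownames(beta)[1], snp_list = rownames(beta)[5])
  once <- filter_probes(ds2, rules)
  twice <- filter_probes(once, rules)
  expect_identical(once$beta, twice$beta)
  expect_setequal(rownames(once$beta), rownames(beta)[2:4])
  rep <- attr(once, "filter_report")
  expect_equal(rep$n[rep$rule == "exclusion_list"], 2)
})

test_that("covariate adjustment removes a rank-1 batch effect and planted sex effect", {
  set.seed(42)
  n <- 40; g <- 60
  # pure rank-1 structure on the M scale
  load <- rnorm(g); score <- rnorm(n)
  m <- outer(load, score)
  beta <- m_to_beta(m + 1)  # offset keeps values intermediate
  ds <- toy_dataset(beta)
  adj <- adjust_covariates(ds, adjustment_spec(n_pcs = 1, use_age = FALSE, use_sex = FALSE))
  v0 <- row_var <- apply(beta_to_m(ds$beta), 1, var)
  v1 <- apply(beta_to_m(adj$beta), 1, var)
  expect_lt(max(v1 / v0), 1e-10)

  # identity: no PCs, no covariates, intercept added back
  ds3 <- toy_dataset(matrix(runif(30 * 10, 0.2, 0.8), 30, 10))
  idn <- adjust_covariates(ds3, adjustment_spec(n_pcs = 0, use_age = FALSE, use_sex = FALSE))
  expect_equal(idn$beta, ds3$beta, tolerance = 1e-12)
  expect_equal(dim(idn$beta), dim(ds3$beta))

  # planted sex effect (delta M = 1) vanishes after adjustment
  sex <- rep(c("male", "female"), each = 20)
  m2 <- matrix(rnorm(50 * 40, 0, 0.4), 50, 40)
  m2[1:10, sex == "male"] <- m2[1:10, sex == "male"] + 1
  ds4 <- toy_dataset(m_to_beta(m2),
                     covariates = tibble::tibble(sample_id = sprintf("S%03d", 1:40),
                                                 age = runif(40, 20, 60), sex = sex))
  adj4 <- adjust_covariates(ds4, adjustment_spec(n_pcs = 0, use_age = FALSE, use_sex = TRUE))
  m_adj <- beta_to_m(adj4$beta)
  for (i in 1:10) {
    a <- m_adj[i, sex == "male"]; b <- m_adj[i, sex == "female"]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
})

test_that("adjustment residuals are orthogonal to the regressors", {
  sim <- small_sim(seed = 21)
  ds <- sim$datasets[[1]]
  spec <- adjustment_spec(n_pcs = 3)
  adj <- adjust_covariates(ds, spec)
  m <- beta_to_m(ds$beta)
  pca <- prcomp(t(m), center = TRUE)
  resid <- t(beta_to_m(adj$beta))
  resid <- sweep(resid, 2, colMeans(resid))   # remove the added-back intercept
  for (k in 1:3) {
    ip <- abs(colSums(resid * pca$x[, k]))
    expect_true(all(ip < 1e-8 * sqrt(colSums(resid^2)) * sqrt(sum(pca$x[, k]^2)) + 1e-8))
  }
  expect_error(adjust_covariates(ds, adjustment_spec(n_pcs = 30)), "n_pcs")
})

test_that("constant covariates are dropped with a warning", {
  beta <- matrix(runif(20 * 10, 0.3, 0.7), 20, 10)
  cov <- tibble::tibble(sample_id = sprintf("S%03d", 1:10),
                        age = rep(30, 10), sex = rep("female", 10))
  ds <- toy_dataset(beta, covariates = cov)
  expect_warning(
    expect_warning(adjust_covariates(ds, adjustment_spec(n_pcs = 0)), "age"),
    "sex")
})

test_that("Tukey outer-fence mask matches a quantile oracle and is monotone in k", {
  vals <- c(1:11, 1000)
  q <- quantile(vals, c(0.25, 0.75), type = 7)  # independent quantile arithmetic
  fence <- c(q[1] - 3 * (q[2] - q[1]), q[2] + 3 * (q[2] - q[1]))
  oracle <- vals < fence[1] | vals > fence[2]
  expect_identical(tukey_outlier_mask(vals, 3), unname(oracle))
  expect_identical(which(tukey_outlier_mask(vals, 3)), 12L)

  # constant vector: IQR 0, nothing masked
  expect_false(any(tukey_outlier_mask(rep(0.4, 10))))

  # k = 3 mask is a subset of k = 1.5 mask; permutation equivariance
  set.seed(7)
  for (rep in 1:20) {
    v <- rnorm(50)
    m3 <- tukey_outlier_mask(v, 3); m15 <- tukey_outlier_mask(v, 1.5)
    expect_true(all(!m3 | m15))
    perm <- sample.int(50)
    expect_identical(tukey_outlier_mask(v[perm], 3), m3[perm])
  }
  expect_error(tukey_outlier_mask(c(NA, NA, NA, NA, 1)), "non-missing")
})

test_that("outlier removal masks fence-crossing values and preserves shape", {
  beta <- matrix(runif(10 * 30, 0.4, 0.6), 10, 30)
  beta[3, 1] <- 0.999
  ds <- toy_dataset(beta)
  out <- remove_outliers(ds, k = 3)
  expect_true(is.na(out$beta[3, 1]))
  expect_equal(dim(out$beta), dim(beta))
  expect_equal(attr(out, "n_outliers_removed"), sum(is.na(out$beta)))
})
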