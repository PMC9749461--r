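test_that("Fisher enrichment handles balance, zero cells and the row/column swap", {
  target <- paste0("t", 1:20); comparator <- paste0("c", 1:20)
  feature <- c(paste0("t", 1:10), paste0("c", 1:10))
  res <- fisher_enrichment(target, comparator, feature)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$sample_or, 1)
  expect_equal(res$p, 1)
  expect_equal(res$fold, 1)

  # complete separation: sample OR uses the Haldane-Anscombe correction
  res2 <- fisher_enrichment(paste0("t", 1:5), paste0("c", 1:5), paste0("t", 1:5))
  expect_equal(res2$sample_or, (5.5 * 5.5) / (0.5 * 0.5))
  # two-sided p: the two equally extreme tables [[5,0],[0,5]] and [[0,5],[5,0]]
  expect_equal(res2$p, 2 / choose(10, 5), tolerance = 1e-12)

  # swapping target/comparator inverts the OR and keeps p
  set.seed(8)
  feats <- sample(c(target, comparator), 17)
  a <- fisher_enrichment(target, comparator, feats)
  b <- fisher_enrichment(comparator, target, feats)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$sample_or, 1 / b$sample_or, tolerance = 1e-12)

  expect_error(fisher_enrichment(character(0), comparator, feats), "empty")
  expect_error(fisher_enrichment(target, target, feats), "disjoint")
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration", {
  # independent oracle: enumerate all tables with the observed margins and sum
  # the probabilities of tables no more likely than the observed one
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(42)
  for (rep in 1:60) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    target <- paste0("t", seq_len(a + b))
    comparator <- paste0("c", seq_len(c_ + d))
    feature <- c(head(target, a), head(comparator, c_))
    res <- fisher_enrichment(target, comparator, feature)
    expect_equal(res$p, fisher_oracle(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("interval proximity uses BED half-open coordinates and is monotone", {
  ann <- tibble::tibble(cpg = c("cg_in", "cg_near", "cg_far", "cgA", "cgB"),
                        chrom = "chr1",
                        pos = c(4200, 5000, 50000, 100000, 200000),
                        reliable = TRUE)
  intervals <- tibble::tibble(chrom = "chr1", start = 4000, end = 4500)
  d <- hvcpg:::cpg_interval_distance(ann, intervals)
  expect_equal(d, c(0, 500, 45500, 95500, 195500))

  res <- proximity_enrichment(c("cg_in", "cg_near"), c("cgA", "cgB"), ann,
                              intervals, distances = c(100, 1000, 1e6))
  prop <- res$prop_target
  expect_equal(prop, c(0.5, 1, 1))               # non-decreasing in distance
  expect_equal(res$prop_comparator, c(0, 0, 1))

  bad <- tibble::tibble(chrom = "chrX", start = 1, end = 10)
  expect_error(proximity_enrichment(c("cg_in"), c("cgA"), ann, bad), "chrX")
})

test_that("bootstrap CIs are percentile, deterministic and honestly degenerate", {
  ci <- bootstrap_ci(mean, rep(3.5, 40), B = 200, seed = 1)
  expect_equal(unname(ci), c(3.5, 3.5), ignore_attr = TRUE)
  expect_true(isTRUE(attr(ci, "degenerate")))

  set.seed(2)
  x <- rnorm(50)
  a <- bootstrap_ci(mean, x, B = 500, seed = 7)
  b <- bootstrap_ci(mean, x, B = 500, seed = 7)
  expect_identical(a, b)
  expect_lt(a[["low"]], a[["high"]])
  expect_error(bootstrap_ci(mean, x, B = 50), "B")
})

test_that("bootstrap interval coverage for a normal mean is close to nominal", {
  set.seed(31)
  hits <- vapply(1:400, function(i) {
    x <- rnorm(30, mean = 2)
    ci <- bootstrap_ci(mean, x, B = 400, seed = i)
    ci[["low"]] <= 2 && 2 <= ci[["high"]]
  }, logical(1))
  expect_gt(mean(hits), 0.89)   # percentile bootstrap runs slightly below 95%
  expect_lt(mean(hits), 0.99)
})

test_that("enrichment p-values are calibrated under random feature draws", {
  set.seed(9)
  universe <- paste0("u", 1:1000)
  target <- universe[1:300]
  comparator <- universe[301:600]
  ps <- vapply(1:400, function(i) {
    feature <- sample(universe, 200)
    fisher_enrichment(target, comparator, feature)$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.01)   # Fisher's exact test is conservative but not inert
  expect_lt(frac, 0.09)
})

test_that("the published-set report applies the 1% filter and BH correction", {
  target <- paste0("t", 1:100)
  comparator <- paste0("c", 1:100)
  sets <- list(
    same = target,                              # identical to the target
    tiny = "t1",                                # does meet 1% exactly
    none = paste0("z", 1:50),                   # disjoint -> excluded
    some = c(paste0("t", 1:30), paste0("c", 1:5))
  )
  rep <- set_overlap_report(target, sets, comparator, trait_min_fraction = 0.01)
  expect_false("none" %in% rep$set)
  expect_true(all(c("same", "tiny", "some") %in% rep$set))
  expect_true(is.infinite(rep$odds_ratio[rep$set == "same"]) ||
                rep$odds_ratio[rep$set == "same"] > 100)
  expect_equal(rep$q, p.adjust(rep$p, "BH"))
  # background restriction happens before testing
  rep2 <- set_overlap_report(target, sets, comparator,
                             background = c(target, comparator))
  expect_false("none" %in% rep2$set)
})

test_that("sex-split stability separates genuine from sex-driven variability", {
  set.seed(12)
  n <- 120
  sex <- rep(c("male", "female"), each = n / 2)
  g <- 400
  m <- matrix(rnorm(g * n, 0, 0.3), g, n)
  # genuinely hypervariable CpGs: bimodal in both sexes
  hv_rows <- 1:8
  for (i in hv_rows) m[i, ] <- sample(c(-1.2, 1.2), n, TRUE) + rnorm(n, 0, 0.3)
  # sex-driven CpGs: bimodal only when sexes are pooled
  sexed_rows <- 9:16
  for (i in sexed_rows) m[i, sex == "male"] <- m[i, sex == "male"] + 2.5
  beta <- m_to_beta(m)
  rownames(beta) <- sprintf("cg%08d", 1:g)
  ds <- toy_dataset(beta,
                    covariates = tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                                                age = runif(n, 20, 60), sex = sex))
  hv_ids <- rownames(beta)[hv_rows]
  sexed_ids <- rownames(beta)[sexed_rows]
  out <- sex_split_stability(list(ds), hv_ids, min_n = 80, top_pct = 5)
  expect_equal(out$proportion, 1)
  expect_equal(out$n_qualifying, 1L)
  out_sexed <- sex_split_stability(list(ds), sexed_ids, min_n = 80, top_pct = 5)
  expect_equal(out_sexed$proportion, 0)

  # empty hvCpG set: undefined, reported as missing
  expect_true(is.na(sex_split_stability(list(ds), character(0))$proportion))
  # no qualifying dataset: error
  small <- toy_dataset(beta[, 1:40],
                       covariates = tibble::tibble(sample_id = sprintf("S%03d", 1:40),
                                                   sex = sex[1:40]))
  expect_error(sex_split_stability(list(small), hv_ids, min_n = 80), "qualifies")
})
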