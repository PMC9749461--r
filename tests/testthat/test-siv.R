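make_fetal <- function(fun, n_cpgs = 5, k = 4) {
  ids <- sprintf("cg%08d", seq_len(n_cpgs))
  groups <- list()
  for (g in c("endo_meso", "endo_ecto", "meso_ecto")) {
    ab <- fun(n_cpgs, k)
    dimnames(ab$a) <- dimnames(ab$b) <- list(ids, sprintf("%s_I%02d", g, 1:k))
    groups[[g]] <- list(tissue_a = ab$a, tissue_b = ab$b,
                        individuals = colnames(ab$a))
  }
  structure(list(groups = groups, truth = NULL, seed = NA_integer_),
            class = "fetal_study")
}

test_that("inter-germ-layer correlation hits the exact limits and affine invariance", {
  set.seed(1)
  # tissue B identical to tissue A -> r = 1 in every group
  st1 <- make_fetal(function(n, k) { a <- matrix(runif(n * k), n, k); list(a = a, b = a) })
  r1 <- inter_germlayer_correlation(st1)
  expect_equal(r1$mean_r, rep(1, 5), tolerance = 1e-12)
  expect_true(all(r1$n_groups == 3))

  # tissue B = -A + c -> r = -1
  st2 <- make_fetal(function(n, k) {
    a <- matrix(runif(n * k, 0, 0.5), n, k); list(a = a, b = 0.9 - a)
  })
  expect_equal(inter_germlayer_correlation(st2)$mean_r, rep(-1, 5), tolerance = 1e-12)

  # common affine rescaling within a group leaves r unchanged
  st3 <- make_fetal(function(n, k) {
    a <- matrix(runif(n * k), n, k); b <- matrix(runif(n * k), n, k)
    list(a = a, b = b)
  })
  base <- inter_germlayer_correlation(st3)
  st3s <- st3
  for (g in names(st3s$groups)) {
    st3s$groups[[g]]$tissue_a <- 0.5 * st3s$groups[[g]]$tissue_a + 0.1
    st3s$groups[[g]]$tissue_b <- 0.5 * st3s$groups[[g]]$tissue_b + 0.1
  }
  expect_equal(inter_germlayer_correlation(st3s)$mean_r, base$mean_r, tolerance = 1e-12)

  # zero-variance groups are excluded and flagged through n_groups
  st4 <- make_fetal(function(n, k) {
    list(a = matrix(0.5, n, k), b = matrix(runif(n * k), n, k))
  })
  r4 <- inter_germlayer_correlation(st4)
  expect_true(all(is.na(r4$mean_r)))
  expect_true(all(r4$n_groups == 0))
})

test_that("a planted cross-tissue correlation of 0.7 is recovered on average", {
  fs <- simulate_fetal_multitissue(c(9, 10, 8), n_cpgs = 3000, rho_planted = 0.7, seed = 2)
  r <- inter_germlayer_correlation(fs)
  expect_lt(abs(mean(r$mean_r) - 0.7), 0.05)
})

test_that("interindividual variation is the range of per-individual cross-tissue means", {
  # all individuals identical -> 0
  st <- make_fetal(function(n, k) {
    a <- matrix(rep(seq(0.2, 0.6, length.out = n), k), n, k)
    list(a = a, b = a)
  })
  expect_true(all(interindividual_variation(st)$range == 0))

  # per-individual means {0.2, 0.5, 0.7} (just three individuals, one group pair)
  a <- matrix(c(0.1, 0.4, 0.6), 1, 3); b <- matrix(c(0.3, 0.6, 0.8), 1, 3)
  st2 <- make_fetal(function(n, k) list(a = a, b = b), n_cpgs = 1, k = 3)
  # per-individual means are 0.2, 0.5, 0.7 in each of the three groups
  expect_equal(interindividual_variation(st2)$range, 0.5)

  # symmetric in the tissue labels
  st2s <- st2
  for (g in names(st2s$groups)) {
    tmp <- st2s$groups[[g]]$tissue_a
    st2s$groups[[g]]$tissue_a <- st2s$groups[[g]]$tissue_b
    st2s$groups[[g]]$tissue_b <- tmp
  }
  expect_equal(interindividual_variation(st2s)$range,
               interindividual_variation(st2)$range)
})

test_that("the SIV predicate matches a hand computation on a listed 4 x 3 matrix", {
  m <- matrix(c(0.10, 0.15, 0.12,
                0.40, 0.45, 0.38,
                0.20, 0.22, 0.21,
                0.55, 0.50, 0.52), 4, 3, byrow = TRUE)
  means <- rowMeans(m)
  expect_equal(means, c(37/300, 0.41, 0.21, (0.55 + 0.50 + 0.52) / 3))
  rng <- max(means) - min(means)
  expect_true(siv_predicate(m, siv_predicate_spec(range_threshold = 0.2)))
  expect_equal(siv_predicate(m, siv_predicate_spec(range_threshold = rng + 1e-9)), FALSE)
  # correlation component: all pairwise correlations here are high
  cm <- cor(m)
  expect_true(all(cm[upper.tri(cm)] > 0.9))
  expect_true(siv_predicate(m, siv_predicate_spec(0.2, corr_threshold = 0.9)))
  expect_false(siv_predicate(m, siv_predicate_spec(0.2, corr_threshold = 0.999)))

  # vacuous predicate and degenerate cases
  expect_true(siv_predicate(m, siv_predicate_spec(range_threshold = 0)))
  flat <- matrix(0.3, 4, 3)
  expect_false(siv_predicate(flat, siv_predicate_spec(0.2)))
  deg <- siv_predicate(flat, siv_predicate_spec(0, corr_threshold = 0.5))
  expect_false(deg)
  expect_true(isTRUE(attr(deg, "degenerate")))
})

test_that("power limits are exact and the estimate is seed-deterministic", {
  mu <- c(0.5, 0.5, 0.5)
  # vacuous predicate: power exactly 1
  p1 <- siv_power(mu, diag(3) * 0.01, predicate = siv_predicate_spec(0), seed = 1)
  expect_equal(p1$power, 1)
  # point mass: no variation, power exactly 0
  p0 <- siv_power(mu, matrix(0, 3, 3), predicate = siv_predicate_spec(0.2), seed = 1)
  expect_equal(p0$power, 0)
  expect_equal(p0$se, 0)
  # determinism
  pa <- siv_power(mu, diag(3) * 0.05^2, seed = 9)
  pb <- siv_power(mu, diag(3) * 0.05^2, seed = 9)
  expect_identical(pa$power, pb$power)
  # non-PSD covariance is rejected
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(siv_power(mu, bad, seed = 1), "positive semidefinite")
})

test_that("power is monotone in the range threshold and the variance scale", {
  mu <- c(0.5, 0.5, 0.5)
  thresholds <- c(0, 0.05, 0.1, 0.2, 0.4)
  powers <- vapply(thresholds, function(t) {
    siv_power(mu, diag(3) * 0.08^2, predicate = siv_predicate_spec(t),
              n_reps = 400, seed = 3)$power
  }, numeric(1))
  expect_true(all(diff(powers) <= 0))
  scales <- c(0.02, 0.05, 0.1, 0.2)
  powers2 <- vapply(scales, function(s) {
    siv_power(mu, diag(3) * s^2, predicate = siv_predicate_spec(0.2),
              n_reps = 400, seed = 3)$power
  }, numeric(1))
  expect_true(all(diff(powers2) >= 0))
})

test_that("power inputs estimated from samples feed the simulator", {
  set.seed(5)
  samp <- matrix(runif(12, 0.3, 0.7), 4, 3)
  inp <- estimate_power_inputs(samp)
  expect_equal(inp$mu[[1]], colMeans(samp))
  expect_equal(inp$sigma[[1]], cov(samp))
  res <- siv_power(inp$mu, inp$sigma, seed = 2)
  expect_true(res$power >= 0 && res$power <= 1)
})
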