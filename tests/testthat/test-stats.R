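# Agreement statistics. kruskal_wallis is validated against the base-R
# implementation as an independent oracle (the package computes H from
# ranks directly).

test_that("kruskal_wallis matches stats::kruskal.test on random data", {
  set.seed(51)
  for (rep in 1:10) {
    g <- lapply(1:3, function(i) round(rnorm(10 + 2 * i, i / 4), 1)) # ties too
    mine <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("kruskal_wallis identity, separation and invariance", {
  ident <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$H, 0, tolerance = 1e-12)
  expect_equal(ident$p, 1)
  sep <- kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)))
  expect_lt(sep$p, 0.05)
  # invariance under strictly monotone transforms
  set.seed(52)
  g <- lapply(1:3, function(i) rnorm(8, i / 3))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(v) exp(v)))$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("linear_r2 reproduces exact and published regressions", {
  x <- 1:10
  expect_equal(linear_r2(x, 2 * x + 1)$r2, 1)
  bmd <- rep(c(0.83, 1.31, 0.50), each = 3)
  tbint <- c(23.22, 22.34, 24.03, 24.66, 26.03, 25.3, 20.61, 21.98, 21.68)
  fit <- linear_r2(bmd, tbint)
  expect_equal(round(fit$r2, 2), 0.87)
  expect_gt(fit$slope, 0)
  # independence: median r2 stays low
  set.seed(53)
  r2s <- replicate(300, linear_r2(rnorm(9), rnorm(9))$r2)
  expect_lt(median(r2s), 0.2)
  expect_error(linear_r2(rep(1, 5), rnorm(5)), "variance")
})

test_that("bland_altman bias and limits", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias, 0)
  expect_equal(ident$limits, c(0, 0))
  rel <- bland_altman(c(10, 20, 30), c(11, 22, 33), relative = TRUE)
  expect_equal(rel$bias, 10)
  set.seed(54)
  a <- rnorm(500, 10); b <- a + 0.7 + rnorm(500, 0, 0.2)
  expect_equal(bland_altman(a, b)$bias, 0.7, tolerance = 0.05)
  expect_error(bland_altman(c(0, 1), c(1, 2), relative = TRUE), "zero")
})

test_that("icc recovers planted agreement levels with the published bands", {
  v <- c(1, 2, 3, 4, 5)
  perfect <- icc(v, v)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$band, "excellent")
  # variance components: between-subject 0.6, error 0.4 -> ICC 0.6
  set.seed(55)
  subj <- rnorm(200, 0, sqrt(0.6))
  a <- subj + rnorm(200, 0, sqrt(0.4))
  b <- subj + rnorm(200, 0, sqrt(0.4))
  sim <- icc(a, b)
  expect_lt(abs(sim$icc - 0.6), 0.05)
  expect_equal(sim$band, "good")
  indep <- icc(rnorm(200), rnorm(200))
  expect_lt(abs(indep$icc), 0.15)
  expect_equal(indep$band, "low")
})

test_that("max_percent_diff follows the published table arithmetic", {
  expect_equal(max_percent_diff(c(0.25, 0.26), c(0.25, 0.24)), 8L)
  expect_equal(max_percent_diff(c(1, 2, 3), c(1, 2, 3)), 0L)
  expect_equal(max_percent_diff(1.0, 1.1), 10L)
  expect_equal(max_percent_diff(c(1, NA, 2), c(1.2, 5, NA)), 20L)
  expect_error(max_percent_diff(c(0, 1), c(1, 1)), "zero")
})

test_that("agreement_summary matches pairs and drops ND pairwise", {
  df <- data.frame(
    sample_id = rep("S1", 12), image_id = rep(1:3, each = 4),
    modality = rep(c("uCT", "MRI"), 6),
    metric = rep(rep(c("BVF", "Tb.OrS"), each = 2), 3),
    value = c(0.25, 0.25, 95, 90, 0.26, 0.24, NA, NA, 0.23, 0.25, 87, 77))
  out <- agreement_summary(df, reference = "uCT")
  bvf <- out[out$metric == "BVF", ]
  expect_equal(bvf$n_pairs, 3)
  tbors <- out[out$metric == "Tb.OrS", ]
  expect_equal(tbors$n_pairs, 2)
  expect_equal(tbors$n_dropped, 1)
})
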