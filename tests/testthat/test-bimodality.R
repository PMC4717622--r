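test_that("mixture fit recovers known generating parameters", {
  set.seed(42)
  v <- c(rnorm(100, 2, 0.5), rnorm(100, 8, 0.5))
  f <- fit_bimodality_index(v)
  expect_true(f$converged)
  expect_lte(abs(f$pi - 0.5), 0.05)
  expect_lte(abs(f$delta - 12) / 12, 0.15)
  expect_lte(abs(f$bi - 6) / 6, 0.15)
  expect_lte(f$mu_low, f$mu_high)
  # bi is definitionally sqrt(pi(1-pi)) * delta for any converged fit
  expect_equal(f$bi, sqrt(f$pi * (1 - f$pi)) * f$delta)
})

test_that("near-constant and unimodal profiles fail every preset", {
  # the ML equal-variance mixture fitted to pure noise still reports a
  # nonzero split, but its standardized separation stays below the loosest
  # delta threshold, so flat genes can never pass a preset
  set.seed(43)
  f0 <- fit_bimodality_index(rep(5, 50) + rnorm(50, 0, 1e-6))
  expect_lt(f0$delta, 2.5)
  fc <- fit_bimodality_index(rep(5, 50))   # exactly constant
  expect_equal(fc$delta, 0)
  expect_equal(fc$bi, 0)
  f1 <- fit_bimodality_index(rnorm(400, 5, 0.8))
  expect_lt(f1$bi, 0.7)   # below the least stringent BI usable for cells
  expect_error(fit_bimodality_index(rnorm(5)), "insufficient")
})

test_that("the bimodality index is invariant to affine transforms", {
  set.seed(44)
  for (rep in 1:10) {
    v <- c(rnorm(60, 0, 1), rnorm(40, 4, 1))
    f <- fit_bimodality_index(v)
    shift <- runif(1, -50, 50)
    scale <- runif(1, 0.1, 20)
    g <- fit_bimodality_index(scale * v + shift)
    expect_equal(g$bi, f$bi, tolerance = 1e-6)
    expect_equal(g$delta, f$delta, tolerance = 1e-6)
    expect_equal(g$pi, f$pi, tolerance = 1e-6)
  }
})

test_that("equal-variance EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  set.seed(45)
  v <- c(rnorm(120, 3, 0.6), rnorm(80, 7, 0.6))
  f <- fit_bimodality_index(v)
  mc <- mclust::Mclust(v, G = 2, modelNames = "E", verbose = FALSE)
  mu <- unname(sort(mc$parameters$mean))
  expect_equal(f$mu_low, mu[1], tolerance = 0.05)
  expect_equal(f$mu_high, mu[2], tolerance = 0.05)
  expect_equal(f$sigma, sqrt(mc$parameters$variance$sigmasq),
               tolerance = 0.05)
  pi_low <- mc$parameters$pro[order(mc$parameters$mean)][1]
  expect_equal(f$pi, pi_low, tolerance = 0.02)
})

test_that("gap midpoint matches the worked example and separation property", {
  v <- c(1.0, 1.2, 1.4, 5.0, 5.1, 5.3, 5.4, 5.5, 5.6, 5.7)
  expect_equal(big_midpoint(v), 3.2)
  # two tight, well-separated clusters: midpoint strictly between them
  set.seed(46)
  a <- rnorm(50, 0, 0.1); b <- rnorm(50, 10, 0.1)
  mid <- big_midpoint(c(a, b))
  expect_gt(mid, max(a))
  expect_lt(mid, min(b))
  # uniform grid with one doubled gap
  grid <- cumsum(c(0, rep(1, 99))); grid[51:100] <- grid[51:100] + 1
  expect_equal(big_midpoint(grid), (grid[50] + grid[51]) / 2)
  expect_error(big_midpoint(rep(2, 20)), "no gap")
})

test_that("gap midpoint equals the exhaustive scan on random vectors", {
  set.seed(47)
  for (rep in 1:200) {
    n <- sample(10:200, 1)
    v <- switch(sample(3, 1),
                rnorm(n),
                c(rnorm(ceiling(n / 2), 0), rnorm(floor(n / 2), 5)),
                rt(n, df = 2))
    expect_identical(big_midpoint(v), oracle_gap_midpoint(v))
  }
})

test_that("presets carry the documented thresholds", {
  expect_equal(bimodal_preset("cell_line")[c("bi_min", "delta_min")],
               list(bi_min = 0.7, delta_min = 2.5))
  expect_equal(bimodal_preset("cell_line_low")[c("bi_min", "delta_min")],
               list(bi_min = 1.1, delta_min = 3.5))
  expect_equal(bimodal_preset("patient")[c("bi_min", "delta_min")],
               list(bi_min = 0.5, delta_min = 2.5))
  expect_equal(bimodal_preset("patient_low")[c("bi_min", "delta_min")],
               list(bi_min = 0.9, delta_min = 3.0))
  expect_error(bimodal_preset("tissue"))
})

test_that("classification window follows the imbalance formula", {
  fit <- structure(list(pi = 0.05, midpoint = 6), class = "bimodal_fit")
  cls <- classify_samples(fit, c(2, 5.5, 5.9, 5.95, 6.5))
  expect_equal(cls$window, 0.05 * 0.9 * 4)  # 0.18
  expect_identical(unname(cls$labels),
                   c("low", "low", "unassigned", "unassigned", "high"))
  # balanced fit: zero window, plain thresholding
  fit2 <- structure(list(pi = 0.5, midpoint = 6), class = "bimodal_fit")
  cls2 <- classify_samples(fit2, c(2, 5.99, 6.01, 8))
  expect_equal(cls2$window_fraction, 0)
  expect_identical(unname(cls2$labels), c("low", "low", "high", "high"))
})

test_that("no sample is labeled against its side of the midpoint", {
  set.seed(48)
  for (rep in 1:20) {
    v <- c(rnorm(30, 0), rnorm(30, runif(1, 2, 8)))
    f <- fit_bimodality_index(v)
    cls <- classify_samples(f, v)
    expect_true(all(v[cls$labels == "low"] < f$midpoint))
    expect_true(all(v[cls$labels == "high"] > f$midpoint))
    un <- v[cls$labels == "unassigned"]
    expect_true(all(un >= f$midpoint - cls$window & un <= f$midpoint))
    expect_gte(cls$window_fraction, 0)
    expect_lte(cls$window_fraction, 0.05)
  }
})

test_that("the matrix screen recovers planted bimodal genes", {
  gen <- generate_expression(n_genes = 100, n_samples = 200, n_bimodal = 5,
                             delta_range = c(6, 6), pi_range = c(0.4, 0.5),
                             seed = 49)
  fit <- bisep(gen$expr, preset = "cell_line")
  found <- bimodal_genes(fit)
  expect_true(all(gen$truth$bimodal$gene %in% found))
  # the mixture index has a small false-positive rate on pure Gaussians
  # (the reason the stricter _low presets exist); it must stay small
  expect_lte(length(setdiff(found, gen$truth$bimodal$gene)), 2)
  expect_equal(nrow(fit$fits), 100)   # diagnostics kept for failing genes
  # every passing gene satisfies both thresholds and has a midpoint
  pass <- fit$fits[fit$fits$passes_filter, ]
  expect_true(all(pass$bi >= 0.7 & pass$delta >= 2.5))
  expect_true(all(is.finite(pass$midpoint)))
})

test_that("raising the BI threshold never adds genes", {
  gen <- generate_expression(n_genes = 60, n_samples = 150, n_bimodal = 20,
                             seed = 50)
  loose <- bimodal_genes(bisep(gen$expr, bi_min = 0.5, delta_min = 2.5))
  strict <- bimodal_genes(bisep(gen$expr, bi_min = 1.2, delta_min = 2.5))
  expect_true(all(strict %in% loose))
})

test_that("unimodal matrices yield empty screens under the small-panel preset", {
  # below ~200 samples the _low presets are the prescribed guard against
  # unimodal false positives
  gen <- generate_expression(n_genes = 40, n_samples = 150, n_bimodal = 0,
                             seed = 51)
  expect_length(bimodal_genes(bisep(gen$expr, preset = "cell_line_low")), 0)
})
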