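test_that("hpd finds the shortest interval and handles degenerate draws", {
  expect_equal(as.numeric(hpd(rep(3.5, 50))), c(3.5, 3.5))
  set.seed(1)
  z <- rnorm(1e6)
  iv <- hpd(z, 0.95)
  expect_equal(unname(iv["lower"]), -1.96, tolerance = 0.02)
  expect_equal(unname(iv["upper"]), 1.96, tolerance = 0.02)
  expect_error(hpd(z, 1.2), "mass")
  expect_error(hpd(1:5), "at least 10")
  # skewed draws: the HPD hugs the mode more tightly than equal tails
  g <- rgamma(1e5, shape = 2)
  ivg <- hpd(g, 0.9)
  qt <- quantile(g, c(0.05, 0.95))
  expect_lt(diff(unname(ivg)), unname(qt[2] - qt[1]))
})

test_that("hpd agrees with the coda implementation on large samples", {
  set.seed(2)
  for (x in list(rnorm(5e4), rgamma(5e4, 3), rbeta(5e4, 2, 5))) {
    ours <- hpd(x, 0.95)
    ref <- coda::HPDinterval(coda::mcmc(x), 0.95)
    expect_equal(unname(ours["lower"]), unname(ref[1, "lower"]), tolerance = 0.01)
    expect_equal(unname(ours["upper"]), unname(ref[1, "upper"]), tolerance = 0.01)
  }
})

test_that("hpd contains the median of unimodal samples", {
  set.seed(3)
  for (x in list(rnorm(2000), rgamma(2000, 4), rnorm(5000, 10, 0.1))) {
    iv <- hpd(x)
    md <- median(x)
    expect_true(iv["lower"] <= md && md <= iv["upper"])
  }
})

test_that("autocorrelation matches definitions and the AR(1) closed form", {
  set.seed(4)
  w <- rnorm(4000)
  expect_equal(autocorr(w, 0), 1)
  expect_lt(abs(autocorr(w, 5)), 3 / sqrt(4000))
  rho <- 0.8
  x <- as.numeric(arima.sim(list(ar = rho), 20000))
  expect_equal(autocorr(x, 1), rho, tolerance = 0.05)
  expect_error(autocorr(w, 4000), "lag")
})

test_that("time-series SE tracks iid and AR(1) asymptotics", {
  expect_equal(timeseries_se(rep(2, 400)), 0)
  set.seed(5)
  x <- rnorm(10000, 0, 2)
  expect_equal(timeseries_se(x), 2 / sqrt(10000), tolerance = 0.2)
  rho <- 0.9
  y <- as.numeric(arima.sim(list(ar = rho), 20000))
  infl <- timeseries_se(y) / (sd(y) / sqrt(length(y)))
  expect_equal(infl, sqrt((1 + rho) / (1 - rho)), tolerance = 0.3)
  expect_error(timeseries_se(rnorm(50)), "at least 100")
})

test_that("prediction scoring matches the textbook correlation formula", {
  set.seed(6)
  y <- rnorm(40); p <- 0.5 * y + rnorm(40)
  idx <- sample(40, 25)
  direct <- {
    a <- y[idx] - mean(y[idx]); b <- p[idx] - mean(p[idx])
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  expect_equal(score_predictions(y, p, idx), direct, tolerance = 1e-12)
  expect_equal(score_predictions(y, y), 1)
  expect_equal(score_predictions(y, -y + 3), -1)
  expect_warning(s <- score_predictions(y, rep(1, 40)), "zero variance")
  expect_true(is.na(s))
  expect_warning(s2 <- score_predictions(y[1:2], p[1:2], 1:2), "fewer than 3")
  expect_true(is.na(s2))
})

test_that("cross-validation partitions are disjoint and reproducible", {
  sim <- simulate_fw_table(n_lines = 25, n_envs = 4, seed = 14)
  res <- crossvalidate(sim$table, methods = c("OLS", "GibbsI"),
                       n_replicates = 2, seed = 9,
                       nIter = 600, burnIn = 200, thin = 2)
  expect_equal(nrow(res), 4)
  expect_true(all(c("train_cor", "valid_cor") %in% names(res)))
  masks <- attr(res, "masks")
  for (m in masks) {
    expect_equal(length(m), 25)
    expect_equal(length(intersect(m, setdiff(seq_len(100), m))), 0)
  }
  res2 <- crossvalidate(sim$table, methods = c("OLS", "GibbsI"),
                        n_replicates = 2, seed = 9,
                        nIter = 600, burnIn = 200, thin = 2)
  expect_identical(res, res2)
  expect_error(crossvalidate(sim$table, methods = "GibbsA", n_replicates = 1),
               "requires")
})

test_that("fitted_lines exposes intercepts, slopes and exact cell means", {
  sim <- simulate_fw_table(n_lines = 6, n_envs = 3, var_e = 0, seed = 15)
  rec <- sim$table$records
  fit <- fw(rec$y, rec$VAR, rec$ENV, method = "OLS")
  fl <- fitted_lines(fit)
  expect_equal(nrow(fl$lines), 6)
  # slope of a b = 0 variety is exactly 1
  fit0 <- fit; fit0$b[, 1] <- 0
  expect_true(all(fitted_lines(fit0)$lines$slope == 1))
  # cell means equal a brute-force group-by average
  oracle <- tapply(rec$y, paste(rec$VAR, rec$ENV), mean)
  got <- setNames(fl$cells$cell_mean, paste(fl$cells$VAR, fl$cells$ENV))
  expect_equal(unname(got[names(oracle)]), as.vector(oracle), tolerance = 1e-12)
  # noise-free data: points fall exactly on the fitted lines
  ints <- setNames(fl$lines$intercept, fl$lines$VAR)
  slps <- setNames(fl$lines$slope, fl$lines$VAR)
  onln <- ints[fl$cells$VAR] + slps[fl$cells$VAR] * fl$cells$h
  expect_equal(unname(onln), fl$cells$cell_mean, tolerance = 1e-8)
})

test_that("sample store summaries and persistence round-trip", {
  tab <- rand_table(6, 3, seed = 16)
  rec <- tab$records
  pre <- file.path(tempdir(), "fwtest_")
  fit <- fw(rec$y, rec$VAR, rec$ENV, nIter = 1500, burnIn = 500, thin = 2,
            seed = 4, saveAt = pre)
  back <- read_samples(pre)
  expect_equal(back$chains[[1]], fit$samples$chains[[1]], tolerance = 1e-12)
  expect_equal(back$config$nIter, 1500)
  sm <- summary(fit$samples)
  expect_true(all(c("mean", "ts_se", "hpd_lower") %in% names(sm)))
  expect_equal(nrow(sm), ncol(fit$samples$chains[[1]]))
})
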