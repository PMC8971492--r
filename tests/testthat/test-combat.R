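test_that("standardization yields mean ~0, variance ~1 per marker", {
  set.seed(41)
  Y <- matrix(rnorm(400 * 6, 3, 0.8), 400, 6)
  batches <- rep(c("b1", "b2"), each = 200)
  std <- fit_standardization(Y, batches)
  expect_true(all(abs(colMeans(std$Z)) < 0.05))
  expect_true(all(abs(apply(std$Z, 2, sd) - 1) < 0.05))
  expect_equal(unname(std$alpha_hat), unname(colMeans(Y)),
               tolerance = 0.02)
})

test_that("a pure additive batch shift appears in gamma_hat", {
  set.seed(42)
  y1 <- matrix(rnorm(100 * 4, 2, 1), 100, 4)
  Y <- rbind(y1, y1 + 0.5)
  batches <- rep(c("b1", "b2"), each = 100)
  std <- fit_standardization(Y, batches)
  eff <- cytofuse:::estimate_batch_effects(std$Z, std$design_info)
  gap <- eff$gamma_hat["b2", ] - eff$gamma_hat["b1", ]
  expect_equal(unname(gap), unname(0.5 / std$sigma_hat),
               tolerance = 1e-10)
})

test_that("standardization flags degenerate designs", {
  Y <- matrix(rnorm(40), 20, 2)
  expect_error(fit_standardization(Y, rep("b1", 20)), "2 batches")
  expect_error(fit_standardization(Y, c("b1", rep("b2", 19))),
               class = "cytofuse_small_batch_error")
  conf <- rep(c("b1", "b2"), each = 10)
  expect_error(fit_standardization(Y, conf, covariates = conf),
               class = "cytofuse_confounding_error")
})

test_that("hyperprior moments match hand computations", {
  # gamma_bar/tau2: across-marker mean and n-1 variance
  pr <- estimate_hyperpriors(gamma_hat = rbind(b1 = c(0.1, 0.3)),
                             delta2_hat = rbind(b1 = c(1, 3)))
  expect_equal(unname(pr$gamma_bar), 0.2)
  expect_equal(unname(pr$tau2), 0.02)
  # inverse-gamma moments: m = 1, s2 = 1 -> a = 3, b = 2
  pr2 <- estimate_hyperpriors(
    gamma_hat = rbind(b1 = c(0, 0, 0)),
    delta2_hat = rbind(b1 = c(0, 1, 2)))  # mean 1, n-1 variance 1
  expect_equal(unname(pr2$a_prior), 3)
  expect_equal(unname(pr2$b_prior), 2)
  expect_error(estimate_hyperpriors(rbind(c(1)), rbind(c(1))),
               ">= 2 markers")
})

test_that("zero spread of delta2_hat disables scale shrinkage", {
  set.seed(43)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  batches <- rep(c("b1", "b2"), each = 30)
  std <- fit_standardization(Y, batches)
  eff <- cytofuse:::estimate_batch_effects(std$Z, std$design_info)
  eff$delta2_hat[] <- 0.7  # force zero across-marker spread
  pr <- estimate_hyperpriors(eff$gamma_hat, eff$delta2_hat)
  expect_true(all(pr$degenerate_scale))
  sh <- shrink_parametric(std$Z, std$design_info, eff, pr)
  expect_equal(sh$delta2_star, eff$delta2_hat)
})

test_that("shrinkage limits behave analytically", {
  set.seed(44)
  Y <- matrix(rnorm(80 * 5, 1, 1), 80, 5)
  batches <- rep(c("b1", "b2"), each = 40)
  std <- fit_standardization(Y, batches)
  eff <- cytofuse:::estimate_batch_effects(std$Z, std$design_info)
  pr <- estimate_hyperpriors(eff$gamma_hat, eff$delta2_hat)
  # tau2 -> infinity: flat location prior, gamma_star -> gamma_hat
  pr_flat <- pr
  pr_flat$tau2[] <- 1e12
  sh <- shrink_parametric(std$Z, std$design_info, eff, pr_flat)
  expect_equal(sh$gamma_star, eff$gamma_hat, tolerance = 1e-5)
  # tau2 = 0: full shrinkage, gamma_star == gamma_bar exactly
  pr_zero <- pr
  pr_zero$tau2[] <- 0
  sh0 <- shrink_parametric(std$Z, std$design_info, eff, pr_zero)
  for (i in 1:2) {
    expect_equal(unname(sh0$gamma_star[i, ]),
                 rep(unname(pr_zero$gamma_bar[i]), 5))
  }
})

test_that("shrinkage pulls gamma_star between gamma_hat and gamma_bar", {
  set.seed(45)
  for (rep in 1:5) {
    Y <- matrix(rnorm(120 * 8, 2, 1), 120, 8) +
      outer(rep(c(0, 0.4, -0.3), each = 40), rep(1, 8))
    batches <- rep(paste0("b", 1:3), each = 40)
    std <- fit_standardization(Y, batches)
    eff <- cytofuse:::estimate_batch_effects(std$Z, std$design_info)
    pr <- estimate_hyperpriors(eff$gamma_hat, eff$delta2_hat)
    sh <- shrink_parametric(std$Z, std$design_info, eff, pr)
    for (i in 1:3) {
      expect_true(all(abs(sh$gamma_star[i, ] - pr$gamma_bar[i]) <=
                        abs(eff$gamma_hat[i, ] - pr$gamma_bar[i]) + 1e-12))
    }
  }
})

test_that("identity adjustment returns the input exactly", {
  set.seed(46)
  Y <- matrix(rnorm(50 * 4, 2), 50, 4)
  batches <- rep(c("b1", "b2"), each = 25)
  std <- fit_standardization(Y, batches)
  sh <- list(gamma_star = matrix(0, 2, 4), delta2_star = matrix(1, 2, 4))
  Y_star <- adjust_cluster(std$Z, std$design_info, sh, std$sigma_hat,
                           std$stand_mean)
  expect_equal(Y_star, Y, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean-only mode shifts means but preserves batch variances", {
  set.seed(47)
  y1 <- matrix(rnorm(200 * 5, 2, 1), 200, 5)
  y2 <- matrix(rnorm(200 * 5, 2.6, 1.4), 200, 5)
  Y <- rbind(y1, y2)
  batches <- rep(c("b1", "b2"), each = 200)
  out <- suppressWarnings(combat_cluster(Y, batches, mean_only = TRUE))
  for (m in 1:5) {
    expect_equal(sd(out[batches == "b1", m]), sd(y1[, m]),
                 tolerance = 1e-6)
    expect_equal(sd(out[batches == "b2", m]), sd(y2[, m]),
                 tolerance = 1e-6)
  }
  expect_lt(max(abs(colMeans(out[batches == "b1", ]) -
                      colMeans(out[batches == "b2", ]))),
            max(abs(colMeans(y1) - colMeans(y2))))
})

test_that("single-batch clusters pass through unchanged with a warning", {
  Y <- matrix(rnorm(30), 10, 3)
  expect_warning(out <- combat_cluster(Y, rep("b1", 10)), "single batch")
  attr(out, "adjust_warnings") <- NULL
  expect_identical(unname(out), unname(Y))
})

test_that("clusters with an undersized batch pass through unchanged", {
  Y <- matrix(rnorm(33), 11, 3)
  expect_warning(out <- combat_cluster(Y, c(rep("b1", 10), "b2")),
                 "< 2 cells")
  attr(out, "adjust_warnings") <- NULL
  expect_identical(unname(out), unname(Y))
})

test_that("adjustment completes with finite output at eight cells", {
  set.seed(48)
  Y <- matrix(rnorm(8 * 6, 2), 8, 6)
  out <- combat_cluster(Y, rep(c("b1", "b2"), each = 4))
  expect_true(all(is.finite(out)))
  expect_identical(dim(out), dim(Y))
})

test_that("a confounded covariate is dropped with a warning", {
  set.seed(49)
  Y <- matrix(rnorm(40 * 4, 1), 40, 4)
  batches <- rep(c("b1", "b2"), each = 20)
  expect_warning(out <- combat_cluster(Y, batches, covariates = batches),
                 "confounded")
  expect_equal(out, suppressWarnings(combat_cluster(Y, batches)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identically distributed batches are adjusted near-identically", {
  set.seed(50)
  Y <- matrix(rnorm(1000 * 8, 2, 1), 1000, 8)
  batches <- rep(c("b1", "b2"), each = 500)
  out <- combat_cluster(Y, batches)
  expect_lt(mean(abs(out - Y)), 0.05)
})

test_that("a simulated condition effect survives correction", {
  set.seed(51)
  n <- 400
  batches <- rep(c("b1", "b2"), each = n / 2)
  cond <- rep(rep(c("HD", "CLL"), each = n / 4), 2)
  Y <- matrix(rnorm(n * 6, 2, 0.5), n, 6)
  Y[batches == "b2", ] <- Y[batches == "b2", ] + 0.8   # batch effect
  Y[cond == "CLL", 1] <- Y[cond == "CLL", 1] + 1.0     # biology
  out <- combat_cluster(Y, batches, covariates = cond)
  effect <- mean(out[cond == "CLL", 1]) - mean(out[cond == "HD", 1])
  expect_lt(abs(effect - 1.0), 0.1)
  # batch effect removed
  gap <- colMeans(out[batches == "b2", ]) - colMeans(out[batches == "b1", ])
  expect_true(all(abs(gap) < 0.05))
})

test_that("cluster adjustment matches the reference implementation", {
  skip_if_not_installed("sva")
  set.seed(52)
  Y <- matrix(rnorm(120 * 10, 2, 1), 120, 10)
  batches <- sample(rep(c("b1", "b2", "b3"), 40))
  cov <- sample(c("HD", "CLL"), 120, replace = TRUE)
  mine <- combat_cluster(Y, batches, covariates = cov)
  ref <- t(suppressMessages(sva::ComBat(
    t(Y), batch = factor(batches),
    mod = model.matrix(~factor(cov)))))
  expect_lt(max(abs(mine - ref)), 1e-6)
})
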