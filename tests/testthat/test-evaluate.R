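test_that("binning produces normalized, clipped histograms", {
  h <- bin_distribution(0.42, binsize = 0.1, range = c(0, 1))
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 1)
  # hand example: [0.05, 0.15, 0.15] over [0,1]
  h2 <- bin_distribution(c(0.05, 0.15, 0.15), 0.1, c(0, 1))
  expect_equal(h2[1:2], c(1 / 3, 2 / 3))
  expect_equal(sum(h2), 1, tolerance = 1e-12)
  # out-of-range values land in the end bins
  h3 <- bin_distribution(c(-5, 5), 0.1, c(0, 1))
  expect_equal(h3[1], 0.5)
  expect_equal(h3[10], 0.5)
  expect_error(bin_distribution(numeric(0), 0.1, c(0, 1)), "no values")
  set.seed(61)
  for (rep in 1:20) {
    h <- bin_distribution(rnorm(50), 0.1, c(-4, 4))
    expect_equal(sum(h), 1, tolerance = 1e-12)
  }
})

test_that("1-D EMD matches exhaustive small-instance transport", {
  z <- rep(0, 11)
  p <- replace(z, 1, 1)
  q <- replace(z, 11, 1)
  expect_equal(emd_1d(p, q), 10)       # point masses 10 bins apart
  expect_equal(emd_1d(p, p), 0)
  expect_equal(emd_1d(c(.5, .5, 0), c(0, .5, .5)), 1)
  expect_error(emd_1d(c(1, 0), c(1, 0, 0)), "bin structure")
  expect_error(emd_1d(c(0.4, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("1-D EMD is a metric on random histograms", {
  set.seed(71)
  rhist <- function() {
    h <- rexp(8)
    h / sum(h)
  }
  for (rep in 1:30) {
    p <- rhist(); q <- rhist(); r <- rhist()
    expect_gte(emd_1d(p, q), 0)
    expect_equal(emd_1d(p, q), emd_1d(q, p))
    expect_lte(emd_1d(p, r), emd_1d(p, q) + emd_1d(q, r) + 1e-12)
    expect_equal(emd_1d(p, p), 0)
  }
})

test_that("EMD reduction reproduces the defining identities", {
  # hand example: surviving records before [4,3], after [1,0]
  tab <- data.frame(emd_before = c(4, 3), emd_after = c(1, 0))
  expect_equal(emd_reduction_score(tab, 2)$reduction, 6 / 7)
  # complete elimination -> 1; identity -> 0
  tab1 <- data.frame(emd_before = c(5, 3.2), emd_after = c(0, 0))
  expect_equal(emd_reduction_score(tab1, 2)$reduction, 1)
  tab0 <- data.frame(emd_before = c(5, 3.2), emd_after = c(5, 3.2))
  expect_equal(emd_reduction_score(tab0, 2)$reduction, 0)
  # scale consistency: duplicating every record changes nothing
  expect_equal(emd_reduction_score(rbind(tab, tab), 2)$reduction, 6 / 7)
  # the filter drops records where both are < threshold
  mixed <- data.frame(emd_before = c(4, 1.5), emd_after = c(1, 1.9))
  expect_equal(emd_reduction_score(mixed, 2)$reduction, 3 / 4)
  expect_equal(emd_reduction_score(mixed, 2)$n_used, 1L)
  # an empty surviving set is flagged undefined, not zero
  small <- data.frame(emd_before = 0.5, emd_after = 0.1)
  res <- emd_reduction_score(small, 2)
  expect_false(res$defined)
  expect_true(is.na(res$reduction))
})

test_that("MAD score reproduces the defining identities", {
  tab <- data.frame(mad_before = c(0.5, 0.7), mad_after = c(0.4, 0.9))
  expect_equal(mad_score_from_table(tab), 0.15)
  # permutation invariance
  expect_equal(mad_score_from_table(tab[2:1, ]), 0.15)
  # identity correction -> 0
  tab0 <- data.frame(mad_before = c(0.3, 0.8), mad_after = c(0.3, 0.8))
  expect_equal(mad_score_from_table(tab0), 0)
})

test_that("evaluate_emd and evaluate_mad work node- and batch-wise", {
  sim <- quick_sim(cells_per_batch = 800, seed = 73)
  shift <- matrix(0, 2, 15, dimnames = list(c("batch1", "batch2"),
                                            markers(sim$dataset)))
  shift["batch2", ] <- 0.6
  distorted <- apply_batch_effects(sim$dataset, shift = shift)
  labels <- create_partition(distorted, correction_config(seed = 79))
  ev <- evaluate_emd(distorted, distorted, labels)
  expect_true(ev$defined)
  expect_equal(ev$reduction, 0)  # after == before
  expect_true(all(ev$table$emd_before >= 0))
  expect_true(all(ev$table$batch_i < ev$table$batch_j))
  mad <- evaluate_mad(distorted, distorted, labels)
  expect_equal(mad$score, 0)
  # scaling one batch's marker doubles its MAD: |delta| = mad_before
  after <- distorted
  b2 <- batch_ids(distorted) == "batch2"
  after$exprs[b2, 1] <- 2 * after$exprs[b2, 1]
  mad2 <- evaluate_mad(distorted, after, labels)
  rec <- mad2$table[mad2$table$marker == markers(distorted)[1] &
                      mad2$table$batch == "batch2", ]
  expect_equal(abs(rec$mad_before - rec$mad_after), rec$mad_before,
               tolerance = 1e-12)
})

test_that("misaligned evaluation inputs are rejected", {
  sim <- quick_sim(cells_per_batch = 100, seed = 83)
  labels <- rep(1L, nrow(sim$dataset$exprs))
  short <- subset_cells(sim$dataset, cells = 1:50)
  expect_error(evaluate_emd(sim$dataset, short, labels), "aligned")
  expect_error(evaluate_emd(sim$dataset, sim$dataset, labels[-1]),
               "labels")
})

test_that("the evaluation protocol trains on corrected data", {
  sim <- quick_sim(cells_per_batch = 600, seed = 89)
  res <- correct(sim$dataset, correction_config(seed = 97))
  ev <- evaluate_correction(sim$dataset, res$dataset, seed = 101)
  # labels shared by both datasets, derived from the corrected one
  direct <- assign_nodes(train_som(res$dataset$exprs, seed = 101),
                         res$dataset$exprs)
  expect_identical(ev$labels, direct)
  expect_true(is.finite(ev$mad$score))
})
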