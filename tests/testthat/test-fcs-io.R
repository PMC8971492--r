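test_that("FCS write/read round-trips matrices and channel names", {
  set.seed(11)
  # values representable exactly in 32-bit floats survive bit-for-bit
  vals <- matrix(sample(0:4095, 15) / 8, 5, 3)
  s <- raw_sample(vals, c("CD3", "CD8", "CD45"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(s, path)
  back <- read_fcs(path)
  expect_identical(dim(back$events), c(5L, 3L))
  expect_identical(back$channel_names, c("CD3", "CD8", "CD45"))
  expect_identical(unname(back$events), unname(vals))
})

test_that("FCS round-trip preserves shape and stain names at scale", {
  set.seed(12)
  vals <- matrix(rexp(1000 * 12, 1 / 50), 1000, 12)
  s <- raw_sample(vals, paste0("ch", 1:12),
                  marker_names = paste0("stain", 1:12))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(s, path)
  back <- read_fcs(path)
  expect_equal(nrow(back$events), 1000)
  expect_length(back$channel_names, 12)
  expect_identical(back$marker_names, paste0("stain", 1:12))
  # float32 storage: agreement to relative 1e-6
  expect_equal(unname(back$events), unname(vals), tolerance = 1e-6)
})

test_that("zero-event FCS files are valid and round-trip", {
  s <- raw_sample(matrix(numeric(0), 0, 2), c("a", "b"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(s, path)
  back <- read_fcs(path)
  expect_equal(nrow(back$events), 0)
  expect_identical(back$channel_names, c("a", "b"))
})

test_that("write_fcs refuses non-finite values (imputation sentinels)", {
  # construct an NA-bearing dataset through the merge path
  a <- make_dataset(matrix(rnorm(20), 10, 2,
                           dimnames = list(NULL, c("x", "y"))), rep("b1", 10))
  b <- make_dataset(matrix(rnorm(20), 10, 2,
                           dimnames = list(NULL, c("y", "z"))), rep("b2", 10))
  plan <- find_marker_overlap(markers(a), markers(b), grid_x = 2,
                              grid_y = 2, min_donors = 50, seed = 1)
  merged <- impute_across_panels(a, b, plan)  # < 50 donors -> NA
  expect_true(anyNA(merged$exprs))
  expect_error(write_fcs(merged, withr::local_tempfile(fileext = ".fcs")),
               "non-finite")
})

test_that("read_fcs rejects missing and non-FCS files", {
  expect_error(read_fcs(file.path(tempdir(), "nope.fcs")), "not found")
  bad <- withr::local_tempfile(fileext = ".fcs")
  writeLines("this is not an fcs file padded to be long enough........",
             bad)
  expect_error(read_fcs(bad), "FCS")
})

test_that("derandomization inverts uniform(-1,0) count randomization", {
  set.seed(21)
  for (rep in 1:5) {
    counts <- matrix(rpois(200, 30), 20, 10)
    noisy <- counts - matrix(runif(200), 20, 10)
    expect_identical(derandomize(noisy), counts + 0)
  }
  expect_identical(derandomize(matrix(c(4.3, 4, 0), 1, 3)),
                   matrix(c(5, 4, 0), 1, 3))
  expect_error(derandomize(matrix(c(-1.2, 3), 1, 2)), "randomized")
})

test_that("arcsinh transform is monotone, invertible, zero-preserving", {
  x <- matrix(c(0, 1, 10, 1000, -5), 1, 5)
  for (cf in c(5, 150, 6000)) {
    y <- arcsinh_transform(x, cf)
    expect_equal(y[1], 0)
    expect_true(all(diff(order(x)) == diff(order(y))))
    expect_equal(inverse_arcsinh(y, cf), x, tolerance = 1e-12)
  }
  expect_error(arcsinh_transform(x, 0), "positive")
  expect_error(arcsinh_transform(x, -3), "positive")
})

test_that("assemble_dataset concatenates, canonicalizes and labels", {
  set.seed(31)
  ev1 <- matrix(rexp(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  ev2 <- matrix(rexp(300), 100, 3, dimnames = list(NULL, c("c", "a", "b")))
  s1 <- raw_sample(ev1, colnames(ev1))
  s2 <- raw_sample(ev2, colnames(ev2))
  meta <- data.frame(sample_id = c("s1", "s2"), batch_id = c("b1", "b2"),
                     condition = c("HD", "CLL"))
  ds <- assemble_dataset(list(s1 = s1, s2 = s2), meta, cofactor = 5)
  expect_equal(nrow(ds$exprs), 200)
  expect_identical(markers(ds), c("a", "b", "c"))
  expect_identical(unique(batch_ids(ds)), c("b1", "b2"))
  expect_equal(unname(ds$exprs[101:200, "a"]),
               unname(asinh(ev2[, "a"] / 5)))
  # channel order canonicalization: permuting columns changes nothing
  s2p <- raw_sample(ev2[, c("b", "c", "a")], c("b", "c", "a"))
  ds_p <- assemble_dataset(list(s1 = s1, s2 = s2p), meta, cofactor = 5)
  expect_identical(ds$exprs, ds_p$exprs)
  # errors: unknown sample, disjoint channels
  expect_error(assemble_dataset(list(sX = s1), meta), "missing")
  s3 <- raw_sample(ev1, c("x", "y", "z"))
  expect_error(assemble_dataset(list(s1 = s1, s2 = s3), meta), "channel")
})

test_that("expression tables ingest as raw samples", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(CD3 = c(1.5, 2.5), CD19 = c(0.5, 30))
  write.csv(df, path, row.names = FALSE)
  s <- read_expression_table(path)
  expect_identical(s$channel_names, c("CD3", "CD19"))
  expect_equal(unname(s$events), unname(as.matrix(df)))
})

test_that("dataset CSV round-trips through read_dataset_csv", {
  sim <- quick_sim(cells_per_batch = 60, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(sim$dataset, path)
  back <- read_dataset_csv(path)
  expect_identical(markers(back), markers(sim$dataset))
  expect_identical(batch_ids(back), batch_ids(sim$dataset))
  expect_equal(back$exprs, sim$dataset$exprs, tolerance = 1e-12)
})
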