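# Small in-code fixtures shared across test files.

# dataset with explicit values and batch labels, one sample per batch
make_dataset <- function(values, batches, condition = NULL) {
  values <- as.matrix(values)
  meta <- data.frame(sample_id = paste0("s_", batches),
                     batch_id = as.character(batches),
                     stringsAsFactors = FALSE)
  if (!is.null(condition)) meta$condition <- as.character(condition)
  cyto_dataset(values, meta)
}

# two well-separated Gaussian blobs (populations), optional batch shift
make_blobs <- function(n_per = 200, n_markers = 5, sep = 10, sd = 0.2,
                       seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_per * n_markers, 0, sd), n_per, n_markers)
  b <- matrix(rnorm(n_per * n_markers, sep, sd), n_per, n_markers)
  x <- rbind(a, b)
  colnames(x) <- paste0("m", seq_len(n_markers))
  list(values = x, population = rep(1:2, each = n_per))
}

# quick simulated dataset for pipeline tests (modest size)
quick_sim <- function(cells_per_batch = 1500, seed = 99, ...) {
  simulate_dataset(simulation_config(cells_per_batch = cells_per_batch,
                                     seed = seed, ...))
}

expect_no_na <- function(x) expect_false(anyNA(x))

# two panels sharing three overlap markers; panel B carries two extra
# markers correlated at rho within every node
make_panels <- function(n = 1000, rho = 0.9, seed = 303) {
  set.seed(seed)
  shared_a <- matrix(rnorm(n * 3, 2, 1), n, 3,
                     dimnames = list(NULL, c("o1", "o2", "o3")))
  shared_b <- matrix(rnorm(n * 3, 2, 1), n, 3,
                     dimnames = list(NULL, c("o1", "o2", "o3")))
  u <- rnorm(n)
  extra <- cbind(e1 = u, e2 = rho * u + sqrt(1 - rho^2) * rnorm(n))
  a <- make_dataset(shared_a, rep("p1", n))
  b <- make_dataset(cbind(shared_b, extra), rep("p2", n))
  list(a = a, b = b)
}
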