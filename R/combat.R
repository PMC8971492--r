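#' @useDynLib cytofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# classed error helpers so callers can distinguish design problems
stop_confounded <- function(msg) {
  stop(errorCondition(msg, class = c("cytofuse_confounding_error",
                                     "error", "condition")))
}
stop_small_batch <- function(msg) {
  stop(errorCondition(msg, class = c("cytofuse_small_batch_error",
                                     "error", "condition")))
}

# design matrix: batch indicators first, then covariate dummy columns
# (any all-ones column from the covariate block is dropped, since the
# batch indicators already span the intercept)
build_design <- function(batches, covariates = NULL) {
  fb <- factor(batches)
  if (nlevels(fb) < 2) {
    stop("need at least 2 batches", call. = FALSE)
  }
  batchmod <- stats::model.matrix(~ -1 + fb)
  design <- batchmod
  if (!is.null(covariates)) {
    fc <- factor(covariates)
    mod <- stats::model.matrix(~fc)
    keep <- !apply(mod, 2, function(x) all(x == 1))
    design <- cbind(batchmod, mod[, keep, drop = FALSE])
  }
  n_batch <- nlevels(fb)
  if (qr(design)$rank < ncol(design)) {
    stop_confounded(paste0(
      "covariate is confounded with batch within this set of cells; ",
      "design matrix is rank-deficient"))
  }
  list(design = design, n_batch = n_batch, batch_factor = fb,
       batch_sizes = as.vector(table(fb)))
}

#' Standardize a cluster's expression for empirical Bayes fitting
#'
#' First stage of the location/scale batch model. Fits marker-wise least
#' squares on batch indicators plus optional condition covariates, forms
#' the batch-size-weighted grand mean `alpha_hat`, the pooled residual
#' standard deviation `sigma_hat` (1/n denominator), and the standardized
#' matrix `Z = (Y - alpha_hat - X beta_hat) / sigma_hat`. Markers with
#' zero pooled variance are flagged and their `Z` column set to zero.
#'
#' @param Y Numeric matrix, cells x markers (ArcSinh scale).
#' @param batches Per-cell batch labels (>= 2 batches, each >= 2 cells).
#' @param covariates Optional per-cell condition labels to preserve.
#' @return List with `alpha_hat`, `beta_hat`, `sigma_hat`, `Z`,
#'   `stand_mean` (the per-cell baseline `alpha_hat + X beta_hat`),
#'   `design` info and `zero_variance` (logical per marker).
#' @export
fit_standardization <- function(Y, batches, covariates = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(batches)) {
    stop("batches must have one label per row of Y", call. = FALSE)
  }
  info <- build_design(batches, covariates)
  if (any(info$batch_sizes < 2)) {
    stop_small_batch(paste0(
      "each batch needs >= 2 cells for a scale estimate; sizes: ",
      paste(info$batch_sizes, collapse = ", ")))
  }
  X <- info$design
  n <- nrow(Y)
  B_hat <- solve(crossprod(X), crossprod(X, Y))
  w <- info$batch_sizes / n
  alpha_hat <- drop(w %*% B_hat[seq_len(info$n_batch), , drop = FALSE])
  var_pooled <- colMeans((Y - X %*% B_hat)^2)
  sigma_hat <- sqrt(var_pooled)
  Xcov <- X
  Xcov[, seq_len(info$n_batch)] <- 0
  stand_mean <- matrix(alpha_hat, n, ncol(Y), byrow = TRUE) + Xcov %*% B_hat
  zero_var <- sigma_hat == 0
  denom <- ifelse(zero_var, Inf, sigma_hat)
  Z <- (Y - stand_mean) / matrix(denom, n, ncol(Y), byrow = TRUE)
  beta_hat <- B_hat[-seq_len(info$n_batch), , drop = FALSE]
  list(alpha_hat = alpha_hat, beta_hat = beta_hat, sigma_hat = sigma_hat,
       Z = Z, stand_mean = stand_mean, design_info = info,
       zero_variance = zero_var)
}

# per-batch location/scale estimates on the standardized scale
estimate_batch_effects <- function(Z, design_info) {
  bd <- design_info$design[, seq_len(design_info$n_batch), drop = FALSE]
  gamma_hat <- solve(crossprod(bd), crossprod(bd, Z))
  fb <- design_info$batch_factor
  delta2_hat <- t(vapply(levels(fb), function(b) {
    apply(Z[fb == b, , drop = FALSE], 2, stats::var)
  }, numeric(ncol(Z))))
  rownames(gamma_hat) <- rownames(delta2_hat) <- levels(fb)
  list(gamma_hat = gamma_hat, delta2_hat = delta2_hat)
}

#' Method-of-moments hyperprior estimates
#'
#' Pools information across markers: per batch, the location effects
#' `gamma_hat` are modeled as Normal(`gamma_bar`, `tau2`) and the scale
#' effects `delta2_hat` as Inverse-Gamma(`a_prior`, `b_prior`), with all
#' four hyperparameters estimated by matching across-marker moments
#' (`a = (2 s2 + m^2)/s2`, `b = (m s2 + m^3)/s2` for mean `m` and
#' variance `s2` of `delta2_hat`).
#'
#' @param gamma_hat,delta2_hat Matrices, batches x markers (from the
#'   standardized fit).
#' @return List with per-batch `gamma_bar`, `tau2`, `a_prior`, `b_prior`
#'   and `degenerate_scale` (TRUE where `delta2_hat` has zero spread
#'   across markers, in which case scale shrinkage must be skipped).
#' @export
estimate_hyperpriors <- function(gamma_hat, delta2_hat) {
  gamma_hat <- as.matrix(gamma_hat)
  delta2_hat <- as.matrix(delta2_hat)
  if (ncol(gamma_hat) < 2) {
    stop("hyperprior moments need >= 2 markers; use mean-only or ",
         "unshrunken adjustment for a single marker", call. = FALSE)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta2_hat)
  s2 <- apply(delta2_hat, 1, stats::var)
  degenerate <- s2 == 0
  a_prior <- ifelse(degenerate, NA_real_, (2 * s2 + m^2) / s2)
  b_prior <- ifelse(degenerate, NA_real_, (m * s2 + m^3) / s2)
  list(gamma_bar = gamma_bar, tau2 = tau2, a_prior = a_prior,
       b_prior = b_prior, degenerate_scale = degenerate)
}

#' Parametric empirical Bayes shrinkage
#'
#' Iterates the coupled posterior updates for each batch: the location
#' adjustment `gamma_star` is the precision-weighted average of
#' `gamma_hat` and the prior mean `gamma_bar`, and the scale adjustment
#' `delta2_star` is the inverse-gamma posterior mode computed from
#' residuals about the current `gamma_star`. Iteration stops when the
#' maximum relative change drops below `conv` (default 1e-4), matching
#' the published algorithm's stopping rule; batches whose scale prior is
#' degenerate (zero spread of `delta2_hat` across markers) keep
#' `delta2_star = delta2_hat`.
#'
#' @param Z Standardized matrix, cells x markers.
#' @param design_info Design description from [fit_standardization()].
#' @param effects List with `gamma_hat`, `delta2_hat`.
#' @param priors List from [estimate_hyperpriors()].
#' @param mean_only If TRUE, shrink locations only and fix
#'   `delta2_star = 1`.
#' @param conv Convergence tolerance on the relative change.
#' @param max_iter Iteration cap (error past it).
#' @return List with matrices `gamma_star`, `delta2_star`
#'   (batches x markers) and `converged`.
#' @export
shrink_parametric <- function(Z, design_info, effects, priors,
                              mean_only = FALSE, conv = 1e-4,
                              max_iter = 500) {
  fb <- design_info$batch_factor
  g_hat <- effects$gamma_hat
  d2_hat <- effects$delta2_hat
  n_batch <- nrow(g_hat)
  p <- ncol(g_hat)
  gamma_star <- matrix(NA_real_, n_batch, p, dimnames = dimnames(g_hat))
  delta2_star <- gamma_star
  for (i in seq_len(n_batch)) {
    t2 <- priors$tau2[i]
    g_bar <- priors$gamma_bar[i]
    if (mean_only) {
      gamma_star[i, ] <- (t2 * 1 * g_hat[i, ] + 1 * g_bar) / (t2 * 1 + 1)
      delta2_star[i, ] <- 1
      next
    }
    if (priors$degenerate_scale[i]) {
      # flat/degenerate scale prior: no information to shrink with
      gamma_star[i, ] <- if (t2 == 0) rep(g_bar, p) else g_hat[i, ]
      delta2_star[i, ] <- d2_hat[i, ]
      next
    }
    Zb <- Z[fb == levels(fb)[i], , drop = FALSE]
    n_i <- nrow(Zb)
    a <- priors$a_prior[i]
    b <- priors$b_prior[i]
    g_old <- g_hat[i, ]
    d_old <- d2_hat[i, ]
    change <- 1
    iter <- 0L
    g_new <- g_old
    d_new <- d_old
    while (change > conv) {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("empirical Bayes shrinkage did not converge in ", max_iter,
             " iterations (last change ", signif(change, 3), ")",
             call. = FALSE)
      }
      g_new <- (t2 * n_i * g_hat[i, ] + d_old * g_bar) /
        (t2 * n_i + d_old)
      sum2 <- colSums((Zb - matrix(g_new, n_i, p, byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + b) / (n_i / 2 + a - 1)
      change <- max(abs(g_new - g_old) / g_old,
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
    }
    gamma_star[i, ] <- g_new
    delta2_star[i, ] <- d_new
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       converged = TRUE)
}

#' Apply the fitted adjustment
#'
#' Removes the shrunken batch location/scale effects on the standardized
#' scale and maps back to the expression scale, restoring the baseline
#' (grand mean plus covariate effects):
#' `Y* = sigma_hat * (Z - gamma_star) / sqrt(delta2_star) + stand_mean`.
#'
#' @param Z Standardized matrix.
#' @param design_info Design description.
#' @param shrunken List with `gamma_star`, `delta2_star`.
#' @param sigma_hat Pooled per-marker standard deviations.
#' @param stand_mean Per-cell baseline matrix.
#' @return Adjusted matrix `Y_star`, cells x markers.
#' @export
adjust_cluster <- function(Z, design_info, shrunken, sigma_hat,
                           stand_mean) {
  if (any(shrunken$delta2_star <= 0, na.rm = TRUE)) {
    stop("internal error: non-positive delta2_star", call. = FALSE)
  }
  fb <- design_info$batch_factor
  p <- ncol(Z)
  out <- Z
  for (i in seq_along(levels(fb))) {
    idx <- fb == levels(fb)[i]
    n_i <- sum(idx)
    out[idx, ] <- (Z[idx, , drop = FALSE] -
                     matrix(shrunken$gamma_star[i, ], n_i, p,
                            byrow = TRUE)) /
      matrix(sqrt(shrunken$delta2_star[i, ]), n_i, p, byrow = TRUE)
  }
  out * matrix(sigma_hat, nrow(Z), p, byrow = TRUE) + stand_mean
}

#' Empirical Bayes batch adjustment of one cluster
#'
#' Full location/scale adjustment of the cells in one SOM cluster:
#' standardization, per-batch effect estimates, method-of-moments
#' hyperpriors, parametric shrinkage and back-transformation. Robust to
#' the degenerate situations that arise in small partitions — the method
#' operates down to eight cells total (two batches of four):
#' \itemize{
#'   \item a single batch present: returned unchanged with a warning;
#'   \item any batch with fewer than 2 cells: returned unchanged (no
#'     scale estimate is defined) with a warning;
#'   \item covariate confounded with batch within the cluster: retried
#'     without the covariate, with a warning;
#'   \item markers constant within some batch: passed through unadjusted
#'     (the remaining markers are adjusted).
#' }
#' Warnings are recorded in the `"adjust_warnings"` attribute of the
#' result as well as emitted.
#'
#' @param Y Numeric matrix, cells x markers, one SOM cluster's cells.
#' @param batches Per-cell batch labels.
#' @param covariates Optional per-cell condition labels whose effect is
#'   preserved.
#' @param mean_only Adjust locations only (scales untouched).
#' @return Adjusted matrix with attribute `adjust_warnings` (character).
#' @export
combat_cluster <- function(Y, batches, covariates = NULL,
                           mean_only = FALSE) {
  Y <- as.matrix(Y)
  notes <- character()
  done <- function(res) {
    if (length(notes)) {
      for (w in notes) warning(w, call. = FALSE)
    }
    attr(res, "adjust_warnings") <- notes
    res
  }
  fb <- factor(batches)
  if (nlevels(fb) < 2) {
    notes <- "single batch in cluster; returned unchanged"
    return(done(Y))
  }
  if (any(table(fb) < 2)) {
    notes <- "a batch has < 2 cells in this cluster; returned unchanged"
    return(done(Y))
  }
  # markers constant within any batch carry no scale information there
  pass <- rep(FALSE, ncol(Y))
  for (b in levels(fb)) {
    v <- apply(Y[fb == b, , drop = FALSE], 2, stats::var)
    pass <- pass | v == 0
  }
  if (sum(!pass) < 2) {
    notes <- paste0("fewer than 2 adjustable markers in cluster ",
                    "(constant within a batch); returned unchanged")
    return(done(Y))
  }
  if (any(pass)) {
    notes <- c(notes, paste0(sum(pass), " marker(s) constant within a ",
                             "batch; passed through unadjusted"))
  }
  Yk <- Y[, !pass, drop = FALSE]
  std <- tryCatch(
    fit_standardization(Yk, batches, covariates),
    cytofuse_confounding_error = function(e) {
      notes <<- c(notes, paste0("covariate confounded with batch in ",
                                "cluster; adjusted without covariate"))
      fit_standardization(Yk, batches, NULL)
    })
  effects <- estimate_batch_effects(std$Z, std$design_info)
  priors <- estimate_hyperpriors(effects$gamma_hat, effects$delta2_hat)
  shrunken <- shrink_parametric(std$Z, std$design_info, effects, priors,
                                mean_only = mean_only)
  out <- Y
  out[, !pass] <- adjust_cluster(std$Z, std$design_info, shrunken,
                                 std$sigma_hat, std$stand_mean)
  done(out)
}
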