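#' Fit a parametric empirical-Bayes ComBat model
#'
#' Location/scale batch-effect model fitted feature-wise across centers.
#' Each feature is standardized with its grand mean (batch-size-weighted) and
#' pooled variance; per-batch means and variances of the standardized data
#' are then shrunk with the parametric empirical-Bayes priors (normal prior
#' on batch means, inverse-gamma on batch variances, hyperparameters by
#' method of moments) through the usual iterative joint update, to a relative
#' tolerance of 1e-6. An optional outcome covariate can be protected so the
#' class signal is not absorbed into the batch adjustment.
#'
#' Fitting and adjustment are separate steps ([combat_apply()]) so the model
#' can be estimated on training lesions only and applied to held-out lesions
#' without information leakage.
#'
#' Zero-variance features cannot be standardized; they are flagged and passed
#' through unchanged by [combat_apply()], with a warning. With a single
#' feature the moment hyperpriors are undefined and the batch estimates are
#' used unshrunk.
#'
#' @param table Feature table (tibble) with a batch column.
#' @param features Feature column names; default all non-identifier columns.
#' @param batch_col Name of the batch (center) column.
#' @param covariate_cols Optional columns (e.g. `outcome`) to protect.
#' @param tol Relative convergence tolerance of the EB iteration.
#' @param max_iter Iteration cap.
#' @return An object of class `combat_model`.
#' @export
combat_fit <- function(table, features = NULL, batch_col = "center_id",
                       covariate_cols = NULL, tol = 1e-6, max_iter = 200) {
  if (is.null(features)) features <- feature_columns(table)
  batch <- factor(table[[batch_col]])
  if (nlevels(batch) < 2) stop("need at least 2 batches", call. = FALSE)
  if (any(table(batch) < 2)) stop("every batch needs at least 2 samples", call. = FALSE)
  x <- as.matrix(table[features])
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  n <- nrow(x)
  batch_design <- stats::model.matrix(~ 0 + batch)
  n_batch <- colSums(batch_design)
  cov_design <- NULL
  if (!is.null(covariate_cols)) {
    cov_design <- stats::model.matrix(
      ~ ., data = as.data.frame(table[covariate_cols]))[, -1, drop = FALSE]
  }
  design <- cbind(batch_design, cov_design)
  zero_var <- apply(x, 2, function(col) stats::sd(col) == 0)
  use <- features[!zero_var]
  if (length(use) == 0) stop("all features have zero variance", call. = FALSE)
  xb <- x[, use, drop = FALSE]
  beta_hat <- solve(crossprod(design), crossprod(design, xb))
  gamma_hat_ols <- beta_hat[seq_len(nlevels(batch)), , drop = FALSE]
  alpha <- drop(crossprod(n_batch / n, gamma_hat_ols))
  fitted <- design %*% beta_hat
  sigma2 <- colMeans((xb - fitted)^2)
  cov_part <- if (is.null(cov_design)) matrix(0, n, length(use))
              else cov_design %*% beta_hat[-seq_len(nlevels(batch)), , drop = FALSE]
  z <- sweep(sweep(xb - cov_part, 2, alpha), 2, sqrt(sigma2), "/")
  # per-batch EB shrinkage of location (gamma) and scale (delta^2)
  g_hat <- rowsum(z, batch) / as.vector(n_batch)
  d_hat <- matrix(NA_real_, nlevels(batch), length(use),
                  dimnames = list(levels(batch), use))
  for (b in seq_len(nlevels(batch))) {
    zb <- z[batch == levels(batch)[b], , drop = FALSE]
    d_hat[b, ] <- apply(zb, 2, stats::var)
  }
  g_star <- g_hat
  d_star <- d_hat
  iters <- integer(nlevels(batch))
  if (length(use) > 1) {
    for (b in seq_len(nlevels(batch))) {
      nb <- n_batch[b]
      g_bar <- mean(g_hat[b, ]); t2 <- stats::var(g_hat[b, ])
      m <- mean(d_hat[b, ]); s2 <- stats::var(d_hat[b, ])
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      zb <- z[batch == levels(batch)[b], , drop = FALSE]
      g_old <- g_hat[b, ]; d_old <- d_hat[b, ]
      change <- Inf; it <- 0L
      while (change > tol && it < max_iter) {
        g_new <- (t2 * nb * g_hat[b, ] + d_old * g_bar) / (t2 * nb + d_old)
        sum2 <- colSums(sweep(zb, 2, g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
        g_old <- g_new; d_old <- d_new
        it <- it + 1L
      }
      g_star[b, ] <- g_old
      d_star[b, ] <- d_old
      iters[b] <- it
    }
  }
  structure(list(features = features, used = use, zero_var = features[zero_var],
                 batch_col = batch_col, batch_levels = levels(batch),
                 covariate_cols = covariate_cols,
                 alpha = alpha, sigma = sqrt(sigma2),
                 beta_cov = if (is.null(cov_design)) NULL
                            else beta_hat[-seq_len(nlevels(batch)), , drop = FALSE],
                 gamma_hat = g_hat, delta2_hat = d_hat,
                 gamma_star = g_star, delta2_star = d_star,
                 n_batch = as.vector(n_batch), iterations = iters),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d feature(s), %d batch(es): %s\n",
              length(x$used), length(x$batch_levels),
              paste(x$batch_levels, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted ComBat model to a feature table
#'
#' Standardizes with the stored grand mean / pooled SD, removes the shrunk
#' batch location, rescales by the shrunk batch scale, and restores the grand
#' mean (and covariate contribution, if the model protected one):
#' x* = sigma (z - gamma*) / delta* + alpha + X beta. Rows must belong to a
#' batch seen at fit time. Zero-variance features pass through unchanged with
#' a warning.
#'
#' @param model A [combat_fit()] model.
#' @param table Feature table containing the model's feature and batch columns.
#' @return The table with harmonized feature values (same shape).
#' @export
combat_apply <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  batch <- as.character(table[[model$batch_col]])
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen)) {
    stop(sprintf("unseen batch label(s): %s", paste(unseen, collapse = ", ")),
         call. = FALSE)
  }
  if (length(model$zero_var)) {
    warning(sprintf("zero-variance feature(s) passed through: %s",
                    paste(model$zero_var, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(table[model$used])
  n <- nrow(x)
  cov_part <- matrix(0, n, length(model$used))
  if (!is.null(model$covariate_cols)) {
    cov_design <- stats::model.matrix(
      ~ ., data = as.data.frame(table[model$covariate_cols]))[, -1, drop = FALSE]
    cov_part <- cov_design %*% model$beta_cov
  }
  z <- sweep(sweep(x - cov_part, 2, model$alpha), 2, model$sigma, "/")
  bi <- match(batch, model$batch_levels)
  adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star)[bi, , drop = FALSE]
  out <- sweep(adj, 2, model$sigma, "*")
  out <- sweep(out, 2, model$alpha, "+") + cov_part
  table[model$used] <- tibble::as_tibble(out)
  table
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ComBat model
#'
#' One row per batch x feature with the raw and shrunk location/scale
#' estimates.
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.combat_model <- function(x, ...) {
  tidyr::expand_grid(batch = x$batch_levels, feature = x$used) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      gamma_star = as.vector(t(x$gamma_star)),
      delta2_hat = as.vector(t(x$delta2_hat)),
      delta2_star = as.vector(t(x$delta2_star)))
}

#' Glance at a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return A one-row tibble with batch/feature counts and iteration info.
#' @exportS3Method generics::glance
glance.combat_model <- function(x, ...) {
  tibble::tibble(n_batches = length(x$batch_levels),
                 n_features = length(x$used),
                 n_zero_var = length(x$zero_var),
                 max_iterations = max(x$iterations))
}
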