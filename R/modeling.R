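#' Modeling protocol configuration
#'
#' Constants of the repeated train/test protocol: the 80/20 outer split
#' (grouped by patient so same-patient lesions never straddle train and
#' test), the inner 80/20 training/validation split, the random
#' hyperparameter search with bootstrap-scored candidates, and the repeat
#' count. Full-scale defaults are 100 repeats with 1000 bootstrap
#' resamples per candidate; analyses at desk scale pass smaller values.
#'
#' @param k_features mRMR selection size per feature set.
#' @param n_repeats Number of outer repetitions.
#' @param n_candidates Random-search candidates per repeat.
#' @param n_boot Bootstrap resamples scoring each candidate.
#' @param test_fraction,val_fraction Outer test and inner validation
#'   fractions.
#' @param split_by `"patient"` (grouped, default) or `"lesion"`.
#' @param combat_fit_on `"train"` (default, leakage-free) or `"all"`
#'   (harmonize the full table before splitting).
#' @param threshold Probability cut for ACC/SEN/SPE.
#' @param max_depth_range,nrounds_range Integer ranges sampled uniformly.
#' @param eta_range Learning-rate range, sampled uniformly on log scale.
#' @param subsample_range,colsample_range Row/column subsampling ranges.
#' @param nthread Threads handed to the booster.
#' @return A list of class `model_config`.
#' @export
model_config <- function(k_features = 10, n_repeats = 100, n_candidates = 20,
                         n_boot = 1000, test_fraction = 0.2, val_fraction = 0.2,
                         split_by = c("patient", "lesion"),
                         combat_fit_on = c("train", "all"), threshold = 0.5,
                         max_depth_range = c(1, 4), eta_range = c(0.01, 0.3),
                         nrounds_range = c(25, 150), subsample_range = c(0.6, 1),
                         colsample_range = c(0.5, 1), nthread = 1) {
  structure(list(k_features = k_features, n_repeats = n_repeats,
                 n_candidates = n_candidates, n_boot = n_boot,
                 test_fraction = test_fraction, val_fraction = val_fraction,
                 split_by = match.arg(split_by),
                 combat_fit_on = match.arg(combat_fit_on),
                 threshold = threshold, max_depth_range = max_depth_range,
                 eta_range = eta_range, nrounds_range = nrounds_range,
                 subsample_range = subsample_range,
                 colsample_range = colsample_range, nthread = nthread),
            class = "model_config")
}

#' The six model variants
#'
#' Harmonized / non-harmonized crossed with the DTP, static, and combined
#' feature sets.
#'
#' @return Character vector of length 6.
#' @export
model_variants <- function() {
  c("H_DTP", "H_Static", "H_DTP_Static",
    "NonH_DTP", "NonH_Static", "NonH_DTP_Static")
}

variant_parts <- function(variant) {
  variant <- match.arg(variant, model_variants())
  list(harmonize = startsWith(variant, "H_"),
       arm = sub("^(H|NonH)_", "", variant))
}

auc_rank <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a probability threshold
#'
#' AUC is threshold-free (rank / Mann-Whitney statistic with ties counted
#' 1/2); accuracy, sensitivity and specificity are computed at the stated
#' probability cut with "responding" as the positive class.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary outcome.
#' @param threshold Probability cut (default 0.5).
#' @param positive Positive class label.
#' @return One-row tibble: `auc`, `acc`, `sen`, `spe`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5,
                            positive = "responding") {
  y <- outcome_binary(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  tibble::tibble(auc = auc_rank(scores, y),
                 acc = (tp + tn) / length(y),
                 sen = tp / (tp + fn),
                 spe = tn / (tn + fp))
}

split_groups <- function(ids, labels, fraction, positive = "responding",
                         max_tries = 100L) {
  groups <- unique(ids)
  n_test <- max(1L, round(length(groups) * fraction))
  y <- outcome_binary(labels, positive)
  for (i in seq_len(max_tries)) {
    test_groups <- sample(groups, n_test)
    in_test <- ids %in% test_groups
    if (length(unique(y[in_test])) == 2 && length(unique(y[!in_test])) == 2) {
      return(in_test)
    }
  }
  stop("could not find a split with both outcomes on each side", call. = FALSE)
}

fit_xgb <- function(x, y, params, nrounds, nthread = 1) {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = nthread,
                    seed = 1L), params),
    data = d, nrounds = nrounds, verbose = 0)
}

predict_xgb <- function(model, x, nthread = 1) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(x, nthread = nthread)))
}

draw_candidates <- function(cfg) {
  n <- cfg$n_candidates
  tibble::tibble(
    max_depth = sample(seq(cfg$max_depth_range[1], cfg$max_depth_range[2]),
                       n, replace = TRUE),
    eta = exp(stats::runif(n, log(cfg$eta_range[1]), log(cfg$eta_range[2]))),
    nrounds = sample(seq(cfg$nrounds_range[1], cfg$nrounds_range[2]),
                     n, replace = TRUE),
    subsample = stats::runif(n, cfg$subsample_range[1], cfg$subsample_range[2]),
    colsample_bytree = stats::runif(n, cfg$colsample_range[1],
                                    cfg$colsample_range[2]))
}

select_features_for_arm <- function(train_tab, arm, k) {
  if (arm == "DTP_Static") {
    sel_d <- mrmr_select(train_tab, feature_columns(train_tab, "dtp_"), k = k)
    sel_s <- mrmr_select(train_tab, feature_columns(train_tab, "static_"), k = k)
    pooled <- c(sel_d$selected, sel_s$selected)
    mrmr_select(train_tab, pooled, k = k)
  } else {
    prefix <- if (arm == "DTP") "dtp_" else "static_"
    mrmr_select(train_tab, feature_columns(train_tab, prefix), k = k)
  }
}

#' Repeated 80/20 train/test evaluation of one model variant
#'
#' One repetition: (1) split lesions 80/20 into training and test, grouped by
#' patient; (2) if the variant is harmonized, fit ComBat on the training
#' lesions (default) and apply it to both splits; (3) mRMR-select
#' `k_features` features on the training split (the combined variant selects
#' 10 per feature set, pools the 20 and re-selects 10); (4) split training
#' 80/20 into inner-training and validation, draw `n_candidates` random
#' hyperparameter candidates and score each by its mean validation AUC over
#' `n_boot` bootstrap resamples of the inner-training lesions; (5) refit the
#' winning candidate on the full training split and measure AUC/ACC/SEN/SPE
#' on the untouched test split. Repeated `n_repeats` times with per-repeat
#' seeds derived from `seed`; the whole procedure is deterministic given
#' `seed`. All training-time artifacts (ComBat parameters, selected features,
#' tuned hyperparameters) depend only on training rows.
#'
#' @param table Feature table with `static_`/`dtp_` feature columns.
#' @param variant One of [model_variants()].
#' @param cfg A [model_config()].
#' @param seed Master seed.
#' @return A `dtp_eval_report`: tibble with one row per repeat (`repeat_id`,
#'   `auc`, `acc`, `sen`, `spe`) carrying the variant, config and per-repeat
#'   training artifacts as attributes. Summaries via [glance()].
#' @export
train_eval_protocol <- function(table, variant = "H_DTP_Static",
                                cfg = model_config(), seed = 1) {
  parts <- variant_parts(variant)
  rows <- vector("list", cfg$n_repeats)
  artifacts <- vector("list", cfg$n_repeats)
  group_ids <- if (cfg$split_by == "patient") table$patient_id else table$lesion_id
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(seed + r)
    in_test <- split_groups(group_ids, table$outcome, cfg$test_fraction)
    train_tab <- table[!in_test, , drop = FALSE]
    test_tab <- table[in_test, , drop = FALSE]
    cm <- NULL
    if (parts$harmonize) {
      fit_tab <- if (cfg$combat_fit_on == "all") table else train_tab
      cm <- combat_fit(fit_tab, features = feature_columns(table))
      train_tab <- combat_apply(cm, train_tab)
      test_tab <- combat_apply(cm, test_tab)
    }
    sel <- select_features_for_arm(train_tab, parts$arm, cfg$k_features)
    feats <- sel$selected
    inner_groups <- if (cfg$split_by == "patient") train_tab$patient_id
                    else train_tab$lesion_id
    in_val <- split_groups(inner_groups, train_tab$outcome, cfg$val_fraction)
    x_tr <- as.matrix(train_tab[!in_val, feats, drop = FALSE])
    y_tr <- outcome_binary(train_tab$outcome[!in_val])
    x_val <- as.matrix(train_tab[in_val, feats, drop = FALSE])
    y_val <- outcome_binary(train_tab$outcome[in_val])
    cand <- draw_candidates(cfg)
    scores <- numeric(cfg$n_candidates)
    for (ci in seq_len(cfg$n_candidates)) {
      prm <- list(max_depth = cand$max_depth[ci], eta = cand$eta[ci],
                  subsample = cand$subsample[ci],
                  colsample_bytree = cand$colsample_bytree[ci])
      val_auc <- numeric(cfg$n_boot)
      for (b in seq_len(cfg$n_boot)) {
        repeat {
          bi <- sample.int(nrow(x_tr), nrow(x_tr), replace = TRUE)
          if (length(unique(y_tr[bi])) == 2) break
        }
        m <- fit_xgb(x_tr[bi, , drop = FALSE], y_tr[bi], prm, cand$nrounds[ci],
                     cfg$nthread)
        val_auc[b] <- auc_rank(predict_xgb(m, x_val, cfg$nthread), y_val)
      }
      scores[ci] <- mean(val_auc)
    }
    best <- which.max(scores)
    winner <- as.list(cand[best, ])
    x_full <- as.matrix(train_tab[, feats, drop = FALSE])
    y_full <- outcome_binary(train_tab$outcome)
    final <- fit_xgb(x_full, y_full,
                     winner[c("max_depth", "eta", "subsample", "colsample_bytree")],
                     winner$nrounds, cfg$nthread)
    test_scores <- predict_xgb(final, as.matrix(test_tab[, feats, drop = FALSE]),
                               cfg$nthread)
    rows[[r]] <- dplyr::mutate(
      compute_metrics(test_scores, test_tab$outcome, cfg$threshold),
      repeat_id = r, .before = 1)
    artifacts[[r]] <- list(
      selected = feats,
      hyperparameters = winner,
      combat = if (is.null(cm)) NULL
               else cm[c("alpha", "sigma", "gamma_star", "delta2_star")],
      test_patients = unique(test_tab$patient_id))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, variant = variant, config = cfg, seed = seed,
            artifacts = artifacts,
            class = c("dtp_eval_report", class(out)))
}

#' Per-repeat results of an evaluation report
#'
#' @param x A `dtp_eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per repeat and the variant name.
#' @exportS3Method generics::tidy
tidy.dtp_eval_report <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), variant = attr(x, "variant"), .before = 1)
}

#' Summary of an evaluation report
#'
#' Mean, SD and percentile 95% CI of each test metric over the repeats.
#'
#' @param x A `dtp_eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per metric.
#' @exportS3Method generics::glance
glance.dtp_eval_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(c("auc", "acc", "sen", "spe")),
                        names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     ci_lo = stats::quantile(.data$value, 0.025, names = FALSE),
                     ci_hi = stats::quantile(.data$value, 0.975, names = FALSE),
                     .groups = "drop") |>
    dplyr::mutate(variant = attr(x, "variant"), n_repeats = nrow(x), .before = 1)
}

#' Pairwise Mann-Whitney comparison of model variants
#'
#' Two-sided Mann-Whitney U tests on the per-repeat metric vectors of each
#' pair of evaluation reports (exact p for small tie-free samples, normal
#' approximation with tie correction otherwise, the standard behaviour of
#' [stats::wilcox.test()]). Comparing a report with itself gives p = 1.
#'
#' @param reports Named list of `dtp_eval_report` objects with equal repeat
#'   counts.
#' @param metric One of `"auc"`, `"acc"`, `"sen"`, `"spe"`.
#' @return A symmetric matrix of p-values with variant dimnames.
#' @export
mann_whitney_compare <- function(reports, metric = "auc") {
  stopifnot(length(reports) >= 2)
  nrep <- vapply(reports, nrow, integer(1))
  if (length(unique(nrep)) != 1) stop("mismatched repeat counts", call. = FALSE)
  nm <- names(reports)
  if (is.null(nm)) nm <- vapply(reports, function(r) attr(r, "variant"), character(1))
  k <- length(reports)
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- reports[[i]][[metric]]; b <- reports[[j]][[metric]]
      pv <- if (isTRUE(all.equal(a, b))) 1
            else suppressWarnings(stats::wilcox.test(a, b)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  p
}
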