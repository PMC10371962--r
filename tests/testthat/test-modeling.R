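cohort_for_modeling <- function(effect = 2, seed = 101, n_pat = c(12, 12)) {
  spec <- cohort_spec(n_patients = n_pat, lesions_per_patient = 1:3,
                      n_features = 12,
                      feature_names = paste0("dtp_f", sprintf("%02d", 1:12)),
                      effect_size = effect,
                      effect_features = paste0("dtp_f", sprintf("%02d", 1:4)),
                      batch_offset = c(0, 0.5))
  tab <- simulate_cohort(spec, seed = seed)
  set.seed(seed + 1)
  for (fn in paste0("static_f", sprintf("%02d", 1:12))) {
    tab[[fn]] <- rnorm(nrow(tab))
  }
  tab
}

fast_cfg <- function(...) {
  model_config(n_repeats = 2, n_candidates = 2, n_boot = 4, k_features = 4, ...)
}

test_that("metrics match a hand-built confusion table and degenerate cases", {
  # TP = 3, FN = 1, TN = 4, FP = 2 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3, 0.4, 0.1, 0.6, 0.7)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m <- compute_metrics(scores, labels)
  expect_equal(m$sen, 0.75)
  expect_equal(m$spe, 2 / 3)
  expect_equal(m$acc, 0.7)

  perfect <- compute_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(auc = 1, acc = 1, sen = 1, spe = 1))
  ties <- compute_metrics(rep(0.5, 10), rep(0:1, 5))
  expect_equal(ties$auc, 0.5)
  expect_error(compute_metrics(1:3 / 3, c(1, 1, 1)), "both classes")
})

test_that("the repeated protocol is deterministic and variant-aware", {
  tab <- cohort_for_modeling()
  cfg <- fast_cfg()
  a <- train_eval_protocol(tab, "NonH_DTP", cfg, seed = 1)
  b <- train_eval_protocol(tab, "NonH_DTP", cfg, seed = 1)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "artifacts"), attr(b, "artifacts"))
  expect_true(all(unlist(a[c("auc", "acc", "sen", "spe")]) >= 0))
  expect_true(all(unlist(a[c("auc", "acc", "sen", "spe")]) <= 1))
  # DTP variant must only use dtp_ features
  sel <- attr(a, "artifacts")[[1]]$selected
  expect_true(all(startsWith(sel, "dtp_")))
  # combined variant draws from both pools and re-selects to k
  ab <- train_eval_protocol(tab, "H_DTP_Static", cfg, seed = 2)
  sel2 <- attr(ab, "artifacts")[[1]]$selected
  expect_lte(length(sel2), cfg$k_features)
  gl <- glance(ab)
  expect_setequal(gl$metric, c("auc", "acc", "sen", "spe"))
  expect_true(all(gl$ci_lo <= gl$ci_hi))
})

test_that("a strong planted effect is learned from the training data", {
  tab <- cohort_for_modeling(effect = 2.5, n_pat = c(15, 15))
  cfg <- model_config(n_repeats = 4, n_candidates = 3, n_boot = 8, k_features = 6)
  rep <- train_eval_protocol(tab, "NonH_DTP", cfg, seed = 3)
  expect_gt(mean(rep$auc), 0.8)
  # at least one planted feature is always selected
  sel <- attr(rep, "artifacts")
  expect_true(all(vapply(sel, function(a) {
    any(a$selected %in% paste0("dtp_f", sprintf("%02d", 1:4)))
  }, logical(1))))
})

test_that("patient-level grouping keeps same-patient lesions on one side", {
  tab <- cohort_for_modeling()
  cfg <- fast_cfg()
  rep <- train_eval_protocol(tab, "NonH_DTP", cfg, seed = 4)
  test_pat <- attr(rep, "artifacts")[[1]]$test_patients
  expect_true(length(test_pat) >= 1)
  expect_lt(length(test_pat), length(unique(tab$patient_id)))
})

test_that("poisoning the test rows leaves every training artifact bit-identical", {
  tab <- cohort_for_modeling()
  cfg <- model_config(n_repeats = 1, n_candidates = 2, n_boot = 4, k_features = 4)
  ref <- train_eval_protocol(tab, "H_DTP", cfg, seed = 5)
  test_pat <- attr(ref, "artifacts")[[1]]$test_patients
  poisoned <- tab
  rows <- poisoned$patient_id %in% test_pat
  for (fn in feature_columns(poisoned)) {
    poisoned[[fn]][rows] <- poisoned[[fn]][rows] * 1000 + 500
  }
  alt <- train_eval_protocol(poisoned, "H_DTP", cfg, seed = 5)
  expect_identical(attr(ref, "artifacts")[[1]]$selected,
                   attr(alt, "artifacts")[[1]]$selected)
  expect_identical(attr(ref, "artifacts")[[1]]$hyperparameters,
                   attr(alt, "artifacts")[[1]]$hyperparameters)
  expect_identical(attr(ref, "artifacts")[[1]]$combat,
                   attr(alt, "artifacts")[[1]]$combat)
  # ... while the test metrics do react to the corrupted test data
  expect_false(isTRUE(all.equal(ref$auc, alt$auc)) &&
                 isTRUE(all.equal(ref$acc, alt$acc)))
})

test_that("Mann-Whitney comparisons use the exact small-sample distribution", {
  mk_report <- function(auc) {
    structure(tibble::tibble(repeat_id = seq_along(auc), auc = auc,
                             acc = auc, sen = auc, spe = auc),
              variant = "x", class = c("dtp_eval_report", "tbl_df", "tbl",
                                       "data.frame"))
  }
  a <- mk_report(c(0.1, 0.2, 0.3))
  b <- mk_report(c(0.4, 0.5, 0.6))
  p <- mann_whitney_compare(list(lo = a, hi = b))
  expect_equal(p["lo", "hi"], 0.1) # U = 0: 2 / choose(6, 3)
  expect_equal(p["lo", "lo"], 1)
  expect_equal(mann_whitney_compare(list(a = a, b = a))["a", "b"], 1)
  expect_error(mann_whitney_compare(list(a = a, b = mk_report(c(0.1, 0.2)))),
               "mismatched repeat")
  # normal approximation tracks the exact p at moderate n
  set.seed(95)
  x <- rnorm(15); y <- rnorm(15) + 0.5
  exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(approx, exact, tolerance = 0.1)
})

test_that("tidier and autoplot surfaces work on evaluation reports", {
  tab <- cohort_for_modeling()
  rep <- train_eval_protocol(tab, "NonH_DTP", fast_cfg(), seed = 6)
  td <- tidy(rep)
  expect_identical(td$variant[1], "NonH_DTP")
  expect_equal(nrow(td), 2)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  p2 <- plot_correlation_tiers(
    spearman_pairs(make_paired_tables()$static, make_paired_tables()$dtp))
  expect_s3_class(p2, "ggplot")
})
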