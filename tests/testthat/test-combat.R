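test_that("null batches shrink to no adjustment: gamma* ~ 0, delta*^2 ~ 1", {
  spec <- cohort_spec(n_patients = c(100, 100), lesions_per_patient = 2,
                      n_features = 30)
  tab <- simulate_cohort(spec, seed = 70)
  cm <- combat_fit(tab)
  expect_lt(max(abs(cm$gamma_star)), 0.15)
  expect_lt(max(abs(cm$delta2_star - 1)), 0.2)
  adj <- combat_apply(cm, tab)
  delta <- as.matrix(adj[feature_columns(adj)]) - as.matrix(tab[feature_columns(tab)])
  expect_lt(max(abs(delta)), 0.5) # bounded by shrinkage noise, far below SD 1
})

test_that("planted location and scale batch effects are removed", {
  spec <- cohort_spec(n_patients = c(100, 100), lesions_per_patient = 2,
                      n_features = 30, batch_offset = c(0, 2),
                      batch_scale = c(1, 3))
  tab <- simulate_cohort(spec, seed = 71)
  adj <- combat_apply(combat_fit(tab), tab)
  in2 <- adj$center_id == "center2"
  gaps <- vapply(feature_columns(adj), function(fn) {
    x <- adj[[fn]]
    abs(mean(x[in2]) - mean(x[!in2])) / stats::sd(x)
  }, numeric(1))
  ratios <- vapply(feature_columns(adj), function(fn) {
    x <- adj[[fn]]
    stats::sd(x[in2]) / stats::sd(x[!in2])
  }, numeric(1))
  # per-feature residuals are shrinkage + sampling noise (~1/sqrt(n) SD), so
  # recovery is judged on the cohort-average gap and SD ratio
  expect_lt(mean(gaps), 0.1)
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
  expect_lt(max(gaps), 0.25)
})

test_that("the implementation matches the reference ComBat on a shared fit", {
  skip_if_not_installed("sva")
  spec <- cohort_spec(n_patients = c(40, 40), lesions_per_patient = 2,
                      n_features = 25, batch_offset = c(0, 1.5),
                      batch_scale = c(1, 2))
  tab <- simulate_cohort(spec, seed = 72)
  ours <- combat_apply(combat_fit(tab), tab)
  ref <- sva::ComBat(t(as.matrix(tab[feature_columns(tab)])),
                     batch = tab$center_id)
  expect_equal(t(as.matrix(ours[feature_columns(ours)])), ref,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("a hand-computed single-feature example matches step by step", {
  # one feature, two batches of two: no EB shrinkage path (hyperpriors
  # undefined with a single feature), so each batch is standardized to the
  # grand mean 5 with the pooled SD: adjusted values 5 -/+ sqrt(1.25)
  tab <- tibble::tibble(lesion_id = sprintf("L%d", 1:4),
                        patient_id = sprintf("P%d", 1:4),
                        center_id = c("c1", "c1", "c2", "c2"),
                        outcome = c("responding", "non-responding",
                                    "responding", "non-responding"),
                        f = c(1, 3, 6, 10))
  cm <- combat_fit(tab, features = "f", batch_col = "center_id")
  expect_equal(cm$alpha, c(f = 5))
  expect_equal(unname(cm$sigma), sqrt(2.5))
  expect_equal(as.vector(cm$gamma_star), c(-3, 3) / sqrt(2.5))
  adj <- combat_apply(cm, tab)
  expect_equal(adj$f, c(5 - sqrt(1.25), 5 + sqrt(1.25),
                        5 - sqrt(1.25), 5 + sqrt(1.25)), tolerance = 1e-12)
})

test_that("re-fitting on harmonized output is approximately a no-op", {
  spec <- cohort_spec(n_patients = c(80, 80), lesions_per_patient = 2,
                      n_features = 20, batch_offset = c(0, 1))
  tab <- simulate_cohort(spec, seed = 73)
  once <- combat_apply(combat_fit(tab), tab)
  twice <- combat_apply(combat_fit(once), once)
  d <- abs(as.matrix(twice[feature_columns(twice)]) -
             as.matrix(once[feature_columns(once)]))
  expect_lt(max(d), 0.15) # residual batch signal is within shrinkage noise
})

test_that("the grand mean of each feature is approximately preserved", {
  spec <- cohort_spec(n_patients = c(50, 50), lesions_per_patient = 2,
                      n_features = 20, batch_offset = c(0, 1))
  tab <- simulate_cohort(spec, seed = 74)
  adj <- combat_apply(combat_fit(tab), tab)
  for (fn in feature_columns(tab)[1:5]) {
    expect_equal(mean(adj[[fn]]), mean(tab[[fn]]), tolerance = 0.05)
  }
})

test_that("degenerate inputs are flagged or rejected", {
  spec <- cohort_spec(n_patients = c(10, 10), n_features = 3)
  tab <- simulate_cohort(spec, seed = 75)
  one <- dplyr::filter(tab, .data$center_id == "center1")
  expect_error(combat_fit(one), "2 batches")
  tab$f03 <- 7
  cm <- combat_fit(tab)
  expect_identical(cm$zero_var, "f03")
  expect_warning(adj <- combat_apply(cm, tab), "zero-variance")
  expect_equal(adj$f03, tab$f03)
  expect_error(combat_apply(cm, dplyr::mutate(tab, center_id = "center9")),
               "unseen batch")
})

test_that("harmonizing a null cohort is calibration-safe", {
  spec <- cohort_spec(n_patients = c(50, 50), lesions_per_patient = 2,
                      n_features = 200)
  tab <- simulate_cohort(spec, seed = 76)
  adj <- combat_apply(combat_fit(tab), tab)
  # between-center tests: the adjustment equalizes in-sample batch means, so
  # rejections can only fall below the nominal level (conservative)
  p_center <- vapply(feature_columns(adj), function(fn) {
    stats::t.test(adj[[fn]] ~ adj$center_id)$p.value
  }, numeric(1))
  expect_lt(mean(p_center < 0.05), 0.06)
  # between-outcome-class tests stay at the nominal 5% rate: the class
  # signal is untouched by the batch adjustment
  p_outcome <- vapply(feature_columns(adj), function(fn) {
    stats::t.test(adj[[fn]] ~ adj$outcome)$p.value
  }, numeric(1))
  expect_gt(mean(p_outcome < 0.05), 0.01)
  expect_lt(mean(p_outcome < 0.05), 0.10)
})

test_that("tidy and glance expose the fitted parameters", {
  spec <- cohort_spec(n_patients = c(10, 10), n_features = 4)
  tab <- simulate_cohort(spec, seed = 77)
  cm <- combat_fit(tab)
  td <- tidy(cm)
  expect_equal(nrow(td), 8) # 2 batches x 4 features
  expect_equal(td$gamma_star[td$batch == "center1" & td$feature == "f01"],
               cm$gamma_star["center1", "f01"], ignore_attr = TRUE)
  gl <- glance(cm)
  expect_equal(gl$n_batches, 2)
  expect_equal(gl$n_features, 4)
})
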