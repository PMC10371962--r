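test_that("shape features of a voxel cube follow the closed forms", {
  mask <- array(FALSE, c(14, 14, 14))
  mask[3:12, 3:12, 3:12] <- TRUE # 10^3 voxels at 4 mm
  s <- shape_features(mask, c(4, 4, 4))
  expect_equal(unname(s["Shape_Volume_vx"]), 1000)
  expect_equal(unname(s["Shape_Volume_mL"]), 64)
  expect_equal(unname(s["Shape_Surface_mm2"]), 9600)
  expect_equal(unname(s["Shape_Sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(unname(s["Shape_Compacity"]),
               64000 / (sqrt(pi) * 9600^1.5), tolerance = 1e-12)
})

test_that("a digitized ball approaches the face-counted sphericity limit 2/3", {
  # exposed voxel faces overestimate a smooth surface by 3/2 (projection
  # argument), so the face-counted sphericity of a ball tends to 2/3, not 1
  v <- image_volume(array(0, c(40, 40, 40)), spacing = c(1, 1, 1))
  m <- sphere_mask(v, c(20, 20, 20), 15)
  s <- shape_features(m, c(1, 1, 1))
  expect_gt(unname(s["Shape_Sphericity"]), 0.55)
  expect_lt(unname(s["Shape_Sphericity"]), 0.75)
})

test_that("histogram features obey the analytic degenerate cases", {
  d <- make_disc(array(4L, c(3, 3, 2)), bin_count = 8)
  h <- histogram_features(d)
  expect_equal(unname(h["HISTO_Uniformity"]), 1)
  expect_equal(unname(h["HISTO_Entropy"]), 0)
  expect_equal(unname(h["HISTO_AUC_CSH"]), 1)

  lev <- array(NA_integer_, c(4, 1, 1))
  lev[, 1, 1] <- c(2L, 2L, 5L, 5L)
  h2 <- histogram_features(make_disc(lev, bin_count = 8))
  expect_equal(unname(h2["HISTO_Uniformity"]), 0.5)
  expect_equal(unname(h2["HISTO_Entropy_log2"]), 1)
})

test_that("AUC-CSH equals the exact integral of the cumulative step function", {
  lev <- array(NA_integer_, c(5, 1, 1))
  lev[, 1, 1] <- c(1L, 2L, 3L, 4L, 8L)
  d <- make_disc(lev, bin_count = 8)
  vals <- (c(1, 2, 3, 4, 8) - 0.5) * 20 / 8
  # step-function oracle on a fine grid
  grid <- seq(0, 1, length.out = 200001)
  frac <- vapply(grid, function(x) mean(vals >= x * max(vals)), numeric(1))
  oracle <- mean(frac[-1] + frac[-length(frac)]) / 2
  expect_equal(unname(histogram_features(d)["HISTO_AUC_CSH"]), oracle,
               tolerance = 1e-4)
})

test_that("moving histogram mass into a new bin lowers uniformity", {
  set.seed(50)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- as.vector(stats::rmultinom(1, 60, runif(k))) / 60
    p <- p[p > 0]
    eps <- 0.05
    q <- c(p * (1 - eps), eps)
    expect_lte(sum(q^2), sum(p^2))
  }
})

test_that("conventional indices on a constant lesion follow the definitions", {
  v <- image_volume(array(5, c(10, 10, 10)), spacing = c(4, 4, 4))
  f <- extract_features(v, voi(array(TRUE, c(10, 10, 10))))
  expect_equal(unname(f["Conventional_mean"]), 5)
  expect_equal(unname(f["Conventional_SD"]), 0)
  expect_equal(unname(f["Conventional_TLG"]), 5 * 64)
  expect_equal(unname(f["Conventional_Skewness"]), 0)
  expect_equal(unname(f["Conventional_ExcessKurtosis"]), 0)
  expect_equal(unname(f["Conventional_peak"]), 5)
})

test_that("quantiles use linear interpolation between order statistics", {
  arr <- array(NA_real_, c(100, 1, 1))
  arr[, 1, 1] <- sample(1:100)
  mask <- array(TRUE, c(100, 1, 1))
  d <- structure(list(levels = array(bin_index(arr, 64, 0, 101), dim(arr)),
                      continuous = arr, mask = mask, bin_count = 64L,
                      bounds = c(0, 101), spacing = c(4, 4, 4), unit = "SUV"),
                 class = "discretized_volume")
  ci <- conventional_indices(d)
  expect_equal(unname(ci["Conventional_Q1"]), 25.75)
  expect_equal(unname(ci["Conventional_Q2"]), 50.5)
  expect_equal(unname(ci["Conventional_Q3"]), 75.25)
  expect_equal(unname(ci["Conventional_min"]), 1)
  expect_equal(unname(ci["Conventional_max"]), 100)
})

test_that("excess kurtosis of a large Gaussian sample is near zero", {
  set.seed(51)
  arr <- array(rnorm(1e5), c(50, 50, 40))
  mask <- array(TRUE, dim(arr))
  d <- structure(list(levels = array(1L, dim(arr)), continuous = arr,
                      mask = mask, bin_count = 4L, bounds = c(0, 20),
                      spacing = c(4, 4, 4), unit = "SUV"),
                 class = "discretized_volume")
  mo <- dtpradiomics:::moments_block(arr[mask])
  expect_lt(abs(mo[["ExcessKurtosis"]]), 0.05)
  expect_lt(abs(mo[["Skewness"]]), 0.05)
})

test_that("the 65-vector is deterministic, complete and translation invariant", {
  f <- input_function()
  st <- simulate_dtp_study(phantom_spec(), f, 61, 133, seed = 60)
  ki <- compute_ki_map(st$suv_t1, st$act_t2, f, 61, 133)
  v <- st$lesion_masks[[1]]
  tab <- extract_all(st$suv_t1, ki, v, v)
  expect_equal(nrow(tab), 65)
  expect_identical(tab$feature, feature_names())
  expect_true(all(is.finite(tab$static)))
  expect_true(all(is.finite(tab$dtp)))
  # identical volumes and VOIs give identical vectors
  tab2 <- extract_all(st$suv_t1, st$suv_t1, v, v)
  expect_equal(tab2$static, tab2$dtp)

  # translation within the grid leaves every feature unchanged
  shift <- c(2L, 1L, 3L)
  perm <- function(a) {
    out <- array(a[c(NA_integer_)], dim(a))
    d <- dim(a)
    out[(1 + shift[1]):d[1], (1 + shift[2]):d[2], (1 + shift[3]):d[3]] <-
      a[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:(d[3] - shift[3])]
    out
  }
  suv_s <- st$suv_t1
  suv_s$data <- perm(st$suv_t1$data)
  suv_s$data[is.na(suv_s$data)] <- 0
  mask_s <- perm(v$mask)
  mask_s[is.na(mask_s)] <- FALSE
  f_orig <- extract_features(st$suv_t1, v)
  f_shift <- extract_features(suv_s, voi(mask_s))
  expect_equal(f_orig, f_shift, tolerance = 1e-10)
})

test_that("random valid lesions always yield 65 finite features", {
  set.seed(61)
  for (i in 1:15) {
    d <- random_lesion(sample(3:6, 3, replace = TRUE), sample(3:8, 1))
    fx <- c(glcm_features(d), ngldm_features(d), glrlm_features(d),
            glzlm_features(d), shape_features(d$mask, d$spacing),
            histogram_features(d), conventional_indices(d))
    expect_length(fx, 65)
    expect_true(all(is.finite(fx)))
  }
})
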