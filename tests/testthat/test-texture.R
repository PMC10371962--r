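test_that("a constant lesion gives the degenerate GLCM/NGLDM values", {
  d <- make_disc(array(3L, c(3, 3, 3)), bin_count = 6)
  g <- glcm_features(d)
  expect_equal(unname(g[c("GLCM_Energy", "GLCM_Homogeneity", "GLCM_Correlation")]),
               c(1, 1, 1))
  expect_equal(unname(g[c("GLCM_Contrast", "GLCM_Entropy", "GLCM_Dissimilarity")]),
               c(0, 0, 0))
  ng <- ngldm_features(d)
  expect_equal(unname(ng[c("NGLDM_Contrast", "NGLDM_Busyness")]), c(0, 0))
  expect_equal(unname(ng["NGLDM_Coarseness"]), 1e6)
})

test_that("a 1D strip co-occurrence along one direction matches hand enumeration", {
  lev <- array(NA_integer_, c(4, 1, 1))
  lev[, 1, 1] <- c(1L, 2L, 1L, 2L)
  d <- make_disc(lev, bin_count = 2)
  p <- glcm_matrix(d, directions = matrix(c(1L, 0L, 0L), 1))
  # pairs (1,2),(2,1),(1,2) symmetrized: 6 counts, all off-diagonal
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  g <- glcm_features(d) # full 13-direction aggregate
  expect_equal(unname(g["GLCM_Entropy_log2"]), unname(g["GLCM_Entropy"]) / log(2))
})

test_that("single-direction run enumeration matches the hand example", {
  lev <- array(NA_integer_, c(5, 1, 1))
  lev[, 1, 1] <- c(1L, 1L, 2L, 2L, 2L)
  d <- make_disc(lev, bin_count = 2)
  m <- glrlm_matrix(d, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(sum(m), 2) # two runs: (1, len 2), (2, len 3)
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 3], 1)
  # derived by hand: two runs -> RLNU = GLNU = (1^2 + 1^2)/2 = 1,
  # SRE = (1/2^2 + 1/3^2)/2
  full <- dtpradiomics:::rl_family_features(m, n_vox = 5, "GLRLM",
                                            c("SRE", "LRE", "LGRE", "HGRE",
                                              "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                                              "GLNU", "RLNU", "RP"))
  expect_equal(unname(full["GLRLM_SRE"]), (1 / 4 + 1 / 9) / 2)
  expect_equal(unname(full["GLRLM_GLNU"]), 1)
  expect_equal(unname(full["GLRLM_RLNU"]), 1)

  # constant strip: one run, RP = 1/n, LRE = n^2
  lev2 <- array(NA_integer_, c(6, 1, 1)); lev2[, 1, 1] <- 2L
  d2 <- make_disc(lev2, bin_count = 3)
  m2 <- glrlm_matrix(d2, directions = matrix(c(1L, 0L, 0L), 1))
  f2 <- dtpradiomics:::rl_family_features(m2, 6, "GLRLM",
                                          c("SRE", "LRE", "LGRE", "HGRE",
                                            "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                                            "GLNU", "RLNU", "RP"))
  expect_equal(unname(f2["GLRLM_RP"]), 1 / 6)
  expect_equal(unname(f2["GLRLM_LRE"]), 36)
})

test_that("zone statistics match the flood-fill definition on hand cases", {
  # constant lesion: one zone of size n, ZP = 1/n, LZE = n^2
  d <- make_disc(array(2L, c(3, 3, 3)), bin_count = 4)
  z <- glzlm_features(d)
  expect_equal(unname(z["GLZLM_ZP"]), 1 / 27)
  expect_equal(unname(z["GLZLM_LZE"]), 27^2)
  # 2x2x1 checkerboard: 4 zones of size 1 under 26-connectivity? adjacent
  # diagonals of the same level touch, so levels 1 and 2 each form ONE zone
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[, , 1] <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  d2 <- make_disc(lev, bin_count = 2)
  m2 <- glzlm_matrix(d2)
  expect_equal(sum(m2), 2) # two diagonal zones of size 2
  expect_equal(m2[1, 2], 1)
  expect_equal(m2[2, 2], 1)
})

test_that("all four texture families equal brute-force enumeration on random lesions", {
  set.seed(40)
  for (i in 1:30) {
    dims <- sample(2:6, 3, replace = TRUE)
    nb <- sample(3:6, 1)
    d <- random_lesion(dims, nb, p_in = runif(1, 0.4, 0.9))
    # GLCM
    expect_equal(glcm_matrix(d), oracle_glcm_matrix(d$levels, nb), tolerance = 1e-12)
    expect_equal(glcm_features(d), oracle_glcm_features(oracle_glcm_matrix(d$levels, nb)),
                 tolerance = 1e-10)
    # GLRLM (matrix padded to common width)
    m <- glrlm_matrix(d); o <- oracle_glrlm_matrix(d$levels, nb)
    w <- max(ncol(m), ncol(o))
    pad <- function(x) cbind(x, matrix(0, nrow(x), w - ncol(x)))
    expect_equal(pad(m), pad(o))
    nv <- sum(!is.na(d$levels))
    expect_equal(unname(glrlm_features(d)), unname(oracle_rl_features(o, nv)),
                 tolerance = 1e-10)
    # GLZLM
    mz <- glzlm_matrix(d); oz <- oracle_glzlm_matrix(d$levels, nb)
    wz <- max(ncol(mz), ncol(oz))
    padz <- function(x) cbind(x, matrix(0, nrow(x), wz - ncol(x)))
    expect_equal(padz(mz), padz(oz))
    expect_equal(unname(glzlm_features(d)), unname(oracle_rl_features(oz, nv)),
                 tolerance = 1e-10)
    # NGLDM
    expect_equal(ngldm_features(d), oracle_ngldm_features(d$levels), tolerance = 1e-10)
  }
})

test_that("NGLDM on the 2x2x1 hand patch matches exhaustive neighbourhood sums", {
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[, , 1] <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  d <- make_disc(lev, bin_count = 2)
  expect_equal(ngldm_features(d), oracle_ngldm_features(lev), tolerance = 1e-12)
})

test_that("coarseness falls as planted lesion heterogeneity rises", {
  f <- input_function()
  coarse_at <- function(amp, seeds) {
    vapply(seeds, function(s) {
      spec <- phantom_spec(lesions = list(list(centre = c(36, 36, 36),
                                               radius_mm = 14, ki = 0.02, v = 0.3,
                                               texture_cor_mm = 8,
                                               texture_amp = amp)))
      st <- simulate_dtp_study(spec, f, 61, 133, seed = s)
      ki <- compute_ki_map(st$suv_t1, st$act_t2, f, 61, 133)
      d <- preprocess_volume(ki, st$lesion_masks[[1]])
      unname(ngldm_features(d)["NGLDM_Coarseness"])
    }, numeric(1))
  }
  # near-homogeneous lesions are much coarser than clearly textured ones;
  # beyond that the occupied-level count grows with the amplitude and the
  # per-level sums dilute, so the contrast is taken at the regime ends
  lo <- coarse_at(0.05, 1:6)
  hi <- coarse_at(0.6, 1:6)
  expect_gt(mean(lo), 2 * mean(hi))
})
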