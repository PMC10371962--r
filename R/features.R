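#' Canonical names of the 65-feature panel
#'
#' The fixed extraction order: GLCM (7), NGLDM (3), GLRLM (11), GLZLM (11),
#' shape (5), histogram (4), conventional (12) and discretized (12) indices.
#'
#' @return Character vector of length 65.
#' @export
feature_names <- function() {
  conv <- c("Q1", "Q2", "Q3", "min", "mean", "max", "SD", "peak", "TLG",
            "Skewness", "Kurtosis", "ExcessKurtosis")
  c(paste0("GLCM_", c("Homogeneity", "Energy", "Contrast", "Correlation",
                      "Entropy", "Entropy_log2", "Dissimilarity")),
    paste0("NGLDM_", c("Coarseness", "Contrast", "Busyness")),
    paste0("GLRLM_", c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
                       "LRLGE", "LRHGE", "GLNU", "RLNU", "RP")),
    paste0("GLZLM_", c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                       "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP")),
    paste0("Shape_", c("Sphericity", "Compacity", "Surface_mm2",
                       "Volume_mL", "Volume_vx")),
    paste0("HISTO_", c("Entropy", "Entropy_log2", "Uniformity", "AUC_CSH")),
    paste0("Conventional_", conv),
    paste0("Discretized_", conv))
}

#' Shape features of a voxelized VOI
#'
#' Volume in voxels and mL, mesh-free surface from exposed voxel faces, and
#' the derived sphericity pi^(1/3) (6V)^(2/3) / S and compacity
#' V / (sqrt(pi) S^(3/2)) (V in mm3, S in mm2). Voxel-face surfaces
#' overestimate smooth surfaces, so the sphericity of a digitized ball sits
#' somewhat below 1 and a cube gives exactly pi^(1/3) 6^(2/3) / 6 ~ 0.806.
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Named numeric vector of length 5.
#' @export
shape_features <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, all(spacing > 0))
  n_vx <- sum(mask)
  if (n_vx == 0) stop("empty VOI", call. = FALSE)
  vol_mm3 <- n_vx * prod(spacing)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  surf <- 0
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      dvec <- c(0L, 0L, 0L)
      dvec[a] <- s
      nb <- shift_array(mask, dvec)
      exposed <- mask & (is.na(nb) | !nb)
      surf <- surf + sum(exposed) * face_area[a]
    }
  }
  c(Shape_Sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / surf,
    Shape_Compacity = vol_mm3 / (sqrt(pi) * surf^(3 / 2)),
    Shape_Surface_mm2 = surf,
    Shape_Volume_mL = vol_mm3 / 1000,
    Shape_Volume_vx = n_vx)
}

#' Histogram features
#'
#' First-order statistics of the discretized gray-level histogram: entropy in
#' nats and bits, uniformity (sum p^2), and the area under the cumulative
#' intensity-volume histogram (AUC-CSH): the fraction of the VOI above x% of
#' the maximum bin-centre intensity, integrated exactly over x in \[0,1\]
#' (the exact integral of the step function, equal to the mean of the
#' clamped intensity fractions).
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 4.
#' @export
histogram_features <- function(d) {
  li <- d$levels[!is.na(d$levels)]
  counts <- tabulate(li, nbins = d$bin_count)
  p <- counts[counts > 0] / length(li)
  ent <- -sum(p * log(p))
  vals <- bin_centres(d)[li]
  vmax <- max(vals)
  auc <- if (vmax > 0) mean(pmin(pmax(vals / vmax, 0), 1)) else 1
  c(HISTO_Entropy = ent,
    HISTO_Entropy_log2 = ent / log(2),
    HISTO_Uniformity = sum(p^2),
    HISTO_AUC_CSH = auc)
}

moments_block <- function(x) {
  n <- length(x)
  mu <- mean(x)
  sdev <- stats::sd(x)
  if (!is.finite(sdev) || sdev == 0) {
    return(c(SD = 0, Skewness = 0, Kurtosis = 0, ExcessKurtosis = 0))
  }
  m2 <- mean((x - mu)^2)
  skew <- mean((x - mu)^3) / m2^1.5
  kurt <- mean((x - mu)^4) / m2^2
  c(SD = sdev, Skewness = skew, Kurtosis = kurt, ExcessKurtosis = kurt - 3)
}

peak_mean <- function(arr, mask, spacing, centre_vox, volume_ml = 0.5) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  cc <- lapply(1:3, function(a) ((seq_len(dim(arr)[a]) - centre_vox[a]) * spacing[a])^2)
  d2 <- outer(outer(cc[[1]], cc[[2]], "+"), cc[[3]], "+")
  sph <- d2 <= r^2 & mask
  mean(arr[sph])
}

conventional_block <- function(x, mask, spacing, arr, peak_volume_ml, prefix) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mo <- moments_block(x)
  vol_ml <- sum(mask) * prod(spacing) / 1000
  centre <- arrayInd(which(mask)[which.max(x)], dim(arr))[1, ]
  pk <- peak_mean(arr, mask, spacing, centre, peak_volume_ml)
  out <- c(q[1], q[2], q[3], min(x), mean(x), max(x), mo["SD"], pk,
           mean(x) * vol_ml, mo["Skewness"], mo["Kurtosis"], mo["ExcessKurtosis"])
  names(out) <- paste0(prefix, "_", c("Q1", "Q2", "Q3", "min", "mean", "max",
                                      "SD", "peak", "TLG", "Skewness",
                                      "Kurtosis", "ExcessKurtosis"))
  out
}

#' Conventional and discretized intensity indices
#'
#' Twelve first-order indices (quartiles with linear-interpolation quantiles,
#' min/mean/max, sample SD, peak as the mean over a 0.5 mL sphere centred on
#' the maximum voxel intersected with the VOI, TLG = mean x volume in mL, and
#' population-moment skewness/kurtosis with excess kurtosis = kurtosis - 3).
#' The conventional variant runs on the raw resampled intensities, the
#' discretized variant on bin-centre values. For a constant lesion SD,
#' skewness, kurtosis and excess kurtosis are all defined as 0.
#'
#' @inheritParams glcm_matrix
#' @param peak_volume_ml Peak-sphere volume in mL.
#' @return Named numeric vector of length 24 (12 `Conventional_`, 12
#'   `Discretized_`).
#' @export
conventional_indices <- function(d, peak_volume_ml = 0.5) {
  x_raw <- d$continuous[d$mask]
  centres <- bin_centres(d)
  disc_arr <- array(NA_real_, dim = dim(d$levels))
  disc_arr[d$mask] <- centres[d$levels[d$mask]]
  x_disc <- disc_arr[d$mask]
  c(conventional_block(x_raw, d$mask, d$spacing, d$continuous, peak_volume_ml,
                       "Conventional"),
    conventional_block(x_disc, d$mask, d$spacing, disc_arr, peak_volume_ml,
                       "Discretized"))
}

#' Extract the full 65-feature panel from one volume + VOI
#'
#' Runs [preprocess_volume()] then all feature families, returning the
#' canonical 65-vector (see [feature_names()]).
#'
#' @param vol [image_volume()] (SUV or KI_SCALED).
#' @param v A [voi()] on the same grid.
#' @param cfg A [pipeline_config()].
#' @return Named numeric vector of length 65.
#' @export
extract_features <- function(vol, v, cfg = pipeline_config()) {
  d <- preprocess_volume(vol, v, cfg)
  out <- c(glcm_features(d), ngldm_features(d), glrlm_features(d),
           glzlm_features(d), shape_features(d$mask, d$spacing),
           histogram_features(d), conventional_indices(d, cfg$peak_volume_ml))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract static and DTP feature vectors for one lesion
#'
#' @param suv Static SUV [image_volume()].
#' @param ki Ki map ([image_volume()], unit `KI_SCALED`).
#' @param voi_suv VOI on the SUV grid.
#' @param voi_ki VOI on the Ki grid (typically [transfer_voi()] output).
#' @param cfg A [pipeline_config()].
#' @return A tibble with columns `feature`, `static`, `dtp` (65 rows).
#' @export
extract_all <- function(suv, ki, voi_suv, voi_ki, cfg = pipeline_config()) {
  fs <- extract_features(suv, voi_suv, cfg)
  fd <- extract_features(ki, voi_ki, cfg)
  tibble::tibble(feature = feature_names(),
                 static = unname(fs), dtp = unname(fd))
}
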