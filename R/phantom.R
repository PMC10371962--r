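#' Pipeline configuration
#'
#' Collects the acquisition and preprocessing constants used throughout the
#' pipeline: the two acquisition times, the fixed-bound discretization (64
#' bins over \[0, 20\] on the SUV scale), the 4 mm isotropic resampling, the
#' 30% fractional-SUVmax segmentation threshold, the x100 Ki intensity
#' scaling, and the 0.5 mL peak-sphere volume.
#'
#' @param t1_min,t2_min Acquisition times in minutes (`t2_min > t1_min > 0`).
#' @param bin_count Number of gray levels for discretization (>= 2).
#' @param intensity_min,intensity_max Absolute discretization bounds on the
#'   SUV scale.
#' @param resample_mm Isotropic voxel size for feature extraction (mm).
#' @param threshold_fraction Segmentation threshold fraction in (0,1).
#' @param ki_scale Multiplier taking raw Ki (1/min) onto the SUV scale.
#' @param peak_volume_ml Volume of the peak-averaging sphere (mL).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(t1_min = 61, t2_min = 133, bin_count = 64,
                            intensity_min = 0, intensity_max = 20,
                            resample_mm = 4, threshold_fraction = 0.30,
                            ki_scale = 100, peak_volume_ml = 0.5) {
  if (!(t2_min > t1_min && t1_min > 0)) stop("need t2_min > t1_min > 0", call. = FALSE)
  if (bin_count < 2) stop("bin_count must be >= 2", call. = FALSE)
  if (intensity_max <= intensity_min) stop("intensity_max must exceed intensity_min", call. = FALSE)
  if (resample_mm <= 0) stop("resample_mm must be positive", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0,1)", call. = FALSE)
  }
  structure(list(t1_min = t1_min, t2_min = t2_min, bin_count = as.integer(bin_count),
                 intensity_min = intensity_min, intensity_max = intensity_max,
                 resample_mm = resample_mm, threshold_fraction = threshold_fraction,
                 ki_scale = ki_scale, peak_volume_ml = peak_volume_ml),
            class = "pipeline_config")
}

#' Seeded Gaussian random field
#'
#' Stationary Gaussian field with a Gaussian correlation kernel of the stated
#' correlation length, generated by circular (FFT) convolution of white noise
#' and normalized to unit variance. Supplies controllable lesion texture for
#' the phantom generator.
#'
#' @param dims Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param cor_mm Correlation length in mm (0 gives white noise).
#' @return Numeric 3D array with (empirical) zero mean and unit SD.
#' @export
gaussian_random_field <- function(dims, spacing, cor_mm) {
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  if (cor_mm <= 0) return(w)
  ax <- lapply(1:3, function(a) {
    n <- dims[a]
    d <- pmin(0:(n - 1), n - (0:(n - 1))) * spacing[a]
    d^2
  })
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  k <- exp(-d2 / (2 * cor_mm^2))
  g <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / prod(dims)
  (g - mean(g)) / stats::sd(g)
}

#' Phantom specification for a dual-time-point study
#'
#' Defines the synthetic patient: a uniform low-uptake background, one or more
#' spherical lesions with a planted net influx rate Ki (optionally textured by
#' a Gaussian random field), a blood-pool sphere carrying the pure plasma
#' signal, and a multiplicative Gaussian noise level per time point.
#'
#' Lesion fields: `centre` (mm), `radius_mm`, `ki` (1/min), `v` (dimensionless
#' intercept), `texture_cor_mm`, `texture_amp` (fractional heterogeneity
#' amplitude, SD of the Ki field relative to its mean).
#'
#' @param dims Grid dimensions (default 24^3).
#' @param spacing Voxel spacing in mm (default 4 mm isotropic).
#' @param background_suv Background tissue level at `t1` (SUV).
#' @param background_ki Background net influx rate (1/min).
#' @param lesions List of lesion definitions (see details above).
#' @param blood_pool List with `centre` (mm), `radius_mm`, `pure_plasma` flag.
#' @param noise_cov Length-2 coefficient of variation of multiplicative
#'   Gaussian noise at (t1, t2); 0 disables noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(24L, 24L, 24L), spacing = c(4, 4, 4),
                         background_suv = 0.5, background_ki = 0.001,
                         lesions = list(list(centre = c(36, 36, 36), radius_mm = 12,
                                             ki = 0.02, v = 0.3,
                                             texture_cor_mm = 8, texture_amp = 0.3)),
                         blood_pool = list(centre = c(72, 72, 72), radius_mm = 10,
                                           pure_plasma = TRUE),
                         noise_cov = c(0, 0)) {
  stopifnot(length(dims) == 3L, all(dims >= 2), length(spacing) == 3L,
            all(spacing > 0))
  if (any(noise_cov < 0)) stop("noise CoV must be >= 0", call. = FALSE)
  lo <- -spacing / 2
  hi <- (dims - 1) * spacing + spacing / 2
  check_sphere <- function(centre, radius, what) {
    if (radius <= 0) stop(sprintf("%s radius must be positive", what), call. = FALSE)
    if (any(centre - radius < lo) || any(centre + radius > hi)) {
      stop(sprintf("%s extends beyond the grid", what), call. = FALSE)
    }
  }
  for (l in lesions) check_sphere(l$centre, l$radius_mm, "lesion")
  if (!is.null(blood_pool)) check_sphere(blood_pool$centre, blood_pool$radius_mm, "blood pool")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 background_suv = background_suv, background_ki = background_ki,
                 lesions = lesions, blood_pool = blood_pool,
                 noise_cov = rep(noise_cov, length.out = 2)),
            class = "phantom_spec")
}

#' Simulate a dual-time-point study under the Patlak model
#'
#' Tissue curves are generated directly from the irreversible-uptake model,
#' C(t) = Ki * Int(0,t) Cp + V * Cp(t), evaluated at the two acquisition
#' times, so that at zero noise [compute_ki_map()] recovers the planted Ki
#' field exactly (an algebraic identity, not an approximation). The background
#' intercept V is chosen so the background tissue level at t1 equals the
#' specified background SUV. Blood-pool voxels carry Cp(t) itself when the
#' `pure_plasma` flag is set.
#'
#' @param spec A [phantom_spec()].
#' @param f An [input_function()].
#' @param t1,t2 Acquisition times in minutes (`t2 > t1 > 0`).
#' @param seed Optional integer seed.
#' @return A list with elements `suv_t1`, `act_t2`, `truth_ki` (Ki x 100,
#'   `KI_SCALED`), `lesion_masks` (list of [voi()]), and `blood_centre`.
#' @export
simulate_dtp_study <- function(spec, f, t1, t2, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(f, "input_function"))
  if (!(t2 > t1 && t1 > 0)) stop("need t2 > t1 > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ref <- image_volume(array(0, dim = spec$dims), spec$spacing, c(0, 0, 0), "SUV")
  cp1 <- if_value(f, t1); cp2 <- if_value(f, t2)
  i1 <- if_integral(f, t1); i2 <- if_integral(f, t2)
  if (cp1 <= 0 || cp2 <= 0) stop("input function must be positive at t1 and t2", call. = FALSE)
  ki <- array(spec$background_ki, dim = spec$dims)
  v_bg <- (spec$background_suv - spec$background_ki * i1) / cp1
  if (v_bg < 0) stop("background SUV too low for the background Ki and Cp", call. = FALSE)
  v_arr <- array(v_bg, dim = spec$dims)
  lesion_masks <- vector("list", length(spec$lesions))
  occupied <- array(FALSE, dim = spec$dims)
  for (j in seq_along(spec$lesions)) {
    l <- spec$lesions[[j]]
    m <- sphere_mask(ref, l$centre, l$radius_mm)
    if (any(occupied & m)) stop("overlapping lesions", call. = FALSE)
    occupied <- occupied | m
    field <- l$ki
    amp <- l$texture_amp %||% 0
    if (amp > 0) {
      g <- gaussian_random_field(spec$dims, spec$spacing, l$texture_cor_mm %||% 0)
      field <- l$ki * (1 + amp * g[m])
    }
    ki[m] <- pmax(field, 0)
    v_arr[m] <- l$v
    lesion_masks[[j]] <- voi(m, source = "USER")
  }
  blood_centre <- NULL
  bp_mask <- NULL
  if (!is.null(spec$blood_pool)) {
    bp <- spec$blood_pool
    bp_mask <- sphere_mask(ref, bp$centre, bp$radius_mm)
    if (any(occupied & bp_mask)) stop("blood pool overlaps a lesion", call. = FALSE)
    blood_centre <- bp$centre
  }
  c1 <- ki * i1 + v_arr * cp1
  c2 <- ki * i2 + v_arr * cp2
  if (!is.null(bp_mask) && isTRUE(spec$blood_pool$pure_plasma)) {
    c1[bp_mask] <- cp1
    c2[bp_mask] <- cp2
    ki[bp_mask] <- 0
  }
  if (spec$noise_cov[1] > 0) {
    c1 <- pmax(c1 * (1 + spec$noise_cov[1] * stats::rnorm(length(c1))), 0)
  }
  if (spec$noise_cov[2] > 0) {
    c2 <- pmax(c2 * (1 + spec$noise_cov[2] * stats::rnorm(length(c2))), 0)
  }
  list(suv_t1 = image_volume(c1, spec$spacing, c(0, 0, 0), "SUV"),
       act_t2 = image_volume(c2, spec$spacing, c(0, 0, 0), "SUV"),
       truth_ki = image_volume(100 * ki, spec$spacing, c(0, 0, 0), "KI_SCALED"),
       lesion_masks = lesion_masks,
       blood_centre = blood_centre)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
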