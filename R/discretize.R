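#' Absolute-bound gray-level discretization index
#'
#' Maps an intensity to a gray level in 1..`n` using fixed absolute bounds
#' (not the lesion's own min-max):
#'
#'   bin(x) = floor((x - lo) / (hi - lo) * n) + 1, clamped to \[1, n\]
#'
#' so `x <= lo` (including negative Ki x 100 values) maps to 1 and `x >= hi`
#' maps to `n`. With the default 64-bin \[0, 20\] configuration the bin width
#' is 0.3125 SUV. Because the bounds are absolute, adding a constant to the
#' intensities changes the features; that is intended.
#'
#' @param x Numeric intensities.
#' @param n Number of bins (>= 2).
#' @param lo,hi Absolute bounds, `hi > lo`.
#' @return Integer gray levels in 1..n.
#' @export
bin_index <- function(x, n = 64, lo = 0, hi = 20) {
  stopifnot(n >= 2, hi > lo)
  lev <- floor((x - lo) / (hi - lo) * n) + 1
  as.integer(pmin(pmax(lev, 1), n))
}

#' Preprocess a volume and VOI for feature extraction
#'
#' Resamples the intensity volume (trilinear) and the VOI mask (nearest
#' neighbour) to the configured isotropic voxel size, then discretizes the
#' in-VOI intensities with [bin_index()] under the configured fixed bounds.
#' Both the integer gray levels (for the texture and histogram families) and
#' the continuous resampled intensities (for the conventional indices) are
#' returned. A Ki input must already carry the `KI_SCALED` tag, i.e. the x100
#' scaling onto the SUV scale has been applied.
#'
#' @param vol [image_volume()] with unit `SUV` or `KI_SCALED`.
#' @param v A [voi()] on the same grid as `vol`.
#' @param cfg A [pipeline_config()].
#' @return A list of class `discretized_volume` with elements `levels`
#'   (integer array, NA outside the VOI), `continuous` (resampled
#'   intensities), `mask`, `bin_count`, `bounds`, `spacing`, `unit`.
#' @export
preprocess_volume <- function(vol, v, cfg = pipeline_config()) {
  stopifnot(inherits(vol, "image_volume"), inherits(v, "voi"),
            inherits(cfg, "pipeline_config"))
  if (vol$unit == "ACTIVITY") {
    stop("feature extraction expects SUV or KI_SCALED input", call. = FALSE)
  }
  if (!identical(dim(vol$data), dim(v$mask))) {
    stop("VOI and volume grids do not match", call. = FALSE)
  }
  needs_resample <- any(abs(vol$spacing - cfg$resample_mm) > 1e-9)
  if (needs_resample) {
    rv <- resample_volume(vol, cfg$resample_mm, mode = "linear")
    mv <- image_volume(array(as.numeric(v$mask), dim = dim(v$mask)),
                       vol$spacing, vol$origin, unit = vol$unit)
    rm_ <- resample_volume(mv, cfg$resample_mm, mode = "nearest")
    mask <- rm_$data > 0.5
    dat <- rv$data
    spacing <- rv$spacing
  } else {
    mask <- v$mask
    dat <- vol$data
    spacing <- vol$spacing
  }
  if (!any(mask)) stop("VOI empty after resampling", call. = FALSE)
  lev <- array(NA_integer_, dim = dim(dat))
  lev[mask] <- bin_index(dat[mask], cfg$bin_count, cfg$intensity_min, cfg$intensity_max)
  structure(list(levels = lev, continuous = dat, mask = mask,
                 bin_count = cfg$bin_count,
                 bounds = c(cfg$intensity_min, cfg$intensity_max),
                 spacing = spacing, unit = vol$unit),
            class = "discretized_volume")
}

#' Bin-centre intensity of each gray level
#'
#' @param d A `discretized_volume`.
#' @return Numeric vector of length `bin_count`.
#' @keywords internal
bin_centres <- function(d) {
  w <- diff(d$bounds) / d$bin_count
  d$bounds[1] + (seq_len(d$bin_count) - 0.5) * w
}
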