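#' Image-derived blood-pool activity
#'
#' Means of two spherical VOIs placed in the left ventricle (15 mm diameter)
#' and left atrium (10 mm diameter) on the static SUV image, averaged with
#' equal weight. The result anchors the population input function to the
#' patient via [scale_input_function()].
#'
#' @param suv_t1 Static SUV [image_volume()].
#' @param lv_centre,la_centre World coordinates (mm) of the sphere centres.
#' @param lv_diameter_mm,la_diameter_mm Sphere diameters in mm.
#' @return A single SUV value.
#' @export
blood_pool_activity <- function(suv_t1, lv_centre, la_centre,
                                lv_diameter_mm = 15, la_diameter_mm = 10) {
  stopifnot(inherits(suv_t1, "image_volume"))
  m_lv <- sphere_mask(suv_t1, lv_centre, lv_diameter_mm / 2)
  m_la <- sphere_mask(suv_t1, la_centre, la_diameter_mm / 2)
  (mean(suv_t1$data[m_lv]) + mean(suv_t1$data[m_la])) / 2
}

#' Dual-time-point Patlak Ki map
#'
#' Computes, voxel by voxel, the slope of the Patlak plot through the two
#' measured points:
#'
#'   Ki = \[C(t2)/Cp(t2) - C(t1)/Cp(t1)\] /
#'        \[Int(0,t2) Cp / Cp(t2) - Int(0,t1) Cp / Cp(t1)\]
#'
#' The irreversible-uptake (Patlak) regime makes this ratio the net influx
#' rate in 1/min when tissue and plasma share intensity units at each time
#' point. The returned map is multiplied by `scale_factor` (default 100) so it
#' lives on the SUV intensity scale used downstream for discretization, and is
#' tagged `KI_SCALED`. Negative slopes are preserved; clamping happens only at
#' feature-extraction time via the fixed discretization bounds.
#'
#' @param suv_t1 Tissue volume at `t1` (SUV units).
#' @param act_t2 Tissue volume at `t2`, co-registered to `suv_t1` and in units
#'   consistent with `Cp` at `t2` (SUV or activity).
#' @param f The patient-scaled [input_function()].
#' @param t1,t2 Acquisition times in minutes, `t2 > t1 > 0`.
#' @param mask Optional logical array; voxels outside are set to 0.
#' @param scale_factor Multiplier applied to the raw 1/min map (default 100).
#' @return An [image_volume()] with unit `KI_SCALED`.
#' @export
compute_ki_map <- function(suv_t1, act_t2, f, t1, t2, mask = NULL,
                           scale_factor = 100) {
  stopifnot(inherits(suv_t1, "image_volume"), inherits(act_t2, "image_volume"),
            inherits(f, "input_function"))
  if (!(t2 > t1 && t1 > 0)) stop("need t2 > t1 > 0", call. = FALSE)
  stop_unless_same_grid(suv_t1, act_t2, "t1 and t2 volumes")
  cp1 <- if_value(f, t1); cp2 <- if_value(f, t2)
  if (cp1 <= 0 || cp2 <= 0) stop("Cp must be positive at both time points", call. = FALSE)
  i1 <- if_integral(f, t1); i2 <- if_integral(f, t2)
  denom <- i2 / cp2 - i1 / cp1
  if (denom <= 0) {
    stop("non-positive Patlak denominator: invalid timing/input-function configuration",
         call. = FALSE)
  }
  ki <- (act_t2$data / cp2 - suv_t1$data / cp1) / denom
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(ki))) stop("mask grid mismatch", call. = FALSE)
    ki[!mask] <- 0
  }
  image_volume(scale_factor * ki, suv_t1$spacing, suv_t1$origin, unit = "KI_SCALED")
}
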