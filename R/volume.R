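#' Image volumes
#'
#' An `image_volume` is the carrier for every 3D scalar map in the pipeline:
#' the routine static SUV image, the delayed activity image, and the Patlak
#' net-influx-rate map (stored as Ki x 100 so it shares the SUV intensity
#' scale). It is a plain list holding the voxel array plus the grid geometry
#' (voxel spacing in mm and the world-space position of the first voxel
#' centre).
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing Numeric length-3, voxel size in mm along each axis (> 0).
#' @param origin Numeric length-3, world coordinates (mm) of the centre of
#'   voxel (1,1,1).
#' @param unit One of `"SUV"`, `"ACTIVITY"`, `"KI_SCALED"`. `KI_SCALED` marks
#'   a Ki map already multiplied by 100.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         unit = c("SUV", "ACTIVITY", "KI_SCALED")) {
  unit <- match.arg(unit)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("expected 3D volume", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("volume dimensions must be positive", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be three finite values (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin, unit = unit),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, dims %s, spacing %s mm\n",
              x$unit, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_unless_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are not on the same grid (dims/spacing/origin differ)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI file
#'
#' Voxel data, spacing and origin are taken from the NIfTI header. The
#' intensity unit is not stored in NIfTI and must be declared by the caller.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param unit Intensity unit tag, see [image_volume()].
#' @return An [image_volume()].
#' @export
read_volume <- function(path, unit = c("SUV", "ACTIVITY", "KI_SCALED")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume", call. = FALSE)
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    spacing <- abs(RNifti::pixdim(img))[1:3]
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-finite or non-positive voxel spacing in header", call. = FALSE)
  }
  origin <- as.numeric(xf[1:3, 4])
  image_volume(array(as.numeric(img), dim = d), spacing, origin, unit)
}

#' Write a volume to a NIfTI file
#'
#' Float data round-trips bit-exactly through [read_volume()]. The affine is
#' diagonal (axis-aligned grid) with the translation set to the origin.
#'
#' @param v An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "image_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  m <- diag(c(v$spacing, 1))
  m[1:3, 4] <- v$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a binary mask as NIfTI
#'
#' @param mask Logical 3D array.
#' @param v Reference [image_volume()] supplying the grid.
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a logical array.
#' @export
write_mask <- function(mask, v, path) {
  write_volume(image_volume(array(as.numeric(mask), dim = dim(mask)),
                            v$spacing, v$origin, unit = v$unit), path)
}

#' @rdname write_mask
#' @param path File path.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  v$data > 0.5
}

#' World coordinates of voxel centres
#'
#' @param v An [image_volume()].
#' @return A list of three numeric vectors (x, y, z centre coordinates in mm).
#' @keywords internal
voxel_centres <- function(v) {
  lapply(1:3, function(a) v$origin[a] + (seq_len(dim(v$data)[a]) - 1) * v$spacing[a])
}

#' Spherical voxel mask
#'
#' Voxels whose centre lies within `radius_mm` of `centre_mm` (world
#' coordinates).
#'
#' @param v An [image_volume()].
#' @param centre_mm Numeric length-3 world coordinates (mm).
#' @param radius_mm Sphere radius (mm).
#' @param require_inside Error if the sphere extends beyond the field of view.
#' @return Logical array of `dim(v)`.
#' @export
sphere_mask <- function(v, centre_mm, radius_mm, require_inside = TRUE) {
  stopifnot(inherits(v, "image_volume"), radius_mm > 0)
  cc <- voxel_centres(v)
  if (require_inside) {
    lo <- v$origin - v$spacing / 2
    hi <- v$origin + (dim(v$data) - 1) * v$spacing + v$spacing / 2
    if (any(centre_mm - radius_mm < lo) || any(centre_mm + radius_mm > hi)) {
      stop("sphere exits the field of view", call. = FALSE)
    }
  }
  dx2 <- (cc[[1]] - centre_mm[1])^2
  dy2 <- (cc[[2]] - centre_mm[2])^2
  dz2 <- (cc[[3]] - centre_mm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  m <- d2 <= radius_mm^2
  if (!any(m)) stop("empty sphere after voxelization", call. = FALSE)
  m
}

trilinear_sample <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  xi <- cl(xi, d[1]); yi <- cl(yi, d[2]); zi <- cl(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - (d[1] > 1)); y0 <- pmin(floor(yi), d[2] - (d[2] > 1))
  z0 <- pmin(floor(zi), d[3] - (d[3] > 1))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  g <- function(ix, iy, iz) {
    lin <- outer(outer(ix, (iy - 1) * d[1], "+"), (iz - 1) * d[1] * d[2], "+")
    array(arr[lin], dim = c(nx, ny, nz))
  }
  wx <- function(w) array(rep(w, times = ny * nz), dim = c(nx, ny, nz))
  wy <- function(w) array(rep(rep(w, each = nx), times = nz), dim = c(nx, ny, nz))
  wz <- function(w) array(rep(w, each = nx * ny), dim = c(nx, ny, nz))
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  g(x0, y0, z0) * wx(1 - fx) * wy(1 - fy) * wz(1 - fz) +
    g(x1, y0, z0) * wx(fx) * wy(1 - fy) * wz(1 - fz) +
    g(x0, y1, z0) * wx(1 - fx) * wy(fy) * wz(1 - fz) +
    g(x1, y1, z0) * wx(fx) * wy(fy) * wz(1 - fz) +
    g(x0, y0, z1) * wx(1 - fx) * wy(1 - fy) * wz(fz) +
    g(x1, y0, z1) * wx(fx) * wy(1 - fy) * wz(fz) +
    g(x0, y1, z1) * wx(1 - fx) * wy(fy) * wz(fz) +
    g(x1, y1, z1) * wx(fx) * wy(fy) * wz(fz)
}

#' Resample a volume to an isotropic grid
#'
#' The physical extent of the volume (edge-to-edge) is preserved to within one
#' voxel; the output grid is aligned so the outer edges of the first voxels
#' coincide. Intensity volumes use trilinear interpolation, masks must use
#' nearest-neighbour so labels stay binary. Resampling at the native spacing
#' of a grid-aligned volume is the identity.
#'
#' @param v An [image_volume()].
#' @param target_mm Target isotropic voxel size in mm (> 0).
#' @param mode `"linear"` (intensities) or `"nearest"` (masks/labels).
#' @return An [image_volume()] with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_volume <- function(v, target_mm, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "image_volume"))
  if (!is.finite(target_mm) || target_mm <= 0) {
    stop("target spacing must be positive", call. = FALSE)
  }
  d <- dim(v$data)
  extent <- d * v$spacing
  nd <- pmax(1L, as.integer(ceiling(extent / target_mm - 1e-9)))
  # continuous input index (1-based) of each output voxel centre, per axis
  idx <- lapply(1:3, function(a) {
    (target_mm - v$spacing[a]) / (2 * v$spacing[a]) +
      (seq_len(nd[a]) - 1) * target_mm / v$spacing[a] + 1
  })
  out <- if (mode == "linear") {
    trilinear_sample(v$data, idx[[1]], idx[[2]], idx[[3]])
  } else {
    cl <- function(x, n) pmin(pmax(round(x), 1), n)
    i <- cl(idx[[1]], d[1]); j <- cl(idx[[2]], d[2]); k <- cl(idx[[3]], d[3])
    lin <- outer(outer(i, (j - 1) * d[1], "+"), (k - 1) * d[1] * d[2], "+")
    array(v$data[lin], dim = nd)
  }
  new_origin <- v$origin + (target_mm - v$spacing) / 2
  image_volume(out, rep(target_mm, 3), new_origin, unit = v$unit)
}
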