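neighbour_offsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off)) > 0
  if (connectivity == 26L) off[nz, , drop = FALSE]
  else if (connectivity == 6L) off[nz & rowSums(abs(off)) == 1, , drop = FALSE]
  else stop("connectivity must be 6 or 26", call. = FALSE)
}

#' Label connected components of a binary mask
#'
#' Flood-fill labelling with 26- (default) or 6-neighbourhood connectivity.
#' Used for the suprathreshold-component restriction in segmentation and for
#' the gray-level zones of the size-zone matrix.
#'
#' @param mask Logical 3D array.
#' @param connectivity 26 or 6.
#' @return Integer array of `dim(mask)`; 0 outside the mask, component labels
#'   1..K inside.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  labels <- array(0L, dims)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  offs <- neighbour_offsets(connectivity)
  coords <- arrayInd(idx, dims)
  ord <- integer(prod(dims))
  ord[idx] <- seq_along(idx)
  pending <- rep(TRUE, length(idx))
  lab <- 0L
  for (s in seq_along(idx)) {
    if (!pending[s]) next
    lab <- lab + 1L
    stack <- s
    pending[s] <- FALSE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      labels[idx[cur]] <- lab
      p <- coords[cur, ]
      nb <- sweep(offs, 2L, p, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (any(ok)) {
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
        o <- ord[lin]
        o <- o[o > 0L]
        o <- o[pending[o]]
        if (length(o)) {
          pending[o] <- FALSE
          stack <- c(stack, o)
        }
      }
    }
  }
  labels
}

#' Lesion volume of interest
#'
#' A `voi` couples a binary mask to the grid it was drawn on and records how
#' it was produced (fractional-SUVmax thresholding, transfer to the Ki map, or
#' user supplied).
#'
#' @param mask Logical 3D array with at least one voxel set.
#' @param source One of `"SUV_THRESHOLD"`, `"TRANSFERRED"`, `"USER"`.
#' @return An object of class `voi`.
#' @export
voi <- function(mask, source = c("USER", "SUV_THRESHOLD", "TRANSFERRED")) {
  source <- match.arg(source)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty VOI", call. = FALSE)
  structure(list(mask = mask, source = source), class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> %d voxels, source %s\n", sum(x$mask), x$source))
  invisible(x)
}

#' Fractional-SUVmax lesion segmentation
#'
#' Keeps voxels whose SUV is at least `fraction` of the maximum SUV inside the
#' seed region (default 30%), then restricts to the connected component that
#' contains the maximum voxel, so nearby unrelated uptake separated by
#' subthreshold voxels is excluded. The maximum is taken within the seed
#' region (not globally), so several lesions per study can be segmented
#' independently.
#'
#' @param suv SUV [image_volume()].
#' @param region Optional seed region: a list with integer voxel bounds `lo`
#'   and `hi` (length-3 each, inclusive). `NULL` uses the whole volume.
#' @param fraction Threshold as a fraction of the regional maximum, in (0,1).
#' @param connectivity Connectivity for the component restriction (26 or 6).
#' @return A [voi()] with source `"SUV_THRESHOLD"` on the full grid.
#' @export
threshold_segment <- function(suv, region = NULL, fraction = 0.30,
                              connectivity = 26L) {
  stopifnot(inherits(suv, "image_volume"))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  d <- dim(suv$data)
  if (is.null(region)) region <- list(lo = c(1L, 1L, 1L), hi = d)
  lo <- pmax(as.integer(region$lo), 1L)
  hi <- pmin(as.integer(region$hi), d)
  if (any(hi < lo)) stop("empty seed region", call. = FALSE)
  inbox <- array(FALSE, d)
  inbox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  vals <- suv$data[inbox]
  mx <- max(vals)
  if (!is.finite(mx) || mx <= 0) stop("seed region has no positive uptake", call. = FALSE)
  mask <- inbox & suv$data >= fraction * mx
  # component containing the (first) regional max voxel
  max_lin <- which(inbox & suv$data == mx)[1]
  labels <- label_components(mask, connectivity)
  keep <- labels == labels[max_lin]
  voi(keep & mask, source = "SUV_THRESHOLD")
}

#' Transfer a VOI to the Ki map, with optional voxel edits
#'
#' Copies the SUV-derived mask onto the (co-registered) Ki grid and applies
#' deterministic add/remove voxel edits, mirroring the manual clean-up step of
#' lesion delineation on parametric maps.
#'
#' @param v A [voi()].
#' @param ki Target [image_volume()] (must share the mask's grid shape).
#' @param add,remove Optional integer matrices (n x 3) of voxel indices to add
#'   or remove.
#' @return A [voi()] with source `"TRANSFERRED"`.
#' @export
transfer_voi <- function(v, ki, add = NULL, remove = NULL) {
  stopifnot(inherits(v, "voi"), inherits(ki, "image_volume"))
  if (!identical(dim(v$mask), dim(ki$data))) {
    stop("VOI and Ki map grids do not match", call. = FALSE)
  }
  mask <- v$mask
  d <- dim(mask)
  apply_edit <- function(m, vox, value) {
    if (is.null(vox)) return(m)
    vox <- matrix(as.integer(vox), ncol = 3)
    if (any(vox < 1) || any(vox[, 1] > d[1]) || any(vox[, 2] > d[2]) ||
        any(vox[, 3] > d[3])) {
      stop("edit voxel outside grid", call. = FALSE)
    }
    m[vox] <- value
    m
  }
  mask <- apply_edit(mask, add, TRUE)
  mask <- apply_edit(mask, remove, FALSE)
  if (!any(mask)) stop("empty VOI", call. = FALSE)
  voi(mask, source = "TRANSFERRED")
}
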