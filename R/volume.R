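# Label volumes: 3-D integer grids with a voxel-to-world affine (NIfTI
# convention, 0-based voxel indices) and a label map assigning each label id
# a name and a tissue class. Recognised classes: scalp, skull, csf, gray,
# white, structure (deep named targets). "Intracranial" means csf/gray/
# white/structure; "inside the outer skull table" additionally includes
# skull.

.INTRACRANIAL_CLASSES <- c("csf", "gray", "white", "structure")
.SKULL_IN_CLASSES <- c("skull", "csf", "gray", "white", "structure")

#' Construct a label volume
#'
#' @param data 3-D integer array of label ids (0 = background).
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices to mm).
#' @param labels Data frame with columns `id`, `name`, `class` describing
#'   every label used in `data`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine, labels) {
  if (length(dim(data)) != 3) stop("label volume data must be a 3-D array")
  .check_affine(affine)
  if (!is.data.frame(labels) ||
      !all(c("id", "name", "class") %in% names(labels)))
    stop("labels must be a data frame with columns id, name, class")
  used <- setdiff(unique(as.vector(data)), 0L)
  unknown <- setdiff(used, labels$id)
  if (length(unknown) > 0)
    stop(sprintf("labels in grid missing from label map: %s",
                 paste(unknown, collapse = ", ")))
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine,
                 labels = labels[order(labels$id), , drop = FALSE]),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  sp <- voxel_spacing(x)
  cat(sprintf("label_volume: %s voxels, spacing %s mm, %d labels\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(sp, 4), collapse = "x"),
              nrow(x$labels)))
  invisible(x)
}

#' Voxel spacing of a volume in mm
#'
#' @param vol A `label_volume` or `distance_field`.
#' @return Length-3 numeric vector (mm per voxel along each axis).
#' @export
voxel_spacing <- function(vol) {
  A <- vol$affine[1:3, 1:3]
  sqrt(colSums(A * A))
}

#' Convert between world (mm) and continuous 0-based voxel coordinates
#'
#' @param vol A `label_volume` or `distance_field`.
#' @param pts n x 3 matrix (or length-3 vector).
#' @return n x 3 matrix of coordinates.
#' @export
world_to_voxel <- function(vol, pts) {
  apply_affine(solve(vol$affine), pts)
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, pts) {
  apply_affine(vol$affine, pts)
}

# label ids at world points via nearest-voxel lookup; 0L outside the grid
labels_at <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  v <- round(world_to_voxel(vol, pts))
  dm <- dim(vol$data)
  ok <- v[, 1] >= 0 & v[, 1] < dm[1] &
        v[, 2] >= 0 & v[, 2] < dm[2] &
        v[, 3] >= 0 & v[, 3] < dm[3]
  out <- integer(nrow(pts))
  if (any(ok)) {
    idx <- 1 + v[ok, 1] + dm[1] * (v[ok, 2] + dm[2] * v[ok, 3])
    out[ok] <- vol$data[idx]
  }
  out
}

# label ids belonging to the given classes
.class_ids <- function(vol, classes) {
  vol$labels$id[vol$labels$class %in% classes]
}

#' Read / write a label volume as NIfTI plus a JSON label-map sidecar
#'
#' The image is written as NIfTI-1 with the affine in the sform; the label
#' map `{id, name, class}` goes to `<path>.labels.json` (or an explicit
#' sidecar path).
#'
#' @param vol A `label_volume`.
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar Label-map JSON path; default `<path>.labels.json`.
#' @return `read_label_volume` returns a `label_volume`.
#' @export
write_label_volume <- function(vol, path,
                               sidecar = paste0(path, ".labels.json")) {
  img <- RNifti::asNifti(vol$data, datatype = "int32")
  RNifti::sform(img) <- structure(.nifti_affine(vol$affine), code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(vol$labels, sidecar, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path, sidecar = paste0(path, ".labels.json")) {
  img <- RNifti::readNifti(path)
  labels <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  A <- .from_nifti_affine(structure(RNifti::xform(img), dimnames = NULL))
  label_volume(array(as.integer(img), dim = dim(img)), A, labels)
}

# RNifti xforms map 0-based voxel indices to mm already (NIfTI convention);
# these hooks exist so any convention fix lives in one place.
.nifti_affine <- function(A) A
.from_nifti_affine <- function(A) matrix(A[1:4, 1:4], 4, 4)

## ---- scalar field utilities -------------------------------------------

# trilinear interpolation of a 3-D array at continuous 0-based voxel coords;
# coordinates are clamped to the grid
.trilinear <- function(arr, v) {
  dm <- dim(arr)
  v[, 1] <- pmin(pmax(v[, 1], 0), dm[1] - 1)
  v[, 2] <- pmin(pmax(v[, 2], 0), dm[2] - 1)
  v[, 3] <- pmin(pmax(v[, 3], 0), dm[3] - 1)
  i0 <- pmin(floor(v[, 1]), dm[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(v[, 2]), dm[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(v[, 3]), dm[3] - 2); k0 <- pmax(k0, 0)
  fx <- v[, 1] - i0; fy <- v[, 2] - j0; fz <- v[, 3] - k0
  at <- function(di, dj, dk)
    arr[1 + (i0 + di) + dm[1] * ((j0 + dj) + dm[2] * (k0 + dk))]
  (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
    fx * fy * (1 - fz) * at(1, 1, 0) +
    (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
    fx * (1 - fy) * fz * at(1, 0, 1) +
    (1 - fx) * fy * fz * at(0, 1, 1) +
    fx * fy * fz * at(1, 1, 1)
}

# separable Gaussian smoothing of a 3-D array (replicated edges),
# sigma in voxels; used to build the level set whose gradient provides
# skull-surface normals
.smooth3d <- function(arr, sigma = 1.5) {
  half <- max(1L, ceiling(3 * sigma))
  off <- seq(-half, half)
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  dm <- dim(arr)
  shift_idx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)
  for (axis in 1:3) {
    out <- array(0, dm)
    for (m in seq_along(off)) {
      idx <- shift_idx(dm[axis], off[m])
      sl <- switch(axis,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + w[m] * sl
    }
    arr <- out
  }
  arr
}

## ---- distance fields ---------------------------------------------------

#' Build a Euclidean distance field from a binary vessel mask
#'
#' Computes the exact Euclidean distance transform of the mask in mm,
#' honouring anisotropic voxel spacing, on the same grid/affine as the
#' mask. The field is zero exactly on foreground (vessel) voxels. Queries
#' through [field_at()] use trilinear interpolation.
#'
#' Voxel axes must be mutually orthogonal (rotations and anisotropic
#' scalings are fine; shears are not).
#'
#' @param mask 3-D logical/0-1 array with at least one foreground voxel.
#' @param affine 4x4 voxel-to-world affine.
#' @return An object of class `distance_field`.
#' @export
build_distance_field <- function(mask, affine) {
  .check_affine(affine)
  if (length(dim(mask)) != 3) stop("mask must be a 3-D array")
  m <- as.logical(mask)
  if (!any(m)) stop("cannot build a distance field from an all-zero mask")
  A <- affine[1:3, 1:3]
  G <- t(A) %*% A
  offdiag <- G - diag(diag(G))
  if (max(abs(offdiag)) > 1e-6 * max(diag(G)))
    stop("distance field requires orthogonal voxel axes")
  sp <- sqrt(diag(G))
  d <- .edt3d(m, as.integer(dim(mask)), as.numeric(sp))
  structure(list(data = array(d, dim(mask)), affine = affine),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("distance_field: %s voxels, spacing %s mm, range [%.3g, %.3g] mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_spacing(x), 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Query a distance field at world points
#'
#' @param field A `distance_field`.
#' @param pts n x 3 matrix (or length-3 vector) of world mm coordinates;
#'   points outside the grid are clamped to its edge.
#' @return Numeric vector of interpolated distances in mm.
#' @export
field_at <- function(field, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  .trilinear(field$data, world_to_voxel(field, pts))
}
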