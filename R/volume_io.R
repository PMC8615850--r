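# NIfTI CT volumes, world-coordinate sampling and oblique-plane resampling.
# All geometry is done in world millimetres (RAS+ as encoded by the NIfTI
# affine), so anisotropic or oblique acquisitions need no special casing.

#' Construct a CT volume object
#'
#' A `ct_volume` bundles a 3D array of Hounsfield units with the 4x4
#' voxel-index-to-world-millimetre affine (NIfTI convention: the affine maps
#' *zero-based* voxel indices to world RAS+ coordinates).
#'
#' @param voxels 3D numeric array of HU values (all finite).
#' @param affine 4x4 invertible voxel-to-world transform.
#' @param fill_HU value returned by [sample_trilinear()] for points outside
#'   the grid. Default -1024 HU (air).
#' @return An object of class `ct_volume` with elements `voxels`, `affine`,
#'   `shape`, `voxel_size_mm` (affine column norms) and `fill_HU`.
#' @export
ct_volume <- function(voxels, affine, fill_HU = -1024) {
  if (length(dim(voxels)) != 3L)
    stop_dbso("dimensionality", "CT volume must be a 3D array")
  if (!all(is.finite(voxels)))
    stop_dbso("validation", "CT volume contains non-finite HU values")
  affine <- unclass(affine)
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!is.numeric(affine) || any(!is.finite(affine)))
    stop_dbso("geometry", "affine must be a finite numeric 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop_dbso("geometry", "affine is singular (degenerate voxel geometry)")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0))
    stop_dbso("geometry", "voxel sizes derived from the affine must be positive")
  structure(
    list(
      voxels = voxels,
      affine = affine,
      inv_affine = solve(affine),
      shape = dim(voxels),
      voxel_size_mm = vs,
      fill_HU = fill_HU
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, voxel size %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' Reads NIfTI-1/NIfTI-2 (optionally gzip-compressed). The sform transform is
#' preferred over the qform when both are present; a file with neither carries
#' no usable geometry and is rejected. On-disk scale factors
#' (`scl_slope`/`scl_inter`) are applied by the reader, so values are returned
#' as Hounsfield units as stored.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D scalar image.
#' @param fill_HU out-of-volume fill value, see [ct_volume()].
#' @return A [ct_volume()].
#' @export
load_ct <- function(path, fill_HU = -1024) {
  if (!file.exists(path))
    stop_dbso("io", sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_dbso("io", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop_dbso("dimensionality",
              sprintf("expected a 3D image, got %dD", length(dm)))
  if (hdr$sform_code > 0) {
    aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  } else if (hdr$qform_code > 0) {
    aff <- RNifti::xform(img, useQuaternionFirst = TRUE)
  } else {
    stop_dbso("geometry", "NIfTI file carries neither an sform nor a qform")
  }
  ct_volume(array(as.numeric(img), dim = dm), aff, fill_HU = fill_HU)
}

#' Write a CT volume to a NIfTI file
#'
#' Voxels are stored as 32-bit floats; the affine is written as the sform (and
#' mirrored into the qform).
#'
#' @param volume a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels, datatype = "float")
  aff <- structure(volume$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) stop_dbso("io", conditionMessage(e)))
  invisible(path)
}

#' Map world coordinates to continuous voxel indices (and back)
#'
#' Indices follow the NIfTI convention (zero-based, continuous); they are
#' legal outside the grid.
#'
#' @param ct a [ct_volume()].
#' @param xyz numeric vector of length 3, or an n x 3 matrix of points.
#' @return same shape as `xyz`.
#' @export
world_to_voxel <- function(ct, xyz) {
  .apply_affine(ct$inv_affine, xyz)
}

#' @rdname world_to_voxel
#' @param ijk continuous zero-based voxel indices, vector or n x 3 matrix.
#' @export
voxel_to_world <- function(ct, ijk) {
  .apply_affine(ct$affine, ijk)
}

.apply_affine <- function(A, pts) {
  if (is.matrix(pts)) {
    out <- pts %*% t(A[1:3, 1:3])
    out[, 1] <- out[, 1] + A[1, 4]
    out[, 2] <- out[, 2] + A[2, 4]
    out[, 3] <- out[, 3] + A[3, 4]
    out
  } else {
    as.numeric(A[1:3, 1:3] %*% pts + A[1:3, 4])
  }
}

#' Trilinear sampling of a CT volume at world points
#'
#' Interpolates the eight neighbouring voxels; any query whose neighbourhood
#' leaves the grid returns the fill value instead of erroring, because
#' sampling circles may graze the volume edge.
#'
#' @param ct a [ct_volume()].
#' @param xyz world point (length 3) or n x 3 matrix of points.
#' @param fill HU value for out-of-grid queries; defaults to `ct$fill_HU`.
#' @return numeric vector of HU values, one per query point.
#' @export
sample_trilinear <- function(ct, xyz, fill = ct$fill_HU) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  v <- world_to_voxel(ct, xyz)
  d <- ct$shape
  i0 <- floor(v[, 1]); j0 <- floor(v[, 2]); k0 <- floor(v[, 3])
  fx <- v[, 1] - i0;   fy <- v[, 2] - j0;   fz <- v[, 3] - k0
  inside <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    (i0 + 1) <= (d[1] - 1) & (j0 + 1) <= (d[2] - 1) & (k0 + 1) <= (d[3] - 1)
  out <- rep(as.numeric(fill), nrow(xyz))
  if (!any(inside)) return(out)
  i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  # 1-based linear indices of the 8 corners
  base <- (i0 + 1) + j0 * d[1] + k0 * d[1] * d[2]
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  vox <- ct$voxels
  c000 <- vox[base];            c100 <- vox[base + sx]
  c010 <- vox[base + sy];       c110 <- vox[base + sx + sy]
  c001 <- vox[base + sz];       c101 <- vox[base + sx + sz]
  c011 <- vox[base + sy + sz];  c111 <- vox[base + sx + sy + sz]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Specify an oblique resampling plane
#'
#' @param center world point (mm) at the centre of the plane.
#' @param basis_u,basis_v orthonormal world unit vectors spanning the plane
#'   (checked to 1e-9).
#' @param extent_mm plane extent `(width_u, height_v)` in mm.
#' @param resolution_mm pixel spacing, default 0.1 mm.
#' @return An object of class `plane_spec`.
#' @export
plane_spec <- function(center, basis_u, basis_v, extent_mm,
                       resolution_mm = 0.1) {
  if (abs(sum(basis_u^2) - 1) > 1e-9 || abs(sum(basis_v^2) - 1) > 1e-9 ||
      abs(sum(basis_u * basis_v)) > 1e-9)
    stop_dbso("geometry", "plane basis vectors must be orthonormal")
  if (resolution_mm <= 0 || any(extent_mm <= 0))
    stop_dbso("validation", "plane extent and resolution must be positive")
  structure(
    list(center = as.numeric(center), basis_u = as.numeric(basis_u),
         basis_v = as.numeric(basis_v),
         extent_mm = as.numeric(extent_mm),
         resolution_mm = as.numeric(resolution_mm)),
    class = "plane_spec"
  )
}

# world coordinates of every pixel centre of a plane, row-major over (i, j)
plane_pixel_grid <- function(plane) {
  n_u <- round(plane$extent_mm[1] / plane$resolution_mm)
  n_v <- round(plane$extent_mm[2] / plane$resolution_mm)
  ci <- (n_u + 1) / 2
  cj <- (n_v + 1) / 2
  du <- (seq_len(n_u) - ci) * plane$resolution_mm
  dv <- (seq_len(n_v) - cj) * plane$resolution_mm
  u <- rep(du, times = n_v)
  v <- rep(dv, each = n_u)
  pts <- cbind(
    plane$center[1] + u * plane$basis_u[1] + v * plane$basis_v[1],
    plane$center[2] + u * plane$basis_u[2] + v * plane$basis_v[2],
    plane$center[3] + u * plane$basis_u[3] + v * plane$basis_v[3]
  )
  list(points = pts, n_u = n_u, n_v = n_v, du = du, dv = dv)
}

#' Resample a CT volume on an oblique plane
#'
#' Each output pixel is the trilinear interpolation of the volume at the
#' pixel's world position `center + (i - ci) res basis_u + (j - cj) res
#' basis_v`. This is the 0.1 mm perpendicular/in-line resampling step used by
#' the center-of-mass ambiguity methods.
#'
#' @param ct a [ct_volume()].
#' @param plane a [plane_spec()].
#' @return An object of class `ct_slice`: `values` (n_u x n_v HU matrix),
#'   `spec` (the plane), and the in-plane pixel offsets `u_mm`, `v_mm`.
#' @export
resample_plane <- function(ct, plane) {
  g <- plane_pixel_grid(plane)
  vox <- world_to_voxel(ct, g$points)
  d <- ct$shape
  any_inside <- any(
    vox[, 1] > -0.5 & vox[, 1] < d[1] - 0.5 &
    vox[, 2] > -0.5 & vox[, 2] < d[2] - 0.5 &
    vox[, 3] > -0.5 & vox[, 3] < d[3] - 0.5
  )
  if (!any_inside)
    stop_dbso("empty_slice", "resampling plane lies entirely outside the volume")
  vals <- sample_trilinear(ct, g$points)
  structure(
    list(values = matrix(vals, nrow = g$n_u, ncol = g$n_v),
         spec = plane, u_mm = g$du, v_mm = g$dv),
    class = "ct_slice"
  )
}
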