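#' Construct a 3D volume
#'
#' A `vol` bundles a 3D scalar array with the 4x4 affine that maps 0-based
#' voxel indices to world coordinates in millimetres. The world convention is
#' RAS+: world x increases toward the right hemisphere, so positive x means
#' the right side of the brain. Tissue-probability maps are nonnegative;
#' Jacobian-modulated maps may exceed 1.
#'
#' @param data Numeric 3D array.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world mm.
#'   Defaults to a 1 mm isotropic grid centred at world (0,0,0).
#' @param space_tag Free-text label of the common space the volume lives in.
#' @return An object of class `vol` with elements `data`, `affine`,
#'   `space_tag`.
#' @examples
#' v <- vol(array(0, dim = c(5, 5, 5)))
#' dim(v$data)
#' @export
vol <- function(data, affine = NULL, space_tag = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop("'data' must have positive dimensions")
  storage.mode(data) <- "double"
  if (is.null(affine))
    affine <- centered_affine(dim(data), c(1, 1, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("'affine' must be invertible")
  structure(list(data = data, affine = affine, space_tag = space_tag),
            class = "vol")
}

#' @export
print.vol <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_sizes(x)
  cat(sprintf("<vol> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space '%s'\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], x$space_tag))
  cat(sprintf("  range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_vol <- function(x) inherits(x, "vol")

#' Affine for a grid centred on the world origin
#'
#' Builds a diagonal RAS+ affine placing the centre of the voxel grid at
#' world (0,0,0); with an odd first dimension the mid-sagittal plane x = 0
#' passes through voxel centres, which makes the grid mirrorable.
#'
#' @param dim Integer vector of 3 voxel counts.
#' @param voxel_size_mm Numeric vector of 3 voxel edge lengths in mm
#'   (scalar recycled).
#' @return A 4x4 affine matrix.
#' @export
centered_affine <- function(dim, voxel_size_mm = 1) {
  vs <- rep_len(as.numeric(voxel_size_mm), 3L)
  a <- diag(c(vs, 1))
  a[1:3, 4] <- -vs * (dim - 1) / 2
  a
}

voxel_sizes <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Map voxel indices to world coordinates
#'
#' @param v A `vol`.
#' @param ijk Integer vector of 3 zero-based voxel indices, or an n x 3
#'   matrix of them.
#' @return World coordinates in mm (vector or n x 3 matrix).
#' @export
voxel_to_world <- function(v, ijk) {
  stopifnot(is_vol(v))
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, nrow = 1L)
  xyz <- cbind(m, 1) %*% t(v$affine)
  out <- xyz[, 1:3, drop = FALSE]
  if (is.matrix(ijk)) out else drop(out)
}

#' Map a world coordinate to the nearest voxel index
#'
#' Inverts the affine and rounds to the nearest voxel. Coordinates mapping
#' outside the grid raise an error.
#'
#' @param v A `vol`.
#' @param xyz_mm World coordinate (length 3), or an n x 3 matrix.
#' @return Zero-based voxel indices (vector or n x 3 matrix).
#' @export
world_to_voxel <- function(v, xyz_mm) {
  stopifnot(is_vol(v))
  m <- if (is.matrix(xyz_mm)) xyz_mm else matrix(xyz_mm, nrow = 1L)
  ijk <- cbind(m, 1) %*% t(solve(v$affine))
  idx <- round(ijk[, 1:3, drop = FALSE])
  d <- dim(v$data)
  bad <- idx < 0 | idx >= matrix(d, nrow(idx), 3, byrow = TRUE)
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    stop(sprintf("world coordinate (%g, %g, %g) maps outside the voxel grid",
                 m[i, 1], m[i, 2], m[i, 3]))
  }
  out <- idx
  if (is.matrix(xyz_mm)) out else as.integer(drop(out))
}

#' Check that a grid is symmetric about the mid-sagittal plane
#'
#' Mid-sagittal flipping by index reversal is only geometrically valid when
#' reversing the first (x) voxel index sends every voxel centre to the
#' mirror position of its partner, i.e. world-x of voxel i and of voxel
#' Nx-1-i sum to zero everywhere. This computes the worst-case |sum| over
#' the grid (analytically, via the affine) and compares it to a tolerance.
#'
#' @param v A `vol`.
#' @param tol_mm Tolerance in mm (default 0.1).
#' @return A list with `is_mirrorable` (logical) and `max_world_error_mm`.
#' @examples
#' v <- vol(array(0, dim = c(5, 5, 5)))
#' check_grid_symmetry(v)
#' @export
check_grid_symmetry <- function(v, tol_mm = 0.1) {
  stopifnot(is_vol(v))
  d <- dim(v$data)
  a <- v$affine
  ## world-x(i,j,k) + world-x(Nx-1-i,j,k) =
  ##   a11*(Nx-1) + 2*a12*j + 2*a13*k + 2*a14  -- independent of i,
  ## so the worst case over the grid is attained at a (j,k) corner.
  jk <- expand.grid(j = c(0, d[2] - 1), k = c(0, d[3] - 1))
  s <- a[1, 1] * (d[1] - 1) + 2 * a[1, 2] * jk$j + 2 * a[1, 3] * jk$k +
    2 * a[1, 4]
  err <- max(abs(s))
  list(is_mirrorable = err <= tol_mm, max_world_error_mm = err)
}

#' Flip a volume about the mid-sagittal plane
#'
#' Reverses the first (x) voxel axis so the left and right hemispheres trade
#' places. This is exact (no interpolation) and valid only when the grid is
#' symmetric about world x = 0, which is guaranteed for data normalized to a
#' symmetric template; [check_grid_symmetry()] enforces it. The affine is
#' unchanged: on a mirror-symmetric grid index reversal already negates the
#' world-x of every voxel's content.
#'
#' @param v A `vol`.
#' @param tol_mm Geometry tolerance passed to [check_grid_symmetry()].
#' @return A `vol` with the x axis reversed.
#' @export
flip_x <- function(v, tol_mm = 0.1) {
  stopifnot(is_vol(v))
  g <- check_grid_symmetry(v, tol_mm)
  if (!g$is_mirrorable)
    stop(sprintf(
      "grid is not symmetric about x = 0 (max world error %.4g mm > %g mm); flipping by index reversal would misplace content",
      g$max_world_error_mm, tol_mm))
  out <- v
  out$data <- v$data[dim(v$data)[1]:1, , , drop = FALSE]
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  ## 6-sigma support: truncation error ~1e-9, so the discrete kernel's
  ## centre matches the continuous normalization closely
  r <- max(1L, ceiling(6 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## Banded convolution matrix (zero padding) for one axis.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  K
}

smooth_axis <- function(a, axis, kernel) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  K <- conv_matrix(d[axis], kernel)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- if (axis == 1L) a else aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- K %*% m
  ap <- array(m, dim = d[perm])
  if (axis == 1L) ap else aperm(ap, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with zero padding outside the grid (the
#' dominant convention in the SPM family of tools; reflect padding would
#' change values near edges). Anisotropic voxels are honoured: the per-axis
#' standard deviation in voxel units is `fwhm_mm / (voxel_size * sqrt(8 log 2))`.
#'
#' @param v A `vol`.
#' @param fwhm_mm Kernel full width at half maximum in mm; 0 returns the
#'   input unchanged.
#' @return The smoothed `vol`.
#' @examples
#' v <- vol(array(1, dim = c(9, 9, 9)))
#' s <- smooth_gaussian(v, 2)
#' s$data[5, 5, 5]  # interior of a constant volume is preserved
#' @export
smooth_gaussian <- function(v, fwhm_mm) {
  stopifnot(is_vol(v))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || is.na(fwhm_mm) ||
      fwhm_mm < 0)
    stop("'fwhm_mm' must be a single nonnegative number")
  if (fwhm_mm == 0) return(v)
  vs <- voxel_sizes(v)
  sigmas <- fwhm_mm / (vs * sqrt(8 * log(2)))
  out <- v$data
  for (ax in 1:3)
    out <- smooth_axis(out, ax, gaussian_kernel_1d(sigmas[ax]))
  v$data <- out
  v
}

## Marginal standard deviation of smoothed unit white noise at interior
## voxels: product over axes of sqrt(sum(k^2)).
smoothed_noise_sd_factor <- function(voxel_size_mm, fwhm_mm) {
  if (fwhm_mm == 0) return(1)
  sigmas <- fwhm_mm / (rep_len(voxel_size_mm, 3L) * sqrt(8 * log(2)))
  prod(vapply(sigmas, function(s) sqrt(sum(gaussian_kernel_1d(s)^2)),
              numeric(1)))
}

#' Read a 3D NIfTI volume
#'
#' Reads a single 3D scalar NIfTI-1 image (`.nii` or `.nii.gz`). When both
#' the qform and the sform are set and disagree beyond 1e-4, the sform is
#' preferred and a warning is emitted.
#'
#' @param path Path to a NIfTI file.
#' @param space_tag Label recorded on the returned volume.
#' @return A `vol`.
#' @export
read_volume <- function(path, space_tag = "unknown") {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L)
    stop("expected a single 3D image: ", path)
  hdr <- RNifti::niftiHeader(im)
  sf <- structure(RNifti::xform(im, useQuaternionFirst = FALSE),
                  imagedim = NULL)
  if (hdr$qform_code > 0 && hdr$sform_code > 0) {
    qf <- RNifti::xform(im, useQuaternionFirst = TRUE)
    if (max(abs(unclass(qf) - unclass(sf))) > 1e-4)
      warning("qform and sform disagree; using sform: ", path)
  }
  aff <- matrix(as.numeric(sf), 4, 4)
  vol(array(as.numeric(a), dim = dim(a)), aff, space_tag = space_tag)
}

#' Write a volume as NIfTI
#'
#' @param v A `vol`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_vol(v))
  im <- RNifti::asNifti(v$data)
  RNifti::sform(im) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}
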