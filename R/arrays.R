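# Voxel-array primitives: physical-unit EDT, labeling, morphology, smoothing.
# 3D arrays are dim = (nz, ny, nx); 2D inputs are promoted to (1, ny, nx).

promote3d <- function(a) {
  if (length(dim(a)) == 2L) array(a, dim = c(1L, dim(a))) else a
}

#' Exact anisotropic Euclidean distance transform
#'
#' Distance (in micrometres) from every voxel to the nearest `TRUE` voxel of
#' `sites`, together with the linear index of that nearest site voxel
#' (the feature transform, used for nearest-vessel ownership).
#'
#' @param sites logical/0-1 array, 2D or 3D `(z, y, x)`.
#' @param voxel_size_um physical voxel size per axis `(z, y, x)`.
#' @return list with `dist` (numeric array, um) and `nearest` (integer array
#'   of 1-based linear indices into `sites`; 0 where no site exists).
#' @export
edt_um <- function(sites, voxel_size_um) {
  a <- promote3d(sites)
  check_positive(voxel_size_um, "voxel_size_um")
  if (length(voxel_size_um) == 2L) voxel_size_um <- c(1, voxel_size_um)
  stopifnot(length(voxel_size_um) == 3L)
  d <- dim(a)
  res <- .cpp_edt(as.integer(a != 0), as.integer(d), as.numeric(voxel_size_um))
  dout <- dim(sites)  # linear indices agree between (1,ny,nx) and (ny,nx)
  list(dist = array(res$dist, dout), nearest = array(res$nearest, dout))
}

#' Label connected components
#'
#' @param mask logical/0-1 array (2D or 3D).
#' @param connectivity 26 (default, = 8 in 2D) or 6 (= 4 in 2D).
#' @return integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  a <- promote3d(mask)
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(a)
  lab <- .cpp_label(as.integer(a != 0), as.integer(d), as.integer(connectivity))
  out <- array(as.integer(lab), if (length(dim(mask)) == 2L) dim(mask) else d)
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

# Voxel offsets (dz, dy, dx) within a physical ball of `radius_um`.
ball_offsets <- function(radius_um, voxel_size_um) {
  if (length(voxel_size_um) == 2L) voxel_size_um <- c(Inf, voxel_size_um)
  r <- pmax(0L, floor(radius_um / voxel_size_um))
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * voxel_size_um[1])^2 + (g$dy * voxel_size_um[2])^2 +
    (g$dx * voxel_size_um[3])^2 <= radius_um^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Grayscale erosion / dilation over a physical ball footprint.
gray_erode <- function(img, radius_um, voxel_size_um) {
  a <- promote3d(img)
  off <- ball_offsets(radius_um, voxel_size_um)
  out <- .cpp_min_filter(as.numeric(a), as.integer(dim(a)), off)
  array(out, dim(img))
}

gray_dilate <- function(img, radius_um, voxel_size_um) {
  a <- promote3d(img)
  off <- ball_offsets(radius_um, voxel_size_um)
  out <- .cpp_max_filter(as.numeric(a), as.integer(dim(a)), off)
  array(out, dim(img))
}

# reflective ("dcba|abcd") boundary index, 1-based
reflect_index <- function(j, n) {
  j0 <- (j - 1L) %% (2L * n)
  j0 <- ifelse(j0 < 0L, j0 + 2L * n, j0)
  ifelse(j0 >= n, 2L * n - 1L - j0, j0) + 1L
}

gaussian_kernel1d <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Separable 1D convolution along one axis of a 3D array, reflective borders.
conv_axis <- function(a, axis, kernel) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in seq_along(kernel)) {
    cols <- reflect_index(idx + (o - 1L - r), n)
    K[cbind(idx, cols)] <- K[cbind(idx, cols)] + kernel[o]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  out <- K %*% m
  ap2 <- array(out, dim(ap))
  aperm(ap2, order(perm))
}

# 3D (or 2D) Gaussian smoothing parameterized by physical FWHM.
smooth_gaussian_um <- function(img, fwhm_um, voxel_size_um) {
  check_positive(fwhm_um, "fwhm_um")
  a <- promote3d(img)
  if (length(voxel_size_um) == 2L) voxel_size_um <- c(1, voxel_size_um)
  for (axis in 1:3) {
    if (dim(a)[axis] == 1L) next
    sigma_px <- fwhm_to_sigma(fwhm_um) / voxel_size_um[axis]
    if (sigma_px < 1e-8) next
    a <- conv_axis(a, axis, gaussian_kernel1d(sigma_px))
  }
  array(a, dim(img))
}
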