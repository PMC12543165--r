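# Image conditioning: FWHM-parameterized Gaussian smoothing, rolling-ball
# background subtraction (structure images only), MIP-based flat-field
# normalization, and affine 3D registration.
#
# Role enforcement guards the quantitative contract: rolling-ball and
# flat-field are refused on leakage-role stacks unless explicitly overridden,
# so leakage frames pass through the default pipeline untouched.

role_guard <- function(stack, op, override) {
  if (stack$channel_role == "leakage" && !override)
    stopf("%s is restricted to structure images; leakage stacks would be distorted (set override = TRUE to force)", op)
  invisible(TRUE)
}

#' 3D Gaussian smoothing parameterized by physical FWHM
#'
#' Separable Gaussian convolution with reflective boundaries, applied per
#' frame for 4D stacks. The per-axis sigma in pixels is
#' `fwhm_um / (2 sqrt(2 ln 2)) / voxel_size_axis`.
#'
#' @param stack an [image_stack()].
#' @param fwhm_um full width at half maximum, micrometres (1 um for in vivo
#'   two-photon stacks, 0.36 um for ex vivo confocal).
#' @return smoothed `image_stack`.
#' @export
gaussian_smooth <- function(stack, fwhm_um) {
  check_positive(fwhm_um, "fwhm_um")
  if (is_4d(stack)) {
    for (t in seq_len(n_frames(stack)))
      stack <- set_frame(stack, t,
                         smooth_gaussian_um(get_frame(stack, t), fwhm_um, stack$voxel_size_um))
  } else {
    stack$data <- smooth_gaussian_um(stack$data, fwhm_um, stack$voxel_size_um)
  }
  stack
}

#' Rolling-ball background subtraction
#'
#' Background is estimated by grayscale opening (erosion then dilation) with
#' a ball structuring element of physical radius `radius_um`, then subtracted;
#' output is clamped at 0. The default radius (25 um) is chosen to exceed the
#' largest vessel radius so foreground tubes survive.
#'
#' Applied only to structure images: on leakage stacks this distorts the
#' subtle fluorescence halos being quantified, so such calls error unless
#' `override = TRUE`.
#'
#' @param stack an [image_stack()] with `channel_role = "structure"`.
#' @param radius_um structuring-element radius, micrometres.
#' @param override force application to a leakage-role stack.
#' @return background-subtracted `image_stack`.
#' @export
rolling_ball_subtract <- function(stack, radius_um = 25, override = FALSE) {
  check_positive(radius_um, "radius_um")
  role_guard(stack, "rolling_ball_subtract", override)
  open1 <- function(a) {
    bg <- gray_dilate(gray_erode(a, radius_um, stack$voxel_size_um),
                      radius_um, stack$voxel_size_um)
    pmax(array(a - bg, dim(a)), 0)
  }
  if (is_4d(stack)) {
    for (t in seq_len(n_frames(stack)))
      stack <- set_frame(stack, t, open1(get_frame(stack, t)))
  } else stack$data <- open1(stack$data)
  stack
}

#' Estimate the illumination nonuniformity field
#'
#' Maximum-intensity projection over z (after zeroing an optional pial-vessel
#' exclusion mask), smoothed with a wide Gaussian and rescaled to mean 1.
#'
#' @param stack a 3D structural [image_stack()].
#' @param fwhm_um smoothing FWHM of the field estimate (default 20 um).
#' @param pial_mask optional logical array, same shape as the stack (or a
#'   vector of z-slice indices to exclude); masked voxels are removed from
#'   the MIP. Apical pial vessels otherwise dominate the projection.
#' @return a `flatfield_ref`: `field` (2D y-x matrix, mean 1, strictly
#'   positive) and the smoothing parameter.
#' @export
build_flatfield <- function(stack, fwhm_um = 20, pial_mask = NULL) {
  stopifnot(!is_4d(stack))
  a <- stack$data
  if (!is.null(pial_mask)) {
    if (is.numeric(pial_mask) && is.null(dim(pial_mask))) {
      a[pial_mask, , ] <- 0
    } else {
      stopifnot(all(dim(pial_mask) == dim(a)))
      a[pial_mask] <- 0
    }
  }
  mip <- apply(a, c(2, 3), max)
  sm <- smooth_gaussian_um(mip, fwhm_um, stack$voxel_size_um[2:3])
  m <- mean(sm)
  if (m <= 0) stopf("flat-field estimate is non-positive; cannot rescale")
  field <- sm / m
  if (any(field <= 0)) stopf("flat-field contains non-positive pixels (division hazard)")
  structure(list(field = field, smoothing_fwhm_um = fwhm_um), class = "flatfield_ref")
}

#' Flat-field normalization
#'
#' Voxelwise division of every z-slice (and frame) by the 2D illumination
#' field. Restricted to structure images; leakage stacks preserve true
#' spatial variation in extravasation and are refused without `override`.
#'
#' @param stack an [image_stack()].
#' @param ref a `flatfield_ref` from [build_flatfield()].
#' @param override force application to a leakage-role stack.
#' @return normalized `image_stack`.
#' @export
flatfield_normalize <- function(stack, ref, override = FALSE) {
  stopifnot(inherits(ref, "flatfield_ref"))
  role_guard(stack, "flatfield_normalize", override)
  d <- dim(stack$data)
  sp <- if (is_4d(stack)) d[3:4] else d[2:3]
  if (!all(dim(ref$field) == sp)) stopf("flat-field shape mismatch")
  if (any(ref$field <= 0)) stopf("flat-field must be strictly positive")
  div3 <- function(a) {
    for (z in seq_len(dim(a)[1])) a[z, , ] <- a[z, , ] / ref$field
    a
  }
  if (is_4d(stack)) {
    for (t in seq_len(n_frames(stack)))
      stack <- set_frame(stack, t, div3(get_frame(stack, t)))
  } else stack$data <- div3(stack$data)
  stack
}

# --- affine registration ----------------------------------------------------

ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

rot3 <- function(ax_deg, ay_deg, az_deg) {
  r <- pi / 180
  cx <- cos(ax_deg * r); sx <- sin(ax_deg * r)
  cy <- cos(ay_deg * r); sy <- sin(ay_deg * r)
  cz <- cos(az_deg * r); sz <- sin(az_deg * r)
  # axis order (z, y, x) coordinates; "in-plane" rotation mixes y and x
  Rin <- matrix(c(1, 0, 0, 0, cz, -sz, 0, sz, cz), 3, 3, byrow = TRUE)
  Ry  <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx  <- matrix(c(cx, -sx, 0, sx, cx, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rin
}

# physical-space params -> voxel-space 3x4 map for .cpp_affine_resample
params_to_voxel_affine <- function(par, vs, dims) {
  R <- rot3(par[4], par[5], par[6])
  tr <- par[1:3]
  ctr <- (dims - 1) / 2 * vs
  S <- diag(vs); Sinv <- diag(1 / vs)
  M <- Sinv %*% R %*% S
  offs <- Sinv %*% (R %*% (-ctr) + ctr + tr)
  cbind(M, offs)
}

resample_par <- function(vol, par, vs) {
  d <- dim(vol)
  A <- params_to_voxel_affine(par, vs, d)
  array(.cpp_affine_resample(as.numeric(vol), as.integer(d), A), d)
}

#' Affine 3D registration by normalized cross-correlation
#'
#' Registers a moving stack onto a fixed stack: a coarse integer-translation
#' search on smoothed volumes seeds a Nelder-Mead refinement of a rigid
#' transform (3 translations in micrometres, 3 rotations in degrees about the
#' volume center). Resampling is trilinear.
#'
#' @param moving,fixed 3D [image_stack()]s (or arrays sharing the fixed
#'   stack's calibration).
#' @param max_shift_vox half-width of the coarse translation search, voxels.
#' @param smooth_fwhm_um pre-smoothing for the metric (stabilizes the NCC
#'   landscape).
#' @return list: `transform` (3 x 4 matrix, micrometre coordinates, mapping
#'   fixed-space points into moving space), `params` (tz,ty,tx um;
#'   ax,ay,az deg), `resampled` (moving resampled into the fixed frame),
#'   `metric` (final NCC).
#' @export
register_affine <- function(moving, fixed, max_shift_vox = 5, smooth_fwhm_um = 3) {
  vs <- fixed$voxel_size_um
  mv <- if (inherits(moving, "image_stack")) moving$data else moving
  fx <- fixed$data
  stopifnot(all(dim(mv) == dim(fx)))
  mv_s <- smooth_gaussian_um(mv, smooth_fwhm_um, vs)
  fx_s <- smooth_gaussian_um(fx, smooth_fwhm_um, vs)

  # coarse integer-translation sweep (z limited: axial shifts are expensive)
  best <- c(0, 0, 0); best_m <- -Inf
  rng <- -max_shift_vox:max_shift_vox
  for (dzv in -1:1) for (dyv in rng) for (dxv in rng) {
    par <- c(dzv * vs[1], dyv * vs[2], dxv * vs[3], 0, 0, 0)
    m <- ncc(resample_par(mv_s, par, vs), fx_s)
    if (m > best_m) { best_m <- m; best <- par[1:3] }
  }

  obj <- function(p) -ncc(resample_par(mv_s, p, vs), fx_s)
  fit <- optim(c(best, 0, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10,
                              parscale = c(vs, 0.5, 0.5, 0.5)))
  if (fit$convergence != 0 && -fit$value < 0.2)
    stopf("registration failed to converge (final NCC = %.3f)", -fit$value)
  par <- fit$par
  res <- resample_par(mv, par, vs)
  ctr <- (dim(fx) - 1) / 2 * vs
  R <- rot3(par[4], par[5], par[6])
  transform <- cbind(R, R %*% (-ctr) + ctr + par[1:3])
  out <- image_stack(res, voxel_size_um = vs,
                     frame_interval_s = fixed$frame_interval_s,
                     channel_role = if (inherits(moving, "image_stack")) moving$channel_role else "structure")
  list(transform = transform, params = par, resampled = out, metric = -fit$value)
}

#' Save an affine transform as JSON
#' @param transform 3 x 4 matrix in micrometre coordinates.
#' @param path output file.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(matrix_3x4_row_major = as.numeric(t(transform)),
                            units = "um"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
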