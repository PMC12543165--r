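# Image conditioning: smoothing, rolling ball, flat-field, registration,
# and the role-enforcement contract protecting leakage stacks.

vs <- c(2, 0.692, 0.692)

test_that("Gaussian smoothing: constants, FWHM->sigma conversion, impulse kernel", {
  st <- image_stack(array(7, c(8, 16, 16)), voxel_size_um = vs)
  sm <- gaussian_smooth(st, 1)
  expect_equal(sm$data, st$data, tolerance = 1e-12)

  expect_equal(vesselleak:::fwhm_to_sigma(1) / 0.692, 0.6137, tolerance = 1e-4)

  # unit impulse far from borders reproduces the sampled separable kernel
  a <- array(0, c(15, 31, 31)); a[8, 16, 16] <- 1
  out <- gaussian_smooth(image_stack(a, voxel_size_um = vs), 2)$data
  expect_equal(sum(out), 1, tolerance = 1e-6)
  sig <- vesselleak:::fwhm_to_sigma(2) / vs
  k <- lapply(sig, function(s) {
    r <- max(1L, ceiling(4 * s)); kk <- exp(-((-r:r)^2) / (2 * s^2)); kk / sum(kk)
  })
  expect_equal(out[8, 16, 16], k[[1]][(length(k[[1]]) + 1) / 2] *
                 k[[2]][(length(k[[2]]) + 1) / 2] * k[[3]][(length(k[[3]]) + 1) / 2],
               tolerance = 1e-10)
  # interior mean conservation
  expect_equal(mean(out), 1 / length(out), tolerance = 1e-4 / length(out))
})

test_that("rolling ball: flattens constants, preserves narrow ridges, enforces role", {
  const <- image_stack(array(5, c(1, 40, 40)), voxel_size_um = c(1, 0.5, 0.5))
  out <- rolling_ball_subtract(const, radius_um = 5)
  expect_true(all(out$data == 0))

  # narrow bright ridge (1 px wide) on a linear ramp, radius >> ridge width
  nr <- 60
  ramp <- matrix(rep(seq(0, 10, length.out = nr), each = nr), nr, nr)
  img <- ramp; img[, 30] <- img[, 30] + 50
  st <- image_stack(array(img, c(1, nr, nr)), voxel_size_um = c(1, 0.5, 0.5))
  sub <- rolling_ball_subtract(st, radius_um = 5)
  ridge_amp <- mean(sub$data[1, 10:50, 30])
  expect_lt(abs(ridge_amp - 50) / 50, 0.05)
  # direct morphological-opening oracle (brute-force min-then-max over a disk)
  off <- vesselleak:::ball_offsets(5, c(1, 0.5, 0.5))
  ero <- matrix(Inf, nr, nr)
  for (y in 1:nr) for (x in 1:nr) {
    yy <- y + off[, 2]; xx <- x + off[, 3]
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nr
    ero[y, x] <- min(img[cbind(yy[ok], xx[ok])])
  }
  opened <- matrix(-Inf, nr, nr)
  for (y in 1:nr) for (x in 1:nr) {
    yy <- y + off[, 2]; xx <- x + off[, 3]
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nr
    opened[y, x] <- max(ero[cbind(yy[ok], xx[ok])])
  }
  expect_equal(sub$data[1, , ], pmax(img - opened, 0), tolerance = 1e-12)

  leak <- image_stack(array(1, c(2, 1, 8, 8)), voxel_size_um = vs,
                      channel_role = "leakage")
  expect_error(rolling_ball_subtract(leak, 5), "leakage")
  expect_no_error(rolling_ball_subtract(leak, 5, override = TRUE))
})

test_that("flat-field: uniform stacks, vignette recovery, pial exclusion", {
  uni <- image_stack(array(3, c(6, 32, 32)), voxel_size_um = vs)
  ff <- build_flatfield(uni)
  expect_equal(ff$field, matrix(1, 32, 32), tolerance = 1e-9)

  # dense structures under a smooth multiplicative vignette
  set.seed(7)
  d <- c(12, 128, 128)
  vol <- array(abs(rnorm(prod(d), 100, 15)), d)
  v <- vesselleak:::vignette_field(d, 0.4)
  st <- image_stack(vol * v, voxel_size_um = vs)
  ffv <- build_flatfield(st)
  expect_gt(cor(as.numeric(ffv$field), as.numeric(v[1, , ])), 0.95)

  # a pial mask zeroes the top slice's contribution to the MIP
  bright <- array(1, c(4, 16, 16))
  bright[1, , ] <- 100 + outer(1:16, 1:16)  # bright, nonuniform pial layer
  stb <- image_stack(bright, voxel_size_um = vs)
  f_all <- build_flatfield(stb)
  f_masked <- build_flatfield(stb, pial_mask = 1L)
  expect_equal(f_masked$field, matrix(1, 16, 16), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f_all$field, f_masked$field)))
})

test_that("flat-field normalization: exact division, shape and role contracts", {
  field <- matrix(runif(16 * 16, 0.5, 1.5), 16, 16)
  field <- field / mean(field)
  ref <- structure(list(field = field, smoothing_fwhm_um = 20), class = "flatfield_ref")
  a <- array(0, c(3, 16, 16)); for (z in 1:3) a[z, , ] <- field
  st <- image_stack(a, voxel_size_um = vs)
  out <- flatfield_normalize(st, ref)
  expect_equal(out$data, array(1, c(3, 16, 16)), tolerance = 1e-12)

  bad <- image_stack(array(1, c(3, 8, 8)), voxel_size_um = vs)
  expect_error(flatfield_normalize(bad, ref), "mismatch")
  leak <- image_stack(array(1, c(2, 3, 16, 16)), voxel_size_um = vs,
                      channel_role = "leakage")
  expect_error(flatfield_normalize(leak, ref), "leakage")
})

test_that("leakage frames pass the default pipeline untouched (checksum)", {
  leak <- image_stack(array(runif(2 * 4 * 8 * 8), c(2, 4, 8, 8)),
                      voxel_size_um = vs, channel_role = "leakage")
  before <- digest::digest(leak$data)
  try(rolling_ball_subtract(leak, 10), silent = TRUE)
  ref <- structure(list(field = matrix(1, 8, 8), smoothing_fwhm_um = 20),
                   class = "flatfield_ref")
  try(flatfield_normalize(leak, ref), silent = TRUE)
  expect_identical(digest::digest(leak$data), before)
})

test_that("affine registration recovers identity, shifts, and in-plane rotation", {
  vol <- blob_volume()
  fx <- image_stack(vol, voxel_size_um = vs, channel_role = "structure")

  r0 <- register_affine(fx, fx)
  expect_lt(max(abs(r0$params[1:3] / vs)), 0.1)

  # known integer shift (z, y, x) = (0, 3, 2) voxels
  sh <- array(0, dim(vol))
  sh[, 4:48, 3:48] <- vol[, 1:45, 1:46]
  r1 <- register_affine(image_stack(sh, voxel_size_um = vs), fx)
  expect_lt(abs(r1$params[1] / vs[1] - 0), 0.25)
  expect_lt(abs(r1$params[2] / vs[2] - 3), 0.25)
  expect_lt(abs(r1$params[3] / vs[3] - 2), 0.25)

  # known 2-degree in-plane rotation
  A <- vesselleak:::params_to_voxel_affine(c(0, 0, 0, 0, 0, 2), vs, dim(vol))
  rot <- array(vesselleak:::.cpp_affine_resample(as.numeric(vol),
                                                 as.integer(dim(vol)), A), dim(vol))
  r2 <- register_affine(image_stack(rot, voxel_size_um = vs), fx)
  expect_lt(abs(abs(r2$params[6]) - 2), 0.2)

  # residual property: NCC(fixed, resampled) >= NCC(fixed, moving)
  expect_gte(r2$metric + 1e-9,
             vesselleak:::ncc(rot, vol))
})
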