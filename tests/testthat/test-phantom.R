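# Generator module: geometry, kinetics, line scans, histology, determinism.

noise_free <- kinetics_spec(noise_sigma = 0, vignette_strength = 0,
                            psf_fwhm_um = 0, bleed_frac = 0)

single_arteriole_spec <- function(diam = 10, dims = c(20, 64, 64)) {
  phantom_spec(volume_shape = dims, capillary_density = 0, branch_orders = 0,
               n_penetrating = c(arteriole = 1, venule = 0),
               diameter_by_order_um = c(`0` = diam, `1` = 7.5, `2` = 6.5))
}

test_that("phantom construction: single unbranched arteriole, deterministic", {
  sp <- single_arteriole_spec()
  ph <- make_vascular_phantom(sp)
  st <- ph$truth$segment_table
  expect_equal(nrow(st), 1L)
  expect_equal(st$class, "arteriole")
  expect_equal(st$order, 0L)
  ph2 <- make_vascular_phantom(sp)
  expect_identical(ph$lumen, ph2$lumen)
  expect_identical(ph$label, ph2$label)
  # condition affects kinetics, not geometry
  ph3 <- make_vascular_phantom(sp, condition = "SE")
  expect_identical(ph3$lumen, ph$lumen)
  expect_false(isTRUE(all.equal(ph3$truth$segment_table$true_Ktrans,
                                ph$truth$segment_table$true_Ktrans)))
})

test_that("spec validation rejects ill-posed geometry", {
  expect_error(phantom_spec(diameter_by_order_um = c(`0` = 5, `1` = 4, `2` = 3)),
               ">= 6")
  expect_error(phantom_spec(capillary_diameter_um = 7), "< 6")
  expect_error(make_vascular_phantom(single_arteriole_spec(dims = c(10, 8, 8))),
               "too small")
})

test_that("cylinder diameter: >90% of centerline voxels within one in-plane voxel of 8 um", {
  sp <- single_arteriole_spec(diam = 8)
  ph <- make_vascular_phantom(sp)
  # centerline voxels from the generator's own axis (a vertical line)
  cl <- ph$truth$centerlines[[1]]
  vs <- sp$voxel_size_um
  yx <- round(cl[1, 2:3] / vs[2:3] + 0.5)
  zs <- 3:18  # interior; tube end caps excluded
  idx <- vesselleak:::zyx_to_index(cbind(zs, yx[1], yx[2]), sp$volume_shape)
  # brute-force EDT oracle: distance to nearest background voxel
  dvals <- 2 * brute_edt_at(!ph$lumen, idx, vs)
  target <- ph$truth$segment_table$diameter_um[1]
  expect_gt(mean(abs(dvals - target) <= vs[2]), 0.90)
})

test_that("two-compartment solver: closed forms and fine-step oracle", {
  t_min <- seq(0, 60, 0.25)
  # k_out = 0, constant input: exactly linear growth
  cp <- two_compartment_cp(rep(50, length(t_min)), t_min, 0.004, 0)
  expect_equal(cp, 0.004 * 50 * t_min, tolerance = 1e-12)
  # realistic input, k_out > 0: fine explicit-Euler oracle (dt = 0.01 s)
  kin <- kinetics_spec()
  C_iv <- plasma_input(t_min, kin)
  cp2 <- two_compartment_cp(C_iv, t_min, 0.01, 0.002)
  dt <- 0.01 / 60
  tf <- seq(0, 60, by = dt)
  Cf <- plasma_input(tf, kin)
  acc <- 0
  for (i in seq_len(length(tf) - 1)) acc <- acc + dt * (0.01 * Cf[i] - 0.002 * acc)
  expect_lt(abs(cp2[length(cp2)] - acc) / acc, 0.005)
})

test_that("extravasation: no source term means dark parenchyma; truth traces attached", {
  sp <- single_arteriole_spec(dims = c(12, 40, 40))
  sp$frame_interval_s <- 600
  kin0 <- noise_free
  kin0$Ktrans_by_type[] <- 0
  ph <- make_vascular_phantom(sp, "SE", kin0)
  tl <- simulate_extravasation(ph, kin0, seed = 1)
  outside <- !ph$lumen
  for (i in seq_len(vesselleak:::n_frames(tl)))
    expect_true(all(vesselleak:::get_frame(tl, i)[outside] == 0))
  tk <- attr(tl, "truth_kinetics")
  expect_true(all(tk$C_p == 0))
})

test_that("mass bookkeeping: rendered perivascular signal proportional to C_p", {
  sp <- single_arteriole_spec(dims = c(12, 40, 40))
  sp$frame_interval_s <- 300
  ph <- make_vascular_phantom(sp, "SE", noise_free)
  tl <- simulate_extravasation(ph, noise_free, seed = 1)
  tk <- attr(tl, "truth_kinetics")
  sh <- perivascular_shells(ph$label, sp$voxel_size_um, r_in = 0, r_out = 15)
  rind <- sh$shell_label == 1L
  ratios <- vapply(2:vesselleak:::n_frames(tl), function(i)
    sum(vesselleak:::get_frame(tl, i)[rind]) / tk$C_p[1, i], numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 0.01)
})

test_that("condition contrast: Ktrans elevated only in the disease-dominant class", {
  kin <- kinetics_spec()
  kt <- kin$Ktrans_by_type
  expect_true(kt["SE", "arteriole"] > 10 * kt["Control", "arteriole"])
  expect_true(kt["NI", "venule"] > 10 * kt["Control", "venule"])
  expect_equal(kt["SE", c("capillary", "venule")], kt["Control", c("capillary", "venule")])
  expect_equal(kt["NI", c("arteriole", "capillary")], kt["Control", c("arteriole", "capillary")])
  # asserted directly on the generated truth ledgers
  sp <- phantom_spec(volume_shape = c(16, 96, 96), capillary_density = 4, branch_orders = 0)
  for (cond in c("Control", "SE", "NI")) {
    ph <- make_vascular_phantom(sp, cond, kin, animal_id = "a1")
    st <- ph$truth$segment_table
    med <- tapply(st$true_Ktrans, st$class, stats::median)
    if (cond == "SE") expect_gt(med[["arteriole"]], 3 * med[["venule"]])
    if (cond == "NI") expect_gt(med[["venule"]], 3 * med[["arteriole"]])
    if (cond == "Control") expect_lt(max(st$true_Ktrans), 1e-3)
  }
})

test_that("lumen voxels map to exactly one segment id", {
  sp <- phantom_spec(volume_shape = c(16, 96, 96), capillary_density = 6, branch_orders = 1)
  ph <- make_vascular_phantom(sp)
  expect_true(all(ph$label[ph$lumen] %in% ph$truth$segment_table$id))
  expect_true(all(ph$label[!ph$lumen] == 0L))
})

test_that("line scans: stationary shadows, centroid-shift oracle, determinism, aliasing", {
  ls0 <- simulate_linescan(0, noise_sd = 0, cell_frac = 0.05, seed = 5)
  expect_true(all(apply(ls0$image, 2, function(col) diff(range(col)) == 0)))

  # moving: per-line centroid (argmin) shift equals v * dt / dx pixels
  v <- 1.0
  ls1 <- simulate_linescan(v, noise_sd = 0, cell_frac = 0.02, seed = 5)
  mins <- apply(ls1$image[1:20, ], 1, which.min)
  shifts <- diff(mins)
  shifts <- shifts[abs(shifts) < 100]  # ignore the periodic wrap line
  expect_equal(stats::median(shifts), round(v * 1000 * ls1$dt_line_s / ls1$dx_um),
               tolerance = 0.35)

  expect_identical(simulate_linescan(2, seed = 9)$image,
                   simulate_linescan(2, seed = 9)$image)
  expect_error(simulate_linescan(80), "aliasing")
})

test_that("histology generator honors leak levels and channel geometry", {
  h0 <- simulate_histology(c(sma_pos = 0, sma_neg = 0), seed = 2)
  expect_equal(unname(h0$truth$placed_fraction), c(0, 0))
  outside <- !h0$truth$vessel_mask
  expect_lt(max(h0$channels$TRITC[outside]), 100)  # no speckle placed

  h5 <- simulate_histology(c(sma_pos = 0.5, sma_neg = 0.5), seed = 2)
  expect_equal(unname(h5$truth$placed_fraction), c(0.5, 0.5), tolerance = 0.01)

  # alpha-SMA footprint is a subset of the vessel footprint
  sma_on <- h5$channels$aSMA > 100
  expect_true(all(h5$truth$sma_mask[!h5$truth$vessel_mask] == FALSE))
  expect_identical(simulate_histology(c(sma_pos = .2, sma_neg = .2), seed = 3)$channels$TRITC,
                   simulate_histology(c(sma_pos = .2, sma_neg = .2), seed = 3)$channels$TRITC)
})

test_that("cohort trace generator: shared plasma input, labeled design", {
  co <- simulate_cohort_traces(n_animals = c(Control = 2, SE = 2, NI = 1),
                               vessels_per_class = c(arteriole = 2, capillary = 3, venule = 2),
                               seed = 11)
  expect_equal(nrow(co$traces), 5 * 7)
  expect_equal(ncol(co$traces), length(co$t_min))
  expect_setequal(unique(co$meta$condition), c("Control", "SE", "NI"))
  # intravascular traces share one input curve (noise apart)
  kin <- kinetics_spec()
  Civ <- plasma_input(co$t_min, kin)
  expect_lt(max(abs(colMeans(co$f_iv) - Civ)), 1)
})
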