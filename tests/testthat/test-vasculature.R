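# Segmentation, skeleton graph, diameters, classification, shells.

vs <- c(2, 0.692, 0.692)
iso05 <- c(0.5, 0.5, 0.5)

make_tube <- function(dims, vs, p0, p1, diam) {
  lab <- array(0L, dims)
  vesselleak:::paint_tube(lab, p0, p1, diam, 1L, vs) > 0
}

test_that("segmentation: Dice >= 0.95 on a noiseless phantom, contracts", {
  sp <- phantom_spec(volume_shape = c(16, 80, 80), capillary_density = 4,
                     branch_orders = 0)
  ph <- make_vascular_phantom(sp)
  a <- array(0, sp$volume_shape); a[ph$lumen] <- 100
  st <- gaussian_smooth(image_stack(a, voxel_size_um = vs), 1)
  mask <- segment_vessels(st, method = "otsu")
  dice <- 2 * sum(mask & ph$lumen) / (sum(mask) + sum(ph$lumen))
  expect_gte(dice, 0.95)

  zero <- image_stack(array(0, c(4, 8, 8)), voxel_size_um = vs)
  expect_warning(m0 <- segment_vessels(zero, "otsu"), "empty")
  expect_false(any(m0))

  ext <- array(c(TRUE, rep(FALSE, 4 * 8 * 8 - 1)), c(4, 8, 8))
  expect_identical(segment_vessels(zero, "external_mask", list(mask = ext)), ext)
})

test_that("skeleton graph: tube, Y, disjoint tubes, Euler cycles", {
  d <- c(9, 40, 40)
  tube <- make_tube(d, vs, c(9, 14, 5), c(9, 14, 22), 4)
  g <- skeletonize_and_graph(tube, vs)
  expect_equal(length(g$edges), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_equal(sum(g$nodes$kind == "junction"), 0L)
  expect_equal(g$n_components, 1L)
  expect_equal(length(g$edges) - nrow(g$nodes) + g$n_components, 0L)  # no cycles

  yshape <- make_tube(d, vs, c(9, 20, 3), c(9, 20, 14), 4) |
    (make_tube(d, vs, c(9, 20, 14), c(9, 12, 24), 4)) |
    (make_tube(d, vs, c(9, 20, 14), c(9, 28, 24), 4))
  gy <- skeletonize_and_graph(yshape, vs)
  expect_equal(length(gy$edges), 3L)
  expect_equal(sum(gy$nodes$kind == "junction"), 1L)
  expect_equal(length(gy$edges) - nrow(gy$nodes) + gy$n_components, 0L)

  two <- make_tube(d, vs, c(9, 6, 5), c(9, 6, 22), 4) |
    make_tube(d, vs, c(9, 21, 5), c(9, 21, 22), 4)
  g2 <- skeletonize_and_graph(two, vs)
  expect_equal(g2$n_components, 2L)
  comp_mask <- label_components(two, 26)
  expect_equal(g2$n_components, attr(comp_mask, "n_components"))

  # a closed rectangular loop has one cycle: |E| - |N| + |C| = 1
  loop <- make_tube(d, vs, c(9, 7, 6), c(9, 7, 21), 3) |
    make_tube(d, vs, c(9, 20, 6), c(9, 20, 21), 3) |
    make_tube(d, vs, c(9, 7, 6), c(9, 20, 6), 3) |
    make_tube(d, vs, c(9, 7, 21), c(9, 20, 21), 3)
  gl <- skeletonize_and_graph(loop, vs)
  expect_equal(length(gl$edges) - nrow(gl$nodes) + gl$n_components, 1L)

  ge <- skeletonize_and_graph(array(FALSE, c(4, 8, 8)), vs)
  expect_equal(length(ge$edges), 0L)
})

test_that("diameter map: cylinder recovery, minimal objects, unit covariance", {
  dims <- c(40, 40, 60)
  cyl <- cylinder_mask(dims, iso05, 4)
  g <- diameter_map(cyl, skeletonize_and_graph(cyl, iso05))
  main <- which.max(vapply(g$edges, function(e) nrow(e$path), integer(1)))
  # interior voxels only (end effects at the open tube ends)
  diam <- g$edges[[main]]$diam_um
  inner <- diam[seq(10, length(diam) - 10)]
  expect_lt(abs(mean(inner) - 8), 0.7)
  # against the brute-force EDT oracle: same medial (neighbourhood-max) rule,
  # distances computed by exhaustive search
  path <- g$edges[[main]]$path
  off26 <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  oracle <- vapply(seq_len(nrow(path)), function(k) {
    nb <- sweep(off26, 2, path[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    idx <- vesselleak:::zyx_to_index(nb[ok, , drop = FALSE], dims)
    idx <- idx[cyl[idx]]
    2 * max(brute_edt_at(!cyl, idx, iso05))
  }, numeric(1))
  expect_equal(diam, oracle, tolerance = 1e-9)

  # one-voxel line: diameter about one voxel
  d1 <- c(5, 9, 30)
  line <- array(FALSE, d1); line[3, 5, 3:28] <- TRUE
  gl <- diameter_map(line, skeletonize_and_graph(line, iso05))
  expect_equal(gl$segments$mean_diameter_um, 1, tolerance = 0.1)

  # doubling the voxel size doubles reported diameters
  g2 <- diameter_map(line, skeletonize_and_graph(line, 2 * iso05))
  expect_equal(g2$segments$mean_diameter_um, 2 * gl$segments$mean_diameter_um,
               tolerance = 1e-9)

  # integrity: skeleton voxel outside the mask
  bad <- line; bad[3, 5, 10] <- FALSE
  expect_error(diameter_map(bad, gl), "outside")
})

test_that("classification: order propagation, diameter rules, seed errors", {
  sp <- phantom_spec(volume_shape = c(30, 140, 140), capillary_density = 0,
                     branch_orders = 2,
                     diameter_by_order_um = c(`0` = 10, `1` = 8, `2` = 7),
                     n_penetrating = c(arteriole = 1, venule = 0), seed = 4)
  ph <- make_vascular_phantom(sp)
  g <- diameter_map(ph$lumen, skeletonize_and_graph(ph$lumen, vs))
  ang <- vapply(g$edges, vesselleak:::edge_z_angle, numeric(1), vs = vs)
  vert <- which(ang <= 30 & g$segments$mean_diameter_um >= 6)
  root <- vert[which.max(g$segments$mean_diameter_um[vert])]
  seeds <- stats::setNames("arteriole", g$segments$id[root])
  segs <- classify_vessels(g, seeds)
  expect_true(all(segs$class[!is.na(segs$order)] == "arteriole"))
  expect_setequal(unique(stats::na.omit(segs$order)), 0:2)
  expect_equal(sum(segs$order == 0, na.rm = TRUE), 1L)
  # ordered non-roots carry parent links
  kids <- segs[!is.na(segs$order) & segs$order > 0, ]
  expect_true(all(!is.na(kids$parent_id)))

  # isolated 5-um segment -> capillary; isolated 7-um unlabeled
  d <- c(9, 40, 40)
  iso5 <- make_tube(d, vs, c(9, 14, 4), c(9, 14, 24), 5)
  gi <- diameter_map(iso5, skeletonize_and_graph(iso5, vs))
  expect_equal(classify_vessels(gi)$class, "capillary")
  iso7 <- make_tube(d, vs, c(9, 20, 4), c(9, 20, 24), 7)
  gj <- diameter_map(iso7, skeletonize_and_graph(iso7, vs))
  expect_equal(classify_vessels(gj)$class, "unlabeled")

  expect_error(classify_vessels(gi, c(`99` = "arteriole")), "nonexistent")
  # two different-class seeds on segments of the same penetrating tree
  tree_ids <- segs$id[!is.na(segs$order)]
  two_seeds <- stats::setNames(c("arteriole", "venule"), tree_ids[1:2])
  expect_error(classify_vessels(g, two_seeds), "conflicting")
})

test_that("classification is invariant to which tree segment carries the seed", {
  sp <- phantom_spec(volume_shape = c(24, 120, 120), capillary_density = 0,
                     branch_orders = 1,
                     diameter_by_order_um = c(`0` = 10, `1` = 8, `2` = 7),
                     n_penetrating = c(arteriole = 1, venule = 0), seed = 6)
  ph <- make_vascular_phantom(sp)
  g <- diameter_map(ph$lumen, skeletonize_and_graph(ph$lumen, vs))
  big <- g$segments$id[g$segments$mean_diameter_um >= 6]
  ref <- classify_vessels(g, stats::setNames("arteriole", big[1]))
  # any seed within the same penetrating tree selects the same root
  tree_ids <- ref$id[!is.na(ref$order)]
  expect_gt(length(tree_ids), 1)
  for (s in setdiff(tree_ids, big[1])) {
    alt <- classify_vessels(g, stats::setNames("arteriole", s))
    expect_identical(alt, ref)
  }
})

test_that("perivascular shells: analytic annulus volume, band, disjointness", {
  dims <- c(76, 76, 100)  # 38 x 38 x 50 um at 0.5-um voxels
  cyl <- cylinder_mask(dims, iso05, 3)
  lab <- array(0L, dims); lab[cyl] <- 1L
  sh <- perivascular_shells(lab, iso05)
  analytic <- pi * ((3 + 15)^2 - (3 + 5)^2) * 50
  expect_lt(abs(sh$table$volume_um3 - analytic) / analytic, 0.10)
  # exact distance-band membership
  in_shell <- sh$shell_label > 0L
  expect_true(all(sh$dist[in_shell] > 5 & sh$dist[in_shell] <= 15))
  expect_true(all(!(in_shell & cyl)))
  expect_error(perivascular_shells(lab, iso05, r_in = 15, r_out = 5), "r_in")
})

test_that("shell ownership is nearest-vessel with an equidistant boundary", {
  dims <- c(30, 72, 40)  # two parallel x-axis cylinders 12 um apart in y
  lab <- array(0L, dims)
  c1 <- cylinder_mask(dims, iso05, 2, center_zy_um = c(7.5, 12))
  c2 <- cylinder_mask(dims, iso05, 2, center_zy_um = c(7.5, 24))
  lab[c1] <- 1L; lab[c2] <- 2L
  sh <- perivascular_shells(lab, iso05)
  own1 <- sh$shell_label == 1L
  own2 <- sh$shell_label == 2L
  expect_false(any(own1 & own2))
  # every voxel owned by 1 is at least as close to vessel 1 as to vessel 2
  d1 <- edt_um(c1, iso05)$dist
  d2 <- edt_um(c2, iso05)$dist
  expect_true(all(d1[own1] <= d2[own1] + 1e-9))
  expect_true(all(d2[own2] <= d1[own2] + 1e-9))
})

test_that("class recovery on a noiseless phantom is essentially diagonal", {
  sp <- phantom_spec(volume_shape = c(20, 110, 110), capillary_density = 8,
                     branch_orders = 0, seed = 3)
  ph <- make_vascular_phantom(sp)
  g <- diameter_map(ph$lumen, skeletonize_and_graph(ph$lumen, vs))
  seeds <- vesselleak:::seed_from_truth(g, ph$truth)
  segs <- classify_vessels(g, seeds)
  lab <- label_lumen_from_graph(ph$lumen, g)
  # map each graph segment to the dominant truth segment it covers
  truth_class <- ph$truth$segment_table$class[
    vapply(segs$id, function(i) {
      tt <- table(ph$label[lab == i & ph$label > 0L])
      as.integer(names(tt)[which.max(tt)])
    }, integer(1))]
  # penetrating vessels perfectly recovered
  pen <- truth_class %in% c("arteriole", "venule")
  expect_true(all(segs$class[pen] == truth_class[pen]))
  # capillary recall >= 95% (errors only at the 6-um rule boundary)
  cap <- truth_class == "capillary"
  expect_gte(mean(segs$class[cap] == "capillary"), 0.95)
})
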