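# Synthetic vascular phantoms: voxelized tube networks with ground truth,
# two-compartment extravasation time-lapses, RBC line scans, and histology
# images. Every downstream module is validated against these generators.

#' Phantom geometry specification
#'
#' Describes a synthetic cortical vascular volume: per-class counts of
#' penetrating (0th-order) vessels, branch depth, diameters per branch order,
#' and capillary density. Defaults mirror a two-photon acquisition
#' (2 x 0.692 x 0.692 um voxels, one frame per 15 s for 60 min) at desk scale.
#'
#' @param volume_shape voxel grid `(z, y, x)`.
#' @param voxel_size_um physical voxel size `(z, y, x)`.
#' @param n_penetrating named count of 0th-order trees per class,
#'   `c(arteriole = , venule = )`.
#' @param branch_orders maximum branch order grown from each penetrating
#'   vessel (0 = unbranched, max 2).
#' @param diameter_by_order_um mean lumen diameter (um) for orders 0..2.
#'   Order-0 diameters must be >= 6 um (the capillary rule boundary).
#' @param capillary_density capillary segments per 100 x 100 x 80 um^3 block.
#' @param capillary_diameter_um mean capillary diameter; draws are clipped
#'   below 6 um.
#' @param frame_interval_s,duration_min acquisition timing of simulated
#'   time-lapses.
#' @param seed integer seed; all phantom randomness derives from it.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(volume_shape = c(40, 128, 128),
                         voxel_size_um = c(2.0, 0.692, 0.692),
                         n_penetrating = c(arteriole = 1, venule = 1),
                         branch_orders = 2,
                         diameter_by_order_um = c(`0` = 10, `1` = 7.5, `2` = 6.5),
                         capillary_density = 8,
                         capillary_diameter_um = 4,
                         frame_interval_s = 15,
                         duration_min = 60,
                         seed = 1L) {
  check_positive(volume_shape, "volume_shape")
  check_positive(voxel_size_um, "voxel_size_um")
  check_positive(diameter_by_order_um, "diameter_by_order_um")
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(duration_min, "duration_min")
  stopifnot(branch_orders %in% 0:2, capillary_density >= 0)
  if (is.null(names(n_penetrating))) names(n_penetrating) <- c("arteriole", "venule")
  stopifnot(all(names(n_penetrating) %in% c("arteriole", "venule")), all(n_penetrating >= 0))
  if (diameter_by_order_um[["0"]] < 6)
    stopf("0th-order diameters must be >= 6 um (vessels < 6 um are capillaries)")
  if (capillary_diameter_um >= 6)
    stopf("capillary diameters must be < 6 um")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size_um = as.numeric(voxel_size_um),
                 n_penetrating = n_penetrating,
                 branch_orders = as.integer(branch_orders),
                 diameter_by_order_um = diameter_by_order_um,
                 capillary_density = capillary_density,
                 capillary_diameter_um = capillary_diameter_um,
                 frame_interval_s = frame_interval_s,
                 duration_min = duration_min,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Extravasation kinetics specification
#'
#' Parameters of the two-compartment forward model: a bi-exponential plasma
#' input curve `C_iv(t) = A_iv (1 - exp(-t/tau_r)) exp(-t/tau_d)` shared by
#' all conditions (intravascular traces are experimentally indistinguishable
#' across groups), and per-(condition, class) volume transfer constants
#' feeding `dC_p/dt = Ktrans C_iv - k_out C_p`. Defaults elevate Ktrans only
#' in arterioles for "SE" and only in venules for "NI".
#'
#' @param A_iv plasma curve amplitude (arbitrary units).
#' @param tau_r_min,tau_d_min rise and decay constants (min). The default
#'   decay (600 min) keeps the intravascular signal near-flat over 60 min.
#' @param Ktrans_by_type matrix `conditions x classes` of Ktrans (1/min),
#'   rownames in (Control, SE, NI), colnames (arteriole, capillary, venule).
#' @param k_out perivascular clearance rate (1/min).
#' @param vessel_sdlog,animal_sdlog log-normal spread of per-vessel and
#'   per-animal Ktrans multipliers (biological variability).
#' @param noise_sigma additive Gaussian noise sd per voxel (intensity units).
#' @param psf_fwhm_um rendering blur FWHM.
#' @param vignette_strength multiplicative illumination falloff amplitude in
#'   `[0, 1)`.
#' @param bleed_frac,scatter_length_um amplitude and length constant of the
#'   vessel-scatter halo that gives perivascular traces a nonzero baseline.
#' @param halo_length_um radial length constant of the rendered perivascular
#'   concentration halo.
#' @return a `kinetics_spec` object.
#' @export
kinetics_spec <- function(A_iv = 100,
                          tau_r_min = 0.1,
                          tau_d_min = 600,
                          Ktrans_by_type = default_ktrans_table(),
                          k_out = 0.002,
                          vessel_sdlog = 0.35,
                          animal_sdlog = 0.15,
                          noise_sigma = 2,
                          psf_fwhm_um = 1.0,
                          vignette_strength = 0.2,
                          bleed_frac = 0.3,
                          scatter_length_um = 10,
                          halo_length_um = 5) {
  check_positive(A_iv, "A_iv"); check_positive(tau_r_min, "tau_r_min")
  check_positive(tau_d_min, "tau_d_min")
  stopifnot(k_out >= 0, noise_sigma >= 0, psf_fwhm_um >= 0,
            vignette_strength >= 0, vignette_strength < 1,
            all(is.finite(Ktrans_by_type)), all(Ktrans_by_type >= 0))
  structure(list(A_iv = A_iv, tau_r_min = tau_r_min, tau_d_min = tau_d_min,
                 Ktrans_by_type = Ktrans_by_type, k_out = k_out,
                 vessel_sdlog = vessel_sdlog, animal_sdlog = animal_sdlog,
                 noise_sigma = noise_sigma, psf_fwhm_um = psf_fwhm_um,
                 vignette_strength = vignette_strength,
                 bleed_frac = bleed_frac, scatter_length_um = scatter_length_um,
                 halo_length_um = halo_length_um),
            class = "kinetics_spec")
}

#' Default condition-by-class Ktrans table (1/min)
#'
#' Control near zero everywhere; "SE" elevates arterioles only; "NI" elevates
#' venules only.
#' @export
default_ktrans_table <- function() {
  m <- matrix(1e-4, nrow = 3, ncol = 3,
              dimnames = list(c("Control", "SE", "NI"),
                              c("arteriole", "capillary", "venule")))
  m["SE", "arteriole"] <- 2e-3
  m["NI", "venule"] <- 1.6e-3
  m
}

#' Plasma input curve
#'
#' @param t_min times in minutes.
#' @param kinetics a [kinetics_spec()].
#' @return intravascular tracer concentration (arbitrary units).
#' @export
plasma_input <- function(t_min, kinetics) {
  kinetics$A_iv * (1 - exp(-t_min / kinetics$tau_r_min)) * exp(-t_min / kinetics$tau_d_min)
}

#' Two-compartment perivascular concentration on a frame grid
#'
#' Solves `dC_p/dt = Ktrans C_iv - k_out C_p` with `C_p(0) = 0` by an
#' exponential-integrator trapezoid step (exact for constant input when
#' `k_out = 0`; second-order otherwise).
#'
#' @param C_iv intravascular concentration at each frame time.
#' @param t_min frame times (min), uniform.
#' @param Ktrans transfer constant (1/min).
#' @param k_out clearance rate (1/min).
#' @return perivascular concentration at each frame time.
#' @export
two_compartment_cp <- function(C_iv, t_min, Ktrans, k_out) {
  stopifnot(length(C_iv) == length(t_min), Ktrans >= 0, k_out >= 0)
  n <- length(t_min)
  cp <- numeric(n)
  if (n < 2) return(cp)
  dt <- diff(t_min)
  ek <- exp(-k_out * dt)
  for (i in seq_len(n - 1)) {
    cp[i + 1] <- cp[i] * ek[i] +
      Ktrans * dt[i] * (C_iv[i] * ek[i] + C_iv[i + 1]) / 2
  }
  cp
}

# --- tube-network construction ---------------------------------------------

# paint a capsule (cylinder with spherical caps) of given diameter into the
# label volume; first-painted voxel wins so segment ownership is unique.
paint_tube <- function(label, p0, p1, diameter_um, id, voxel_size_um) {
  d <- dim(label)
  r <- diameter_um / 2
  step <- min(voxel_size_um) / 2
  len <- sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
  off <- ball_offsets(r, voxel_size_um)
  for (s in ts) {
    p <- p0 + s * (p1 - p0)
    cz <- round(p[1] / voxel_size_um[1] + 0.5)
    cy <- round(p[2] / voxel_size_um[2] + 0.5)
    cx <- round(p[3] / voxel_size_um[3] + 0.5)
    zz <- cz + off[, 1]; yy <- cy + off[, 2]; xx <- cx + off[, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    if (!any(ok)) next
    idx <- zyx_to_index(cbind(zz[ok], yy[ok], xx[ok]), d)
    # refine: keep only voxel centers within r of the axis point
    ctr <- index_to_zyx(idx, d)
    pc <- sweep(sweep(ctr, 2, 0.5), 2, voxel_size_um, `*`)
    keep <- rowSums(sweep(pc, 2, p)^2) <= r^2 + 1e-9
    idx <- idx[keep]
    idx <- idx[label[idx] == 0L]
    label[idx] <- id
  }
  label
}

# minimum distance between two 3D line segments (a0-a1, b0-b1)
seg_seg_dist <- function(a0, a1, b0, b1) {
  u <- a1 - a0; v <- b1 - b0; w <- a0 - b0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  dd <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  if (D < 1e-12) { sc <- 0 } else sc <- max(0, min(1, (b * e - cc * dd) / D))
  tc <- if (cc < 1e-12) 0 else max(0, min(1, (b * sc + e) / cc))
  # re-clamp sc for the clamped tc
  sc <- if (a < 1e-12) 0 else max(0, min(1, (b * tc - dd) / a))
  sqrt(sum((a0 + sc * u - (b0 + tc * v))^2))
}

# reference RBC velocities by class (mm/s), log-normal per-vessel spread
reference_velocity <- function(class) {
  mu <- c(arteriole = 5.0, capillary = 1.0, venule = 1.8)[class]
  rlnorm(length(class), log(mu), 0.3)
}

#' Generate a voxelized vascular phantom with ground truth
#'
#' Builds, per class, `n_penetrating` vertical 0th-order tubes with up to
#' second-order branches, plus randomly oriented capillary tubes, voxelizes
#' them into a uniquely-owned segment label volume, and returns the ground
#' truth ledger (segment table, centerlines, per-segment Ktrans and
#' velocity). Deterministic for a fixed spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @param condition phantom condition label, one of `"Control"`, `"SE"`,
#'   `"NI"` (selects the Ktrans row of the kinetics table).
#' @param kinetics a [kinetics_spec()] used to assign per-segment true Ktrans.
#' @param animal_id identifier recorded in the truth tables.
#' @return list with `lumen` (logical array), `label` (integer array of
#'   segment ids), and `truth` (a `phantom_truth` list: `segment_table`,
#'   `centerlines`, acquisition metadata, condition/animal labels).
#' @export
make_vascular_phantom <- function(spec, condition = "Control",
                                  kinetics = kinetics_spec(),
                                  animal_id = "animal1") {
  stopifnot(inherits(spec, "phantom_spec"),
            condition %in% rownames(kinetics$Ktrans_by_type))
  d <- spec$volume_shape
  vs <- spec$voxel_size_um
  ext <- d * vs  # physical extent (z, y, x) um
  margin <- spec$diameter_by_order_um[["0"]] / 2 + 2
  if (any(ext[2:3] <= 2 * margin) && sum(spec$n_penetrating) > 0)
    stopf("volume too small to fit requested penetrating vessels (extent %.1f x %.1f um, margin %.1f um)",
          ext[2], ext[3], margin)

  # geometry depends on (seed, animal) but not condition, so paired
  # condition contrasts share vasculature and differ only in kinetics
  with_seed(derive_seed(spec$seed, "geometry", animal_id), {
    label <- array(0L, d)
    seg <- list(); cl <- list()
    nid <- 0L
    add_seg <- function(p0, p1, diam, class, ord, parent) {
      nid <<- nid + 1L
      label <<- paint_tube(label, p0, p1, diam, nid, vs)
      seg[[nid]] <<- data.frame(id = nid, class = class,
                                order = ord, diameter_um = diam,
                                length_um = sqrt(sum((p1 - p0)^2)),
                                parent_id = parent)
      cl[[nid]] <<- rbind(p0, p1)
      nid
    }

    placed_yx <- matrix(numeric(0), 0, 2)
    for (class in names(spec$n_penetrating)) {
      n <- spec$n_penetrating[[class]]
      if (n == 0) next
      for (i in seq_len(n)) {
        # penetrating roots keep >= one diameter of clearance from each other
        sep <- spec$diameter_by_order_um[["0"]] + 4
        yx <- NULL
        for (try in 1:50) {
          cand <- runif(2, margin, ext[2:3] - margin)
          if (nrow(placed_yx) == 0 ||
              min(sqrt(rowSums(sweep(placed_yx, 2, cand)^2))) >= sep) {
            yx <- cand; break
          }
        }
        if (is.null(yx))
          stopf("volume too small to place %d penetrating vessels with %.0f um separation",
                sum(spec$n_penetrating), sep)
        placed_yx <- rbind(placed_yx, yx)
        d0 <- spec$diameter_by_order_um[["0"]] * exp(rnorm(1, 0, 0.05))
        d0 <- max(d0, 6.2)
        root <- add_seg(c(0, yx), c(ext[1], yx), d0, class, 0L, NA_integer_)
        if (spec$branch_orders >= 1) {
          for (b in 1:2) {
            z0 <- runif(1, 0.25, 0.75) * ext[1]
            dir1 <- c(runif(1, -0.3, 0.3), rnorm(2))
            dir1[2:3] <- dir1[2:3] / sqrt(sum(dir1[2:3]^2))
            dir1 <- dir1 / sqrt(sum(dir1^2))
            len1 <- runif(1, 20, 30)
            p0 <- c(z0, yx); p1 <- p0 + dir1 * len1
            d1 <- spec$diameter_by_order_um[["1"]] * exp(rnorm(1, 0, 0.05))
            id1 <- add_seg(p0, p1, max(d1, 6.1), class, 1L, root)
            if (spec$branch_orders >= 2) {
              dir2 <- dir1 + c(runif(1, -0.3, 0.3), rnorm(2, 0, 0.4))
              dir2 <- dir2 / sqrt(sum(dir2^2))
              len2 <- runif(1, 15, 25)
              d2 <- spec$diameter_by_order_um[["2"]] * exp(rnorm(1, 0, 0.05))
              add_seg(p1, p1 + dir2 * len2, max(d2, 6.05), class, 2L, id1)
            }
          }
        }
      }
    }

    # capillaries keep clearance from the penetrating trees (lumens are solid
    # tubes and must not interpenetrate, which would dice their skeletons)
    n_cap <- round(spec$capillary_density * prod(ext) / (100 * 100 * 80))
    pen <- seq_len(nid)  # all segments so far are penetrating-tree tubes
    for (i in seq_len(n_cap)) {
      for (try in 1:30) {
        p0 <- runif(3, 2, ext - 2)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        len <- runif(1, 30, 60)
        dc <- min(5.9, max(2, spec$capillary_diameter_um * exp(rnorm(1, 0, 0.2))))
        p1 <- p0 + dir * len
        ok <- all(vapply(pen, function(j) {
          seg_seg_dist(p0, p1, cl[[j]][1, ], cl[[j]][2, ]) >
            (dc + seg[[j]]$diameter_um) / 2 + 1
        }, logical(1)))
        if (ok || length(pen) == 0) {
          add_seg(p0, p1, dc, "capillary", NA_integer_, NA_integer_)
          break
        }
      }
    }

    st <- do.call(rbind, seg)
    # drop segments whose paint never landed in-volume
    present <- sort(unique(as.integer(label[label > 0L])))
    st <- st[st$id %in% present, , drop = FALSE]
    cl <- cl[st$id]
    rownames(st) <- NULL
    st$true_velocity_mm_s <- reference_velocity(st$class)
  })

  kt <- kinetics$Ktrans_by_type[condition, ]
  with_seed(derive_seed(spec$seed, "kinetics", condition, animal_id), {
    animal_mult <- rlnorm(1, 0, kinetics$animal_sdlog)
    st$true_Ktrans <- kt[st$class] * animal_mult *
      rlnorm(nrow(st), 0, kinetics$vessel_sdlog)
  })

  truth <- structure(list(segment_table = st, centerlines = cl,
                          voxel_size_um = vs, volume_shape = d,
                          frame_interval_s = spec$frame_interval_s,
                          duration_min = spec$duration_min,
                          condition = condition, animal_id = animal_id),
                     class = "phantom_truth")
  list(lumen = label > 0L, label = label, truth = truth)
}

# smooth multiplicative illumination field in (1 - strength, 1]
vignette_field <- function(d, strength) {
  yc <- (d[2] + 1) / 2; xc <- (d[3] + 1) / 2
  ry <- matrix(rep((seq_len(d[2]) - yc) / d[2], d[3]), d[2], d[3])
  rx <- matrix(rep((seq_len(d[3]) - xc) / d[3], each = d[2]), d[2], d[3])
  f2d <- 1 - strength * 2 * (ry^2 + rx^2) / 1.0
  aperm(array(rep(f2d, d[1]), c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Simulate an extravasation time-lapse from a phantom
#'
#' Intravascular voxels carry the plasma curve; each segment's perivascular
#' rind (0-15 um from the lumen, owned by nearest-vessel assignment) carries
#' its two-compartment concentration as a radially decaying halo plus a
#' vessel-scatter term, then PSF blur, vignette, and Gaussian noise are
#' applied. Ground-truth traces are attached for validation.
#'
#' @param phantom result of [make_vascular_phantom()].
#' @param kinetics a [kinetics_spec()].
#' @param seed integer seed for the noise draw.
#' @return an `image_stack` (role `"leakage"`) with attribute `truth_kinetics`
#'   holding `t_min`, `C_iv`, and the per-segment `C_p` matrix.
#' @export
simulate_extravasation <- function(phantom, kinetics = kinetics_spec(), seed = 1L) {
  truth <- phantom$truth
  d <- truth$volume_shape
  vs <- truth$voxel_size_um
  st <- truth$segment_table
  t_min <- seq(0, truth$duration_min, by = truth$frame_interval_s / 60)
  nt <- length(t_min)
  C_iv <- plasma_input(t_min, kinetics)
  if (any(C_iv[t_min > 0] <= 0)) stopf("plasma input curve must be positive on (0, duration]")
  Cp <- t(vapply(st$true_Ktrans,
                 function(k) two_compartment_cp(C_iv, t_min, k, kinetics$k_out),
                 numeric(nt)))
  if (any(Cp < 0)) stopf("negative perivascular concentrations; check kinetic parameters")

  ed <- edt_um(phantom$lumen, vs)
  owner <- array(0L, d)
  inside <- ed$dist > 0 & ed$dist <= 15
  owner[inside] <- phantom$label[ed$nearest[inside]]
  halo_w <- array(0, d)
  halo_w[inside] <- exp(-ed$dist[inside] / kinetics$halo_length_um)
  bleed_w <- array(0, d)
  bleed_w[inside] <- kinetics$bleed_frac * exp(-ed$dist[inside] / kinetics$scatter_length_um)
  lum_idx <- which(phantom$lumen)
  in_idx <- which(inside)
  own_in <- owner[in_idx]
  row_of <- match(own_in, st$id)

  vf <- if (kinetics$vignette_strength > 0) vignette_field(d, kinetics$vignette_strength) else NULL
  data <- array(0, c(nt, d))
  with_seed(derive_seed(seed, "render"), {
    for (i in seq_len(nt)) {
      fr <- array(0, d)
      fr[lum_idx] <- C_iv[i]
      fr[in_idx] <- Cp[cbind(row_of, i)] * halo_w[in_idx] + bleed_w[in_idx] * C_iv[i]
      if (kinetics$psf_fwhm_um > 0) fr <- smooth_gaussian_um(fr, kinetics$psf_fwhm_um, vs)
      if (!is.null(vf)) fr <- fr * vf
      if (kinetics$noise_sigma > 0) fr <- fr + array(rnorm(prod(d), 0, kinetics$noise_sigma), d)
      data[i, , , ] <- fr
    }
  })
  out <- image_stack(data, voxel_size_um = vs,
                     frame_interval_s = truth$frame_interval_s,
                     channel_role = "leakage")
  attr(out, "truth_kinetics") <- list(t_min = t_min, C_iv = C_iv, C_p = Cp,
                                      segment_id = st$id)
  out
}

#' Simulate an RBC line-scan space-time image
#'
#' Bright plasma with dark streaks: rows are successive scan lines, columns
#' spatial position along the vessel axis. Red blood cells are Gaussian dips
#' advected at the given velocity (periodic in space); a stationary object
#' yields vertical streaks.
#'
#' @param velocity_mm_s RBC velocity (>= 0).
#' @param dx_um pixel pitch along the scan (default 0.144 um).
#' @param dt_line_s line period (default 0.5 ms, i.e. 2 kHz).
#' @param n_lines,n_px image height (lines) and width (pixels).
#' @param cell_frac approximate fraction of the scan length occupied by RBCs.
#' @param rbc_length_um RBC shadow length (FWHM of the intensity dip); the
#'   default 6 um matches the red-cell scale, which keeps streaks continuous
#'   between successive lines even at arteriolar velocities.
#' @param noise_sd additive Gaussian noise sd relative to plasma intensity 1.
#' @param seed integer seed.
#' @return a `line_scan` object: `image` (n_lines x n_px matrix), `dx_um`,
#'   `dt_line_s`, plus the generating truth.
#' @export
simulate_linescan <- function(velocity_mm_s, dx_um = 0.144, dt_line_s = 5e-4,
                              n_lines = 400, n_px = 256, cell_frac = 0.15,
                              rbc_length_um = 6, noise_sd = 0.03, seed = 1L) {
  stopifnot(velocity_mm_s >= 0)
  check_positive(dx_um, "dx_um"); check_positive(dt_line_s, "dt_line_s")
  v_px <- velocity_mm_s * 1000 * dt_line_s / dx_um  # px per line
  if (v_px > n_px)
    stopf("aliasing: per-line displacement (%.1f px) exceeds the spatial window (%d px)", v_px, n_px)
  with_seed(derive_seed(seed, "linescan"), {
    # super-Gaussian dip: flat cell body with sharp edges (FWHM = rbc length)
    cell_w <- rbc_length_um / dx_um / 1.82
    n_cells <- max(1L, round(cell_frac * n_px * dx_um / rbc_length_um))
    x0 <- runif(n_cells, 0, n_px)
    xg <- seq_len(n_px) - 0.5
    img <- matrix(1, n_lines, n_px)
    for (li in seq_len(n_lines)) {
      pos <- (x0 + v_px * (li - 1)) %% n_px
      dip <- numeric(n_px)
      for (p in pos) {
        dd <- abs(xg - p)
        dd <- pmin(dd, n_px - dd)  # periodic
        dip <- dip + exp(-(dd / cell_w)^4)
      }
      img[li, ] <- 1 - 0.6 * pmin(dip, 1)
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd), n_lines, n_px)
  })
  structure(list(image = img, dx_um = dx_um, dt_line_s = dt_line_s,
                 truth = list(velocity_mm_s = velocity_mm_s, v_px_per_line = v_px)),
            class = "line_scan")
}

# draw n random filled disks into a mask, returning also per-disk info
random_disks <- function(d, n, r_range, margin) {
  centers <- cbind(runif(n, margin, d[1] - margin), runif(n, margin, d[2] - margin))
  radii <- runif(n, r_range[1], r_range[2])
  yy <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  xx <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  mask <- matrix(FALSE, d[1], d[2])
  per <- vector("list", n)
  for (i in seq_len(n)) {
    m <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <= radii[i]^2
    per[[i]] <- m
    mask <- mask | m
  }
  list(mask = mask, disks = per, centers = centers, radii = radii)
}

#' Simulate a multi-channel 2D histology image
#'
#' Renders vessel cross-sections (AQP4 or CD31 channel), an arterial subset
#' (alpha-SMA channel, strictly inside the vessel footprint), and either
#' TRITC extravasation speckle placed in 15-um perivascular rings at requested
#' area fractions (`panel = "extravasation"`) or a ZO-1 channel whose
#' intensity is scaled per vessel class (`panel = "tight_junction"`).
#'
#' @param leak_level_by_class target TRITC-positive area fraction in `[0, 1]`
#'   of the perivascular ring, named `c(sma_pos = , sma_neg = )`.
#' @param panel which staining panel to emulate.
#' @param zo1_scale_by_class multiplicative ZO-1 intensity per compartment,
#'   named `c(sma_pos = , sma_neg = )` (tight-junction panel only).
#' @param size image size in pixels (square).
#' @param pixel_size_um pixel pitch (default 0.18 um... scaled up to keep
#'   desk-scale images small; configurable).
#' @param n_vessels number of vessel cross-sections (first half arterial).
#' @param seed integer seed.
#' @return a `histology_image`: `channels` (named list of matrices),
#'   `pixel_size_um`, and `truth` (vessel/SMA masks, rings, placed fractions).
#' @export
simulate_histology <- function(leak_level_by_class = c(sma_pos = 0.25, sma_neg = 0.25),
                               panel = c("extravasation", "tight_junction"),
                               zo1_scale_by_class = c(sma_pos = 1, sma_neg = 1),
                               size = 220, pixel_size_um = 0.5,
                               n_vessels = 6, seed = 1L) {
  panel <- match.arg(panel)
  stopifnot(all(leak_level_by_class >= 0), all(leak_level_by_class <= 1))
  d <- c(size, size)
  ring_px <- 15 / pixel_size_um
  with_seed(derive_seed(seed, "histology", panel), {
    vs <- random_disks(d, n_vessels, r_range = c(8, 16), margin = ring_px + 20)
    n_art <- ceiling(n_vessels / 2)
    sma <- Reduce(`|`, vs$disks[seq_len(n_art)])
    vessel <- vs$mask
    # rings per compartment (disk dilation via EDT, nearest-owner by compartment)
    ed <- edt_um(vessel, c(pixel_size_um, pixel_size_um))
    ring <- ed$dist > 0 & ed$dist <= 15
    owner_is_sma <- matrix(FALSE, d[1], d[2])
    owner_is_sma[ring] <- sma[ed$nearest[ring]]
    rings <- list(sma_pos = ring & owner_is_sma, sma_neg = ring & !owner_is_sma)

    base_noise <- function() matrix(abs(rnorm(prod(d), 8, 3)), d[1], d[2])
    aqp4 <- base_noise(); aqp4[vessel] <- aqp4[vessel] + 120
    smac <- base_noise(); smac[sma] <- smac[sma] + 110
    dapi <- base_noise()
    ndapi <- 150
    dy <- round(runif(ndapi, 3, d[1] - 3)); dx2 <- round(runif(ndapi, 3, d[2] - 3))
    for (k in seq_len(ndapi)) dapi[dy[k] + (-1:1), dx2[k] + (-1:1)] <- 90

    channels <- list(DAPI = dapi, aSMA = smac)
    placed <- c(sma_pos = 0, sma_neg = 0)
    if (panel == "extravasation") {
      tritc <- base_noise(); tritc[vessel] <- tritc[vessel] + 100
      for (comp in names(rings)) {
        lev <- leak_level_by_class[[comp]]
        idx <- which(rings[[comp]])
        n_on <- round(lev * length(idx))
        if (n_on > 0) {
          on <- sample(idx, n_on)
          tritc[on] <- tritc[on] + 100
          placed[comp] <- n_on / length(idx)
        }
      }
      channels$TRITC <- tritc
      channels$AQP4 <- aqp4
    } else {
      zo1 <- base_noise()
      for (comp in c("sma_pos", "sma_neg")) {
        m <- if (comp == "sma_pos") vessel & sma else vessel & !sma
        zo1[m] <- zo1[m] + 100 * zo1_scale_by_class[[comp]]
      }
      channels$CD31 <- aqp4
      channels$ZO1 <- zo1
    }
    truth <- list(vessel_mask = vessel, sma_mask = sma, rings = rings,
                  placed_fraction = placed)
  })
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 truth = truth),
            class = "histology_image")
}

#' Simulate a cohort of per-vessel leakage traces
#'
#' Generates trace-level data for virtual animals (default 4 Control / 4 SE /
#' 3 NI, mirroring the study design) without volumetric rendering: each vessel
#' gets a two-compartment perivascular curve under its class- and
#' condition-specific Ktrans plus a vessel-scatter baseline and frame noise.
#' Used for cohort-scale validation of the index / embedding / diagnostic
#' stages, which operate purely on traces; volumetric rendering and
#' re-segmentation are exercised separately on small volumes.
#'
#' @param n_animals named condition counts.
#' @param vessels_per_class vessels per animal per class.
#' @param kinetics a [kinetics_spec()].
#' @param frame_interval_s,duration_min acquisition timing.
#' @param seed integer seed.
#' @return list with `traces` (vessels x frames matrix of perivascular F),
#'   `f_iv` (intravascular trace matrix), `t_min`, and `meta` (data.frame:
#'   vessel_id, animal_id, condition, class, true_Ktrans, n_voxels).
#' @export
simulate_cohort_traces <- function(n_animals = c(Control = 4, SE = 4, NI = 3),
                                   vessels_per_class = c(arteriole = 8, capillary = 20, venule = 12),
                                   kinetics = kinetics_spec(),
                                   frame_interval_s = 15, duration_min = 60,
                                   seed = 1L) {
  t_min <- seq(0, duration_min, by = frame_interval_s / 60)
  nt <- length(t_min)
  C_iv <- plasma_input(t_min, kinetics)
  rows <- list(); F <- list(); Fiv <- list()
  vid <- 0L
  for (cond in names(n_animals)) {
    for (a in seq_len(n_animals[[cond]])) {
      aid <- sprintf("%s_%d", cond, a)
      sa <- derive_seed(seed, "cohort", cond, a)
      with_seed(sa, {
        animal_mult <- rlnorm(1, 0, kinetics$animal_sdlog)
        for (class in names(vessels_per_class)) {
          n <- vessels_per_class[[class]]
          kt0 <- kinetics$Ktrans_by_type[cond, class]
          for (v in seq_len(n)) {
            vid <- vid + 1L
            kt <- kt0 * animal_mult * rlnorm(1, 0, kinetics$vessel_sdlog)
            cp <- two_compartment_cp(C_iv, t_min, kt, kinetics$k_out)
            n_vox <- round(runif(1, 200, 800))
            w_bleed <- kinetics$bleed_frac * runif(1, 0.35, 0.55)
            w_halo <- runif(1, 0.15, 0.25)
            sig <- kinetics$noise_sigma / sqrt(n_vox)
            F[[vid]] <- w_bleed * C_iv + w_halo * cp + rnorm(nt, 0, sig)
            Fiv[[vid]] <- C_iv + rnorm(nt, 0, sig)
            rows[[vid]] <- data.frame(vessel_id = vid, animal_id = aid,
                                      condition = cond, class = class,
                                      true_Ktrans = kt, n_voxels = n_vox)
          }
        }
      })
    }
  }
  list(traces = do.call(rbind, F), f_iv = do.call(rbind, Fiv),
       t_min = t_min, meta = do.call(rbind, rows))
}

#' Simulate a graded-severity (Ktrans ladder) trace cohort
#'
#' Vessels are drawn in groups around logarithmically spaced Ktrans levels,
#' producing a continuum of leakage severities. This is the reference world
#' for correlation properties of the UMAP-distance index (real cohorts span
#' severities continuously; the disease cohort of
#' [simulate_cohort_traces()] concentrates most vessels at control-level
#' leakage, where rank correlations are noise-dominated by construction).
#'
#' @param levels Ktrans rung means (1/min).
#' @param n_per vessels per rung.
#' @param sdlog within-rung log-normal spread of Ktrans. The default (0.3)
#'   gives the overlapping severity continuum used for correlation
#'   properties; distinct-regime worlds (cluster recovery) use a tighter
#'   spread so rungs are actual regimes.
#' @param fixed_geometry hold the per-vessel rendering weights (scatter
#'   baseline and halo capture fraction) at their class-typical midpoints.
#'   Regime-recovery worlds use `TRUE` so cluster structure reflects the
#'   kinetic regimes rather than geometric nuisance variation; with jittered
#'   geometry the rungs blur into a severity continuum.
#' @param kinetics a [kinetics_spec()].
#' @param frame_interval_s,duration_min acquisition timing.
#' @param seed integer seed.
#' @return list: `traces`, `t_min`, `level` (rung index per vessel),
#'   `true_Ktrans`.
#' @export
simulate_ktrans_ladder <- function(levels = 10^seq(-4, -2, length.out = 5),
                                   n_per = 25, sdlog = 0.3,
                                   fixed_geometry = FALSE,
                                   kinetics = kinetics_spec(),
                                   frame_interval_s = 15, duration_min = 60,
                                   seed = 1L) {
  t_min <- seq(0, duration_min, by = frame_interval_s / 60)
  C_iv <- plasma_input(t_min, kinetics)
  with_seed(derive_seed(seed, "ladder"), {
    F <- list(); lev <- integer(0); kt <- numeric(0)
    for (g in seq_along(levels)) for (i in seq_len(n_per)) {
      k <- levels[g] * rlnorm(1, 0, sdlog)
      cp <- two_compartment_cp(C_iv, t_min, k, kinetics$k_out)
      n_vox <- round(runif(1, 200, 800))
      w_b <- if (fixed_geometry) 0.45 else runif(1, 0.35, 0.55)
      w_h <- if (fixed_geometry) 0.20 else runif(1, 0.15, 0.25)
      F[[length(F) + 1]] <- kinetics$bleed_frac * w_b * C_iv + w_h * cp +
        rnorm(length(t_min), 0, kinetics$noise_sigma / sqrt(n_vox))
      lev <- c(lev, g); kt <- c(kt, k)
    }
    list(traces = do.call(rbind, F), t_min = t_min, level = lev, true_Ktrans = kt)
  })
}

#' Write phantom truth tables to disk
#'
#' Segment table as CSV, acquisition/kinetics metadata as JSON.
#' @param truth a `phantom_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(truth$segment_table, file.path(dir, "segment_table.csv"), row.names = FALSE)
  meta <- truth[c("voxel_size_um", "volume_shape", "frame_interval_s",
                  "duration_min", "condition", "animal_id")]
  jsonlite::write_json(meta, file.path(dir, "truth_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
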