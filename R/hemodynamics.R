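# Radon-transform line-scan velocimetry, Patlak Ktrans, and Renkin-Crone
# flow-normalized permeability.

# Sobel gradient along the space axis (columns) of a space-time image,
# replicate borders.
sobel_space <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[, c(1, seq_len(nc), nc)]
  gx <- pad[, 3:(nc + 2)] - pad[, 1:nc]            # horizontal difference
  padr <- gx[c(1, seq_len(nr), nr), ]
  padr[1:nr, ] + 2 * padr[2:(nr + 1), ] + padr[3:(nr + 2), ]  # vertical smooth
}

# Radon projection sharpness at streak slope `s` (px displacement per line),
# via shear projection with linear-interpolation binning: pixel weight is
# split between the two bins flanking p = c - s * r (one-column bin width at
# every slope; shearing avoids the tan-compression of a rotation-grid Radon
# near 90 degrees). Returns an excess-variance z-score: under unstructured
# noise the weighted variance of per-bin means scales as
# sigma^2 * n_bins / n_px with chi-square fluctuations, so the standardized
# excess is ~N(0, 1) for noise at every slope (the bin count cancels) and
# large only where the projection aligns with the streaks.
slope_variance <- function(vals, rr, cc, s, pixvar) {
  p <- cc - s * rr
  p <- p - min(p)
  b0 <- floor(p)
  w1 <- p - b0
  bin <- c(b0, b0 + 1) + 1L
  wts <- c(1 - w1, w1)
  sums <- rowsum(c(vals * (1 - w1), vals * w1), bin)
  cnt <- rowsum(wts, bin)
  keep <- cnt > 1e-9
  sums <- sums[keep]; cnt <- cnt[keep]
  m <- sums / cnt
  mu <- sum(sums) / sum(cnt)
  wvar <- sum(cnt * (m - mu)^2) / sum(cnt)
  nb <- length(sums)
  (wvar * sum(cnt) / pixvar - nb) / sqrt(2 * nb)
}

#' RBC velocity from a line-scan space-time image via the Radon transform
#'
#' The image is split into sliding windows of `window_lines` rows. Per
#' window: Sobel filtering along the space axis enhances streak edges, the
#' Radon projection variance is evaluated over a 0.5-degree grid of streak
#' angles (measured from the time axis), the argmax is refined by a parabolic
#' fit, and velocity follows as `v = (dx / dt_line) * tan(theta)`. A vertical
#' streak (stationary shadow) gives theta = 0, v = 0. Windows with a flat
#' variance profile, or whose implied per-line displacement exceeds half the
#' spatial window width (aliasing guard), are marked invalid.
#'
#' @param linescan a `line_scan` (see [simulate_linescan()]) or a list with
#'   `image`, `dx_um`, `dt_line_s`.
#' @param window_lines sliding-window height in lines (default 40).
#' @param overlap fractional window overlap (default 0.5).
#' @param theta_step angle grid step, degrees.
#' @param min_snr validity threshold on the peak excess-variance z-score of
#'   the aligned projection (approximately N(0,1) under unstructured noise at
#'   every slope); windows whose best angle does not beat this are invalid.
#' @return data.frame: `window_start_line`, `theta_deg`, `v_mm_s`, `valid`.
#' @export
radon_velocity <- function(linescan, window_lines = 40, overlap = 0.5,
                           theta_step = 0.5, min_snr = 6) {
  img <- linescan$image
  dx <- linescan$dx_um; dt <- linescan$dt_line_s
  nr <- nrow(img); nc <- ncol(img)
  if (window_lines > nr) stopf("window (%d lines) exceeds the image (%d lines)", window_lines, nr)
  step <- max(1L, round(window_lines * (1 - overlap)))
  starts <- seq(1L, nr - window_lines + 1L, by = step)
  thetas <- seq(-90 + theta_step, 90 - theta_step, by = theta_step)
  out <- data.frame(window_start_line = starts, theta_deg = NA_real_,
                    v_mm_s = NA_real_, valid = FALSE)

  for (w in seq_along(starts)) {
    sub <- img[starts[w]:(starts[w] + window_lines - 1L), , drop = FALSE]
    g <- sobel_space(sub)
    g <- g - mean(g)
    rr <- as.numeric(row(g)); cc <- as.numeric(col(g)); vals <- as.numeric(g)
    pixvar <- var(vals)
    if (pixvar == 0) next  # flat window
    vr <- vapply(thetas, function(th) slope_variance(vals, rr, cc, tan(th * pi / 180), pixvar),
                 numeric(1))
    i <- which.max(vr)
    # refine in slope space: the angle grid is coarse in tan(theta) near 90
    s0 <- tan(thetas[i] * pi / 180)
    sg <- if (abs(s0) < 1) seq(s0 - 0.05, s0 + 0.05, length.out = 41)
          else s0 * seq(0.85, 1.15, length.out = 41)
    vs_ <- vapply(sg, function(s) slope_variance(vals, rr, cc, s, pixvar), numeric(1))
    j <- which.max(vs_)
    s_hat <- sg[j]
    if (j > 1 && j < length(sg)) {  # parabolic peak interpolation
      y1 <- vs_[j - 1]; y2 <- vs_[j]; y3 <- vs_[j + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) s_hat <- s_hat + (sg[j + 1] - sg[j]) * 0.5 * (y1 - y3) / den
    }
    # validity: the z-score is computed on the RAW window (independent pixel
    # noise, so the chi-square standardization holds; the Sobel image is
    # spatially correlated and only used for angle estimation)
    rawv <- as.numeric(sub) - mean(sub)
    rawvar <- var(rawv)
    if (rawvar == 0) next
    if (slope_variance(rawv, rr, cc, s_hat, rawvar) < min_snr) next  # no streaks
    if (abs(s_hat) > nc / 2) next  # aliasing guard: reject, never silently wrong
    out$theta_deg[w] <- atan(s_hat) * 180 / pi
    out$v_mm_s[w] <- dx / dt * s_hat / 1000
    out$valid[w] <- TRUE
  }
  out
}

#' Patlak plot estimate of the volume transfer constant
#'
#' Ordinary least squares of `y(t) = F_peri(t) / F_iv(t)` against
#' `x(t) = [integral_0^t F_iv dtau] / F_iv(t)` (trapezoidal integral,
#' minutes) over frames with `t >= fit_start`. The slope is Ktrans (1/min),
#' the intercept the apparent blood volume fraction v_b. Negative slopes are
#' reported raw with a flag, not clipped.
#'
#' @param F_peri,F_iv perivascular and intravascular traces.
#' @param t_min frame times, minutes.
#' @param fit_start first time included in the fit (default 5 min,
#'   post-bolus).
#' @return list: `Ktrans`, `v_b`, `r2`, `fit_window` (frame index range),
#'   `negative_slope` flag.
#' @export
patlak_ktrans <- function(F_peri, F_iv, t_min, fit_start = 5) {
  n <- length(t_min)
  stopifnot(length(F_peri) == n, length(F_iv) == n)
  cum <- c(0, cumsum(diff(t_min) * (F_iv[-1] + F_iv[-n]) / 2))
  sel <- which(t_min >= fit_start)
  if (length(sel) < 5) stopf("Patlak fit requires >= 5 points after fit_start")
  if (any(F_iv[sel] <= 0)) stopf("F_iv must be positive on the fit window")
  x <- cum[sel] / F_iv[sel]
  y <- F_peri[sel] / F_iv[sel]
  if (var(x) < 1e-12 * max(1, mean(x)^2)) stopf("degenerate Patlak abscissa (constant x)")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2]); icpt <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2); ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(Ktrans = slope, v_b = icpt, r2 = r2,
       fit_window = range(sel), negative_slope = slope < 0)
}

#' Plasma flow surrogate from vessel geometry and RBC velocity
#'
#' `F_p = v * A * (1 - Hct)` with `A = pi (d/2)^2`, in um^3/s; when the
#' perivascular ROI volume is supplied, F_p is additionally normalized by it
#' and converted to 1/min so it shares units with Ktrans (the ROI is the
#' distribution volume the trace measures).
#'
#' @param diameter_um lumen diameter, um.
#' @param velocity_mm_s RBC velocity, mm/s.
#' @param Hct hematocrit (default 0.45).
#' @param roi_volume_um3 optional perivascular ROI volume, um^3.
#' @return list: `F_p_um3_s`, `A_um2`, and `F_p_min` (1/min; `NA` without a
#'   normalization volume).
#' @export
plasma_flow <- function(diameter_um, velocity_mm_s, Hct = 0.45, roi_volume_um3 = NULL) {
  check_positive(diameter_um, "diameter_um")
  check_positive(velocity_mm_s, "velocity_mm_s")
  stopifnot(Hct >= 0, Hct < 1)
  A <- pi * (diameter_um / 2)^2
  Fp <- velocity_mm_s * 1000 * A * (1 - Hct)  # um^3 / s
  Fp_min <- if (is.null(roi_volume_um3)) NA_real_ else Fp / roi_volume_um3 * 60
  list(F_p_um3_s = Fp, A_um2 = A, F_p_min = Fp_min)
}

#' Renkin-Crone flow normalization of Ktrans
#'
#' Inverts `Ktrans = F_p (1 - exp(-PS / F_p))` to the permeability-surface
#' product `PS = -F_p log(1 - Ktrans / F_p)` (same units as Ktrans).
#' `PS >= Ktrans` always, and `PS -> Ktrans` in the extraction limit
#' `Ktrans << F_p`. At `Ktrans >= F_p` transfer is flow-limited and PS is
#' undefined: an error is raised so such vessels are flagged and excluded
#' from summaries.
#'
#' @param Ktrans volume transfer constant (>= 0).
#' @param F_p plasma flow in the same units.
#' @return PS in the units of Ktrans.
#' @export
renkin_crone_ps <- function(Ktrans, F_p) {
  stopifnot(length(Ktrans) == 1, length(F_p) == 1)
  if (Ktrans < 0) stopf("Ktrans must be non-negative")
  check_positive(F_p, "F_p")
  if (Ktrans >= F_p)
    stopf("flow-limited regime (Ktrans = %.3g >= F_p = %.3g): PS undefined", Ktrans, F_p)
  -F_p * log(1 - Ktrans / F_p)
}
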