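# Ex vivo 2D histology quantification: local-threshold binarization,
# alpha-SMA-based vessel partition, 15-um perivascular rings, TRITC-positive
# area ratios, and ZO-1 mean intensity in endothelial ROIs.

# box-filter local mean and sd via integral images
local_stats <- function(img, half_px) {
  nr <- nrow(img); nc <- ncol(img)
  pad_cum <- function(m) {
    cs <- apply(m, 2, cumsum)
    cs <- t(apply(cs, 1, cumsum))
    I <- matrix(0, nrow(m) + 1, ncol(m) + 1)
    I[-1, -1] <- cs
    I
  }
  I1 <- pad_cum(img); I2 <- pad_cum(img^2)
  r0 <- as.vector(pmax(row(img) - half_px, 1)); r1 <- as.vector(pmin(row(img) + half_px, nr))
  c0 <- as.vector(pmax(col(img) - half_px, 1)); c1 <- as.vector(pmin(col(img) + half_px, nc))
  area <- (r1 - r0 + 1) * (c1 - c0 + 1)
  box <- function(I) I[cbind(r1 + 1, c1 + 1)] - I[cbind(r0, c1 + 1)] -
    I[cbind(r1 + 1, c0)] + I[cbind(r0, c0)]
  m <- box(I1) / area
  v <- pmax(box(I2) / area - m^2, 0)
  list(mean = matrix(m, nr, nc), sd = matrix(sqrt(v), nr, nc))
}

#' Local adaptive binarization
#'
#' Sauvola (default) or Niblack thresholding over a square window of physical
#' width `window_um`. `polarity = "dark"` segments dark-on-bright structures
#' by operating on the negated image, so flipping the image contrast together
#' with the polarity flag reproduces the same mask.
#'
#' @param channel 2D intensity matrix.
#' @param method `"sauvola"` or `"niblack"`.
#' @param window_um window width, micrometres (default 25).
#' @param pixel_size_um pixel pitch.
#' @param k sensitivity parameter (0.2 Sauvola, -0.2 Niblack typical).
#' @param polarity `"bright"` (default) or `"dark"`.
#' @param floor `"otsu"` (default) additionally requires pixels to clear the
#'   global Otsu threshold: purely local thresholds always "find" structure
#'   in noise-only regions, so a global noise floor suppresses speckle false
#'   positives where no bright class exists locally. `"none"` disables it.
#' @return logical mask.
#' @export
local_threshold <- function(channel, method = c("sauvola", "niblack"),
                            window_um = 25, pixel_size_um = 0.5, k = 0.2,
                            polarity = c("bright", "dark"),
                            floor = c("otsu", "none")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  floor <- match.arg(floor)
  stopifnot(is.matrix(channel))
  if (length(channel) == 0) stopf("empty channel")
  # dark polarity reflects intensities (keeps them positive for Sauvola);
  # exact mask symmetry under contrast inversion holds for Niblack
  img <- if (polarity == "dark") max(channel) + min(channel) - channel else channel
  half <- max(1L, round(window_um / pixel_size_um / 2))
  if (2 * half + 1 < 3) stopf("window must be >= 3 px")
  ls <- local_stats(img, half)
  thr <- switch(method,
    sauvola = {
      R <- max(ls$sd, 1e-12)
      ls$mean * (1 + k * (ls$sd / R - 1))
    },
    niblack = ls$mean + k * ls$sd)
  if (floor == "otsu") thr <- pmax(thr, otsu_threshold(img))
  img > thr
}

#' Perivascular ring of a 2D vessel mask
#'
#' Dilation by a disk of physical radius `width_um` minus the original mask
#' (equivalently, pixels whose distance to the vessel lies in `(0, width]`).
#'
#' @param vessel_mask logical matrix.
#' @param width_um ring width, micrometres (default 15).
#' @param pixel_size_um pixel pitch.
#' @return logical ring mask, disjoint from the vessel mask.
#' @export
perivascular_ring <- function(vessel_mask, width_um = 15, pixel_size_um = 0.5) {
  stopifnot(is.matrix(vessel_mask))
  if (!any(vessel_mask)) return(vessel_mask & FALSE)
  ed <- edt_um(vessel_mask, c(pixel_size_um, pixel_size_um))
  ed$dist > 0 & ed$dist <= width_um
}

#' Partition vessels into alpha-SMA positive and negative compartments
#'
#' Connected components of the vessel mask are alpha-SMA+ (arterial) when
#' their overlap fraction with the SMA mask exceeds `overlap_frac`, else
#' alpha-SMA- (other vessels). The partition is exhaustive and disjoint.
#'
#' @param vessel_mask,sma_mask logical matrices of identical shape.
#' @param overlap_frac overlap threshold (default 0.3).
#' @return list of logical masks `sma_pos`, `sma_neg`.
#' @export
split_by_sma <- function(vessel_mask, sma_mask, overlap_frac = 0.3) {
  stopifnot(all(dim(vessel_mask) == dim(sma_mask)))
  lab <- label_components(vessel_mask, 26)
  n <- attr(lab, "n_components")
  pos <- vessel_mask & FALSE
  for (i in seq_len(n)) {
    comp <- lab == i
    if (sum(comp & sma_mask) / sum(comp) > overlap_frac) pos <- pos | comp
  }
  list(sma_pos = pos, sma_neg = vessel_mask & !pos)
}

#' TRITC-positive area ratio within a perivascular ring
#'
#' @param tritc_mask binarized extravasation channel.
#' @param ring_mask perivascular ring mask.
#' @return percentage `100 * |tritc & ring| / |ring|`.
#' @export
tritc_area_ratio <- function(tritc_mask, ring_mask) {
  stopifnot(all(dim(tritc_mask) == dim(ring_mask)))
  if (!any(ring_mask)) stopf("empty perivascular ring: area ratio undefined")
  100 * sum(tritc_mask & ring_mask) / sum(ring_mask)
}

#' ZO-1 mean intensity within endothelial ROIs
#'
#' Arithmetic mean of the ZO-1 channel over CD31-mask pixels, per image;
#' [normalize_to_control()] expresses per-group values relative to the
#' control-group mean (so the control group normalizes to 1 exactly).
#'
#' @param zo1_channel 2D intensity matrix.
#' @param cd31_mask logical endothelial ROI mask.
#' @return raw mean intensity (arbitrary units).
#' @export
zo1_mean_intensity <- function(zo1_channel, cd31_mask) {
  stopifnot(all(dim(zo1_channel) == dim(cd31_mask)))
  if (!any(cd31_mask)) stopf("empty CD31 mask")
  mean(zo1_channel[cd31_mask])
}

#' Normalize per-image values to the control-group mean
#'
#' @param values per-image measurements.
#' @param groups per-image group labels.
#' @param control label of the control group.
#' @return values divided by the mean of the control group.
#' @export
normalize_to_control <- function(values, groups, control = "Control") {
  stopifnot(length(values) == length(groups), any(groups == control))
  values / mean(values[groups == control])
}
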