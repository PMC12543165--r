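# Per-vessel leakage traces and the conventional intensity-based indices:
# AUC, dF/F0 (50-60 min window), and dF/dt.

#' Extract per-vessel leakage traces from a time-lapse
#'
#' For every perivascular ROI, the trace F(t) is the arithmetic mean of the
#' frame intensity over the ROI voxels; F_iv(t) is the mean over the owner
#' segment's lumen voxels. ROIs smaller than `min_roi_voxels` are dropped
#' with a warning.
#'
#' @param timelapse a 4D [image_stack()] (registered to the structural frame).
#' @param shells result of [perivascular_shells()].
#' @param lumen_label integer array of lumen segment ids.
#' @param min_roi_voxels minimum ROI size (default 20).
#' @return a `trace_set`: `t_min`, `F` (vessels x frames), `F_iv`, and `meta`
#'   (segment_id, n_voxels).
#' @export
extract_traces <- function(timelapse, shells, lumen_label, min_roi_voxels = 20) {
  stopifnot(is_4d(timelapse))
  d <- dim(timelapse$data)
  if (!all(d[2:4] == dim(shells$shell_label))) stopf("time-lapse / ROI shape mismatch")
  ids <- shells$table$segment_id
  keep <- shells$table$n_voxels >= min_roi_voxels
  if (any(!keep))
    warnf("dropping %d ROI(s) below %d voxels (segments: %s)",
          sum(!keep), min_roi_voxels, paste(ids[!keep], collapse = ", "))
  ids <- ids[keep]
  if (length(ids) == 0) stopf("no usable ROIs")
  nt <- d[1]
  roi_idx <- lapply(ids, function(i) which(shells$shell_label == i))
  lum_idx <- lapply(ids, function(i) which(lumen_label == i))
  F <- matrix(0, length(ids), nt)
  Fiv <- matrix(0, length(ids), nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(timelapse, t)
    F[, t] <- vapply(roi_idx, function(ix) mean(fr[ix]), numeric(1))
    Fiv[, t] <- vapply(lum_idx, function(ix) if (length(ix)) mean(fr[ix]) else NA_real_, numeric(1))
  }
  list(t_min = frame_times_min(timelapse), F = F, F_iv = Fiv,
       meta = data.frame(segment_id = ids,
                         n_voxels = shells$table$n_voxels[keep]))
}

#' Baseline-normalize a trace
#'
#' `f(t) = F(t) / F0` with F0 the mean of `baseline_frames` early frames.
#' The first `skip_frames` frames are excluded from the baseline: the
#' injection frame precedes bolus arrival, and folding it into F0 would
#' inflate every fold-change index by the bolus rise. Traces with
#' non-positive F0 cannot be normalized and are excluded by the matrix-level
#' helpers (with a logged reason).
#'
#' @param F numeric intensity trace.
#' @param baseline_frames number of baseline frames averaged into F0.
#' @param skip_frames initial frames excluded from the baseline (default 1,
#'   the injection frame).
#' @return list `f` (normalized trace) and `F0`, or `NULL` (with a warning)
#'   when F0 <= 0.
#' @export
normalize_trace <- function(F, baseline_frames = 5, skip_frames = 1) {
  sel <- seq(skip_frames + 1, min(skip_frames + baseline_frames, length(F)))
  F0 <- mean(F[sel])
  if (!is.finite(F0) || F0 <= 0) {
    warnf("trace excluded: baseline F0 = %.3g is not positive", F0)
    return(NULL)
  }
  list(f = F / F0, F0 = F0)
}

# matrix version: rows normalized, non-positive-baseline rows dropped
normalize_trace_matrix <- function(F, baseline_frames = 5, skip_frames = 1) {
  sel <- seq(skip_frames + 1, min(skip_frames + baseline_frames, ncol(F)))
  F0 <- rowMeans(F[, sel, drop = FALSE])
  keep <- is.finite(F0) & F0 > 0
  if (any(!keep)) warnf("excluding %d trace(s) with non-positive baseline", sum(!keep))
  list(f = F[keep, , drop = FALSE] / F0[keep], F0 = F0[keep], keep = keep)
}

#' Leakage index: area under the normalized trace
#'
#' Trapezoidal integral of f over the full acquisition (fold x min); a
#' constant trace of 1 over 60 min gives 60.
#'
#' @param f normalized trace.
#' @param t_min frame times, minutes.
#' @param raw set `TRUE` to integrate a raw (unnormalized) trace instead.
#' @param F raw trace, used when `raw = TRUE`.
#' @return AUC in fold x min.
#' @export
index_auc <- function(f, t_min, raw = FALSE, F = NULL) {
  y <- if (raw) F else f
  n <- length(y)
  if (n < 2) stopf("AUC requires at least 2 frames")
  stopifnot(length(t_min) == n)
  sum(diff(t_min) * (y[-1] + y[-n]) / 2)
}

#' Leakage index: late-window fold change dF/F0
#'
#' Mean of the normalized trace over frames with `t` in the window
#' (default 50-60 min), expressed as a fold of baseline.
#'
#' @param f normalized trace.
#' @param t_min frame times, minutes.
#' @param window late measurement window `c(lo, hi)` in minutes.
#' @return fold change (dimensionless).
#' @export
index_dff0 <- function(f, t_min, window = c(50, 60)) {
  sel <- t_min >= window[1] & t_min <= window[2]
  if (!any(sel)) stopf("empty dF/F0 window [%g, %g] min", window[1], window[2])
  mean(f[sel])
}

#' Leakage index: averaged differential coefficient dF/dt
#'
#' Mean of successive finite differences of the normalized trace
#' (fold / min). On a uniform grid this telescopes to
#' `(f_N - f_1) / (t_N - t_1)`; both forms are computed and their equality
#' asserted.
#'
#' @param f normalized trace.
#' @param t_min frame times (uniform grid), minutes.
#' @return mean rate of change, fold / min.
#' @export
index_dfdt <- function(f, t_min) {
  n <- length(f)
  if (n < 2) stopf("dF/dt requires at least 2 frames")
  dt <- diff(t_min)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) stopf("dF/dt requires uniform sampling")
  brute <- mean(diff(f) / dt)
  telescoped <- (f[n] - f[1]) / (t_min[n] - t_min[1])
  if (abs(brute - telescoped) > 1e-9 * max(1, abs(telescoped)))
    stopf("finite-difference identity violated (numerical fault)")
  telescoped
}

#' Compute all conventional leakage indices for a trace set
#'
#' @param traces a `trace_set` from [extract_traces()] (or any list with
#'   `F`, `t_min`, `meta`).
#' @param baseline_frames baseline window for F0.
#' @param window late window for dF/F0, minutes.
#' @return data.frame: segment_id, auc, dff0, dfdt, F0 (rows with
#'   non-positive baseline are excluded).
#' @export
compute_indices <- function(traces, baseline_frames = 5, window = c(50, 60)) {
  nm <- normalize_trace_matrix(traces$F, baseline_frames)
  meta <- traces$meta[nm$keep, , drop = FALSE]
  out <- data.frame(
    segment_id = meta$segment_id,
    auc = apply(nm$f, 1, index_auc, t_min = traces$t_min),
    dff0 = apply(nm$f, 1, index_dff0, t_min = traces$t_min, window = window),
    dfdt = apply(nm$f, 1, index_dfdt, t_min = traces$t_min),
    F0 = nm$F0)
  extra <- setdiff(names(meta), "segment_id")
  for (cn in extra) out[[cn]] <- meta[[cn]]
  out
}
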