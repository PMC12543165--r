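# ImageStack container: 3D (z,y,x) structural stacks and 4D (t,z,y,x)
# time-lapses with physical calibration, plus plain-text serialization.
# (No TIFF reader exists in the target R environment, so stacks are stored as
# a JSON header plus a flat CSV of voxel values in column-major order.)

#' Construct an image stack
#'
#' The raw substrate of the pipeline: a fluorescence intensity grid with
#' physical calibration. 3D stacks are indexed `(z, y, x)`, time-lapses
#' `(t, z, y, x)` with a uniform frame interval.
#'
#' @param data numeric array, 3D `(z,y,x)` or 4D `(t,z,y,x)`, values >= 0
#'   (arbitrary fluorescence units).
#' @param voxel_size_um physical voxel size `(z, y, x)` in micrometres
#'   (default the two-photon acquisition geometry, 2 x 0.692 x 0.692 um).
#' @param frame_interval_s seconds between frames (4D only; default 15 s).
#' @param channel_role one of `"structure"`, `"leakage"`, `"histology"`.
#'   Preprocessing steps that would distort quantitative leakage signals
#'   (rolling-ball, flat-field) refuse `"leakage"` stacks unless overridden.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data,
                        voxel_size_um = c(2.0, 0.692, 0.692),
                        frame_interval_s = if (length(dim(data)) == 4L) 15 else NA_real_,
                        channel_role = c("structure", "leakage", "histology")) {
  channel_role <- match.arg(channel_role)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stopf("`data` must be a 3D (z,y,x) or 4D (t,z,y,x) array")
  check_positive(voxel_size_um, "voxel_size_um")
  stopifnot(length(voxel_size_um) == 3L)
  if (nd == 4L) check_positive(frame_interval_s, "frame_interval_s")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         frame_interval_s = as.numeric(frame_interval_s), channel_role = channel_role),
    class = "image_stack")
}

is_4d <- function(stack) length(dim(stack$data)) == 4L

n_frames <- function(stack) if (is_4d(stack)) dim(stack$data)[1] else 1L

get_frame <- function(stack, t) {
  if (!is_4d(stack)) return(stack$data)
  d <- dim(stack$data)
  array(stack$data[t, , , ], d[-1])
}

set_frame <- function(stack, t, frame) {
  stack$data[t, , , ] <- frame
  stack
}

#' Frame times of a time-lapse, in minutes
#' @param stack an `image_stack`.
#' @export
frame_times_min <- function(stack) {
  (seq_len(n_frames(stack)) - 1L) * stack$frame_interval_s / 60
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_stack> ", paste(d, collapse = " x "),
      if (is_4d(x)) " (t,z,y,x)" else " (z,y,x)",
      "; voxel ", paste(signif(x$voxel_size_um, 4), collapse = " x "),
      " um; role=", x$channel_role, "\n", sep = "")
  invisible(x)
}

#' Write / read an image stack as plain text
#'
#' Serializes the stack as `<path>.json` (dimensions and calibration) plus
#' `<path>.csv` (voxel values, column-major). A plain-text stand-in for
#' OME-TIFF, which has no reader in this package's dependency set.
#'
#' @param stack an `image_stack`.
#' @param path file path prefix (without extension).
#' @return `write_stack` returns `path` invisibly; `read_stack` the stack.
#' @export
write_stack <- function(stack, path) {
  meta <- list(dim = dim(stack$data),
               voxel_size_um = stack$voxel_size_um,
               frame_interval_s = stack$frame_interval_s,
               channel_role = stack$channel_role)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(value = as.numeric(stack$data)),
            paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @param path file path prefix used by [write_stack()].
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- read.csv(paste0(path, ".csv"))$value
  image_stack(array(vals, meta$dim),
              voxel_size_um = meta$voxel_size_um,
              frame_interval_s = meta$frame_interval_s %||% NA_real_,
              channel_role = meta$channel_role)
}
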