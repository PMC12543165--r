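# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("`%s` must be positive and finite", name)
  invisible(x)
}

# FWHM of a Gaussian -> sigma (same units)
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Column-major (z fastest) linear index <-> (z, y, x) voxel coordinates,
# matching the C++ kernels. 1-based.
index_to_zyx <- function(idx, dims) {
  idx0 <- idx - 1L
  nz <- dims[1]; ny <- dims[2]
  cbind(z = idx0 %% nz + 1L,
        y = (idx0 %/% nz) %% ny + 1L,
        x = idx0 %/% (nz * ny) + 1L)
}

zyx_to_index <- function(zyx, dims) {
  nz <- dims[1]; ny <- dims[2]
  (zyx[, 1] - 1L) + nz * ((zyx[, 2] - 1L) + ny * (zyx[, 3] - 1L)) + 1L
}

# Deterministic child seeds derived from a master seed (kept < 2^31).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- digest::digest(key, algo = "xxhash32", serialize = FALSE)
  as.integer(strtoi(substr(h, 1, 7), 16L))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
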