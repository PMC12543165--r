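# Independent oracles used to freeze expected values. These deliberately use
# brute-force formulations (double loops, fine-grid integration, exhaustive
# pair counting) and never call the implementation paths they check.

# exact Euclidean distance (um) from each voxel of `query_idx` to the nearest
# TRUE voxel of `sites`, by exhaustive search
brute_edt_at <- function(sites, query_idx, voxel_size_um) {
  d <- dim(sites)
  site_idx <- which(sites)
  sp <- t(vesselleak:::index_to_zyx(site_idx, d)) * voxel_size_um
  vapply(query_idx, function(i) {
    p <- vesselleak:::index_to_zyx(i, d)[1, ] * voxel_size_um
    sqrt(min(colSums((sp - p)^2)))
  }, numeric(1))
}

# fine-grid Riemann integral of a linear interpolant of (t, f)
riemann_oracle <- function(f, t, oversample = 100) {
  tf <- seq(t[1], t[length(t)], length.out = (length(t) - 1) * oversample + 1)
  ff <- approx(t, f, xout = tf)$y
  sum((ff[-1] + ff[-length(ff)]) / 2 * diff(tf))
}

# Spearman rank correlation from first principles
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sd(rx) * sd(ry)) /
    ((length(x) - 1) / length(x))
}

# ROC-AUC by exhaustive concordant-pair counting (ties = 1/2)
roc_pairs_oracle <- function(values, positive_mask) {
  pos <- values[positive_mask]; neg <- values[!positive_mask]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# mean silhouette coefficient over all points (Euclidean)
silhouette_mean <- function(coords, labels) {
  dm <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(dm[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# digital cylinder mask along the x axis, spanning the full x extent
cylinder_mask <- function(dims, voxel_size_um, radius_um,
                          center_zy_um = dims[1:2] * voxel_size_um[1:2] / 2) {
  m <- array(FALSE, dims)
  zc <- (seq_len(dims[1]) - 0.5) * voxel_size_um[1]
  yc <- (seq_len(dims[2]) - 0.5) * voxel_size_um[2]
  inplane <- outer(zc - center_zy_um[1], yc - center_zy_um[2],
                   function(a, b) a^2 + b^2) <= radius_um^2
  for (x in seq_len(dims[3])) m[, , x] <- inplane
  m
}

# small smoothed blob volume used by registration tests
blob_volume <- function(seed = 7, dims = c(16, 48, 48), vs = c(2, 0.692, 0.692)) {
  withr::with_seed(seed, {
    vol <- array(0, dims)
    for (i in 1:25) {
      z <- sample(3:(dims[1] - 2), 1); y <- sample(5:(dims[2] - 4), 1)
      x <- sample(5:(dims[3] - 4), 1)
      vol[z + (-1:1), y + (-1:1), x + (-1:1)] <- 100
    }
    vesselleak:::smooth_gaussian_um(vol, 2, vs)
  })
}
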