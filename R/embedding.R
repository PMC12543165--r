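# UMAP projection of normalized single-vessel extravasation patterns, the
# UMAP-distance leakage index, hyperparameter tuning by correlation with the
# conventional indices, k-means cluster composition, and ROC diagnostics.

#' Build the vessels-x-frames feature matrix
#'
#' Rows are baseline-normalized traces f(t); optional decimation to a fixed
#' frame count is recorded in the attributes.
#'
#' @param F vessels x frames intensity matrix (or a `trace_set`).
#' @param baseline_frames baseline window for normalization.
#' @param decimate_to optional output frame count (uniform subsampling).
#' @return numeric matrix with attributes `keep` (rows retained) and
#'   `decimated_to`.
#' @export
build_feature_matrix <- function(F, baseline_frames = 5, decimate_to = NULL) {
  if (is.list(F) && !is.null(F$F)) F <- F$F
  stopifnot(is.matrix(F))
  nm <- normalize_trace_matrix(F, baseline_frames)
  m <- nm$f
  if (!is.null(decimate_to)) {
    sel <- unique(round(seq(1, ncol(m), length.out = decimate_to)))
    m <- m[, sel, drop = FALSE]
  }
  attr(m, "keep") <- nm$keep
  attr(m, "decimated_to") <- if (is.null(decimate_to)) ncol(m) else decimate_to
  m
}

#' 2D UMAP embedding of extravasation patterns
#'
#' Euclidean input metric, seeded and single-threaded so the embedding is
#' reproducible run to run. Defaults (`n_neighbors = 5`, `min_dist = 0.4`)
#' are the tuned values that maximize correlation of the UMAP distance with
#' the conventional indices.
#'
#' @param m feature matrix (vessels x frames).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed integer seed (recorded in the result).
#' @return an `embedding_result`: `coords` (n x 2), `params`,
#'   `input_matrix_hash`.
#' @export
embed_umap <- function(m, n_neighbors = 5, min_dist = 0.4, seed = 42L) {
  stopifnot(is.matrix(m))
  if (nrow(m) < n_neighbors + 1)
    stopf("need at least n_neighbors + 1 = %d rows, got %d", n_neighbors + 1, nrow(m))
  coords <- with_seed(seed, uwot::umap(m, n_neighbors = n_neighbors,
                                       min_dist = min_dist, metric = "euclidean",
                                       n_threads = 1, n_sgd_threads = 0,
                                       init = "spca"))
  dimnames(coords) <- list(rownames(m), c("u1", "u2"))
  structure(list(coords = coords,
                 params = list(metric = "euclidean", n_neighbors = n_neighbors,
                               min_dist = min_dist, seed = as.integer(seed)),
                 input_matrix_hash = digest::digest(m)),
            class = "embedding_result")
}

#' UMAP-distance leakage index
#'
#' For each vessel, the mean Euclidean distance in the embedding plane to the
#' control-group reference vessels. Control vessels exclude themselves from
#' their own reference; when `classes` is supplied the reference is
#' restricted to control vessels of the same vascular class.
#'
#' @param coords n x 2 embedding coordinates (or an `embedding_result`).
#' @param control logical vector marking control-group vessels.
#' @param classes optional per-vessel class labels for stratified reference.
#' @return numeric vector of per-vessel distances.
#' @export
umap_distance <- function(coords, control, classes = NULL) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  n <- nrow(coords)
  stopifnot(length(control) == n, is.logical(control))
  if (!is.null(classes)) stopifnot(length(classes) == n)
  dm <- as.matrix(dist(coords))
  out <- numeric(n)
  for (i in seq_len(n)) {
    ref <- control & seq_len(n) != i
    if (!is.null(classes)) ref <- ref & classes == classes[i]
    if (!any(ref)) stopf("empty control reference set for vessel %d", i)
    out[i] <- mean(dm[i, ref])
  }
  out
}

#' Tune UMAP hyperparameters against the conventional indices
#'
#' Embeds the feature matrix for every grid cell and returns the cell whose
#' UMAP distance has the largest mean Spearman correlation with the
#' conventional indices (AUC, dF/F0, dF/dt).
#'
#' @param m feature matrix.
#' @param indices data.frame with columns `auc`, `dff0`, `dfdt` for the same
#'   rows as `m`.
#' @param control logical control-group marker per row.
#' @param grid data.frame with columns `n_neighbors`, `min_dist`.
#' @param seed seed passed to every embedding.
#' @return list: `best` (one grid row), `table` (per-cell correlations).
#' @export
tune_umap <- function(m, indices, control,
                      grid = expand.grid(n_neighbors = c(5, 15, 30),
                                         min_dist = c(0.1, 0.4, 0.8)),
                      seed = 42L) {
  stopifnot(nrow(grid) >= 1, all(c("auc", "dff0", "dfdt") %in% names(indices)),
            nrow(indices) == nrow(m))
  for (cn in c("auc", "dff0", "dfdt"))
    if (var(indices[[cn]]) == 0) stopf("index '%s' is degenerate (zero variance)", cn)
  res <- grid
  res$rho_auc <- res$rho_dff0 <- res$rho_dfdt <- res$rho_mean <- NA_real_
  for (i in seq_len(nrow(grid))) {
    emb <- embed_umap(m, n_neighbors = grid$n_neighbors[i],
                      min_dist = grid$min_dist[i], seed = seed)
    D <- umap_distance(emb$coords, control)
    res$rho_auc[i] <- cor(D, indices$auc, method = "spearman")
    res$rho_dff0[i] <- cor(D, indices$dff0, method = "spearman")
    res$rho_dfdt[i] <- cor(D, indices$dfdt, method = "spearman")
    res$rho_mean[i] <- mean(c(res$rho_auc[i], res$rho_dff0[i], res$rho_dfdt[i]))
  }
  list(best = res[which.max(res$rho_mean), c("n_neighbors", "min_dist")],
       table = res)
}

# k-means++ seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' k-means clustering of the embedding with composition tables
#'
#' k-means++ initialization with `n_init` restarts (best inertia kept).
#' Raw k-means labels are arbitrary, so when `order_by` is given (e.g.
#' dF/F0) clusters are relabeled by ascending cluster mean, making cluster 1
#' the least-leaky — matching how extravasation severity tiers are reported.
#'
#' @param coords n x 2 embedding coordinates (or `embedding_result`).
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param groups optional per-vessel condition labels for the composition
#'   table (per-cluster group fractions, rows summing to 1).
#' @param classes optional per-vessel class labels; with `groups`, adds the
#'   per-(class, condition) cluster-fraction table (rows summing to 1).
#' @param order_by optional numeric per-vessel value used to order cluster
#'   labels (ascending cluster means).
#' @return list: `labels`, `centers`, `inertia`, `composition_by_cluster`,
#'   `composition_by_stratum`.
#' @export
kmeans_clusters <- function(coords, k = 3, seed = 42L, n_init = 100,
                            groups = NULL, classes = NULL, order_by = NULL) {
  if (inherits(coords, "embedding_result")) coords <- coords$coords
  n <- nrow(coords)
  if (k > n) stopf("k = %d exceeds the number of points (%d)", k, n)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      ctr <- kmeanspp_centers(coords, k)
      km <- suppressWarnings(kmeans(coords, centers = ctr, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  labels <- best$cluster
  if (!is.null(order_by)) {
    mu <- tapply(order_by, labels, mean)
    remap <- match(seq_len(k), order(mu))
    labels <- remap[labels]
  }
  comp_cluster <- NULL
  comp_stratum <- NULL
  if (!is.null(groups)) {
    tab <- table(cluster = labels, group = groups)
    comp_cluster <- prop.table(tab, margin = 1)
    if (!is.null(classes)) {
      stratum <- interaction(classes, groups, sep = ":")
      tab2 <- table(stratum = stratum, cluster = labels)
      comp_stratum <- prop.table(tab2, margin = 1)
    }
  }
  list(labels = labels, centers = best$centers, inertia = best$tot.withinss,
       composition_by_cluster = comp_cluster,
       composition_by_stratum = comp_stratum)
}

#' ROC-AUC diagnostic via the rank (Mann-Whitney) formulation
#'
#' ROC-AUC for discriminating the positive group by an index, computed as
#' `U / (n1 * n2)` with ties counted one-half. By default vessels are first
#' averaged within animal so the test unit matches the study design
#' (per-animal n); per-vessel mode is available behind the `unit` flag. The
#' Mann-Whitney p-value is exact (full enumeration) when both groups have at
#' most `exact_max` observations, otherwise a tie-corrected normal
#' approximation.
#'
#' @param values numeric index values.
#' @param labels group labels.
#' @param positive the positive-class label; all other labels are negatives.
#' @param unit `"per_animal"` (average within `animal_ids` first) or
#'   `"per_vessel"`.
#' @param animal_ids required for per-animal mode.
#' @param exact_max maximum group size for exact permutation p-values.
#' @return a `diagnostic_result`: `roc_auc`, `mann_whitney_U`, `p_value`,
#'   `positive_label`, `unit`, `n_pos`, `n_neg`.
#' @export
roc_diagnostic <- function(values, labels, positive,
                           unit = c("per_animal", "per_vessel"),
                           animal_ids = NULL, exact_max = 10) {
  unit <- match.arg(unit)
  if (unit == "per_animal") {
    if (is.null(animal_ids)) stopf("per-animal ROC requires animal_ids")
    agg <- tapply(values, animal_ids, mean)
    lab1 <- tapply(labels, animal_ids, function(l) l[1])
    values <- as.numeric(agg)
    labels <- as.character(lab1)
  }
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stopf("both classes must be present")
  r <- rank(values)
  U <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)

  p <- if (max(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 1e5) {
    stat_obs <- abs(U - n1 * n2 / 2)
    combs <- utils::combn(n1 + n2, n1)
    stats_all <- apply(combs, 2, function(ix) {
      abs(sum(r[ix]) - n1 * (n1 + 1) / 2 - n1 * n2 / 2)
    })
    mean(stats_all >= stat_obs - 1e-12)
  } else {
    ties <- table(values)
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sig2)
    2 * pnorm(-abs(z))
  }
  structure(list(roc_auc = auc, mann_whitney_U = U, p_value = p,
                 positive_label = positive, unit = unit,
                 n_pos = n1, n_neg = n2),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("<diagnostic_result> ROC-AUC = %.3f (U = %g, p = %.4g, %s; %d vs %d, positive = %s)\n",
              x$roc_auc, x$mann_whitney_U, x$p_value, x$unit, x$n_pos, x$n_neg,
              x$positive_label))
  invisible(x)
}
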