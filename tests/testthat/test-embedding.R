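# UMAP embedding, UMAP-distance index, tuning, clustering, ROC diagnostics.

make_families <- function(n_per = 20, nt = 60, seed = 5) {
  withr::with_seed(seed, {
    t_ <- seq(0, 60, length.out = nt)
    rows <- lapply(1:3, function(fam) {
      slope <- c(0, 0.005, 0.02)[fam]
      t(replicate(n_per, 1 + slope * t_ + rnorm(nt, 0, 0.01)))
    })
    list(m = do.call(rbind, rows), labels = rep(1:3, each = n_per), t_min = t_)
  })
}

test_that("feature matrix: shape, constant rows, baseline normalization", {
  F <- matrix(5, 10, 240)
  m <- build_feature_matrix(F)
  expect_equal(dim(m), c(10, 240))
  expect_true(all(m == 1))
  md <- build_feature_matrix(F, decimate_to = 40)
  expect_equal(ncol(md), 40)
  co <- simulate_cohort_traces(n_animals = c(Control = 2, SE = 1, NI = 0),
                               vessels_per_class = c(arteriole = 3, capillary = 3, venule = 3),
                               seed = 2)
  mc <- build_feature_matrix(co$traces)
  ctrl <- co$meta$condition == "Control"
  expect_equal(mean(rowMeans(mc[ctrl, 2:6])), 1, tolerance = 1e-6)  # baseline window
})

test_that("UMAP embedding: determinism, locality, family separation", {
  fam <- make_families()
  e1 <- embed_umap(fam$m, seed = 42)
  e2 <- embed_umap(fam$m, seed = 42)
  expect_identical(e1$coords, e2$coords)
  expect_equal(e1$input_matrix_hash, digest::digest(fam$m))

  # duplicated rows land closer than the median pairwise distance
  mdup <- rbind(fam$m, fam$m[1, , drop = FALSE])
  ed <- embed_umap(mdup, seed = 42)
  dm <- as.matrix(dist(ed$coords))
  n <- nrow(mdup)
  expect_lt(dm[1, n], stats::median(dm[upper.tri(dm)]))

  # three well-separated trace families: silhouette > 0.5 in the embedding
  expect_gt(silhouette_mean(e1$coords, fam$labels), 0.5)

  expect_error(embed_umap(fam$m[1:4, ], n_neighbors = 5), "at least")
})

test_that("UMAP distance: hand-placed cases, brute-force oracle, invariances", {
  coords <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  ctrl <- c(FALSE, TRUE, TRUE)
  expect_equal(umap_distance(coords, ctrl)[1], 1.0)

  same <- matrix(0, 5, 2)
  expect_equal(umap_distance(same, rep(TRUE, 5)), rep(0, 5))

  withr::with_seed(8, {
    pts <- matrix(rnorm(40), 20, 2)
    ctrl20 <- rep(c(TRUE, FALSE), 10)
    D <- umap_distance(pts, ctrl20)
    # brute-force double loop
    Do <- vapply(1:20, function(i) {
      ref <- which(ctrl20 & seq_len(20) != i)
      mean(vapply(ref, function(j) sqrt(sum((pts[i, ] - pts[j, ])^2)), numeric(1)))
    }, numeric(1))
    expect_equal(D, Do, tolerance = 1e-12)

    # rigid-motion invariance
    th <- 0.7
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- sweep(pts %*% R, 2, c(3, -2), `+`)
    expect_equal(umap_distance(moved, ctrl20), D, tolerance = 1e-10)

    # class stratification restricts the reference set
    cls <- rep(c("a", "v"), each = 10)
    Ds <- umap_distance(pts, ctrl20, classes = cls)
    i <- 2  # non-control vessel of class "a"
    refs <- which(ctrl20 & cls == "a" & seq_len(20) != i)
    expect_equal(Ds[i], mean(sqrt(colSums((t(pts[refs, ]) - pts[i, ])^2))))
  })
  expect_error(umap_distance(coords, c(FALSE, FALSE, FALSE)), "empty")
})

test_that("tuning: single-cell grids, Spearman oracle, degenerate guard", {
  fam <- make_families()
  idx <- data.frame(auc = apply(fam$m, 1, index_auc, t_min = fam$t_min),
                    dff0 = apply(fam$m, 1, index_dff0, t_min = fam$t_min),
                    dfdt = apply(fam$m, 1, index_dfdt, t_min = fam$t_min))
  ctrl <- fam$labels == 1
  one <- data.frame(n_neighbors = 5, min_dist = 0.4)
  tu <- tune_umap(fam$m, idx, ctrl, grid = one)
  expect_equal(tu$best$n_neighbors, 5)
  expect_equal(tu$best$min_dist, 0.4)

  withr::with_seed(12, {
    for (r in 1:15) {
      x <- rnorm(30); y <- rnorm(30)
      expect_equal(cor(x, y, method = "spearman"), spearman_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
  bad <- idx; bad$auc <- 1
  expect_error(tune_umap(fam$m, bad, ctrl, grid = one), "degenerate")
})

test_that("k-means: perfect blobs, k = 1, composition normalization", {
  withr::with_seed(9, {
    blobs <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
                   matrix(rnorm(60, 10, 0.1), 30, 2),
                   matrix(rnorm(60, -10, 0.1), 30, 2))
  })
  truth <- rep(1:3, each = 30)
  km <- kmeans_clusters(blobs, k = 3, seed = 1, n_init = 20)
  expect_equal(ari(km$labels, truth), 1.0)

  km1 <- kmeans_clusters(blobs, k = 1, seed = 1, n_init = 5)
  expect_true(all(km1$labels == 1))
  expect_error(kmeans_clusters(blobs[1:2, ], k = 3), "exceeds")

  grp <- rep(c("Control", "SE", "NI"), 30)
  cls <- rep(c("arteriole", "venule"), length.out = 90)
  km3 <- kmeans_clusters(blobs, k = 3, seed = 1, n_init = 20,
                         groups = grp, classes = cls, order_by = blobs[, 1])
  expect_equal(unname(rowSums(km3$composition_by_cluster)), rep(1, 3))
  expect_equal(unname(rowSums(km3$composition_by_stratum)), rep(1, 6))
  # order_by relabeling: cluster means ascend
  mu <- tapply(blobs[, 1], km3$labels, mean)
  expect_true(all(diff(mu) > 0))
})

test_that("ROC: rank formula equals pair counting; known exact cases", {
  # perfectly separated
  r <- roc_diagnostic(c(1, 2, 3, 11, 12), rep(c("n", "p"), c(3, 2)),
                      positive = "p", unit = "per_vessel")
  expect_equal(r$roc_auc, 1.0)

  # 4 positives vs 7 negatives with exactly one discordant pair -> 27/28
  neg <- c(1, 2, 3, 4, 5, 6, 8)
  pos <- c(7, 9, 10, 11)
  r2 <- roc_diagnostic(c(neg, pos), rep(c("n", "p"), c(7, 4)),
                       positive = "p", unit = "per_vessel")
  expect_equal(r2$roc_auc, 27 / 28)

  withr::with_seed(13, {
    for (rep_ in 1:10) {
      v <- sample(1:8, 12, replace = TRUE)  # ties included
      lab <- rep(c("p", "n"), c(5, 7))
      got <- roc_diagnostic(v, lab, positive = "p", unit = "per_vessel")
      expect_equal(got$roc_auc, roc_pairs_oracle(v, lab == "p"), tolerance = 1e-12)
      # complement property (exact in the absence of ties)
      vu <- sample(seq(0, 1, length.out = 50), 12)
      g1 <- roc_diagnostic(vu, lab, positive = "p", unit = "per_vessel")$roc_auc
      g2 <- roc_diagnostic(-vu, lab, positive = "p", unit = "per_vessel")$roc_auc
      expect_equal(g1 + g2, 1)
    }
  })

  # per-animal averaging happens before ranking
  vals <- c(3, 5, 10, 14, 2, 2)
  ani <- c("a1", "a1", "a2", "a2", "a3", "a3")
  lab <- c("p", "p", "p", "p", "n", "n")
  ra <- roc_diagnostic(vals, lab, positive = "p", animal_ids = ani)
  expect_equal(ra$n_pos, 2L)
  expect_equal(ra$roc_auc, 1.0)
  expect_error(roc_diagnostic(1:3, c("p", "p", "p"), positive = "p",
                              unit = "per_vessel"), "both classes")
})

test_that("exact Mann-Whitney p matches the classical 4-vs-7 separated case", {
  x <- c(1:7, 20, 21, 22, 23)
  lab <- rep(c("n", "p"), c(7, 4))
  r <- roc_diagnostic(x, lab, positive = "p", unit = "per_vessel")
  # perfectly separated two-sided exact p = 2 / choose(11, 4)
  expect_equal(r$p_value, 2 / choose(11, 4), tolerance = 1e-12)
})
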