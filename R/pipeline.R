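# End-to-end orchestration: simulate -> preprocess -> segment/classify ->
# traces/indices -> permeability -> cohort embedding/diagnostics, with config
# echo, manifest, and append-only run directories.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a small phantom volume (20 x 64 x 64 voxels,
#' 40 x 44 x 44 um) at a 60-s frame interval keeps the full volumetric run in
#' memory and under a minute, while the cohort stage uses trace-level
#' simulation at the full 15-s cadence. Rolling-ball and registration are
#' off by default (phantom frames are already aligned; both remain available
#' as explicit steps).
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    condition = "SE",
    stages = c("simulate", "preprocess", "segment", "indices",
               "permeability", "cohort"),
    phantom = list(volume_shape = c(20, 64, 64), n_penetrating = c(arteriole = 1, venule = 1),
                   branch_orders = 0, capillary_density = 6, frame_interval_s = 60),
    kinetics = list(),
    preprocess = list(smooth_fwhm_um = 1, rolling_ball_radius_um = NULL,
                      flatfield = TRUE, register = FALSE),
    segment = list(method = "otsu"),
    traces = list(baseline_frames = 5, min_roi_voxels = 20),
    patlak = list(fit_start = 5),
    umap = list(n_neighbors = 5, min_dist = 0.4, seed = 42),
    kmeans = list(k = 3, n_init = 100),
    cohort = list(n_animals = c(Control = 4, SE = 4, NI = 3),
                  vessels_per_class = c(arteriole = 8, capillary = 20, venule = 12))
  )
}

# merge user config over defaults (shallow per section)
merge_config <- function(config) {
  base <- default_config(config$seed %||% 1L)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) base[[nm]][[k]] <- config[[nm]][[k]]
    } else base[[nm]] <- config[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML or JSON
#' @param path configuration file.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg)
}

# seed labels for classify_vessels(): nearest vertical thick graph segment to
# each ground-truth penetrating root (stands in for the manual artery/vein
# identification of live imaging)
seed_from_truth <- function(graph, truth) {
  roots <- truth$segment_table[truth$segment_table$order %in% 0L, , drop = FALSE]
  if (nrow(roots) == 0 || length(graph$edges) == 0) return(NULL)
  vs <- graph$voxel_size_um
  labs <- character(0)
  for (i in seq_len(nrow(roots))) {
    mid <- colMeans(truth$centerlines[[match(roots$id[i], truth$segment_table$id)]])
    d2 <- vapply(graph$edges, function(e) {
      p <- sweep(sweep(e$path, 2, 0.5), 2, vs, `*`)
      min(colSums((t(p) - mid)^2))
    }, numeric(1))
    best <- which.min(d2)
    labs[as.character(graph$edges[[best]]$id)] <- roots$class[i]
  }
  # conflicting assignments (two roots mapping to one edge) keep the first
  labs[!duplicated(names(labs))]
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated phantom,
#' writing CSV/JSON artifacts plus a machine-readable manifest (package
#' version, seeds, per-file MD5 hashes) into `out_dir`. Stages never mutate
#' upstream artifacts; a non-empty `out_dir` is refused.
#'
#' @param config configuration list (see [default_config()]) or a path to a
#'   YAML/JSON file.
#' @param out_dir output directory (created; must be empty or absent).
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(config)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0)
    stopf("out_dir '%s' is not empty (runs are append-only)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stages <- cfg$stages
  res <- list(config = cfg)
  msg <- function(...) message("[vesselleak] ", sprintf(...))

  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stopf("stage '%s' requires upstream stage '%s' which did not run", stage, dep)
  }

  if ("simulate" %in% stages) {
    msg("simulate: phantom + extravasation (%s)", cfg$condition)
    spec <- do.call(phantom_spec, c(cfg$phantom, list(seed = cfg$seed)))
    kin <- do.call(kinetics_spec, cfg$kinetics)
    ph <- make_vascular_phantom(spec, condition = cfg$condition, kinetics = kin)
    tl <- simulate_extravasation(ph, kin, seed = derive_seed(cfg$seed, "render"))
    # structural channel: lumen intensity + mild noise
    sdata <- array(0, spec$volume_shape)
    sdata[ph$lumen] <- kin$A_iv
    sdata <- sdata + with_seed(derive_seed(cfg$seed, "structure"),
                               array(rnorm(length(sdata), 0, kin$noise_sigma),
                                     dim(sdata)))
    struct <- image_stack(sdata, voxel_size_um = spec$voxel_size_um,
                          channel_role = "structure")
    write_truth(ph$truth, file.path(out_dir, "truth"))
    res$simulate <- list(phantom = ph, timelapse = tl, structure = struct, kinetics = kin)
  }

  if ("preprocess" %in% stages) {
    need("preprocess", "simulate")
    msg("preprocess: smoothing / flat-field (leakage frames pass untouched)")
    pp <- cfg$preprocess
    st <- gaussian_smooth(res$simulate$structure, pp$smooth_fwhm_um)
    if (!is.null(pp$rolling_ball_radius_um))
      st <- rolling_ball_subtract(st, pp$rolling_ball_radius_um)
    if (isTRUE(pp$flatfield)) {
      ff <- build_flatfield(st)
      st <- flatfield_normalize(st, ff)
    }
    tl <- res$simulate$timelapse
    if (isTRUE(pp$register)) {
      for (t in seq_len(n_frames(tl))) {
        fr <- image_stack(get_frame(tl, t), voxel_size_um = tl$voxel_size_um,
                          channel_role = "structure")
        reg <- register_affine(fr, st)
        tl <- set_frame(tl, t, reg$resampled$data)
      }
    }
    res$preprocess <- list(structure = st, timelapse = tl)
  }

  if ("segment" %in% stages) {
    need("segment", "preprocess")
    msg("segment: lumen -> skeleton graph -> classes -> shells")
    sg <- cfg$segment
    lumen <- segment_vessels(res$preprocess$structure, method = sg$method,
                             params = sg$params %||% list())
    graph <- skeletonize_and_graph(lumen, res$preprocess$structure$voxel_size_um)
    graph <- diameter_map(lumen, graph)
    seeds <- seed_from_truth(graph, res$simulate$phantom$truth)
    segments <- classify_vessels(graph, seeds)
    lumen_label <- label_lumen_from_graph(lumen, graph)
    shells <- perivascular_shells(lumen_label, graph$voxel_size_um)
    write.csv(segments, file.path(out_dir, "segments.csv"), row.names = FALSE)
    res$segment <- list(lumen = lumen, graph = graph, segments = segments,
                        lumen_label = lumen_label, shells = shells)
  }

  if ("indices" %in% stages) {
    need("indices", "segment")
    msg("indices: per-vessel traces and AUC / dF/F0 / dF/dt")
    tr <- extract_traces(res$preprocess$timelapse, res$segment$shells,
                         res$segment$lumen_label,
                         min_roi_voxels = cfg$traces$min_roi_voxels)
    idx <- compute_indices(tr, baseline_frames = cfg$traces$baseline_frames)
    idx$class <- res$segment$segments$class[match(idx$segment_id, res$segment$segments$id)]
    idx$condition <- cfg$condition
    tr_long <- data.frame(segment_id = rep(tr$meta$segment_id, each = length(tr$t_min)),
                          t_min = rep(tr$t_min, nrow(tr$F)),
                          F = as.numeric(t(tr$F)), F_iv = as.numeric(t(tr$F_iv)))
    write.csv(tr_long, file.path(out_dir, "traces.csv"), row.names = FALSE)
    write.csv(idx, file.path(out_dir, "indices.csv"), row.names = FALSE)
    res$indices <- list(traces = tr, indices = idx)
  }

  if ("permeability" %in% stages) {
    need("permeability", "indices")
    msg("permeability: Patlak Ktrans + Renkin-Crone PS")
    tr <- res$indices$traces
    segs <- res$segment$segments
    shells_tab <- res$segment$shells$table
    rows <- lapply(seq_len(nrow(tr$meta)), function(i) {
      sid <- tr$meta$segment_id[i]
      pk <- tryCatch(patlak_ktrans(tr$F[i, ], tr$F_iv[i, ], tr$t_min,
                                   fit_start = cfg$patlak$fit_start),
                     error = function(e) NULL)
      if (is.null(pk)) return(NULL)
      cls <- segs$class[match(sid, segs$id)]
      vel <- c(arteriole = 5.0, capillary = 1.0, venule = 1.8,
               unlabeled = 2.0)[cls]  # class-reference RBC velocities (mm/s)
      dia <- segs$mean_diameter_um[match(sid, segs$id)]
      vol <- shells_tab$volume_um3[match(sid, shells_tab$segment_id)]
      fp <- plasma_flow(dia, vel, roi_volume_um3 = vol)
      ps <- if (pk$Ktrans >= 0 && pk$Ktrans < fp$F_p_min)
        renkin_crone_ps(pk$Ktrans, fp$F_p_min) else NA_real_
      data.frame(segment_id = sid, class = cls, Ktrans_min = pk$Ktrans,
                 v_b = pk$v_b, r2 = pk$r2, negative_slope = pk$negative_slope,
                 Fp_min = fp$F_p_min, PS_min = ps)
    })
    perm <- do.call(rbind, rows)
    write.csv(perm, file.path(out_dir, "permeability.csv"), row.names = FALSE)
    res$permeability <- perm
  }

  if ("cohort" %in% stages) {
    msg("cohort: trace-level virtual animals -> UMAP distance, clusters, ROC")
    co <- simulate_cohort_traces(n_animals = cfg$cohort$n_animals,
                                 vessels_per_class = cfg$cohort$vessels_per_class,
                                 seed = derive_seed(cfg$seed, "cohort"))
    res$cohort <- analyze_cohort(co, umap_params = cfg$umap, k = cfg$kmeans$k,
                                 n_init = cfg$kmeans$n_init)
    write.csv(res$cohort$embedding, file.path(out_dir, "embedding.csv"), row.names = FALSE)
    jsonlite::write_json(res$cohort$diagnostics, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(package = "vesselleak",
                   version = as.character(utils::packageVersion("vesselleak")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed,
                   stages = stages,
                   hashes = as.list(tools::md5sum(files)))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Analyze a cohort of traces: indices, embedding, distance, clusters, ROC
#'
#' The downstream half of the pipeline operating purely on per-vessel traces:
#' conventional indices, UMAP embedding of the normalized patterns,
#' class-stratified UMAP distance to control vessels, k-means composition,
#' and per-animal ROC diagnostics (arteriole indices for "SE", venule indices
#' for "NI"; the positive condition is tested against all other animals).
#'
#' @param cohort output of [simulate_cohort_traces()] (or a compatible list
#'   with `traces`, `f_iv`, `t_min`, `meta`).
#' @param umap_params list with `n_neighbors`, `min_dist`, `seed`.
#' @param k,n_init k-means parameters.
#' @param baseline_frames baseline window for normalization.
#' @return list: `embedding` (per-vessel data.frame with indices, coords,
#'   cluster, umap_dist), `diagnostics` (per disease x index ROC results),
#'   `kmeans` (composition tables).
#' @export
analyze_cohort <- function(cohort,
                           umap_params = list(n_neighbors = 5, min_dist = 0.4, seed = 42),
                           k = 3, n_init = 100, baseline_frames = 5) {
  meta <- cohort$meta
  m <- build_feature_matrix(cohort$traces, baseline_frames)
  keep <- attr(m, "keep")
  meta <- meta[keep, , drop = FALSE]
  t_min <- cohort$t_min
  idx <- data.frame(
    auc = apply(m, 1, index_auc, t_min = t_min),
    dff0 = apply(m, 1, index_dff0, t_min = t_min),
    dfdt = apply(m, 1, index_dfdt, t_min = t_min))
  emb <- embed_umap(m, n_neighbors = umap_params$n_neighbors,
                    min_dist = umap_params$min_dist, seed = umap_params$seed)
  ctrl <- meta$condition == "Control"
  D <- umap_distance(emb$coords, ctrl, classes = meta$class)
  km <- kmeans_clusters(emb$coords, k = k, seed = umap_params$seed,
                        n_init = n_init, groups = meta$condition,
                        classes = meta$class, order_by = idx$dff0)
  embedding <- cbind(meta, idx,
                     u1 = emb$coords[, 1], u2 = emb$coords[, 2],
                     umap_dist = D, cluster = km$labels)

  diag_for <- function(disease, class) {
    sel <- meta$class == class
    out <- list()
    for (index in c("umap_dist", "auc", "dff0", "dfdt")) {
      v <- if (index == "umap_dist") D[sel] else idx[[index]][sel]
      r <- roc_diagnostic(v, meta$condition[sel], positive = disease,
                          unit = "per_animal", animal_ids = meta$animal_id[sel])
      out[[index]] <- list(index = index, class = class, positive = disease,
                           roc_auc = r$roc_auc, U = r$mann_whitney_U,
                           p = r$p_value, unit = r$unit)
    }
    out
  }
  diagnostics <- list(SE = diag_for("SE", "arteriole"),
                      NI = diag_for("NI", "venule"))
  list(embedding = embedding, diagnostics = diagnostics, kmeans = km,
       umap = emb)
}
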