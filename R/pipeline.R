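# Orchestration: one configuration object drives the full analysis
# (alignment -> morphospace -> theoretical grid -> surface selection ->
# trade-off weights -> w surface -> sliding windows -> PLS transfer ->
# comparative models), with every artifact written as CSV/JSON plus a
# provenance record. All randomness flows from the config seed.

#' Assemble a pipeline configuration
#'
#' @param landmarks path to a TPS (`.tps`) or long-format CSV landmark file.
#' @param traits named list with paths `f1`, `f2` to trait CSV tables
#'   (`pc1`, `pc2`, `value`); their positions are used as the theoretical
#'   reference grid.
#' @param tree optional newick path (enables the comparative stage).
#' @param rates optional named list of rate-table CSV paths (e.g.
#'   `shape`, `w`) produced by external variable-rates software.
#' @param output_dir where result tables are written.
#' @param grid_n,grid_extension theoretical-grid shape (used only when no
#'   trait tables supply a grid).
#' @param cv_k cross-validation folds for surface selection.
#' @param candidates candidate table for [crossvalidate_surfaces()].
#' @param w_resolution grid-search resolution for the trade-off weight.
#' @param wsurface_n cells per axis of the w surface (default 40).
#' @param window_step,window_size sliding-window geometry over w.
#' @param cluster_max_k largest per-window cluster count.
#' @param floor_eps floor for non-positive combined heights (default 1e-9;
#'   logged whenever it is engaged).
#' @param allometry_test run a PGLS of shape on log centroid size when a
#'   tree is available.
#' @param n_perm permutations for PGLS/Mantel tests.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks, traits, tree = NULL, rates = NULL,
                            output_dir = "tradescape_out",
                            grid_n = 8, grid_extension = 0.10, cv_k = 10,
                            candidates = default_candidates(),
                            w_resolution = 0.001, wsurface_n = 40,
                            window_step = 0.0002, window_size = 0.011,
                            cluster_max_k = 5, floor_eps = 1e-9,
                            allometry_test = TRUE, n_perm = 499, seed = 1) {
  structure(list(landmarks = landmarks, traits = traits, tree = tree,
                 rates = rates, output_dir = output_dir, grid_n = grid_n,
                 grid_extension = grid_extension, cv_k = cv_k,
                 candidates = candidates, w_resolution = w_resolution,
                 wsurface_n = wsurface_n, window_step = window_step,
                 window_size = window_size, cluster_max_k = cluster_max_k,
                 floor_eps = floor_eps, allometry_test = allometry_test,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("config must be .yaml/.yml or .json: %s", path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  if (!is.null(raw$candidates)) raw$candidates <- as.data.frame(raw$candidates)
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full morpho-functional trade-off analysis
#'
#' Executes every stage the configuration enables and writes all result
#' tables (CSV), fitted surfaces (JSON) and a provenance record into
#' `output_dir`. Re-running the same configuration reproduces every output
#' byte-for-byte: all randomness is derived from the config seed.
#'
#' @param config a [pipeline_config()] or a path readable by
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage:
#'   `alignment`, `morphospace`, `grid`, `cv` (per trait), `surfaces`,
#'   `species_w`, `w_surface`, `windows`, `association`, `pls`,
#'   `comparative`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)
  res <- list(config = config)

  sample <- run_stage("read_landmarks", {
    if (grepl("\\.tps$", config$landmarks, ignore.case = TRUE))
      read_landmarks_tps(config$landmarks)
    else read_landmarks_csv(config$landmarks)
  })

  res$alignment <- run_stage("gpa", gpa(sample))
  run_stage("write_aligned", {
    aligned <- sample
    aligned$coords <- res$alignment$aligned
    write_landmarks_csv(aligned, out_path("aligned.csv"))
  })

  res$morphospace <- run_stage("pca", pca_morphospace(res$alignment))
  run_stage("write_scores", {
    sc <- data.frame(species = rownames(res$morphospace$scores),
                     res$morphospace$scores, check.names = FALSE)
    utils::write.csv(sc, out_path("scores.csv"), row.names = FALSE)
  })

  grid_stage <- run_stage("theoretical_grid", {
    t1 <- read_trait_csv(config$traits$f1)
    t2 <- read_trait_csv(config$traits$f2)
    if (nrow(t1) != nrow(t2) ||
        max(abs(t1$pc1 - t2$pc1), abs(t1$pc2 - t2$pc2)) > 1e-8)
      stopf("trait tables f1 and f2 are on different grids")
    g <- t1[c("pc1", "pc2")]
    utils::write.csv(g, out_path("grid.csv"), row.names = FALSE)
    list(grid = g, values = list(f1 = t1$value, f2 = t2$value))
  })
  res$grid <- grid_stage$grid
  res$trait_values <- grid_stage$values

  res$cv <- run_stage("surface_selection", {
    cv <- lapply(c(f1 = "f1", f2 = "f2"), function(tr)
      crossvalidate_surfaces(res$grid, res$trait_values[[tr]],
                             candidates = config$candidates,
                             k = config$cv_k, seed = config$seed))
    for (tr in names(cv))
      utils::write.csv(cv[[tr]]$table, out_path(sprintf("cv_%s.csv", tr)),
                       row.names = FALSE)
    cv
  })

  res$surfaces <- run_stage("surface_fit", {
    s <- lapply(c(f1 = "f1", f2 = "f2"), function(tr) {
      best <- res$cv[[tr]]$best
      fit_surface(res$grid, res$trait_values[[tr]],
                  family = best$family, order = best$order)
    })
    for (tr in names(s))
      write_surface_json(s[[tr]], out_path(sprintf("surface_%s.json", tr)))
    s
  })

  res$species_w <- run_stage("tradeoff", {
    pos <- res$morphospace$scores[, 1:2, drop = FALSE]
    colnames(pos) <- c("pc1", "pc2")
    sw <- species_w(pos, res$surfaces$f1, res$surfaces$f2, res$grid,
                    resolution = config$w_resolution,
                    floor_eps = config$floor_eps)
    utils::write.csv(sw, out_path("species_w.csv"), row.names = FALSE)
    sw
  })

  res$w_surface <- run_stage("w_surface", {
    ws <- w_surface(res$surfaces$f1, res$surfaces$f2, res$grid,
                    n = config$wsurface_n, resolution = config$w_resolution,
                    floor_eps = config$floor_eps)
    utils::write.csv(as.data.frame(ws), out_path("w_surface.csv"),
                     row.names = FALSE)
    ws
  })

  res$windows <- run_stage("windows", {
    rng <- range(res$w_surface$w)
    if (diff(rng) < config$window_size) rng[2] <- rng[1] + config$window_size
    wins <- make_windows(rng[1], rng[2], step = config$window_step,
                         size = config$window_size)
    shapes <- t(apply(res$alignment$aligned, 3, flatten_config))
    wd <- windowed_disparity(res$species_w$w,
                             res$species_w[c("pc1", "pc2")], shapes,
                             wins, res$w_surface$w,
                             seed = config$seed, max_k = config$cluster_max_k)
    utils::write.csv(wd, out_path("windows.csv"), row.names = FALSE)
    wd
  })

  res$association <- run_stage("association", {
    ok <- is.finite(res$windows$disparity)
    if (sum(ok) >= 3) {
      a <- association(res$windows$volume, res$windows$disparity,
                       seed = config$seed)
      jsonlite::write_json(list(n_windows = attr(a, "n"),
                                estimates = as.list(stats::setNames(a$estimate, rownames(a))),
                                p_values = as.list(stats::setNames(a$p_value, rownames(a)))),
                           out_path("association.json"),
                           auto_unbox = TRUE, digits = NA)
      a
    } else NULL
  })

  clade <- sample$clade
  if (!is.null(clade) && length(unique(clade)) == 2) {
    res$pls <- run_stage("pls", {
      shapes <- t(apply(res$alignment$aligned, 3, flatten_config))
      func <- as.matrix(res$species_w[c("f1", "f2")])
      lv <- sort(unique(clade))
      a_idx <- clade == lv[1]
      model <- fit_pls2b(shapes[a_idx, , drop = FALSE],
                         func[a_idx, , drop = FALSE])
      tr <- transfer_assessment(model,
                                shapes[a_idx, , drop = FALSE], func[a_idx, , drop = FALSE],
                                shapes[!a_idx, , drop = FALSE], func[!a_idx, , drop = FALSE],
                                groups = lv)
      per <- tr$per_specimen
      per$species <- c(sample$species[a_idx], sample$species[!a_idx])
      utils::write.csv(per[c("species", "group", "s_shape", "s_func",
                             "residual_distance")],
                       out_path("pls_transfer.csv"), row.names = FALSE)
      list(model = model, transfer = tr)
    })
  }

  if (!is.null(config$tree)) {
    res$comparative <- run_stage("comparative", {
      tree <- read_tree_file(config$tree)
      miss <- setdiff(tree$tip.label, res$species_w$species)
      if (length(miss)) stopf("tree tips absent from the landmark sample: %s",
                              paste(utils::head(miss, 5), collapse = ", "))
      w_vec <- stats::setNames(res$species_w$w, res$species_w$species)
      cmp <- list(w_models = fit_trait_models(w_vec, tree))
      utils::write.csv(cmp$w_models, out_path("w_trait_models.csv"),
                       row.names = FALSE)
      if (config$allometry_test) {
        logcs <- log(stats::setNames(res$alignment$centroid_sizes,
                                     res$alignment$species))
        shapes <- t(apply(res$alignment$aligned, 3, flatten_config))
        rownames(shapes) <- res$alignment$species
        cmp$allometry <- pgls(shapes,
                              matrix(logcs[tree$tip.label], ncol = 1,
                                     dimnames = list(tree$tip.label, "log_cs")),
                              tree, n_perm = config$n_perm, seed = config$seed)
      }
      if (!is.null(config$rates)) {
        rt <- lapply(config$rates, read_rates_csv)
        if (all(c("shape", "w") %in% names(rt))) {
          cmp$rate_assoc <- rate_association(rt$shape, rt$w, tree)
          tips <- intersect(intersect(rt$shape$id, rt$w$id), tree$tip.label)
          if (length(tips) >= 4) {
            shape_tip_rates <- stats::setNames(rt$shape$rate, rt$shape$id)[tips]
            sub <- if (length(tips) < length(tree$tip.label))
              ape::keep.tip(tree, tips) else tree
            cmp$rates_on_w <- pgls_polynomial(shape_tip_rates, w_vec[tips],
                                              sub, degrees = 0:2,
                                              n_perm = config$n_perm,
                                              seed = config$seed)
            dr <- abs(outer(shape_tip_rates, shape_tip_rates, "-"))
            cmp$rate_mantel <- mantel(dr, ape::cophenetic.phylo(sub),
                                      n_perm = config$n_perm,
                                      seed = config$seed)
          }
        }
      }
      cmp
    })
  }

  run_stage("provenance", {
    cfg_json <- out_path("pipeline_config.json")
    cfg <- config
    cfg$candidates <- as.list(cfg$candidates)
    jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                         digits = NA, null = "null")
    prov <- list(package = "tradescape",
                 version = as.character(utils::packageVersion("tradescape")),
                 seed = config$seed,
                 config_md5 = unname(tools::md5sum(cfg_json)),
                 inputs = list(landmarks = config$landmarks,
                               traits = config$traits, tree = config$tree))
    jsonlite::write_json(prov, out_path("provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  invisible(res)
}
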