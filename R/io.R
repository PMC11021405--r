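# Readers and writers: TPS landmark files (LM3 blocks), long-format landmark
# CSV, newick trees, functional-trait CSV tables, serialized surface models
# (JSON) and pipeline configs (YAML/JSON). All strict: malformed records
# raise errors naming the offending record or column.

#' Read 3D landmarks from a TPS-dialect file
#'
#' Expects blocks of the form `LM3=<p>` followed by `p` whitespace-separated
#' coordinate triplets and an `ID=<label>` line; unknown `KEY=value` lines
#' within a block are tolerated, anything else is an error.
#'
#' @param path file path.
#' @return A [landmark_sample()].
#' @export
read_landmarks_tps <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  configs <- list(); ids <- character(0)
  i <- 1
  while (i <= length(lines)) {
    hdr <- lines[i]
    if (!grepl("^LM3=", hdr))
      stopf("line %d: expected an 'LM3=' block header, got '%s'", i, hdr)
    p <- suppressWarnings(as.integer(sub("^LM3=", "", hdr)))
    if (is.na(p) || p < 1) stopf("line %d: invalid landmark count", i)
    if (i + p > length(lines)) stopf("block starting at line %d is truncated", i)
    coord_lines <- lines[(i + 1):(i + p)]
    m <- t(vapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "[ \t]+")[[1]]))
      if (length(v) != 3 || anyNA(v))
        stopf("line %d: expected 3 numeric coordinates, got '%s'",
              i + j, coord_lines[j])
      v
    }, numeric(3)))
    i <- i + p + 1
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM3=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      else if (!grepl("^[A-Z0-9_]+=", lines[i]))
        stopf("line %d: unexpected content '%s'", i, lines[i])
      i <- i + 1
    }
    if (is.na(id)) stopf("block ending near line %d has no ID= line", i - 1)
    configs[[length(configs) + 1]] <- m
    ids <- c(ids, id)
  }
  if (!length(configs)) stopf("no landmark blocks found in %s", path)
  landmark_sample(configs, species = ids)
}

#' Write a landmark sample as a TPS-dialect file
#'
#' @param sample a [landmark_sample()].
#' @param path output path.
#' @export
write_landmarks_tps <- function(sample, path) {
  stopifnot(inherits(sample, "landmark_sample"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(sample$n_specimens)) {
    writeLines(sprintf("LM3=%d", sample$n_landmarks), con)
    m <- sample$coords[, , i]
    writeLines(apply(m, 1, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    writeLines(sprintf("ID=%s", sample$species[i]), con)
  }
  invisible(path)
}

#' Read landmarks from a long-format CSV
#'
#' Columns: `specimen`, `landmark`, `x`, `y`, `z`, optionally `clade`.
#'
#' @param path file path.
#' @return A [landmark_sample()].
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("landmark CSV is missing column(s): %s",
                          paste(miss, collapse = ", "))
  sp <- unique(d$specimen)
  p <- sort(unique(d$landmark))
  if (!isTRUE(all.equal(as.numeric(p), as.numeric(seq_along(p)))))
    stopf("landmark indices must be 1..p")
  configs <- lapply(sp, function(s) {
    sub <- d[d$specimen == s, ]
    if (nrow(sub) != length(p))
      stopf("specimen '%s' has %d landmarks, expected %d", s, nrow(sub), length(p))
    sub <- sub[order(sub$landmark), ]
    as.matrix(sub[, c("x", "y", "z")])
  })
  clade <- NULL
  if ("clade" %in% names(d)) {
    cl <- unique(d[, c("specimen", "clade")])
    if (nrow(cl) != length(sp)) stopf("inconsistent clade labels within a specimen")
    clade <- cl$clade[match(sp, cl$specimen)]
  }
  landmark_sample(configs, species = sp, clade = clade)
}

#' @rdname read_landmarks_csv
#' @param sample a [landmark_sample()].
#' @export
write_landmarks_csv <- function(sample, path) {
  stopifnot(inherits(sample, "landmark_sample"))
  rows <- lapply(seq_len(sample$n_specimens), function(i) {
    m <- sample$coords[, , i]
    out <- data.frame(specimen = sample$species[i],
                      landmark = seq_len(sample$n_landmarks),
                      x = m[, 1], y = m[, 2], z = m[, 3])
    if (!is.null(sample$clade)) out$clade <- sample$clade[i]
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a newick tree
#'
#' @param path newick file.
#' @return An `ape::phylo` tree (validated: branch lengths present and
#'   finite, tip labels unique).
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stopf("cannot parse newick file %s: %s", path, conditionMessage(e)))
  if (is.null(tr)) stopf("cannot parse newick file %s", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1)
      stopf("%s contains %d trees; a single tree is expected", path, length(tr))
    tr <- tr[[1]]
  }
  check_tree(tr)
}

#' Read a functional-trait table (pc1, pc2, value)
#'
#' @param path CSV with columns `pc1`, `pc2`, `value`.
#' @return Data frame with those columns.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("pc1", "pc2", "value"), names(d))
  if (length(miss)) stopf("trait CSV is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!all(vapply(d[c("pc1", "pc2", "value")], is.numeric, TRUE)))
    stopf("trait CSV columns pc1, pc2, value must be numeric")
  d[c("pc1", "pc2", "value")]
}

#' Read a rate table (id, rate)
#'
#' @param path CSV with columns `id` (branch id or tip label) and `rate`.
#' @return Data frame `id`, `rate` (rates positive).
#' @export
read_rates_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "rate"), names(d))
  if (length(miss)) stopf("rate CSV is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!is.numeric(d$rate) || any(!is.finite(d$rate)) || any(d$rate <= 0))
    stopf("rates must be positive finite numbers")
  d[c("id", "rate")]
}

#' Serialize a fitted surface model to JSON
#'
#' Polynomial, TPS and kriging parameter blocks are stored as plain JSON so
#' a fitted surface can be re-used across sessions and from the command
#' line. `read_surface_json` reconstructs a predict-capable model.
#'
#' @param model a `surface_model`.
#' @param path output path.
#' @export
write_surface_json <- function(model, path) {
  stopifnot(inherits(model, "surface_model"))
  pl <- model$params
  ser <- switch(model$family,
    polynomial = list(coefficients = as.list(stats::setNames(pl$coefficients,
                                                             names(pl$coefficients))),
                      degree = pl$degree),
    tps = list(centers = unclass(as.data.frame(pl$centers)), c = pl$c,
               d = as.numeric(pl$d), order = pl$order, lambda = pl$lambda,
               kernel_sign = pl$kernel_sign),
    kriging = list(centers = unclass(as.data.frame(pl$centers)), z = pl$z,
                   variogram = pl$variogram[c("model", "nugget", "psill", "range_")],
                   order = pl$order))
  obj <- list(family = model$family, order = model$order,
              training_rmse = model$training_rmse, n_params = model$n_params,
              n_train = model$n_train, params = ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("family", "order", "params")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stopf("surface JSON is missing field(s): %s",
                          paste(miss, collapse = ", "))
  pl <- obj$params
  params <- switch(obj$family,
    polynomial = list(coefficients = unlist(pl$coefficients), degree = pl$degree),
    tps = list(centers = cbind(pc1 = pl$centers$pc1, pc2 = pl$centers$pc2),
               c = pl$c, d = pl$d, order = pl$order, lambda = pl$lambda,
               kernel_sign = pl$kernel_sign),
    kriging = {
      centers <- cbind(pc1 = pl$centers$pc1, pc2 = pl$centers$pc2)
      vg <- as.list(pl$variogram)
      D <- as.matrix(stats::dist(centers))
      G <- variogram_value(D, vg$model, vg$nugget, vg$psill, vg$range_)
      n <- nrow(centers)
      A <- rbind(cbind(G, 1), c(rep(1, n), 0))
      list(centers = centers, z = pl$z, variogram = vg, A_inv = solve(A),
           order = pl$order)
    },
    stopf("unknown surface family '%s'", obj$family))
  structure(list(family = obj$family, order = obj$order, params = params,
                 n_params = obj$n_params, n_train = obj$n_train,
                 training_rmse = obj$training_rmse),
            class = "surface_model")
}

#' Write a synthetic study to the pipeline's input formats
#'
#' Writes `landmarks.tps`, `landmarks.csv`, `tree.nwk`, `trait_f1.csv`,
#' `trait_f2.csv`, `species.csv` (positions, true w, clade) and
#' `config.json` into `dir`.
#'
#' @param study a [gen_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_landmarks_tps(study$sample, file.path(dir, "landmarks.tps"))
  write_landmarks_csv(study$sample, file.path(dir, "landmarks.csv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(study$traits$f1, file.path(dir, "trait_f1.csv"), row.names = FALSE)
  utils::write.csv(study$traits$f2, file.path(dir, "trait_f2.csv"), row.names = FALSE)
  sp <- data.frame(species = rownames(study$species_positions),
                   pc1 = study$species_positions[, 1],
                   pc2 = study$species_positions[, 2],
                   true_w = unname(study$true_w),
                   clade = unname(study$groups[rownames(study$species_positions)]))
  utils::write.csv(sp, file.path(dir, "species.csv"), row.names = FALSE)
  cfg <- study$config
  cfg$spec <- list(
    f1 = list(centers = as.vector(t(cfg$spec$f1$centers)), widths = cfg$spec$f1$widths,
              heights = cfg$spec$f1$heights, base = cfg$spec$f1$base),
    f2 = list(centers = as.vector(t(cfg$spec$f2$centers)), widths = cfg$spec$f2$widths,
              heights = cfg$spec$f2$heights, base = cfg$spec$f2$base))
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Rebuild a synthetic study from its written directory
#'
#' Reads `config.json` and regenerates the study with [gen_study()]; because
#' every generator is a pure function of (config, seed), the rebuilt study
#' reproduces the written one exactly.
#'
#' @param dir directory written by [write_study()].
#' @return A `synthetic_study`.
#' @export
read_study <- function(dir) {
  path <- file.path(dir, "config.json")
  if (!file.exists(path)) stopf("no config.json under %s", dir)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- surface_spec(
    f1 = list(centers = matrix(cfg$spec$f1$centers, ncol = 2, byrow = TRUE),
              widths = cfg$spec$f1$widths, heights = cfg$spec$f1$heights,
              base = cfg$spec$f1$base),
    f2 = list(centers = matrix(cfg$spec$f2$centers, ncol = 2, byrow = TRUE),
              widths = cfg$spec$f2$widths, heights = cfg$spec$f2$heights,
              base = cfg$spec$f2$base))
  gen_study(synthetic_config(
    n_tips = cfg$n_tips, n_landmarks = cfg$n_landmarks, bm_rate = cfg$bm_rate,
    spec = spec, noise_sd = cfg$noise_sd, clade_split = cfg$clade_split,
    grid_n = cfg$grid_n, grid_extension = cfg$grid_extension, seed = cfg$seed))
}
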