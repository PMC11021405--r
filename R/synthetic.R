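# Synthetic-study generator: complete pipelines' worth of data with known
# ground truth (tree, BM-evolved landmark shapes, analytic performance
# functions over the PC plane, oracle trade-off weights), plus the
# brute-force weight oracle used in parameter-recovery tests.

#' Gaussian-peak specification for a pair of performance functions
#'
#' The synthetic performance functions are sums of isotropic Gaussian peaks
#' over the PC1/PC2 plane, specified in normalized coordinates: peak centres
#' live in the unit square (mapped affinely onto the grid extent) and widths
#' are fractions of the mean axis span. The default plants a narrow
#' high-performance peak for F1 against a broad plateau for F2 -- the
#' "narrow high-w region, broad low-w region" structure in which few shapes
#' optimise F1 while many support F2.
#'
#' @param f1,f2 lists with `centers` (k x 2 matrix, unit-square units),
#'   `widths` (k), `heights` (k), `base` (scalar baseline).
#' @return List of class `surface_spec`.
#' @export
surface_spec <- function(f1, f2) {
  chk <- function(s, nm) {
    s$centers <- matrix(s$centers, ncol = 2)
    if (length(s$widths) != nrow(s$centers) ||
        length(s$heights) != nrow(s$centers))
      stopf("%s: centers, widths and heights must agree", nm)
    if (any(s$widths <= 0)) stopf("%s: widths must be positive", nm)
    s$base <- s$base %||% 0
    s
  }
  structure(list(f1 = chk(f1, "f1"), f2 = chk(f2, "f2")),
            class = "surface_spec")
}

#' @rdname surface_spec
#' @export
default_surface_spec <- function() {
  # F1 ("force"): a sharp dominant peak plus progressively broader, weaker
  # secondary peaks -- only a small corner of morphospace performs well.
  # F2 ("velocity"): several broad overlapping hills forming a plateau over
  # most of the space. The texture (multiple peaks per function) mimics the
  # wiggliness of surfaces fitted to measured data and gives the combined
  # landscape many maximum-switch points, so trade-off weights take several
  # distinct values rather than collapsing onto one or two.
  # All peak widths are at or above the 8 x 8 grid spacing (~0.14 of the
  # axis span), so the functions are resolvable on -- and interpolable
  # from -- the theoretical grid, matching the smoothness real fitted
  # performance surfaces display at that sampling density.
  surface_spec(
    f1 = list(centers = rbind(c(0.85, 0.40), c(0.78, 0.58), c(0.45, 0.80),
                              c(0.30, 0.70), c(0.60, 0.15)),
              widths = c(0.15, 0.16, 0.22, 0.28, 0.24),
              heights = c(1, 0.75, 0.55, 0.4, 0.45), base = 0.05),
    f2 = list(centers = rbind(c(0.28, 0.38), c(0.45, 0.30), c(0.20, 0.60),
                              c(0.55, 0.55)),
              widths = c(0.40, 0.30, 0.35, 0.25),
              heights = c(1, 0.7, 0.8, 0.5), base = 0.05))
}

# evaluate one Gaussian-peak component at actual-unit positions, given the
# extent (2 x 2 matrix: rows = min/max, cols = pc1/pc2) that the unit square
# maps onto
gaussian_peaks_value <- function(component, pos, extent) {
  span <- extent[2, ] - extent[1, ]
  wscale <- mean(span)
  out <- rep(component$base, nrow(pos))
  for (j in seq_len(nrow(component$centers))) {
    ctr <- extent[1, ] + component$centers[j, ] * span
    d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
    out <- out + component$heights[j] * exp(-d2 / (2 * (component$widths[j] * wscale)^2))
  }
  out
}

grid_extent <- function(grid) {
  pos <- as_positions(grid)
  apply(pos, 2, range)
}

#' Analytic performance surfaces from a specification
#'
#' @param spec a [surface_spec()].
#' @param grid positions defining the extent the unit square maps onto.
#' @param scaled if `TRUE` (default), each surface is min-max scaled by its
#'   own range over `grid`, matching how measured metrics are scaled before
#'   fitting.
#' @return List of two [analytic_surface()] objects, `f1` and `f2`.
#' @export
analytic_performance <- function(spec, grid, scaled = TRUE) {
  extent <- grid_extent(grid)
  pos <- as_positions(grid)
  make <- function(component, name) {
    raw_fun <- function(p) gaussian_peaks_value(component, as_positions(p), extent)
    if (!scaled) return(analytic_surface(raw_fun, name))
    raw <- raw_fun(pos)
    r <- range(raw)
    if (r[2] <= r[1]) stopf("surface '%s' is constant over the grid", name)
    analytic_surface(function(p) (raw_fun(p) - r[1]) / (r[2] - r[1]), name)
  }
  list(f1 = make(spec$f1, "f1"), f2 = make(spec$f2, "f2"))
}

#' Simulate a pure-birth ultrametric phylogeny of unit depth
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @return An `ape::phylo` tree, tips `t1..tn`, root-to-tip depth 1.
#' @export
gen_tree <- function(n_tips, seed = 1) {
  if (n_tips < 3) stopf("need at least 3 tips")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Evolve landmark configurations by Brownian motion along a tree
#'
#' Every coordinate of the base configuration evolves as an independent
#' Brownian motion with rate `bm_rate` (variance per unit branch length);
#' tip configurations are returned as a [landmark_sample()].
#'
#' @param tree an `ape::phylo` tree.
#' @param base_config `p x 3` matrix, the root configuration.
#' @param bm_rate BM variance rate (>= 0).
#' @param seed integer seed.
#' @return A `landmark_sample` with one configuration per tip.
#' @export
gen_shapes_bm <- function(tree, base_config, bm_rate, seed = 1) {
  check_tree(tree)
  if (bm_rate < 0) stopf("bm_rate must be non-negative")
  base <- flatten_config(as.matrix(base_config))
  p <- nrow(as.matrix(base_config))
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")
  nn <- max(tr$edge)
  vals <- matrix(NA_real_, nn, length(base))
  vals[ntip + 1, ] <- base
  with_seed(seed, {
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      step <- if (bm_rate == 0) 0 else
        stats::rnorm(length(base), 0, sqrt(bm_rate * tr$edge.length[e]))
      vals[child, ] <- vals[par, ] + step
    }
  })
  coords <- array(NA_real_, dim = c(p, 3, ntip))
  for (i in seq_len(ntip)) coords[, , i] <- unflatten_config(vals[i, ], p)
  landmark_sample(coords, species = tr$tip.label)
}

#' Deterministic base skull-like configuration
#'
#' Landmarks placed on an ellipsoid by a golden-spiral rule: deterministic,
#' well-conditioned, no coincident points.
#'
#' @param n_landmarks number of landmarks (default 35).
#' @return `p x 3` matrix.
#' @export
base_configuration <- function(n_landmarks = 35) {
  i <- seq_len(n_landmarks)
  phi <- acos(1 - 2 * (i - 0.5) / n_landmarks)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = 1.6 * sin(phi) * cos(theta),
        y = 1.0 * sin(phi) * sin(theta),
        z = 0.7 * cos(phi))
}

#' Synthetic functional traits over a grid
#'
#' Evaluates the analytic performance functions at the grid positions, adds
#' seeded Gaussian noise (with standard deviation `noise_sd` expressed on
#' the scaled, unit-interval metric scale) and min-max scales the result.
#' The noiseless scaled values are retained for oracles.
#'
#' @param grid_positions morphospace positions (e.g. [theoretical_grid()]).
#' @param spec a [surface_spec()].
#' @param noise_sd noise standard deviation on the scaled metric (>= 0).
#' @param seed integer seed.
#' @return List of class `functional_traits`: `f1`, `f2` (data frames
#'   `pc1`, `pc2`, `value`), `noiseless` (same shape, no noise), `seed`.
#' @export
gen_performance <- function(grid_positions, spec, noise_sd = 0.01, seed = 1) {
  pos <- as_positions(grid_positions)
  if (nrow(pos) < 4) stopf("need at least 4 grid positions")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  extent <- grid_extent(pos)
  out_one <- function(component, sub_seed) {
    raw <- gaussian_peaks_value(component, pos, extent)
    r <- range(raw)
    if (r[2] <= r[1]) stopf("constant synthetic surface")
    noise <- with_seed(sub_seed, stats::rnorm(nrow(pos), 0, noise_sd * (r[2] - r[1])))
    list(noisy = scale_unit_interval(raw + noise),
         clean = (raw - r[1]) / (r[2] - r[1]))
  }
  v1 <- out_one(spec$f1, seed)
  v2 <- out_one(spec$f2, seed + 1L)
  df <- function(v) data.frame(pc1 = pos[, 1], pc2 = pos[, 2], value = v)
  structure(list(f1 = df(v1$noisy), f2 = df(v2$noisy),
                 noiseless = list(f1 = df(v1$clean), f2 = df(v2$clean)),
                 seed = seed),
            class = "functional_traits")
}

#' Brute-force oracle for the trade-off weight
#'
#' Independent reference implementation of the weight estimate: the analytic
#' (noiseless) surfaces are min-max scaled over the reference grid, and the
#' log-ratio objective is scanned exhaustively over
#' `w in {0, w_step, ..., 1}`. Used as ground truth in parameter-recovery
#' tests; deliberately written as a plain loop, independent of
#' [estimate_w()].
#'
#' @param position a single morphospace position.
#' @param spec a [surface_spec()].
#' @param reference_grid grid over which the maximum (and the scaling) is
#'   taken.
#' @param w_step scan resolution (default 1e-4).
#' @param floor_eps floor applied to non-positive combined heights
#'   (default 1e-9).
#' @return Scalar `w` (midpoint of the tying set under exact ties).
#' @export
oracle_w <- function(position, spec, reference_grid, w_step = 1e-4,
                     floor_eps = 1e-9) {
  pos <- as_positions(position)
  grid <- as_positions(reference_grid)
  extent <- grid_extent(grid)
  scale_pair <- function(component) {
    raw_grid <- gaussian_peaks_value(component, grid, extent)
    r <- range(raw_grid)
    raw_z <- gaussian_peaks_value(component, pos, extent)
    list(grid = (raw_grid - r[1]) / (r[2] - r[1]),
         z = (raw_z - r[1]) / (r[2] - r[1]))
  }
  s1 <- scale_pair(spec$f1)
  s2 <- scale_pair(spec$f2)
  ws <- seq(0, 1, by = w_step)
  if (ws[length(ws)] < 1) ws <- c(ws, 1)
  obj <- numeric(length(ws))
  for (i in seq_along(ws)) {
    w <- ws[i]
    num <- max(w * s1$z + (1 - w) * s2$z, floor_eps)
    den <- max(max(w * s1$grid + (1 - w) * s2$grid), floor_eps)
    obj[i] <- log(num) - log(den)
  }
  ties <- which(obj >= max(obj) - 1e-12)
  (ws[min(ties)] + ws[max(ties)]) / 2
}

#' Configuration of a synthetic study
#'
#' @param n_tips species count (default 132, a carnivoran-scale sample).
#' @param n_landmarks landmarks per configuration (default 35).
#' @param bm_rate BM variance rate for shape evolution (default 0.01).
#' @param spec performance-function specification
#'   (default [default_surface_spec()]).
#' @param noise_sd measurement noise on the scaled metrics (default 0.01).
#' @param clade_split fraction of species labelled `groupA` (default 0.7).
#' @param grid_n theoretical-grid points per axis (default 8).
#' @param grid_extension total range extension per axis (default 0.10).
#' @param seed master seed; all stage seeds derive from it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tips = 132, n_landmarks = 35, bm_rate = 0.01,
                             spec = default_surface_spec(), noise_sd = 0.01,
                             clade_split = 0.7, grid_n = 8,
                             grid_extension = 0.10, seed = 1) {
  stopifnot(n_tips >= 3, n_landmarks >= 3, bm_rate >= 0, noise_sd >= 0,
            clade_split > 0, clade_split < 1, grid_n >= 2)
  structure(list(n_tips = n_tips, n_landmarks = n_landmarks,
                 bm_rate = bm_rate, spec = spec, noise_sd = noise_sd,
                 clade_split = clade_split, grid_n = grid_n,
                 grid_extension = grid_extension, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a complete synthetic study
#'
#' Assembles, from one seeded configuration: a pure-birth tree; landmark
#' shapes evolved by BM; their Procrustes alignment and PC morphospace; the
#' theoretical grid; noisy and noiseless functional traits over the grid;
#' species positions (tip PC1/PC2 scores); oracle trade-off weights per
#' species (from the noiseless surfaces); and clade labels (the first
#' `clade_split` fraction of tips are `groupA`, sharing the single planted
#' form-function mapping with `groupB`).
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_study` with elements `config`, `tree`,
#'   `sample`, `alignment`, `morphospace`, `grid`, `traits`,
#'   `species_positions`, `species_f` (noiseless scaled f1/f2 at species
#'   positions), `true_w`, `groups`.
#' @export
gen_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- config$seed
  tree <- gen_tree(config$n_tips, seed = seed)
  sample <- gen_shapes_bm(tree, base_configuration(config$n_landmarks),
                          config$bm_rate, seed = seed + 1L)
  n <- config$n_tips
  n_a <- max(1, min(n - 1, ceiling(config$clade_split * n)))
  groups <- stats::setNames(rep(c("groupA", "groupB"), c(n_a, n - n_a)),
                            sample$species)
  sample$clade <- unname(groups[sample$species])
  alignment <- gpa(sample)
  morphospace <- pca_morphospace(alignment)
  grid <- theoretical_grid(morphospace, n_per_axis = config$grid_n,
                           extension = config$grid_extension)
  traits <- gen_performance(grid, config$spec, noise_sd = config$noise_sd,
                            seed = seed + 2L)
  pos <- morphospace$scores[, 1:2, drop = FALSE]
  colnames(pos) <- c("pc1", "pc2")
  surf <- analytic_performance(config$spec, grid, scaled = TRUE)
  species_f <- data.frame(species = rownames(pos),
                          f1 = predict_surface(surf$f1, pos),
                          f2 = predict_surface(surf$f2, pos))
  true_w <- vapply(seq_len(nrow(pos)), function(i)
    oracle_w(pos[i, ], config$spec, grid), 0)
  names(true_w) <- rownames(pos)
  structure(list(config = config, tree = tree, sample = sample,
                 alignment = alignment, morphospace = morphospace,
                 grid = grid, traits = traits,
                 species_positions = pos, species_f = species_f,
                 true_w = true_w, groups = groups),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d species (%d landmarks), seed %d\n",
    x$config$n_tips, x$config$n_landmarks, x$config$seed))
  cat(sprintf("true w: min %.3f, median %.3f, max %.3f\n",
              min(x$true_w), stats::median(x$true_w), max(x$true_w)))
  invisible(x)
}
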