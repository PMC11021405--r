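# Combined functional landscape and trade-off weight estimation.
#
# Two scaled performance surfaces F1 and F2 are mixed with a weight w in
# [0, 1]; the height of the combined landscape at a morphospace position z is
#   W(z; w) = w * F1(z) + (1 - w) * F2(z)
# and the log-fitness of z under weight w is the log-ratio of that height to
# the maximum height the combined landscape attains anywhere on a reference
# grid (the maximum is recomputed for every w). The trade-off weight of a
# shape is the w maximising its log-fitness.

#' Combine two performance surfaces into a functional landscape
#'
#' Cell-wise `w * F1 + (1 - w) * F2` over a common grid.
#'
#' @param grid morphospace positions of the cells.
#' @param f1,f2 surface heights per cell (equal lengths).
#' @param w mixing weight in `[0, 1]`.
#' @return Data frame of class `combined_landscape` with columns `pc1`,
#'   `pc2`, `f1`, `f2`, `height`, and attribute `w`.
#' @export
combined_landscape <- function(grid, f1, f2, w) {
  pos <- as_positions(grid)
  if (length(f1) != nrow(pos) || length(f2) != nrow(pos))
    stopf("grid (%d cells) and surface values (%d, %d) are not congruent",
          nrow(pos), length(f1), length(f2))
  if (w < 0 || w > 1) stopf("w must lie in [0, 1]")
  out <- data.frame(pc1 = pos[, 1], pc2 = pos[, 2], f1 = f1, f2 = f2,
                    height = w * f1 + (1 - w) * f2)
  attr(out, "w") <- w
  class(out) <- c("combined_landscape", "data.frame")
  out
}

# predictions of both surfaces on the reference grid, computed once
reference_heights <- function(f1_model, f2_model, reference_grid) {
  pos <- as_positions(reference_grid)
  if (nrow(pos) == 0) stopf("empty reference grid")
  list(F1 = predict_surface(f1_model, pos), F2 = predict_surface(f2_model, pos))
}

# max_j [ w * F1_j + (1 - w) * F2_j ] for each w in ws, vectorised
eq_denominator <- function(ws, F1, F2) {
  m <- outer(ws, F1) + outer(1 - ws, F2)
  row_max(m)
}

guard_positive <- function(x, floor_eps, what) {
  bad <- x <= 0
  if (any(bad)) {
    if (is.null(floor_eps))
      stopf(paste0("non-positive combined landscape %s (min %.3g); unclipped ",
                   "surface predictions can fall below zero off-sample -- ",
                   "pass floor_eps (e.g. 1e-9) to floor them"), what, min(x))
    x[x < floor_eps] <- floor_eps
  }
  x
}

#' Log-fitness of a morphospace position under a given trade-off weight
#'
#' `log( (w F1(z) + (1-w) F2(z)) / max_grid(w F1 + (1-w) F2) )`: the log of
#' the position's combined-landscape height relative to the highest point of
#' the same landscape over the reference grid. Always `<= 0`, with 0 attained
#' only at the landscape peak.
#'
#' @param position a single morphospace position (length-2 vector or 1-row
#'   data frame/matrix).
#' @param w mixing weight in `[0, 1]`.
#' @param f1_model,f2_model fitted [fit_surface()] models (or
#'   [analytic_surface()] objects).
#' @param reference_grid positions over which the landscape maximum is taken
#'   (typically the theoretical 8x8 grid).
#' @param floor_eps optional positive floor applied to non-positive combined
#'   heights (default `NULL`: a hard error, since unclipped surface
#'   predictions can stray below zero off-sample).
#' @return Scalar log-fitness (`<= 0` up to floating point).
#' @export
log_fitness <- function(position, w, f1_model, f2_model, reference_grid,
                        floor_eps = NULL) {
  if (w < 0 || w > 1) stopf("w must lie in [0, 1]")
  pos <- as_positions(position)
  if (nrow(pos) != 1) stopf("log_fitness expects a single position")
  refs <- reference_heights(f1_model, f2_model, reference_grid)
  f1z <- predict_surface(f1_model, pos)
  f2z <- predict_surface(f2_model, pos)
  num <- guard_positive(w * f1z + (1 - w) * f2z, floor_eps, "height at the position")
  den <- guard_positive(max(w * refs$F1 + (1 - w) * refs$F2), floor_eps,
                        "maximum over the reference grid")
  log(num / den)
}

# core grid-search estimator shared by estimate_w / species_w / w_surface.
# f1z, f2z: surface heights at the focal position; F1, F2: heights on the
# reference grid; den may be precomputed with eq_denominator().
estimate_w_core <- function(f1z, f2z, ws, den, floor_eps, tie_tol = 1e-12) {
  num <- ws * f1z + (1 - ws) * f2z
  num <- guard_positive(num, floor_eps, "height at the position")
  obj <- log(num) - log(den)
  top <- max(obj)
  ties <- which(obj >= top - tie_tol)
  w_hat <- (ws[min(ties)] + ws[max(ties)]) / 2
  list(w = w_hat, log_fitness = top, tied = length(ties) > 1,
       w_tie_range = c(ws[min(ties)], ws[max(ties)]))
}

#' Estimate the trade-off weight of a morphospace position
#'
#' Exhaustive grid search over `w in {0, resolution, ..., 1}` for the weight
#' maximising [log_fitness()]. The landscape maximum inside the objective
#' makes it piecewise and potentially multi-modal, so grid search is used
#' rather than smooth optimisation. Weights whose objective lies within
#' `1e-12` of the maximum form a tie set; the reported `w` is then the
#' midpoint of that set and `tied` is `TRUE` (two identical surfaces, for
#' instance, give `w = 0.5`).
#'
#' @inheritParams log_fitness
#' @param resolution spacing of the search grid, in `(0, 0.1]`
#'   (default 0.001).
#' @return A list of class `tradeoff_estimate`: `w`, `log_fitness`, `tied`,
#'   `w_tie_range`.
#' @export
estimate_w <- function(position, f1_model, f2_model, reference_grid,
                       resolution = 0.001, floor_eps = NULL) {
  if (resolution <= 0 || resolution > 0.1)
    stopf("resolution must lie in (0, 0.1]")
  pos <- as_positions(position)
  if (nrow(pos) != 1) stopf("estimate_w expects a single position; see species_w()")
  refs <- reference_heights(f1_model, f2_model, reference_grid)
  ws <- seq(0, 1, by = resolution)
  if (ws[length(ws)] < 1) ws <- c(ws, 1)
  den <- guard_positive(eq_denominator(ws, refs$F1, refs$F2), floor_eps,
                        "maximum over the reference grid")
  est <- estimate_w_core(predict_surface(f1_model, pos),
                         predict_surface(f2_model, pos), ws, den, floor_eps)
  structure(est, class = "tradeoff_estimate")
}

#' @export
print.tradeoff_estimate <- function(x, ...) {
  cat(sprintf("tradeoff_estimate: w = %.4f (log-fitness %.4f)%s\n",
              x$w, x$log_fitness,
              if (x$tied) sprintf(", tied over [%.4f, %.4f]",
                                  x$w_tie_range[1], x$w_tie_range[2]) else ""))
  invisible(x)
}

#' Trade-off weights for a table of species positions
#'
#' One [estimate_w()] per species, sharing a single evaluation of the
#' reference-grid maxima, plus the predicted surface heights at each
#' position.
#'
#' @param species_positions `n x 2` matrix/data frame of positions; row
#'   names (or a `species` column) become species labels.
#' @inheritParams estimate_w
#' @return Data frame: `species`, `pc1`, `pc2`, `f1`, `f2`, `w`,
#'   `log_fitness`, `tied`.
#' @export
species_w <- function(species_positions, f1_model, f2_model, reference_grid,
                      resolution = 0.001, floor_eps = NULL) {
  labels <- NULL
  if (is.data.frame(species_positions) && "species" %in% names(species_positions))
    labels <- as.character(species_positions$species)
  pos <- as_positions(species_positions)
  labels <- labels %||% rownames(species_positions) %||%
    paste0("sp", seq_len(nrow(pos)))
  refs <- reference_heights(f1_model, f2_model, reference_grid)
  ws <- seq(0, 1, by = resolution)
  if (ws[length(ws)] < 1) ws <- c(ws, 1)
  den <- guard_positive(eq_denominator(ws, refs$F1, refs$F2), floor_eps,
                        "maximum over the reference grid")
  f1z <- predict_surface(f1_model, pos)
  f2z <- predict_surface(f2_model, pos)
  ests <- lapply(seq_len(nrow(pos)), function(i)
    estimate_w_core(f1z[i], f2z[i], ws, den, floor_eps))
  data.frame(species = labels, pc1 = pos[, 1], pc2 = pos[, 2],
             f1 = f1z, f2 = f2z,
             w = vapply(ests, `[[`, 0, "w"),
             log_fitness = vapply(ests, `[[`, 0, "log_fitness"),
             tied = vapply(ests, `[[`, TRUE, "tied"),
             row.names = NULL)
}

#' Trade-off weight surface over the morphospace
#'
#' Estimates `w` at every cell of an `n x n` grid spanning the extent of the
#' reference grid (default 40 x 40 = 1600 cells, the resolution used for the
#' sliding-window volume analysis). By default the landscape maximum inside
#' the objective is still taken over `reference_grid` (the fitting grid);
#' `reference = "cells"` uses the finer cell grid itself instead.
#'
#' @inheritParams estimate_w
#' @param n cells per axis (default 40).
#' @param reference `"grid"` (default) or `"cells"`, see Details.
#' @return Data frame of class `w_surface`: `pc1`, `pc2`, `f1`, `f2`, `w`,
#'   `log_fitness`, `tied`; attributes `n_per_axis`, `reference`.
#' @export
w_surface <- function(f1_model, f2_model, reference_grid, n = 40,
                      resolution = 0.001, reference = c("grid", "cells"),
                      floor_eps = NULL) {
  if (n < 2) stopf("n must be at least 2")
  reference <- match.arg(reference)
  ref_pos <- as_positions(reference_grid)
  r1 <- range(ref_pos[, 1]); r2 <- range(ref_pos[, 2])
  cells <- expand.grid(pc1 = seq(r1[1], r1[2], length.out = n),
                       pc2 = seq(r2[1], r2[2], length.out = n),
                       KEEP.OUT.ATTRS = FALSE)
  ref_use <- if (reference == "grid") ref_pos else as_positions(cells)
  out <- species_w(cells, f1_model, f2_model, ref_use,
                   resolution = resolution, floor_eps = floor_eps)
  out$species <- NULL
  attr(out, "n_per_axis") <- n
  attr(out, "reference") <- reference
  class(out) <- c("w_surface", "data.frame")
  out
}

#' @export
print.w_surface <- function(x, ...) {
  cat(sprintf("w_surface: %d cells (%d per axis), w in [%.3f, %.3f]\n",
              nrow(x), attr(x, "n_per_axis"), min(x$w), max(x$w)))
  invisible(x)
}
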