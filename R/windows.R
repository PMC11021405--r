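# Sliding-window analysis over the trade-off weight: theoretical "w volume"
# (how many morphospace cells support a given w interval) versus observed
# morphological disparity of the species falling in the same interval.

#' Build consecutive overlapping windows over the weight axis
#'
#' Windows start at `w_min, w_min + step, ...` for as long as
#' `start + size <= w_max`, giving `floor((w_max - w_min - size) / step) + 1`
#' windows.
#'
#' @param w_min,w_max range to cover (`w_max - w_min >= size`).
#' @param step start-to-start spacing (default 0.0002).
#' @param size window width (default 0.011).
#' @return Data frame with columns `start`, `end`, `center`, ordered by
#'   `start`.
#' @export
make_windows <- function(w_min, w_max, step = 0.0002, size = 0.011) {
  if (step <= 0 || size <= 0) stopf("step and size must be positive")
  if (w_max - w_min < size - 1e-12)
    stopf("range [%g, %g] is smaller than one window (size %g)", w_min, w_max, size)
  n_win <- floor((w_max - w_min - size) / step + 1e-9) + 1
  starts <- w_min + step * (seq_len(n_win) - 1)
  data.frame(start = starts, end = starts + size, center = starts + size / 2)
}

#' Count morphospace cells with w inside a window
#'
#' Membership is half-open, `start <= w < start + size`, so adjacent
#' non-overlapping windows never double-count a cell (overlapping windows do,
#' by construction).
#'
#' @param w_grid_values vector of per-cell weights (e.g. `w_surface()$w`).
#' @param window a one-row slice of [make_windows()] output, or a numeric
#'   `c(start, end)`.
#' @return Integer count.
#' @export
w_volume <- function(w_grid_values, window) {
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  sum(w_grid_values >= window[1] & w_grid_values < window[2])
}

#' Multivariate variance (trace of the covariance matrix)
#'
#' Sum over columns of the unbiased sample variance -- the disparity measure
#' used throughout the sliding-window analysis.
#'
#' @param data_matrix numeric matrix, rows = specimens (at least 2).
#' @return Non-negative scalar.
#' @export
multivariate_variance <- function(data_matrix) {
  m <- as.matrix(data_matrix)
  if (nrow(m) < 2) stopf("multivariate variance needs at least 2 rows")
  sum(apply(m, 2, stats::var))
}

#' Cluster morphospace positions with a Gaussian mixture
#'
#' Fits Gaussian mixtures with full covariances for `K = 1..min(max_k, n-1)`
#' via `mclust::Mclust` and selects `K` by BIC. Used to split the species of
#' a w window into groups occupying distant areas of the landscape, so that
#' within-window disparity is not inflated by between-area spread. Degenerate
#' inputs (near-identical points, or mixtures mclust cannot fit) collapse to
#' a single cluster.
#'
#' @param points_2d `n x 2` matrix of positions (n >= 2).
#' @param max_k largest number of clusters to consider (default 5).
#' @param seed integer seed (mclust's initialisation is deterministic, but
#'   the seed guards any internal randomness).
#' @return Integer vector of cluster labels with attribute `k`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_positions <- function(points_2d, max_k = 5, seed = 1) {
  pts <- as_positions(points_2d)
  n <- nrow(pts)
  if (n < 2) stopf("clustering needs at least 2 points")
  if (max_k < 1) stopf("max_k must be at least 1")
  kmax <- min(max_k, n - 1)
  # effectively coincident points: one blob by convention
  if (max(apply(pts, 2, function(v) diff(range(v)))) < 1e-9) {
    labels <- rep(1L, n); attr(labels, "k") <- 1L
    return(labels)
  }
  fit <- with_seed(seed, tryCatch(
    suppressWarnings(Mclust(pts, G = seq_len(kmax), verbose = FALSE)),
    error = function(e) NULL))
  if (is.null(fit)) {
    labels <- rep(1L, n); attr(labels, "k") <- 1L
    return(labels)
  }
  labels <- as.integer(fit$classification)
  attr(labels, "k") <- as.integer(fit$G)
  labels
}

#' Sliding-window disparity versus theoretical w volume
#'
#' For every window over the weight axis: counts the morphospace cells whose
#' `w` falls in the window (the "w volume"); finds the species whose
#' estimated `w` falls in the window; and, when at least two species are
#' present, clusters them on their 2D landscape positions
#' ([cluster_positions()]), computes the multivariate variance of the FULL
#' shape variables separately per cluster (clusters of one contribute 0) and
#' sums across clusters. Windows with fewer than two species get `NA`
#' disparity but still report their volume.
#'
#' @param species_w vector of per-species trade-off weights.
#' @param species_positions_2d `n x 2` positions of the species in the
#'   morphospace (used for clustering only).
#' @param species_shapes `n x q` matrix of full shape variables (used for
#'   disparity).
#' @param windows data frame from [make_windows()].
#' @param w_grid_values per-cell weights of the `w` surface.
#' @param seed seed forwarded to the per-window clustering.
#' @param max_k largest cluster count per window.
#' @return Data frame of class `window_result`: `w_center`, `volume`,
#'   `n_species`, `n_clusters`, `disparity`.
#' @export
windowed_disparity <- function(species_w, species_positions_2d, species_shapes,
                               windows, w_grid_values, seed = 1, max_k = 5) {
  pos <- as_positions(species_positions_2d)
  shapes <- as.matrix(species_shapes)
  n <- length(species_w)
  if (nrow(pos) != n || nrow(shapes) != n)
    stopf("species tables are misaligned (w: %d, positions: %d, shapes: %d)",
          n, nrow(pos), nrow(shapes))
  out <- data.frame(w_center = windows$center,
                    volume = NA_integer_, n_species = NA_integer_,
                    n_clusters = NA_integer_, disparity = NA_real_)
  for (i in seq_len(nrow(windows))) {
    win <- c(windows$start[i], windows$end[i])
    out$volume[i] <- w_volume(w_grid_values, win)
    idx <- which(species_w >= win[1] & species_w < win[2])
    out$n_species[i] <- length(idx)
    if (length(idx) >= 2) {
      labels <- cluster_positions(pos[idx, , drop = FALSE], max_k = max_k,
                                  seed = seed)
      out$n_clusters[i] <- attr(labels, "k")
      disp <- 0
      for (g in unique(labels)) {
        members <- idx[labels == g]
        if (length(members) >= 2)
          disp <- disp + multivariate_variance(shapes[members, , drop = FALSE])
      }
      out$disparity[i] <- disp
    } else {
      out$n_clusters[i] <- length(idx)
    }
  }
  class(out) <- c("window_result", "data.frame")
  out
}

# xi rank-based dependence coefficient: sort by x (ties in x broken at
# random), take the ranks r of y in that order, then
#   xi = 1 - 3 * sum |r_{i+1} - r_i| / (n^2 - 1).
xi_coefficient <- function(x, y, seed = NULL) {
  n <- length(x)
  ord <- with_seed(seed, order(x, sample.int(n)))
  r <- rank(y, ties.method = "average")[ord]
  xi <- 1 - 3 * sum(abs(diff(r))) / (n^2 - 1)
  # asymptotic right-tailed normal null: sqrt(n) * xi ~ N(0, 2/5)
  p <- stats::pnorm(sqrt(n) * xi / sqrt(2 / 5), lower.tail = FALSE)
  list(estimate = xi, p.value = p)
}

#' Association between two profiles: Pearson, Spearman and xi
#'
#' Pairwise-removes undefined entries, then reports Pearson's r and
#' Spearman's rho with their standard tests, and the xi rank dependence
#' coefficient (sensitive to non-monotone association) with its right-tailed
#' asymptotic normal p-value. Ties in `x` are broken uniformly at random
#' under `seed` before computing xi, as the coefficient prescribes.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param seed seed for xi's tie-breaking.
#' @return Data frame with rows `pearson`, `spearman`, `xi` and columns
#'   `estimate`, `p_value`, plus attribute `n` (complete pairs used).
#' @export
association <- function(x, y, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs (got %d)", n)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stopf("constant vector: association undefined")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  xi <- xi_coefficient(x, y, seed = seed)
  out <- data.frame(estimate = c(pe$estimate, sp$estimate, xi$estimate),
                    p_value = c(pe$p.value, sp$p.value, xi$p.value),
                    row.names = c("pearson", "spearman", "xi"))
  attr(out, "n") <- n
  out
}
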