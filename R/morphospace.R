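#' Principal-component morphospace of aligned shapes
#'
#' Eigen-decomposition of the covariance of the flattened tangent-space
#' coordinates. Components are ordered by decreasing eigenvalue and each
#' eigenvector is flipped, if necessary, so that its largest-magnitude
#' loading is positive (a reproducible sign convention).
#'
#' @param alignment a `gpa_alignment` (or an `n x q` matrix of shape
#'   variables, one row per specimen).
#' @param tol relative tolerance below which trailing components are dropped.
#' @return An object of class `morphospace_model`: `mean_shape` (flattened
#'   vector), `eigenvectors` (`q x k`, orthonormal columns), `eigenvalues`
#'   (non-increasing), `scores` (`n x k`), `n_landmarks`, `species`, `clade`.
#' @export
pca_morphospace <- function(alignment, tol = 1e-10) {
  if (inherits(alignment, "gpa_alignment")) {
    n <- dim(alignment$aligned)[3]
    x <- t(apply(alignment$aligned, 3, flatten_config))
    p <- dim(alignment$aligned)[1]
    species <- alignment$species; clade <- alignment$clade
  } else {
    x <- as.matrix(alignment)
    n <- nrow(x); p <- NA_integer_
    species <- rownames(x) %||% paste0("sp", seq_len(n)); clade <- NULL
  }
  if (n < 3) stopf("PCA morphospace needs at least 3 specimens")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  keep <- sv$d > tol * sv$d[1]
  d <- sv$d[keep]
  vec <- sv$v[, keep, drop = FALSE]
  scores <- xc %*% vec
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) { vec[, j] <- -vec[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- d^2 / (n - 1)
  colnames(scores) <- colnames(vec) <- paste0("PC", seq_along(ev))
  rownames(scores) <- species
  structure(list(mean_shape = mu, eigenvectors = vec, eigenvalues = ev,
                 scores = scores, total_variance = sum(xc^2) / (n - 1),
                 n_landmarks = p, species = species, clade = clade),
            class = "morphospace_model")
}

#' @export
print.morphospace_model <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("morphospace_model: %d specimens, %d components\n",
              nrow(x$scores), length(x$eigenvalues)))
  cat(sprintf("PC1 %.2f%%, PC2 %.2f%% (PC1+PC2 %.2f%%) of total variance\n",
              pct[1], pct[2], pct[1] + pct[2]))
  invisible(x)
}

#' Reconstruct a landmark configuration from PC scores
#'
#' Computes `mean_shape + sum_k score_k * eigenvector_k`; scores beyond the
#' supplied vector are treated as zero, so a shape can be reconstructed from
#' its first two components only (as for the theoretical-grid shapes).
#'
#' @param scores numeric vector of component scores (length <= number of
#'   components in the model).
#' @param model a `morphospace_model`.
#' @return A `p x 3` landmark matrix if the model records a landmark count,
#'   otherwise the flattened shape vector.
#' @export
reconstruct_shape <- function(scores, model) {
  k <- length(scores)
  if (k > ncol(model$eigenvectors))
    stopf("%d scores supplied but the model has only %d components",
          k, ncol(model$eigenvectors))
  v <- model$mean_shape
  if (k > 0)
    v <- v + as.vector(model$eigenvectors[, seq_len(k), drop = FALSE] %*% scores)
  if (!is.na(model$n_landmarks)) unflatten_config(v, model$n_landmarks) else v
}

#' Project configurations into an existing morphospace
#'
#' @param model a `morphospace_model`.
#' @param config a `p x 3` matrix, flattened shape vector, or an `n x q`
#'   matrix of flattened shapes (rows).
#' @return Matrix of scores (`n x k`).
#' @export
project_scores <- function(model, config) {
  q <- length(model$mean_shape)
  if (is.matrix(config) && ncol(config) == 3 && 3 * nrow(config) == q)
    config <- flatten_config(config)
  x <- if (is.matrix(config)) config else matrix(config, nrow = 1)
  if (ncol(x) != q) stopf("shape dimension %d does not match the model (%d)",
                          ncol(x), q)
  sweep(x, 2, model$mean_shape) %*% model$eigenvectors
}

#' Evenly spaced theoretical grid over the first two PC axes
#'
#' Builds the `n_per_axis x n_per_axis` grid of morphospace positions used to
#' generate theoretical shapes. Each axis spans the empirical score range
#' extended by `extension` of that range in total, split equally between the
#' two ends.
#'
#' @param model a `morphospace_model` (or an `n x 2` matrix of scores).
#' @param n_per_axis points per axis (default 8, i.e. 64 positions).
#' @param extension fraction of the empirical range added in total per axis
#'   (default 0.10); must satisfy `0 <= extension < 1`.
#' @param axes which two components to use (default PC1, PC2).
#' @return A data frame of class `morpho_grid` with columns `pc1`, `pc2`
#'   (pc1 varies fastest), and attributes `n_per_axis`, `ranges`.
#' @export
theoretical_grid <- function(model, n_per_axis = 8, extension = 0.10,
                             axes = c(1, 2)) {
  if (n_per_axis < 2) stopf("n_per_axis must be at least 2")
  if (extension < 0 || extension >= 1) stopf("extension must be in [0, 1)")
  sc <- if (inherits(model, "morphospace_model")) model$scores else as.matrix(model)
  if (ncol(sc) < max(axes)) stopf("model has fewer components than requested axes")
  rng <- apply(sc[, axes, drop = FALSE], 2, range)
  axis_seq <- function(r) {
    span <- r[2] - r[1]
    if (span <= 0) stopf("degenerate (zero) empirical range on a grid axis")
    e <- extension * span / 2
    seq(r[1] - e, r[2] + e, length.out = n_per_axis)
  }
  g <- expand.grid(pc1 = axis_seq(rng[, 1]), pc2 = axis_seq(rng[, 2]),
                   KEEP.OUT.ATTRS = FALSE)
  attr(g, "n_per_axis") <- n_per_axis
  attr(g, "ranges") <- rng
  class(g) <- c("morpho_grid", "data.frame")
  g
}
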