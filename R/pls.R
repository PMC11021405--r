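# Two-block partial least squares between shape and function, with
# major-axis shape prediction and cross-clade transfer assessment.

#' Fit a two-block PLS model (first axis pair)
#'
#' Centres the shape block, centres and scales the functional block to unit
#' variance, and extracts the first singular triplet of the between-block
#' cross-covariance matrix: the pair of unit axes (one per block) maximising
#' covariance between the blocks' projections. The sign convention makes the
#' first loading of the functional axis positive. The first principal axis
#' of the 2D cloud of training score pairs (the "major axis") is stored for
#' shape prediction.
#'
#' @param shape_block `n x q` matrix of shape variables (tangent
#'   coordinates), rows = specimens.
#' @param func_block `n x m` matrix of functional metrics (same rows).
#' @return Object of class `pls_model`: `shape_mean`, `func_mean`,
#'   `func_scale`, `shape_axis`, `func_axis`, `singular_value`, `scores`
#'   (`n x 2`: shape score, functional score), `major_axis` (unit direction
#'   and centre in score space).
#' @export
fit_pls2b <- function(shape_block, func_block) {
  X <- as.matrix(shape_block); Y <- as.matrix(func_block)
  n <- nrow(X)
  if (nrow(Y) != n) stopf("blocks have different specimen counts")
  if (n < 3) stopf("two-block PLS needs at least 3 specimens")
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  y_sd <- apply(Y, 2, stats::sd)
  if (any(y_sd <= 0)) stopf("constant functional metric cannot be scaled to unit variance")
  Xc <- sweep(X, 2, x_mean)
  Ys <- sweep(sweep(Y, 2, y_mean), 2, y_sd, "/")
  C <- crossprod(Xc, Ys) / (n - 1)
  sv <- svd(C, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  if (v[1] < 0) { u <- -u; v <- -v }
  scores <- cbind(shape = drop(Xc %*% u), func = drop(Ys %*% v))
  cv <- stats::cov(scores)
  eg <- eigen(cv, symmetric = TRUE)
  axis <- eg$vectors[, 1]
  if (axis[1] < 0) axis <- -axis
  structure(list(shape_mean = x_mean, func_mean = y_mean, func_scale = y_sd,
                 shape_axis = u, func_axis = v, singular_value = sv$d[1],
                 scores = scores,
                 major_axis = list(direction = axis, center = c(0, 0),
                                   var_explained = eg$values[1] / sum(eg$values))),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: first axis pair, singular value %.4g; %d training specimens\n",
              x$singular_value, nrow(x$scores)))
  invisible(x)
}

#' PLS scores of observations in original units
#'
#' Centres (and, for the functional block, scales) new observations with the
#' training parameters and projects them on the fitted axes. The training
#' mean observation scores exactly `(0, 0)`.
#'
#' @param model a `pls_model`.
#' @param shape_obs vector or `n x q` matrix of shapes.
#' @param func_obs vector or `n x m` matrix of functional metrics.
#' @return `n x 2` matrix with columns `shape`, `func`.
#' @export
pls_scores <- function(model, shape_obs, func_obs) {
  X <- if (is.matrix(shape_obs)) shape_obs else matrix(shape_obs, nrow = 1)
  Y <- if (is.matrix(func_obs)) func_obs else matrix(func_obs, nrow = 1)
  if (ncol(X) != length(model$shape_mean)) stopf("shape dimension mismatch")
  if (ncol(Y) != length(model$func_mean)) stopf("functional dimension mismatch")
  Xc <- sweep(X, 2, model$shape_mean)
  Ys <- sweep(sweep(Y, 2, model$func_mean), 2, model$func_scale, "/")
  cbind(shape = drop(Xc %*% model$shape_axis),
        func = drop(Ys %*% model$func_axis))
}

#' Predict shapes through the major axis of the PLS score cloud
#'
#' Projects each observation's score pair orthogonally onto the major axis of
#' the training score cloud, and back-transforms the shape-score coordinate
#' of the projected point through the shape axis: predicted shape =
#' `shape_mean + s_hat * shape_axis`.
#'
#' @inheritParams pls_scores
#' @return `n x q` matrix of predicted shape vectors.
#' @export
major_axis_predict <- function(model, shape_obs, func_obs) {
  if (sum(diag(stats::cov(model$scores))) <= .Machine$double.eps)
    stopf("degenerate training score cloud (zero variance)")
  sc <- pls_scores(model, shape_obs, func_obs)
  a <- model$major_axis$direction
  ctr <- model$major_axis$center
  t_par <- (sc[, 1] - ctr[1]) * a[1] + (sc[, 2] - ctr[2]) * a[2]
  s_hat <- ctr[1] + t_par * a[1]
  out <- outer(s_hat, model$shape_axis)
  sweep(out, 2, model$shape_mean, `+`)
}

#' Assess transfer of a form-function model to a second clade
#'
#' Fits nothing: takes a `pls_model` fitted on group A, predicts shapes for
#' both groups via [major_axis_predict()], and reports per-specimen residual
#' distances between actual and predicted shapes (Euclidean in tangent-space
#' shape coordinates, which coincides with Procrustes distance to first
#' order). A model fitted on A is expected to overfit A, so same-model
#' residuals for B should be comparable, and clearly larger only when B
#' follows a different form-function mapping. Group distributions are
#' compared with a two-sided Wilcoxon rank-sum test (reported alongside the
#' medians, not as a gate).
#'
#' @param model a `pls_model` fitted on group A only.
#' @param shapeA,funcA group-A blocks (the training clade).
#' @param shapeB,funcB group-B blocks (the transfer clade).
#' @param groups optional names for the two groups.
#' @return List of class `transfer_result`: `per_specimen` (data frame with
#'   `group`, `s_shape`, `s_func`, `residual_distance`), `medians`,
#'   `median_ratio` (B / A), `wilcox_p`.
#' @export
transfer_assessment <- function(model, shapeA, funcA, shapeB, funcB,
                                groups = c("groupA", "groupB")) {
  blocks <- list(list(shape = as.matrix(shapeA), func = as.matrix(funcA)),
                 list(shape = as.matrix(shapeB), func = as.matrix(funcB)))
  if (any(vapply(blocks, function(b) nrow(b$shape) == 0, TRUE)))
    stopf("empty group")
  per <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    sc <- pls_scores(model, b$shape, b$func)
    pred <- major_axis_predict(model, b$shape, b$func)
    resid <- sqrt(rowSums((b$shape - pred)^2))
    data.frame(group = groups[i], s_shape = sc[, 1], s_func = sc[, 2],
               residual_distance = resid, row.names = NULL)
  })
  per <- do.call(rbind, per)
  med <- tapply(per$residual_distance, per$group, stats::median)
  med <- med[groups]
  wt <- stats::wilcox.test(residual_distance ~ factor(group, levels = groups),
                           data = per, exact = FALSE)
  structure(list(per_specimen = per, medians = med,
                 median_ratio = unname(med[2] / med[1]),
                 wilcox_p = wt$p.value),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("transfer_result\n")
  print(x$medians)
  cat(sprintf("median residual ratio (transfer / training): %.3f; Wilcoxon p = %.3g\n",
              x$median_ratio, x$wilcox_p))
  invisible(x)
}
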