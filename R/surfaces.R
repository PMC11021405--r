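#' Trimmed mean of element stresses
#'
#' Averages a vector of per-element values after discarding the top
#' `fraction` largest entries (`ceiling(fraction * n)` of them). Used to
#' summarise finite-element von Mises stress fields while avoiding
#' artificially high values at boundaries and loading points.
#'
#' @param values numeric vector (non-empty).
#' @param fraction fraction of the largest values to drop, `0 <= fraction < 1`
#'   (default 0.02, i.e. the top 2 percent).
#' @return Scalar mean of the retained values.
#' @export
trim_top_fraction_mean <- function(values, fraction = 0.02) {
  if (length(values) == 0) stopf("empty value vector")
  if (!all(is.finite(values))) stopf("non-finite values")
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  drop_n <- ceiling(fraction * length(values))
  if (drop_n == 0) return(mean(values))
  keep <- sort(values)[seq_len(length(values) - drop_n)]
  mean(keep)
}

#' Min-max scale a metric to the unit interval
#'
#' `(v - min) / (max - min)`, the scaling applied to each functional metric
#' before surfaces are fitted so that competing metrics are comparable.
#'
#' @param values numeric vector with at least 2 values and `max > min`.
#' @return Vector with minimum 0 and maximum 1.
#' @export
scale_unit_interval <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values to scale")
  if (!all(is.finite(values))) stopf("non-finite values")
  r <- range(values)
  if (r[2] <= r[1]) stopf("constant vector: unit-interval scaling is undefined")
  (values - r[1]) / (r[2] - r[1])
}

# ---- polynomial surfaces ----------------------------------------------------

# bivariate monomial design x^i y^j, i + j <= degree; deterministic column order
poly_design <- function(pos, degree) {
  x <- pos[, 1]; y <- pos[, 2]
  cols <- list(); nms <- character(0)
  for (d in 0:degree) for (i in d:0) {
    j <- d - i
    cols[[length(cols) + 1]] <- x^i * y^j
    nms <- c(nms, paste0("x", i, "y", j))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

fit_polynomial_surface <- function(pos, z, degree) {
  X <- poly_design(pos, degree)
  if (nrow(X) < ncol(X)) stopf("too few points (%d) for a degree-%d surface (%d coefficients)",
                               nrow(X), degree, ncol(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stopf("rank-deficient polynomial design (degree %d)", degree)
  coef <- qr.coef(qx, z)
  list(coefficients = coef, degree = degree)
}

predict_polynomial_surface <- function(params, pos) {
  drop(poly_design(pos, params$degree) %*% params$coefficients)
}

# ---- thin-plate splines -----------------------------------------------------

# polyharmonic kernel for spline order m in 2D: r^(2m-2) * log(r), 0 at r = 0
tps_kernel <- function(r, m) {
  k <- r^(2 * m - 2) * log(r)
  k[r == 0] <- 0
  k
}

tps_drift <- function(pos, m) poly_design(pos, m - 1)

fit_tps_surface <- function(pos, z, order, lambda = NULL) {
  if (!order %in% 2:4) stopf("TPS order must be 2, 3 or 4")
  n <- nrow(pos)
  Tm <- tps_drift(pos, order)
  t_n <- ncol(Tm)
  if (n < t_n + 1) stopf("too few points for a TPS of order %d", order)
  if (anyDuplicated(round(pos, 12)))
    stopf("duplicate positions: interpolating TPS is undefined")
  D <- as.matrix(stats::dist(pos))
  K <- tps_kernel(D, order)
  qt <- qr(Tm)
  if (qt$rank < t_n) stopf("rank-deficient TPS drift design")
  Qfull <- qr.Q(qt, complete = TRUE)
  Q1 <- Qfull[, seq_len(t_n), drop = FALSE]
  Q2 <- Qfull[, -seq_len(t_n), drop = FALSE]
  B <- crossprod(Q2, K %*% Q2)
  B <- (B + t(B)) / 2
  # the polyharmonic kernel is conditionally definite up to sign; orient it
  # so the reduced bending-energy matrix is positive definite
  sgn <- if (mean(diag(B)) < 0) -1 else 1
  B <- sgn * B; Ku <- sgn * K
  eg <- eigen(B, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  u <- crossprod(eg$vectors, crossprod(Q2, z))
  if (is.null(lambda)) {
    # generalized cross-validation over a log-spaced grid scaled to the kernel
    scale <- mean(abs(evals)) + .Machine$double.eps
    grid <- scale * 10^seq(-10, 4, length.out = 71)
    gcv <- vapply(grid, function(l) {
      denom <- sum(l / (evals + l))
      if (denom <= 0) return(Inf)
      n * sum((l * u / (evals + l))^2) / denom^2
    }, 0)
    lambda <- grid[which.min(gcv)]
  }
  gamma <- eg$vectors %*% (u / (evals + lambda))
  cvec <- drop(Q2 %*% gamma)
  resid_rhs <- z - (Ku %*% cvec + lambda * cvec)
  dvec <- qr.coef(qt, drop(resid_rhs))
  list(centers = pos, c = cvec, d = dvec, order = order, lambda = lambda,
       kernel_sign = sgn)
}

predict_tps_surface <- function(params, pos) {
  D <- sqrt(outer(pos[, 1], params$centers[, 1], "-")^2 +
            outer(pos[, 2], params$centers[, 2], "-")^2)
  K <- params$kernel_sign * tps_kernel(D, params$order)
  drop(K %*% params$c + tps_drift(pos, params$order) %*% params$d)
}

# ---- ordinary kriging -------------------------------------------------------

variogram_value <- function(h, model, nugget, psill, range_) {
  g <- switch(model,
    spherical = ifelse(h < range_,
                       psill * (1.5 * h / range_ - 0.5 * (h / range_)^3),
                       psill),
    exponential = psill * (1 - exp(-h / range_)),
    gaussian = psill * (1 - exp(-(h / range_)^2)),
    stopf("unknown variogram model '%s'", model))
  out <- nugget + g
  out[h == 0] <- 0
  out
}

empirical_variogram <- function(pos, z, n_bins = 12, cutoff = NULL) {
  d <- as.vector(stats::dist(pos))
  g <- as.vector(stats::dist(z)^2) / 2
  cutoff <- cutoff %||% (max(d) / 2)
  keep <- d <= cutoff & d > 0
  d <- d[keep]; g <- g[keep]
  br <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(d, br, include.lowest = TRUE)
  ok <- !is.na(bin)
  agg_h <- tapply(d[ok], bin[ok], mean)
  agg_g <- tapply(g[ok], bin[ok], mean)
  agg_n <- tapply(g[ok], bin[ok], length)
  keep2 <- !is.na(agg_h)
  data.frame(h = as.numeric(agg_h[keep2]), gamma = as.numeric(agg_g[keep2]),
             n = as.numeric(agg_n[keep2]))
}

fit_variogram_wls <- function(emp, model, z_var, cutoff) {
  obj <- function(par) {
    th <- variogram_value(emp$h, model, par[1], par[2], par[3])
    sum(emp$n * (emp$gamma - th)^2 / pmax(emp$h, 1e-12)^2)
  }
  start <- c(nugget = 0.01 * z_var, psill = z_var, range_ = cutoff / 2)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10 * z_var, 1e-6 * cutoff),
                      upper = c(z_var, 10 * z_var, 10 * cutoff))
  list(model = model, nugget = fit$par[1], psill = fit$par[2],
       range_ = fit$par[3], sse = fit$value)
}

fit_kriging_surface <- function(pos, z, order = 0) {
  n <- nrow(pos)
  if (n < 10) stopf("too few points (%d) for kriging", n)
  families <- c("spherical", "exponential", "gaussian")
  cutoff <- max(stats::dist(pos)) / 2
  emp <- empirical_variogram(pos, z, cutoff = cutoff)
  if (nrow(emp) < 4) stopf("too few variogram bins for kriging")
  zv <- stats::var(z)
  cands <- if (order == 0) families else families[order]
  fits <- lapply(cands, fit_variogram_wls, emp = emp, z_var = zv, cutoff = cutoff)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "sse"))]]
  D <- as.matrix(stats::dist(pos))
  G <- variogram_value(D, best$model, best$nugget, best$psill, best$range_)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  list(centers = pos, z = z, variogram = best, A_inv = solve(A),
       order = order)
}

predict_kriging_surface <- function(params, pos) {
  vg <- params$variogram
  D0 <- sqrt(outer(pos[, 1], params$centers[, 1], "-")^2 +
             outer(pos[, 2], params$centers[, 2], "-")^2)
  G0 <- variogram_value(D0, vg$model, vg$nugget, vg$psill, vg$range_)
  rhs <- cbind(G0, 1)
  lam <- rhs %*% t(params$A_inv)
  drop(lam[, seq_along(params$z), drop = FALSE] %*% params$z)
}

# ---- generic surface interface ----------------------------------------------

#' Fit a performance surface over the first two morphospace axes
#'
#' Fits `z = f(pc1, pc2)` with one of three families:
#' \describe{
#'   \item{polynomial}{bivariate least-squares polynomial of degree
#'     `order` (1--5).}
#'   \item{tps}{thin-plate (polyharmonic) spline of order `order` (2--4),
#'     i.e. polynomial drift of degree `order - 1`, with the smoothing
#'     parameter chosen by generalized cross-validation unless `lambda` is
#'     given (`lambda = 0` interpolates).}
#'   \item{kriging}{ordinary kriging with the variogram family (spherical,
#'     exponential, Gaussian) fitted by weighted least squares to the
#'     empirical variogram; `order` 0 selects the family automatically,
#'     1--3 fix it.}
#' }
#'
#' @param positions morphospace positions (`n x 2` matrix or data frame with
#'   `pc1`, `pc2`).
#' @param values functional metric per position.
#' @param family one of `"polynomial"`, `"tps"`, `"kriging"`.
#' @param order family-specific order, see Details.
#' @param lambda optional TPS smoothing parameter (NULL = GCV).
#' @return An object of class `surface_model` with elements `family`,
#'   `order`, `params`, `training_rmse`, `n_params`.
#' @seealso [predict_surface()], [crossvalidate_surfaces()]
#' @export
fit_surface <- function(positions, values, family = c("polynomial", "tps", "kriging"),
                        order = 2, lambda = NULL) {
  family <- match.arg(family)
  pos <- as_positions(positions)
  z <- as.numeric(values)
  if (length(z) != nrow(pos)) stopf("positions (%d) and values (%d) differ",
                                    nrow(pos), length(z))
  if (!all(is.finite(z))) stopf("non-finite functional values")
  params <- switch(family,
    polynomial = {
      if (!order %in% 1:5) stopf("polynomial order must be 1..5")
      fit_polynomial_surface(pos, z, order)
    },
    tps = fit_tps_surface(pos, z, order, lambda = lambda),
    kriging = {
      if (!order %in% 0:3) stopf("kriging order must be 0 (auto) or 1..3")
      fit_kriging_surface(pos, z, order)
    })
  n_params <- switch(family,
    polynomial = choose(order + 2, 2),
    tps = nrow(pos) + choose(order + 1, 2),
    kriging = nrow(pos) + 3)
  model <- structure(list(family = family, order = order, params = params,
                          n_params = n_params, n_train = nrow(pos)),
                     class = "surface_model")
  model$training_rmse <- sqrt(mean((predict_surface(model, pos) - z)^2))
  model
}

#' Predict a fitted performance surface
#'
#' Deterministic evaluation of a `surface_model` (or an
#' [analytic_surface()]) at new morphospace positions. Predictions are not
#' clipped to the unit interval: off-sample values may fall slightly outside
#' `[0, 1]`, and downstream likelihood code must handle them (see
#' [log_fitness()]'s `floor_eps`).
#'
#' @param model a `surface_model` or `analytic_surface`.
#' @param positions positions to predict at.
#' @return Numeric vector of surface heights.
#' @export
predict_surface <- function(model, positions) {
  pos <- as_positions(positions)
  if (inherits(model, "analytic_surface")) return(unname(model$fun(pos)))
  if (!inherits(model, "surface_model")) stopf("not a fitted surface model")
  unname(switch(model$family,
    polynomial = predict_polynomial_surface(model$params, pos),
    tps = predict_tps_surface(model$params, pos),
    kriging = predict_kriging_surface(model$params, pos)))
}

#' @export
predict.surface_model <- function(object, newdata, ...) predict_surface(object, newdata)

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface_model: %s (order %d), training RMSE %.4g, %d points\n",
              x$family, x$order, x$training_rmse, x$n_train))
  invisible(x)
}

#' Wrap a plain function as a surface
#'
#' Used for analytic (closed-form) performance functions, e.g. the
#' Gaussian-mixture surfaces of the synthetic-study generator, so they can be
#' passed anywhere a fitted `surface_model` is accepted.
#'
#' @param fun function taking an `n x 2` position matrix and returning a
#'   numeric vector of heights.
#' @param name optional label.
#' @return An object of class `analytic_surface`.
#' @export
analytic_surface <- function(fun, name = "analytic") {
  stopifnot(is.function(fun))
  structure(list(fun = function(pos) as.numeric(fun(as_positions(pos))),
                 name = name),
            class = "analytic_surface")
}

#' @export
predict.analytic_surface <- function(object, newdata, ...) object$fun(as_positions(newdata))

#' Default candidate menu for surface selection
#'
#' Polynomials of degree 1--5, thin-plate splines of order 2--4, and
#' automatic-variogram ordinary kriging.
#'
#' @return Data frame with columns `family`, `order`.
#' @export
default_candidates <- function() {
  data.frame(family = c(rep("polynomial", 5), rep("tps", 3), "kriging"),
             order = c(1:5, 2:4, 0), stringsAsFactors = FALSE)
}

#' Select a performance surface by k-fold cross-validation
#'
#' Randomly partitions the data into `k` folds (seeded, recorded) and scores
#' every candidate `(family, order)` by its out-of-fold root-mean-square
#' error; the candidate with the lowest RMSE wins, ties broken toward fewer
#' parameters. Candidates that fail to fit on some training fold are flagged
#' with `failed = TRUE` (RMSE `NA`) rather than silently dropped.
#'
#' @param positions,values training data as in [fit_surface()].
#' @param candidates data frame with columns `family`, `order`
#'   (default [default_candidates()]).
#' @param k number of folds (default 10); `k = n` gives leave-one-out.
#' @param seed integer seed for the fold assignment.
#' @return An object of class `cv_report`: `table` (family, order, n_params,
#'   rmse, failed), `folds`, `seed`, `best` (list with family and order),
#'   `fold_id`.
#' @export
crossvalidate_surfaces <- function(positions, values, candidates = default_candidates(),
                                   k = 10, seed = 1) {
  pos <- as_positions(positions)
  z <- as.numeric(values)
  n <- nrow(pos)
  if (k < 2 || k > n) stopf("need 2 <= k <= n (n = %d)", n)
  fold_id <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  res <- candidates
  res$n_params <- NA_real_; res$rmse <- NA_real_; res$failed <- FALSE
  for (i in seq_len(nrow(candidates))) {
    fam <- candidates$family[i]; ord <- candidates$order[i]
    pred <- rep(NA_real_, n)
    ok <- TRUE
    for (f in seq_len(k)) {
      test <- fold_id == f
      fit <- tryCatch(fit_surface(pos[!test, , drop = FALSE], z[!test],
                                  family = fam, order = ord),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred[test] <- predict_surface(fit, pos[test, , drop = FALSE])
    }
    if (ok && all(is.finite(pred))) {
      res$rmse[i] <- sqrt(mean((pred - z)^2))
      res$n_params[i] <- switch(fam, polynomial = choose(ord + 2, 2),
                                tps = n + choose(ord + 1, 2), kriging = n + 3)
    } else res$failed[i] <- TRUE
  }
  if (all(res$failed)) stopf("every candidate failed to fit")
  usable <- which(!res$failed)
  best_i <- usable[order(res$rmse[usable], res$n_params[usable])][1]
  structure(list(table = res, folds = k, seed = seed,
                 best = list(family = res$family[best_i], order = res$order[best_i]),
                 best_rmse = res$rmse[best_i], fold_id = fold_id),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold CV, seed %d\n", x$folds, x$seed))
  print(x$table, row.names = FALSE)
  cat(sprintf("best: %s order %d (RMSE %.4g)\n",
              x$best$family, x$best$order, x$best_rmse))
  invisible(x)
}
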