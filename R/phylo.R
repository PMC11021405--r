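# Phylogeny-aware statistics: trait-model covariance matrices, univariate
# BM/OU/EB maximum-likelihood fitting with AICc, PGLS with permutation
# significance, independent contrasts, Mantel tests, phylogenetic PCA and
# evolutionary-rate associations.

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stopf("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label)) stopf("duplicated tip labels")
  tree
}

tree_depth <- function(tree) max(ape::node.depth.edgelength(tree))

match_trait <- function(trait, tree) {
  if (is.null(names(trait)))
    stopf("trait vector must be named with tip labels")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stopf("trait missing for tips: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  trait[tree$tip.label]
}

#' Trait covariance matrix under BM, OU or EB evolution
#'
#' \describe{
#'   \item{BM}{shared path length from the root, scaled by `sigma2`.}
#'   \item{OU}{standard Ornstein-Uhlenbeck covariance on an ultrametric tree
#'     of depth T: `sigma2/(2 alpha) * exp(-2 alpha (T - s_ij)) *
#'     (1 - exp(-2 alpha s_ij))` with `s_ij` the shared path length.
#'     Non-ultrametric input is an error (documented limitation).}
#'   \item{EB}{BM on early-burst-rescaled branch lengths: covariance
#'     `sigma2 * (exp(r s_ij) - 1) / r` (rate parameter `r <= 0`; the limit
#'     `r -> 0` recovers BM).}
#' }
#'
#' @param tree an `ape::phylo` tree.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param params named list/vector: `sigma2` (default 1), `alpha` (OU, > 0),
#'   `r` (EB, <= 0).
#' @return `n x n` covariance matrix ordered like `tree$tip.label`.
#' @export
model_vcv <- function(tree, model = c("BM", "OU", "EB"), params = list()) {
  model <- match.arg(model)
  check_tree(tree)
  sigma2 <- params$sigma2 %||% 1
  S <- ape::vcv.phylo(tree)  # shared path lengths
  out <- switch(model,
    BM = sigma2 * S,
    OU = {
      alpha <- params$alpha %||% stopf("OU needs params$alpha")
      if (alpha <= 0) stopf("OU alpha must be positive")
      if (!ape::is.ultrametric(tree, tol = 1e-8))
        stopf("the OU covariance used here requires an ultrametric tree")
      T_ <- max(diag(S))
      sigma2 / (2 * alpha) * exp(-2 * alpha * (T_ - S)) * (1 - exp(-2 * alpha * S))
    },
    EB = {
      r <- params$r %||% stopf("EB needs params$r")
      if (r > 0) stopf("EB rate parameter r must be <= 0")
      if (abs(r) < 1e-300) sigma2 * S else sigma2 * expm1(r * S) / r
    })
  out
}

# profile log-likelihood of a univariate trait under N(z0 * 1, sigma2 * V0),
# with z0 (GLS root state) and sigma2 concentrated out
profile_loglik <- function(y, V0) {
  n <- length(y)
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  logdet <- 2 * sum(log(diag(ch)))
  ty <- backsolve(ch, y, transpose = TRUE)
  t1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  z0 <- sum(t1 * ty) / sum(t1 * t1)
  q <- sum((ty - z0 * t1)^2)
  sigma2 <- q / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(loglik = ll, sigma2 = sigma2, z0 = z0)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 LL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tips).
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stopf("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a univariate trait-evolution model by maximum likelihood
#'
#' Maximises the multivariate-normal likelihood implied by [model_vcv()].
#' BM is closed-form; OU's `alpha` and EB's `r` are profiled over a bounded
#' 1D search (coarse deterministic grid of restarts followed by local
#' optimisation; bounds `alpha` in `[1e-8, 50/depth]`, `r` in
#' `[-10/depth, 0]`). Free-parameter counts: BM 2 (`sigma2`, root), OU 3,
#' EB 3.
#'
#' @param trait named numeric vector (names = tip labels, complete).
#' @param tree an `ape::phylo` tree with at least 4 tips.
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @return List of class `trait_model_fit`: `model`, `params` (sigma2, z0,
#'   and alpha or r where applicable), `loglik`, `k`, `aicc`, `convergence`.
#' @export
fit_trait_model <- function(trait, tree, model = c("BM", "OU", "EB")) {
  model <- match.arg(model)
  check_tree(tree)
  y <- match_trait(trait, tree)
  n <- length(y)
  if (n < 4) stopf("need at least 4 tips")
  if (!all(is.finite(y))) stopf("trait must be complete and finite")
  S <- ape::vcv.phylo(tree)
  depth <- max(diag(S))
  fit1d <- function(par_name, lower, upper, V0_fun) {
    grid <- seq(lower, upper, length.out = 25)
    ll_grid <- vapply(grid, function(p) profile_loglik(y, V0_fun(p))$loglik, 0)
    best <- grid[which.max(ll_grid)]
    opt <- stats::optimize(function(p) profile_loglik(y, V0_fun(p))$loglik,
                           lower = max(lower, best - (upper - lower) / 12),
                           upper = min(upper, best + (upper - lower) / 12),
                           maximum = TRUE, tol = 1e-10)
    if (opt$objective < max(ll_grid)) list(par = best, loglik = max(ll_grid))
    else list(par = opt$maximum, loglik = opt$objective)
  }
  if (model == "BM") {
    pr <- profile_loglik(y, S)
    out <- list(model = "BM",
                params = list(sigma2 = pr$sigma2, z0 = pr$z0),
                loglik = pr$loglik, k = 2)
  } else if (model == "OU") {
    if (!ape::is.ultrametric(tree, tol = 1e-8))
      stopf("OU fitting requires an ultrametric tree")
    # same covariance as model_vcv(tree, "OU", .), built from the cached S
    V0_fun <- function(a)
      1 / (2 * a) * exp(-2 * a * (depth - S)) * (1 - exp(-2 * a * S))
    sol <- fit1d("alpha", 1e-8, 50 / depth, V0_fun)
    pr <- profile_loglik(y, V0_fun(sol$par))
    out <- list(model = "OU",
                params = list(alpha = sol$par, sigma2 = pr$sigma2, z0 = pr$z0),
                loglik = pr$loglik, k = 3)
  } else {
    V0_fun <- function(r) if (abs(r) < 1e-300) S else expm1(r * S) / r
    sol <- fit1d("r", -10 / depth, 0, V0_fun)
    pr <- profile_loglik(y, V0_fun(sol$par))
    out <- list(model = "EB",
                params = list(r = sol$par, sigma2 = pr$sigma2, z0 = pr$z0),
                loglik = pr$loglik, k = 3)
  }
  out$n <- n
  out$aicc <- aicc(out$loglik, out$k, n)
  out$convergence <- is.finite(out$loglik)
  class(out) <- "trait_model_fit"
  out
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("trait_model_fit: %s, logLik %.3f, AICc %.3f\n",
              x$model, x$loglik, x$aicc))
  cat("params:", paste(sprintf("%s = %.4g", names(x$params),
                               unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Compare BM, OU and EB fits by AICc
#'
#' @inheritParams fit_trait_model
#' @param models subset of `c("BM", "OU", "EB")`.
#' @return Data frame (one row per model) with `loglik`, `k`, `aicc`,
#'   `delta_aicc`, ordered by AICc; attribute `fits` holds the full fits.
#' @export
fit_trait_models <- function(trait, tree, models = c("BM", "OU", "EB")) {
  fits <- lapply(models, function(m) fit_trait_model(trait, tree, m))
  tab <- data.frame(model = models,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, `[[`, 0, "k"),
                    aicc = vapply(fits, `[[`, 0, "aicc"))
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, models)
  tab
}

#' Phylogenetic generalized least squares with permutation p-value
#'
#' GLS regression under a Brownian-motion residual covariance
#' (`ape::vcv.phylo`). Coefficients are the exact
#' `(X' V^-1 X)^-1 X' V^-1 y`; the coefficient of determination uses GLS
#' sums of squares around the GLS intercept fit; significance is assessed by
#' seeded permutation of the phylogenetically whitened residuals (the
#' design and response are transformed by the inverse Cholesky factor of V,
#' reduced-model residuals are permuted and the R-squared refitted). On a
#' star phylogeny with equal tip branches the estimates equal ordinary
#' least squares.
#'
#' @param response numeric vector or matrix (rows = tips, named/rownamed).
#' @param predictors numeric vector, matrix or data frame of predictors
#'   (an intercept is added), or `NULL` for an intercept-only model.
#' @param tree an `ape::phylo` tree.
#' @param n_perm number of residual permutations (default 999).
#' @param seed permutation seed.
#' @return List of class `pgls_fit`: `coefficients`, `r2`, `p`, `loglik`,
#'   `aicc`, `n`, `n_perm`, `seed`.
#' @export
pgls <- function(response, predictors = NULL, tree, n_perm = 999, seed = 1) {
  check_tree(tree)
  tips <- tree$tip.label
  Y <- if (is.matrix(response)) response else
    matrix(response, ncol = 1, dimnames = list(names(response), NULL))
  if (!is.null(rownames(Y))) {
    miss <- setdiff(tips, rownames(Y))
    if (length(miss)) stopf("response missing for tips: %s",
                            paste(utils::head(miss, 5), collapse = ", "))
    Y <- Y[tips, , drop = FALSE]
  } else if (nrow(Y) != length(tips)) stopf("response rows do not match tips")
  n <- nrow(Y)
  X <- if (is.null(predictors)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else {
    P <- as.matrix(predictors)
    if (!is.null(rownames(P))) P <- P[tips, , drop = FALSE]
    if (nrow(P) != n) stopf("predictor rows do not match tips")
    cbind("(Intercept)" = 1, P)
  }
  V <- ape::vcv.phylo(tree)
  ch <- chol(V)
  tY <- backsolve(ch, Y, transpose = TRUE)
  tX <- backsolve(ch, X, transpose = TRUE)
  qx <- qr(tX)
  if (qx$rank < ncol(tX)) stopf("singular design")
  beta <- qr.coef(qx, tY)
  res <- tY - tX %*% beta
  rss <- sum(res^2)
  t1 <- tX[, 1, drop = FALSE]
  q0 <- qr(t1)
  res0 <- tY - t1 %*% qr.coef(q0, tY)
  tss <- sum(res0^2)
  r2 <- 1 - rss / tss
  # GLS Gaussian likelihood with a common concentrated variance
  N <- length(tY)
  sigma2 <- rss / N
  logdet <- 2 * sum(log(diag(ch))) * ncol(Y)
  ll <- -0.5 * (N * log(2 * pi) + N * log(sigma2) + logdet + N)
  k <- ncol(X) * ncol(Y) + 1
  aicc_val <- if (n - k - 1 > 0) aicc(ll, k, n) else NA_real_
  p_val <- NA_real_
  if (n_perm > 0 && ncol(X) > 1) {
    fit0 <- t1 %*% qr.coef(q0, tY)
    r2_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      tY_star <- fit0 + res0[sample.int(n), , drop = FALSE]
      res_s <- tY_star - tX %*% qr.coef(qx, tY_star)
      res0_s <- tY_star - t1 %*% qr.coef(q0, tY_star)
      1 - sum(res_s^2) / sum(res0_s^2)
    }, 0))
    p_val <- (1 + sum(r2_perm >= r2)) / (n_perm + 1)
  }
  structure(list(coefficients = beta, r2 = r2, p = p_val, loglik = ll,
                 aicc = aicc_val, n = n, n_perm = n_perm, seed = seed),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("pgls_fit: r2 = %.4f, permutation p = %s, AICc = %.3f\n",
              x$r2, format(x$p), x$aicc))
  print(x$coefficients)
  invisible(x)
}

#' Compare polynomial PGLS designs by AICc
#'
#' Fits intercept-only, linear and higher-degree polynomial PGLS regressions
#' of `response` on a single `predictor` and tabulates their AICc, mirroring
#' the comparison of rate-on-weight regression designs.
#'
#' @param response,predictor named numeric vectors over the tips.
#' @param tree an `ape::phylo` tree.
#' @param degrees polynomial degrees to compare (0 = intercept-only).
#' @param n_perm,seed forwarded to [pgls()].
#' @return Data frame with one row per degree: `degree`, `r2`, `p`, `aicc`,
#'   `delta_aicc`; attribute `fits`.
#' @export
pgls_polynomial <- function(response, predictor, tree, degrees = 0:2,
                            n_perm = 999, seed = 1) {
  check_tree(tree)
  x <- match_trait(predictor, tree)
  fits <- lapply(degrees, function(d) {
    X <- if (d == 0) NULL else {
      m <- sapply(seq_len(d), function(j) x^j)
      m <- matrix(m, ncol = d, dimnames = list(tree$tip.label,
                                               paste0("x^", seq_len(d))))
      m
    }
    pgls(response, X, tree, n_perm = n_perm, seed = seed)
  })
  tab <- data.frame(degree = degrees,
                    r2 = vapply(fits, `[[`, 0, "r2"),
                    p = vapply(fits, function(f) f$p %||% NA_real_, 0),
                    aicc = vapply(fits, `[[`, 0, "aicc"))
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  attr(tab, "fits") <- fits
  tab
}

#' Phylogenetic independent contrasts
#'
#' Standardized contrasts via `ape::pic`; polytomies are resolved to
#' zero-length branches first (with a message).
#'
#' @param trait named numeric vector over the tips.
#' @param tree an `ape::phylo` tree.
#' @return Numeric vector of `n_tips - 1` standardized contrasts.
#' @export
pic_contrasts <- function(trait, tree) {
  check_tree(tree)
  y <- match_trait(trait, tree)
  if (!ape::is.binary(tree)) {
    message("resolving polytomies to zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
    y <- y[tree$tip.label]
  }
  ape::pic(y, tree)
}

#' Mantel test on two distance matrices
#'
#' The statistic is the classical unnormalized cross-product
#' `Z = sum_{i<j} d1_ij * d2_ij`; the p-value comes from seeded permutation
#' of one matrix's labels (via `ape::mantel.test`).
#'
#' @param d1,d2 symmetric matrices (or `dist` objects) with matching order.
#' @param n_perm permutations (default 999).
#' @param seed permutation seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with `z`, `p`, `n_perm`, `alternative`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1, alternative = "greater") {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stopf("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) stopf("matrix labels do not match")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  res <- with_seed(seed, ape::mantel.test(m1, m2, nperm = n_perm,
                                          alternative = alternative))
  list(z = res$z.stat, p = res$p, n_perm = n_perm, alternative = alternative)
}

#' Phylogenetic principal component analysis
#'
#' Eigen-decomposition of the evolutionary covariance matrix
#' `(X - 1 a')' V^-1 (X - 1 a') / (n - 1)` where `a` is the GLS
#' (phylogenetic) mean and `V` the BM covariance; scores are the centred
#' data projected on the eigenvectors. On a star tree with unit branches
#' this reduces to ordinary PCA of the centred data. The eigenvector sign
#' convention matches [pca_morphospace()].
#'
#' @param trait_matrix `n x q` matrix, rownames = tip labels.
#' @param tree an `ape::phylo` tree.
#' @return List of class `ppca_fit`: `eigenvectors`, `eigenvalues`,
#'   `scores`, `phylo_mean`, `evol_vcv`.
#' @export
ppca <- function(trait_matrix, tree) {
  check_tree(tree)
  X <- as.matrix(trait_matrix)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  else if (nrow(X) != length(tree$tip.label)) stopf("rows do not match tips")
  n <- nrow(X)
  V <- ape::vcv.phylo(tree)
  ch <- chol(V)
  tX <- backsolve(ch, X, transpose = TRUE)
  t1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  a <- drop(crossprod(t1, tX)) / sum(t1^2)
  Xc <- sweep(X, 2, a)
  tXc <- backsolve(ch, Xc, transpose = TRUE)
  R <- crossprod(tXc) / (n - 1)
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  vec <- eg$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- Xc %*% vec
  colnames(scores) <- colnames(vec) <- paste0("pPC", seq_len(ncol(vec)))
  structure(list(eigenvectors = vec, eigenvalues = eg$values[keep],
                 scores = scores, phylo_mean = a, evol_vcv = R),
            class = "ppca_fit")
}

#' @export
print.ppca_fit <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("ppca_fit: %d components; pPC1 %.1f%%, pPC2 %.1f%%\n",
              length(x$eigenvalues), pct[1], if (length(pct) > 1) pct[2] else NA))
  invisible(x)
}

# Pearson correlation through the origin (the contrasts convention) with a
# two-sided t-test on n - 1 df
origin_correlation <- function(a, b) {
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  df <- length(a) - 1
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  c(estimate = r, p_value = p)
}

#' Association between two evolutionary-rate tables
#'
#' Given two rate tables (data frames with `id` and `rate`, ids being branch
#' identifiers and/or tip labels), reports Pearson and Spearman correlations
#' on all shared identifiers ("branch" scale), on the shared tip labels
#' only, and -- when a tree is supplied -- on PIC-transformed tip rates
#' using the regression-through-the-origin convention for contrasts.
#'
#' @param ratesA,ratesB data frames with columns `id`, `rate` (rates > 0),
#'   or named numeric vectors.
#' @param tree optional `ape::phylo` tree for the PIC block.
#' @return List of class `rate_association` with elements `branch`, `tip`,
#'   `pic` (each a data frame of estimates and p-values) and `n_shared`.
#' @export
rate_association <- function(ratesA, ratesB, tree = NULL) {
  to_named <- function(r) {
    if (is.data.frame(r)) stats::setNames(r$rate, as.character(r$id))
    else if (!is.null(names(r))) r
    else stopf("rate tables need identifiers (an 'id' column or names)")
  }
  a <- to_named(ratesA); b <- to_named(ratesB)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stopf("fewer than 3 shared identifiers between rate tables")
  a <- a[shared]; b <- b[shared]
  cor_block <- function(x, y) {
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(estimate = c(pe$estimate, sp$estimate),
               p_value = c(pe$p.value, sp$p.value),
               row.names = c("pearson", "spearman"))
  }
  out <- list(branch = cor_block(a, b), tip = NULL, pic = NULL,
              n_shared = length(shared))
  if (!is.null(tree)) {
    check_tree(tree)
    tips <- intersect(shared, tree$tip.label)
    if (length(tips) >= 3) {
      out$tip <- cor_block(a[tips], b[tips])
      sub <- if (length(tips) < length(tree$tip.label))
        ape::keep.tip(tree, tips) else tree
      pa <- pic_contrasts(a[tips], sub)
      pb <- pic_contrasts(b[tips], sub)
      oc <- origin_correlation(pa, pb)
      sp <- suppressWarnings(stats::cor.test(pa, pb, method = "spearman"))
      out$pic <- data.frame(estimate = c(oc["estimate"], sp$estimate),
                            p_value = c(oc["p_value"], sp$p.value),
                            row.names = c("pearson_origin", "spearman"))
    }
  }
  class(out) <- "rate_association"
  out
}

#' @export
print.rate_association <- function(x, ...) {
  cat(sprintf("rate_association over %d shared identifiers\n", x$n_shared))
  cat("all shared ids:\n"); print(x$branch)
  if (!is.null(x$tip)) { cat("tips only:\n"); print(x$tip) }
  if (!is.null(x$pic)) { cat("PIC-transformed tip rates:\n"); print(x$pic) }
  invisible(x)
}
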