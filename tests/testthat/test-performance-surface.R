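test_that("trimmed stress mean drops the top fraction before averaging", {
  expect_equal(trim_top_fraction_mean(1:100, 0.02), mean(1:98))
  expect_equal(trim_top_fraction_mean(1:100, 0.02), 49.5)
  v <- with_seed(2, runif(57))
  expect_equal(trim_top_fraction_mean(v, 0), mean(v))
  expect_equal(trim_top_fraction_mean(rep(3.2, 40), 0.1), 3.2)
  expect_error(trim_top_fraction_mean(numeric(0)), "empty")
  expect_error(trim_top_fraction_mean(1:5, 1), "fraction")
})

test_that("unit-interval scaling is affine-invariant and idempotent", {
  expect_equal(scale_unit_interval(c(2, 4, 6)), c(0, 0.5, 1))
  v <- with_seed(8, rnorm(30))
  expect_equal(scale_unit_interval(5 * v + 2), scale_unit_interval(v))
  s <- scale_unit_interval(v)
  expect_equal(range(s), c(0, 1))
  expect_equal(order(s), order(v))
  expect_equal(scale_unit_interval(s), s)
  expect_error(scale_unit_interval(rep(1, 5)), "constant")
})

test_that("polynomial surfaces recover generating coefficients exactly", {
  g <- unit_grid()
  z <- 1 + 2 * g[, 1] + 3 * g[, 2]
  f <- fit_surface(g, z, "polynomial", 1)
  expect_equal(unname(f$params$coefficients), c(1, 2, 3))
  expect_lt(f$training_rmse, 1e-12)
  expect_equal(predict_surface(f, c(0, 0)), 1)  # intercept at the origin

  # z = x^2 + y^2 against the normal-equations oracle
  z2 <- g[, 1]^2 + g[, 2]^2
  f2 <- fit_surface(g, z2, "polynomial", 2)
  X <- cbind(1, g[, 2], g[, 1], g[, 2]^2, g[, 1] * g[, 2], g[, 1]^2)
  beta_oracle <- solve(crossprod(X), crossprod(X, z2))
  expect_equal(sort(unname(f2$params$coefficients)), sort(drop(beta_oracle)),
               tolerance = 1e-10)
  expect_equal(unname(f2$params$coefficients[c("x2y0", "x0y2", "x1y1")]),
               c(1, 1, 0), tolerance = 1e-10)

  expect_error(fit_surface(g[1:4, ], z2[1:4], "polynomial", 3), "too few")
})

test_that("thin-plate splines interpolate at zero smoothing", {
  pts <- with_seed(3, cbind(runif(20), runif(20)))
  z <- sin(3 * pts[, 1]) + cos(2 * pts[, 2])
  for (ord in 2:4) {
    f <- fit_surface(pts, z, "tps", ord, lambda = 0)
    expect_lt(max(abs(predict_surface(f, pts) - z)), 1e-10)
  }
  expect_error(fit_surface(rbind(pts, pts[1, ]), c(z, z[1]), "tps", 2),
               "duplicate")
})

test_that("TPS predictions match an independent radial-basis expansion", {
  pts <- with_seed(5, cbind(runif(30), runif(30)))
  z <- pts[, 1]^2 - pts[, 2] + 0.3 * sin(5 * pts[, 1])
  f <- fit_surface(pts, z, "tps", 2)
  new <- with_seed(6, cbind(runif(100), runif(100)))
  # independent re-implementation of c' eta(r) + drift
  pl <- f$params
  pred_oracle <- vapply(seq_len(100), function(i) {
    r <- sqrt((new[i, 1] - pl$centers[, 1])^2 + (new[i, 2] - pl$centers[, 2])^2)
    eta <- ifelse(r == 0, 0, r^2 * log(r)) * pl$kernel_sign
    sum(eta * pl$c) + sum(c(1, new[i, 2], new[i, 1]) *
                            pl$d[c("x0y0", "x0y1", "x1y0")])
  }, 0)
  expect_lt(max(abs(predict_surface(f, new) - pred_oracle)), 1e-8)
})

test_that("ordinary kriging reproduces a smooth field", {
  g <- unit_grid()
  z <- exp(-((g[, 1] - 0.3)^2 + (g[, 2] + 0.2)^2))
  f <- fit_surface(g, z, "kriging", 0)
  expect_true(f$params$variogram$model %in%
                c("spherical", "exponential", "gaussian"))
  expect_lt(f$training_rmse, 0.05)
  # fixed-family fits work too
  f2 <- fit_surface(g, z, "kriging", 2)
  expect_identical(f2$params$variogram$model, "exponential")
})

test_that("cross-validation selects the generating model and is seeded", {
  g <- unit_grid()
  z <- 0.5 + g[, 1]^2 + 0.8 * g[, 2]^2
  cands <- data.frame(family = "polynomial", order = c(1, 2))
  cv <- crossvalidate_surfaces(g, z, cands, k = 10, seed = 42)
  expect_equal(cv$best$order, 2)
  expect_lt(cv$table$rmse[cv$table$order == 2], 1e-10)
  expect_gt(cv$table$rmse[cv$table$order == 1], 0.1)

  cv_again <- crossvalidate_surfaces(g, z, cands, k = 10, seed = 42)
  expect_identical(cv, cv_again)
  cv_other <- crossvalidate_surfaces(g, z + with_seed(1, rnorm(64, 0, 0.1)),
                                     cands, k = 5, seed = 7)
  expect_identical(cv_other$seed, 7)
  expect_identical(cv_other$folds, 5)
})

test_that("k = n cross-validation equals analytic leave-one-out", {
  pts <- with_seed(12, cbind(runif(24, -1, 1), runif(24, -1, 1)))
  z <- 1 + pts[, 1] - 2 * pts[, 2] + with_seed(13, rnorm(24, 0, 0.2))
  cv <- crossvalidate_surfaces(pts, z,
                               data.frame(family = "polynomial", order = 1),
                               k = 24, seed = 1)
  # hat-matrix identity: LOO residual_i = e_i / (1 - h_ii)
  X <- cbind(1, pts[, 2], pts[, 1])  # any column order spans the same space
  H <- X %*% solve(crossprod(X), t(X))
  e <- z - H %*% z
  loo <- sqrt(mean((e / (1 - diag(H)))^2))
  expect_equal(cv$table$rmse[1], loo, tolerance = 1e-10)
})

test_that("unfittable candidates are flagged, not dropped", {
  pts <- unit_grid(4)  # 16 points: degree-5 poly (21 params) cannot fit
  z <- pts[, 1] + pts[, 2]
  cv <- crossvalidate_surfaces(pts, z,
                               data.frame(family = "polynomial", order = c(1, 5)),
                               k = 4, seed = 3)
  expect_true(cv$table$failed[cv$table$order == 5])
  expect_true(is.na(cv$table$rmse[cv$table$order == 5]))
  expect_equal(cv$best$order, 1)
})

test_that("noise never improves expected out-of-fold error", {
  g <- unit_grid()
  clean <- 0.2 + g[, 1]^2 + 0.5 * g[, 2]
  cands <- data.frame(family = "polynomial", order = 2)
  rmse_pair <- vapply(1:20, function(s) {
    noisy <- clean + with_seed(100 + s, rnorm(64, 0, 0.1))
    c(crossvalidate_surfaces(g, clean, cands, k = 10, seed = s)$best_rmse,
      crossvalidate_surfaces(g, noisy, cands, k = 10, seed = s)$best_rmse)
  }, numeric(2))
  expect_gt(mean(rmse_pair[2, ] - rmse_pair[1, ]), 0)
})

test_that("fit-predict round trip reproduces the training RMSE", {
  g <- unit_grid()
  z <- with_seed(31, exp(-g[, 1]^2) + 0.1 * rnorm(64))
  for (fam_ord in list(c("polynomial", 3), c("tps", 3), c("kriging", 0))) {
    f <- fit_surface(g, z, fam_ord[[1]], as.integer(fam_ord[[2]]))
    expect_equal(sqrt(mean((predict_surface(f, g) - z)^2)), f$training_rmse)
  }
})
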