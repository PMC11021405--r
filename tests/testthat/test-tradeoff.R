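# lookup surface: returns preset values at a fixed set of positions
# (analytic_surface already coerces query positions to an n x 2 matrix)
lookup_surface <- function(pos, values) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  analytic_surface(function(p) {
    idx <- vapply(seq_len(nrow(p)), function(i) {
      d <- (pos[, 1] - p[i, 1])^2 + (pos[, 2] - p[i, 2])^2
      which.min(d)
    }, 1L)
    values[idx]
  })
}

test_that("combined landscape is the weighted sum of its surfaces", {
  g <- unit_grid(4)
  f1 <- with_seed(1, runif(16)); f2 <- with_seed(2, runif(16))
  expect_equal(combined_landscape(g, f1, f2, 1)$height, f1)
  expect_equal(combined_landscape(g, f1, f2, 0)$height, f2)
  cl <- combined_landscape(g, f1, f1, 0.37)
  expect_equal(cl$height, f1)
  expect_equal(combined_landscape(g, f1, f2, 0.25)$height, 0.25 * f1 + 0.75 * f2)
  expect_error(combined_landscape(g, f1[-1], f2, 0.5), "congruent")
  expect_error(combined_landscape(g, f1, f2, 1.2), "\\[0, 1\\]")
})

test_that("log-fitness is the log height ratio to the landscape maximum", {
  grid2 <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  f1 <- lookup_surface(grid2, c(0.2, 0.4, 0.6, 1.0))
  f2 <- lookup_surface(grid2, c(1.0, 0.5, 0.3, 0.1))
  # z at cell 3, w = 0.5: height 0.45; combined heights over the grid are
  # (0.60, 0.45, 0.45, 0.55), so the maximum is 0.60 -> ln(0.45 / 0.60)
  expect_equal(log_fitness(c(0, 1), 0.5, f1, f2, grid2), log(0.45 / 0.60))
  expect_equal(log_fitness(c(0, 1), 0.5, f1, f2, grid2), -0.2876821,
               tolerance = 1e-6)
  # the cell achieving the maximum scores exactly 0
  expect_equal(log_fitness(c(1, 1), 1, f1, f2, grid2), 0)
  # any position scores <= 0
  for (i in 1:4) {
    for (w in c(0, 0.3, 0.8, 1)) {
      expect_lte(log_fitness(grid2[i, ], w, f1, f2, grid2), 1e-12)
    }
  }
})

test_that("non-positive combined heights error unless floored", {
  grid2 <- cbind(c(0, 1), c(0, 0))
  f1 <- lookup_surface(grid2, c(-0.2, 1))
  f2 <- lookup_surface(grid2, c(-0.1, 0.5))
  expect_error(log_fitness(c(0, 0), 0.5, f1, f2, grid2), "floor_eps")
  expect_lt(log_fitness(c(0, 0), 0.5, f1, f2, grid2, floor_eps = 1e-9), 0)
})

test_that("estimate_w finds endpoint and degenerate optima", {
  grid2 <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  f1 <- lookup_surface(grid2, c(0.2, 0.4, 0.6, 1.0))
  f2 <- lookup_surface(grid2, c(1.0, 0.5, 0.3, 0.1))
  # species at F1's scaled maximum: pure F1 weighting attains log-fitness 0;
  # the objective stays 0 for every w at which this cell tops the landscape,
  # so the estimate is the midpoint of that tying interval, reaching w = 1
  est <- estimate_w(c(1, 1), f1, f2, grid2)
  expect_equal(est$log_fitness, 0)
  expect_true(est$tied)
  expect_equal(est$w_tie_range[2], 1)
  expect_gt(est$w, 0.5)
  # identical surfaces: every w ties; midpoint convention gives 0.5
  est2 <- estimate_w(c(0, 0), f1, f1, grid2)
  expect_true(est2$tied)
  expect_equal(est2$w, 0.5)
  expect_equal(est2$w_tie_range, c(0, 1))
  expect_error(estimate_w(c(0, 0), f1, f2, grid2, resolution = 0.5),
               "resolution")
})

test_that("estimate_w matches the brute-force oracle within one step", {
  study <- small_study()
  spec <- study$config$spec
  surf <- analytic_performance(spec, study$grid)
  pos <- with_seed(71, cbind(runif(200, min(study$grid$pc1), max(study$grid$pc1)),
                             runif(200, min(study$grid$pc2), max(study$grid$pc2))))
  est <- species_w(pos, surf$f1, surf$f2, study$grid,
                   resolution = 0.001, floor_eps = 1e-9)
  orc <- vapply(seq_len(200), function(i)
    oracle_w(pos[i, ], spec, study$grid, w_step = 1e-4), 0)
  expect_lt(max(abs(est$w - orc)), 0.001 + 1e-9)
})

test_that("w surface covers the morphospace at the requested resolution", {
  study <- small_study()
  surf <- analytic_performance(study$config$spec, study$grid)
  ws <- w_surface(surf$f1, surf$f2, study$grid, n = 40, floor_eps = 1e-9)
  expect_equal(nrow(ws), 1600)
  expect_true(all(ws$w >= 0 & ws$w <= 1))
  expect_identical(attr(ws, "n_per_axis"), 40)

  # the cell holding F1's peak weights F1 at least as much as F2's peak cell
  f1v <- predict_surface(surf$f1, ws[, c("pc1", "pc2")])
  f2v <- predict_surface(surf$f2, ws[, c("pc1", "pc2")])
  expect_gte(ws$w[which.max(f1v)], ws$w[which.max(f2v)])
})

test_that("species weights agree with the w surface and are deterministic", {
  study <- small_study()
  surf <- analytic_performance(study$config$spec, study$grid)
  ws <- w_surface(surf$f1, surf$f2, study$grid, n = 8, floor_eps = 1e-9)
  sw <- species_w(ws[, c("pc1", "pc2")], surf$f1, surf$f2, study$grid,
                  floor_eps = 1e-9)
  expect_equal(sw$w, ws$w)
  dup <- species_w(rbind(c(0.01, 0.01), c(0.01, 0.01)),
                   surf$f1, surf$f2, study$grid, floor_eps = 1e-9)
  expect_equal(dup$w[1], dup$w[2])
})

test_that("weight estimates obey ratio invariance and surface symmetry", {
  study <- small_study()
  surf <- analytic_performance(study$config$spec, study$grid)
  pos <- with_seed(77, cbind(runif(30, min(study$grid$pc1), max(study$grid$pc1)),
                             runif(30, min(study$grid$pc2), max(study$grid$pc2))))
  base <- species_w(pos, surf$f1, surf$f2, study$grid, floor_eps = 1e-9)

  # common positive rescaling of both surfaces changes nothing
  s1 <- analytic_surface(function(p) 3.7 * predict_surface(surf$f1, p))
  s2 <- analytic_surface(function(p) 3.7 * predict_surface(surf$f2, p))
  scaled <- species_w(pos, s1, s2, study$grid, floor_eps = 1e-9)
  expect_equal(scaled$w, base$w)
  expect_equal(scaled$log_fitness, base$log_fitness, tolerance = 1e-10)

  # swapping F1 and F2 maps w -> 1 - w
  swapped <- species_w(pos, surf$f2, surf$f1, study$grid, floor_eps = 1e-9)
  expect_equal(swapped$w, 1 - base$w, tolerance = 1e-12)
})

test_that("log-fitness is continuous in w at fixed position", {
  study <- small_study()
  surf <- analytic_performance(study$config$spec, study$grid)
  pos <- c(mean(range(study$grid$pc1)), mean(range(study$grid$pc2)))
  ws <- seq(0, 1, by = 0.001)
  lf <- vapply(ws, function(w)
    log_fitness(pos, w, surf$f1, surf$f2, study$grid, floor_eps = 1e-9), 0)
  # increments vanish as the grid refines: no jumps
  expect_lt(max(abs(diff(lf))), 0.02)
})
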