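test_that("window construction tiles the weight range as specified", {
  w <- make_windows(0, 1, step = 0.25, size = 0.5)
  expect_equal(w$start, c(0, 0.25, 0.5))
  expect_equal(w$end, c(0.5, 0.75, 1))

  w2 <- make_windows(0, 0.4, step = 0.2, size = 0.2)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$start, c(0, 0.2))

  # count formula on random geometries
  for (s in 1:5) {
    par <- with_seed(s, c(runif(1, 0, 0.2), runif(1, 0.5, 1),
                          runif(1, 0.001, 0.05), runif(1, 0.05, 0.2)))
    if (par[2] - par[1] < par[4]) next
    w3 <- make_windows(par[1], par[2], step = par[3], size = par[4])
    expect_equal(nrow(w3),
                 floor((par[2] - par[1] - par[4]) / par[3] + 1e-9) + 1)
    expect_true(all(w3$end <= par[2] + 1e-9))
  }
  expect_error(make_windows(0, 0.005, 0.0002, 0.011), "smaller than one window")
})

test_that("w volume counts half-open window membership", {
  study <- small_study()
  surf <- analytic_performance(study$config$spec, study$grid)
  ws <- w_surface(surf$f1, surf$f2, study$grid, n = 40, floor_eps = 1e-9)
  expect_equal(w_volume(ws$w, c(0, 1 + 1e-9)), 1600)
  expect_equal(w_volume(ws$w, c(2, 3)), 0)

  vals <- c(0.1, 0.2, 0.2, 0.3, 0.35, 0.4, 0.55, 0.6, 0.9)
  expect_equal(w_volume(vals, c(0.2, 0.4)), 4)  # 0.2, 0.2, 0.3, 0.35; 0.4 out
  expect_equal(w_volume(vals, c(0.9, 0.95)), 1)
})

test_that("multivariate variance is the trace of the covariance matrix", {
  expect_equal(multivariate_variance(rbind(c(0, 0), c(2, 0))), 2)
  expect_equal(multivariate_variance(matrix(5, 4, 7)), 0)
  m <- with_seed(14, matrix(rnorm(20 * 50), 20, 50))
  expect_equal(multivariate_variance(m), sum(diag(cov(m))))
  expect_error(multivariate_variance(m[1, , drop = FALSE]), "2 rows")

  # invariant to column permutation and per-column shifts
  m2 <- m[, sample(50)] ; m2[, 3] <- m2[, 3] + 100
  expect_equal(multivariate_variance(m2), multivariate_variance(m))
})

test_that("position clustering selects K by BIC and is deterministic", {
  # coincident points collapse to one blob
  same <- matrix(0.5, 6, 2)
  lab <- cluster_positions(same, max_k = 5, seed = 1)
  expect_identical(attr(lab, "k"), 1L)

  # two well-separated blobs
  pts <- with_seed(9, rbind(cbind(rnorm(15, 0, 0.1), rnorm(15, 0, 0.1)),
                            cbind(rnorm(15, 5, 0.1), rnorm(15, 5, 0.1))))
  lab2 <- cluster_positions(pts, max_k = 5, seed = 2)
  expect_identical(attr(lab2, "k"), 2L)
  expect_equal(length(unique(lab2[1:15])), 1)
  expect_equal(length(unique(lab2[16:30])), 1)
  expect_true(lab2[1] != lab2[16])

  lab3 <- cluster_positions(pts, max_k = 5, seed = 2)
  expect_identical(unclass(lab2), unclass(lab3))
})

test_that("windowed disparity follows the two-species and clustering rules", {
  wins <- make_windows(0, 1, step = 0.2, size = 0.2)
  grid_w <- seq(0, 0.999, length.out = 100)
  pos <- with_seed(4, cbind(rnorm(10), rnorm(10)))
  shapes <- with_seed(5, matrix(rnorm(10 * 12), 10, 12))

  # a window holding one species reports volume but undefined disparity
  sw <- c(0.05, rep(0.5, 9))
  wd <- windowed_disparity(sw, pos, shapes, wins, grid_w, seed = 1)
  expect_equal(wd$n_species[1], 1)
  expect_true(is.na(wd$disparity[1]))
  expect_equal(wd$volume[1], sum(grid_w >= 0 & grid_w < 0.2))

  # all species in one cluster: summed disparity = plain multivariate variance
  pos_tight <- with_seed(6, matrix(rnorm(20, 0, 0.05), 10, 2))
  wd2 <- windowed_disparity(rep(0.5, 10), pos_tight, shapes, wins, grid_w,
                            seed = 1, max_k = 1)
  i <- which(wd2$n_species == 10)
  expect_true(all(wd2$n_clusters[i] == 1))
  expect_equal(wd2$disparity[i], rep(multivariate_variance(shapes), length(i)))

  # well-separated position groups are never merged, and removing the
  # between-cluster spread shrinks the summed disparity below the pooled one
  pos_two <- rbind(pos_tight[1:5, ], pos_tight[6:10, ] + 8)
  shapes_two <- rbind(shapes[1:5, ], shapes[6:10, ] + 5)
  wd3 <- windowed_disparity(rep(0.5, 10), pos_two, shapes_two, wins, grid_w,
                            seed = 1)
  j <- which(wd3$n_species == 10)[1]
  expect_gte(wd3$n_clusters[j], 2)
  lab <- cluster_positions(pos_two, max_k = 5, seed = 1)
  expect_length(intersect(lab[1:5], lab[6:10]), 0)
  expect_lt(wd3$disparity[j], multivariate_variance(shapes_two))

  expect_error(windowed_disparity(sw[-1], pos, shapes, wins, grid_w),
               "misaligned")
})

test_that("association reports Pearson, Spearman and xi coherently", {
  x <- c(1, 2, 3, 4, 5)
  a <- association(x, x, seed = 1)
  expect_equal(a["pearson", "estimate"], 1)
  expect_equal(a["spearman", "estimate"], 1)
  # strictly monotone y over n distinct x: xi = 1 - 3/(n+1)
  expect_equal(a["xi", "estimate"], 0.5)
  y7 <- c(2, 5, 9, 11, 20, 21, 30)
  expect_equal(association(1:7, y7, seed = 1)["xi", "estimate"], 1 - 3 / 8)

  # direct formula re-implementation on random pairs
  set.seed(20); xr <- rnorm(50); yr <- rnorm(50)
  a2 <- association(xr, yr, seed = 99)
  r <- rank(yr)[order(xr)]
  xi_direct <- 1 - 3 * sum(abs(diff(r))) / (50^2 - 1)
  expect_equal(a2["xi", "estimate"], xi_direct, tolerance = 1e-12)

  # scaling both variables by positive constants changes nothing
  a3 <- association(3 * xr, 7 * yr, seed = 99)
  expect_equal(a3$estimate, a2$estimate, tolerance = 1e-12)

  # undefined entries removed pairwise
  xna <- c(xr, NA, 1); yna <- c(yr, 2, NA)
  expect_equal(attr(association(xna, yna, seed = 1), "n"), 50)
  expect_error(association(rep(1, 5), 1:5), "constant")
})

test_that("non-overlapping window volumes never exceed the cell count", {
  study <- small_study()
  surf <- analytic_performance(study$config$spec, study$grid)
  ws <- w_surface(surf$f1, surf$f2, study$grid, n = 20, floor_eps = 1e-9)
  wins <- make_windows(0, 1, step = 0.1, size = 0.1)
  vols <- vapply(seq_len(nrow(wins)), function(i)
    w_volume(ws$w, c(wins$start[i], wins$end[i])), 0)
  expect_lte(sum(vols), 400)
})
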