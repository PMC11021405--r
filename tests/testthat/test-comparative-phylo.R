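test_that("model covariances match their closed forms and limits", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(model_vcv(two, "BM")), diag(2))

  tr <- fixture_tree(n = 8, seed = 3)
  S <- ape::vcv.phylo(tr)
  expect_equal(model_vcv(tr, "BM", list(sigma2 = 2.5)), 2.5 * S)

  # EB at r -> 0 recovers BM
  v_eb <- model_vcv(tr, "EB", list(r = -1e-9))
  expect_lt(max(abs(v_eb - S)), 1e-8)
  expect_error(model_vcv(tr, "EB", list(r = 0.1)), "<= 0")

  nonultra <- ape::read.tree(text = "((a:1,b:2):1,c:4);")
  expect_error(model_vcv(nonultra, "OU", list(alpha = 1)), "ultrametric")
})

test_that("the OU covariance matches exact branch-wise simulation", {
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,(c:0.7,d:0.7):0.3);")
  alpha <- 1.5; sigma2 <- 1
  V <- model_vcv(tr, "OU", list(alpha = alpha, sigma2 = sigma2))

  # exact OU transitions along each branch, vectorised over replicates;
  # the root starts at the stationary optimum (= 0)
  nrep <- 100000
  simulate_tips <- function(seed) {
    with_seed(seed, {
      vals <- matrix(NA_real_, max(tr$edge), nrep)  # tips + internal nodes
      vals[5, ] <- 0                                # root
      edges <- tr$edge; lens <- tr$edge.length
      for (e in seq_len(nrow(edges))) {
        t_ <- lens[e]
        m <- vals[edges[e, 1], ] * exp(-alpha * t_)
        s <- sqrt(sigma2 * (1 - exp(-2 * alpha * t_)) / (2 * alpha))
        vals[edges[e, 2], ] <- m + rnorm(nrep, 0, s)
      }
      t(vals[1:4, ])
    })
  }
  tips <- simulate_tips(42)
  emp <- cov(tips)  # tip numbering matches tip.label order
  expect_lt(max(abs(emp - unname(V))), 0.01)
})

test_that("AICc follows its defining arithmetic", {
  expect_equal(aicc(-10, 2, 20), 24.7059, tolerance = 1e-4)
  expect_equal(aicc(-10, 2, 20), -2 * -10 + 2 * 2 + 2 * 2 * 3 / 17)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("BM fitting matches the closed-form GLS solution on a star tree", {
  tr <- star_tree(20)
  y <- with_seed(6, setNames(rnorm(20, 3, 1.4), tr$tip.label))
  fit <- fit_trait_model(y, tr, "BM")
  expect_equal(fit$params$z0, mean(y))
  expect_equal(fit$params$sigma2, mean((y - mean(y))^2))
  expect_equal(fit$k, 2)
  ll_direct <- sum(dnorm(y, mean(y), sqrt(fit$params$sigma2), log = TRUE))
  expect_equal(fit$loglik, ll_direct)
})

test_that("BM simulations are recovered by AICc model comparison", {
  tr <- gen_tree(100, seed = 9)
  wins <- 0; sig_err <- numeric(40)
  for (r in 1:40) {
    y <- with_seed(1000 + r, {
      edges <- tr$edge; nn <- max(edges)
      vals <- numeric(nn); vals[101] <- 0
      for (e in seq_len(nrow(edges)))
        vals[edges[e, 2]] <- vals[edges[e, 1]] +
          rnorm(1, 0, sqrt(tr$edge.length[e]))
      setNames(vals[1:100], tr$tip.label)
    })
    tab <- fit_trait_models(y, tr)
    if (tab$model[1] == "BM") wins <- wins + 1
    sig_err[r] <- attr(tab, "fits")$BM$params$sigma2
  }
  expect_gt(wins, 20)                 # BM preferred in the majority
  expect_lt(abs(mean(sig_err) - 1), 0.2)  # sigma^2 within 20% on average
})

test_that("PGLS reduces to OLS on a star tree and matches GLS algebra", {
  tr <- star_tree(15)
  x <- with_seed(11, setNames(rnorm(15), tr$tip.label))
  y <- 2 + 0.8 * x + with_seed(12, rnorm(15, 0, 0.3))
  names(y) <- tr$tip.label
  fit <- pgls(y, matrix(x, dimnames = list(names(x), "x")), tr,
              n_perm = 199, seed = 1)
  ols <- lm(y ~ x)
  expect_equal(unname(drop(fit$coefficients)), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-8)

  # perfect fit
  fit2 <- pgls(x, matrix(x, dimnames = list(names(x), "x")), tr, n_perm = 0)
  expect_equal(fit2$r2, 1)
  expect_equal(unname(fit2$coefficients[2, 1]), 1)

  # explicit (X' V^-1 X)^-1 X' V^-1 y oracle on a non-star tree
  tr2 <- fixture_tree(n = 10, seed = 8)
  x2 <- with_seed(13, setNames(rnorm(10), tr2$tip.label))
  y2 <- with_seed(14, setNames(rnorm(10), tr2$tip.label))
  fit3 <- pgls(y2, matrix(x2, dimnames = list(names(x2), "x")), tr2, n_perm = 0)
  V <- ape::vcv.phylo(tr2); Vi <- solve(V)
  X <- cbind(1, x2[tr2$tip.label])
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y2[tr2$tip.label])
  expect_equal(unname(drop(fit3$coefficients)), unname(drop(beta)),
               tolerance = 1e-10)
  expect_error(pgls(y2, cbind(x2, x2), tr2), "singular")
})

test_that("PGLS permutation detects a real slope and AICc ranks designs", {
  tr <- fixture_tree(n = 30, seed = 21)
  x <- with_seed(22, setNames(rnorm(30), tr$tip.label))
  y <- 1 + x + with_seed(23, setNames(rnorm(30, 0, 0.2), tr$tip.label))
  fit <- pgls(y, matrix(x, dimnames = list(names(x), "x")), tr,
              n_perm = 199, seed = 5)
  expect_lt(fit$p, 0.05)
  tab <- pgls_polynomial(y, x, tr, degrees = 0:2, n_perm = 99, seed = 5)
  expect_equal(nrow(tab), 3)
  expect_gt(tab$aicc[1], min(tab$aicc))  # intercept-only loses to linear
  expect_equal(tab$degree[which.min(tab$aicc)], 1)
})

test_that("independent contrasts follow the pruning formulas", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  ct <- pic_contrasts(setNames(c(0, 2), c("a", "b")), two)
  expect_equal(abs(unname(ct)), 2 / sqrt(2))

  tr <- fixture_tree(n = 12, seed = 31)
  expect_equal(unname(pic_contrasts(setNames(rep(4, 12), tr$tip.label), tr)),
               rep(0, 11))

  # BM-simulated trait: mean squared standardized contrast estimates sigma^2
  tr2 <- gen_tree(200, seed = 33)
  y <- with_seed(34, {
    edges <- tr2$edge; vals <- numeric(max(edges)); vals[201] <- 0
    for (e in seq_len(nrow(edges)))
      vals[edges[e, 2]] <- vals[edges[e, 1]] +
        rnorm(1, 0, sqrt(2 * tr2$edge.length[e]))
    setNames(vals[1:200], tr2$tip.label)
  })
  msc <- mean(pic_contrasts(y, tr2)^2)
  expect_lt(abs(msc - 2) / 2, 0.15)
})

test_that("Mantel Z is the raw cross-product and permutation p is exact", {
  m1 <- matrix(0, 3, 3); m1[lower.tri(m1)] <- c(1, 2, 3)
  m1 <- m1 + t(m1)
  m2 <- matrix(0, 3, 3); m2[lower.tri(m2)] <- c(4, 5, 6)
  m2 <- m2 + t(m2)
  res <- mantel(m1, m2, n_perm = 99, seed = 1)
  expect_equal(res$z, 4 + 10 + 18)

  # self-association is maximally significant
  d <- as.matrix(dist(with_seed(41, matrix(rnorm(20), 10, 2))))
  self <- mantel(d, d, n_perm = 999, seed = 2)
  expect_lte(self$p, 0.01)

  # n = 4: permutation p approximates the exhaustive null over 24 relabelings
  d1 <- as.matrix(dist(c(0, 1, 3, 6))); d2 <- as.matrix(dist(c(2, 2.5, 4, 9)))
  z_obs <- sum(d1[lower.tri(d1)] * d2[lower.tri(d2)])
  idx <- 1:4
  z_all <- apply(expand.grid(rep(list(idx), 4)), 1, function(pp) {
    if (length(unique(pp)) < 4) return(NA_real_)
    dp <- d2[pp, pp]
    sum(d1[lower.tri(d1)] * dp[lower.tri(dp)])
  })
  z_all <- z_all[!is.na(z_all)]
  p_exact <- mean(z_all >= z_obs - 1e-12)
  res4 <- mantel(d1, d2, n_perm = 9999, seed = 3)
  expect_lt(abs(res4$p - p_exact), 0.03)
})

test_that("phylogenetic PCA reduces to ordinary PCA on a star tree", {
  tr <- star_tree(12)
  X <- with_seed(51, matrix(rnorm(12 * 4), 12, 4,
                            dimnames = list(tr$tip.label, NULL)))
  pp <- ppca(X, tr)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  for (j in seq_len(ncol(rot))) {   # apply the same sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  expect_equal(unname(pp$eigenvectors), unname(rot), tolerance = 1e-8)
  expect_equal(pp$eigenvalues, unname(pr$sdev^2), tolerance = 1e-8)

  # invertibility: scores back-transform to the data
  rec <- pp$scores %*% t(pp$eigenvectors) +
    matrix(pp$phylo_mean, 12, 4, byrow = TRUE)
  expect_equal(rec, X, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("the evolutionary covariance matches its GLS formula", {
  tr <- fixture_tree(n = 6, seed = 55)
  X <- with_seed(56, matrix(rnorm(6 * 3), 6, 3,
                            dimnames = list(tr$tip.label, NULL)))
  pp <- ppca(X, tr)
  V <- ape::vcv.phylo(tr); Vi <- solve(V); one <- rep(1, 6)
  a <- drop(solve(t(one) %*% Vi %*% one) %*% t(one) %*% Vi %*% X)
  Xc <- sweep(X, 2, a)
  R <- t(Xc) %*% Vi %*% Xc / 5
  expect_equal(pp$evol_vcv, R, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rate associations behave for identical, null and PIC cases", {
  tr <- fixture_tree(n = 30, seed = 61)
  rates <- data.frame(id = tr$tip.label,
                      rate = with_seed(62, rlnorm(30)))
  res <- rate_association(rates, rates, tr)
  expect_equal(res$branch["pearson", "estimate"], 1)
  expect_equal(res$tip["spearman", "estimate"], 1)
  expect_equal(res$pic["pearson_origin", "estimate"], 1)

  # independent lognormal rates are mostly uncorrelated
  small_r <- vapply(1:60, function(s) {
    ra <- with_seed(700 + s, rlnorm(100))
    rb <- with_seed(900 + s, rlnorm(100))
    abs(cor(ra, rb))
  }, 0)
  expect_gte(mean(small_r < 0.2), 0.9)

  # PIC block equals direct computation from contrasts
  rB <- data.frame(id = tr$tip.label, rate = with_seed(63, rlnorm(30)))
  res2 <- rate_association(rates, rB, tr)
  pa <- pic_contrasts(setNames(rates$rate, rates$id), tr)
  pb <- pic_contrasts(setNames(rB$rate, rB$id), tr)
  r0 <- sum(pa * pb) / sqrt(sum(pa^2) * sum(pb^2))
  expect_equal(res2$pic["pearson_origin", "estimate"], r0)
  expect_error(rate_association(rates, data.frame(id = "zz", rate = 1)),
               "shared")
})

test_that("BM likelihood is invariant to tip order", {
  tr <- fixture_tree(n = 12, seed = 71)
  y <- with_seed(72, setNames(rnorm(12), tr$tip.label))
  f1 <- fit_trait_model(y, tr, "BM")
  f2 <- fit_trait_model(y[sample(names(y))], tr, "BM")
  expect_equal(f1$loglik, f2$loglik)
  V <- model_vcv(tr, "BM")
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})
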