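#' Generalized Procrustes alignment
#'
#' Least-squares superimposition of a sample of landmark configurations:
#' each configuration is translated to the origin, scaled to unit centroid
#' size and rotated onto the current mean shape; the mean is re-estimated and
#' the procedure iterated until the mean changes by less than `tol`. Aligned
#' configurations are finally projected orthogonally onto the tangent space
#' at the mean shape.
#'
#' Rotations are proper by default (no reflections); set
#' `allow_reflection = TRUE` to permit improper rotations.
#'
#' @param sample a `landmark_sample`, a `p x 3 x n` array, or a list of
#'   `p x 3` matrices (at least two configurations).
#' @param tol convergence tolerance on the root-mean-square change of the
#'   mean shape between iterations.
#' @param max_iter maximum number of alignment iterations.
#' @param allow_reflection logical, see Details.
#' @param project logical; apply the tangent-space projection (default TRUE).
#' @return An object of class `gpa_alignment`: `aligned` (`p x 3 x n` array of
#'   tangent-space coordinates), `rotated` (pre-projection unit-size aligned
#'   coordinates), `centroid_sizes`, `mean_shape` (`p x 3`), `objective`
#'   (per-iteration sum of squared distances to the mean), `iterations`,
#'   `species`, `clade`.
#' @export
gpa <- function(sample, tol = 1e-10, max_iter = 100,
                allow_reflection = FALSE, project = TRUE) {
  if (!inherits(sample, "landmark_sample")) sample <- landmark_sample(sample)
  n <- sample$n_specimens; p <- sample$n_landmarks
  if (n < 2) stopf("GPA needs at least 2 configurations")

  cs <- numeric(n)
  conf <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sample$coords[, , i]
    ctr <- colMeans(m)
    mc <- sweep(m, 2, ctr)
    cs[i] <- sqrt(sum(mc^2))
    if (cs[i] <= sqrt(.Machine$double.eps))
      stopf("specimen '%s' has zero centroid size", sample$species[i])
    conf[[i]] <- mc / cs[i]
  }

  mean_shape <- conf[[1]]
  objective <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    for (i in seq_len(n))
      conf[[i]] <- conf[[i]] %*% optimal_rotation(conf[[i]], mean_shape,
                                                  allow_reflection)
    new_mean <- Reduce(`+`, conf) / n
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    objective[iter] <- sum(vapply(conf, function(m) sum((m - new_mean)^2), 0))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if ((iter > 1 && delta < tol) || iter >= max_iter) break
  }

  rotated <- array(unlist(conf), dim = c(p, 3, n),
                   dimnames = dimnames(sample$coords))

  aligned <- rotated
  if (project) {
    # orthogonal projection onto the tangent hyperplane {y : <y, m> = 1}
    mvec <- flatten_config(mean_shape)
    for (i in seq_len(n)) {
      v <- flatten_config(rotated[, , i])
      aligned[, , i] <- unflatten_config(v + (1 - sum(v * mvec)) * mvec, p)
    }
  }
  # the reported mean is the mean of the aligned (projected) configurations
  mean_out <- apply(aligned, c(1, 2), mean)

  structure(list(aligned = aligned, rotated = rotated, centroid_sizes = cs,
                 mean_shape = mean_out, objective = objective,
                 iterations = iter, converged = iter < max_iter,
                 species = sample$species, clade = sample$clade),
            class = "gpa_alignment")
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat(sprintf(
    "gpa_alignment: %d specimens, %d landmarks; %d iterations (%s)\n",
    dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
    if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}
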