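#' Assemble a sample of 3D landmark configurations
#'
#' The central input container of the pipeline: a `p x 3 x n` array of
#' homologous landmark coordinates (one slice per specimen), with species
#' labels and optional clade assignments (e.g. placental vs marsupial roles).
#'
#' @param coords numeric array `p x 3 x n` (landmarks x dimensions x
#'   specimens), or a list of `p x 3` matrices.
#' @param species character vector of specimen labels (length `n`); defaults
#'   to the array's `dimnames` or `sp1..spn`.
#' @param clade optional character/factor of clade labels per specimen.
#' @return An object of class `landmark_sample` with elements `coords`,
#'   `species`, `clade`, `n_landmarks`, `n_specimens`.
#' @export
landmark_sample <- function(coords, species = NULL, clade = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    p <- unique(vapply(coords, nrow, 1L))
    if (length(p) != 1L)
      stopf("all configurations must share the same landmark count (got %s)",
            paste(p, collapse = ", "))
    coords <- array(unlist(coords), dim = c(p, 3, length(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stopf("coords must be a p x 3 x n array of 3D landmarks")
  if (!all(is.finite(coords))) stopf("landmark coordinates contain non-finite values")
  p <- dim(coords)[1]; n <- dim(coords)[3]
  if (p < 3) stopf("at least 3 landmarks per configuration are required")
  if (is.null(species)) species <- dimnames(coords)[[3]] %||% paste0("sp", seq_len(n))
  if (length(species) != n) stopf("species labels (%d) do not match specimens (%d)",
                                  length(species), n)
  if (anyDuplicated(species)) stopf("species labels must be unique")
  if (!is.null(clade)) {
    clade <- as.character(clade)
    if (length(clade) != n) stopf("clade labels must match the specimen count")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"), species)
  structure(list(coords = coords, species = as.character(species), clade = clade,
                 n_landmarks = p, n_specimens = n),
            class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  cat(sprintf("landmark_sample: %d specimens, %d 3D landmarks\n",
              x$n_specimens, x$n_landmarks))
  if (!is.null(x$clade)) {
    tb <- table(x$clade)
    cat("clades:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances between each landmark and
#' the configuration centroid -- the size measure removed by Procrustes
#' superimposition. Equals the Frobenius norm of the centered coordinate
#' matrix.
#'
#' @param config a `p x 3` (or `p x k`) numeric matrix, or a
#'   `landmark_sample` (then a vector of sizes is returned).
#' @return Positive scalar (or vector over specimens).
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_sample"))
    return(apply(config$coords, 3, centroid_size))
  m <- as.matrix(config)
  if (nrow(m) < 2) stopf("centroid size needs at least 2 landmarks")
  if (!all(is.finite(m))) stopf("non-finite coordinates")
  ctr <- colMeans(m)
  cs <- sqrt(sum(sweep(m, 2, ctr)^2))
  if (cs <= sqrt(.Machine$double.eps))
    stopf("degenerate configuration: all landmarks coincide (zero centroid size)")
  cs
}

# flatten p x 3 -> length 3p vector, column-major (all x, all y, all z)
flatten_config <- function(m) as.vector(as.matrix(m))
unflatten_config <- function(v, p) matrix(v, nrow = p, ncol = 3,
                                          dimnames = list(NULL, c("x", "y", "z")))

#' Procrustes distance between two configurations
#'
#' Partial Procrustes distance: both configurations are centered, scaled to
#' unit centroid size and optimally rotated onto each other; the distance is
#' the Frobenius norm of the remaining difference.
#'
#' @param a,b `p x 3` matrices with matching landmark counts.
#' @param allow_reflection logical; permit improper rotations.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("configurations differ in dimensions")
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  ac <- ac / sqrt(sum(ac^2)); bc <- bc / sqrt(sum(bc^2))
  r <- optimal_rotation(ac, bc, allow_reflection)
  sqrt(sum((ac %*% r - bc)^2))
}

# rotation R minimising ||X R - Y||_F; det(R) = +1 unless reflections allowed
optimal_rotation <- function(x, y, allow_reflection = FALSE) {
  s <- svd(crossprod(x, y))
  r <- s$u %*% t(s$v)
  if (!allow_reflection && det(r) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    r <- u %*% t(s$v)
  }
  r
}
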