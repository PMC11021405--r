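# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_env <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small random landmark sample around the deterministic base configuration
random_landmark_sample <- function(n = 6, p = 10, sd = 0.05, seed = 1) {
  base <- base_configuration(p)
  with_seed(seed, landmark_sample(
    lapply(seq_len(n), function(i) base + matrix(rnorm(3 * p, 0, sd), p, 3))))
}

# a compact synthetic study reused across test files
small_study <- function() {
  cache_fixture("small_study", function()
    gen_study(synthetic_config(n_tips = 40, n_landmarks = 12, seed = 11)))
}

# the default-size study used by the heavier, study-level tests
default_study <- function() {
  cache_fixture("default_study", function() gen_study(synthetic_config(seed = 1)))
}

# 8 x 8 grid on [-1, 1]^2 for surface-fitting tests
unit_grid <- function(n = 8) {
  as.matrix(expand.grid(pc1 = seq(-1, 1, length.out = n),
                        pc2 = seq(-1, 1, length.out = n)))
}

# a random unit-depth pure-birth tree fixture
fixture_tree <- function(n = 10, seed = 5) gen_tree(n, seed = seed)

# star tree with unit-length branches
star_tree <- function(n) {
  tr <- ape::read.tree(text = paste0("(", paste0("t", seq_len(n), ":1",
                                                 collapse = ","), ");"))
  tr
}

# planted rank-1 form-function data shared by PLS unit and acceptance tests:
# shape = t a' + noise, func = [t b1, t b2] + noise
planted_pls_data <- function(n, q, noise = 0, seed = 1, a = NULL, b = c(1, 0.6)) {
  with_seed(seed, {
    t_var <- rnorm(n)
    if (is.null(a)) a <- { v <- rnorm(q); v / sqrt(sum(v^2)) }
    shape <- outer(t_var, a) + matrix(rnorm(n * q, 0, noise), n, q)
    func <- cbind(t_var * b[1], t_var * b[2]) +
      matrix(rnorm(n * 2, 0, noise), n, 2)
    list(shape = shape, func = func, t = t_var, a = a, b = b)
  })
}
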