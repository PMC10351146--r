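# Shared fixtures: all built in code, sized for speed.

tiny_config <- function(scale = 0.02, n_chromosomes = 2, n_generations = 9) {
  program_config(scale = scale, n_chromosomes = n_chromosomes,
                 n_generations = n_generations)
}

tiny_founders <- function(seed = 42, ...) {
  make_founders(tiny_config(...), seed)
}

# independent path-counting kinship oracle (recursive, memo-free; fine for
# toy pedigrees): a(i, j) on the relationship scale
path_kinship <- function(sire, dam) {
  a <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i == j) {
      return(1 + 0.5 * a(sire[i], dam[i]))
    }
    if (j > i) { k <- i; i <- j; j <- k }  # i is the younger
    0.5 * (a(sire[i], j) + a(dam[i], j))
  }
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# textbook pedigrees for NRM checks
textbook_pedigrees <- function() {
  list(
    # Mrode-style 6-animal pedigree
    list(sire = c(0, 0, 1, 1, 4, 5), dam = c(0, 0, 2, 0, 3, 2)),
    # full-sib mating producing an inbred animal
    list(sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4)),
    # three generations of half sibs
    list(sire = c(0, 0, 0, 1, 1, 4, 4), dam = c(0, 0, 0, 2, 3, 5, 3))
  )
}

random_ocs_problem <- function(n, k, C = NULL) {
  a <- rnorm(n)
  X <- matrix(rnorm((n + 1) * 6), n + 1)
  R <- tcrossprod(X) / 12 + diag(n + 1) * 0.25
  if (is.null(C)) {
    # anchor the bound near the attainable range so both feasible and
    # binding instances occur
    C <- stats::quantile(diag(R), 0.5) / (2 * k) + runif(1, 0, 0.2)
  }
  ocs_problem(a, R, k, C)
}

# dense generalized-least-squares oracle for the animal model
gls_blup <- function(y, rec, K, lambda) {
  Zm <- diag(nrow(K))[rec, , drop = FALSE]
  V <- Zm %*% K %*% t(Zm) + diag(length(y)) * lambda
  one <- rep(1, length(y))
  Vi <- solve(V)
  mu <- drop(solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% y))
  list(mu = mu, a = drop(K %*% t(Zm) %*% Vi %*% (y - mu)))
}

# strip provenance attributes for numeric comparisons
bare <- function(x) {
  x <- as.matrix(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# one small end-to-end run shared across test files (built once per session)
.run_cache <- new.env(parent = emptyenv())
cached_tiny_run <- function() {
  if (is.null(.run_cache$res)) {
    cfg <- program_config(scale = 0.04, n_chromosomes = 2, n_generations = 9)
    .run_cache$cfg <- cfg
    .run_cache$res <- run_experiment(
      cfg, replicates = 1,
      scenarios = scenario_specs()[c(1, 9), ],  # VR1 Base, Pedigree
      master_seed = 424242)
  }
  list(res = .run_cache$res, cfg = .run_cache$cfg)
}
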