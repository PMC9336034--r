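# shared fixtures, all generated in code

# a valid random parameter surface with well-behaved scales
random_surface <- function(n, M = 2L, seed = 1L) {
  set.seed(seed)
  w <- matrix(rexp(n * M), n, M)
  w <- w / rowSums(w)
  mixture_surface(weights = w,
                  means = matrix(rnorm(n * M, sd = 2), n, M),
                  scales = matrix(runif(n * M, 0.3, 2), n, M))
}

# small two-component dataset with a clear vertical gap
toy_mixture_data <- function(n = 200L, seed = 1L) {
  cfg <- dgp_config("independent", n = n, seed = seed)
  simulate_dataset(cfg)
}

# finite-difference gradient of the MDN loss at a weight configuration;
# the step balances central-difference truncation against roundoff in an
# objective of magnitude ~10^2 (h = 1e-6 leaves ~3e-5 roundoff noise on
# small-gradient coordinates, h = 1e-4 shows visible truncation)
fd_gradient <- function(w, x, y, h = 1e-5) {
  par <- flatten_weights(w)
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h
    fp <- mdn_nll_grad(unflatten_weights(par + e, w), x, y)$nll
    fm <- mdn_nll_grad(unflatten_weights(par - e, w), x, y)$nll
    (fp - fm) / (2 * h)
  }, numeric(1))
}

# build a minimal mixref_fit around given MDN weights (for detector tests)
fake_mdn_fit <- function(weights, x = seq(0, 1, length.out = 100L)) {
  structure(list(method = "bfgs_full", init_kind = "random", seed = 1L,
                 weights = weights, loss = 0, converged = TRUE,
                 standardization = structure(list(x_mean = 0, x_sd = 1,
                                                  y_mean = 0, y_sd = 1),
                                             class = "standardization"),
                 x = x, n = length(x), M = weights$M, B = weights$H,
                 relabeled = FALSE),
            class = "mixref_fit")
}
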