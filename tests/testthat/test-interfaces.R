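test_that("standardization centers, scales and round-trips", {
  expect_equal(standardize(c(5, 9), c(0, 2))$y, c(-sqrt(0.5), sqrt(0.5)))
  set.seed(2)
  x <- runif(200, 10, 20); y <- rnorm(200, 100, 7)
  std <- standardize(x, y)
  expect_equal(mean(std$x), 0, tolerance = 1e-10)
  expect_equal(sd(std$y), 1, tolerance = 1e-10)
  cs <- std$constants
  expect_equal(cs$x_mean, sum(x) / length(x))
  expect_equal(cs$y_sd, sqrt(sum((y - mean(y))^2) / (length(y) - 1)))
  expect_equal(std$y * cs$y_sd + cs$y_mean, y, tolerance = 1e-12)
  expect_error(standardize(rep(1, 10), rnorm(10)), "variance")
})

test_that("destandardization maps the surface affinely and preserves weights", {
  s <- random_surface(20L, seed = 6)
  id <- structure(list(x_mean = 0, x_sd = 1, y_mean = 0, y_sd = 1),
                  class = "standardization")
  expect_equal(destandardize_surface(s, id)$means, s$means)
  cs <- structure(list(x_mean = 2, x_sd = 3, y_mean = 10, y_sd = 4),
                  class = "standardization")
  d <- destandardize_surface(s, cs)
  expect_identical(d$weights, s$weights)
  expect_equal(d$means, s$means * 4 + 10)
  # affine equivariance of Gaussian quantiles: destandardizing then taking
  # the quantile equals destandardizing the standardized-scale quantile
  q_after <- component_quantile(d, 1L, 0.975)
  q_before <- component_quantile(s, 1L, 0.975) * 4 + 10
  expect_equal(q_after, q_before, tolerance = 1e-12)
})

test_that("restart selection returns the minimum-loss non-degenerate fit", {
  ds <- toy_mixture_data(700L, seed = 14)
  one <- fit_mixture(ds$x, ds$y, method = "bfgs_full", init = "random",
                     seed = 3L)
  viaRestart <- fit_with_restarts(ds$x, ds$y, method = "bfgs_full",
                                  init = "random", restarts = 1L, seed = 3L)
  expect_equal(viaRestart$loss, one$loss)
  multi <- fit_with_restarts(ds$x, ds$y, method = "bfgs_full", init = "random",
                             restarts = 5L, seed = 11L)
  keep <- !multi$restart_degenerate
  expect_equal(multi$loss, min(multi$restart_losses[keep]))
  expect_false(detect_location_crossing(multi))
})

test_that("reference intervals are monotone across probabilities", {
  ds <- toy_mixture_data(800L, seed = 19)
  fit <- fit_mixture(ds$x, ds$y, method = "em", init = "custom")
  grid <- seq(0.05, 0.95, length.out = 25L)
  tab <- reference_intervals(fit, grid, probabilities = c(0.5, 0.025, 0.975, 0.25))
  expect_s3_class(tab, "reference_interval_table")
  expect_identical(names(tab), c("grid", "alpha1", "q0.025", "q0.25", "q0.5",
                                 "q0.975"))
  qcols <- as.matrix(tab[, -(1:2)])
  expect_true(all(diff(t(qcols)) >= 0))
  # p = 0.5 column is the main mean curve; two-path equality with the
  # destandardized component quantile
  surf <- predict(fit, grid)
  expect_equal(tab$q0.5, surf$means[, 1L], tolerance = 1e-12)
  surf_std <- predict(fit, grid, scale = "standardized")
  cs <- fit$standardization
  expect_equal(tab$q0.975,
               component_quantile(surf_std, 1L, 0.975) * cs$y_sd + cs$y_mean,
               tolerance = 1e-10)
  # an unrelabeled fit is rejected
  raw <- fit_mixture(ds$x, ds$y, method = "em", relabel = FALSE)
  expect_error(reference_intervals(raw, grid), "relabel")
})

test_that("fitting an affinely transformed outcome transforms the intervals", {
  ds <- toy_mixture_data(700L, seed = 25)
  grid <- seq(0.1, 0.9, length.out = 11L)
  f1 <- fit_mixture(ds$x, ds$y, method = "em", init = "custom", seed = 2)
  f2 <- fit_mixture(ds$x, 3 * ds$y + 7, method = "em", init = "custom",
                    seed = 2)
  t1 <- reference_intervals(f1, grid)
  t2 <- reference_intervals(f2, grid)
  # the transformed data standardize to the same values only up to rounding,
  # so the two fits agree to the EM convergence tolerance, not bitwise
  expect_lt(max(abs(t2$q0.975 - (3 * t1$q0.975 + 7))), 0.05)
  expect_lt(max(abs(t2$alpha1 - t1$alpha1)), 0.005)
})

test_that("the CLI simulates, fits and studies end to end, deterministically", {
  tmp <- withr::local_tempdir()
  sim <- file.path(tmp, "sim.csv")
  expect_identical(suppressMessages(
    cli_main(c("simulate", "--setting", "independent", "--n", "500",
               "--seed", "4", "--out", sim))), 0L)
  expect_true(file.exists(sim) && file.exists(paste0(sim, ".config")))
  df <- read.csv(sim)
  expect_identical(names(df), c("x", "y", "label"))
  expect_identical(nrow(df), 500L)

  out1 <- file.path(tmp, "iv1.csv"); out2 <- file.path(tmp, "iv2.csv")
  args <- c("fit", "--data", sim, "--method", "em", "--seed", "2",
            "--grid-n", "40")
  expect_identical(suppressMessages(cli_main(c(args, "--out", out1))), 0L)
  expect_identical(suppressMessages(cli_main(c(args, "--out", out2))), 0L)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  tab <- read.csv(out1)
  expect_identical(nrow(tab), 40L)
  expect_identical(names(tab)[1:3], c("grid", "alpha1", "q0.025"))

  # a config file overrides flags
  cfgf <- file.path(tmp, "override.cfg")
  writeLines(c("method = bfgs-const", "grid-n = 10"), cfgf)
  out3 <- file.path(tmp, "iv3.csv")
  expect_identical(suppressMessages(
    cli_main(c(args, "--out", out3, "--config", cfgf))), 0L)
  expect_identical(nrow(read.csv(out3)), 10L)

  # malformed inputs exit nonzero
  expect_identical(suppressMessages(cli_main(c("fit", "--data", sim,
                                               "--method", "nope"))), 1L)
  bad <- file.path(tmp, "bad.csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_identical(suppressMessages(cli_main(c("fit", "--data", bad))), 1L)
  expect_identical(suppressMessages(cli_main("frobnicate")), 1L)
})

test_that("the reduced study subcommand writes per-run and summary tables", {
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "study")
  settingsR <- 2L
  expect_identical(suppressMessages(
    cli_main(c("study", "--R", "2", "--seed", "3",
               "--algorithms", "em", "--out", prefix))), 0L)
  runs <- read.csv(paste0(prefix, "_runs.csv"))
  expect_identical(nrow(runs), 4L * settingsR)
  smry <- read.csv(paste0(prefix, "_summary.csv"))
  expect_identical(nrow(smry), 4L)
  expect_true(all(c("crossing", "mean_ise_alpha") %in% names(smry)))
})
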