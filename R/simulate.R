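#' Data-generating process configuration
#'
#' Describes the synthetic two-component conditional Gaussian mixture used by
#' the simulation harness: a uniform covariate on (0, 1), a lower
#' "physiological" component and an upper "pathological" component whose
#' means and standard deviations vary nonlinearly with the covariate, and a
#' mixture weight for the physiological component that is either constant
#' (`independent`) or itself a nonlinear function of the covariate
#' (`dependent`).
#'
#' The default truth functions are package defaults chosen to produce two
#' clearly stacked components with mild overlap:
#' \eqn{\mu_1(x) = 1 + 1.5\sin(\pi x)}, \eqn{\sigma_1(x) = 0.25 + 0.15x},
#' \eqn{\mu_2(x) = \mu_1(x) + 2.5 - x}, \eqn{\sigma_2(x) = 0.5},
#' \eqn{\alpha_1(x) = 0.70 + 0.20\sin(\pi x)} in the dependent setting and
#' \eqn{\alpha_1 = 0.80} in the independent one. All functions are
#' injectable, so an alternative process can be dropped in unchanged.
#'
#' @param setting `"dependent"` or `"independent"` mixture weights.
#' @param n sample size.
#' @param seed integer seed.
#' @param mean1,mean2 functions x -> component means; `mean2(x)` must exceed
#'   `mean1(x)` on \[0, 1\].
#' @param scale1,scale2 functions x -> component standard deviations (> 0).
#' @param weight1 function x -> physiological-component weight, with values
#'   in \[0.05, 0.99\] (keeps both components identifiable); ignored in the
#'   independent setting in favor of `const_weight1`.
#' @param const_weight1 constant physiological weight for the independent
#'   setting (default 0.80).
#' @return An object of class `dgp_config`.
#' @export
dgp_config <- function(setting = c("dependent", "independent"),
                       n = 5000L, seed = 1L,
                       mean1 = function(x) 1 + 1.5 * sin(pi * x),
                       scale1 = function(x) 0.25 + 0.15 * x,
                       mean2 = function(x) 1 + 1.5 * sin(pi * x) + 2.5 - x,
                       scale2 = function(x) rep(0.5, length(x)),
                       weight1 = function(x) 0.70 + 0.20 * sin(pi * x),
                       const_weight1 = 0.80) {
  setting <- match.arg(setting)
  wfun <- if (setting == "independent") {
    force(const_weight1)
    function(x) rep(const_weight1, length(x))
  } else weight1
  xs <- seq(0, 1, length.out = 101L)
  if (any(mean2(xs) <= mean1(xs)))
    stop("mean2 must exceed mean1 over the whole unit interval")
  w <- wfun(xs)
  if (any(w < 0.05) || any(w > 0.99))
    stop("weight1 must stay within [0.05, 0.99] for identifiability")
  if (any(scale1(xs) <= 0) || any(scale2(xs) <= 0))
    stop("scale functions must be strictly positive")
  structure(list(setting = setting, n = as.integer(n), seed = as.integer(seed),
                 mean1 = mean1, mean2 = mean2,
                 scale1 = scale1, scale2 = scale2, weight1 = wfun),
            class = "dgp_config")
}

#' @export
print.dgp_config <- function(x, ...) {
  cat(sprintf("Synthetic mixture DGP: %s weights, n = %d, seed = %d\n",
              x$setting, x$n, x$seed))
  invisible(x)
}

#' Draw a synthetic dataset
#'
#' Samples `n` observations: covariate uniform on (0, 1), latent component
#' label Bernoulli with the configured physiological weight, outcome Gaussian
#' with that component's mean and scale. The true labels are retained for
#' evaluation but must never be passed to the estimators.
#'
#' @param config a [dgp_config].
#' @return list of class `labeled_dataset` with `x`, `y`, `label` (1 =
#'   physiological, 2 = pathological) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  set.seed(config$seed)
  n <- config$n
  x <- stats::runif(n)
  a1 <- config$weight1(x)
  label <- 2L - stats::rbinom(n, 1L, a1)  # 1 with prob a1, else 2
  mu <- ifelse(label == 1L, config$mean1(x), config$mean2(x))
  sg <- ifelse(label == 1L, config$scale1(x), config$scale2(x))
  y <- stats::rnorm(n, mu, sg)
  structure(list(x = x, y = y, label = label, config = config),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled synthetic dataset: n = %d (%.1f%% physiological)\n",
              length(x$x), 100 * mean(x$label == 1L)))
  invisible(x)
}

#' True parameter curves of the generating process
#'
#' @param config a [dgp_config].
#' @param grid covariate values in \[0, 1\].
#' @return a [mixture_surface] of the configured truth functions on the grid.
#' @export
true_curves <- function(config, grid) {
  stopifnot(inherits(config, "dgp_config"))
  if (any(grid < 0) || any(grid > 1)) stop("grid must lie within [0, 1]")
  a1 <- config$weight1(grid)
  mixture_surface(cbind(a1, 1 - a1),
                  cbind(config$mean1(grid), config$mean2(grid)),
                  cbind(config$scale1(grid), config$scale2(grid)))
}

#' The factorial simulation-study design
#'
#' The study crosses the two weight settings with two sample sizes,
#' `{dependent, independent} x {5000, 10000}`; each of the four cells is
#' replicated `R` times (default 100, i.e. 400 datasets in total).
#'
#' @param R replicates per cell, attached as attribute `"R"`.
#' @return list of four [dgp_config] templates (seed set per replicate by the
#'   harness).
#' @export
study_grid <- function(R = 100L) {
  grid <- list()
  for (setting in c("dependent", "independent"))
    for (n in c(10000L, 5000L))
      grid[[length(grid) + 1L]] <- dgp_config(setting = setting, n = n)
  attr(grid, "R") <- as.integer(R)
  grid
}
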