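#' Tanh basis specification
#'
#' A deterministic basis of B shifted/scaled tanh functions covering the
#' covariate range \[lower, upper\]. The b-th basis is
#' \eqn{\tanh(a_b + c_b x)} with offset
#' \eqn{a_b = -B\,(lower + \frac{b-1}{B-1}(upper - lower)) / (upper - lower)}
#' and common slope \eqn{c_b = B / (upper - lower)}, so the inflection points
#' are spread evenly over the range. The same construction gives the hidden
#' layer of the mixture density network its regression-spline analogue.
#'
#' @param count number of bases B (>= 2; the offset formula divides by B - 1).
#' @param lower,upper covariate range endpoints, `upper > lower`.
#' @return An object of class `basis_spec` with elements `count`, `lower`,
#'   `upper`, `offsets` (a_b) and `slope` (c_b, common to all bases).
#' @export
basis_spec <- function(count, lower, upper) {
  if (count < 2L) stop("basis count must be at least 2")
  if (!(upper > lower)) stop("upper must exceed lower strictly")
  b <- seq_len(count)
  rng <- upper - lower
  offsets <- -count * (lower + (b - 1) / (count - 1) * rng) / rng
  slope <- count / rng
  structure(list(count = as.integer(count), lower = lower, upper = upper,
                 offsets = offsets, slope = slope),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("tanh basis: B = %d on [%g, %g], slope %g\n",
              x$count, x$lower, x$upper, x$slope))
  invisible(x)
}

#' Evaluate the tanh basis
#'
#' @param covariate numeric vector. Values outside the spec's range are
#'   permitted (the bases extrapolate smoothly towards their asymptotes),
#'   which is needed when predicting on a grid slightly wider than the
#'   training covariates.
#' @param spec a [basis_spec].
#' @return matrix (n x B), column b equal to `tanh(offsets[b] + slope * x)`.
#' @export
tanh_basis <- function(covariate, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  outer(covariate, seq_len(spec$count),
        function(x, b) tanh(spec$offsets[b] + spec$slope * x))
}

# design matrix [1, tanh basis] used by the OLS init and the EM regressions
.basis_design <- function(covariate, spec) {
  cbind(1, tanh_basis(covariate, spec))
}

#' Custom starting weights for the mixture density network
#'
#' Builds partially customized initial network weights that position the two
#' component location curves above each other from the start, so that the
#' optimizer does not have to break the label symmetry itself. The outcome is
#' regressed on the tanh basis by ordinary least squares; the 10% and 90%
#' empirical quantiles of the residuals are added to the intercept to form two
#' vertically shifted copies of the OLS curve, which seed the two location
#' output heads (the lower shift becomes component 1). The hidden layer is
#' fixed at the basis offsets and slope, and all remaining weights (scale and
#' mixture-weight heads) stay randomly initialized.
#'
#' @param x,y standardized covariate and outcome vectors.
#' @param spec a [basis_spec] consistent with `range(x)`.
#' @param seed integer seed for the random part of the initialization.
#' @param M number of mixture components (the shift construction requires 2).
#' @param alpha_connected should the mixture-weight head be connected to the
#'   hidden layer (covariate-dependent weights)?
#' @param scale_activation `"exponential"` or `"softplus"` output activation
#'   for the standard deviations.
#' @return An [mdn_weights] object.
#' @export
custom_mdn_init <- function(x, y, spec = basis_spec(5L, min(x), max(x)),
                            seed = 1L, M = 2L,
                            alpha_connected = TRUE,
                            scale_activation = c("exponential", "softplus")) {
  scale_activation <- match.arg(scale_activation)
  if (M != 2L) stop("the shifted-intercept construction is defined for M = 2")
  Z <- .basis_design(x, spec)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop(sprintf("rank-deficient basis design matrix (rank %d < %d columns); ",
                 qrz$rank, ncol(Z)),
         "increase the covariate spread or reduce the basis count")
  coef <- qr.coef(qrz, y)
  resid <- y - Z %*% coef
  qs <- stats::quantile(resid, c(0.10, 0.90), names = FALSE)

  H <- spec$count
  w <- glorot_init(H = H, M = M, seed = seed,
                   alpha_connected = alpha_connected,
                   scale_activation = scale_activation)
  w$W1 <- matrix(spec$slope, 1L, H)
  w$b1 <- spec$offsets
  w$Wm <- matrix(coef[-1L], H, M)          # both heads share the OLS curve
  w$bm <- c(coef[1L] + qs[1L], coef[1L] + qs[2L])
  w
}

#' CDF-based initial responsibilities for the EM algorithm
#'
#' Soft initial component assignments derived from the cumulative distribution
#' function of a single ("naive") Gaussian maximum-likelihood fit to the
#' outcome: observations high in the marginal distribution are initially
#' credited to the upper (pathological) component with probability
#' \eqn{\Phi((y - \hat\mu)/\hat\sigma)}, and to the lower (physiological)
#' component with the complement. Rows sum to 1 exactly.
#'
#' @param outcome numeric vector (n >= 2) with nonzero variance.
#' @return matrix (n x 2) of initial responsibilities; column 1 is the lower
#'   (main) component.
#' @export
em_initial_responsibilities <- function(outcome) {
  n <- length(outcome)
  if (n < 2L) stop("need at least two observations")
  mu <- mean(outcome)
  sigma <- sqrt(mean((outcome - mu)^2))  # ML variance (divisor n)
  if (sigma <= 0) stop("outcome has zero variance")
  upper <- unname(stats::pnorm((outcome - mu) / sigma))
  out <- cbind(1 - upper, upper)
  dimnames(out) <- NULL
  out
}

#' Random initial responsibilities
#'
#' Uniform-Dirichlet rows, the uninformative alternative to
#' [em_initial_responsibilities] used to demonstrate the label-switching
#' fragility of random starts.
#'
#' @param n number of observations.
#' @param M number of components.
#' @param seed integer seed.
#' @return matrix (n x M) with rows summing to 1.
#' @export
random_responsibilities <- function(n, M = 2L, seed = 1L) {
  set.seed(seed)
  g <- matrix(stats::rexp(n * M), n, M)
  g / rowSums(g)
}
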