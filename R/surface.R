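#' Conditional mixture parameter surface
#'
#' Container for the per-observation parameters of a conditional Gaussian
#' mixture: at each covariate value the mixture is described by component
#' weights \eqn{\alpha_m(x)}, means \eqn{\mu_m(x)} and standard deviations
#' \eqn{\sigma_m(x)}, stored as three n-by-M matrices.
#'
#' @param weights numeric matrix (n x M) of component weights; every row must
#'   sum to 1 and all entries must be nonnegative.
#' @param means numeric matrix (n x M) of component means (outcome units).
#' @param scales numeric matrix (n x M) of component standard deviations
#'   (outcome units); strictly positive.
#' @return An object of class `mixture_surface`.
#' @examples
#' s <- mixture_surface(weights = matrix(0.5, 2, 2),
#'                      means = cbind(c(0, 0), c(3, 3)),
#'                      scales = matrix(1, 2, 2))
#' mixture_pdf(s, c(0, 3))
#' @export
mixture_surface <- function(weights, means, scales) {
  weights <- as.matrix(weights); means <- as.matrix(means); scales <- as.matrix(scales)
  dimnames(weights) <- dimnames(means) <- dimnames(scales) <- NULL
  if (!all(dim(weights) == dim(means)) || !all(dim(weights) == dim(scales)))
    stop("weights, means and scales must have identical dimensions")
  n <- nrow(weights); M <- ncol(weights)
  if (n < 1L || M < 1L) stop("surface needs at least one row and one component")
  if (any(!is.finite(weights)) || any(!is.finite(means)) || any(!is.finite(scales)))
    stop("surface entries must be finite")
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  if (any(abs(rowSums(weights) - 1) > 1e-10))
    stop("every row of the weight matrix must sum to 1 (tolerance 1e-10)")
  if (any(scales <= 0)) stop("all scales must be strictly positive")
  structure(list(weights = weights, means = means, scales = scales,
                 n = n, M = M),
            class = "mixture_surface")
}

#' @export
print.mixture_surface <- function(x, ...) {
  cat(sprintf("Conditional Gaussian mixture surface: %d observations, %d components\n",
              x$n, x$M))
  cat(sprintf("  mean weight per component: %s\n",
              paste(sprintf("%.3f", colMeans(x$weights)), collapse = ", ")))
  invisible(x)
}

#' Mixture density
#'
#' Evaluates the conditional mixture density
#' \eqn{f(y \mid x) = \sum_m \alpha_m(x)\, N(y;\, \mu_m(x), \sigma_m(x))}
#' at one outcome value per surface row.
#'
#' @param surface a [mixture_surface].
#' @param outcome numeric vector, one outcome per surface row.
#' @param sigma_floor lower bound applied to the scales before evaluation,
#'   guarding against degenerate optimizer excursions. Default `1e-8`.
#' @return numeric vector of densities, strictly positive and finite.
#' @export
mixture_pdf <- function(surface, outcome, sigma_floor = 1e-8) {
  stopifnot(inherits(surface, "mixture_surface"))
  if (length(outcome) != surface$n)
    stop("outcome length must equal the number of surface rows")
  exp(.mixture_logpdf(surface, outcome, sigma_floor))
}

# row-wise max without apply() (the surfaces here can have 10^4+ rows)
.row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

# row-wise log f(y|x) with a log-sum-exp contract
.mixture_logpdf <- function(surface, outcome, sigma_floor = 1e-8) {
  s <- pmax(surface$scales, sigma_floor)
  lc <- log(surface$weights) +
    stats::dnorm(outcome, mean = surface$means, sd = s, log = TRUE)
  m <- .row_max(lc)
  m + log(rowSums(exp(lc - m)))
}

#' Mixture negative log-likelihood
#'
#' Computes \eqn{-\sum_i \ln \sum_m \alpha_m(x_i) N(y_i; \mu_m(x_i),
#' \sigma_m(x_i))} using a log-sum-exp evaluation so that well-separated
#' components do not underflow at large n.
#'
#' @inheritParams mixture_pdf
#' @return a single number, the negative log-likelihood.
#' @export
mixture_nll <- function(surface, outcome, sigma_floor = 1e-8) {
  stopifnot(inherits(surface, "mixture_surface"))
  if (length(outcome) == 0L) stop("empty dataset")
  if (length(outcome) != surface$n)
    stop("outcome length must equal the number of surface rows")
  -sum(.mixture_logpdf(surface, outcome, sigma_floor))
}

#' Component quantile curve
#'
#' Gaussian quantile of a single mixture component along the covariate:
#' \eqn{Q_p(x) = \mu_m(x) + \sigma_m(x)\,\Phi^{-1}(p)}. With the main
#' (physiological) component this is the age-dependent reference threshold.
#'
#' @param surface a [mixture_surface].
#' @param component component index m.
#' @param p probability in (0, 1).
#' @return numeric vector, the quantile at each surface row.
#' @export
component_quantile <- function(surface, component, p) {
  stopifnot(inherits(surface, "mixture_surface"))
  if (!(is.numeric(p) && length(p) == 1L && p > 0 && p < 1))
    stop("p must be a single probability strictly inside (0, 1)")
  if (component < 1L || component > surface$M) stop("component index out of range")
  surface$means[, component] + surface$scales[, component] * stats::qnorm(p)
}
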