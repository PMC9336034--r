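#' EM parameters for the tanh-basis mixture
#'
#' Parameters of the benchmark two-component Gaussian location-scale mixture
#' fitted by expectation-maximization: per component a coefficient vector for
#' the mean (intercept + B tanh bases) and one for the log standard
#' deviation, plus constant mixture weights.
#'
#' @param mean_coef list of per-component coefficient vectors (length B + 1).
#' @param logscale_coef list of per-component coefficient vectors
#'   (length B + 1) on the log-scale.
#' @param alpha numeric vector of constant mixture weights summing to 1.
#' @param spec the [basis_spec] the coefficients refer to.
#' @return An object of class `em_params`.
#' @export
em_params <- function(mean_coef, logscale_coef, alpha, spec) {
  M <- length(alpha)
  stopifnot(length(mean_coef) == M, length(logscale_coef) == M,
            inherits(spec, "basis_spec"))
  if (any(alpha <= 0) || abs(sum(alpha) - 1) > 1e-8)
    stop("mixture weights must be positive and sum to 1")
  structure(list(mean_coef = mean_coef, logscale_coef = logscale_coef,
                 alpha = as.numeric(alpha), spec = spec, M = M),
            class = "em_params")
}

#' Evaluate EM parameters on a covariate vector
#'
#' @param params an [em_params] object.
#' @param covariate numeric vector.
#' @param sigma_floor scale floor (default 1e-8).
#' @return a [mixture_surface].
#' @export
em_surface <- function(params, covariate, sigma_floor = 1e-8) {
  stopifnot(inherits(params, "em_params"))
  Z <- .basis_design(covariate, params$spec)
  ev <- .em_eval(Z, params, sigma_floor)
  alpha <- matrix(params$alpha, length(covariate), params$M, byrow = TRUE)
  mixture_surface(alpha, ev$mu, ev$sigma)
}

#' E-step: posterior responsibilities
#'
#' Computes \eqn{\pi_{im} = \alpha_m N(y_i; \mu_m(x_i), \sigma_m(x_i)) /
#' \sum_k \alpha_k N(y_i; \mu_k(x_i), \sigma_k(x_i))} on the log scale.
#'
#' @param x,y covariate and outcome vectors.
#' @param params an [em_params] object.
#' @param sigma_floor scale floor.
#' @return matrix (n x M) of responsibilities; rows sum to 1.
#' @export
e_step <- function(x, y, params, sigma_floor = 1e-8) {
  Z <- .basis_design(x, params$spec)
  .e_step_design(Z, y, params, sigma_floor)
}

# E-step given a pre-built design matrix (the EM loop caches Z)
.e_step_design <- function(Z, y, params, sigma_floor = 1e-8) {
  ev <- .em_eval(Z, params, sigma_floor)
  lc <- matrix(log(params$alpha), nrow(Z), params$M, byrow = TRUE) +
    stats::dnorm(y, mean = ev$mu, sd = ev$sigma, log = TRUE)
  mx <- .row_max(lc)
  if (any(!is.finite(mx))) stop("all components have vanishing density at some observation")
  p <- exp(lc - mx)
  p / rowSums(p)
}

# component means / scales from a design matrix
.em_eval <- function(Z, params, sigma_floor = 1e-8) {
  n <- nrow(Z)
  mu <- vapply(params$mean_coef, function(b) as.numeric(Z %*% b), numeric(n))
  sg <- vapply(params$logscale_coef, function(g) exp(as.numeric(Z %*% g)),
               numeric(n))
  list(mu = matrix(mu, n), sigma = pmax(matrix(sg, n), sigma_floor))
}

# observed-data NLL given a design matrix
.em_nll_design <- function(Z, y, params, sigma_floor = 1e-8) {
  ev <- .em_eval(Z, params, sigma_floor)
  lc <- matrix(log(params$alpha), nrow(Z), params$M, byrow = TRUE) +
    stats::dnorm(y, mean = ev$mu, sd = ev$sigma, log = TRUE)
  mx <- .row_max(lc)
  -sum(mx + log(rowSums(exp(lc - mx))))
}

# weighted Gaussian location-scale fit for one component:
# minimizes sum_i w_i * -log N(y_i; Z beta, exp(Z gamma)) by alternating
# exact WLS for beta and step-halved Fisher scoring for gamma (compiled).
.fit_component <- function(Z, y, w, start, fixed_logscale = NULL,
                           maxit = 100L, sigma_floor = 1e-8) {
  p <- ncol(Z)
  if (!is.null(fixed_logscale)) {
    # profile over beta only: weighted least squares with known sigma
    sig <- pmax(exp(as.numeric(Z %*% fixed_logscale)), sigma_floor)
    wls <- w / sig^2
    beta <- qr.coef(qr(Z * sqrt(wls)), y * sqrt(wls))
    return(list(beta = beta, gamma = fixed_logscale, ok = TRUE))
  }
  res <- try(cpp_fit_component(Z, y, w, start[seq_len(p)],
                               start[p + seq_len(p)], as.integer(maxit),
                               1e-9, sigma_floor), silent = TRUE)
  if (inherits(res, "try-error") || !all(is.finite(res$beta)) ||
      !all(is.finite(res$gamma))) {
    return(list(beta = start[seq_len(p)], gamma = start[p + seq_len(p)],
                ok = FALSE))
  }
  list(beta = as.numeric(res$beta), gamma = as.numeric(res$gamma),
       ok = isTRUE(res$ok))
}

#' M-step: weighted maximum-likelihood update
#'
#' For each component maximizes the responsibility-weighted Gaussian
#' log-likelihood over the mean and log-scale coefficient vectors (an inner
#' quasi-Newton optimization warm-started at the previous coefficients), and
#' updates the constant mixture weights to the responsibility means. If the
#' inner optimizer fails for a component, its previous coefficients are
#' retained and the update is flagged.
#'
#' @param x,y covariate and outcome vectors.
#' @param resp matrix (n x M) of responsibilities.
#' @param spec a [basis_spec].
#' @param previous optional [em_params] supplying warm starts.
#' @param fixed_logscale optional list of per-component log-scale coefficient
#'   vectors to hold fixed (then the mean update is closed-form weighted
#'   least squares).
#' @param inner_maxit iteration cap of the inner optimizer (default 100;
#'   the EM loop uses a small cap with warm starts, a generalized-EM
#'   update that still never increases the objective).
#' @return An [em_params] object with attribute `"ok"` (per-component inner
#'   optimizer status).
#' @export
m_step <- function(x, y, resp, spec, previous = NULL, fixed_logscale = NULL,
                   inner_maxit = 100L) {
  .m_step_design(.basis_design(x, spec), y, resp, spec, previous,
                 fixed_logscale, inner_maxit)
}

.m_step_design <- function(Z, y, resp, spec, previous = NULL,
                           fixed_logscale = NULL, inner_maxit = 100L) {
  M <- ncol(resp)
  p <- ncol(Z)
  alpha <- pmax(colMeans(resp), 1e-12)
  alpha <- alpha / sum(alpha)
  mean_coef <- vector("list", M); logscale_coef <- vector("list", M)
  ok <- logical(M)
  for (m in seq_len(M)) {
    w <- resp[, m]
    if (!is.null(fixed_logscale)) {
      fit <- .fit_component(Z, y, w, start = NULL,
                            fixed_logscale = fixed_logscale[[m]])
    } else {
      start <- if (!is.null(previous)) {
        c(previous$mean_coef[[m]], previous$logscale_coef[[m]])
      } else {
        # first pass: weighted least squares mean, constant log-scale
        beta0 <- qr.coef(qr(Z * sqrt(w)), y * sqrt(w))
        r <- y - Z %*% beta0
        s0 <- sqrt(max(sum(w * r^2) / sum(w), 1e-6))
        c(beta0, log(s0), rep(0, p - 1L))
      }
      fit <- .fit_component(Z, y, w, start, maxit = inner_maxit)
    }
    mean_coef[[m]] <- as.numeric(fit$beta)
    logscale_coef[[m]] <- as.numeric(fit$gamma)
    ok[m] <- fit$ok
  }
  out <- em_params(mean_coef, logscale_coef, alpha, spec)
  attr(out, "ok") <- ok
  out
}

#' Fit the mixture by expectation-maximization
#'
#' Alternates [m_step] and [e_step] from the given initial responsibilities
#' (the M-step comes first, since the initialization supplies observation
#' weights) until the observed-data negative log-likelihood improves by less
#' than `tol` or the iteration cap is reached. The observed-data NLL is
#' nonincreasing across iterations up to the inner-optimizer tolerance.
#'
#' @param x,y standardized covariate and outcome vectors.
#' @param init matrix (n x M) of initial responsibilities, e.g.
#'   [em_initial_responsibilities].
#' @param spec a [basis_spec] (default B = 5 on `range(x)`).
#' @param tol absolute NLL convergence tolerance (default 1e-6).
#' @param maxit EM iteration cap (default 500).
#' @param inner_maxit inner optimizer cap per M-step (default 15; warm
#'   starts make this a generalized-EM update, still monotone).
#' @return list with `params` ([em_params]), `loss` (final observed-data
#'   NLL), `iterations`, `converged` and `nll_trace`.
#' @export
fit_em <- function(x, y, init, spec = basis_spec(5L, min(x), max(x)),
                   tol = 1e-6, maxit = 500L, inner_maxit = 15L) {
  stopifnot(nrow(init) == length(x), length(x) == length(y))
  Z <- .basis_design(x, spec)
  params <- NULL
  resp <- init
  trace <- numeric(0)
  prev_nll <- Inf
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    params <- .m_step_design(Z, y, resp, spec, previous = params,
                             inner_maxit = inner_maxit)
    nll <- .em_nll_design(Z, y, params)
    trace <- c(trace, nll)
    if (is.finite(prev_nll) && abs(prev_nll - nll) < tol) {
      converged <- TRUE
      break
    }
    prev_nll <- nll
    resp <- .e_step_design(Z, y, params)
  }
  list(params = params, loss = trace[length(trace)], iterations = it,
       converged = converged, nll_trace = trace)
}
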