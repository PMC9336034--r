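#' Standardize covariate and outcome
#'
#' Centers and scales both columns to mean 0 and sample standard deviation 1
#' (n - 1 convention); all estimators are fitted on this scale and results
#' are mapped back afterwards.
#'
#' @param x,y numeric vectors of equal length (n >= 2), nonzero variance.
#' @return list with standardized `x`, `y` and `constants` (class
#'   `standardization`: `x_mean`, `x_sd`, `y_mean`, `y_sd`).
#' @export
standardize <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  cs <- structure(list(x_mean = mean(x), x_sd = stats::sd(x),
                       y_mean = mean(y), y_sd = stats::sd(y)),
                  class = "standardization")
  if (cs$x_sd <= 0 || cs$y_sd <= 0)
    stop("zero variance in x or y; standardization undefined")
  list(x = (x - cs$x_mean) / cs$x_sd, y = (y - cs$y_mean) / cs$y_sd,
       constants = cs)
}

#' Map a fitted surface back to the original outcome scale
#'
#' Means are mapped by \eqn{\mu \cdot s_y + \bar y}, scales by
#' \eqn{\sigma \cdot s_y}; mixture weights are unchanged.
#'
#' @param surface a [mixture_surface] on the standardized scale.
#' @param constants a `standardization` object from [standardize].
#' @return a [mixture_surface] on the original scale.
#' @export
destandardize_surface <- function(surface, constants) {
  stopifnot(inherits(surface, "mixture_surface"),
            inherits(constants, "standardization"))
  mixture_surface(surface$weights,
                  surface$means * constants$y_sd + constants$y_mean,
                  surface$scales * constants$y_sd)
}

#' Fit a conditional Gaussian mixture to unlabeled data
#'
#' Front end to the four estimators compared by the package. The data are
#' standardized internally; `bfgs_full` trains the mixture density network
#' with covariate-dependent mixture weights, `bfgs_const` the variant whose
#' mixture-weight units are disconnected from the hidden layer (constant
#' weights), `adam` the network trained by ADAM with early stopping
#' (softplus scale activation), and `em` the benchmark
#' expectation-maximization fit with tanh regression bases and constant
#' weights.
#'
#' @param x,y covariate and outcome vectors on their original scales.
#' @param method one of `"bfgs_full"`, `"bfgs_const"`, `"adam"`, `"em"`.
#' @param init `"custom"` (OLS-shifted location heads / CDF-based
#'   responsibilities) or `"random"` (glorot-uniform weights /
#'   uniform-Dirichlet responsibilities).
#' @param B number of tanh bases = hidden units (default 5).
#' @param M number of mixture components (default 2; the custom
#'   initializations require 2).
#' @param seed integer seed for every random element of the fit.
#' @param relabel relabel components so component 1 is the lower (main) one
#'   (default TRUE).
#' @param scale_activation scale-output activation; defaults to
#'   `"exponential"` for the BFGS variants and `"softplus"` for ADAM.
#' @param ... passed on to [train_bfgs], [train_adam] or [fit_em].
#' @return An object of class `mixref_fit`.
#' @export
fit_mixture <- function(x, y,
                        method = c("bfgs_full", "bfgs_const", "adam", "em"),
                        init = c("custom", "random"),
                        B = 5L, M = 2L, seed = 1L, relabel = TRUE,
                        scale_activation = NULL, ...) {
  method <- match.arg(method)
  init <- match.arg(init)
  std <- standardize(x, y)
  spec <- basis_spec(B, min(std$x), max(std$x))

  if (method == "em") {
    resp <- if (init == "custom") em_initial_responsibilities(std$y)
            else random_responsibilities(length(x), M, seed)
    res <- fit_em(std$x, std$y, resp, spec, ...)
    fit <- structure(list(method = method, init_kind = init, seed = seed,
                          params = res$params, loss = res$loss,
                          converged = res$converged,
                          iterations = res$iterations,
                          standardization = std$constants,
                          x = x, n = length(x), M = M, B = as.integer(B),
                          relabeled = FALSE),
                     class = "mixref_fit")
  } else {
    if (is.null(scale_activation))
      scale_activation <- if (method == "adam") "softplus" else "exponential"
    alpha_connected <- method != "bfgs_const"
    w0 <- if (init == "custom") {
      custom_mdn_init(std$x, std$y, spec, seed = seed, M = M,
                      alpha_connected = alpha_connected,
                      scale_activation = scale_activation)
    } else {
      glorot_init(H = B, M = M, seed = seed,
                  alpha_connected = alpha_connected,
                  scale_activation = scale_activation)
    }
    res <- if (method == "adam") train_adam(std$x, std$y, w0, seed = seed, ...)
           else train_bfgs(std$x, std$y, w0, ...)
    fit <- structure(list(method = method, init_kind = init, seed = seed,
                          weights = res$weights, loss = res$loss,
                          converged = res$converged,
                          standardization = std$constants,
                          x = x, n = length(x), M = M, B = as.integer(B),
                          relabeled = FALSE,
                          training = res[setdiff(names(res),
                                                 c("weights", "loss", "converged"))]),
                     class = "mixref_fit")
  }
  if (!is.finite(fit$loss)) fit$converged <- FALSE
  if (relabel) fit <- relabel_main(fit) else fit
}

#' @export
print.mixref_fit <- function(x, ...) {
  cat(sprintf("mixref fit: method = %s, init = %s, n = %d, M = %d\n",
              x$method, x$init_kind, x$n, x$M))
  cat(sprintf("  final NLL (standardized scale): %.4f; converged: %s; relabeled: %s\n",
              x$loss, x$converged, x$relabeled))
  invisible(x)
}

#' Predict the conditional mixture parameters
#'
#' @param object a `mixref_fit`.
#' @param newdata covariate values on the original scale (defaults to the
#'   training covariates).
#' @param scale `"original"` (destandardized, default) or `"standardized"`.
#' @param ... unused.
#' @return a [mixture_surface].
#' @export
predict.mixref_fit <- function(object, newdata = object$x,
                               scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  cs <- object$standardization
  xs <- (newdata - cs$x_mean) / cs$x_sd
  surf <- if (object$method == "em") em_surface(object$params, xs)
          else mdn_forward(object$weights, xs)
  if (scale == "original") destandardize_surface(surf, cs) else surf
}

#' Repeated-initialization fit with minimum-loss selection
#'
#' Runs the chosen estimator once per restart seed, discards runs flagged as
#' degenerate (a component with mean mixture weight below 0.05), and returns
#' the fit with the smallest final negative log-likelihood. All restart
#' losses are recorded for stability inspection.
#'
#' @inheritParams fit_mixture
#' @param restarts number of restarts (>= 1).
#' @param seed base seed; restart r uses `seed + r - 1`.
#' @return The selected `mixref_fit`, with `restart_losses`,
#'   `restart_seeds` and `restart_degenerate` fields attached.
#' @export
fit_with_restarts <- function(x, y, method = "bfgs_full", init = "random",
                              restarts = 10L, seed = 1L, ...) {
  stopifnot(restarts >= 1L)
  seeds <- seed + seq_len(restarts) - 1L
  fits <- lapply(seeds, function(s)
    fit_mixture(x, y, method = method, init = init, seed = s, ...))
  losses <- vapply(fits, `[[`, numeric(1), "loss")
  degen <- vapply(fits, detect_degenerate, logical(1))
  keep <- which(!degen & is.finite(losses))
  if (length(keep) == 0L)
    stop("all restarts produced degenerate fits (a component collapsed below ",
         "mean weight 0.05); the data may not support two components")
  best <- keep[which.min(losses[keep])]
  fit <- fits[[best]]
  fit$restart_losses <- losses
  fit$restart_seeds <- seeds
  fit$restart_degenerate <- degen
  fit
}

#' Reference-interval table of the main component
#'
#' Extracts the age-dependent quantile curves of the main (physiological)
#' component on the original scale — the continuous analogue of a
#' reference-interval table — together with the fitted physiological
#' mixture-weight curve.
#'
#' @param fit a relabeled `mixref_fit` (see [relabel_main]; [fit_mixture]
#'   relabels by default).
#' @param grid covariate values (original units).
#' @param probabilities quantile levels; default
#'   `c(0.025, 0.05, 0.1, 0.25, 0.75, 0.9, 0.95, 0.975)`.
#' @return data.frame of class `reference_interval_table` with columns
#'   `grid`, `alpha1` and one `q<p>` column per probability (sorted
#'   ascending, hence pointwise nondecreasing across columns).
#' @export
reference_intervals <- function(fit, grid,
                                probabilities = c(0.025, 0.05, 0.1, 0.25,
                                                  0.75, 0.9, 0.95, 0.975)) {
  stopifnot(inherits(fit, "mixref_fit"))
  if (!isTRUE(fit$relabeled))
    stop("reference intervals require a relabeled fit; call relabel_main() first")
  if (any(probabilities <= 0) || any(probabilities >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  probabilities <- sort(probabilities)
  surf <- predict(fit, grid, scale = "original")
  qs <- vapply(probabilities, function(p) component_quantile(surf, 1L, p),
               numeric(length(grid)))
  out <- data.frame(grid = grid, alpha1 = surf$weights[, 1L], qs)
  names(out) <- c("grid", "alpha1",
                  paste0("q", sub("0\\.", "0.", format(probabilities,
                                                       trim = TRUE, drop0trailing = TRUE))))
  class(out) <- c("reference_interval_table", "data.frame")
  out
}
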