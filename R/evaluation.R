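#' Relabel components so the main component comes first
#'
#' Because mixture component labels are interchangeable, fitted components
#' are unified by identifying the component with the smaller
#' \eqn{\sum_i \mu_m(x_i)} over the training covariates — the one mainly
#' positioned below the other — as the main (physiological) component,
#' m = 1. Exact ties preserve the current order.
#'
#' @param fit a `mixref_fit` with M = 2.
#' @param covariate covariate values (original scale) over which the
#'   location sums are compared; defaults to the training covariates.
#' @return The fit with components permuted if necessary and `relabeled`
#'   set to TRUE.
#' @export
relabel_main <- function(fit, covariate = fit$x) {
  stopifnot(inherits(fit, "mixref_fit"))
  if (fit$M != 2L) stop("relabeling is defined for two-component fits")
  surf <- predict(fit, covariate, scale = "standardized")
  if (sum(surf$means[, 2L]) < sum(surf$means[, 1L])) {
    perm <- c(2L, 1L)
    if (fit$method == "em") {
      p <- fit$params
      fit$params <- em_params(p$mean_coef[perm], p$logscale_coef[perm],
                              p$alpha[perm], p$spec)
    } else {
      w <- fit$weights
      fit$weights <- mdn_weights(w$W1, w$b1,
                                 w$Wa[, perm, drop = FALSE], w$ba[perm],
                                 w$Wm[, perm, drop = FALSE], w$bm[perm],
                                 w$Ws[, perm, drop = FALSE], w$bs[perm],
                                 alpha_connected = w$alpha_connected,
                                 scale_activation = w$scale_activation)
    }
  }
  fit$relabeled <- TRUE
  fit
}

# strict sign change of the location gap along a grid; touching zero without
# changing sign does not count
.crossing_from_means <- function(means) {
  d <- means[, 2L] - means[, 1L]
  s <- sign(d)
  s <- s[s != 0]
  length(s) > 1L && any(s[-1L] != s[-length(s)])
}

#' Detect location crossing of the fitted component means
#'
#' TRUE when the two fitted location curves swap order somewhere over the
#' grid — the label-switching failure mode in which each fitted "component"
#' mixes physiological and pathological regimes and the derived reference
#' intervals are invalid.
#'
#' @param fit a `mixref_fit` with M = 2.
#' @param grid at least 50 covariate values (original scale) spanning the
#'   covariate range; defaults to 201 points over the training range.
#' @return logical.
#' @export
detect_location_crossing <- function(fit,
                                     grid = seq(min(fit$x), max(fit$x),
                                                length.out = 201L)) {
  stopifnot(inherits(fit, "mixref_fit"))
  if (length(grid) < 50L) stop("crossing detection needs a grid of >= 50 points")
  surf <- predict(fit, grid, scale = "standardized")
  .crossing_from_means(surf$means)
}

#' Detect failure to identify two components
#'
#' TRUE when any component's mean fitted mixture weight over the data falls
#' below the identification threshold
#' \eqn{\frac{1}{n}\sum_i \alpha_m(x_i) \ge 0.05} (inclusive: exactly 0.05
#' still counts as identified).
#'
#' @param fit a `mixref_fit`.
#' @param covariate covariate values over which weights are averaged;
#'   defaults to the training covariates.
#' @param threshold identification threshold (default 0.05).
#' @return logical.
#' @export
detect_degenerate <- function(fit, covariate = fit$x, threshold = 0.05) {
  stopifnot(inherits(fit, "mixref_fit"))
  surf <- predict(fit, covariate, scale = "standardized")
  any(colMeans(surf$weights) < threshold)
}

#' Integrated squared error of a curve estimate
#'
#' Trapezoid quadrature of \eqn{\int (\hat\theta(x) - \theta(x))^2 dx} over
#' the common grid.
#'
#' @param estimated,truth numeric vectors, the two curves on `grid`.
#' @param grid sorted covariate grid.
#' @return nonnegative scalar.
#' @export
ise <- function(estimated, truth, grid) {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  stopifnot(length(estimated) == length(grid), length(truth) == length(grid))
  d2 <- (estimated - truth)^2
  sum(diff(grid) * (d2[-1L] + d2[-length(d2)]) / 2)
}

#' Run the simulation study
#'
#' For every combination of algorithm, initialization, study setting and
#' replicate: draw a dataset, fit (the estimators standardize internally and
#' see only covariate and outcome, never the labels), relabel so component 1
#' is the main component, flag location crossing and degeneracy, and — for
#' clean runs — score the integrated squared error of the main component's
#' weight, location, scale and 95%-quantile curves against the generating
#' truth on a 201-point grid, on the original scale. A failed fit is
#' recorded as a flagged row, never aborts the study.
#'
#' @param algorithms subset of `c("em", "bfgs_const", "bfgs_full", "adam")`.
#' @param inits subset of `c("custom", "random")`.
#' @param R replicates per cell.
#' @param base_seed base seed; every dataset and fit seed derives from it.
#' @param settings list of [dgp_config] templates (default [study_grid]).
#' @param grid_n evaluation grid size (default 201).
#' @param ... passed to [fit_mixture].
#' @return data.frame with one row per run: `algorithm`, `init`, `setting`,
#'   `n`, `replicate`, `seed`, `converged`, `crossing`, `degenerate`,
#'   `loss`, and `ise_alpha`, `ise_mu`, `ise_sigma`, `ise_q95` (NA unless
#'   the run is clean).
#' @export
run_study <- function(algorithms = c("em", "bfgs_const", "bfgs_full", "adam"),
                      inits = "custom", R = 100L, base_seed = 1L,
                      settings = study_grid(R), grid_n = 201L, ...) {
  grid <- seq(0, 1, length.out = grid_n)
  rows <- list()
  for (ci in seq_along(settings)) {
    template <- settings[[ci]]
    for (r in seq_len(R)) {
      data_seed <- base_seed + 10000L * ci + r
      config <- template
      config$seed <- data_seed
      ds <- simulate_dataset(config)
      truth <- true_curves(config, grid)
      truth_q95 <- component_quantile(truth, 1L, 0.95)
      for (alg in algorithms) for (ik in inits) {
        rec <- list(algorithm = alg, init = ik, setting = config$setting,
                    n = config$n, replicate = r, seed = data_seed,
                    converged = NA, crossing = NA, degenerate = NA,
                    loss = NA_real_, ise_alpha = NA_real_, ise_mu = NA_real_,
                    ise_sigma = NA_real_, ise_q95 = NA_real_)
        fit <- try(fit_mixture(ds$x, ds$y, method = alg, init = ik,
                               seed = data_seed + 1L, ...), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          rec$converged <- fit$converged
          rec$crossing <- detect_location_crossing(fit, grid)
          rec$degenerate <- detect_degenerate(fit)
          rec$loss <- fit$loss
          if (!rec$crossing && !rec$degenerate) {
            est <- predict(fit, grid, scale = "original")
            rec$ise_alpha <- ise(est$weights[, 1L], truth$weights[, 1L], grid)
            rec$ise_mu <- ise(est$means[, 1L], truth$means[, 1L], grid)
            rec$ise_sigma <- ise(est$scales[, 1L], truth$scales[, 1L], grid)
            rec$ise_q95 <- ise(component_quantile(est, 1L, 0.95), truth_q95,
                               grid)
          }
        }
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Summarize a simulation study
#'
#' Per (algorithm, init, setting, n) cell: number of runs, crossing and
#' degeneracy counts, and the mean integrated squared errors over clean
#' runs (crossing and degenerate runs excluded, as in the study design).
#'
#' @param records the data.frame returned by [run_study].
#' @return summary data.frame, one row per cell.
#' @export
summarize_study <- function(records) {
  key <- interaction(records$algorithm, records$init, records$setting,
                     records$n, drop = TRUE)
  out <- lapply(split(records, key), function(d) {
    clean <- d[!is.na(d$crossing) & !d$crossing & !d$degenerate, ]
    data.frame(algorithm = d$algorithm[1L], init = d$init[1L],
               setting = d$setting[1L], n = d$n[1L],
               runs = nrow(d),
               failed = sum(is.na(d$crossing)),
               crossing = sum(d$crossing, na.rm = TRUE),
               degenerate = sum(d$degenerate, na.rm = TRUE),
               clean = nrow(clean),
               mean_ise_alpha = mean(clean$ise_alpha),
               mean_ise_mu = mean(clean$ise_mu),
               mean_ise_sigma = mean(clean$ise_sigma),
               mean_ise_q95 = mean(clean$ise_q95))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
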