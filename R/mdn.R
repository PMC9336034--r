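#' Mixture density network weights
#'
#' The network has one input (the covariate), a single hidden layer of H tanh
#' units, and (K+1)M = 3M output units for a Gaussian mixture with M
#' components: M mixture-weight units (softmax), M location units (identity)
#' and M scale units (exponential or softplus activation). When
#' `alpha_connected = FALSE` the mixture-weight units are cut off from the
#' hidden layer — their hidden weights are frozen at zero and excluded from
#' the trainable parameter vector, so only the biases are trained and the
#' fitted mixture weights are constant in the covariate.
#'
#' @param W1 1 x H hidden weight matrix; `b1` hidden bias vector (length H).
#' @param Wa,ba,Wm,bm,Ws,bs head weight matrices (H x M) and bias vectors
#'   (length M) for the mixture-weight, location and scale outputs.
#' @param alpha_connected logical; are the mixture-weight units connected to
#'   the hidden layer?
#' @param scale_activation `"exponential"` or `"softplus"`.
#' @return An object of class `mdn_weights`.
#' @export
mdn_weights <- function(W1, b1, Wa, ba, Wm, bm, Ws, bs,
                        alpha_connected = TRUE,
                        scale_activation = c("exponential", "softplus")) {
  scale_activation <- match.arg(scale_activation)
  H <- length(b1); M <- length(ba)
  W1 <- matrix(W1, 1L, H); Wa <- matrix(Wa, H, M)
  Wm <- matrix(Wm, H, M); Ws <- matrix(Ws, H, M)
  if (!alpha_connected && any(Wa != 0))
    stop("with alpha_connected = FALSE the hidden-to-weight matrix must be zero")
  w <- list(W1 = W1, b1 = as.numeric(b1), Wa = Wa, ba = as.numeric(ba),
            Wm = Wm, bm = as.numeric(bm), Ws = Ws, bs = as.numeric(bs),
            alpha_connected = isTRUE(alpha_connected),
            scale_activation = scale_activation, H = H, M = M)
  if (any(!vapply(w[c("W1", "b1", "Wa", "ba", "Wm", "bm", "Ws", "bs")],
                  function(v) all(is.finite(v)), logical(1))))
    stop("network weights must be finite")
  structure(w, class = "mdn_weights")
}

#' @export
print.mdn_weights <- function(x, ...) {
  cat(sprintf("MDN weights: H = %d hidden units, M = %d components, %s scale, %s\n",
              x$H, x$M, x$scale_activation,
              if (x$alpha_connected) "covariate-dependent mixture weights"
              else "constant mixture weights"))
  cat(sprintf("  %d trainable parameters\n", length(flatten_weights(x))))
  invisible(x)
}

#' Flatten / rebuild the trainable parameter vector
#'
#' The flat layout is fixed (hidden weights, hidden biases, weight-head
#' matrix when connected, weight-head biases, location head, scale head) and
#' shared with the compiled loss, so the round trip is lossless.
#'
#' @param w an [mdn_weights] object.
#' @return `flatten_weights`: numeric vector of the trainable parameters.
#' @export
flatten_weights <- function(w) {
  stopifnot(inherits(w, "mdn_weights"))
  c(as.numeric(w$W1), w$b1,
    if (w$alpha_connected) as.numeric(w$Wa),
    w$ba, as.numeric(w$Wm), w$bm, as.numeric(w$Ws), w$bs)
}

#' @rdname flatten_weights
#' @param par flat parameter vector as produced by `flatten_weights`.
#' @param template an [mdn_weights] object supplying dimensions and flags.
#' @return `unflatten_weights`: an [mdn_weights] object.
#' @export
unflatten_weights <- function(par, template) {
  H <- template$H; M <- template$M
  k <- 0L
  take <- function(len) {
    out <- par[(k + 1L):(k + len)]; k <<- k + len; out
  }
  W1 <- take(H); b1 <- take(H)
  Wa <- if (template$alpha_connected) take(H * M) else matrix(0, H, M)
  ba <- take(M); Wm <- take(H * M); bm <- take(M); Ws <- take(H * M); bs <- take(M)
  if (k != length(par)) stop("parameter vector length does not match template")
  mdn_weights(W1, b1, Wa, ba, Wm, bm, Ws, bs,
              alpha_connected = template$alpha_connected,
              scale_activation = template$scale_activation)
}

#' Glorot-uniform random initialization
#'
#' Draws every weight matrix uniformly on
#' \eqn{\pm\sqrt{6 / (fan_{in} + fan_{out})}}; biases start at zero.
#'
#' @param H hidden units (default 5, matching the B = 5 tanh bases).
#' @param M mixture components.
#' @param seed integer seed; identical seeds give identical weights.
#' @param alpha_connected,scale_activation see [mdn_weights].
#' @return An [mdn_weights] object.
#' @export
glorot_init <- function(H = 5L, M = 2L, seed = 1L, alpha_connected = TRUE,
                        scale_activation = c("exponential", "softplus")) {
  scale_activation <- match.arg(scale_activation)
  set.seed(seed)
  gl <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  Wa <- if (alpha_connected) gl(H, M) else matrix(0, H, M)
  mdn_weights(W1 = gl(1L, H), b1 = rep(0, H),
              Wa = Wa, ba = rep(0, M),
              Wm = gl(H, M), bm = rep(0, M),
              Ws = gl(H, M), bs = rep(0, M),
              alpha_connected = alpha_connected,
              scale_activation = scale_activation)
}

#' Network forward pass
#'
#' Maps covariate values through the network to the conditional mixture
#' parameters: hidden tanh layer, softmax over the mixture-weight head,
#' identity location head and positive scale head.
#'
#' @param weights an [mdn_weights] object.
#' @param covariate numeric vector of covariate values.
#' @param sigma_floor lower bound on the emitted scales (default 1e-8).
#' @return a [mixture_surface] with one row per covariate value.
#' @export
mdn_forward <- function(weights, covariate, sigma_floor = 1e-8) {
  stopifnot(inherits(weights, "mdn_weights"))
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  n <- length(covariate)
  Z <- tanh(covariate %*% weights$W1 + matrix(weights$b1, n, weights$H, byrow = TRUE))
  Aa <- Z %*% weights$Wa + matrix(weights$ba, n, weights$M, byrow = TRUE)
  Aa <- Aa - apply(Aa, 1L, max)
  ea <- exp(Aa)
  alpha <- ea / rowSums(ea)
  mu <- Z %*% weights$Wm + matrix(weights$bm, n, weights$M, byrow = TRUE)
  As <- Z %*% weights$Ws + matrix(weights$bs, n, weights$M, byrow = TRUE)
  sigma <- if (weights$scale_activation == "softplus") .softplus(As) else exp(As)
  mixture_surface(alpha, mu, pmax(sigma, sigma_floor))
}

.softplus <- function(a) ifelse(a > 30, a, log1p(exp(a)))

#' Network loss and analytic gradient
#'
#' Negative log-likelihood of the mixture produced by the forward pass,
#' together with its gradient with respect to the flattened trainable
#' parameters (the classical back-propagated mixture-density gradients:
#' posterior responsibilities drive the weight-head gradient
#' \eqn{\alpha_m - \pi_m}, the location gradient
#' \eqn{\pi_m(\mu_m - y)/\sigma_m^2} and the scale gradient
#' \eqn{\pi_m(1 - (y-\mu_m)^2/\sigma_m^2)}, chained through the softplus
#' derivative under that parameterization).
#'
#' @param weights an [mdn_weights] object.
#' @param x,y covariate and outcome vectors.
#' @param sigma_floor scale floor (default 1e-8).
#' @return list with `nll` (scalar) and `grad` (vector matching
#'   [flatten_weights]).
#' @export
mdn_nll_grad <- function(weights, x, y, sigma_floor = 1e-8) {
  stopifnot(inherits(weights, "mdn_weights"))
  out <- cpp_mdn_nll_grad(flatten_weights(weights), x, y, weights$H, weights$M,
                          weights$alpha_connected,
                          weights$scale_activation == "softplus",
                          sigma_floor, TRUE)
  list(nll = out$nll, grad = as.numeric(out$grad))
}

.mdn_nll_flat <- function(par, x, y, H, M, alpha_connected, softplus_scale,
                          sigma_floor) {
  v <- cpp_mdn_nll_grad(par, x, y, H, M, alpha_connected, softplus_scale,
                        sigma_floor, FALSE)$nll
  if (!is.finite(v)) 1e10 else v
}

.mdn_grad_flat <- function(par, x, y, H, M, alpha_connected, softplus_scale,
                           sigma_floor) {
  g <- as.numeric(cpp_mdn_nll_grad(par, x, y, H, M, alpha_connected,
                                   softplus_scale, sigma_floor, TRUE)$grad)
  g[!is.finite(g)] <- 0
  g
}

#' Train the network by quasi-Newton minimization
#'
#' Minimizes the mixture negative log-likelihood with BFGS (analytic
#' gradients) until the relative improvement drops below `reltol` or the
#' iteration cap is reached. Intended for standardized data.
#'
#' @param x,y standardized covariate and outcome vectors.
#' @param init an [mdn_weights] object with the starting weights.
#' @param maxit iteration cap (default 2000).
#' @param reltol relative convergence tolerance passed to [stats::optim()]
#'   (default 1e-8).
#' @param sigma_floor scale floor (default 1e-8).
#' @return list with `weights` (fitted [mdn_weights]), `loss` (final NLL),
#'   `initial_loss` and `converged`.
#' @export
train_bfgs <- function(x, y, init, maxit = 2000L, reltol = 1e-8,
                       sigma_floor = 1e-8) {
  stopifnot(inherits(init, "mdn_weights"))
  sp <- init$scale_activation == "softplus"
  par0 <- flatten_weights(init)
  loss0 <- .mdn_nll_flat(par0, x, y, init$H, init$M, init$alpha_connected, sp,
                         sigma_floor)
  opt <- stats::optim(par0, fn = .mdn_nll_flat, gr = .mdn_grad_flat,
                      x = x, y = y, H = init$H, M = init$M,
                      alpha_connected = init$alpha_connected,
                      softplus_scale = sp, sigma_floor = sigma_floor,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  list(weights = unflatten_weights(opt$par, init),
       loss = opt$value, initial_loss = loss0,
       converged = opt$convergence == 0L)
}

#' Train the network by ADAM with early stopping
#'
#' Splits the data 80/20 into training and validation sets under the given
#' seed, takes full-batch ADAM steps on the training negative log-likelihood,
#' monitors the validation loss after every epoch and stops once the best
#' validation loss has not improved for `patience` consecutive epochs (or at
#' the epoch cap). The weights achieving the best validation loss are
#' returned.
#'
#' @param x,y standardized covariate and outcome vectors (n >= 10).
#' @param init an [mdn_weights] object with the starting weights.
#' @param lr learning rate (default 0.01).
#' @param epochs epoch cap (default 2000).
#' @param patience early-stopping patience in epochs (default 20).
#' @param val_fraction validation fraction (default 0.2).
#' @param seed seed for the train/validation split.
#' @param beta1,beta2,eps ADAM moment parameters at their canonical values.
#' @param sigma_floor scale floor (default 1e-8).
#' @return list with `weights`, `loss` (training NLL of the returned
#'   weights on the full training split), `val_loss`, `initial_loss`,
#'   `history` (validation-loss trace), `stopped_epoch` and `converged`
#'   (TRUE when patience triggered before the cap).
#' @export
train_adam <- function(x, y, init, lr = 0.01, epochs = 2000L, patience = 20L,
                       val_fraction = 0.2, seed = 1L,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       sigma_floor = 1e-8) {
  stopifnot(inherits(init, "mdn_weights"))
  n <- length(x)
  if (n < 10L) stop("ADAM training with a validation split needs n >= 10")
  set.seed(seed)
  n_val <- max(1L, round(val_fraction * n))
  idx_val <- sample.int(n, n_val)
  xt <- x[-idx_val]; yt <- y[-idx_val]
  xv <- x[idx_val]; yv <- y[idx_val]

  sp <- init$scale_activation == "softplus"
  par <- flatten_weights(init)
  m <- v <- numeric(length(par))
  args <- list(H = init$H, M = init$M, alpha_connected = init$alpha_connected,
               softplus_scale = sp)
  val_nll <- function(p) .mdn_nll_flat(p, xv, yv, args$H, args$M,
                                       args$alpha_connected, args$softplus_scale,
                                       sigma_floor)
  best_par <- par
  best_val <- val_nll(par)
  best_epoch <- 0L
  history <- numeric(0)
  initial_loss <- .mdn_nll_flat(par, xt, yt, args$H, args$M,
                                args$alpha_connected, args$softplus_scale,
                                sigma_floor)
  stopped <- epochs
  for (t in seq_len(epochs)) {
    g <- .mdn_grad_flat(par, xt, yt, args$H, args$M, args$alpha_connected,
                        args$softplus_scale, sigma_floor)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    par <- par - lr * mhat / (sqrt(vhat) + eps)
    vl <- val_nll(par)
    history <- c(history, vl)
    if (vl < best_val) {
      best_val <- vl; best_par <- par; best_epoch <- t
    } else if (t - best_epoch >= patience) {
      stopped <- t
      break
    }
    stopped <- t
  }
  final_train <- .mdn_nll_flat(best_par, xt, yt, args$H, args$M,
                               args$alpha_connected, args$softplus_scale,
                               sigma_floor)
  list(weights = unflatten_weights(best_par, init),
       loss = final_train, val_loss = best_val, initial_loss = initial_loss,
       history = history, stopped_epoch = stopped,
       converged = stopped < epochs || best_epoch == epochs)
}
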