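test_that("forward pass reduces to known values with zero head weights", {
  H <- 4L
  zero <- function(ac, sa) mdn_weights(W1 = rnorm(H), b1 = rnorm(H),
                                       Wa = matrix(0, H, 2), ba = c(0, 0),
                                       Wm = matrix(0, H, 2), bm = c(0, 0),
                                       Ws = matrix(0, H, 2), bs = c(0, 0),
                                       alpha_connected = ac,
                                       scale_activation = sa)
  set.seed(2)
  x <- runif(10)
  s <- mdn_forward(zero(TRUE, "exponential"), x)
  expect_equal(s$weights, matrix(0.5, 10, 2))       # softmax of zeros
  expect_equal(s$means, matrix(0, 10, 2))
  expect_equal(s$scales, matrix(1, 10, 2))          # exp(0)
  s2 <- mdn_forward(zero(FALSE, "softplus"), x)
  expect_equal(s2$scales, matrix(log(2), 10, 2))    # softplus(0)
})

test_that("constant-weight variant emits covariate-independent mixture weights", {
  w <- glorot_init(H = 5L, M = 2L, seed = 3, alpha_connected = FALSE)
  s <- mdn_forward(w, seq(-2, 2, length.out = 40L))
  expect_equal(s$weights, s$weights[rep(1L, 40L), ])
  # but the weights are excluded from the trainable vector, bias still there
  wc <- glorot_init(H = 5L, M = 2L, seed = 3, alpha_connected = TRUE)
  expect_equal(length(flatten_weights(wc)) - length(flatten_weights(w)), 10L)
})

test_that("flatten/unflatten is a lossless round trip", {
  for (ac in c(TRUE, FALSE)) {
    w <- glorot_init(H = 3L, M = 2L, seed = 11, alpha_connected = ac)
    par <- flatten_weights(w)
    w2 <- unflatten_weights(par, w)
    expect_identical(flatten_weights(w2), par)
    expect_equal(w2$Wm, w$Wm)
    expect_equal(w2$b1, w$b1)
  }
})

test_that("glorot initialization respects bounds, determinism and moments", {
  w <- glorot_init(H = 5L, M = 2L, seed = 4)
  expect_true(all(abs(w$W1) <= 1))  # fan_in + fan_out = 6 for the hidden layer
  expect_true(all(w$b1 == 0) && all(w$bm == 0))
  expect_identical(flatten_weights(glorot_init(H = 5L, M = 2L, seed = 4)),
                   flatten_weights(w))
  expect_false(identical(flatten_weights(glorot_init(H = 5L, M = 2L, seed = 5)),
                         flatten_weights(w)))
  # Monte-Carlo moment check on the hidden-layer draws
  draws <- unlist(lapply(1:2000, function(s) glorot_init(H = 5L, seed = s)$W1))
  se <- 1 / sqrt(3) / sqrt(length(draws))  # sd of U(-1,1) is 1/sqrt(3)
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("analytic gradients match central finite differences in all variants", {
  set.seed(42)
  x <- runif(50); y <- rnorm(50)
  for (ac in c(TRUE, FALSE)) for (sa in c("exponential", "softplus")) {
    w <- glorot_init(H = 3L, M = 2L, seed = 7, alpha_connected = ac,
                     scale_activation = sa)
    g <- mdn_nll_grad(w, x, y)$grad
    fd <- fd_gradient(w, x, y)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-5)
  }
})

test_that("weight-head pre-activation gradients sum to zero per observation", {
  # softmax constraint: sum_m dE/da_alpha,m = 0, so the bias gradient of a
  # one-observation dataset sums to zero
  w <- glorot_init(H = 3L, M = 3L, seed = 1)
  g <- mdn_nll_grad(w, 0.3, 1.2)$grad
  # locate the weight-head bias block: after W1, b1, Wa
  off <- 3L + 3L + 9L
  expect_equal(sum(g[(off + 1L):(off + 3L)]), 0, tolerance = 1e-12)
})

test_that("with one component the location gradient vanishes at the mean", {
  set.seed(8)
  y <- rnorm(30, 2, 1)
  # H hidden units but zero hidden->head weights: mu is the bias alone
  mk <- function(bm) mdn_weights(W1 = rep(0, 2), b1 = rep(0, 2),
                                 Wa = matrix(0, 2, 1), ba = 0,
                                 Wm = matrix(0, 2, 1), bm = bm,
                                 Ws = matrix(0, 2, 1), bs = 0,
                                 alpha_connected = FALSE)
  x <- runif(30)
  idx_bm <- 2L + 2L + 1L + 2L + 1L  # W1, b1, ba, Wm, then bm
  g_at <- function(bm) mdn_nll_grad(mk(bm), x, y)$grad[idx_bm]
  expect_equal(g_at(mean(y)), 0, tolerance = 1e-10)
  expect_gt(abs(g_at(mean(y) + 0.5)), 0.1)
})

test_that("NLL from the compiled path equals the R forward + mixture_nll path", {
  set.seed(10)
  x <- runif(80); y <- rnorm(80)
  for (sa in c("exponential", "softplus")) {
    w <- glorot_init(H = 5L, M = 2L, seed = 2, scale_activation = sa)
    expect_equal(mdn_nll_grad(w, x, y)$nll, mixture_nll(mdn_forward(w, x), y),
                 tolerance = 1e-10)
  }
})

test_that("BFGS training is a descent method with a fixed point", {
  ds <- toy_mixture_data(400L, seed = 6)
  std <- standardize(ds$x, ds$y)
  w0 <- glorot_init(H = 5L, M = 2L, seed = 3)
  fit <- train_bfgs(std$x, std$y, w0)
  expect_lte(fit$loss, fit$initial_loss)
  # restarting at the optimum changes the loss only negligibly
  fit2 <- train_bfgs(std$x, std$y, fit$weights)
  expect_lt(abs(fit2$loss - fit$loss), 1e-6)
})

test_that("nested models: full variant attains at most the constant-weight loss", {
  ds <- toy_mixture_data(800L, seed = 9)
  std <- standardize(ds$x, ds$y)
  fit_const <- train_bfgs(std$x, std$y,
                          custom_mdn_init(std$x, std$y, seed = 1,
                                          alpha_connected = FALSE))
  # start the full model at the constant-weight solution
  wc <- fit_const$weights
  w_full <- mdn_weights(wc$W1, wc$b1, matrix(0, wc$H, wc$M), wc$ba,
                        wc$Wm, wc$bm, wc$Ws, wc$bs,
                        alpha_connected = TRUE,
                        scale_activation = wc$scale_activation)
  fit_full <- train_bfgs(std$x, std$y, w_full)
  expect_lte(fit_full$loss, fit_const$loss + 1e-6)
})

test_that("permuting component heads of the init permutes the fitted components", {
  ds <- toy_mixture_data(500L, seed = 13)
  std <- standardize(ds$x, ds$y)
  w <- glorot_init(H = 5L, M = 2L, seed = 21)
  swap <- mdn_weights(w$W1, w$b1, w$Wa[, 2:1], w$ba[2:1], w$Wm[, 2:1],
                      w$bm[2:1], w$Ws[, 2:1], w$bs[2:1])
  # floating-point reorderings make the two trajectories drift slightly, so
  # the permuted fits agree up to optimizer tolerance, not bitwise
  f1 <- train_bfgs(std$x, std$y, w)
  f2 <- train_bfgs(std$x, std$y, swap)
  expect_equal(f1$loss, f2$loss, tolerance = 5e-3)
  s1 <- mdn_forward(f1$weights, std$x)
  s2 <- mdn_forward(f2$weights, std$x)
  expect_lt(mean(abs(s1$means - s2$means[, 2:1])), 0.05)
})

test_that("ADAM with zero learning rate returns the initial weights", {
  ds <- toy_mixture_data(100L, seed = 1)
  std <- standardize(ds$x, ds$y)
  w0 <- glorot_init(H = 5L, M = 2L, seed = 2, scale_activation = "softplus")
  fit <- train_adam(std$x, std$y, w0, lr = 0, epochs = 100L, seed = 3)
  expect_identical(flatten_weights(fit$weights), flatten_weights(w0))
})

test_that("ADAM improves the training loss and obeys the patience rule", {
  ds <- toy_mixture_data(600L, seed = 17)
  std <- standardize(ds$x, ds$y)
  w0 <- custom_mdn_init(std$x, std$y, seed = 5, scale_activation = "softplus")
  fit <- train_adam(std$x, std$y, w0, seed = 5, epochs = 400L)
  expect_lt(fit$loss, fit$initial_loss)
  # running best of the validation history is nonincreasing, and when the
  # patience rule triggers the stop epoch is argbest + patience
  run_best <- cummin(fit$history)
  expect_true(all(diff(run_best) <= 0))
  if (fit$stopped_epoch < 400L) {
    expect_equal(fit$stopped_epoch, which.min(fit$history) + 20L)
  }
})
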