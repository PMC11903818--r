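test_that("the transfer function is the stated trapezoid", {
  p <- transfer_params() # alpha 0.05, upper bound 0.8, ramp 0.1
  expect_equal(transfer(p$alpha, p), 0)
  expect_equal(transfer(0, p), 0)
  mid <- (p$alpha + p$ramp + p$alpha + p$beta) / 2
  expect_equal(transfer(mid, p), 1)
  expect_equal(transfer(p$alpha + p$beta + p$ramp, p), 0)
  expect_equal(transfer(1, p), 0)
  # continuity and piecewise linearity on a fine grid
  q <- seq(0, 1, by = 1e-3)
  Tq <- transfer(q, p)
  expect_true(all(Tq >= 0 & Tq <= 1))
  expect_lt(max(abs(diff(Tq))), 1.1e-2) # slope bounded by 1/ramp
  # plateau has positive measure beta - ramp
  expect_equal(sum(Tq == 1) * 1e-3, p$beta - p$ramp, tolerance = 5e-3)
})

test_that("the pooling neuron is the masked mean", {
  a1 <- matrix(1, 8, 8); m1 <- matrix(1L, 8, 8)
  expect_equal(pooled_activation(a1, m1), 1)
  expect_equal(pooled_activation(matrix(0, 8, 8), m1), 0)
  m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L
  expect_equal(pooled_activation(m * 1.0, m), 1) # activation exactly on mask
  expect_error(pooled_activation(a1, matrix(0L, 8, 8)), "all zero")
})

test_that("pooling is equivariant under every dihedral op", {
  set.seed(8)
  a <- matrix(stats::runif(64^2), 64, 64)
  m <- matrix(as.integer(stats::runif(64^2) < 0.3), 64, 64)
  m[1, 1] <- 1L
  q0 <- pooled_activation(a, m)
  for (op in 0:7) {
    expect_equal(pooled_activation(apply_dihedral(a, op),
                                   apply_dihedral(m, op)), q0)
    expect_equal(classify_roi(pooled_activation(apply_dihedral(a, op),
                                                apply_dihedral(m, op))),
                 classify_roi(q0))
  }
})

test_that("the learning-rate schedule decays 0.9 every 50 epochs", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 5e-4)
  expect_equal(lr_schedule(49, cfg), 5e-4)
  expect_equal(lr_schedule(50, cfg), 4.5e-4)
  expect_equal(lr_schedule(100, cfg), 4.05e-4)
})

test_that("the model maps spectral patches to bounded activation maps", {
  model <- build_compsegnet(16, base_features = 2, seed = 3)
  x <- array(stats::rnorm(64 * 64 * 16), c(64, 64, 16))
  a <- compseg_forward(model, x)
  expect_equal(dim(a), c(64L, 64L))
  expect_true(all(a >= 0 & a <= 1))

  model2 <- build_compsegnet(16, base_features = 2, seed = 3)
  expect_identical(model$params, model2$params) # seeded init
  model3 <- build_compsegnet(16, base_features = 2, seed = 4)
  expect_false(identical(model$params, model3$params))

  expect_error(compseg_forward(model, array(0, c(60, 60, 16))), "divisible")
  expect_error(compseg_forward(model, array(0, c(64, 64, 3))), "H, W")
})

test_that("backprop matches finite differences", {
  model <- build_compsegnet(2, base_features = 2, depth = 2, seed = 5)
  set.seed(2)
  x <- array(stats::rnorm(16 * 16 * 2), c(16, 16, 2))
  m <- matrix(rbinom(256, 1, 0.3), 16, 16); m[1, 1] <- 1L
  p <- transfer_params()
  lossfun <- function(mod) {
    a <- compseg_forward(mod, x)
    compseg_loss(list(list(a = a, m = m, y = 1L)), p, c(1, 1), 1)$loss
  }
  fw <- compseg_forward(model, x, want_cache = TRUE)
  ls <- compseg_loss(list(list(a = fw$a, m = m, y = 1L)), p, c(1, 1), 1,
                     want_grads = TRUE)
  g <- irplaque:::compseg_backward(model, fw$cache, ls$grads[[1]])
  paths <- c("$enc[[1]]$c1W", "$bott$c2W", "$dec[[1]]$upW", "$out$W")
  for (pth in paths) {
    W <- eval(parse(text = paste0("model$params", pth)))
    G <- eval(parse(text = paste0("g", pth)))
    set.seed(nchar(pth))
    for (i in sample(length(W), min(3, length(W)))) {
      eps <- 1e-5
      m2 <- model
      eval(parse(text = paste0("m2$params", pth, "[i] <- W[i] + eps")))
      lp <- lossfun(m2)
      eval(parse(text = paste0("m2$params", pth, "[i] <- W[i] - eps")))
      lm <- lossfun(m2)
      expect_equal(G[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("the two-term loss behaves at its anchor points", {
  p <- transfer_params()
  m <- matrix(0L, 16, 16); m[5:10, 5:10] <- 1L
  ones <- matrix(1L, 16, 16)

  # ideal prediction: half the (dilated) mask activated on a positive --
  # pooled activation mid-plateau -- and nothing on a negative; activating
  # the entire mask would be overdetection (q = 1 lies beyond the upper
  # bound, where the transfer returns to 0)
  perfect <- list(list(a = m * 0.5, m = m, y = 1L),
                  list(a = matrix(0, 16, 16), m = ones, y = 0L))
  expect_equal(transfer(pooled_activation(m * 0.5, m), p), 1)
  expect_equal(transfer(pooled_activation(m * 1.0, m), p), 0) # overdetection
  ls <- compseg_loss(perfect, p)
  expect_lt(ls$loss, 1e-5)

  # fully activated negative ROI: background term saturates near -log(eps)
  bad <- list(list(a = matrix(1, 16, 16), m = ones, y = 0L))
  ls2 <- compseg_loss(bad, p)
  expect_gt(ls2$bg_loss, 15) # -log(1e-7) ~ 16.1

  # balanced batches give unit class weights
  expect_equal(compseg_loss(perfect, p, class_weights = c(1, 1))$class_loss,
               compseg_loss(perfect, p)$class_loss)
})

test_that("class weights derive from the training composition", {
  # 3 positives, 1 negative: w0 = 4/2, w1 = 4/6
  y <- c(1, 1, 1, 0)
  n_tot <- length(y)
  w0 <- n_tot / (2 * sum(y == 0)); w1 <- n_tot / (2 * sum(y == 1))
  expect_equal(w0, 2)
  expect_equal(w1, 2 / 3)
})

test_that("a short seeded run strictly decreases the loss on one ROI", {
  s <- toy_sample(11, y = 1L, C = 3)
  model <- build_compsegnet(3, base_features = 2, seed = 7)
  p <- transfer_params()
  state <- NULL
  losses <- numeric(50)
  for (step in 1:50) {
    fw <- compseg_forward(model, s$patch, want_cache = TRUE)
    ls <- compseg_loss(list(list(a = fw$a, m = s$effective_mask, y = 1L)),
                       p, c(1, 1), 1, want_grads = TRUE)
    losses[step] <- ls$loss
    g <- irplaque:::compseg_backward(model, fw$cache, ls$grads[[1]])
    if (is.null(state)) state <- irplaque:::zero_like(model$params)
    upd <- irplaque:::rmsprop_update(model$params, g, state, 5e-4)
    model$params <- upd$p; state <- upd$s
  }
  expect_lt(losses[50], losses[1])
  expect_lt(stats::median(diff(losses)), 0) # decreasing trend throughout
})

test_that("training rejects case leakage before any epoch", {
  tr <- list(toy_sample(1, case_id = "A"), toy_sample(2, y = 0L, case_id = "A"))
  va <- list(toy_sample(3, case_id = "A"))
  expect_error(train_compsegnet(tr, va, train_config(max_epochs = 1,
                                                     base_features = 1)),
               "leakage")
})

test_that("a two-epoch training run is bit-reproducible under one seed", {
  tr <- list(toy_sample(1, y = 1L, case_id = "A"),
             toy_sample(2, y = 0L, case_id = "A"),
             toy_sample(3, y = 1L, case_id = "B"),
             toy_sample(4, y = 0L, case_id = "B"))
  va <- list(toy_sample(5, y = 1L, case_id = "C"),
             toy_sample(6, y = 0L, case_id = "C"))
  cfg <- train_config(max_epochs = 2, base_features = 1, batch_size = 2,
                      patience = 10, seed = 13)
  f1 <- train_compsegnet(tr, va, cfg)
  f2 <- train_compsegnet(tr, va, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$metrics, f2$metrics)
  expect_equal(nrow(f1$metrics), 2L)
  expect_equal(f1$metrics$lr, c(5e-4, 5e-4))
})
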