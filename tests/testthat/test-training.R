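# training smoke/property tests use the gru_only variant, the cheapest
# architecture sharing the full optimizer/loss/checkpoint path

test_that("three epochs on a balanced synthetic set reduce the loss", {
  ex <- random_examples(20, seed = 51)
  m <- build_variant(model_config("gru_only", dropout_rate = 0.1),
                     seed = 51)
  fit <- train_model(m, ex[1:16], ex[17:20],
                     train_config(epochs = 3, batch_size = 4, seed = 51))
  expect_equal(nrow(fit$history), 3L)
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
})

test_that("training is deterministic given the seed", {
  ex <- random_examples(8, seed = 52)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 99)
  f1 <- train_model(build_variant(model_config("gru_only"), seed = 52),
                    ex[1:6], ex[7:8], cfg)
  f2 <- train_model(build_variant(model_config("gru_only"), seed = 52),
                    ex[1:6], ex[7:8], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("degenerate streams are rejected", {
  ex <- random_examples(4, seed = 53, pos_frac = 0)
  m <- build_variant(model_config("gru_only"), seed = 53)
  expect_error(train_model(m, ex[1:3], ex[4], train_config(epochs = 1)),
               "no positive frames")
  expect_error(train_model(m, list(), list(), train_config(epochs = 1)),
               "non-empty")
})

test_that("the checkpoint keeps the best-validation-F1 epoch", {
  ex <- random_examples(12, seed = 54)
  m <- build_variant(model_config("gru_only", dropout_rate = 0.2),
                     seed = 54)
  fit <- train_model(m, ex[1:9], ex[10:12],
                     train_config(epochs = 4, batch_size = 4, seed = 54))
  expect_equal(fit$best_val_f1, max(fit$history$val_f1, na.rm = TRUE))
  expect_equal(fit$best_epoch,
               which.max(fit$history$val_f1))
})

test_that("early stopping caps the epoch count once the target F1 is
           reached", {
  ex <- random_examples(12, seed = 55)
  m <- build_variant(model_config("gru_only", dropout_rate = 0),
                     seed = 55)
  fit <- train_model(m, ex[1:9], ex[10:12],
                     train_config(epochs = 50, batch_size = 4, seed = 55,
                                  early_stop_f1 = 0.8))
  expect_lt(nrow(fit$history), 50L)
  expect_gte(fit$best_val_f1, 0.8)
})

test_that("zero dropout and zero L2 reproduce plain focal-loss training", {
  ex <- random_examples(6, seed = 56)
  cfg0 <- train_config(epochs = 1, batch_size = 3, seed = 7,
                       dropout_rate = 0, l2_weight = 0)
  m <- build_variant(model_config("gru_only"), seed = 56)
  fit0 <- train_model(m, ex[1:4], ex[5:6], cfg0)
  # the penalty term vanishes: reported loss equals the pure focal loss
  p <- predict(fit0$model, ex[5:6])
  lab <- swdnet:::gather_labels(ex[5:6])
  expect_equal(fit0$history$val_loss,
               focal_loss(p, lab$y, cfg0$focal_alpha, cfg0$focal_gamma,
                          lab$mask))
})

test_that("L2 regularization penalizes conv and dense kernels only", {
  m <- build_variant(model_config("resnet_bigru"), seed = 57)
  g0 <- swdnet:::tree_map(function(x) x * 0, m$params)
  g <- swdnet:::add_l2(g0, m$params, l2 = 1)
  expect_equal(g$enc$b1$conv1$w, m$params$enc$b1$conv1$w)
  expect_equal(g$enc$b2$proj$w, m$params$enc$b2$proj$w)
  expect_equal(g$head$dense1$w, m$params$head$dense1$w)
  # biases, batch-norm and recurrent weights are not penalized
  expect_true(all(g$enc$b2$proj$b == 0))
  expect_true(all(g$enc$b1$bn1$gamma == 0))
  expect_true(all(g$head$gru1f$w == 0))
  expect_true(all(g$head$gru1f$u == 0))
  # penalty value matches its gradient convention (0.5 * l2 * sum w^2)
  expect_equal(swdnet:::l2_penalty(m$params, 2),
               sum(m$params$enc$b1$conv1$w^2) +
                 sum(m$params$enc$b1$conv2$w^2) +
                 sum(m$params$enc$b1$proj$w^2) +
                 sum(m$params$enc$b2$conv1$w^2) +
                 sum(m$params$enc$b2$conv2$w^2) +
                 sum(m$params$enc$b2$proj$w^2) +
                 sum(m$params$enc$b3$conv1$w^2) +
                 sum(m$params$enc$b3$conv2$w^2) +
                 sum(m$params$enc$b3$proj$w^2) +
                 sum(m$params$enc$b4$conv1$w^2) +
                 sum(m$params$enc$b4$conv2$w^2) +
                 sum(m$params$enc$b4$proj$w^2) +
                 sum(m$params$head$dense1$w^2) +
                 sum(m$params$head$dense2$w^2))
})

test_that("Adam takes a bias-corrected step of the configured size", {
  params <- list(a = c(1, 2), b = matrix(0, 2, 2))
  grads <- list(a = c(0.5, -0.5), b = matrix(1, 2, 2))
  opt <- swdnet:::adam_init(params)
  st <- swdnet:::adam_step(params, grads, opt, lr = 0.1)
  # first step moves every coordinate by ~lr * sign(grad)
  expect_equal(st$params$a, c(1, 2) - 0.1 * sign(c(0.5, -0.5)),
               tolerance = 1e-3)
  expect_equal(st$opt$t, 1L)
})

test_that("fit objects tidy, glance and plot", {
  ex <- random_examples(6, seed = 58)
  m <- build_variant(model_config("gru_only"), seed = 58)
  fit <- train_model(m, ex[1:4], ex[5:6],
                     train_config(epochs = 2, batch_size = 3, seed = 58))
  expect_equal(nrow(generics::tidy(fit)), 2L)
  expect_equal(generics::glance(fit)$variant, "gru_only")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
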