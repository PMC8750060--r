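test_that("parameter count equals the per-layer arithmetic", {
  m <- build_model(model_config(), input_shape = c(20L, 32L, 32L))
  by_hand <- (32 * 20 * 9 + 32) +            # conv1: filters*k^2*in + bias
    (64 * 32 * 9 + 64) +                     # conv2
    (128 * 64 * 28 * 28 + 128) +             # fc1 on the flattened 64x28x28
    (32 * 128 + 32) + (1 * 32 + 1)           # fc2, fc3
  expect_identical(parameter_count(m), as.integer(by_hand))

  m2 <- build_model(mini_model_config(), input_shape = mini_input_shape)
  by_hand2 <- (4 * 4 * 9 + 4) + (6 * 4 * 9 + 6) +
    (16 * 6 * 4 * 4 + 16) + (8 * 16 + 8) + (1 * 8 + 1)
  expect_identical(parameter_count(m2), as.integer(by_hand2))
})

test_that("model building is deterministic and validates kernels", {
  m1 <- build_model(mini_model_config(seed = 4L), mini_input_shape)
  m2 <- build_model(mini_model_config(seed = 4L), mini_input_shape)
  expect_identical(m1$conv, m2$conv)
  expect_identical(m1$fc, m2$fc)
  m3 <- build_model(mini_model_config(seed = 5L), mini_input_shape)
  expect_false(identical(m1$conv[[1]]$W, m3$conv[[1]]$W))
  expect_error(build_model(model_config(conv = list(c(4L, 9L), c(4L, 3L))),
                           mini_input_shape),
               "layer 1")
})

test_that("forward probabilities lie in [0, 1] for arbitrary inputs", {
  m <- build_model(mini_model_config(), mini_input_shape)
  set.seed(10)
  x <- array(rnorm(prod(mini_input_shape) * 7, sd = 50), c(mini_input_shape, 7))
  p <- fccnn:::forward_fccnn(m, x)$prob
  expect_length(p, 7L)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("backpropagated gradients match finite differences", {
  m <- build_model(mini_model_config(seed = 2L), mini_input_shape)
  set.seed(3)
  x <- array(rnorm(prod(mini_input_shape) * 4), c(mini_input_shape, 4))
  y <- c(0, 1, 1, 0)
  fw <- fccnn:::forward_fccnn(m, x, keep_cache = TRUE)
  gr <- fccnn:::backward_fccnn(m, fw, y)
  loss_at <- function(model) {
    fccnn:::bce_loss(fccnn:::forward_fccnn(model, x)$prob, y)
  }
  eps <- 1e-6
  probes <- list(
    list(part = "conv", layer = 1L, idx = c(2L, 5L)),
    list(part = "conv", layer = 2L, idx = c(3L, 17L)),
    list(part = "fc", layer = 1L, idx = c(4L, 40L)),
    list(part = "fc", layer = 3L, idx = c(1L, 2L))
  )
  for (pr in probes) {
    mp <- m; mm <- m
    mp[[pr$part]][[pr$layer]]$W[pr$idx[1], pr$idx[2]] <-
      mp[[pr$part]][[pr$layer]]$W[pr$idx[1], pr$idx[2]] + eps
    mm[[pr$part]][[pr$layer]]$W[pr$idx[1], pr$idx[2]] <-
      mm[[pr$part]][[pr$layer]]$W[pr$idx[1], pr$idx[2]] - eps
    numeric_grad <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    analytic <- gr[[pr$part]][[pr$layer]]$dW[pr$idx[1], pr$idx[2]]
    expect_equal(analytic, numeric_grad, tolerance = 1e-4)
  }
})

test_that("training contract: history, single-class rejection, lr = 0", {
  segs <- mini_segments(n_per_class = 4L, duration = 4)
  split <- split_by_subject(segs, 0.25, seed = 1L)
  m <- build_model(mini_model_config(), mini_input_shape)

  single <- split
  single$train <- Filter(function(s) s$class_label == 1L, single$train)
  expect_error(train_model(m, single, train_config(epochs = 1L)),
               "both classes")

  tc <- train_config(epochs = 3L, batch_size = 16L, seed = 2L)
  tm <- train_model(m, split, tc)
  expect_true(tm$trained)
  expect_equal(nrow(tm$history), 3L)
  expect_setequal(names(tm$history),
                  c("epoch", "loss", "accuracy", "val_loss", "val_accuracy"))

  frozen <- train_model(m, split, train_config(epochs = 1L, lr = 0,
                                               batch_size = 16L, seed = 2L))
  expect_identical(frozen$conv[[1]]$W, m$conv[[1]]$W)
  expect_identical(frozen$fc[[1]]$W, m$fc[[1]]$W)
})

test_that("seeded training runs are bit-for-bit reproducible", {
  segs <- mini_segments(n_per_class = 4L, duration = 4)
  split <- split_by_subject(segs, 0.25, seed = 1L)
  tc <- train_config(epochs = 2L, batch_size = 16L, seed = 7L)
  t1 <- train_model(build_model(mini_model_config(seed = 1L),
                                mini_input_shape), split, tc)
  t2 <- train_model(build_model(mini_model_config(seed = 1L),
                                mini_input_shape), split, tc)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$fc, t2$fc)
})

test_that("prediction applies the inclusive 0.5 threshold deterministically", {
  segs <- mini_segments(n_per_class = 4L, duration = 4)
  split <- split_by_subject(segs, 0.25, seed = 1L)
  tm <- train_model(build_model(mini_model_config(), mini_input_shape), split,
                    train_config(epochs = 2L, batch_size = 16L))
  p1 <- predict(tm, split$test)
  p2 <- predict(tm, split$test)
  expect_identical(p1, p2)
  expect_true(all(p1$probability >= 0 & p1$probability <= 1))
  expect_identical(p1$label, as.integer(p1$probability >= 0.5))
  wrong_shape <- split$test[[1]]
  wrong_shape$tensor <- array(0, c(2, 8, 8))
  expect_error(predict(tm, list(wrong_shape)), "shape")
})

test_that("training loss trends downward on separable data", {
  segs <- mini_segments(n_per_class = 6L, duration = 8)
  split <- split_by_subject(segs, 0.2, seed = 2L)
  tm <- train_model(build_model(mini_model_config(seed = 1L),
                                mini_input_shape),
                    split, train_config(epochs = 10L, batch_size = 32L,
                                        seed = 1L))
  h <- tm$history$loss
  expect_lt(mean(utils::tail(h, 3)), mean(utils::head(h, 3)))
})
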