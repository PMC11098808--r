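# Training-contract tests run on small phantom slices (32 x 28, scaled
# morphologies from helper-phantoms.R) so each gradient step is cheap;
# the full-size regime is exercised end to end in the acceptance suite.

test_that("history has one fully populated row per epoch", {
  dat <- small_phantoms(4, seed = 1)
  m <- build_model(resmini_config(input_height = 32, input_width = 28),
                   seed = 1)
  fit <- train(m, dat, dat,
               training_config(learning_rate = 1e-3, epochs = 1,
                               batch_size = 6, seed = 1))
  expect_equal(nrow(fit$history), 1)
  fit3 <- train(m, dat, dat,
                training_config(learning_rate = 1e-3, epochs = 3,
                                batch_size = 6, seed = 1))
  h <- fit3$history
  expect_equal(h$epoch, 1:3)
  expect_true(all(is.finite(unlist(h))))
  expect_true(all(h$train_accuracy >= 0 & h$train_accuracy <= 1))
  expect_true(all(h$val_accuracy >= 0 & h$val_accuracy <= 1))
  expect_true(all(h$train_loss >= 0))
})

test_that("identical seeds give identical histories and weights", {
  dat <- small_phantoms(4, seed = 2)
  run <- function() {
    m <- build_model(resmini_config(input_height = 32, input_width = 28),
                     seed = 7)
    train(m, dat, dat,
          training_config(learning_rate = 1e-3, epochs = 2,
                          batch_size = 6, seed = 11))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("model outputs remain a valid simplex during training", {
  dat <- small_phantoms(4, seed = 3)
  m <- build_model(resmini_config(input_height = 32, input_width = 28),
                   seed = 3)
  fit <- train(m, dat, dat,
               training_config(learning_rate = 1e-3, epochs = 2,
                               batch_size = 6, seed = 3))
  p <- predict(fit$model, dat$x)
  expect_equal(rowSums(p), rep(1, dim(dat$x)[4]), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("bad labels and empty sets are rejected", {
  dat <- small_phantoms(2, seed = 4)
  m <- build_model(resmini_config(input_height = 32, input_width = 28),
                   seed = 4)
  bad <- dat
  bad$y[1] <- 7L
  cfg <- training_config(epochs = 1)
  expect_error(train(m, bad, dat, cfg), "labels")
  empty <- list(x = dat$x[, , , 0, drop = FALSE], y = integer(0))
  expect_error(train(m, empty, dat, cfg), "empty")
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(epochs = 0), "epochs")
})

test_that("history CSV round-trips with one row per epoch", {
  h <- data.frame(epoch = 1:3, train_loss = c(1.2, 0.8, 0.5),
                  train_accuracy = c(0.4, 0.6, 0.9),
                  val_loss = c(1.3, 1.0, 0.7),
                  val_accuracy = c(0.3, 0.5, 0.8))
  path <- tempfile(fileext = ".csv")
  save_history(h, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4)  # header + epochs
  back <- utils::read.csv(path)
  expect_equal(back, h)
  expect_true(all(is.finite(back$train_loss)))
  unlink(path)
})

test_that("a trained model survives save/load with identical predictions", {
  dat <- small_phantoms(3, seed = 5)
  m <- build_model(resmini_config(input_height = 32, input_width = 28),
                   seed = 5)
  fit <- train(m, dat, dat,
               training_config(learning_rate = 1e-3, epochs = 1,
                               batch_size = 9, seed = 5))
  path <- tempfile(fileext = ".rds")
  save_model(fit$model, path)
  expect_identical(predict(load_model(path), dat$x),
                   predict(fit$model, dat$x))
  unlink(path)
})
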