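#' Training configuration
#'
#' The study regime: ADAM (beta1 0.9, beta2 0.999), learning rate 2e-5,
#' batches of 24, 200 epochs, categorical cross-entropy on the softmax
#' head, shuffling each epoch. No early stopping, schedule or weight
#' decay.
#'
#' @param learning_rate ADAM step size.
#' @param batch_size Images per gradient step.
#' @param epochs Number of passes over the training set.
#' @param beta1,beta2,epsilon ADAM moment decays and stabilizer.
#' @param seed Integer seed driving epoch shuffling.
#' @param shuffle_each_epoch Reshuffle the training order every epoch?
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 2e-5, batch_size = 24L,
                            epochs = 200L, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-7, seed = 0L,
                            shuffle_each_epoch = TRUE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch)),
            class = "training_config")
}

check_labels <- function(y, K) {
  if (length(y) == 0L) stop("empty dataset", call. = FALSE)
  if (any(y < 0L | y >= K))
    stop(sprintf("labels must lie in [0, %d)", K), call. = FALSE)
}

# mean loss and accuracy of a model on (x, y) in inference mode
eval_loss_acc <- function(model, x, y, batch_size = 64L) {
  N <- dim(x)[4]
  loss_sum <- 0
  correct <- 0
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fw <- resmini_forward(model, x[, , , idx, drop = FALSE],
                          training = FALSE)
    sx <- softmax_xent(fw$logits, y[idx] + 1L)
    loss_sum <- loss_sum + sx$loss * length(idx)
    pred <- max.col(t(sx$probs), ties.method = "first")
    correct <- correct + sum(pred == y[idx] + 1L)
  }
  c(loss = loss_sum / N, accuracy = correct / N)
}

#' Train a ResMini model
#'
#' Mini-batch ADAM with categorical cross-entropy. Each epoch shuffles
#' the training order (seeded), takes one gradient step per batch (batch
#' norm in batch-statistics mode), then records training loss/accuracy
#' (weighted over the epoch's batches) and validation loss/accuracy
#' (inference mode). Two runs with the same seed and data produce
#' identical histories.
#'
#' @param model A [build_model()] result.
#' @param train_set,val_set Lists with `x` (array `(H, W, C, N)`) and `y`
#'   (0-based integer labels), e.g. from [load_dataset()].
#' @param config A [training_config()].
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return List with `model` (trained) and `history` (data frame with
#'   columns epoch, train_loss, train_accuracy, val_loss, val_accuracy).
#' @export
train <- function(model, train_set, val_set,
                  config = training_config(), verbose = 0L) {
  stopifnot(inherits(model, "resmini_model"),
            inherits(config, "training_config"))
  K <- model$config$num_classes
  x <- as_input_batch(train_set$x, model$config$input_channels)
  y <- as.integer(train_set$y)
  xv <- as_input_batch(val_set$x, model$config$input_channels)
  yv <- as.integer(val_set$y)
  check_labels(y, K)
  check_labels(yv, K)
  N <- dim(x)[4]
  if (length(y) != N) stop("x/y length mismatch", call. = FALSE)

  state <- adam_init(model$params)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = NA_real_, train_accuracy = NA_real_,
                        val_loss = NA_real_, val_accuracy = NA_real_)
  set.seed(config$seed)
  order_now <- seq_len(N)
  for (ep in seq_len(config$epochs)) {
    if (config$shuffle_each_epoch || ep == 1L)
      order_now <- sample(N)
    loss_sum <- 0
    correct <- 0
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- order_now[start:min(start + config$batch_size - 1L, N)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx] + 1L
      fw <- resmini_forward(model, xb, training = TRUE)
      model$buffers <- fw$buffers
      sx <- softmax_xent(fw$logits, yb)
      grads <- resmini_backward(model, fw$caches, sx$dz)
      upd <- adam_step(model$params, grads, state, config$learning_rate,
                       config$beta1, config$beta2, config$epsilon)
      model$params <- upd$params
      state <- upd$state
      loss_sum <- loss_sum + sx$loss * length(idx)
      pred <- max.col(t(sx$probs), ties.method = "first")
      correct <- correct + sum(pred == yb)
    }
    val <- eval_loss_acc(model, xv, yv)
    history$train_loss[ep] <- loss_sum / N
    history$train_accuracy[ep] <- correct / N
    history$val_loss[ep] <- val["loss"]
    history$val_accuracy[ep] <- val["accuracy"]
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf(
        "epoch %3d | loss %.4f acc %.3f | val loss %.4f acc %.3f",
        ep, history$train_loss[ep], history$train_accuracy[ep],
        history$val_loss[ep], history$val_accuracy[ep]))
  }
  list(model = model, history = history)
}

#' Save a training history as CSV
#'
#' One row per epoch with the four logged metrics.
#'
#' @param history The `history` data frame returned by [train()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
save_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
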