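#' Build a trainable ResMini network
#'
#' Instantiates weights for the plan produced by [layer_specs()]:
#' He-normal convolution kernels, Glorot-uniform dense weights, batch-norm
#' scale 1 / shift 0 and zeroed running statistics. The realized parameter
#' total (weights plus batch-norm statistics) equals
#' `count_parameters(layer_specs(config))$total_parameters`.
#'
#' @param config A [resmini_config()].
#' @param seed Integer seed for weight initialization (`NULL` leaves the
#'   R random stream untouched).
#' @return An object of class `resmini_model`: list with `config`,
#'   `params` (named list of weight arrays) and `buffers` (batch-norm
#'   running statistics).
#' @examples
#' m <- build_model(resmini_config(), seed = 1)
#' p <- predict(m, array(runif(95 * 79 * 2), c(95, 79, 1, 2)))
#' rowSums(p)  # each 1: softmax output
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "resmini_config"))
  if (!is.null(seed)) set.seed(seed)
  f <- config$base_width
  c0 <- config$input_channels
  K <- config$num_classes

  he_conv <- function(kh, kw, cin, cout) {
    fan_in <- kh * kw * cin
    matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
           nrow = fan_in, ncol = cout)
  }
  params <- list()
  buffers <- list()
  add_bn <- function(name, ch) {
    params[[paste0(name, ".gamma")]] <<- rep(1, ch)
    params[[paste0(name, ".beta")]] <<- rep(0, ch)
    buffers[[paste0(name, ".mean")]] <<- rep(0, ch)
    buffers[[paste0(name, ".var")]] <<- rep(1, ch)
  }

  params[["stem.conv.W"]] <- he_conv(3, 3, c0, f)
  add_bn("stem.bn", f)
  in_ch <- f
  for (i in 1:4) {
    out_ch <- f * 2L^(i - 1L)
    pre <- sprintf("m%d", i)
    params[[paste0(pre, ".conv1.W")]] <- he_conv(3, 3, in_ch, out_ch)
    add_bn(paste0(pre, ".bn1"), out_ch)
    params[[paste0(pre, ".conv2.W")]] <- he_conv(3, 3, out_ch, out_ch)
    add_bn(paste0(pre, ".bn2"), out_ch)
    if (module_has_projection(config, i)) {
      params[[paste0(pre, ".shortcut.conv.W")]] <- he_conv(1, 1, in_ch, out_ch)
      add_bn(paste0(pre, ".shortcut.bn"), out_ch)
    }
    in_ch <- out_ch
  }
  lim <- sqrt(6 / (in_ch + K))
  params[["dense.W"]] <- matrix(stats::runif(K * in_ch, -lim, lim),
                                nrow = K, ncol = in_ch)
  params[["dense.b"]] <- rep(0, K)

  structure(list(config = config, params = params, buffers = buffers),
            class = "resmini_model")
}

module_has_projection <- function(config, i) {
  in_ch <- config$base_width * if (i == 1L) 1L else 2L^(i - 2L)
  out_ch <- config$base_width * 2L^(i - 1L)
  config$shortcut_policy == "projection_all" ||
    config$module_strides[i] != 1L || in_ch != out_ch
}

#' Realized parameter count of a built model
#'
#' Sums the lengths of every weight array (and, optionally, batch-norm
#' running statistics) actually held by the model; by construction this
#' equals the closed-form count from [count_parameters()].
#'
#' @param model A [build_model()] result.
#' @param include_bn_statistics Include running mean/variance buffers?
#' @return Numeric total.
#' @export
realized_parameter_count <- function(model, include_bn_statistics = TRUE) {
  n <- sum(vapply(model$params, length, numeric(1)))
  if (include_bn_statistics)
    n <- n + sum(vapply(model$buffers, length, numeric(1)))
  n
}

as_input_batch <- function(x, channels) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1], d[2], channels, d[3] / channels)
  d <- dim(x)
  if (length(d) != 4L)
    stop("input must be an (H, W, C, N) array", call. = FALSE)
  if (d[3] != channels)
    stop(sprintf("expected %d input channel(s), got %d", channels, d[3]),
         call. = FALSE)
  x
}

# Full forward pass. training=TRUE uses batch statistics, records caches
# for backprop and returns updated running statistics.
resmini_forward <- function(model, x, training = FALSE) {
  p <- model$params
  b <- model$buffers
  cfg <- model$config
  caches <- list()

  bn <- function(x, name) {
    r <- batchnorm_forward(x, p[[paste0(name, ".gamma")]],
                           p[[paste0(name, ".beta")]],
                           b[[paste0(name, ".mean")]],
                           b[[paste0(name, ".var")]],
                           training = training)
    if (training) {
      b[[paste0(name, ".mean")]] <<- r$run_mean
      b[[paste0(name, ".var")]] <<- r$run_var
      caches[[name]] <<- r$ctx
    }
    r$y
  }
  conv <- function(x, name, kh, kw, stride, pad) {
    r <- conv2d_forward(x, p[[paste0(name, ".W")]], kh, kw, stride, pad)
    if (training) caches[[name]] <<- r$ctx
    r$y
  }

  h <- conv(x, "stem.conv", 3L, 3L, 1L, 3L)
  h <- relu_forward(bn(h, "stem.bn"))
  if (training) caches[["stem.relu"]] <- h
  mp <- maxpool_forward(h)
  if (training) caches[["stem.maxpool"]] <- mp$ctx
  h <- mp$y

  for (i in 1:4) {
    pre <- sprintf("m%d", i)
    s <- cfg$module_strides[i]
    inp <- h
    a <- conv(inp, paste0(pre, ".conv1"), 3L, 3L, s, 1L)
    a <- relu_forward(bn(a, paste0(pre, ".bn1")))
    if (training) caches[[paste0(pre, ".relu1")]] <- a
    a <- conv(a, paste0(pre, ".conv2"), 3L, 3L, 1L, 1L)
    a <- relu_forward(bn(a, paste0(pre, ".bn2")))
    if (training) caches[[paste0(pre, ".relu2")]] <- a
    if (module_has_projection(cfg, i)) {
      sc <- conv(inp, paste0(pre, ".shortcut.conv"), 1L, 1L, s, 0L)
      sc <- bn(sc, paste0(pre, ".shortcut.bn"))
    } else {
      sc <- inp
    }
    h <- relu_forward(a + sc)
    if (training) caches[[paste0(pre, ".relu_out")]] <- h
  }

  g <- global_avgpool_forward(h)
  if (training) caches[["gap"]] <- g$ctx
  dn <- dense_forward(g$g, p[["dense.W"]], p[["dense.b"]])
  if (training) caches[["dense"]] <- dn$ctx

  list(logits = dn$z, caches = caches, buffers = b)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
resmini_backward <- function(model, caches, dz) {
  p <- model$params
  cfg <- model$config
  grads <- list()

  dn <- dense_backward(dz, p[["dense.W"]], caches[["dense"]])
  grads[["dense.W"]] <- dn$dw
  grads[["dense.b"]] <- dn$db
  dh <- global_avgpool_backward(dn$dg, caches[["gap"]])

  bn_back <- function(dy, name) {
    r <- batchnorm_backward(dy, caches[[name]])
    grads[[paste0(name, ".gamma")]] <<- r$dgamma
    grads[[paste0(name, ".beta")]] <<- r$dbeta
    r$dx
  }
  conv_back <- function(dy, name) {
    r <- conv2d_backward(dy, p[[paste0(name, ".W")]], caches[[name]])
    grads[[paste0(name, ".W")]] <<- r$dw
    r$dx
  }

  for (i in 4:1) {
    pre <- sprintf("m%d", i)
    dh <- relu_backward(dh, caches[[paste0(pre, ".relu_out")]])
    dsc <- dh
    da <- relu_backward(dh, caches[[paste0(pre, ".relu2")]])
    da <- bn_back(da, paste0(pre, ".bn2"))
    da <- conv_back(da, paste0(pre, ".conv2"))
    da <- relu_backward(da, caches[[paste0(pre, ".relu1")]])
    da <- bn_back(da, paste0(pre, ".bn1"))
    da <- conv_back(da, paste0(pre, ".conv1"))
    if (module_has_projection(cfg, i)) {
      dsc <- bn_back(dsc, paste0(pre, ".shortcut.bn"))
      dsc <- conv_back(dsc, paste0(pre, ".shortcut.conv"))
    }
    dh <- da + dsc
  }

  dh <- maxpool_backward(dh, caches[["stem.maxpool"]])
  dh <- relu_backward(dh, caches[["stem.relu"]])
  dh <- bn_back(dh, "stem.bn")
  conv_back(dh, "stem.conv")
  grads
}

#' Predict class probabilities
#'
#' Runs the network in inference mode (batch norm uses running
#' statistics). Rows of the result sum to 1.
#'
#' @param object A `resmini_model`.
#' @param newdata An `(H, W, C, N)` array, or `(H, W, N)` for
#'   single-channel models, or a single `(H, W)` matrix.
#' @param batch_size Images per forward chunk (memory bound).
#' @param ... Unused.
#' @return An `N x K` matrix of class probabilities.
#' @export
predict.resmini_model <- function(object, newdata, batch_size = 64L, ...) {
  x <- as_input_batch(newdata, object$config$input_channels)
  N <- dim(x)[4]
  K <- object$config$num_classes
  out <- matrix(NA_real_, N, K)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fw <- resmini_forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- t(softmax_probs(fw$logits))
  }
  out
}

#' Predict hard class labels
#'
#' Argmax over [predict.resmini_model()] probabilities; ties break toward
#' the lower class index.
#'
#' @inheritParams predict.resmini_model
#' @return Integer vector of 0-based class labels.
#' @export
predict_classes <- function(object, newdata, batch_size = 64L) {
  probs <- predict(object, newdata, batch_size = batch_size)
  max.col(probs, ties.method = "first") - 1L
}

#' @export
print.resmini_model <- function(x, ...) {
  cat(sprintf("ResMini model: f=%d, K=%d, %s parameters (incl. BN statistics)\n",
              x$config$base_width, x$config$num_classes,
              format(realized_parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model
#'
#' The entire model (configuration, weights, batch-norm statistics) is
#' serialized to a single RDS archive; loading restores bit-identical
#' predictions.
#'
#' @param model A `resmini_model`.
#' @param path File path for the archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "resmini_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "resmini_model"))
  model
}
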