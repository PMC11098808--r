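# Minimal CNN engine: forward/backward primitives on arrays laid out as
# (H, W, C, N), double precision. Convolutions go through im2col + BLAS
# GEMM; batch norm and pooling use reshape tricks so no per-pixel R loops
# run anywhere. All functions are internal.

conv_out_dim <- function(size, kernel, stride, pad) {
  as.integer((size + 2L * pad - kernel) %/% stride + 1L)
}

# Linear indices into a padded (ph, pw, cin) plane for im2col.
# Rows ordered (dh fastest, dw, c); columns ordered (oi fastest, oj).
im2col_index <- function(ph, pw, cin, kh, kw, stride, oh, ow) {
  r_off <- rep(seq_len(kh), times = kw * cin)
  c_off <- rep(rep(seq_len(kw), each = kh), times = cin)
  ch <- rep(seq_len(cin), each = kh * kw)
  row_lin <- r_off + (c_off - 1L) * ph + (ch - 1L) * (ph * pw)
  col_start <- as.vector(outer((seq_len(oh) - 1L) * stride,
                               (seq_len(ow) - 1L) * stride * ph, "+"))
  outer(row_lin, col_start, "+")
}

# Gather indices are pure geometry, identical for every batch of the same
# shape; memoize the batched index vector.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index_batch <- function(ph, pw, cin, kh, kw, stride, oh, ow, N) {
  key <- paste(ph, pw, cin, kh, kw, stride, oh, ow, N, sep = "x")
  val <- .im2col_cache[[key]]
  if (is.null(val)) {
    idx <- as.integer(im2col_index(ph, pw, cin, kh, kw, stride, oh, ow))
    plane <- as.integer(ph * pw * cin)
    val <- rep(idx, times = N) + rep((seq_len(N) - 1L) * plane, each = length(idx))
    .im2col_cache[[key]] <- val
  }
  val
}

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[-(1:2)]))
  idx <- c(list(pad + seq_len(d[1]), pad + seq_len(d[2])),
           rep(list(quote(expr = )), length(d) - 2L))
  do.call(`[<-`, c(list(xp), idx, list(value = x)))
}

# weights: matrix (kh*kw*cin) x cout, row order matching im2col_index
conv2d_forward <- function(x, w, kh, kw, stride, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  oh <- conv_out_dim(H, kh, stride, pad)
  ow <- conv_out_dim(W, kw, stride, pad)
  if (oh < 1L || ow < 1L)
    stop(sprintf("input %dx%d collapses below 1 pixel in a %dx%d/stride-%d convolution",
                 H, W, kh, kw, stride), call. = FALSE)
  cout <- ncol(w)
  xp <- pad_hw(x, pad)
  ph <- H + 2L * pad; pw <- W + 2L * pad
  idxN <- im2col_index_batch(ph, pw, C, kh, kw, stride, oh, ow, N)
  xcol <- xp[idxN]
  dim(xcol) <- c(kh * kw * C, oh * ow * N)
  y <- crossprod(w, xcol)
  dim(y) <- c(cout, oh, ow, N)
  y <- aperm(y, c(2, 3, 1, 4))
  list(y = y,
       ctx = list(xcol = xcol, in_dim = d, oh = oh, ow = ow,
                  ph = ph, pw = pw, kh = kh, kw = kw,
                  stride = stride, pad = pad))
}

conv2d_backward <- function(dy, w, ctx) {
  d <- ctx$in_dim
  C <- d[3]; N <- d[4]
  oh <- ctx$oh; ow <- ctx$ow
  cout <- ncol(w)
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(cout, oh * ow * N)
  dw <- tcrossprod(ctx$xcol, dym)
  dxcol <- w %*% dym
  dxp <- cpp_col2im(dxcol, ctx$kh, ctx$kw, C, oh, ow, N,
                    ctx$ph, ctx$pw, ctx$stride)
  p <- ctx$pad
  if (p > 0L) {
    dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
    dim(dx) <- d
  } else {
    dx <- dxp
  }
  list(dx = dx, dw = dw)
}

channel_sum <- function(a, HW, C, N) {
  dim(a) <- c(HW, C, N)
  if (N == 1L) colSums(a[, , 1, drop = FALSE])[, 1] else rowSums(colSums(a))
}

# expand a per-channel vector to the flat (H,W,C,N) layout (recycled over N)
.ch_expand <- function(v, HW) rep(v, each = HW)

# Running statistics use the 0.9 exponential-average convention so they
# track batch statistics within a few dozen steps -- important at this
# dataset scale, where an epoch is only a handful of batches.
batchnorm_forward <- function(x, gamma, beta, run_mean, run_var,
                              training, momentum = 0.9, eps = 1e-3) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (training) {
    M <- HW * N
    mu <- channel_sum(x, HW, C, N) / M
    ssq <- channel_sum(x * x, HW, C, N) / M
    v <- pmax(ssq - mu^2, 0)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - .ch_expand(mu, HW)) * .ch_expand(inv, HW)
  y <- xhat * .ch_expand(gamma, HW) + .ch_expand(beta, HW)
  dim(y) <- d
  dim(xhat) <- d
  list(y = y, run_mean = run_mean, run_var = run_var,
       ctx = list(xhat = xhat, inv = inv, gamma = gamma,
                  HW = HW, C = C, N = N))
}

batchnorm_backward <- function(dy, ctx) {
  HW <- ctx$HW; C <- ctx$C; N <- ctx$N
  M <- HW * N
  d <- dim(dy)
  dbeta <- channel_sum(dy, HW, C, N)
  dim(dy) <- d
  dgamma <- channel_sum(dy * ctx$xhat, HW, C, N)
  gi <- ctx$gamma * ctx$inv
  dx <- .ch_expand(gi, HW) *
    (dy - .ch_expand(dbeta / M, HW) - ctx$xhat * .ch_expand(dgamma / M, HW))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_backward <- function(dy, y) {
  dx <- dy
  dx[y <= 0] <- 0
  dx
}

maxpool_forward <- function(x, kh = 3L, kw = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; M <- d[3] * d[4]
  oh <- conv_out_dim(H, kh, stride, pad)
  ow <- conv_out_dim(W, kw, stride, pad)
  xp <- pad_hw(array(x, c(H, W, M)), pad, value = -Inf)
  ph <- H + 2L * pad; pw <- W + 2L * pad
  R <- kh * kw
  idxN <- im2col_index_batch(ph, pw, 1L, kh, kw, stride, oh, ow, M)
  xcol <- xp[idxN]
  dim(xcol) <- c(R, oh * ow * M)
  cm <- cpp_colmax(xcol)
  y <- cm$max
  which_r <- cm$which
  chosen <- idxN[(seq_along(y) - 1L) * R + which_r]
  dim(y) <- c(oh, ow, d[3], d[4])
  list(y = y,
       ctx = list(chosen = chosen, which_r = which_r, R = R,
                  ph = ph, pw = pw, M = M, pad = pad, in_dim = d))
}

maxpool_backward <- function(dy, ctx) {
  d <- ctx$in_dim
  dxp <- cpp_scatter_add(ctx$ph * ctx$pw * ctx$M, ctx$chosen, as.numeric(dy))
  dim(dxp) <- c(ctx$ph, ctx$pw, ctx$M)
  p <- ctx$pad
  dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
  dim(dx) <- d
  dx
}

global_avgpool_forward <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  x3 <- x
  dim(x3) <- c(HW, d[3], d[4])
  g <- colMeans(x3)
  if (is.null(dim(g))) dim(g) <- c(d[3], d[4])
  list(g = g, ctx = list(in_dim = d, HW = HW))
}

global_avgpool_backward <- function(dg, ctx) {
  d <- ctx$in_dim
  dx <- rep(as.numeric(dg) / ctx$HW, each = ctx$HW)
  dim(dx) <- d
  dx
}

dense_forward <- function(g, w, b) {
  z <- w %*% g + b
  list(z = z, ctx = list(g = g))
}

dense_backward <- function(dz, w, ctx) {
  list(dg = crossprod(w, dz),
       dw = tcrossprod(dz, ctx$g),
       db = rowSums(dz))
}

# logits: K x N; labels: 1-based integer vector of length N
softmax_probs <- function(z) {
  K <- nrow(z)
  zm <- z - rep(apply(z, 2, max), each = K)
  e <- exp(zm)
  e / rep(colSums(e), each = K)
}

softmax_xent <- function(z, labels) {
  N <- ncol(z)
  p <- softmax_probs(z)
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dz <- p
  dz[cbind(labels, seq_len(N))] <- dz[cbind(labels, seq_len(N))] - 1
  list(loss = loss, probs = p, dz = dz / N)
}

# ---- ADAM ------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)  # keeps matrix/vector shape
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsilon)
  }
  list(params = params, state = state)
}
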