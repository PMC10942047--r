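## Small convolutional network backend, written directly in R.
##
## Layout convention: activations are arrays of dim (H, W, N, C) so that
## the im2col slices used by the 3x3 "same" convolutions are contiguous
## matrix views (H*W*N rows, C columns). Kernels are arrays (9, Cin, Cout).
## The network is 3 conv blocks (ReLU, 2x2 mean-pool after the first two),
## global average pooling and a dense head with one logit per finding —
## deliberately small so cross-validated training is cheap on a single
## CPU; larger models plug in through the same backend contract.

conv_forward <- function(x, kernel, bias) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; n <- d[3L]; cin <- d[4L]
  cout <- dim(kernel)[3L]
  xp <- array(0, c(h + 2L, w + 2L, n, cin))
  xp[2:(h + 1L), 2:(w + 1L), , ] <- x
  ymat <- matrix(rep(bias, each = h * w * n), h * w * n, cout)
  slices <- vector("list", 9L)
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1L
      s <- matrix(xp[dy + (1:h), dx + (1:w), , , drop = FALSE], h * w * n, cin)
      slices[[k]] <- s
      ymat <- ymat + s %*% matrix(kernel[k, , ], cin, cout)
    }
  }
  list(out = array(ymat, c(h, w, n, cout)), slices = slices, dim_in = d)
}

conv_backward <- function(dy, kernel, cache) {
  d <- cache$dim_in
  h <- d[1L]; w <- d[2L]; n <- d[3L]; cin <- d[4L]
  cout <- dim(kernel)[3L]
  g <- matrix(dy, h * w * n, cout)
  dk <- array(0, dim(kernel))
  dxp <- array(0, c(h + 2L, w + 2L, n, cin))
  k <- 0L
  for (dx in 0:2) {
    for (dy_ in 0:2) {
      k <- k + 1L
      dk[k, , ] <- crossprod(cache$slices[[k]], g)
      contrib <- array(g %*% t(matrix(kernel[k, , ], cin, cout)),
                       c(h, w, n, cin))
      dxp[dy_ + (1:h), dx + (1:w), , ] <-
        dxp[dy_ + (1:h), dx + (1:w), , , drop = FALSE] + contrib
    }
  }
  list(dx = dxp[2:(h + 1L), 2:(w + 1L), , , drop = FALSE],
       dk = dk, db = colSums(g))
}

meanpool2 <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1L], by = 2L)
  jo <- seq(1L, d[2L], by = 2L)
  (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
     x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

meanpool2_backward <- function(dy, dim_in) {
  dx <- array(0, dim_in)
  io <- seq(1L, dim_in[1L], by = 2L)
  jo <- seq(1L, dim_in[2L], by = 2L)
  q <- dy / 4
  dx[io, jo, , ] <- q
  dx[io + 1L, jo, , ] <- q
  dx[io, jo + 1L, , ] <- q
  dx[io + 1L, jo + 1L, , ] <- q
  dx
}

cnn_init <- function(side, channels, n_out, seed) {
  withr::with_seed(seed, {
    cin <- c(1L, channels[-length(channels)])
    kernels <- purrr::map2(cin, channels, function(ci, co) {
      array(stats::rnorm(9L * ci * co, 0, sqrt(2 / (9L * ci))), c(9L, ci, co))
    })
    biases <- purrr::map(channels, function(co) numeric(co))
    cl <- channels[length(channels)]
    list(kernels = kernels, biases = biases,
         w_dense = matrix(stats::rnorm(cl * n_out, 0, sqrt(2 / cl)), cl, n_out),
         b_dense = numeric(n_out))
  })
}

cnn_forward <- function(params, x, want_grads = FALSE) {
  caches <- list()
  a <- x
  n_layers <- length(params$kernels)
  for (l in seq_len(n_layers)) {
    cv <- conv_forward(a, params$kernels[[l]], params$biases[[l]])
    pre <- cv$out
    act <- pre * (pre > 0)
    pooled <- if (l < n_layers) meanpool2(act) else act
    caches[[l]] <- list(conv = cv, pre = pre, act_dim = dim(act))
    a <- pooled
  }
  # a: last conv activations (H', W', N, C)
  d <- dim(a)
  z <- matrix(colMeans(matrix(a, d[1L] * d[2L], d[3L] * d[4L])),
              d[3L], d[4L])  # GAP: (N, C)
  logits <- z %*% params$w_dense +
    matrix(params$b_dense, d[3L], length(params$b_dense), byrow = TRUE)
  list(logits = logits, feature_maps = a, gap = z,
       caches = if (want_grads) caches else NULL)
}

cnn_backward <- function(params, fw, dlogits) {
  d <- dim(fw$feature_maps)
  grads <- list(kernels = vector("list", length(params$kernels)),
                biases = vector("list", length(params$biases)))
  grads$w_dense <- crossprod(fw$gap, dlogits)
  grads$b_dense <- colSums(dlogits)
  dz <- dlogits %*% t(params$w_dense)           # (N, C)
  # undo GAP: spread evenly over spatial positions
  da <- array(rep(as.vector(dz), each = d[1L] * d[2L]) / (d[1L] * d[2L]), d)
  n_layers <- length(params$kernels)
  for (l in rev(seq_len(n_layers))) {
    cache <- fw$caches[[l]]
    if (l < n_layers) da <- meanpool2_backward(da, cache$act_dim)
    da <- da * (cache$pre > 0)
    bk <- conv_backward(da, params$kernels[[l]], cache$conv)
    grads$kernels[[l]] <- bk$dk
    grads$biases[[l]] <- bk$db
    da <- bk$dx
  }
  grads
}

adam_init <- function(params) {
  zeros_like <- function(p) {
    if (is.list(p)) lapply(p, zeros_like) else p * 0
  }
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

# Stack images into the (H, W, N, 1) input array. Each image is centred
# by its own mean: zero-mean inputs condition the first-layer gradients
# and make small-sample training far more reliable.
images_to_array <- function(images) {
  side <- nrow(images[[1L]])
  x <- array(0, c(side, side, length(images), 1L))
  for (i in seq_along(images)) x[, , i, 1L] <- images[[i]] - mean(images[[i]])
  x
}

#' Small convolutional network backend
#'
#' The default trainable backend: three 3x3 convolution blocks
#' (ReLU, 2x2 mean pooling after the first two), global average pooling
#' and a dense head with one logit per finding. Training uses ADAM on the
#' multi-target binary cross-entropy with logits ([multi_target_loss()]).
#' The object satisfies the backend contract used by
#' [train_and_predict()] and [grad_cam()]: functions `fit`,
#' `predict_logits` and `feature_maps_and_grads`.
#'
#' @param channels Channel widths of the three conv blocks.
#' @return A list of class `rp_backend`.
#' @export
cnn_backend <- function(channels = c(8L, 16L, 32L)) {
  backend <- list(name = "cnn", channels = channels)
  backend$fit <- function(images, labels, config) {
    stopifnot(is.matrix(labels), nrow(labels) == length(images))
    n_out <- ncol(labels)
    side <- nrow(images[[1L]])
    params <- cnn_init(side, channels, n_out, config$seed)
    state <- adam_init(params)
    n <- length(images)
    history <- numeric(config$epochs)
    withr::with_seed(config$seed + 1L, {
      for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(n)
        epoch_loss <- 0
        for (start in seq(1L, n, by = config$batch_size)) {
          idx <- ord[start:min(start + config$batch_size - 1L, n)]
          batch <- images[idx]
          if (isTRUE(config$augment)) {
            batch <- lapply(batch, augment_once, policy = config$policy)
          }
          x <- images_to_array(batch)
          y <- labels[idx, , drop = FALSE]
          fw <- cnn_forward(params, x, want_grads = TRUE)
          u <- fw$logits
          # stable BCE-with-logits, summed over findings, averaged over batch
          loss <- sum(pmax(u, 0) - u * y + log1p(exp(-abs(u)))) / nrow(y)
          dlogits <- (sigmoid(u) - y) / nrow(y)
          grads <- cnn_backward(params, fw, dlogits)
          st <- adam_step(params, grads, state, config$learning_rate)
          params <- st$params
          state <- st$state
          epoch_loss <- epoch_loss + loss * nrow(y)
        }
        history[[epoch]] <- epoch_loss / n
      }
    })
    structure(list(params = params, side = side, n_out = n_out,
                   history = history, backend = backend),
              class = "rp_model")
  }
  backend$predict_logits <- function(model, images, batch_size = 256L) {
    n <- length(images)
    out <- matrix(0, n, model$n_out)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, n)
      x <- images_to_array(images[idx])
      out[idx, ] <- cnn_forward(model$params, x)$logits
    }
    out
  }
  backend$feature_maps_and_grads <- function(model, image, finding) {
    x <- images_to_array(list(image))
    fw <- cnn_forward(model$params, x)
    d <- dim(fw$feature_maps)
    maps <- array(fw$feature_maps[, , 1L, ], c(d[1L], d[2L], d[4L]))
    # with GAP + dense head the gradient of a logit w.r.t. map c is the
    # constant w_dense[c, finding] / (H' * W')
    grads <- array(rep(model$params$w_dense[, finding],
                       each = d[1L] * d[2L]) / (d[1L] * d[2L]),
                   c(d[1L], d[2L], d[4L]))
    list(maps = maps, grads = grads)
  }
  structure(backend, class = "rp_backend")
}
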