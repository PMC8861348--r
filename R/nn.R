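# Minimal dense/conv neural-network kernels used by the cGAN module.
#
# Tensors are R arrays with dim (H, W, N, C): spatial, batch, channels.
# Convolutions are 3x3 (stride 1 "same" or stride 2 down-sampling) or 1x1,
# implemented as 9 strided-slice matrix products against BLAS, which keeps
# everything in base R and bit-reproducible. Backward passes are exact
# transposes of the forward computations (checked against finite
# differences in the test suite).

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

conv_out_len <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1L

# forward convolution; W dim (k, k, Cin, Cout), b length Cout
conv_fwd <- function(x, W, b, s = 1L, p = 1L) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x)
  ho <- conv_out_len(d[1], k, s, p); wo <- conv_out_len(d[2], k, s, p)
  xp <- pad_hw(x, p)
  nrow <- ho * wo * d[3]
  outm <- matrix(0, nrow, cout)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    xs <- xp[di + s * (seq_len(ho) - 1), dj + s * (seq_len(wo) - 1), , ,
             drop = FALSE]
    dim(xs) <- c(nrow, cin)
    outm <- outm + xs %*% matrix(W[di, dj, , ], cin, cout)
  }
  out <- array(outm, c(ho, wo, d[3], cout))
  for (c in seq_len(cout)) out[, , , c] <- out[, , , c] + b[c]
  out
}

# backward convolution: gradients for input, weights and bias (either
# component can be skipped when not needed)
conv_bwd <- function(x, W, dout, s = 1L, p = 1L, need_dx = TRUE,
                     need_dW = TRUE) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); do_ <- dim(dout)
  ho <- do_[1]; wo <- do_[2]
  xp <- if (need_dW) pad_hw(x, p) else NULL
  dxp <- if (need_dx) array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], cin))
         else NULL
  nrow <- ho * wo * d[3]
  dm <- dout; dim(dm) <- c(nrow, cout)
  dW <- if (need_dW) array(0, dim(W)) else NULL
  iz <- seq_len(ho); jz <- seq_len(wo)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    ri <- di + s * (iz - 1); rj <- dj + s * (jz - 1)
    if (need_dW) {
      xs <- xp[ri, rj, , , drop = FALSE]
      dim(xs) <- c(nrow, cin)
      dW[di, dj, , ] <- crossprod(xs, dm)
    }
    if (need_dx) {
      dxs <- dm %*% t(matrix(W[di, dj, , ], cin, cout))
      dim(dxs) <- c(ho, wo, d[3], cin)
      dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] + dxs
    }
  }
  dx <- if (!need_dx) NULL
        else if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , ,
                            drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = colSums(dm))
}

# 3x3 stride-2 transpose convolution doubling H and W.
# W dim (3, 3, Cout, Cin): the weights of the stride-2 convolution whose
# adjoint this layer applies; forward = conv backward-data, backward-data =
# conv forward, so both reuse the kernels above.
tconv_fwd <- function(x, W, b) {
  d <- dim(x) # (H, W, N, Cin)
  cout <- dim(W)[3]
  big <- c(2L * d[1], 2L * d[2], d[3], cout)
  dummy <- array(0, big)
  out <- conv_bwd(dummy, W, dout = x, s = 2L, p = 1L, need_dW = FALSE)$dx
  for (c in seq_len(cout)) out[, , , c] <- out[, , , c] + b[c]
  out
}

tconv_bwd <- function(x, W, dout) {
  # dout has the big (2H) shape; dx the small; dW via the underlying conv
  cout <- dim(W)[3]
  dx <- conv_fwd(dout, W, b = rep(0, dim(W)[4]), s = 2L, p = 1L)
  bw <- conv_bwd(dout, W, dout = x, s = 2L, p = 1L, need_dx = FALSE)
  dm <- dout; dim(dm) <- c(prod(dim(dout)[1:3]), cout)
  list(dx = dx, dW = bw$dW, db = colSums(dm))
}

# batch normalization over (H, W, N) per channel
bn_fwd <- function(x, gamma, beta, training, rmean, rvar, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x); nc <- d[4]
  xm <- x; dim(xm) <- c(prod(d[1:3]), nc)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(invstd, each = nrow(xm))
  outm <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  out <- array(outm, d)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                               d = d),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(cache, dout) {
  d <- cache$d; n <- prod(d[1:3])
  dm <- dout; dim(dm) <- c(n, d[4])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  g <- rep(cache$gamma * cache$invstd, each = n)
  dx <- g * (dm - rep(dbeta / n, each = n) -
               cache$xhat * rep(dgamma / n, each = n))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dout) dout * (x > 0)
lrelu_fwd <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(x, dout, slope) dout * ifelse(x > 0, 1, slope)

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, mask = NULL))
  mask <- array(runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}
dropout_bwd <- function(mask, dout) if (is.null(mask)) dout else dout * mask

# parameter initialization: N(0, sd), biases zero, BN gamma 1 / beta 0
init_conv <- function(k, cin, cout, sd) {
  list(W = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = rep(0, cout))
}
init_bn <- function(nc) list(gamma = rep(1, nc), beta = rep(0, nc),
                             rmean = rep(0, nc), rvar = rep(1, nc))
init_dense <- function(nin, nout, sd) {
  list(W = matrix(rnorm(nin * nout, 0, sd), nin, nout), b = rep(0, nout))
}

# ---- Adam ---------------------------------------------------------------

# params/grads are flat named lists of numeric arrays with matching names
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# binary cross-entropy on sigmoid outputs; returns loss and dlogits
bce_loss <- function(p, target) {
  eps <- 1e-7
  loss <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  list(loss = loss, dlogit = (p - target) / length(p))
}
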