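#' Configuration for the conditional-GAN sCT model
#'
#' Defaults follow the published training recipe (learning rate 1e-4, batch
#' size 10, adversarial and L1 loss weights both 1, weight initialization
#' N(0, 1e-4), dropout 0.5, leaky-ReLU slope 0.2). The full-scale profile
#' uses 320x320 slices with a base of 64 encoder filters doubling to 1024 at
#' the bottleneck; the desk profile (the package default) runs the same
#' architecture at 64x64 with filter counts scaled by 1/4 and 5 epochs so it
#' trains on a CPU in minutes.
#'
#' @param matrix_size slice size in pixels; must be divisible by 32
#'   (four generator down-sampling stages, five in the discriminator).
#' @param base_filters encoder width of the first block (desk 16,
#'   full-scale 64).
#' @param learning_rate,batch_size,epochs Adam learning rate, slices per
#'   batch, training epochs.
#' @param loss_weight_adv,loss_weight_l1 weights of the adversarial and L1
#'   terms of the generator loss.
#' @param init_sd SD of the Gaussian weight initialization.
#' @param dropout_rate,leaky_slope dropout after the bottleneck and widest
#'   decoder block; discriminator leaky-ReLU slope.
#' @param hu_range HU window mapped onto the tanh output range.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return A `cgan_config` list.
#' @export
cgan_config <- function(matrix_size = 64L, base_filters = 16L,
                        learning_rate = 1e-4, batch_size = 10L,
                        epochs = 5L, loss_weight_adv = 1,
                        loss_weight_l1 = 1, init_sd = 1e-4,
                        dropout_rate = 0.5, leaky_slope = 0.2,
                        hu_range = c(-1000, 1500), seed = 1L) {
  stopifnot(matrix_size %% 32 == 0, learning_rate > 0, batch_size >= 1,
            epochs >= 1, init_sd > 0, dropout_rate >= 0, dropout_rate < 1)
  structure(list(matrix_size = as.integer(matrix_size),
                 base_filters = as.integer(base_filters),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 loss_weight_adv = loss_weight_adv,
                 loss_weight_l1 = loss_weight_l1, init_sd = init_sd,
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 hu_range = hu_range, seed = as.integer(seed)),
            class = "cgan_config")
}

# encoder/decoder widths: base doubling at each of 4 down-sampling stages
gen_widths <- function(base) as.integer(base * c(1, 2, 4, 8, 16))

#' Build an untrained generator (U-Net) from a config
#'
#' Encoder: per level a 3x3 stride-1 conv block then a 3x3 stride-2
#' down-sampling conv, widths doubling from `base_filters` to the 16x
#' bottleneck; decoder: 3x3 stride-2 transpose convs with encoder skip
#' concatenation and 3x3 conv blocks; 1x1 conv + tanh output. Batch norm +
#' ReLU everywhere except the output block; dropout after the bottleneck
#' and after the widest decoder block.
#'
#' @param cfg a [cgan_config()].
#' @return A `cgan_generator` (list of parameter tensors).
#' @export
build_generator <- function(cfg) {
  f <- gen_widths(cfg$base_filters)
  sd <- cfg$init_sd
  L <- list()
  cin <- 1L
  for (i in 1:4) {
    L[[paste0("enc", i)]] <- c(init_conv(3, cin, f[i], sd), init_bn(f[i]))
    L[[paste0("down", i)]] <- c(init_conv(3, f[i], f[i + 1], sd),
                                init_bn(f[i + 1]))
    cin <- f[i + 1]
  }
  L$bottleneck <- c(init_conv(3, f[5], f[5], sd), init_bn(f[5]))
  for (i in 4:1) {
    up <- init_conv(3, f[i], f[i + 1], sd) # tconv: (k, k, Cout, Cin)
    dim(up$W) <- c(3, 3, f[i], f[i + 1])
    up$b <- rep(0, f[i])
    L[[paste0("up", i)]] <- c(up, init_bn(f[i]))
    L[[paste0("dec", i)]] <- c(init_conv(3, 2L * f[i], f[i], sd),
                               init_bn(f[i]))
  }
  L$final <- init_conv(1, f[1], 1L, sd)
  structure(list(layers = L, cfg = cfg), class = "cgan_generator")
}

#' @rdname build_generator
#' @export
build_discriminator <- function(cfg) {
  filt <- c(8L, 16L, 32L, 64L, 128L)
  sd <- cfg$init_sd
  L <- list()
  cin <- 2L # (MRI, CT-or-sCT) channel pair
  for (i in seq_along(filt)) {
    L[[paste0("cd", i)]] <- c(init_conv(3, cin, filt[i], sd),
                              init_bn(filt[i]))
    cin <- filt[i]
  }
  L$c128 <- init_conv(1, 128L, 128L, sd)
  side <- cfg$matrix_size %/% 32L
  L$fc <- init_dense(side * side * 128L, 1L, sd)
  structure(list(layers = L, cfg = cfg), class = "cgan_discriminator")
}

#' Number of trainable parameters of a model
#' @param model a `cgan_generator` or `cgan_discriminator`.
#' @return Integer count (batch-norm running statistics excluded).
#' @export
count_parameters <- function(model) {
  s <- 0L
  for (lay in model$layers)
    for (nm in intersect(names(lay), c("W", "b", "gamma", "beta")))
      s <- s + length(lay[[nm]])
  s
}

# ---- generator forward / backward ---------------------------------------

bn_block_fwd <- function(lay, x, s, training) {
  z <- conv_fwd(x, lay$W, lay$b, s = s, p = 1L)
  bn <- bn_fwd(z, lay$gamma, lay$beta, training, lay$rmean, lay$rvar)
  list(out = relu_fwd(bn$out),
       cache = list(x = x, bn = bn$cache, bnout = bn$out),
       rmean = bn$rmean, rvar = bn$rvar)
}

bn_block_bwd <- function(lay, cache, dout, s) {
  da <- relu_bwd(cache$bnout, dout)
  b <- bn_bwd(cache$bn, da)
  cv <- conv_bwd(cache$x, lay$W, b$dx, s = s, p = 1L)
  list(dx = cv$dx, g = list(W = cv$dW, b = cv$db, gamma = b$dgamma,
                            beta = b$dbeta))
}

generator_forward <- function(gen, mri, training = TRUE) {
  L <- gen$layers
  cfg <- gen$cfg
  cache <- list()
  upd <- list()
  x <- mri
  skips <- list()
  for (i in 1:4) {
    nm <- paste0("enc", i)
    r <- bn_block_fwd(L[[nm]], x, 1L, training)
    cache[[nm]] <- r$cache; upd[[nm]] <- r[c("rmean", "rvar")]
    skips[[i]] <- r$out
    nm <- paste0("down", i)
    r <- bn_block_fwd(L[[nm]], r$out, 2L, training)
    cache[[nm]] <- r$cache; upd[[nm]] <- r[c("rmean", "rvar")]
    x <- r$out
  }
  r <- bn_block_fwd(L$bottleneck, x, 1L, training)
  cache$bottleneck <- r$cache; upd$bottleneck <- r[c("rmean", "rvar")]
  dr <- dropout_fwd(r$out, cfg$dropout_rate, training)
  cache$drop_b <- dr$mask
  x <- dr$out
  for (i in 4:1) {
    nm <- paste0("up", i)
    lay <- L[[nm]]
    z <- tconv_fwd(x, lay$W, lay$b)
    bn <- bn_fwd(z, lay$gamma, lay$beta, training, lay$rmean, lay$rvar)
    a <- relu_fwd(bn$out)
    cache[[nm]] <- list(x = x, bn = bn$cache, bnout = bn$out)
    upd[[nm]] <- bn[c("rmean", "rvar")]
    cat_in <- abind4(a, skips[[i]])
    nm <- paste0("dec", i)
    r <- bn_block_fwd(L[[nm]], cat_in, 1L, training)
    cache[[nm]] <- r$cache; upd[[nm]] <- r[c("rmean", "rvar")]
    x <- r$out
    if (i == 4) { # widest decoder block
      dr <- dropout_fwd(x, cfg$dropout_rate, training)
      cache$drop_d <- dr$mask
      x <- dr$out
    }
  }
  z <- conv_fwd(x, L$final$W, L$final$b, s = 1L, p = 0L)
  out <- tanh(z)
  cache$final <- list(x = x, out = out)
  list(out = out, cache = cache, bn_updates = upd)
}

abind4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

generator_backward <- function(gen, cache, dout) {
  L <- gen$layers
  g <- list()
  fc <- cache$final
  dz <- dout * (1 - fc$out^2) # tanh'
  cv <- conv_bwd(fc$x, L$final$W, dz, s = 1L, p = 0L)
  g$final <- list(W = cv$dW, b = cv$db)
  dx <- cv$dx
  dskip <- vector("list", 4)
  for (i in 1:4) {
    if (i == 4) dx <- dropout_bwd(cache$drop_d, dx)
    nm <- paste0("dec", i)
    b <- bn_block_bwd(L[[nm]], cache[[nm]], dx, 1L)
    g[[nm]] <- b$g
    nc <- dim(b$dx)[4] / 2
    da <- b$dx[, , , seq_len(nc), drop = FALSE]
    dskip[[i]] <- b$dx[, , , nc + seq_len(nc), drop = FALSE]
    nm <- paste0("up", i)
    ca <- cache[[nm]]
    dbn_out <- relu_bwd(ca$bnout, da)
    bb <- bn_bwd(ca$bn, dbn_out)
    tc <- tconv_bwd(ca$x, L[[nm]]$W, bb$dx)
    g[[nm]] <- list(W = tc$dW, b = tc$db, gamma = bb$dgamma,
                    beta = bb$dbeta)
    dx <- tc$dx
  }
  dx <- dropout_bwd(cache$drop_b, dx)
  b <- bn_block_bwd(L$bottleneck, cache$bottleneck, dx, 1L)
  g$bottleneck <- b$g
  dx <- b$dx
  for (i in 4:1) {
    nm <- paste0("down", i)
    b <- bn_block_bwd(L[[nm]], cache[[nm]], dx, 2L)
    g[[nm]] <- b$g
    dx <- b$dx + dskip[[i]]
    nm <- paste0("enc", i)
    b <- bn_block_bwd(L[[nm]], cache[[nm]], dx, 1L)
    g[[nm]] <- b$g
    dx <- b$dx
  }
  g
}

# ---- discriminator forward / backward -----------------------------------

discriminator_forward <- function(dis, mri, ct, training = TRUE) {
  L <- dis$layers
  slope <- dis$cfg$leaky_slope
  x <- abind4(mri, ct)
  cache <- list(input_nc = dim(mri)[4])
  upd <- list()
  for (i in 1:5) {
    nm <- paste0("cd", i)
    lay <- L[[nm]]
    z <- conv_fwd(x, lay$W, lay$b, s = 2L, p = 1L)
    bn <- bn_fwd(z, lay$gamma, lay$beta, training, lay$rmean, lay$rvar)
    a <- lrelu_fwd(bn$out, slope)
    cache[[nm]] <- list(x = x, bn = bn$cache, bnout = bn$out)
    upd[[nm]] <- bn[c("rmean", "rvar")]
    x <- a
  }
  z <- conv_fwd(x, L$c128$W, L$c128$b, s = 1L, p = 0L)
  a <- lrelu_fwd(z, slope)
  cache$c128 <- list(x = x, z = z)
  nb <- dim(a)[3]
  flat <- aperm(a, c(1, 2, 4, 3))
  dim(flat) <- c(length(a) / nb, nb)
  logits <- crossprod(flat, L$fc$W) + L$fc$b # (nb, 1)
  p <- 1 / (1 + exp(-logits))
  cache$fc <- list(flat = flat, p = p, adim = dim(a))
  list(p = as.vector(p), cache = cache, bn_updates = upd)
}

discriminator_backward <- function(dis, cache, dlogit) {
  L <- dis$layers
  slope <- dis$cfg$leaky_slope
  g <- list()
  fc <- cache$fc
  dlog <- matrix(dlogit, ncol = 1)
  g$fc <- list(W = fc$flat %*% dlog, b = sum(dlog))
  dflat <- L$fc$W %*% t(dlog) # (nflat, nb)
  da <- array(dflat, c(fc$adim[1], fc$adim[2], fc$adim[4], fc$adim[3]))
  da <- aperm(da, c(1, 2, 4, 3))
  cc <- cache$c128
  dz <- lrelu_bwd(cc$z, da, slope)
  cv <- conv_bwd(cc$x, L$c128$W, dz, s = 1L, p = 0L)
  g$c128 <- list(W = cv$dW, b = cv$db)
  dx <- cv$dx
  for (i in 5:1) {
    nm <- paste0("cd", i)
    ca <- cache[[nm]]
    dbn <- lrelu_bwd(ca$bnout, dx, slope)
    bb <- bn_bwd(ca$bn, dbn)
    cv <- conv_bwd(ca$x, L[[nm]]$W, bb$dx, s = 2L, p = 1L)
    g[[nm]] <- list(W = cv$dW, b = cv$db, gamma = bb$dgamma,
                    beta = bb$dbeta)
    dx <- cv$dx
  }
  list(g = g, dinput_ct = dx[, , , cache$input_nc +
                               seq_len(dim(dx)[4] - cache$input_nc),
                             drop = FALSE])
}

# ---- parameter plumbing --------------------------------------------------

flatten_params <- function(model) {
  out <- list()
  for (lnm in names(model$layers))
    for (pnm in intersect(names(model$layers[[lnm]]),
                          c("W", "b", "gamma", "beta")))
      out[[paste0(lnm, ".", pnm)]] <- model$layers[[lnm]][[pnm]]
  out
}

unflatten_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    model$layers[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  model
}

flatten_grads <- function(g) {
  out <- list()
  for (lnm in names(g))
    for (pnm in names(g[[lnm]]))
      out[[paste0(lnm, ".", pnm)]] <- g[[lnm]][[pnm]]
  out
}

apply_bn_updates <- function(model, upd) {
  for (nm in names(upd)) {
    model$layers[[nm]]$rmean <- upd[[nm]]$rmean
    model$layers[[nm]]$rvar <- upd[[nm]]$rvar
  }
  model
}
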