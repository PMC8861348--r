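ns <- asNamespace("pelvisct")

test_that("preprocessing maps both channels into [-1, 1] and inverts CT", {
  cs <- small_case()
  cfg <- cgan_config()
  pp <- preprocess_pair(cs$ct, cs$mri$in_phase, cs$masks$body, cfg)
  expect_true(all(pp$mri >= -1 & pp$mri <= 1))
  expect_true(all(pp$ct >= -1 & pp$ct <= 1))
  expect_equal(dim(pp$mri)[1:2], rep(cfg$matrix_size, 2))
  # the CT affine scaling inverts exactly (sub-0.5 HU round trip)
  hu <- cfg$hu_range
  a <- vol_data(cs$ct)
  a[!cs$masks$body] <- hu[1]
  scaled <- (pmin(pmax(a, hu[1]), hu[2]) - hu[1]) / (hu[2] - hu[1]) * 2 - 1
  back <- (scaled + 1) / 2 * (hu[2] - hu[1]) + hu[1]
  sel <- a >= hu[1] & a <= hu[2]
  expect_lt(max(abs(back[sel] - a[sel])), 0.5)
})

test_that("intensity-peak standardization removes global scale factors", {
  cs <- small_case()
  m2 <- vol_like(vol_data(cs$mri$in_phase) * 2, cs$mri$in_phase, "MRI")
  p1 <- preprocess_pair(NULL, cs$mri$in_phase, cs$masks$body, cgan_config())
  p2 <- preprocess_pair(NULL, m2, cs$masks$body, cgan_config())
  expect_equal(p2$meta$mri_mode / p1$meta$mri_mode, 2, tolerance = 0.02)
  expect_equal(p1$mri, p2$mri, tolerance = 1e-12)
})

test_that("conv, transpose-conv and batch-norm gradients are exact", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  W <- array(rnorm(3 * 3 * 3 * 4, 0, 0.3), c(3, 3, 3, 4))
  b <- rnorm(4)
  num_grad <- function(arr, fn, eps = 1e-5) {
    g <- arr * 0
    for (i in seq_along(arr)) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      g[i] <- (fn(a1) - fn(a2)) / (2 * eps)
    }
    g
  }
  for (s in c(1L, 2L)) {
    out <- ns$conv_fwd(x, W, b, s, 1L)
    gr <- ns$conv_bwd(x, W, 2 * out, s, 1L)
    expect_equal(gr$dx, num_grad(x, function(a)
      sum(ns$conv_fwd(a, W, b, s, 1L)^2)), tolerance = 1e-6)
    expect_equal(gr$dW, num_grad(W, function(a)
      sum(ns$conv_fwd(x, a, b, s, 1L)^2)), tolerance = 1e-6)
  }
  Wt <- array(rnorm(3 * 3 * 5 * 2, 0, 0.3), c(3, 3, 5, 2))
  xt <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  bt <- rnorm(5)
  outt <- ns$tconv_fwd(xt, Wt, bt)
  expect_equal(dim(outt), c(8, 8, 2, 5)) # doubles H and W
  grt <- ns$tconv_bwd(xt, Wt, 2 * outt)
  expect_equal(grt$dx, num_grad(xt, function(a)
    sum(ns$tconv_fwd(a, Wt, bt)^2)), tolerance = 1e-6)
  expect_equal(grt$dW, num_grad(Wt, function(a)
    sum(ns$tconv_fwd(xt, a, bt)^2)), tolerance = 1e-6)
  xb <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gm <- runif(2, 0.5, 1.5); be <- rnorm(2)
  r <- ns$bn_fwd(xb, gm, be, TRUE, rep(0, 2), rep(1, 2))
  gb <- ns$bn_bwd(r$cache, 3 * r$out^2)
  expect_equal(gb$dx, num_grad(xb, function(a) {
    rr <- ns$bn_fwd(a, gm, be, TRUE, rep(0, 2), rep(1, 2)); sum(rr$out^3)
  }), tolerance = 1e-6)
})

test_that("the full generator backward pass matches finite differences", {
  set.seed(3)
  cfg <- cgan_config(matrix_size = 32L, base_filters = 2L,
                     init_sd = 0.05, dropout_rate = 0)
  gen <- build_generator(cfg)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2, 1))
  tgt <- array(tanh(rnorm(32 * 32 * 2)), c(32, 32, 2, 1))
  # a smooth loss keeps the finite-difference comparison kink-free
  fw <- ns$generator_forward(gen, x, training = TRUE)
  gr <- ns$flatten_grads(
    ns$generator_backward(gen, fw$cache, 2 * (fw$out - tgt)))
  fp <- ns$flatten_params(gen)
  loss <- function(g) sum((ns$generator_forward(g, x, TRUE)$out - tgt)^2)
  for (nm in c("enc1.W", "down2.gamma", "up3.W", "dec1.beta", "final.W")) {
    p <- fp[[nm]]
    i <- sample(length(p), 1)
    eps <- 1e-5
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    fd <- (loss(ns$unflatten_params(gen, setNames(list(p1), nm))) -
             loss(ns$unflatten_params(gen, setNames(list(p2), nm)))) /
      (2 * eps)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-3,
                 label = sprintf("grad %s[%d]", nm, i))
  }
})

test_that("parameter counts match the closed-form architecture formula", {
  cfg <- cgan_config(matrix_size = 64L, base_filters = 16L)
  gen <- build_generator(cfg)
  f <- 16L * c(1L, 2L, 4L, 8L, 16L)
  conv_n <- function(cin, cout) 9L * cin * cout + cout # W + b
  bn_n <- function(c) 2L * c                            # gamma + beta
  expected <- 0L
  cin <- 1L
  for (i in 1:4) {
    expected <- expected + conv_n(cin, f[i]) + bn_n(f[i]) +        # enc
      conv_n(f[i], f[i + 1]) + bn_n(f[i + 1])                      # down
    cin <- f[i + 1]
  }
  expected <- expected + conv_n(f[5], f[5]) + bn_n(f[5])           # bottleneck
  for (i in 4:1)
    expected <- expected + (9L * f[i + 1] * f[i] + f[i]) + bn_n(f[i]) + # up
      conv_n(2L * f[i], f[i]) + bn_n(f[i])                         # dec
  expected <- expected + (1L * f[1] * 1L + 1L)                     # 1x1 + tanh
  expect_equal(count_parameters(gen), expected)

  dis <- build_discriminator(cfg)
  filt <- c(8L, 16L, 32L, 64L, 128L)
  dexp <- 0L; cin <- 2L
  for (fc in filt) { dexp <- dexp + conv_n(cin, fc) + bn_n(fc); cin <- fc }
  dexp <- dexp + (128L * 128L + 128L) + (4L * 128L + 1L) # C128 then FC
  expect_equal(count_parameters(dis), dexp)
})

test_that("desk-profile training decreases the generator L1 loss", {
  cs <- small_case()
  cfg <- cgan_config(seed = 5)
  pp <- preprocess_pair(cs$ct, cs$mri$in_phase, cs$masks$body, cfg)
  expect_gte(dim(pp$mri)[3], 2 * cfg$batch_size)
  fit <- train_cgan(pp, cfg)
  h <- fit$history
  expect_equal(nrow(h), cfg$epochs)
  expect_lt(h$loss_l1[nrow(h)], h$loss_l1[1])
  expect_true(all(is.finite(unlist(h[-1]))))
  # discriminator probabilities remained in (0, 1): BCE losses are finite
  expect_true(all(h$loss_disc > 0))

  sct <- predict_sct(fit, cs$mri$in_phase, cs$masks$body)
  expect_equal(dim(sct), dim(cs$labels))
  expect_equal(vol_spacing(sct), cs$spacing)
  hu <- cfg$hu_range
  v <- vol_data(sct)
  expect_true(all(v[cs$masks$body] >= hu[1] - 0.5 &
                    v[cs$masks$body] <= hu[2] + 0.5))
  expect_true(all(v[!cs$masks$body] == -1000))
  # smoke-level accuracy on the training phantom (oracle-derived bound)
  mae <- mean(abs(v[cs$masks$body] - vol_data(cs$ct)[cs$masks$body]))
  expect_lt(mae, 300)
  # prediction is bit-reproducible
  sct2 <- predict_sct(fit, cs$mri$in_phase, cs$masks$body)
  expect_identical(unclass(sct), unclass(sct2))
})

test_that("training is deterministic for a fixed seed", {
  cs <- small_case()
  cfg <- cgan_config(matrix_size = 32L, base_filters = 4L, batch_size = 5L,
                     epochs = 2L, seed = 17)
  pp <- preprocess_pair(cs$ct, cs$mri$in_phase, cs$masks$body, cfg)
  pp$mri <- pp$mri[, , 1:10]; pp$ct <- pp$ct[, , 1:10]
  f1 <- train_cgan(pp, cfg)
  f2 <- train_cgan(pp, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(ns$flatten_params(f1$generator),
                   ns$flatten_params(f2$generator))
  expect_error(train_cgan(list(mri = pp$mri[, , 1:3], ct = pp$ct[, , 1:3]),
                          cfg),
               "batch_size")
})
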