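#' Preprocess a co-registered CT/MRI pair into paired 2D slice tensors
#'
#' Background (outside body) is zeroed, every axial slice is resampled to
#' `matrix_size^2` (bilinear), the MRI is standardized so its dominant
#' in-body intensity peak (histogram mode) sits at a fixed value across
#' cases, and both channels are affinely mapped to `[-1, 1]`. The returned
#' metadata inverts the CT scaling exactly. Slices with an empty body mask
#' are skipped and counted.
#'
#' @param ct `image_volume` (HU); may be `NULL` for inference-only
#'   preprocessing.
#' @param mri `image_volume`, a single MRI channel (typically in-phase).
#' @param body logical body mask.
#' @param cfg a [cgan_config()].
#' @return List: `mri`, `ct` (arrays `(ms, ms, n_slices)` in `[-1, 1]`),
#'   `body` (resampled slice masks), `meta` (scaling metadata:
#'   `hu_lo`, `hu_hi`, `mri_mode`, original slice dims, kept slice
#'   indices, `n_skipped`).
#' @export
preprocess_pair <- function(ct, mri, body, cfg = cgan_config()) {
  d <- dim(mri)
  ms <- cfg$matrix_size
  keep <- which(apply(body, 1, any))
  n_skipped <- d[1] - length(keep)
  if (length(keep) == 0) stop("body mask is empty on every slice")
  m <- vol_array(mri)
  m[!body] <- 0
  mode_val <- intensity_mode(m[body])
  m <- m / (2 * mode_val) # peak at 0.5 on the unit scale
  m <- pmin(pmax(m, 0), 1) * 2 - 1
  hu <- cfg$hu_range
  cts <- NULL
  if (!is.null(ct)) {
    a <- vol_array(ct)
    a[!body] <- hu[1]
    a <- (pmin(pmax(a, hu[1]), hu[2]) - hu[1]) / (hu[2] - hu[1]) * 2 - 1
    cts <- resample_slices(a, keep, ms)
  }
  list(mri = resample_slices(m, keep, ms),
       ct = cts,
       body = resample_slices(body + 0, keep, ms) > 0.5,
       meta = list(hu_lo = hu[1], hu_hi = hu[2], mri_mode = mode_val,
                   slice_dims = d[2:3], grid_dims = d, kept_slices = keep,
                   n_skipped = n_skipped, matrix_size = ms))
}

# dominant intensity peak via a kernel density estimate
intensity_mode <- function(v) {
  dens <- density(v, n = 512)
  dens$x[which.max(dens$y)]
}

# bilinearly resample axial slices (rows of the z axis) to ms x ms
resample_slices <- function(a, keep, ms) {
  d <- dim(a)
  out <- array(0, c(ms, ms, length(keep)))
  yi <- (seq_len(ms) - 1) * (d[2] - 1) / (ms - 1)
  xi <- (seq_len(ms) - 1) * (d[3] - 1) / (ms - 1)
  yg <- rep(yi, times = ms)
  xg <- rep(xi, each = ms)
  for (s in seq_along(keep)) {
    sl <- array(a[keep[s], , ], c(1, d[2], d[3]))
    out[, , s] <- sample_at_index(sl, rep(0, ms * ms), yg, xg, "linear")
  }
  out
}

# inverse of resample_slices for one slice stack
resample_slices_back <- function(slices, dims_yx) {
  ms <- dim(slices)[1]
  n <- dim(slices)[3]
  out <- array(0, c(n, dims_yx[1], dims_yx[2]))
  yi <- (seq_len(dims_yx[1]) - 1) * (ms - 1) / (dims_yx[1] - 1)
  xi <- (seq_len(dims_yx[2]) - 1) * (ms - 1) / (dims_yx[2] - 1)
  yg <- rep(yi, times = dims_yx[2])
  xg <- rep(xi, each = dims_yx[1])
  for (s in seq_len(n)) {
    sl <- array(slices[, , s], c(1, ms, ms))
    out[s, , ] <- sample_at_index(sl, rep(0, length(yg)), yg, xg, "linear")
  }
  out
}

#' Train the conditional GAN on paired slices
#'
#' Alternating updates: the discriminator minimizes binary cross-entropy on
#' (MRI, CT) = real versus (MRI, sCT) = fake pairs; the generator minimizes
#' `loss_weight_adv * BCE(D(MRI, sCT), real) + loss_weight_l1 * L1(sCT,
#' CT)`. Both use Adam at the configured learning rate. Deterministic for a
#' fixed seed (initialization, shuffling and dropout all draw from the
#' seeded R RNG).
#'
#' @param pairs output of [preprocess_pair()] (or several, with slice
#'   tensors concatenated): needs `mri` and `ct` slice stacks.
#' @param cfg a [cgan_config()].
#' @return List: `generator`, `discriminator`, `history` (data.frame with
#'   per-epoch mean adversarial, L1 and discriminator losses), `meta`.
#' @export
train_cgan <- function(pairs, cfg = cgan_config()) {
  mri <- pairs$mri; ct <- pairs$ct
  n <- dim(mri)[3]
  if (n < cfg$batch_size)
    stop(sprintf("need at least batch_size = %d slice pairs, got %d",
                 cfg$batch_size, n))
  with_seed(cfg$seed, {
    gen <- build_generator(cfg)
    dis <- build_discriminator(cfg)
    gp <- flatten_params(gen)
    dp <- flatten_params(dis)
    gstate <- adam_init(gp)
    dstate <- adam_init(dp)
    hist <- data.frame()
    nb <- n %/% cfg$batch_size
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      e_adv <- e_l1 <- e_d <- numeric(0)
      for (bi in seq_len(nb)) {
        sel <- ord[(bi - 1) * cfg$batch_size + seq_len(cfg$batch_size)]
        xm <- array(mri[, , sel], c(dim(mri)[1], dim(mri)[2], 1,
                                    length(sel)))
        xm <- aperm(xm, c(1, 2, 4, 3)) # (H, W, N, 1)
        xc <- aperm(array(ct[, , sel], c(dim(ct)[1], dim(ct)[2], 1,
                                         length(sel))), c(1, 2, 4, 3))
        gf <- generator_forward(gen, xm, training = TRUE)
        gen <- apply_bn_updates(gen, gf$bn_updates)
        fake <- gf$out

        # --- discriminator step: real vs (detached) fake
        dr <- discriminator_forward(dis, xm, xc, training = TRUE)
        dis <- apply_bn_updates(dis, dr$bn_updates)
        lr_real <- bce_loss(dr$p, rep(1, length(dr$p)))
        br <- discriminator_backward(dis, dr$cache, lr_real$dlogit)
        df <- discriminator_forward(dis, xm, fake, training = TRUE)
        dis <- apply_bn_updates(dis, df$bn_updates)
        lr_fake <- bce_loss(df$p, rep(0, length(df$p)))
        bf <- discriminator_backward(dis, df$cache, lr_fake$dlogit)
        dgrad <- Map(`+`, flatten_grads(br$g), flatten_grads(bf$g))
        up <- adam_step(dp, dgrad, dstate, cfg$learning_rate)
        dp <- up$params; dstate <- up$state
        dis <- unflatten_params(dis, dp)
        dloss <- (lr_real$loss + lr_fake$loss) / 2

        # --- generator step: adversarial + L1
        dg <- discriminator_forward(dis, xm, fake, training = TRUE)
        dis <- apply_bn_updates(dis, dg$bn_updates)
        ladv <- bce_loss(dg$p, rep(1, length(dg$p)))
        bg <- discriminator_backward(dis, dg$cache,
                                     cfg$loss_weight_adv * ladv$dlogit)
        l1 <- mean(abs(fake - xc))
        dfake <- cfg$loss_weight_l1 * sign(fake - xc) / length(fake) +
          bg$dinput_ct
        ggrad <- flatten_grads(generator_backward(gen, gf$cache, dfake))
        up <- adam_step(gp, ggrad, gstate, cfg$learning_rate)
        gp <- up$params; gstate <- up$state
        gen <- unflatten_params(gen, gp)

        if (!all(is.finite(c(dloss, ladv$loss, l1))))
          stop(sprintf("non-finite loss at epoch %d batch %d", epoch, bi))
        e_adv <- c(e_adv, ladv$loss); e_l1 <- c(e_l1, l1)
        e_d <- c(e_d, dloss)
      }
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     loss_adv = mean(e_adv),
                                     loss_l1 = mean(e_l1),
                                     loss_disc = mean(e_d)))
    }
    list(generator = gen, discriminator = dis, history = hist,
         meta = pairs$meta, cfg = cfg)
  })
}

#' Predict a synthetic CT from MRI with a trained generator
#'
#' Slice-wise inference (inference mode: batch-norm running statistics,
#' dropout off), exact inverse of the CT intensity mapping back to HU,
#' bilinear resampling to the original in-plane grid, and -1000 HU outside
#' the body. A pure function of (weights, input, metadata): repeated calls
#' are bit-identical.
#'
#' @param model result of [train_cgan()] (or a list with `generator`).
#' @param mri `image_volume`, the MRI channel the model was trained on.
#' @param body logical body mask.
#' @return sCT `image_volume` in HU on the MRI grid.
#' @export
predict_sct <- function(model, mri, body) {
  gen <- model$generator
  cfg <- gen$cfg
  pp <- preprocess_pair(NULL, mri, body, cfg)
  sl <- pp$mri
  n <- dim(sl)[3]
  x <- aperm(array(sl, c(dim(sl)[1], dim(sl)[2], 1, n)), c(1, 2, 4, 3))
  out <- generator_forward(gen, x, training = FALSE)$out
  out <- array(aperm(out, c(1, 2, 4, 3)), c(cfg$matrix_size,
                                            cfg$matrix_size, n))
  meta <- pp$meta
  hu_slices <- (out + 1) / 2 * (meta$hu_hi - meta$hu_lo) + meta$hu_lo
  full <- array(-1000, meta$grid_dims)
  back <- resample_slices_back(hu_slices, meta$slice_dims)
  full[meta$kept_slices, , ] <- back
  full[!body] <- -1000
  vol_like(full, mri, "HU")
}
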