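#' Estimate and remove a multiplicative MRI bias field
#'
#' Fits a low-order 3D polynomial (total degree <= 3) to the log intensity
#' inside the body by iteratively reweighted least squares with a Tukey
#' biweight, so voxels whose intensity departs from the dominant
#' soft-tissue surface (bone, gas, strongly contrasting organs) are
#' down-weighted and the fit captures shading rather than anatomy. The fit
#' is exponentiated into a smooth multiplicative field normalized to mean 1
#' inside the body and divided out.
#'
#' @param mri `image_volume`, a single MRI channel.
#' @param body logical body mask.
#' @param degree maximum total polynomial degree (default 3).
#' @param iters IRLS iterations (default 4).
#' @param max_nonpositive_frac error if more than this fraction of in-body
#'   voxels is non-positive (default 0.01).
#' @return The corrected `image_volume`, with the estimated field in
#'   attribute `bias_field`.
#' @export
correct_bias_field <- function(mri, body, degree = 3, iters = 4,
                               max_nonpositive_frac = 0.01) {
  if (!any(body)) stop("body mask is empty")
  a <- vol_array(mri)
  nonpos <- sum(a[body] <= 0)
  if (nonpos > max_nonpositive_frac * sum(body))
    stop(sprintf("%d non-positive in-body intensities exceed tolerance",
                 nonpos))
  d <- dim(a)
  basis <- poly_basis3(d, degree)
  idx <- which(body & a > 0)
  X <- basis[idx, , drop = FALSE]
  yv <- log(a[idx])
  w <- rep(1, length(yv))
  fit <- NULL
  for (it in seq_len(iters)) {
    fit <- stats::lm.wfit(X, yv, w)
    res <- yv - drop(X %*% fit$coefficients)
    s <- 4 * stats::mad(res)
    # an (effectively) exact fit, e.g. a constant image: stop iterating
    if (!is.finite(s) || s < 1e-8) break
    u <- pmin(abs(res) / s, 1)
    w <- (1 - u^2)^2
  }
  logf <- drop(basis %*% fit$coefficients)
  field <- array(exp(logf - mean(logf[body])), d)
  field <- field / mean(field[body])
  out <- vol_like(a / field, mri)
  attr(out, "bias_field") <- field
  out
}

# monomial basis up to total degree `deg` on [-1, 1]^3 coordinates
poly_basis3 <- function(d, deg) {
  ax <- lapply(1:3, function(a) if (d[a] > 1) seq(-1, 1, length.out = d[a])
               else 0)
  z <- rep.int(ax[[1]], d[2] * d[3])
  y <- rep.int(rep(ax[[2]], each = d[1]), d[3])
  x <- rep(ax[[3]], each = d[1] * d[2])
  cols <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) for (k in 0:(deg - i - j))
    cols[[length(cols) + 1]] <- z^i * y^j * x^k
  do.call(cbind, cols)
}

#' Parameters for local weighted voting
#'
#' @param patch_radius patch radius in voxels (3D cube half-width,
#'   default 2).
#' @param gain positive sharpness of the patch-similarity weights
#'   (default 10).
#' @return An `lwv_params` list.
#' @export
lwv_params <- function(patch_radius = 2L, gain = 10) {
  stopifnot(patch_radius >= 0, gain > 0)
  structure(list(patch_radius = as.integer(patch_radius), gain = gain,
                 intensity_metric = "mean-squared-difference"),
            class = "lwv_params")
}

# sliding-window sum over a (2r+1)^3 box, edge windows truncated
box_filter3 <- function(a, r) {
  if (r == 0) return(a)
  for (ax in 1:3) {
    out <- a
    for (off in c(-r:-1, 1:r)) out <- out + shift_axis_zero(a, ax, off)
    a <- out
  }
  a
}

shift_axis_zero <- function(a, ax, off) {
  d <- dim(a)
  n <- d[ax]
  src <- seq_len(n) + off
  keep <- src >= 1 & src <= n
  out <- array(0, d)
  dst <- seq_len(n)[keep]
  src <- src[keep]
  switch(ax,
         out[dst, , ] <- a[src, , , drop = FALSE],
         out[, dst, ] <- a[, src, , drop = FALSE],
         out[, , dst] <- a[, , src, drop = FALSE])
  out
}

#' Fuse propagated atlas CTs by local weighted voting
#'
#' For each in-body voxel, the patch dissimilarity to atlas `i` is the mean
#' squared intensity difference between the target patch and the warped
#' atlas patch of radius `patch_radius`; the weight is
#' `w_i = exp(-gain * d_i / sigma2)` with `sigma2` the in-body target
#' intensity variance, and the fused value is the weighted mean of the
#' warped CTs. Weights are computed relative to the best-matching atlas at
#' each voxel (a common factor that cancels in the normalization), so they
#' cannot collectively underflow; the output is a convex combination of the
#' atlas CT values everywhere.
#'
#' @param target_mri target intensity array (or `image_volume`).
#' @param warped_pairs list of `list(mri = , ct = )` pairs on the target
#'   grid.
#' @param body logical body mask.
#' @param params an [lwv_params()].
#' @param return_weights also return the per-atlas weight volumes.
#' @return `image_volume` in HU (outside body: -1000); attributes
#'   `n_fallback` (voxels fused by plain averaging because the target
#'   variance is zero) and, on request, `weights`.
#' @export
local_weighted_voting <- function(target_mri, warped_pairs, body,
                                  params = lwv_params(),
                                  return_weights = FALSE) {
  if (length(warped_pairs) < 1) stop("need at least one warped atlas pair")
  tgt <- if (inherits(target_mri, "image_volume")) vol_array(target_mri)
         else target_mri
  d <- dim(tgt)
  r <- params$patch_radius
  cnt <- box_filter3(array(1, d), r)
  sigma2 <- var(tgt[body])
  n <- length(warped_pairs)
  dists <- vector("list", n)
  for (i in seq_len(n)) {
    m <- warped_pairs[[i]]$mri
    if (inherits(m, "image_volume")) m <- vol_array(m)
    dists[[i]] <- box_filter3((tgt - m)^2, r) / cnt
  }
  dmin <- Reduce(pmin, dists)
  fallback <- 0L
  if (!is.finite(sigma2) || sigma2 <= 0) {
    w <- lapply(seq_len(n), function(i) array(1, d)) # degenerate target
    fallback <- sum(body)
  } else {
    w <- lapply(dists, function(dd) exp(-params$gain * (dd - dmin) / sigma2))
  }
  wsum <- Reduce(`+`, w)
  num <- array(0, d)
  for (i in seq_len(n)) {
    ct <- warped_pairs[[i]]$ct
    if (inherits(ct, "image_volume")) ct <- vol_array(ct)
    num <- num + w[[i]] * ct
  }
  out <- num / wsum
  out[!body] <- -1000
  geom <- warped_pairs[[1]]$ct
  res <- if (inherits(geom, "image_volume")) vol_like(out, geom, "HU")
         else image_volume(out, c(1, 1, 1), kind = "HU")
  attr(res, "n_fallback") <- fallback
  if (return_weights) attr(res, "weights") <- w
  res
}

#' Hybrid multi-atlas synthetic CT
#'
#' End-to-end atlas pipeline: bias-correct the target and each atlas
#' in-phase MRI, register every atlas to the target (structure-guided rigid
#' + demons via [register_atlas_to_target()]), propagate each atlas CT
#' (linear interpolation) and masks (nearest) through its deformation, and
#' fuse with [local_weighted_voting()]. Deterministic given its inputs.
#'
#' @param target a `phantom_case`-like list (`mri`, `masks`, `spacing`).
#' @param atlas list of cases of the same form, each with `ct`; must not
#'   include the target (identity pairs are allowed for testing).
#' @param params an [lwv_params()].
#' @param bias_correct logical; bias-correct in-phase channels first.
#' @param ... passed to [register_atlas_to_target()].
#' @return List with `sct` (`image_volume`, HU), and `report`: one row per
#'   atlas pair with rigid and post-registration Dice diagnostics.
#' @export
multi_atlas_sct <- function(target, atlas, params = lwv_params(),
                            bias_correct = TRUE, ...) {
  if (length(atlas) < 1) stop("atlas set is empty")
  sp <- target$spacing
  prep <- function(case) {
    # the water channel carries the strongest soft-tissue contrast
    ch <- case$mri$water
    if (bias_correct) ch <- correct_bias_field(ch, case$masks$body)
    a <- vol_array(ch)
    ref <- median(a[case$masks$body]) # unit-scale intensity normalization
    list(intensity = a / ref,
         masks = case$masks[intersect(c("body", "bone", "bladder"),
                                      names(case$masks))])
  }
  tgt <- prep(target)
  warped <- vector("list", length(atlas))
  rows <- vector("list", length(atlas))
  for (i in seq_along(atlas)) {
    mov <- prep(atlas[[i]])
    def <- register_atlas_to_target(mov, tgt, sp, ...)
    ct_w <- warp_volume(atlas[[i]]$ct, def$disp, "linear")
    mri_w <- array(sample_field(mov$intensity, def$disp, sp), dim(ct_w))
    warped[[i]] <- list(mri = mri_w, ct = ct_w)
    rows[[i]] <- data.frame(atlas = i, rigid_dice = def$rigid$dice,
                            body_dice = unname(def$dice["body"]),
                            bone_dice = if ("bone" %in% names(def$dice))
                              unname(def$dice["bone"]) else NA_real_)
  }
  sct <- local_weighted_voting(tgt$intensity, warped, target$masks$body,
                               params)
  list(sct = sct, report = do.call(rbind, rows))
}

sample_field <- function(a, disp, spacing) {
  d <- dim(a)
  g <- index_grid(d)
  sample_at_index(a, g$z + as.vector(disp$dz) / spacing[1],
                  g$y + as.vector(disp$dy) / spacing[2],
                  g$x + as.vector(disp$dx) / spacing[3], "linear")
}
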