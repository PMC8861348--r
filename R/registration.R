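#' Structure-guided rigid registration (6 degrees of freedom)
#'
#' Aligns a moving case to a fixed case using binary masks only: the
#' translation is initialized from body-mask centroids, then rotation and
#' translation are refined by Nelder-Mead on the sum of squared differences
#' between Gaussian-smoothed masks (body, plus bone and bladder when both
#' sides provide them). The transform maps fixed physical points to moving
#' physical points (the backward map used to resample the moving volumes).
#'
#' @param moving_masks,fixed_masks named lists of logical arrays; `body`
#'   required, `bone` and `bladder` used when present on both sides.
#' @param spacing voxel spacing (mm) shared by both grids.
#' @param sigma_mm smoothing applied to the masks before matching.
#' @param maxit Nelder-Mead iteration budget.
#' @return A `rigid_transform`: list with `angles` (radians, about z/y/x),
#'   `translation` (mm), `center` (mm, rotation centre) and `dice` (body
#'   Dice after alignment).
#' @export
rigid_register <- function(moving_masks, fixed_masks, spacing,
                           sigma_mm = 6, maxit = 300) {
  used <- intersect(c("body", "bone", "bladder"),
                    intersect(names(moving_masks), names(fixed_masks)))
  if (!"body" %in% used) stop("both cases must provide a body mask")
  d <- dim(fixed_masks$body)
  co_fix <- mask_phys_coords(d, spacing)
  cen_fix <- mask_centroid(fixed_masks$body, spacing)
  cen_mov <- mask_centroid(moving_masks$body, spacing)
  t0 <- cen_mov - cen_fix

  sm_mov <- lapply(moving_masks[used], function(m)
    gauss_smooth3(m + 0, sigma_mm, spacing))
  sm_fix <- lapply(fixed_masks[used], function(m)
    gauss_smooth3(m + 0, sigma_mm, spacing))

  # evaluate cost on a subsample around the fixed body for speed
  roi <- dilate_mask(fixed_masks$body, 2 * max(spacing), spacing)
  sub <- array(FALSE, d)
  sub[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2)] <- TRUE
  sel <- which(roi & sub)
  pz <- co_fix$z[sel]; py <- co_fix$y[sel]; px <- co_fix$x[sel]
  fx <- lapply(sm_fix, function(a) a[sel])

  cost <- function(par) {
    p <- rigid_apply(par, pz, py, px, cen_fix, t0)
    s <- 0
    for (nm in used) {
      mv <- sample_at_index(sm_mov[[nm]], p$z / spacing[1], p$y / spacing[2],
                            p$x / spacing[3], "linear")
      s <- s + sum((mv - fx[[nm]])^2)
    }
    s
  }
  fit <- optim(rep(0, 6), cost, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  # restart once: Nelder-Mead simplices collapse prematurely on occasion
  fit <- optim(fit$par, cost, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  par <- fit$par
  tr <- structure(list(angles = par[1:3], translation = t0 + par[4:6],
                       center = cen_fix), class = "rigid_transform")
  warped_body <- resample_rigid(moving_masks$body + 0, tr, spacing,
                                "nearest") > 0.5
  tr$dice <- dice_coefficient(warped_body, fixed_masks$body)
  if (tr$dice < 0.5)
    stop(sprintf("rigid registration failed: body Dice %.2f < 0.5", tr$dice))
  tr
}

# apply candidate parameters: rotate about cen, then translate by t0 + dt
rigid_apply <- function(par, pz, py, px, cen, t0) {
  R <- rot3(par[1], par[2], par[3])
  z <- pz - cen[1]; y <- py - cen[2]; x <- px - cen[3]
  list(z = R[1, 1] * z + R[1, 2] * y + R[1, 3] * x + cen[1] + t0[1] + par[4],
       y = R[2, 1] * z + R[2, 2] * y + R[2, 3] * x + cen[2] + t0[2] + par[5],
       x = R[3, 1] * z + R[3, 2] * y + R[3, 3] * x + cen[3] + t0[3] + par[6])
}

rot3 <- function(az, ay, ax) {
  cz <- cos(az); sz <- sin(az); cy <- cos(ay); sy <- sin(ay)
  cx <- cos(ax); sx <- sin(ax)
  Rz <- matrix(c(1, 0, 0, 0, cz, -sz, 0, sz, cz), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(cx, -sx, 0, sx, cx, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

mask_phys_coords <- function(d, spacing) {
  g <- index_grid(d)
  list(z = g$z * spacing[1], y = g$y * spacing[2], x = g$x * spacing[3])
}

mask_centroid <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE) - 1
  colMeans(idx) * spacing
}

#' Displacement field (mm) of a rigid transform on a grid
#' @noRd
rigid_field <- function(tr, d, spacing) {
  co <- mask_phys_coords(d, spacing)
  p <- rigid_apply(c(tr$angles, 0, 0, 0), co$z, co$y, co$x, tr$center,
                   tr$translation)
  list(dz = array(p$z - co$z, d), dy = array(p$y - co$y, d),
       dx = array(p$x - co$x, d))
}

#' Resample an array through a rigid transform (fixed grid -> moving)
#' @noRd
resample_rigid <- function(a, tr, spacing, interp = "linear") {
  d <- dim(a)
  fld <- rigid_field(tr, d, spacing)
  g <- index_grid(d)
  zi <- g$z + as.vector(fld$dz) / spacing[1]
  yi <- g$y + as.vector(fld$dy) / spacing[2]
  xi <- g$x + as.vector(fld$dx) / spacing[3]
  array(sample_at_index(a, zi, yi, xi, interp), d)
}

#' Multi-resolution demons deformable registration
#'
#' Estimates a dense displacement field aligning a moving image to a fixed
#' image with a diffeomorphic-demons-style iteration: per-channel Thirion
#' forces, Gaussian fluid smoothing of each update and elastic smoothing of
#' the accumulated field, run coarse-to-fine. The similarity combines the
#' intensity channel with smoothed binary label channels (bone, bladder)
#' weighted by `label_weight`, so registration is structure-guided.
#'
#' @param fixed_int,moving_int intensity arrays (same grid), roughly
#'   normalized to a unit scale.
#' @param fixed_labels,moving_labels named lists of logical arrays (may be
#'   empty).
#' @param spacing voxel spacing, mm.
#' @param label_weight weight of each label channel relative to intensity
#'   (default 0.5).
#' @param iters iterations per level, coarse to fine.
#' @param sigma_fluid,sigma_elastic Gaussian sigmas (mm) for update and
#'   field smoothing.
#' @param step update scaling; each iteration's update is also capped at
#'   one voxel.
#' @return Displacement field `list(dz, dy, dx)` in mm on the fixed grid
#'   (maps fixed points to moving points when added).
#' @export
demons_register <- function(fixed_int, moving_int, fixed_labels = list(),
                            moving_labels = list(), spacing,
                            label_weight = 0.5, iters = c(60, 30),
                            sigma_fluid = 6, sigma_elastic = 3,
                            step = 0.8) {
  label_sigma <- 2 * max(spacing)
  chan_f <- c(list(int = fixed_int),
              lapply(fixed_labels, function(m)
                gauss_smooth3(m + 0, label_sigma, spacing)))
  chan_m <- c(list(int = moving_int),
              lapply(moving_labels, function(m)
                gauss_smooth3(m + 0, label_sigma, spacing)))
  wts <- c(1, rep(label_weight, length(fixed_labels)))

  n_level <- length(iters)
  field <- NULL
  for (lev in seq_len(n_level)) {
    f <- 2^(n_level - lev)
    sp_l <- spacing * f
    cf <- lapply(chan_f, downsample3, f = f, spacing = spacing)
    cm <- lapply(chan_m, downsample3, f = f, spacing = spacing)
    dl <- dim(cf[[1]])
    if (is.null(field)) {
      field <- list(dz = array(0, dl), dy = array(0, dl), dx = array(0, dl))
    } else {
      field <- lapply(field, resize_to, d_new = dl)
    }
    field <- demons_level(cf, cm, wts, field, sp_l, iters[lev], sigma_fluid,
                          sigma_elastic, step)
  }
  field
}

demons_level <- function(cf, cm, wts, field, sp, n_iter, sigma_fluid,
                         sigma_elastic, step) {
  d <- dim(cf[[1]])
  g <- index_grid(d)
  grads <- lapply(cf, grad3, spacing = sp)
  cap <- min(sp)
  for (it in seq_len(n_iter)) {
    zi <- g$z + as.vector(field$dz) / sp[1]
    yi <- g$y + as.vector(field$dy) / sp[2]
    xi <- g$x + as.vector(field$dx) / sp[3]
    uz <- 0; uy <- 0; ux <- 0
    for (c in seq_along(cf)) {
      mw <- array(sample_at_index(cm[[c]], zi, yi, xi, "linear"), d)
      diff <- mw - cf[[c]]
      gr <- grads[[c]]
      den <- gr$gz^2 + gr$gy^2 + gr$gx^2 + diff^2 / cap^2
      fac <- ifelse(den > 1e-12, -wts[c] * diff / den, 0)
      uz <- uz + fac * gr$gz; uy <- uy + fac * gr$gy; ux <- ux + fac * gr$gx
    }
    uz <- gauss_smooth3(uz, sigma_fluid, sp)
    uy <- gauss_smooth3(uy, sigma_fluid, sp)
    ux <- gauss_smooth3(ux, sigma_fluid, sp)
    mag <- sqrt(uz^2 + uy^2 + ux^2)
    mx <- max(mag)
    sc <- if (mx > 0) step * min(1, cap / mx) else 0
    field$dz <- gauss_smooth3(field$dz + sc * uz, sigma_elastic, sp)
    field$dy <- gauss_smooth3(field$dy + sc * uy, sigma_elastic, sp)
    field$dx <- gauss_smooth3(field$dx + sc * ux, sigma_elastic, sp)
  }
  field
}

# central-difference gradient, per mm
grad3 <- function(a, spacing) {
  list(gz = (shift_axis(a, 1, 1) - shift_axis(a, 1, -1)) / (2 * spacing[1]),
       gy = (shift_axis(a, 2, 1) - shift_axis(a, 2, -1)) / (2 * spacing[2]),
       gx = (shift_axis(a, 3, 1) - shift_axis(a, 3, -1)) / (2 * spacing[3]))
}

# smooth-then-stride downsampling by integer factor f (f = 1: identity)
downsample3 <- function(a, f, spacing) {
  if (f <= 1) return(a)
  a <- gauss_smooth3(a, 0.7 * f * min(spacing), spacing)
  d <- dim(a)
  a[seq(1, d[1], f), seq(1, d[2], f), seq(1, d[3], f), drop = FALSE]
}

# trilinear resize of an array to new dims (values unchanged in units)
resize_to <- function(a, d_new) {
  d <- dim(a)
  sc <- (d - 1) / pmax(d_new - 1, 1)
  g <- index_grid(d_new)
  array(sample_at_index(a, g$z * sc[1], g$y * sc[2], g$x * sc[3], "linear"),
        d_new)
}

#' Full structure-guided registration: rigid then demons
#'
#' Runs [rigid_register()] on the masks, resamples the moving intensity and
#' labels through the rigid transform, refines with [demons_register()],
#' and composes the two into a single displacement field on the fixed grid:
#' `total(x) = rigid(x + demons(x)) - x`, so one resampling of the original
#' moving volumes suffices.
#'
#' @param moving,fixed lists with `intensity` (array, unit-scale) and
#'   `masks` (named list; `body` required).
#' @param spacing voxel spacing, mm.
#' @param ... passed to [demons_register()].
#' @return A `deformation_field`: list with `disp` (total field, mm),
#'   `rigid` (the [rigid_register()] result), `dice` (per-structure Dice
#'   after full registration).
#' @export
register_atlas_to_target <- function(moving, fixed, spacing, ...) {
  tr <- rigid_register(moving$masks, fixed$masks, spacing)
  used <- intersect(c("bone", "bladder"),
                    intersect(names(moving$masks), names(fixed$masks)))
  mov_int_r <- resample_rigid(moving$intensity, tr, spacing, "linear")
  mov_lab_r <- lapply(moving$masks[used], function(m)
    resample_rigid(m + 0, tr, spacing, "nearest") > 0.5)
  dem <- demons_register(fixed$intensity, mov_int_r,
                         fixed_labels = fixed$masks[used],
                         moving_labels = mov_lab_r, spacing = spacing, ...)
  d <- dim(fixed$intensity)
  co <- mask_phys_coords(d, spacing)
  p <- rigid_apply(c(tr$angles, 0, 0, 0),
                   co$z + as.vector(dem$dz), co$y + as.vector(dem$dy),
                   co$x + as.vector(dem$dx), tr$center, tr$translation)
  disp <- list(dz = array(p$z - co$z, d), dy = array(p$y - co$y, d),
               dx = array(p$x - co$x, d))
  dice <- vapply(c("body", used), function(nm) {
    w <- warp_mask_by(moving$masks[[nm]], disp, spacing)
    dice_coefficient(w, fixed$masks[[nm]])
  }, numeric(1))
  structure(list(disp = disp, rigid = tr, dice = dice),
            class = "deformation_field")
}

warp_mask_by <- function(mask, disp, spacing) {
  d <- dim(mask)
  g <- index_grid(d)
  zi <- g$z + as.vector(disp$dz) / spacing[1]
  yi <- g$y + as.vector(disp$dy) / spacing[2]
  xi <- g$x + as.vector(disp$dx) / spacing[3]
  array(sample_at_index(mask + 0, zi, yi, xi, "nearest"), d) > 0.5
}
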