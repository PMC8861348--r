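#' Specification of a digital pelvis phantom
#'
#' Builds the parameter bundle from which [generate_phantom()] renders a
#' paired pseudo-CT / pseudo-Dixon-MRI case with exact ground truth. Anatomy
#' is parametric-geometric (ellipsoids and tubes): an elliptical body
#' cylinder with a subcutaneous fat rind, muscle/viscera interior, sacrum and
#' two lateral hip bones (cortical shell + marrow core), a bladder, a rectal
#' tube with an optional gas pocket, and a PTV surrounding the rectum.
#'
#' @param grid_shape voxels per axis (z, y, x); each >= 16.
#' @param spacing voxel spacing in mm (z, y, x).
#' @param sex_variant `"male"` or `"female"`; the female variant widens the
#'   bony pelvis and body contour and enlarges the bladder.
#' @param organ_geometry per-structure geometry (mm), as produced by
#'   [default_organ_geometry()]; entries may be overridden.
#' @param tissue_hu named list of `c(mean, sd)` HU per tissue class
#'   (`fat`, `muscle`, `bone_cortical`, `bone_marrow`, `bladder`, `gas`).
#' @param mri_intensity named list of `c(fat_signal, water_signal)` means per
#'   class, on a unit intensity scale.
#' @param bias_field_amplitude fractional amplitude of the multiplicative
#'   MRI bias field (0 disables it).
#' @param noise_sd `c(ct = , mri = )`: `ct` multiplies the per-class HU SDs,
#'   `mri` is the absolute Gaussian SD added to the unit-scale MRI channels.
#' @param gas_pocket logical; include a rectal gas pocket.
#' @param gas_size_mm semi-axis (mm) of the gas pocket ellipsoid.
#' @param prescription_dose prescription in Gy reported at the reference
#'   point.
#' @param seed default seed used when [generate_phantom()] is called without
#'   one.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40L, 56L, 56L),
                         spacing = c(4, 4, 4),
                         sex_variant = c("male", "female"),
                         organ_geometry = NULL,
                         tissue_hu = default_tissue_hu(),
                         mri_intensity = default_mri_intensity(),
                         bias_field_amplitude = 0.2,
                         noise_sd = c(ct = 1, mri = 0.02),
                         gas_pocket = FALSE,
                         gas_size_mm = 14,
                         prescription_dose = 50,
                         seed = 1L) {
  sex_variant <- match.arg(sex_variant)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            length(spacing) == 3L, all(spacing > 0),
            bias_field_amplitude >= 0, all(noise_sd >= 0), gas_size_mm > 0)
  if (tissue_hu$gas[1] > -800)
    stop("tissue_hu$gas mean must be <= -800 HU")
  for (cl in names(tissue_hu))
    if (tissue_hu[[cl]][2] < 0) stop("tissue HU SDs must be >= 0")
  if (is.null(organ_geometry))
    organ_geometry <- default_organ_geometry(sex_variant)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 sex_variant = sex_variant,
                 organ_geometry = organ_geometry,
                 tissue_hu = tissue_hu,
                 mri_intensity = mri_intensity,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sd = noise_sd,
                 gas_pocket = gas_pocket,
                 gas_size_mm = gas_size_mm,
                 prescription_dose = prescription_dose,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_tissue_hu <- function() {
  list(fat = c(-100, 20), muscle = c(45, 15), bone_cortical = c(800, 150),
       bone_marrow = c(250, 80), bladder = c(15, 10), gas = c(-1000, 5))
}

#' @rdname phantom_spec
#' @export
default_mri_intensity <- function() {
  list(fat = c(fat = 0.88, water = 0.09),
       muscle = c(fat = 0.15, water = 0.81),
       bone_cortical = c(fat = 0.05, water = 0.05),
       bone_marrow = c(fat = 0.35, water = 0.45), # red (hematopoietic) marrow
       bladder = c(fat = 0.03, water = 0.95),
       gas = c(fat = 0.01, water = 0.01))
}

#' Default pelvis geometry (mm, offsets relative to the grid centre)
#'
#' Centres are (z, y, x) offsets in mm; +y is posterior, +x is patient left.
#' Semi-axes are mm. The female variant is ~8% wider with a larger bladder.
#'
#' @param sex_variant `"male"` or `"female"`.
#' @return Named list of structure geometries.
#' @export
default_organ_geometry <- function(sex_variant = "male") {
  w <- if (sex_variant == "female") 1.08 else 1.0
  list(
    body = list(type = "tube", center = c(0, 0, 0),
                semi = c(NA, 84, 100 * w), z_half = Inf),
    fat_rind_mm = 12,
    sacrum = list(type = "ellipsoid", center = c(0, 54, 0),
                  semi = c(50, 16, 26 * w)),
    hip_left = list(type = "ellipsoid", center = c(-5, 8, 62 * w),
                    semi = c(48, 28, 17)),
    hip_right = list(type = "ellipsoid", center = c(-5, 8, -62 * w),
                     semi = c(48, 28, 17)),
    marrow_fraction = 0.60,
    bladder = list(type = "ellipsoid", center = c(-8, -34, 0),
                   semi = c(24, 28, 30) * if (sex_variant == "female") 1.1 else 1),
    rectum = list(type = "tube", center = c(0, 24, 0),
                  semi = c(NA, 12, 12), z_half = 52),
    ptv = list(type = "ellipsoid", center = c(0, 22, 0),
               semi = c(46, 30, 32))
  )
}

class_labels <- function() {
  c(fat = 1L, muscle = 2L, bone_cortical = 3L, bone_marrow = 4L,
    bladder = 5L, gas = 6L)
}

# physical coordinate arrays (mm, relative to grid centre) for a spec grid
phantom_coords <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) - (d[a] - 1) / 2) * sp[a])
  list(z = array(rep.int(ax[[1]], d[2] * d[3]), d),
       y = array(rep.int(rep(ax[[2]], each = d[1]), d[3]), d),
       x = array(rep(ax[[3]], each = d[1] * d[2]), d))
}

geom_mask <- function(geom, co, scale = 1) {
  s <- geom$semi * scale
  if (geom$type == "ellipsoid") {
    ((co$z - geom$center[1]) / s[1])^2 + ((co$y - geom$center[2]) / s[2])^2 +
      ((co$x - geom$center[3]) / s[3])^2 <= 1
  } else { # tube along z
    inxy <- ((co$y - geom$center[2]) / s[2])^2 +
      ((co$x - geom$center[3]) / s[3])^2 <= 1
    inxy & abs(co$z - geom$center[1]) <= geom$z_half
  }
}

check_geometry_fits <- function(spec) {
  half <- (spec$grid_shape - 1) / 2 * spec$spacing
  for (nm in names(spec$organ_geometry)) {
    g <- spec$organ_geometry[[nm]]
    if (!is.list(g)) next
    s <- g$semi
    if (g$type == "tube") s[1] <- min(g$z_half, half[1])
    hi <- abs(g$center) + s
    if (any(hi > half + 1e-9))
      stop(sprintf("structure '%s' exceeds the grid extent", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a seeded digital pelvis phantom case
#'
#' Renders the geometry of `spec` into a ground-truth tissue label map, then
#' draws the CT (HU) per class, synthesizes the four Dixon channels from the
#' per-class fat/water signal means (in-phase = water + fat, out-of-phase =
#' |water - fat| before noise), applies a smooth multiplicative bias field to
#' the MRI channels only, and adds Gaussian noise. Deterministic for a fixed
#' `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return A `phantom_case`: list with elements `ct` (`image_volume`, HU),
#'   `mri` ([dixon_set()]), `labels` (integer array, 0 = air), `masks`
#'   (named list of logical arrays: body, bone, bladder, rectum, ptv,
#'   oar_bladder), `reference_point` (mm), `prescription_dose` (Gy),
#'   `spacing`, `origin`.
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_geometry_fits(spec)
  d <- spec$grid_shape
  co <- phantom_coords(spec)
  og <- spec$organ_geometry
  cl <- class_labels()

  body <- geom_mask(og$body, co)
  rind <- spec$spacing[2] * 0 + og$fat_rind_mm
  inner <- geom_mask(og$body, co,
                     scale = c(1, (og$body$semi[2] - rind) / og$body$semi[2],
                               (og$body$semi[3] - rind) / og$body$semi[3]))
  labels <- array(0L, d)
  labels[body] <- cl["fat"]
  labels[inner] <- cl["muscle"]
  bladder <- geom_mask(og$bladder, co) & body
  labels[bladder] <- cl["bladder"]
  rectum <- geom_mask(og$rectum, co) & body
  labels[rectum] <- cl["muscle"]
  # bone last: the bony contour is authoritative over soft-tissue organs
  bone <- geom_mask(og$sacrum, co) | geom_mask(og$hip_left, co) |
    geom_mask(og$hip_right, co)
  marrow <- geom_mask(og$sacrum, co, og$marrow_fraction) |
    geom_mask(og$hip_left, co, og$marrow_fraction) |
    geom_mask(og$hip_right, co, og$marrow_fraction)
  labels[bone & body] <- cl["bone_cortical"]
  labels[marrow & body] <- cl["bone_marrow"]
  if (isTRUE(spec$gas_pocket)) {
    gasg <- list(type = "ellipsoid", center = og$rectum$center,
                 semi = rep(spec$gas_size_mm, 3))
    gas <- geom_mask(gasg, co) & rectum & labels == cl["muscle"]
    labels[gas] <- cl["gas"]
  }
  ptv <- geom_mask(og$ptv, co) & body

  seeds <- derive_seeds(seed, 3L)
  nvox <- prod(d)

  ct <- array(-1000, d)
  ct_noise <- with_seed(seeds[1], rnorm(nvox))
  for (nm in names(cl)) {
    sel <- labels == cl[nm]
    if (!any(sel)) next
    hu <- spec$tissue_hu[[nm]]
    ct[sel] <- hu[1] + spec$noise_sd["ct"] * hu[2] * ct_noise[sel]
  }

  fat_sig <- array(0, d); water_sig <- array(0, d)
  for (nm in names(cl)) {
    sel <- labels == cl[nm]
    if (!any(sel)) next
    m <- spec$mri_intensity[[nm]]
    fat_sig[sel] <- m["fat"]; water_sig[sel] <- m["water"]
  }
  ip <- water_sig + fat_sig
  op <- abs(water_sig - fat_sig)
  bias <- phantom_bias_field(d, spec$spacing, spec$bias_field_amplitude,
                             seeds[2])
  chans <- list(in_phase = ip * bias, out_phase = op * bias,
                fat = fat_sig * bias, water = water_sig * bias)
  mri_noise <- with_seed(seeds[3], rnorm(4 * nvox))
  for (i in seq_along(chans))
    chans[[i]] <- chans[[i]] +
      spec$noise_sd["mri"] * array(mri_noise[((i - 1) * nvox + 1):(i * nvox)], d)

  origin <- c(0, 0, 0)
  vol <- function(a, kind) image_volume(a, spec$spacing, origin, kind)
  bone_lab <- array(labels == cl["bone_cortical"] |
                      labels == cl["bone_marrow"], d)
  bladder_lab <- array(labels == cl["bladder"], d)
  masks <- list(body = body, bone = bone_lab, bladder = bladder_lab,
                rectum = rectum, ptv = ptv, oar_bladder = bladder_lab)
  ref_pt <- mask_centroid_point(ptv, spec$spacing, origin)

  structure(list(
    ct = vol(ct, "HU"),
    mri = dixon_set(vol(chans$in_phase, "MRI"), vol(chans$out_phase, "MRI"),
                    vol(chans$fat, "MRI"), vol(chans$water, "MRI")),
    labels = labels,
    masks = masks,
    reference_point = ref_pt,
    prescription_dose = spec$prescription_dose,
    spacing = spec$spacing, origin = origin,
    spec = spec, seed = as.integer(seed)
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, %d-voxel body, seed %d\n",
              paste(dim(x$labels), collapse = "x"), sum(x$masks$body),
              x$seed))
  invisible(x)
}

# physical centroid of a mask, snapped to the nearest in-mask voxel centre
mask_centroid_point <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE) - 1
  cen <- colMeans(idx)
  d2 <- colSums((t(idx) - cen)^2 * spacing^2)
  best <- idx[which.min(d2), ]
  origin + best * spacing
}

# exp of a centred random polynomial (degree <= 3), max |log field| limited
phantom_bias_field <- function(d, spacing, amplitude, seed) {
  if (amplitude <= 0) return(array(1, d))
  ax <- lapply(1:3, function(a) seq(-1, 1, length.out = d[a]))
  z <- array(rep.int(ax[[1]], d[2] * d[3]), d)
  y <- array(rep.int(rep(ax[[2]], each = d[1]), d[3]), d)
  x <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  co <- with_seed(seed, rnorm(9))
  p <- co[1] * z + co[2] * y + co[3] * x + co[4] * z * y + co[5] * y * x +
    co[6] * z * x + co[7] * z^2 + co[8] * y^2 + co[9] * x^2
  p <- p - mean(p)
  m <- max(abs(p))
  if (m > 0) p <- p * (log1p(amplitude) / m)
  exp(p)
}

#' Generate a cohort of jittered phantom cases
#'
#' Renders `n` cases from `base` with controlled inter-subject variability:
#' per-case, every structure's semi-axes are scaled by independent uniform
#' factors in `1 +/- geometry_jitter`, structure centres are shifted by up to
#' `center_jitter_mm`, and tissue HU / MRI means are scaled by
#' `1 +/- tissue_jitter`. Child seeds are derived from `seed`, so the cohort
#' is fully reproducible.
#'
#' @param base a [phantom_spec()].
#' @param n number of cases (>= 2; atlas workflows need at least one
#'   non-target pair).
#' @param seed master seed.
#' @param geometry_jitter,tissue_jitter fractional half-ranges (defaults
#'   0.08 and 0.03).
#' @param center_jitter_mm maximum per-axis centre shift in mm (default 4).
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(base, n, seed = 1L, geometry_jitter = 0.08,
                            tissue_jitter = 0.03, center_jitter_mm = 4) {
  stopifnot(inherits(base, "phantom_spec"))
  if (n < 2) stop("a cohort needs n >= 2 cases")
  seeds <- derive_seeds(seed, 2L * n)
  lapply(seq_len(n), function(i) {
    sp <- with_seed(seeds[i], jitter_spec(base, geometry_jitter,
                                          tissue_jitter, center_jitter_mm))
    generate_phantom(sp, seed = seeds[n + i])
  })
}

jitter_spec <- function(base, gj, tj, cj) {
  sp <- base
  half <- (sp$grid_shape - 1) / 2 * sp$spacing
  for (nm in names(sp$organ_geometry)) {
    g <- sp$organ_geometry[[nm]]
    if (!is.list(g)) next
    g$semi <- g$semi * runif(3, 1 - gj, 1 + gj)
    shift <- runif(3, -cj, cj)
    if (nm == "body") shift[] <- 0 # keep the couch position fixed
    g$center <- g$center + shift
    # clamp semi-axes so jitter cannot push the structure off the grid
    room <- half - abs(g$center)
    sel <- is.finite(g$semi) & g$semi > room
    g$semi[sel] <- room[sel]
    sp$organ_geometry[[nm]] <- g
  }
  for (nm in names(sp$tissue_hu))
    sp$tissue_hu[[nm]][1] <- sp$tissue_hu[[nm]][1] * runif(1, 1 - tj, 1 + tj)
  sp
}

#' Warp a phantom case by a smooth random displacement field
#'
#' Draws a smooth random vector field (a superposition of random Fourier
#' modes with wavelengths of at least `smoothness` mm per component),
#' scales it so the maximum displacement magnitude equals `amplitude` mm,
#' and warps every channel, the label map and all masks by the same field
#' (backward mapping; linear interpolation for images, nearest for
#' labels/masks). Sampling positions falling outside the grid are clamped
#' to the boundary and counted.
#'
#' @param case a `phantom_case`.
#' @param amplitude maximum displacement magnitude in mm (0 = identity).
#' @param smoothness minimum spatial wavelength of the field, mm.
#' @param seed integer seed.
#' @return The warped `phantom_case`, with `$warp` carrying the displacement
#'   field (`list(dz, dy, dx)` in mm) and `clamped`, the count of clamped
#'   sample positions.
#' @export
warp_phantom <- function(case, amplitude, smoothness = 40, seed = 1L) {
  stopifnot(amplitude >= 0)
  d <- dim(case$labels)
  if (amplitude == 0) {
    case$warp <- list(field = list(dz = array(0, d), dy = array(0, d),
                                   dx = array(0, d)), clamped = 0L)
    return(case)
  }
  sp <- case$spacing
  co <- phantom_coords(case$spec)
  fld <- with_seed(seed, lapply(1:3, function(a) {
    f <- array(0, d)
    for (j in 1:4) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      lambda <- runif(1, smoothness, 2 * smoothness)
      phase <- runif(1, 0, 2 * pi)
      amp <- rnorm(1)
      f <- f + amp * sin(2 * pi * (u[1] * co$z + u[2] * co$y +
                                     u[3] * co$x) / lambda + phase)
    }
    f
  }))
  mag <- sqrt(fld[[1]]^2 + fld[[2]]^2 + fld[[3]]^2)
  scale <- amplitude / max(mag)
  fld <- lapply(fld, function(f) f * scale)
  names(fld) <- c("dz", "dy", "dx")

  g <- index_grid(d)
  zi <- g$z + as.vector(fld$dz) / sp[1]
  yi <- g$y + as.vector(fld$dy) / sp[2]
  xi <- g$x + as.vector(fld$dx) / sp[3]
  clamped <- sum(zi < 0 | zi > d[1] - 1 | yi < 0 | yi > d[2] - 1 |
                   xi < 0 | xi > d[3] - 1)

  out <- case
  out$ct <- warp_volume(case$ct, fld, "linear")
  out$mri <- dixon_set(warp_volume(case$mri$in_phase, fld),
                       warp_volume(case$mri$out_phase, fld),
                       warp_volume(case$mri$fat, fld),
                       warp_volume(case$mri$water, fld))
  lab_vol <- image_volume(case$labels + 0, case$spacing, case$origin, "label")
  out$labels <- array(as.integer(warp_volume(lab_vol, fld, "nearest")), d)
  cl <- class_labels()
  out$masks$body <- out$labels > 0L
  out$masks$bone <- out$labels %in% cl[c("bone_cortical", "bone_marrow")]
  dim(out$masks$bone) <- d
  out$masks$bladder <- out$labels == cl["bladder"]
  out$masks$oar_bladder <- out$masks$bladder
  for (nm in c("rectum", "ptv")) {
    mv <- image_volume(case$masks[[nm]] + 0, case$spacing, case$origin, "mask")
    out$masks[[nm]] <- array(warp_volume(mv, fld, "nearest") > 0.5, d)
  }
  out$reference_point <- mask_centroid_point(out$masks$ptv, sp, case$origin)
  out$warp <- list(field = fld, clamped = as.integer(clamped))
  out
}
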