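#' 3D image volumes with physical geometry
#'
#' `image_volume()` wraps a 3D numeric array together with voxel spacing,
#' origin and a value-semantics tag. All `pelvisct` modules share one
#' coordinate convention: axis order is (z, y, x) — array `dim` is
#' `c(nz, ny, nx)` — voxel indices are 0-based, and the physical position of
#' voxel `(i, j, k)` is `origin + c(i, j, k) * spacing` in millimetres.
#'
#' @param data 3D numeric array, dim `(nz, ny, nx)`.
#' @param spacing numeric length-3, voxel spacing in mm per axis (z, y, x).
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @param kind value semantics: `"HU"`, `"MRI"`, `"RED"`, `"Gy"`, `"label"`
#'   or `"mask"`.
#' @return An `image_volume` object (the array, with geometry attributes).
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0), kind = "HU") {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  kind <- match.arg(kind, c("HU", "MRI", "RED", "Gy", "label", "mask"))
  structure(data,
            spacing = as.numeric(spacing),
            origin = as.numeric(origin),
            kind = kind,
            class = c("image_volume", "array"))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels, spacing %s mm\n",
              vol_kind(x), d[1], d[2], d[3],
              paste(format(vol_spacing(x)), collapse = " x ")))
  cat(sprintf("  range [%.6g, %.6g], origin (%s) mm\n",
              min(x), max(x), paste(format(vol_origin(x)), collapse = ", ")))
  invisible(x)
}

#' @rdname image_volume
#' @param x an `image_volume`.
#' @export
vol_spacing <- function(x) attr(x, "spacing")

#' @rdname image_volume
#' @export
vol_origin <- function(x) attr(x, "origin")

#' @rdname image_volume
#' @export
vol_kind <- function(x) attr(x, "kind")

#' @rdname image_volume
#' @param data_new replacement array on the same grid.
#' @export
vol_like <- function(data_new, x, kind = vol_kind(x)) {
  if (is.null(dim(data_new))) dim(data_new) <- dim(x)
  image_volume(data_new, vol_spacing(x), vol_origin(x), kind)
}

vol_array <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)) ||
      max(abs(vol_spacing(a) - vol_spacing(b))) > 1e-9 ||
      max(abs(vol_origin(a) - vol_origin(b))) > 1e-9)
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  invisible(TRUE)
}

#' Physical coordinates of every voxel centre along each axis
#' @noRd
axis_coords <- function(x) {
  d <- dim(x); sp <- vol_spacing(x); o <- vol_origin(x)
  lapply(1:3, function(a) o[a] + (seq_len(d[a]) - 1) * sp[a])
}

#' Convert a physical point (mm) to continuous 0-based voxel index
#' @noRd
phys_to_index <- function(x, pt) (pt - vol_origin(x)) / vol_spacing(x)

#' A four-channel Dixon MRI set
#'
#' Bundles the four co-registered Dixon reconstructions. Channel semantics:
#' in-phase = water + fat, out-of-phase = |water - fat|.
#'
#' @param in_phase,out_phase,fat,water co-registered MRI `image_volume`s.
#' @return A `dixon_set` (list of the four channels).
#' @export
dixon_set <- function(in_phase, out_phase, fat, water) {
  ch <- list(in_phase = in_phase, out_phase = out_phase,
             fat = fat, water = water)
  for (v in ch[-1]) stop_if_grid_mismatch(ch[[1]], v, "Dixon channels")
  structure(ch, class = "dixon_set")
}

#' @export
print.dixon_set <- function(x, ...) {
  cat("<dixon_set> channels: in_phase, out_phase, fat, water\n")
  print(x$in_phase)
  invisible(x)
}

# ---- interpolation and warping ------------------------------------------

#' Sample a volume at continuous 0-based voxel indices
#'
#' Trilinear or nearest-neighbour interpolation; indices outside the grid are
#' clamped to the boundary.
#' @noRd
sample_at_index <- function(a, zi, yi, xi, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(a)
  zi <- pmin(pmax(zi, 0), d[1] - 1)
  yi <- pmin(pmax(yi, 0), d[2] - 1)
  xi <- pmin(pmax(xi, 0), d[3] - 1)
  if (interp == "nearest") {
    return(a[cbind(round(zi) + 1, round(yi) + 1, round(xi) + 1)])
  }
  z0 <- pmax(pmin(floor(zi), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(yi), d[2] - 2), 0)
  x0 <- pmax(pmin(floor(xi), d[3] - 2), 0)
  fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
  z1 <- pmin(z0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  x1 <- pmin(x0 + 1, d[3] - 1)
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
      (if (dx) fx else 1 - fx)
    acc <- acc + w * a[cbind((if (dz) z1 else z0) + 1,
                             (if (dy) y1 else y0) + 1,
                             (if (dx) x1 else x0) + 1)]
  }
  acc
}

#' Index grids for a volume (0-based), as three vectors of length prod(dim)
#' @noRd
index_grid <- function(d) {
  list(z = rep.int(0:(d[1] - 1), d[2] * d[3]),
       y = rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]),
       x = rep(0:(d[3] - 1), each = d[1] * d[2]))
}

#' Warp a volume by a displacement field
#'
#' Backward warping: `out(x) = in(x + disp(x))`, displacements in mm on the
#' output grid. `disp` is a list of three arrays (`dz`, `dy`, `dx`).
#'
#' @param vol an `image_volume`.
#' @param disp list of three arrays, per-voxel displacement in mm (z, y, x).
#' @param interp `"linear"` for images, `"nearest"` for masks/labels.
#' @return The warped `image_volume`.
#' @export
warp_volume <- function(vol, disp, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(vol); sp <- vol_spacing(vol)
  g <- index_grid(d)
  zi <- g$z + as.vector(disp[[1]]) / sp[1]
  yi <- g$y + as.vector(disp[[2]]) / sp[2]
  xi <- g$x + as.vector(disp[[3]]) / sp[3]
  out <- sample_at_index(vol_array(vol), zi, yi, xi, interp)
  vol_like(array(out, d), vol)
}

# ---- smoothing -----------------------------------------------------------

#' Separable Gaussian smoothing of a 3D array (sigma in mm, spacing-aware)
#' @noRd
gauss_smooth3 <- function(a, sigma_mm, spacing) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_mm / spacing[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      out <- out + k[j] * shift_axis(a, ax, off)
    }
    a <- out
  }
  a
}

#' Shift array along one axis by `off` voxels, replicating edges
#' @noRd
shift_axis <- function(a, ax, off) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])
  switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# ---- binary morphology ---------------------------------------------------

#' Voxel offsets of a spacing-aware spherical structuring element
#' @noRd
ball_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dx * spacing[3])^2 <= radius_mm^2
  g[keep, , drop = FALSE]
}

#' Shift a 3D array by integer voxel offsets, filling with `fill`
#' @noRd
shift3 <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
  tz <- sz + dz; ty <- sy + dy; tx <- sx + dx
  okz <- tz >= 1 & tz <= d[1]; oky <- ty >= 1 & ty <= d[2]
  okx <- tx >= 1 & tx <= d[3]
  out[tz[okz], ty[oky], tx[okx]] <- a[sz[okz], sy[oky], sx[okx]]
  out
}

#' Binary erosion / dilation with a spherical element of given radius (mm)
#'
#' @param mask logical 3D array.
#' @param radius_mm structuring-element radius in mm.
#' @param spacing voxel spacing (mm, z/y/x).
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, radius_mm, spacing) {
  off <- ball_offsets(radius_mm, spacing)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift3(mask, off$dz[i], off$dy[i], off$dx[i], fill = FALSE)
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius_mm, spacing) {
  off <- ball_offsets(radius_mm, spacing)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift3(mask, off$dz[i], off$dy[i], off$dx[i], fill = FALSE)
  out
}

#' Label 6-connected components of a binary 3D array
#'
#' @param mask logical 3D array.
#' @return Integer array: 0 background, 1..k component labels.
#' @export
label_components <- function(mask) {
  .cc_label3(as.logical(mask), as.integer(dim(mask)))
}

#' Fill interior holes of a binary mask (background not connected to border)
#' @param mask logical 3D array.
#' @return Logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  inv <- !mask
  lab <- label_components(inv)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (inv & !(lab %in% border))
}

#' Dice similarity coefficient of two binary masks
#' @param a,b logical arrays on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# ---- NIfTI I/O -----------------------------------------------------------

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. On write, spacing is stored in `pixdim`;
#' axis order follows this package's (z, y, x) convention via a transpose to
#' NIfTI's fastest-varying-first layout.
#'
#' @param vol an `image_volume` (write) or file path (read).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param kind value tag to attach on read.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `image_volume`.
#' @export
write_volume <- function(vol, path) {
  a <- aperm(vol_array(vol), c(3, 2, 1)) # x fastest-varying for NIfTI
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rev(vol_spacing(vol))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, kind = "HU") {
  img <- RNifti::readNifti(path)
  sp <- rev(RNifti::pixdim(img)[1:3])
  image_volume(aperm(as.array(img), c(3, 2, 1)), spacing = sp, kind = kind)
}

# ---- seeded RNG helper ---------------------------------------------------

#' Evaluate code under a local RNG seed, restoring the global state after
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream of child seeds from a master seed (kept below 2^31)
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
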