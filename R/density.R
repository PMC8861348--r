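#' CT density calibration curve
#'
#' A piecewise-linear, strictly increasing map between Hounsfield units and
#' relative electron density (RED). The default two-segment curve is
#' `(-1000 HU, 0.00) - (0 HU, 1.00) - (1500 HU, 1.85)`: air maps to zero
#' electron density, water anchors (0, 1), and the bone branch has the
#' flatter slope typical of clinical CT calibrations. Under this default,
#' soft-tissue RED 0.97 maps to -30 HU and bone RED 1.20 to about 245 HU.
#'
#' @param breakpoints two-column matrix or data.frame `(HU, RED)`, strictly
#'   increasing in both columns, containing `(0, 1)` and spanning at least
#'   `[-1000, 1500]` HU.
#' @return A `density_calibration` object.
#' @export
density_calibration <- function(breakpoints = cbind(HU = c(-1000, 0, 1500),
                                                    RED = c(0, 1, 1.85))) {
  bp <- as.matrix(breakpoints)
  stopifnot(ncol(bp) == 2L, nrow(bp) >= 2L)
  colnames(bp) <- c("HU", "RED")
  if (any(diff(bp[, 1]) <= 0) || any(diff(bp[, 2]) <= 0))
    stop("calibration breakpoints must be strictly increasing in HU and RED")
  if (min(abs(bp[, 1])) > 1e-9 || abs(bp[which(bp[, 1] == 0), 2] - 1) > 1e-9)
    stop("calibration must contain the water anchor (0 HU, RED 1.0)")
  if (bp[1, 1] > -1000 || bp[nrow(bp), 1] < 1500)
    stop("calibration must span at least [-1000, 1500] HU")
  structure(list(breakpoints = bp), class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat("<density_calibration> breakpoints (HU, RED):\n")
  print(x$breakpoints)
  invisible(x)
}

#' Read a calibration curve from a two-column CSV (HU, RED)
#'
#' The default curve ships as
#' `system.file("extdata", "default_calibration.csv", package = "pelvisct")`.
#'
#' @param path CSV file path.
#' @return A [density_calibration()].
#' @export
read_calibration <- function(path) {
  density_calibration(utils::read.csv(path))
}

cal_interp <- function(v, from, to, strict, what) {
  rng <- range(from)
  out_of_range <- v < rng[1] | v > rng[2]
  if (any(out_of_range)) {
    if (strict)
      stop(sprintf("%d %s value(s) outside the calibrated range",
                   sum(out_of_range), what), call. = FALSE)
    warning(sprintf("%d %s value(s) clamped to the calibrated range",
                    sum(out_of_range), what), call. = FALSE)
    v <- pmin(pmax(v, rng[1]), rng[2])
  }
  stats::approx(from, to, xout = v, method = "linear", rule = 2)$y
}

#' Convert relative electron density to HU (and back)
#'
#' Piecewise-linear interpolation on the calibration curve; exact at
#' breakpoints, and `hu_to_red(red_to_hu(x))` round-trips exactly on the
#' calibrated range. Out-of-range inputs are clamped with a warning, or are
#' an error when `strict = TRUE`.
#'
#' @param red,hu numeric vector, array or `image_volume`.
#' @param cal a [density_calibration()].
#' @param strict error instead of clamping out-of-range values.
#' @return Same shape as the input; `image_volume`s keep their grid and get
#'   the appropriate `kind` tag.
#' @export
red_to_hu <- function(red, cal = density_calibration(), strict = FALSE) {
  bp <- cal$breakpoints
  out <- cal_interp(as.vector(red), bp[, "RED"], bp[, "HU"], strict, "RED")
  reshape_as(out, red, "HU")
}

#' @rdname red_to_hu
#' @export
hu_to_red <- function(hu, cal = density_calibration(), strict = FALSE) {
  bp <- cal$breakpoints
  out <- cal_interp(as.vector(hu), bp[, "HU"], bp[, "RED"], strict, "HU")
  reshape_as(out, hu, "RED")
}

reshape_as <- function(out, template, kind) {
  if (inherits(template, "image_volume"))
    return(vol_like(array(out, dim(template)), template, kind))
  if (is.array(template)) dim(out) <- dim(template)
  out
}

#' Override bowel gas with the surrounding tissue HU
#'
#' Replaces each connected pocket of in-body gas (voxels below
#' `gas_threshold`) with the mean HU of the non-gas voxels inside a shell of
#' radius `shell_radius` mm around that pocket, mirroring the bowel-gas
#' override applied before dose comparison. Replacement is per connected
#' component, so the value is stable across the pocket. Idempotent: a second
#' application replaces zero voxels.
#'
#' @param volume `image_volume` in HU.
#' @param body logical body mask on the same grid.
#' @param gas_threshold HU below which an in-body voxel counts as gas
#'   (default -200).
#' @param shell_radius shell radius in mm (default 10).
#' @return The corrected `image_volume`, with attribute `n_replaced`.
#' @export
override_bowel_gas <- function(volume, body, gas_threshold = -200,
                               shell_radius = 10) {
  if (!any(body)) stop("body mask is empty")
  a <- vol_array(volume)
  gas <- body & (a < gas_threshold)
  out <- a
  n_replaced <- 0L
  if (any(gas)) {
    sp <- vol_spacing(volume)
    lab <- label_components(gas)
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      shell <- dilate_mask(comp, shell_radius, sp) & !gas
      if (!any(shell))
        stop(sprintf(
          "gas component %d has no tissue voxel within %g mm", k,
          shell_radius), call. = FALSE)
      out[comp] <- mean(a[shell])
      n_replaced <- n_replaced + sum(comp)
    }
  }
  res <- vol_like(out, volume)
  attr(res, "n_replaced") <- n_replaced
  res
}
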