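#' Density values for the two classic sCT methods
#'
#' `bulk_density_values()` holds the two-class (bone / soft tissue)
#' assignment; `tissue_class_values()` the three-class (bone / muscle-
#' viscera / fat) assignment. Defaults are the optimized pelvic values in
#' relative electron density (RED) with the matching mass densities in
#' g/cm^3: bulk bone 1.20 (1.25) and tissue 0.97 (0.99); tissue-class bone
#' 1.16 (1.20), muscle 1.02 (1.03) and fat 0.91 (0.92).
#'
#' @param bone_red,tissue_red,muscle_red,fat_red relative electron
#'   densities.
#' @param bone_mass,tissue_mass,muscle_mass,fat_mass mass densities, g/cm^3
#'   (carried for reporting; dose uses RED).
#' @return A named list of class `bulk_density_values` /
#'   `tissue_class_values`.
#' @export
bulk_density_values <- function(bone_red = 1.20, tissue_red = 0.97,
                                bone_mass = 1.25, tissue_mass = 0.99) {
  if (!(bone_red > tissue_red && tissue_red > 0))
    stop("need bone_red > tissue_red > 0")
  structure(list(bone_red = bone_red, tissue_red = tissue_red,
                 bone_mass = bone_mass, tissue_mass = tissue_mass),
            class = "bulk_density_values")
}

#' @rdname bulk_density_values
#' @export
tissue_class_values <- function(bone_red = 1.16, muscle_red = 1.02,
                                fat_red = 0.91, bone_mass = 1.20,
                                muscle_mass = 1.03, fat_mass = 0.92) {
  if (!(bone_red > muscle_red && muscle_red > fat_red))
    stop("need bone_red > muscle_red > fat_red")
  structure(list(bone_red = bone_red, muscle_red = muscle_red,
                 fat_red = fat_red, bone_mass = bone_mass,
                 muscle_mass = muscle_mass, fat_mass = fat_mass),
            class = "tissue_class_values")
}

#' Segment the body contour from an in-phase Dixon image
#'
#' Thresholds the in-phase volume, keeps the largest connected
#' supra-threshold component and fills interior holes. The default
#' `"otsu"` strategy picks the threshold by minimizing intra-class variance
#' of the intensity histogram (a bimodal split between air background and
#' body); a numeric `threshold_strategy` is used as a manual threshold.
#'
#' @param mri_in_phase `image_volume`, in-phase MRI.
#' @param threshold_strategy `"otsu"` or a numeric threshold.
#' @return Logical body mask.
#' @export
segment_body <- function(mri_in_phase, threshold_strategy = "otsu") {
  a <- vol_array(mri_in_phase)
  if (max(a) - min(a) <= 0) stop("volume is constant; cannot threshold")
  thr <- if (is.numeric(threshold_strategy)) threshold_strategy
         else otsu_threshold(as.vector(a))
  supra <- a > thr
  lab <- label_components(supra)
  if (max(lab) == 0) stop("no supra-threshold component found")
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < 0.05 * length(a))
    stop("largest component is below 5% of the grid; body not found")
  fill_holes(lab == which.max(sizes))
}

# histogram-based minimal intra-class variance split (256 bins)
otsu_threshold <- function(v) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = 257)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), 256)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-257]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[length(mu1)]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment fat from a Dixon set by fat-fraction thresholding
#'
#' Computes the voxel fat fraction `F / (F + W)` from the fat- and
#' water-weighted channels and returns in-body voxels above
#' `ff_threshold`. The fat fraction is undefined where the total Dixon
#' signal vanishes (cortical bone, gas), so voxels with `F + W` below
#' `signal_floor_frac` of the in-body median total signal are excluded.
#'
#' @param dixon a [dixon_set()].
#' @param body logical body mask.
#' @param ff_threshold fat-fraction threshold (default 0.5).
#' @param signal_floor_frac minimum `F + W` as a fraction of the in-body
#'   median (default 0.25).
#' @return Logical fat mask.
#' @export
segment_fat <- function(dixon, body, ff_threshold = 0.5,
                        signal_floor_frac = 0.25) {
  if (!any(body)) stop("body mask is empty")
  f <- vol_array(dixon$fat); w <- vol_array(dixon$water)
  tot <- f + w
  floor_val <- max(signal_floor_frac * median(tot[body]), 0)
  ff <- ifelse(tot > floor_val, f / pmax(tot, .Machine$double.eps), 0)
  body & tot > floor_val & ff > ff_threshold
}

#' Bulk density sCT: two classes (bone, soft tissue)
#'
#' Assigns `red_to_hu(bone_red)` to the bone mask, `red_to_hu(tissue_red)`
#' to the rest of the body, and -1000 HU outside the body. The bone mask is
#' taken as an input (ground truth or a manually outlined contour), not
#' derived from MRI intensity.
#'
#' @param body,bone logical masks, `bone` contained in `body`.
#' @param values a [bulk_density_values()].
#' @param cal a [density_calibration()].
#' @param geometry an `image_volume` on the target grid supplying
#'   spacing/origin (e.g. the MRI); defaults to unit spacing.
#' @return sCT `image_volume` in HU.
#' @export
assign_bulk_density <- function(body, bone, values = bulk_density_values(),
                                cal = density_calibration(),
                                geometry = NULL) {
  check_mask_subset(bone, body)
  out <- array(-1000, dim(body))
  out[body] <- red_to_hu(values$tissue_red, cal)
  out[bone] <- red_to_hu(values$bone_red, cal)
  as_sct_volume(out, geometry, dim(body))
}

#' Tissue-class density sCT: bone, fat, muscle/viscera
#'
#' Muscle/viscera is the Boolean subtraction of fat and bone from the body
#' contour; overlaps resolve by the precedence bone > fat > muscle (the
#' manual bone contour is authoritative).
#'
#' @param fat logical fat mask (from [segment_fat()]), contained in `body`.
#' @inheritParams assign_bulk_density
#' @param values a [tissue_class_values()].
#' @return sCT `image_volume` in HU.
#' @export
assign_tissue_class <- function(body, bone, fat,
                                values = tissue_class_values(),
                                cal = density_calibration(),
                                geometry = NULL) {
  check_mask_subset(bone, body)
  check_mask_subset(fat, body, "fat")
  out <- array(-1000, dim(body))
  out[body] <- red_to_hu(values$muscle_red, cal)
  out[fat] <- red_to_hu(values$fat_red, cal)
  out[bone] <- red_to_hu(values$bone_red, cal)
  as_sct_volume(out, geometry, dim(body))
}

check_mask_subset <- function(sub, body, what = "bone") {
  bad <- sum(sub & !body)
  if (bad > 0)
    stop(sprintf("%s mask has %d voxel(s) outside the body mask", what, bad),
         call. = FALSE)
  invisible(TRUE)
}

as_sct_volume <- function(a, geometry, d) {
  if (!is.null(geometry)) return(vol_like(array(a, d), geometry, "HU"))
  image_volume(array(a, d), spacing = c(1, 1, 1), kind = "HU")
}
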