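#' Beam configuration for the attenuation dose engine
#'
#' The engine is a deliberately simplified surrogate for a clinical TPS: it
#' exists to make dose sensitive to HU/RED differences along ray paths, not
#' to model clinical beams. `n_beams` equally spaced coplanar parallel beams
#' (a VMAT-arc surrogate) deposit `exp(-mu_eff * radiological depth)` per
#' voxel inside a rectangular aperture around the PTV projection; no
#' scatter, build-up or inverse-square effects are modelled.
#'
#' @param n_beams number of equally spaced coplanar gantry angles
#'   (default 36).
#' @param isocenter physical point (mm, z/y/x); defaults to the case
#'   reference point at calculation time.
#' @param aperture_margin_mm margin around the PTV projection, mm.
#' @param mu_eff effective linear attenuation per mm of water-equivalent
#'   depth (default 0.006/mm, a 6-MV-like effective value).
#' @param prescription_dose prescription (Gy) delivered at the isocenter on
#'   the reference volume.
#' @return A `beam_config` list.
#' @export
beam_config <- function(n_beams = 36, isocenter = NULL,
                        aperture_margin_mm = 10, mu_eff = 0.006,
                        prescription_dose = 50) {
  stopifnot(n_beams >= 1, mu_eff > 0, prescription_dose > 0)
  structure(list(n_beams = as.integer(n_beams), isocenter = isocenter,
                 aperture_margin_mm = aperture_margin_mm, mu_eff = mu_eff,
                 prescription_dose = prescription_dose),
            class = "beam_config")
}

#' Calculate dose on a RED volume with the attenuation engine
#'
#' Per beam, every voxel inside the aperture receives a contribution
#' proportional to `exp(-mu_eff * d_rad)`, where the radiological depth
#' `d_rad` is the exact Siddon-style path integral of RED (mm of
#' water-equivalent depth) from the body surface to the voxel along the ray.
#' Contributions are summed over beams and scaled so the isocenter voxel
#' receives `prescription_dose`; pass that frozen `scale` back in for the
#' paired sCT run so both runs use identical "monitor units".
#'
#' @param red `image_volume` of relative electron density (from
#'   [hu_to_red()]).
#' @param body logical body mask.
#' @param beams a [beam_config()].
#' @param ptv logical PTV mask defining the aperture.
#' @param scale reuse a normalization factor from a reference run (default
#'   `NULL`: normalize so the isocenter receives the prescription).
#' @return `image_volume` in Gy with attributes `scale` (the normalization
#'   factor) and `isocenter`.
#' @export
calculate_dose <- function(red, body, beams, ptv, scale = NULL) {
  d <- dim(red); sp <- vol_spacing(red)
  iso <- beams$isocenter
  if (is.null(iso)) stop("beam_config has no isocenter; supply one")
  iso_idx <- round(phys_to_index(red, iso))
  if (any(iso_idx < 0) || any(iso_idx > d - 1))
    stop("isocenter lies outside the dose grid")
  if (!body[iso_idx[1] + 1, iso_idx[2] + 1, iso_idx[3] + 1])
    stop("isocenter lies outside the body")

  g <- index_grid(d)
  # physical coordinates (origin-free: relative positions suffice)
  pz <- g$z * sp[1]; py <- g$y * sp[2]; px <- g$x * sp[3]
  ptv_idx <- which(ptv)
  if (length(ptv_idx) == 0) stop("PTV mask is empty")
  angles <- 2 * pi * (seq_len(beams$n_beams) - 1) / beams$n_beams
  mgn <- beams$aperture_margin_mm
  ptv_z <- pz[ptv_idx]
  acc <- numeric(prod(d))
  redv <- as.numeric(vol_array(red))
  for (th in angles) {
    # beam direction in the axial (y, x) plane
    dir <- c(0, cos(th), sin(th))
    # in-plane coordinate perpendicular to the beam
    tp <- py * (-sin(th)) + px * cos(th)
    ptv_t <- tp[ptv_idx]
    in_ap <- pz >= min(ptv_z) - mgn & pz <= max(ptv_z) + mgn &
      tp >= min(ptv_t) - mgn & tp <= max(ptv_t) + mgn & as.vector(body)
    vox <- which(in_ap) - 1L
    if (length(vox) == 0) next
    depth <- .ray_depth(redv, as.integer(d), as.numeric(sp),
                        as.numeric(dir), as.integer(vox))
    acc[vox + 1L] <- acc[vox + 1L] + exp(-beams$mu_eff * depth)
  }
  iso_lin <- iso_idx[1] + d[1] * (iso_idx[2] + d[2] * iso_idx[3]) + 1
  if (is.null(scale)) {
    if (acc[iso_lin] <= 0) stop("no beam reaches the isocenter")
    scale <- beams$prescription_dose / acc[iso_lin]
  }
  out <- vol_like(array(acc * scale, d), red, "Gy")
  attr(out, "scale") <- scale
  attr(out, "isocenter") <- iso
  out
}

#' Dose at a physical reference point (trilinear)
#' @param dose `image_volume` in Gy.
#' @param point physical coordinates, mm (z, y, x).
#' @return Dose in Gy.
#' @export
dose_at_point <- function(dose, point) {
  ci <- phys_to_index(dose, point)
  sample_at_index(vol_array(dose), ci[1], ci[2], ci[3], "linear")
}

#' DVH metrics for a structure
#'
#' `Dx` is the dose received by at least `x`% of the structure volume, read
#' from the dose-volume histogram with linear interpolation between sorted
#' voxel doses (the "at least" convention: at an exact plateau boundary the
#' colder value is reported, so two equal halves at 40/60 Gy give
#' D50 = 40 Gy). `Vy` is the percentage of the structure receiving at least
#' `y`% of the prescription.
#'
#' @param dose `image_volume` in Gy.
#' @param mask logical structure mask (non-empty).
#' @param prescription prescription dose in Gy (for `Vy`).
#' @param d_pct percentages for `Dx` (default 98, 95, 50, 2).
#' @param v_pct percentages of prescription for `Vy` (default 95).
#' @return Named list, e.g. `D98`, `D95`, `D50`, `D2` (Gy) and `V95` (%).
#' @export
dvh_metrics <- function(dose, mask, prescription,
                        d_pct = c(98, 95, 50, 2), v_pct = 95) {
  if (!any(mask)) stop("structure mask is empty")
  dv <- vol_array(dose)[mask]
  out <- list()
  for (x in d_pct)
    out[[paste0("D", x)]] <-
      unname(quantile(dv, probs = 1 - x / 100, type = 4))
  for (y in v_pct)
    out[[paste0("V", y)]] <- 100 * mean(dv >= y / 100 * prescription)
  out
}

#' Percentage dose difference
#'
#' `(d_sct - d_ct) / d_ct * 100`: the sign convention makes a cold sCT
#' negative. Accepts scalars, vectors or named metric lists (compared
#' elementwise by name); for metric sets the mean of the per-metric
#' differences is also returned, the combined-average convention used for
#' multi-parameter DVH comparison.
#'
#' @param d_sct,d_ct doses (Gy) or named metric lists from [dvh_metrics()].
#' @return For scalars/vectors, the percentage difference(s); for metric
#'   lists, a list with `per_metric` and `average`.
#' @export
percent_dose_difference <- function(d_sct, d_ct) {
  if (is.list(d_sct) || is.list(d_ct)) {
    stopifnot(identical(names(d_sct), names(d_ct)))
    per <- mapply(function(s, c) percent_dose_difference(s, c),
                  d_sct, d_ct)
    return(list(per_metric = per, average = mean(per)))
  }
  if (any(d_ct == 0)) stop("reference dose is zero; %DD undefined")
  (d_sct - d_ct) / d_ct * 100
}
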