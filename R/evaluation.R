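#' Gamma-analysis criteria
#'
#' @param dose_diff_pct dose-difference criterion, % of the normalization
#'   dose (global normalization: the maximum reference dose inside the
#'   eroded body).
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param low_dose_threshold_pct exclude voxels whose reference dose is
#'   below this % of the normalization dose (default 10).
#' @param erosion_mm body-perimeter erosion before evaluation, mm (default
#'   15; excludes skin-edge failures).
#' @param search_radius_factor candidate search radius as a multiple of
#'   `dta_mm` (default 3).
#' @param interp_step_mm candidate grid step, mm; default `dta_mm / 10`.
#' @return A `gamma_criteria` list.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 2,
                           low_dose_threshold_pct = 10, erosion_mm = 15,
                           search_radius_factor = 3,
                           interp_step_mm = dta_mm / 10) {
  stopifnot(dose_diff_pct > 0, dta_mm > 0, low_dose_threshold_pct > 0,
            erosion_mm >= 0, search_radius_factor >= 1, interp_step_mm > 0)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 erosion_mm = erosion_mm,
                 search_radius_factor = search_radius_factor,
                 interp_step_mm = interp_step_mm),
            class = "gamma_criteria")
}

gamma_offsets <- function(crit) {
  r <- crit$search_radius_factor * crit$dta_mm
  s <- seq(-r, r, by = crit$interp_step_mm)
  g <- as.matrix(expand.grid(z = s, y = s, x = s))
  nrm <- sqrt(rowSums(g^2))
  keep <- nrm <= r + 1e-9
  g <- g[keep, , drop = FALSE]; nrm <- nrm[keep]
  ord <- order(nrm)
  list(offsets = g[ord, , drop = FALSE], norm = nrm[ord])
}

#' 3D gamma analysis of two dose grids
#'
#' Computes the gamma index of `eval_dose` against the reference `ref_dose`
#' over the eroded body above the low-dose threshold. For each evaluated
#' voxel, candidate points on a regular grid of step `interp_step_mm` within
#' the search radius are visited in order of increasing distance;
#' `gamma = min sqrt((dd / DD)^2 + (dist / dta)^2)` with the evaluated dose
#' trilinearly interpolated at each candidate. The distance-ordered early
#' exit is exact: results are identical to the exhaustive search
#' (`exhaustive = TRUE`, a plain-R reference used for verification).
#'
#' The comparison is asymmetric: pass the planned (CT) dose as `ref_dose`.
#'
#' @param ref_dose,eval_dose `image_volume`s in Gy on the same grid.
#' @param body logical body mask.
#' @param crit a [gamma_criteria()].
#' @param exhaustive use the brute-force reference implementation.
#' @return A `gamma_result`: list with `pass_rate` (% of evaluated voxels
#'   with gamma <= 1), `mean_gamma`, `gamma_map` (`image_volume`, `NA`
#'   outside the evaluated region), `n_evaluated`, and the normalization
#'   dose `norm_dose`.
#' @export
gamma_3d <- function(ref_dose, eval_dose, body, crit = gamma_criteria(),
                     exhaustive = FALSE) {
  stop_if_grid_mismatch(ref_dose, eval_dose, "dose grids")
  sp <- vol_spacing(ref_dose)
  ref <- vol_array(ref_dose); ev <- vol_array(eval_dose)
  eroded <- if (crit$erosion_mm > 0) erode_mask(body, crit$erosion_mm, sp)
            else body
  if (!any(eroded)) stop("eroded body mask is empty")
  norm_dose <- max(ref[eroded])
  if (norm_dose <= 0)
    stop("reference dose is zero inside the eroded body; no voxel above ",
         "the low-dose threshold")
  evalmask <- eroded & ref >= crit$low_dose_threshold_pct / 100 * norm_dose
  if (!any(evalmask)) stop("no voxel above the low-dose threshold")
  dd_abs <- crit$dose_diff_pct / 100 * norm_dose
  off <- gamma_offsets(crit)
  vox <- which(evalmask) - 1L
  g <- if (exhaustive) {
    gamma_exhaustive(ref, ev, dim(ref), sp, vox, off$offsets, off$norm,
                     dd_abs, crit$dta_mm)
  } else {
    .gamma_search(as.numeric(ref), as.numeric(ev), as.integer(dim(ref)),
                  as.numeric(sp), as.integer(vox), off$offsets, off$norm,
                  dd_abs, crit$dta_mm)
  }
  gmap <- array(NA_real_, dim(ref))
  gmap[evalmask] <- g
  structure(list(pass_rate = 100 * mean(g <= 1), mean_gamma = mean(g),
                 gamma_map = vol_like(gmap, ref_dose, "Gy"),
                 n_evaluated = length(g), norm_dose = norm_dose,
                 criteria = crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result %g%%/%g mm> pass rate %.2f%%, mean gamma %.4f (n = %d)\n",
    x$criteria$dose_diff_pct, x$criteria$dta_mm, x$pass_rate, x$mean_gamma,
    x$n_evaluated))
  invisible(x)
}

# Plain-R exhaustive gamma: every candidate for every voxel, no early exit.
# Arithmetic mirrors the compiled search (same candidate set, same trilinear
# accumulation order) so results agree bitwise.
gamma_exhaustive <- function(ref, ev, d, sp, vox, offsets, offnorm, dd_abs,
                             dta) {
  z <- vox %% d[1]
  r <- vox %/% d[1]
  y <- r %% d[2]
  x <- r %/% d[2]
  rv <- ref[vox + 1L]
  best <- rep(Inf, length(vox))
  for (k in seq_len(nrow(offsets))) {
    zi <- z + offsets[k, 1] / sp[1]
    yi <- y + offsets[k, 2] / sp[2]
    xi <- x + offsets[k, 3] / sp[3]
    ok <- zi >= 0 & zi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
      xi >= 0 & xi <= d[3] - 1
    if (!any(ok)) next
    e <- trilinear_exact(ev, d, zi[ok], yi[ok], xi[ok])
    dd <- (e - rv[ok]) / dd_abs
    g2 <- dd * dd + (offnorm[k] / dta)^2
    best[ok] <- pmin(best[ok], g2)
  }
  sqrt(best)
}

# trilinear interpolation matching the compiled kernel's accumulation order
trilinear_exact <- function(a, d, zi, yi, xi) {
  z0 <- pmax(pmin(floor(zi), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(yi), d[2] - 2), 0)
  x0 <- pmax(pmin(floor(xi), d[3] - 2), 0)
  fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
      (if (dx) fx else 1 - fx)
    idx <- (z0 + dz) + d[1] * ((y0 + dy) + d[2] * (x0 + dx)) + 1
    acc <- acc + w * a[idx]
  }
  acc
}

#' HU mean error and mean absolute error with end-slab exclusion
#'
#' `ME = mean(sct - ct)` and `MAE = mean(|sct - ct|)` over the region mask,
#' after dropping the superior and inferior `exclusion_mm` of the scan
#' (`ceiling(exclusion_mm / spacing_z)` axial slices at each end), where
#' image quality typically degrades.
#'
#' @param sct,ct `image_volume`s in HU on the same grid.
#' @param region logical mask (e.g. whole body, bone, or body minus bone
#'   for soft tissue).
#' @param exclusion_mm end-slab exclusion, mm (default 30).
#' @param region_name label carried into the report.
#' @return List with `me`, `mae`, `n_voxels`, `region`.
#' @export
hu_error <- function(sct, ct, region, exclusion_mm = 30,
                     region_name = "region") {
  stop_if_grid_mismatch(sct, ct, "HU volumes")
  d <- dim(region)
  nz_excl <- ceiling(exclusion_mm / vol_spacing(ct)[1])
  keep <- region
  if (nz_excl > 0) {
    if (2 * nz_excl >= d[1]) stop("exclusion removes the whole scan")
    keep[c(seq_len(nz_excl), d[1] - seq_len(nz_excl) + 1L), , ] <- FALSE
  }
  if (!any(keep)) stop("region is empty after end-slab exclusion")
  diff <- vol_array(sct)[keep] - vol_array(ct)[keep]
  list(me = mean(diff), mae = mean(abs(diff)), n_voxels = sum(keep),
       region = region_name)
}

#' Mann-Whitney U test
#'
#' Computes `U` for sample `a` versus `b` (number of pairs with `a > b`,
#' ties counted one half). When `min(n, m) <= 8` and there are no ties, the
#' two-sided p-value comes from the exact null distribution of `U`
#' (enumeration over all arrangements via the standard counting recursion);
#' otherwise a normal approximation with tie and continuity corrections is
#' used. The result records which path was taken.
#'
#' @param a,b numeric samples (each non-empty).
#' @return List with `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approximation"`), `n`, `m`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (min(n, m) <= 8 && !ties) {
    cnt <- u_count_table(n, m) # counts of each U value 0..nm under the null
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(floor(u) + 1)]) / tot      # P(U <= u)
    hi <- sum(cnt[(floor(u) + 1):(n * m + 1)]) / tot # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * m / 2
    t <- table(c(a, b))
    tie_term <- sum(t^3 - t) / ((n + m) * (n + m - 1))
    sig2 <- n * m / 12 * ((n + m + 1) - tie_term)
    if (sig2 <= 0) return(list(U = u, p_value = 1,
                               method = "normal_approximation", n = n, m = m))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(U = u, p_value = p, method = method, n = n, m = m)
}

# Number of rank arrangements giving each U in 0..n*m, by the classical
# recursion C(i, j, u) = C(i-1, j, u-j) + C(i, j-1, u): the largest rank is
# either an a-element (beating all j b's) or a b-element. C[i+1, u+1] holds
# the counts for i a-elements at the current number of b-elements.
u_count_table <- function(n, m) {
  nu <- n * m + 1
  C <- matrix(0, nrow = n + 1, ncol = nu)
  C[, 1] <- 1 # j = 0: only a's, U = 0
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      shifted <- c(rep(0, min(j, nu)), C[i, seq_len(max(nu - j, 0))])
      C[i + 1, ] <- C[i + 1, ] + shifted[seq_len(nu)]
    }
    # C[1, ] (i = 0) stays: U = 0 with probability 1 regardless of j
  }
  C[n + 1, ]
}

#' Summarize per-case metrics over a cohort
#'
#' Mirrors the cohort-table layout of the validation workflow: percentage
#' dose differences are summarized as median and IQR (25th/75th percentiles,
#' linear interpolation); gamma and HU-error metrics as mean and SD (SD
#' reported as 0 for a single case).
#'
#' @param metrics long data.frame with columns `case`, `group`, `method`,
#'   `family` (`"dd"`, `"gamma"` or `"hu"`), `metric`, `value`.
#' @param grouping `"all"`, `"male"` or `"female"`.
#' @return data.frame with one row per (method, metric): columns `center`
#'   (median or mean), `spread_lo`/`spread_hi` (IQR bounds) or `spread_sd`,
#'   `summary` ("median_iqr" or "mean_sd"), `n_cases`.
#' @export
summarize_cohort <- function(metrics, grouping = "all") {
  stopifnot(is.data.frame(metrics),
            all(c("case", "group", "method", "family", "metric", "value")
                %in% names(metrics)))
  if (!grouping %in% c("all", "male", "female"))
    stop(sprintf("unknown group label '%s'", grouping))
  if (grouping != "all") {
    metrics <- metrics[metrics$group == grouping, , drop = FALSE]
    if (nrow(metrics) == 0) stop(sprintf("no cases in group '%s'", grouping))
  }
  key <- interaction(metrics$method, metrics$metric, metrics$family,
                     drop = TRUE)
  rows <- lapply(split(metrics, key), function(df) {
    v <- df$value
    if (df$family[1] == "dd") {
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(group = grouping, method = df$method[1],
                 metric = df$metric[1], family = "dd", center = q[2],
                 spread_lo = q[1], spread_hi = q[3], spread_sd = NA_real_,
                 summary = "median_iqr", n_cases = length(v))
    } else {
      data.frame(group = grouping, method = df$method[1],
                 metric = df$metric[1], family = df$family[1],
                 center = mean(v), spread_lo = NA_real_,
                 spread_hi = NA_real_,
                 spread_sd = if (length(v) > 1) sd(v) else 0,
                 summary = "mean_sd", n_cases = length(v))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$metric), ]
}
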