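slice_index <- function(d, axis) {
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  array(g[[axis]], d)
}

slab_setup <- function(d = c(21, 41, 41), sp = c(4, 4, 4)) {
  red <- image_volume(array(1, d), sp, kind = "RED")
  ctr <- (d - 1) %/% 2 + 1 # 1-based central voxel
  ptv <- array(FALSE, d)
  ptv[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2),
      (ctr[3] - 2):(ctr[3] + 2)] <- TRUE
  list(red = red, body = array(TRUE, d), ptv = ptv,
       iso = (ctr - 1) * sp)
}

test_that("single-beam central-axis dose follows the exponential", {
  s <- slab_setup()
  bc <- beam_config(n_beams = 1, isocenter = s$iso, mu_eff = 0.006,
                    prescription_dose = 50)
  dg <- calculate_dose(s$red, s$body, bc, s$ptv)
  # beam 0 deg travels along +y; compare along the central axis
  v <- unclass(dg)[11, 15:26, 21]
  depth_rel <- (seq(15, 26) - 1 - 20) * 4
  expect_equal(v, 50 * exp(-0.006 * depth_rel), tolerance = 0.01)
  expect_equal(dose_at_point(dg, s$iso), 50, tolerance = 1e-9)
})

test_that("halving RED everywhere raises dose at fixed depth and scale", {
  s <- slab_setup()
  bc <- beam_config(n_beams = 1, isocenter = s$iso)
  d1 <- calculate_dose(s$red, s$body, bc, s$ptv)
  half <- vol_like(unclass(s$red) * 0.5, s$red, "RED")
  d2 <- calculate_dose(half, s$body, bc, s$ptv,
                       scale = attr(d1, "scale"))
  sel <- unclass(d1) > 0 & unclass(d2) > 0
  deep <- sel & slice_index(dim(sel), 2) > 21 # beyond the entry surface
  expect_true(all(unclass(d2)[deep] > unclass(d1)[deep]))
})

test_that("dose is linear in the normalization scale", {
  s <- slab_setup(d = c(13, 25, 25))
  bc <- beam_config(n_beams = 4, isocenter = c(6, 12, 12) * 4)
  ptv <- array(FALSE, dim(s$red)); ptv[5:9, 10:15, 10:15] <- TRUE
  d1 <- calculate_dose(s$red, s$body, bc, ptv)
  d2 <- calculate_dose(s$red, s$body, bc, ptv,
                       scale = attr(d1, "scale") * 3)
  expect_equal(as.vector(d2), as.vector(d1) * 3, tolerance = 1e-12)
})

test_that("a 36-beam arc on a cylinder is rotationally symmetric", {
  d <- c(13, 41, 41); sp <- c(4, 4, 4)
  ctr <- c(20, 20) # 0-based in-plane centre
  g <- expand.grid(y = 0:40, x = 0:40)
  r2 <- (g$y - ctr[1])^2 + (g$x - ctr[2])^2
  disk <- matrix(r2 <= 18^2, 41, 41)
  body <- array(rep(as.vector(disk), each = d[1]), d)
  red <- image_volume(array(ifelse(body, 1, 0.001), d), sp, kind = "RED")
  ptv <- array(FALSE, d); ptv[5:9, 18:24, 18:24] <- TRUE
  bc <- beam_config(n_beams = 36, isocenter = c(6, 20, 20) * 4)
  dg <- calculate_dose(red, body, bc, ptv)
  # compare the four 90-degree rotations of a mid-plane ring
  sl <- unclass(dg)[7, , ]
  ring <- list(sl[20 + 1, 28 + 1], sl[28 + 1, 20 + 1],
               sl[20 + 1, 12 + 1], sl[12 + 1, 20 + 1])
  base <- ring[[1]]
  for (v in ring) expect_equal(v, base, tolerance = 0.02)
})


test_that("isocenter outside the body or grid is rejected", {
  s <- slab_setup(d = c(9, 17, 17))
  body <- array(FALSE, dim(s$red)); body[3:7, 5:13, 5:13] <- TRUE
  bc <- beam_config(n_beams = 1, isocenter = c(0, 0, 0))
  expect_error(calculate_dose(s$red, body, bc, s$ptv), "outside the body")
  bc2 <- beam_config(n_beams = 1, isocenter = c(-50, 0, 0))
  expect_error(calculate_dose(s$red, body, bc2, s$ptv), "grid")
})

test_that("DVH metrics follow the at-least-coverage convention", {
  d <- c(10, 10, 10); sp <- c(4, 4, 4)
  m <- array(TRUE, d)
  u <- image_volume(array(50, d), sp, kind = "Gy")
  dv <- dvh_metrics(u, m, prescription = 50)
  expect_equal(dv$D98, 50); expect_equal(dv$D50, 50); expect_equal(dv$D2, 50)
  expect_equal(dv$V95, 100)
  # two equal halves at 40/60 Gy: D50 reads the colder plateau
  h <- image_volume(array(c(rep(40, 500), rep(60, 500)), d), sp,
                    kind = "Gy")
  dvh <- dvh_metrics(h, m, prescription = 50)
  expect_equal(dvh$D50, 40)
  expect_equal(dvh$D2, 60)
  expect_equal(dvh$V95, 50) # half the volume receives >= 47.5 Gy
  # Dx is monotone non-increasing in x
  set.seed(9)
  r <- image_volume(array(runif(prod(d), 20, 70), d), sp, kind = "Gy")
  dx <- unlist(dvh_metrics(r, m, 50, d_pct = c(98, 95, 50, 10, 2),
                           v_pct = numeric(0)))
  expect_true(all(diff(dx) >= 0)) # listed from D98 up to D2
  expect_error(dvh_metrics(u, array(FALSE, d), 50), "empty")
})

test_that("percentage dose difference preserves sign and aggregates", {
  expect_equal(percent_dose_difference(99, 100), -1)
  expect_equal(percent_dose_difference(100, 100), 0)
  expect_error(percent_dose_difference(1, 0), "zero")
  m_ct <- list(D98 = 50, D50 = 52, D2 = 54)
  m_sct <- list(D98 = 49, D50 = 52, D2 = 55)
  pd <- percent_dose_difference(m_sct, m_ct)
  expect_equal(unname(pd$per_metric),
               c(-1 / 50, 0, 1 / 54) * 100)
  expect_equal(pd$average, mean(pd$per_metric))
})
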