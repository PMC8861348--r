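make_dose <- function(a, sp = c(4, 4, 4)) image_volume(a, sp, kind = "Gy")

test_that("hu_error recovers constructed perturbations analytically", {
  d <- c(20, 10, 10)
  ct <- image_volume(array(0, d), c(4, 4, 4), kind = "HU")
  reg <- array(TRUE, d)
  he <- hu_error(vol_like(unclass(ct) + 20, ct), ct, reg)
  expect_equal(he$me, 20)
  expect_equal(he$mae, 20)
  # +/-20 alternating in equal halves: ME 0, MAE 20
  alt <- array(rep(c(20, -20), length.out = prod(d)), d)
  he2 <- hu_error(vol_like(unclass(ct) + alt, ct), ct, reg)
  expect_equal(he2$me, 0)
  expect_equal(he2$mae, 20)
  # additivity of the mean error
  he3 <- hu_error(vol_like(unclass(ct) + alt + 7, ct), ct, reg)
  expect_equal(he3$me, he2$me + 7)
})

test_that("end-slab exclusion removes exactly ceil(30 / dz) slices per end", {
  for (dz in c(2, 3, 4)) {
    d <- c(40, 6, 6)
    ct <- image_volume(array(0, d), c(dz, 4, 4), kind = "HU")
    he <- hu_error(vol_like(unclass(ct) + 1, ct), ct, array(TRUE, d),
                   exclusion_mm = 30)
    expect_equal(he$n_voxels, (40 - 2 * ceiling(30 / dz)) * 36)
  }
  d <- c(10, 4, 4)
  ct <- image_volume(array(0, d), c(4, 4, 4), kind = "HU")
  expect_error(hu_error(ct, ct, array(TRUE, d), exclusion_mm = 30),
               "whole scan")
})

test_that("Mann-Whitney exact path reproduces the enumerated distribution", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1) # 2/20 arrangements
  expect_equal(mw$method, "exact")
  # identical samples: ties force the approximation; p is ~1
  mw2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(mw2$p_value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("U(a,b) + U(b,a) = n*m and exact p matches wilcox.test", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:8, 1); m <- sample(2:10, 1)
    a <- rnorm(n); b <- rnorm(m, 0.5)
    ua <- mann_whitney_u(a, b); ub <- mann_whitney_u(b, a)
    expect_equal(ua$U + ub$U, n * m)
    if (ua$method == "exact") {
      ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
      expect_equal(ua$U, unname(ref$statistic))
      expect_equal(ua$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  # large samples: tie-corrected normal approximation against wilcox.test
  a <- rnorm(30); b <- rnorm(26, 0.4)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$method, "normal_approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("cohort summaries use median/IQR for %DD and mean/SD otherwise", {
  metrics <- rbind(
    data.frame(case = 1:5, group = "male", method = "bulk", family = "dd",
               metric = "icru_point", value = c(1, 2, 3, 4, 5)),
    data.frame(case = 1:5, group = "male", method = "bulk",
               family = "gamma", metric = "pass_3_2",
               value = c(99, 98, 97, 99, 100)))
  s <- summarize_cohort(metrics, "all")
  dd <- s[s$family == "dd", ]
  expect_equal(dd$center, 3)
  expect_equal(c(dd$spread_lo, dd$spread_hi), c(2, 4))
  gm <- s[s$family == "gamma", ]
  expect_equal(gm$center, mean(c(99, 98, 97, 99, 100)))
  expect_equal(gm$spread_sd, sd(c(99, 98, 97, 99, 100)))
  # single case: SD reported as 0, median degenerate
  s1 <- summarize_cohort(metrics[c(1, 6), ], "all")
  expect_equal(s1$spread_sd[s1$family == "gamma"], 0)
  expect_error(summarize_cohort(metrics, "children"), "unknown group")
  expect_error(summarize_cohort(metrics, "female"), "no cases")
})

test_that("gamma of identical dose grids is zero everywhere", {
  d <- c(16, 20, 20)
  set.seed(5)
  a <- array(50, d) + array(runif(prod(d), 0, 5), d)
  ref <- make_dose(a)
  body <- array(TRUE, d)
  for (cr in list(gamma_criteria(3, 2, erosion_mm = 8),
                  gamma_criteria(1, 1, erosion_mm = 8))) {
    g <- gamma_3d(ref, ref, body, cr)
    expect_equal(g$pass_rate, 100)
    expect_equal(g$mean_gamma, 0)
  }
})

test_that("uniform 2% scaling gives gamma exactly 2/3 at 3%/2 mm", {
  d <- c(16, 20, 20)
  a <- array(0, d); a[3:14, 4:17, 4:17] <- 50
  ref <- make_dose(a)
  ev <- vol_like(unclass(ref) * 1.02, ref)
  body <- array(a > 0, d)
  g <- gamma_3d(ref, ev, body, gamma_criteria(3, 2, erosion_mm = 8))
  gv <- unclass(g$gamma_map)
  expect_equal(unique(gv[!is.na(gv)]), 2 / 3, tolerance = 1e-12)
  expect_equal(g$pass_rate, 100)
})

test_that("optimized gamma equals the exhaustive reference bitwise", {
  set.seed(31)
  cr <- gamma_criteria(3, 2, erosion_mm = 0, search_radius_factor = 2,
                       interp_step_mm = 0.5)
  for (i in 1:8) {
    d <- sample(6:12, 3, replace = TRUE)
    sp <- runif(3, 2, 5)
    ref <- image_volume(array(runif(prod(d), 10, 60), d), sp, kind = "Gy")
    ev <- vol_like(unclass(ref) + array(rnorm(prod(d), 0, 2.5), d), ref)
    g1 <- gamma_3d(ref, ev, array(TRUE, d), cr)
    g2 <- gamma_3d(ref, ev, array(TRUE, d), cr, exhaustive = TRUE)
    expect_identical(g1$pass_rate, g2$pass_rate)
    expect_identical(g1$mean_gamma, g2$mean_gamma)
    expect_identical(unclass(g1$gamma_map), unclass(g2$gamma_map))
  }
})

test_that("gamma is asymmetric in general and degrades with tighter criteria", {
  set.seed(41)
  d <- c(10, 12, 12)
  ref <- make_dose(array(30 + 20 * (seq_len(prod(d)) %% 7) / 7, d),
                   sp = c(3, 3, 3))
  ev <- vol_like(unclass(ref) * 1.015 + 0.4, ref)
  body <- array(TRUE, d)
  cr3 <- gamma_criteria(3, 2, erosion_mm = 0)
  g_fwd <- gamma_3d(ref, ev, body, cr3)
  g_bwd <- gamma_3d(ev, ref, body, cr3)
  expect_false(isTRUE(all.equal(g_fwd$mean_gamma, g_bwd$mean_gamma)))
  p3 <- g_fwd$pass_rate
  p2 <- gamma_3d(ref, ev, body, gamma_criteria(2, 2, erosion_mm = 0))$pass_rate
  p1 <- gamma_3d(ref, ev, body, gamma_criteria(1, 1, erosion_mm = 0))$pass_rate
  expect_gte(p3, p2)
  expect_gte(p2, p1)
})

test_that("gamma validates its inputs", {
  d <- c(8, 8, 8)
  ref <- make_dose(array(1, d))
  expect_error(gamma_3d(ref, ref, array(FALSE, d),
                        gamma_criteria(3, 2, erosion_mm = 0)), "empty")
  z <- make_dose(array(0, d))
  expect_error(gamma_3d(z, z, array(TRUE, d),
                        gamma_criteria(3, 2, erosion_mm = 0)), "threshold")
})
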