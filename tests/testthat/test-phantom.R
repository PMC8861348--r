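test_that("phantom generation is deterministic and internally consistent", {
  spec <- small_spec()
  a <- generate_phantom(spec, seed = 1)
  b <- generate_phantom(spec, seed = 1)
  expect_identical(unclass(a$ct), unclass(b$ct))
  expect_identical(a$labels, b$labels)
  expect_identical(unclass(a$mri$fat), unclass(b$mri$fat))
  c2 <- generate_phantom(spec, seed = 2)
  expect_false(identical(unclass(a$ct), unclass(c2$ct)))

  # labels partition the body; every mask is inside the body
  expect_equal(sum(a$labels > 0), sum(a$masks$body))
  for (nm in names(a$masks))
    expect_true(all(a$masks$body[a$masks[[nm]]]), label = nm)
  # per-class counts sum to the body count
  expect_equal(sum(tabulate(a$labels[a$labels > 0], 6)), sum(a$masks$body))
  # reference point lies inside the PTV
  i <- round((a$reference_point - a$origin) / a$spacing)
  expect_true(a$masks$ptv[i[1] + 1, i[2] + 1, i[3] + 1])
})

test_that("degenerate noise yields exact per-class HU and Dixon identities", {
  cs <- noiseless_case()
  hu <- small_spec()$tissue_hu
  expect_true(all(vol_data(cs$ct)[cs$labels == 1L] == hu$fat[1]))
  expect_true(all(vol_data(cs$ct)[cs$labels == 2L] == hu$muscle[1]))
  expect_true(all(vol_data(cs$ct)[cs$labels == 0L] == -1000))
  # in-phase = water + fat, out-of-phase = |water - fat| (no noise)
  ip_res <- vol_data(cs$mri$in_phase) -
    (vol_data(cs$mri$water) + vol_data(cs$mri$fat))
  expect_lt(max(abs(ip_res)), 1e-12)
  op_res <- vol_data(cs$mri$out_phase) -
    abs(vol_data(cs$mri$water) - vol_data(cs$mri$fat))
  expect_lt(max(abs(op_res)), 1e-12)
})

test_that("gas pockets form connected sub--800 HU components in the rectum", {
  cs <- generate_phantom(small_spec(gas_pocket = TRUE,
                                    noise_sd = c(ct = 0, mri = 0)), 3)
  gas <- vol_data(cs$ct) < -800 & cs$masks$body
  lab <- flood_components(gas)
  expect_gte(max(lab), 1)
  expect_true(all(cs$masks$rectum[gas]))
})

test_that("oversized organ geometry fails naming the structure", {
  og <- default_organ_geometry("male")
  og$bladder$semi <- c(500, 500, 500)
  expect_error(generate_phantom(small_spec(organ_geometry = og), 1),
               "bladder")
})

test_that("cohorts are jittered, reproducible and volume-stable", {
  base <- small_spec()
  expect_error(generate_cohort(base, 1), "n >= 2")
  coh <- generate_cohort(base, 5, seed = 7)
  expect_length(coh, 5)
  for (i in 2:5)
    expect_false(identical(unclass(coh[[1]]$ct), unclass(coh[[i]]$ct)))
  coh2 <- generate_cohort(base, 5, seed = 7)
  expect_identical(unclass(coh[[3]]$ct), unclass(coh2[[3]]$ct))

  # zero jitter degenerates to re-rendering the base spec
  coh0 <- generate_cohort(base, 2, seed = 7, geometry_jitter = 0,
                          tissue_jitter = 0, center_jitter_mm = 0)
  expect_identical(coh0[[1]]$labels, coh0[[2]]$labels)

  # mean body volume across a larger cohort stays near the base volume
  cohv <- generate_cohort(base, 12, seed = 3)
  base_vol <- sum(generate_phantom(base, 1)$masks$body)
  vols <- vapply(cohv, function(c) sum(c$masks$body), numeric(1))
  expect_lt(abs(mean(vols) / base_vol - 1), 0.10)
})

test_that("warp_phantom: identity at amplitude 0, bounded and reproducible", {
  cs <- small_case()
  w0 <- warp_phantom(cs, amplitude = 0, seed = 5)
  expect_identical(unclass(w0$ct), unclass(cs$ct))
  expect_identical(w0$labels, cs$labels)

  w1 <- warp_phantom(cs, amplitude = 5, smoothness = 60, seed = 9)
  w2 <- warp_phantom(cs, amplitude = 5, smoothness = 60, seed = 9)
  expect_identical(w1$warp$field, w2$warp$field)
  mag <- sqrt(w1$warp$field$dz^2 + w1$warp$field$dy^2 + w1$warp$field$dx^2)
  expect_lte(max(mag), 5 + 1e-9)
  expect_equal(max(mag), 5, tolerance = 1e-9)

  # warped labels still partition the warped body
  expect_equal(sum(w1$labels > 0), sum(w1$masks$body))
  i <- round((w1$reference_point - w1$origin) / w1$spacing)
  expect_true(w1$masks$ptv[i[1] + 1, i[2] + 1, i[3] + 1])
})

test_that("spec validation rejects non-physical parameters", {
  bad_hu <- default_tissue_hu(); bad_hu$gas[1] <- -500
  expect_error(phantom_spec(tissue_hu = bad_hu), "gas")
  bad_sd <- default_tissue_hu(); bad_sd$muscle[2] <- -1
  expect_error(phantom_spec(tissue_hu = bad_sd), "SD")
  expect_error(phantom_spec(grid_shape = c(8L, 44L, 44L)))
})
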