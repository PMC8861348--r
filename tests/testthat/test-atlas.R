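test_that("bias correction is near-neutral on bias-free input", {
  cs <- generate_phantom(small_spec(bias_field_amplitude = 0), 6)
  out <- correct_bias_field(cs$mri$in_phase, cs$masks$body)
  a0 <- vol_data(cs$mri$in_phase); a1 <- vol_data(out)
  rel <- abs(a1 - a0) / pmax(abs(a0), 1e-6)
  expect_lt(max(rel[cs$masks$body]), 0.02)
  # the field averages to 1 inside the body
  expect_equal(mean(attr(out, "bias_field")[cs$masks$body]), 1)
})

test_that("a known 20% quadratic bias is removed (CoV halved)", {
  cs <- generate_phantom(small_spec(bias_field_amplitude = 0.2,
                                    noise_sd = c(ct = 1, mri = 0)), 5)
  out <- correct_bias_field(cs$mri$in_phase, cs$masks$body)
  mus <- cs$labels == 2L
  cov <- function(v) sd(v) / mean(v)
  cv0 <- cov(vol_data(cs$mri$in_phase)[mus])
  cv1 <- cov(vol_data(out)[mus])
  expect_lt(cv1, 0.5 * cv0)
})

test_that("constant images and bad intensities are handled", {
  d <- c(20, 20, 20)
  body <- array(FALSE, d); body[3:18, 3:18, 3:18] <- TRUE
  const <- image_volume(array(5, d), c(4, 4, 4), kind = "MRI")
  out <- correct_bias_field(const, body)
  expect_equal(vol_data(out), array(5, d), tolerance = 1e-9)
  neg <- image_volume(array(-1, d), c(4, 4, 4), kind = "MRI")
  expect_error(correct_bias_field(neg, body), "non-positive")
  expect_error(correct_bias_field(const, array(FALSE, d)), "empty")
})

test_that("local weighted voting degenerates correctly", {
  cs <- small_case()
  body <- cs$masks$body
  tgt <- vol_data(cs$mri$water)
  ct <- vol_data(cs$ct)
  # one atlas: the warped CT itself, for any gain
  for (gain in c(0.1, 10, 1000)) {
    s <- local_weighted_voting(tgt, list(list(mri = tgt, ct = ct)), body,
                               lwv_params(gain = gain))
    expect_equal(max(abs(vol_data(s)[body] - ct[body])), 0)
  }
  # identical MRI channels: exact arithmetic mean of the CTs
  s2 <- local_weighted_voting(tgt, list(list(mri = tgt, ct = ct),
                                        list(mri = tgt, ct = ct + 100)),
                              body)
  expect_equal(vol_data(s2)[body], ct[body] + 50, tolerance = 1e-10)
})

test_that("a matching atlas dominates a mismatched one at high gain", {
  cs <- small_case()
  other <- generate_phantom(small_spec(), 7)
  body <- cs$masks$body
  tgt <- vol_data(cs$mri$water)
  pairs <- list(list(mri = tgt, ct = vol_data(cs$ct)),
                list(mri = vol_data(other$mri$water) * 2 + 3,
                     ct = vol_data(cs$ct) + 500))
  s <- local_weighted_voting(tgt, pairs, body, lwv_params(gain = 200))
  expect_lt(max(abs(vol_data(s)[body] - vol_data(cs$ct)[body])), 1)
})

test_that("LWV is a convex combination with unit weight sums", {
  cs <- small_case()
  body <- cs$masks$body
  tgt <- vol_data(cs$mri$water)
  set.seed(13)
  pairs <- lapply(1:3, function(i)
    list(mri = tgt + array(rnorm(length(tgt), 0, 0.1), dim(tgt)),
         ct = vol_data(cs$ct) + array(rnorm(length(tgt), 0, 50), dim(tgt))))
  s <- local_weighted_voting(tgt, pairs, body, lwv_params(),
                             return_weights = TRUE)
  lo <- pmin(pairs[[1]]$ct, pairs[[2]]$ct, pairs[[3]]$ct)
  hi <- pmax(pairs[[1]]$ct, pairs[[2]]$ct, pairs[[3]]$ct)
  v <- vol_data(s)
  expect_true(all(v[body] >= lo[body] - 1e-9 & v[body] <= hi[body] + 1e-9))
  # stabilized weights: the best-matching atlas carries weight 1 per voxel,
  # so the normalizing sum is always in [1, n] and can never underflow
  w <- attr(s, "weights")
  expect_equal(max(abs(pmax(w[[1]], w[[2]], w[[3]]) - 1)), 0)
  wsum <- w[[1]] + w[[2]] + w[[3]]
  expect_true(all(wsum >= 1 & wsum <= 3))
  expect_equal(attr(s, "n_fallback"), 0L)
  # gain -> 0 recovers the unweighted mean
  s0 <- local_weighted_voting(tgt, pairs, body, lwv_params(gain = 1e-9))
  mn <- (pairs[[1]]$ct + pairs[[2]]$ct + pairs[[3]]$ct) / 3
  expect_equal(vol_data(s0)[body], mn[body], tolerance = 1e-6)
})

test_that("an atlas containing the target reproduces its CT", {
  cs <- small_case()
  ma <- multi_atlas_sct(cs, list(cs))
  body <- cs$masks$body
  err <- abs(vol_data(ma$sct)[body] - vol_data(cs$ct)[body])
  expect_lte(max(err), 2) # interpolation-level error only
  expect_equal(nrow(ma$report), 1)
  expect_true(all(c("rigid_dice", "body_dice", "bone_dice") %in%
                    names(ma$report)))
  expect_error(multi_atlas_sct(cs, list()), "empty")
})
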