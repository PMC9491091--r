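sch <- pk11195_frame_schedule()

test_that("cumulative integral is exact for frame-averaged data", {
  # constant activity c over total time T integrates to c*T
  const <- tac(rep(2, 22), sch)
  ci <- cumulative_integral(const)
  expect_equal(ci[22], 2 * 3600)
  expect_equal(cumulative_integral(tac(rep(1, 22), sch))[22], 3600)
  # matches a fine-grid trapezoid on the frame-averaged step function
  set.seed(4)
  v <- runif(22)
  x <- tac(v, sch)
  step_fun <- stats::stepfun(sch$start[-1], v)
  tgrid <- seq(0, 3600, by = 0.5)
  trap <- cumsum(c(0, (step_fun(head(tgrid, -1) + 0.25)) * diff(tgrid)))
  ends <- sch$start + sch$duration
  expect_equal(cumulative_integral(x), trap[match(ends, tgrid)],
               tolerance = 1e-12)
  # non-decreasing for non-negative TACs
  expect_true(all(diff(cumulative_integral(x)) >= 0))
})

test_that("self-reference Logan fit returns DVR exactly 1 for any positive TAC", {
  set.seed(11)
  for (i in 1:10) {
    v <- runif(22, 0.1, 5)
    x <- tac(v, sch)
    fit <- logan_fit(x, x, tstar = 30)
    expect_equal(fit$dvr, 1, tolerance = 1e-6)
    expect_equal(fit$intercept, 0, tolerance = 1e-6)
  }
})

test_that("Logan fit is scale invariant and matches the normal equations", {
  fine <- reference_tac_fine(sch)
  ref <- reference_tac(sch)
  ct <- srtm_tac(fine, srtm_params(R1 = 1, k2 = 0.4, BP = -0.144), sch)
  fit <- logan_fit(ct, ref, tstar = 30)
  expect_equal(fit$dvr, 0.856, tolerance = 0.856 * 0.01)

  # scaling both TACs leaves slope and r2 unchanged
  fit3 <- logan_fit(tac(3 * ct$values, sch), tac(3 * ref$values, sch))
  expect_equal(fit3$dvr, fit$dvr, tolerance = 1e-12)
  expect_equal(fit3$r2, fit$r2, tolerance = 1e-12)

  # OLS slope equals a brute-force normal-equations solution
  oracle <- normal_eq_fit(fit$x, fit$y)
  expect_equal(fit$dvr, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-10)

  expect_equal(unname(coef(fit)["dvr"]), fit$dvr)
})

test_that("Logan fit rejects unusable windows", {
  ref <- reference_tac(sch)
  expect_error(logan_fit(ref, ref, tstar = 70), "no frames at or beyond")
  expect_error(logan_fit(ref, ref, tstar = 52), "fewer than 3")
  bad <- ref$values; bad[20] <- 0
  expect_error(logan_fit(tac(bad, sch), ref), "non-positive")
  other <- frame_schedule(c(0, 30, 60), c(30, 30, 30))
  expect_error(logan_fit(tac(1:3, other), ref), "share one frame schedule")
})

test_that("voxelwise DVR maps recover label DVR and flag undefined voxels", {
  atlas <- make_toy_atlas(c(16, 16, 16))
  img <- simulate_subject(atlas, toy_label_dvr(0.559), sch, 0, seed = 1)
  m <- dvr_map(img, atlas)
  tab <- roi_means(m, atlas)
  expect_equal(tab$mean_dvr[tab$name == "choroid_plexus"], 0.559,
               tolerance = 0.01 * 0.559)
  # reference region averages to 1
  expect_equal(tab$mean_dvr[tab$name == "cerebellar_gray"], 1,
               tolerance = 1e-6)
  # outside the role masks the map is undefined
  expect_true(all(is.nan(m$data[atlas$labels == 0])))

  # all-zero image: every voxel undefined, with a message
  zero <- suppressMessages(dynamic_image(
    array(0, dim = c(16, 16, 16, 22)), sch, atlas$affine))
  expect_message(mz <- dvr_map(zero, atlas), "undefined")
  expect_true(all(is.nan(mz$data)))
  expect_equal(mz$n_defined, 0)
})

test_that("reference-region mean DVR stays at 1.00 under noise", {
  atlas <- make_toy_atlas(c(16, 16, 16))
  ref_means <- vapply(1:10, function(i) {
    img <- simulate_subject(atlas, toy_label_dvr(0.856), sch, 0.05, seed = i)
    tab <- roi_means(dvr_map(img, atlas), atlas)
    tab$mean_dvr[tab$name == "cerebellar_gray"]
  }, numeric(1))
  expect_true(all(abs(ref_means - 1) <= 0.02))
})

test_that("DVR maps roundtrip through NIfTI with provenance", {
  atlas <- make_toy_atlas(c(16, 16, 16))
  img <- simulate_subject(atlas, toy_label_dvr(0.7), sch, 0.05, seed = 2)
  m <- dvr_map(img, atlas, tstar = 30)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_dvr_map(m, path)
  back <- read_dvr_map(path)
  expect_equal(back$data, m$data, tolerance = 1e-5)
  expect_equal(back$tstar, 30)
  expect_equal(back$reference_label, m$reference_label)
})
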