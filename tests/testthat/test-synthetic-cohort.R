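sch <- pk11195_frame_schedule()

test_that("the toy atlas hosts five disjoint roles at any admissible grid", {
  for (n in c(16, 24, 32)) {
    atlas <- make_toy_atlas(c(n, n, n))
    counts <- tabulate(atlas$labels, nbins = 5)
    expect_true(all(counts >= 30))   # labels are disjoint by construction
    expect_length(atlas$roles, 5)
  }
  # deterministic
  expect_identical(make_toy_atlas(c(20, 20, 20))$labels,
                   make_toy_atlas(c(20, 20, 20))$labels)
  expect_error(make_toy_atlas(c(8, 8, 8)), "at least 16")
  # choroid plexus large enough for stable ROI means at full scale
  expect_gte(sum(make_toy_atlas(c(32, 32, 32))$labels == 5L), 200)
})

test_that("frame-averaged reference curve matches adaptive quadrature", {
  A <- 1; tau <- 15
  ref <- reference_tac(sch, A = A, tau = tau)
  oracle <- quadrature_frame_means(function(t) A * t * exp(-t / tau), sch)
  expect_equal(ref$values, oracle, tolerance = 1e-8)
  # peak frame sits near t = tau
  expect_lt(abs(sch$mid[which.max(ref$values)] / 60 - tau), 3)
  # linearity in A
  expect_equal(reference_tac(sch, A = 2, tau = tau)$values, 2 * ref$values)
  # near-linear regime for very slow washout
  slow <- reference_tac(sch, A = 1, tau = 1e5)
  expect_equal(slow$values, sch$mid / 60, tolerance = 1e-3)
  expect_error(reference_tac(sch, A = -1), "positive")
})

test_that("SRTM collapses to the reference at BP = 0, R1 = 1", {
  fine <- reference_tac_fine(sch)
  ref <- reference_tac(sch)
  ct <- srtm_tac(fine, srtm_params(R1 = 1, k2 = 0.4, BP = 0), sch)
  expect_equal(ct$values, ref$values, tolerance = 1e-3)
  # negative binding pulls the late curve below the reference
  lo <- srtm_tac(fine, srtm_params(R1 = 1, k2 = 0.4, BP = -0.5), sch)
  expect_true(all(lo$values[15:22] < ref$values[15:22]))
  expect_error(srtm_params(BP = -1), "BP")
})

test_that("noiseless SRTM forward + Logan inverse recovers DVR within 1%", {
  fine <- reference_tac_fine(sch)
  ref <- reference_tac(sch)
  for (bp in c(-0.5, -0.399, -0.144, 0.25, 0.5, 1.0)) {
    ct <- srtm_tac(fine, srtm_params(R1 = 1, k2 = 0.4, BP = bp), sch)
    fit <- logan_fit(ct, ref, tstar = 30)
    expect_lt(abs(fit$dvr - (1 + bp)) / (1 + bp), 0.01)
  }
})

test_that("subject simulation is seed-deterministic and recovers label DVR", {
  atlas <- make_toy_atlas(c(16, 16, 16))
  a <- simulate_subject(atlas, toy_label_dvr(0.856), sch, 0.05, seed = 7)
  b <- simulate_subject(atlas, toy_label_dvr(0.856), sch, 0.05, seed = 7)
  expect_identical(a$data, b$data)
  c2 <- simulate_subject(atlas, toy_label_dvr(0.856), sch, 0.05, seed = 8)
  expect_false(identical(a$data, c2$data))

  # noiseless: voxelwise Logan DVR equals the assigned label DVR within 1%
  img0 <- simulate_subject(atlas, toy_label_dvr(0.6), sch, 0, seed = 1)
  tab <- roi_means(dvr_map(img0, atlas), atlas)
  expect_equal(tab$mean_dvr[tab$name == "choroid_plexus"], 0.6,
               tolerance = 0.01)
  expect_equal(tab$mean_dvr[tab$name != "choroid_plexus"], rep(1, 4),
               tolerance = 0.01)

  expect_error(simulate_subject(atlas, c(cerebellar_gray = 1), sch),
               "missing label")
})

test_that("ROI-mean DVR stays within 0.02 of truth under acquisition noise", {
  atlas <- make_toy_atlas(c(32, 32, 32))
  est <- vapply(1:20, function(i) {
    img <- simulate_subject(atlas, toy_label_dvr(0.856), sch, 0.05, seed = i)
    tab <- roi_means(dvr_map(img, atlas), atlas)
    tab$mean_dvr[tab$name == "choroid_plexus"]
  }, numeric(1))
  expect_true(all(abs(est - 0.856) <= 0.02))
})

test_that("cohort simulation honours the design and the master seed", {
  atlas <- make_toy_atlas(c(16, 16, 16))
  design <- cohort_design(seed = 3)
  sim <- simulate_cohort(design, atlas, sch)
  expect_equal(nrow(sim$cohort), 19)
  expect_equal(as.vector(table(factor(sim$cohort$group, COHORT_GROUPS))),
               c(7, 4, 4, 4))
  expect_length(sim$images, 19)
  expect_true(all(ASSESSMENTS %in% names(sim$cohort)))

  sim2 <- simulate_cohort(design, atlas, sch)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$images[[1]]$data, sim2$images[[1]]$data)

  # streaming handler sees every subject and suppresses accumulation
  seen <- character()
  out <- simulate_cohort(design, atlas, sch,
                         image_handler = function(id, img)
                           seen <<- c(seen, id))
  expect_null(out$images)
  expect_equal(seen, sim$cohort$subject_id)

  # an empty group is a valid design; the cohort simply lacks that level
  d0 <- cohort_design(n_per_group = c(CH = 4, DELIRIUM = 4, DEMENTIA = 0,
                                      DSD = 0), seed = 1)
  s0 <- simulate_cohort(d0, atlas, sch)
  expect_equal(nrow(s0$cohort), 8)
  expect_false("DSD" %in% s0$cohort$group)
})
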