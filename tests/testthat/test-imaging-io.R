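test_that("dynamic images roundtrip through NIfTI with affine and timing", {
  sch <- pk11195_frame_schedule()
  set.seed(1)
  arr <- array(runif(8^3 * 22), dim = c(8, 8, 8, 22))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-8, -8, -8)
  img <- dynamic_image(arr, sch, aff)
  ipath <- withr::local_tempfile(fileext = ".nii.gz")
  tpath <- withr::local_tempfile(fileext = ".json")
  write_dynamic_image(img, ipath, tpath)
  back <- read_dynamic_image(ipath, tpath)
  expect_equal(back$data, img$data, tolerance = 1e-6)  # float32 storage
  expect_equal(back$affine, img$affine, tolerance = 1e-5)
  expect_equal(back$schedule$start, sch$start)
})

test_that("dynamic image validation clips negatives and checks shape", {
  sch <- frame_schedule(c(0, 30, 60), c(30, 30, 30))
  arr <- array(1, dim = c(4, 4, 4, 3))
  arr[1, 1, 1, 1] <- -5
  expect_message(img <- dynamic_image(arr, sch), "clipped 1 negative")
  expect_equal(img$data[1, 1, 1, 1], 0)
  expect_error(dynamic_image(array(1, dim = c(4, 4, 4)), sch), "4D")
  expect_error(dynamic_image(array(1, dim = c(4, 4, 4, 5)), sch),
               "frame-count mismatch")
  expect_error(dynamic_image(array(1, dim = c(4, 4, 4, 3)), sch,
                             affine = matrix(0, 4, 4)), "invertible")

  # a 3D file on disk is rejected on read
  p3 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(4, 4, 4))), p3)
  tpath <- withr::local_tempfile(fileext = ".json")
  write_frame_schedule(sch, tpath)
  expect_error(read_dynamic_image(p3, tpath), "4D")
})

test_that("label atlases roundtrip losslessly and resolve all roles", {
  atlas <- make_toy_atlas(c(16, 16, 16))
  lpath <- withr::local_tempfile(fileext = ".nii.gz")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_label_atlas(atlas, lpath, dpath)
  back <- read_label_atlas(lpath, dpath)
  expect_identical(back$labels, atlas$labels)  # bitwise for integer labels
  expect_equal(back$roles, atlas$roles)
  for (r in ATLAS_ROLES) expect_true(any(role_mask(back, r)))
})

test_that("atlas validation flags missing roles and unknown labels", {
  lab <- array(0L, dim = c(6, 6, 6))
  lab[1:2, 1:2, 1:2] <- 1L; lab[3:4, 1:2, 1:2] <- 2L
  lab[1:2, 3:4, 1:2] <- 3L; lab[3:4, 3:4, 1:2] <- 4L
  lab[5, 5, 1:2] <- 5L
  dict <- toy_dictionary()
  expect_silent(label_atlas(lab, dict))
  # dictionary without a reference region
  expect_error(label_atlas(lab, dict[dict$role != "reference_region", ]),
               "reference_region")
  # a volume label missing from the dictionary warns and is ignored later
  lab7 <- lab; lab7[6, 6, 6] <- 7L
  expect_warning(a7 <- label_atlas(lab7, dict), "not in dictionary")
  expect_false(7 %in% roi_means(
    structure(list(data = array(1, dim = dim(lab7)), affine = diag(4)),
              class = "dvr_map"), a7)$label)
  # non-integer volumes are rejected
  expect_error(label_atlas(lab + 0.5, dict), "integer")
})

test_that("cohort QC bookkeeping matches the recruitment structure", {
  df <- make_qc_manifest()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(df, path)
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort), 28)
  expect_equal(sum(cohort$movement_artifact), 3)
  expect_equal(sum(cohort$technical_issue), 6)
  expect_equal(sum(qc_pass(cohort)), 19)
  kept <- cohort[qc_pass(cohort), ]
  expect_equal(as.vector(table(factor(kept$group, COHORT_GROUPS))),
               c(7, 4, 4, 4))
})

test_that("cohort validation rejects duplicates, bad groups, empty files", {
  df <- make_qc_manifest()
  df$subject_id[2] <- df$subject_id[1]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(df, path)
  expect_error(read_cohort(path), "sub-01")

  df2 <- make_qc_manifest()
  df2$group[5] <- "CONTROLS"
  write_cohort(df2, path)
  expect_error(read_cohort(path), "CONTROLS")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("subject_id", "group", ASSESSMENTS,
                     "movement_artifact", "technical_issue"),
                   collapse = "\t"), empty)
  expect_error(read_cohort(empty), "empty")
})
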