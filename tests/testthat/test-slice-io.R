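test_that("middle slice uses the floor rule on even and odd depths", {
  for (depth in c(10, 11)) {
    v <- array(0, c(4, 5, depth))
    for (k in seq_len(depth)) v[, , k] <- k - 1  # plane k holds value k-1
    s <- extract_middle_axial_slice(v)
    expect_equal(dim(s), c(4, 5))
    expect_true(all(s == depth %/% 2))  # 0-based floor(D/2)
  }
})

test_that("the axial axis is configurable and shape follows the non-axial dims", {
  v <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  expect_equal(dim(extract_middle_axial_slice(v, 1)), c(4, 5))
  expect_equal(dim(extract_middle_axial_slice(v, 2)), c(3, 5))
  expect_equal(extract_middle_axial_slice(v, 1), v[2, , ])
  expect_error(extract_middle_axial_slice(array(0, c(2, 2)), 1), "3 axes")
  expect_error(extract_middle_axial_slice(v, 5), "axial_axis")
})

test_that("4D volumes are sliced from the first time frame", {
  v <- array(0, c(4, 4, 6, 3))
  v[, , , 1] <- 1
  v[, , , 2] <- 2
  s <- extract_middle_axial_slice(v)
  expect_true(all(s == 1))
})

test_that("intensity normalization maps to [0,1] and is idempotent", {
  img <- matrix(c(0, 5, 10, 10), 2, 2, byrow = TRUE)
  expect_equal(normalize_intensity(img),
               matrix(c(0, 0.5, 1, 1), 2, 2, byrow = TRUE))
  expect_equal(normalize_intensity(matrix(7, 3, 3)), matrix(0, 3, 3))
  set.seed(1)
  r <- matrix(runif(30), 5, 6)
  n1 <- normalize_intensity(r)
  expect_equal(normalize_intensity(n1), n1)
  expect_error(normalize_intensity(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("manifest round-trips losslessly and rejects malformed input", {
  rec <- make_records(c(a = 3, b = 2))
  rec$split[1] <- "test"
  mf <- manifest(rec, c("a", "b"), 10, 12)
  path <- tempfile(fileext = ".csv")
  write_manifest(mf, path)
  mf2 <- read_manifest(path)
  expect_equal(mf2$class_names, mf$class_names)
  expect_equal(mf2$records, mf$records)
  expect_equal(c(mf2$image_height, mf2$image_width), c(10, 12))
  # byte stability of a rewrite
  path2 <- tempfile(fileext = ".csv")
  write_manifest(mf2, path2)
  expect_identical(readLines(path), readLines(path2))
  unlink(c(path, path2))

  rec_dup <- rbind(rec, rec[1, ])
  expect_error(manifest(rec_dup, c("a", "b")), "duplicate")
  expect_error(manifest(rec, c("a")), "unknown class_name")
  rec_bad <- rec
  rec_bad$provenance[2] <- "augmented"  # dangling source reference
  rec_bad$source_id[2] <- "nope"
  expect_error(manifest(rec_bad, c("a", "b")), "existing original")
})

test_that("a 155-record phantom manifest matches the study composition", {
  dir <- tempfile()
  mf <- make_phantom_manifest(dir, per_class = c(65, 57, 33),
                              noise_sd = 0)
  expect_equal(nrow(mf$records), 155)
  expect_true(all(mf$records$split == "unassigned"))
  expect_equal(unname(table(mf$records$class_name)[mf$class_names]),
               c(65, 57, 33), ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("NIfTI write/read/slice round trip preserves the designed plane", {
  vol <- phantom_volume(class_morphology(), depth = 11)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  slice <- extract_middle_axial_slice(as.array(RNifti::readNifti(path)))
  expect_equal(slice, phantom_image(class_morphology()),
               tolerance = 1e-5, ignore_attr = TRUE)
  unlink(path)
})

test_that("PNG slice export quantizes to 8-bit but preserves structure", {
  img <- phantom_image(class_morphology())
  path <- tempfile(fileext = ".png")
  write_slice_png(img, path)
  back <- read_slice_png(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
  unlink(path)
})
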