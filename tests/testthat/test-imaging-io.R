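test_that("image write/read round-trips preserve 8-bit pixel values", {
  tmp <- withr::local_tempdir()
  checker <- matrix(rep(c(0, 255), 8), 4, 4)
  p <- file.path(tmp, "checker.png")
  write_image(checker, p)
  expect_identical(read_image(p), checker)

  # known pixel values, cross-decoded with a second decoder (EBImage)
  px <- matrix(c(0, 128, 255, 64), 2, 2, byrow = TRUE)
  p2 <- file.path(tmp, "px.png")
  write_image(px, p2)
  expect_identical(read_image(p2), px)
  via_ebimage <- t(as.matrix(EBImage::readImage(p2))) * 255
  expect_equal(unname(read_image(p2)), unname(via_ebimage),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("unsupported and missing files raise informative errors", {
  tmp <- withr::local_tempdir()
  txt <- file.path(tmp, "notes.txt")
  writeLines("not an image", txt)
  expect_error(read_image(txt), "unsupported")
  expect_error(read_image(file.path(tmp, "absent.png")), "does not exist")
})

test_that("PNM (PGM/PPM) reader handles ASCII and binary variants", {
  tmp <- withr::local_tempdir()
  # ASCII PGM, 3x2, with a comment line
  p <- file.path(tmp, "a.pgm")
  writeLines(c("P2", "# comment", "3 2", "255", "0 10 20", "30 40 50"), p)
  expect_equal(read_image(p), matrix(c(0, 10, 20, 30, 40, 50), 2, 3, byrow = TRUE))
  # binary PGM
  pb <- file.path(tmp, "b.pgm")
  con <- file(pb, "wb")
  writeChar("P5\n3 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(0, 10, 20, 30, 40, 50)), con)
  close(con)
  expect_equal(read_image(pb), matrix(c(0, 10, 20, 30, 40, 50), 2, 3, byrow = TRUE))
  # binary PPM: green channel must land in channel 2
  pc <- file.path(tmp, "c.ppm")
  con <- file(pc, "wb")
  writeChar("P6\n2 1\n255\n", con, eos = NULL)
  writeBin(as.raw(c(10, 200, 30, 1, 2, 3)), con)
  close(con)
  img <- read_image(pc)
  expect_equal(dim(img), c(1, 2, 3))
  expect_equal(img[1, 1, ], c(10, 200, 30))
})

test_that("mask binarization thresholds at luminance >= 128 and auto-detects 0/1", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "m.pgm")
  writeLines(c("P2", "2 1", "255", "127 128"), p)
  expect_equal(read_mask(p), matrix(c(0, 1), 1, 2))
  # constant zero image
  p0 <- file.path(tmp, "z.png")
  write_image(matrix(0, 3, 3), p0)
  expect_equal(read_mask(p0), matrix(0, 3, 3))
  # already-binary dialect (max <= 1)
  p1 <- file.path(tmp, "bin.pgm")
  writeLines(c("P2", "2 1", "1", "0 1"), p1)
  expect_equal(read_mask(p1), matrix(c(0, 1), 1, 2))
})

test_that("mask write/read is the identity and stores 1 as 255", {
  tmp <- withr::local_tempdir()
  set.seed(4)
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  p <- file.path(tmp, "m.png")
  write_mask(m, p)
  expect_identical(read_mask(p), m * 1)
  expect_true(all(read_image(p) %in% c(0, 255)))
  expect_error(write_mask(matrix(numeric(0), 0, 0), file.path(tmp, "e.png")))
  expect_error(write_mask(matrix(0.5, 2, 2), file.path(tmp, "e.png")), "binary")
})

test_that("probability maps round-trip at 16-bit precision", {
  tmp <- withr::local_tempdir()
  set.seed(9)
  V <- matrix(runif(256), 16, 16)
  p <- file.path(tmp, "v.tif")
  write_probability_map(V, p)
  expect_equal(read_probability_map(p), V, tolerance = 1 / 65535)
})

test_that("flat-layout manifests resolve deterministically with a split file", {
  ds <- make_flat_dataset(n = 3, n_train = 2)
  cfg <- list(name = "toy", layout = "flat", root = ds$dir, split_file = "train.txt")
  man <- load_manifest(cfg)
  expect_s3_class(man, "vs_manifest")
  expect_equal(man$n_train, 2L)
  expect_equal(man$n_test, 1L)
  expect_equal(length(man$samples), 3L)
  man2 <- load_manifest(cfg)
  expect_identical(vapply(man$samples, `[[`, "", "id"),
                   vapply(man2$samples, `[[`, "", "id"))
  # reloaded masks match the generated ones
  s1 <- load_sample(man$samples[[1]])
  expect_identical(s1$gt_mask, ds$samples[[1]]$gt_mask)
  expect_identical(s1$fov_mask, ds$samples[[1]]$fov_mask)
})

test_that("manifest loading rejects empty roots and warns on missing GT", {
  tmp <- withr::local_tempdir()
  dir.create(file.path(tmp, "images"))
  expect_error(load_manifest(list(layout = "flat", root = tmp)), "no images")
  # an image without a matching mask file
  write_image(matrix(runif(64), 8, 8), file.path(tmp, "images", "img1.png"))
  expect_warning(man <- load_manifest(list(layout = "flat", root = tmp)),
                 "no ground truth")
  expect_null(man$samples[[1]]$gt_path)
  # stare layout demands an explicit split
  expect_error(load_manifest(list(layout = "stare", root = tmp)), "split_file")
})

test_that("drive-style layouts map training/test subtrees to splits", {
  tmp <- withr::local_tempdir()
  for (sub in c("training", "test")) {
    for (d in c("images", "1st_manual", "mask")) {
      dir.create(file.path(tmp, sub, d), recursive = TRUE)
    }
  }
  s <- make_phantom(seed = 3, height = 32, width = 32)
  write_image(s$image, file.path(tmp, "training", "images", "21_training.png"))
  write_mask(s$gt_mask, file.path(tmp, "training", "1st_manual", "21_manual1.png"))
  write_mask(s$fov_mask, file.path(tmp, "training", "mask", "21_training_mask.png"))
  write_image(s$image, file.path(tmp, "test", "images", "01_test.png"))
  write_mask(s$gt_mask, file.path(tmp, "test", "1st_manual", "01_manual1.png"))
  write_mask(s$fov_mask, file.path(tmp, "test", "mask", "01_test_mask.png"))
  man <- load_manifest(list(name = "drive", layout = "drive", root = tmp))
  expect_equal(man$n_train, 1L)
  expect_equal(man$n_test, 1L)
  splits <- vapply(man$samples, `[[`, "", "split")
  expect_setequal(splits, c("train", "test"))
  expect_false(any(vapply(man$samples, function(x) is.null(x$gt_path), TRUE)))
})
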