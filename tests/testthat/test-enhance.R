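test_that("z-score normalization matches the direct population oracle", {
  img <- matrix(c(0, 4, 2, 6), 2, 2)  # column-major: [[0,2],[4,6]]
  n <- normalize_image(img)
  mu <- sum(img) / 4
  sigma <- sqrt(sum((img - mu)^2) / 4)
  expect_equal(n$mu, 3)
  expect_equal(n$sigma, sqrt(5))
  expect_equal(n$values, (img - mu) / sigma, tolerance = 1e-12)
  expect_equal(n$values[1, 1], -1.34164, tolerance = 1e-5)
  expect_equal(n$values[2, 2], 1.34164, tolerance = 1e-5)
  # fixed point: renormalizing changes nothing
  n2 <- normalize_image(n$values)
  expect_equal(n2$values, n$values, tolerance = 1e-6)
  expect_error(normalize_image(matrix(5, 3, 3)), "constant")
})

test_that("normalization restricted to a domain zeroes the outside", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  dom <- matrix(0, 8, 8); dom[3:6, 3:6] <- 1
  n <- normalize_image(img, dom)
  expect_equal(mean(n$values[dom == 1]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(n$values[dom == 1]^2)), 1, tolerance = 1e-9)
  expect_true(all(n$values[dom == 0] == 0))
})

test_that("vessel-channel extraction picks green and rescales to [0,1]", {
  rgb <- array(0, dim = c(1, 1, 3))
  rgb[1, 1, ] <- c(10, 200, 30)
  expect_equal(extract_vessel_channel(rgb)[1, 1], 200 / 255, tolerance = 1e-9)
  g <- matrix(c(0, 255, 128, 64), 2, 2)
  expect_equal(extract_vessel_channel(g), g / 255)
  expect_error(extract_vessel_channel(array(0, dim = c(2, 2, 4))), "3 channels")
})

test_that("the matched-filter bank has the documented structure", {
  bank <- build_filter_bank(widths = 1.5, orientations = seq(0, 165, 15), length = 9)
  expect_length(bank$kernels, 12L)
  full <- build_filter_bank()
  expect_length(full$kernels, 36L)
  sums <- vapply(full$kernels, sum, numeric(1))
  expect_true(all(abs(sums) < 1e-9))
  # 90-degree kernel is the transpose of the 0-degree kernel
  k0 <- full$kernels[[which(full$orientations == 0 & full$widths == 1.5)[1]]]
  k90 <- full$kernels[[which(full$orientations == 90 & full$widths == 1.5)[1]]]
  expect_equal(k90, t(k0), tolerance = 1e-6)
  expect_error(build_filter_bank(length = 8), "odd")
  expect_error(build_filter_bank(widths = -1), "positive")
})

test_that("matched filtering reduces to identity/zero in the degenerate cases", {
  set.seed(3)
  img <- matrix(rnorm(15 * 15), 15, 15)
  ident <- structure(list(kernels = list(matrix(1, 1, 1)), widths = 1,
                          orientations = 0, length = 1L),
                     class = "vs_filter_bank")
  r <- matched_filter_response(img, ident)
  expect_equal(r$values, img, tolerance = 1e-9)
  # zero-mean kernels give zero response on a constant region
  flat <- matrix(1, 21, 21)
  rb <- matched_filter_response(flat, build_filter_bank())
  expect_lt(max(abs(rb$values[9:13, 9:13])), 1e-9)
  expect_error(matched_filter_response(img,
    structure(list(kernels = list(), length = 1L), class = "vs_filter_bank")),
    "empty")
})

test_that("a vertical dark bar is claimed by the vertically aligned kernel", {
  img <- matrix(1, 15, 15)
  img[, 7:9] <- 0  # dark vertical bar (constant along rows)
  n <- normalize_image(img)
  bank <- build_filter_bank()
  r <- matched_filter_response(n, bank)
  centre <- r$argmax_index[4:12, 8]
  expect_true(all(bank$orientations[centre] == 90))
})

test_that("Hessian vesselness is zero on constants and peaks on the centerline", {
  expect_equal(line_detection_response(matrix(3, 20, 20), 1)$values,
               matrix(0, 20, 20))
  # ideal dark bar of width 3
  img <- matrix(1, 40, 40)
  img[, 19:21] <- 0
  r <- line_detection_response(normalize_image(img), c(1, 1.5, 2))
  on_line <- mean(r$values[10:30, 20])
  off_line <- mean(r$values[10:30, 29])  # 3 widths away
  expect_gt(on_line, off_line)
  expect_error(line_detection_response(img, numeric(0)), "at least one")
  expect_error(line_detection_response(img, -1), "positive")
})

test_that("vesselness commutes with 90-degree rotation away from borders", {
  s <- make_phantom(seed = 21, height = 48, width = 48, noise_sigma = 0)
  img <- s$image
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  r1 <- rot90(line_detection_response(img, c(1, 2))$values)
  r2 <- line_detection_response(rot90(img), c(1, 2))$values
  inner <- 10:38
  expect_lt(max(abs(r1[inner, inner] - r2[inner, inner])), 1e-4)
})

test_that("scale space is identity at sigma 0 and contracts extremes", {
  set.seed(8)
  img <- matrix(rnorm(32 * 32), 32, 32)
  ss <- scale_space(img, c(0, 1, 2, 3))
  expect_identical(ss$images[[1]], img)
  maxima <- vapply(ss$images, max, numeric(1))
  minima <- vapply(ss$images, min, numeric(1))
  expect_true(all(diff(maxima) <= 1e-12))
  expect_true(all(diff(minima) >= -1e-12))
  expect_error(scale_space(img, c(-1, 2)), "non-negative")
  expect_error(scale_space(img, c(2, 1)), "ascending")
})

test_that("feature stacks assemble, rescale over FOV, and honour channel choice", {
  s <- make_phantom(seed = 13, height = 48, width = 48)
  norm <- normalize_image(extract_vessel_channel(s$image), s$fov_mask)
  mf <- matched_filter_response(norm, build_filter_bank(length = 7))
  ld <- line_detection_response(norm, c(1, 2))
  ss <- scale_space(norm, c(0, 1, 2))
  fs <- build_feature_stack(norm, mf, ld, ss, s$fov_mask)
  expect_equal(dim(fs$channels)[3], 6L)
  expect_length(fs$channel_names, 6L)
  idx <- s$fov_mask == 1
  for (c in seq_len(6)) {
    ch <- fs$channels[, , c]
    expect_equal(min(ch[idx]), 0, tolerance = 1e-12)
    expect_equal(max(ch[idx]), 1, tolerance = 1e-12)
    expect_true(all(ch[!idx] == 0))
  }
  # single-channel configuration equals the rescaled normalized image
  f1 <- build_feature_stack(norm, fov = s$fov_mask, channels = "norm")
  expect_equal(dim(f1$channels)[3], 1L)
  v <- norm$values
  sc <- (v - min(v[idx])) / (max(v[idx]) - min(v[idx]))
  sc[!idx] <- 0
  expect_equal(f1$channels[, , 1], sc, tolerance = 1e-12)
  expect_error(build_feature_stack(norm, fov = s$fov_mask[1:10, 1:10]), "FOV")
  expect_error(build_feature_stack(norm, fov = s$fov_mask, channels = "matched_filter"),
               "NULL")
})

test_that("noise weakens matched-filter contrast between vessel and background", {
  contrast_at <- function(noise) {
    s <- make_phantom(seed = 17, noise_sigma = noise)
    n <- normalize_image(extract_vessel_channel(s$image), s$fov_mask)
    r <- matched_filter_response(n, build_filter_bank())
    mean(r$values[s$gt_mask == 1]) -
      mean(r$values[s$fov_mask == 1 & s$gt_mask == 0])
  }
  cs <- vapply(c(0, 0.05, 0.15), contrast_at, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("Otsu-thresholded responses reject constant inputs", {
  expect_error(otsu_response_mask(matrix(1, 8, 8), matrix(1, 8, 8)), "constant")
})
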