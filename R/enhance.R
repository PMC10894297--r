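#' Z-score normalization of an intensity image
#'
#' Computes `(I - mu) / sigma` with `mu` and `sigma` the population mean and
#' standard deviation over the computation domain (all pixels by default, or
#' a binary mask such as the field of view). Pixels outside the domain are
#' set to 0.
#'
#' @param image `H x W` numeric matrix.
#' @param domain Optional binary `H x W` mask restricting the statistics.
#' @return A `vs_norm` list: `values` (zero mean, unit variance over the
#'   domain), `mu`, `sigma`, `domain`.
#' @export
normalize_image <- function(image, domain = NULL) {
  if (length(image) == 0L) stop_vs("cannot normalize an empty image")
  if (is.null(domain)) domain <- matrix(1, nrow(image), ncol(image))
  if (!identical(dim(domain), dim(image))) stop_vs("domain shape mismatch")
  idx <- domain != 0
  if (sum(idx) < 2L) stop_vs("normalization domain needs at least 2 pixels")
  mu <- mean(image[idx])
  sigma <- pop_sd(image[idx])
  if (sigma == 0) {
    stop_vs("degenerate input: image is constant over the domain (sigma = 0)")
  }
  values <- (image - mu) / sigma
  values[!idx] <- 0
  structure(list(values = values, mu = mu, sigma = sigma, domain = domain * 1),
            class = "vs_norm")
}

#' Extract the vessel-bearing channel
#'
#' Color fundus photographs carry the strongest vessel contrast in the green
#' channel; grayscale inputs are used as-is. Output is scaled to `[0, 1]`
#' (inputs on the 0--255 scale are divided by 255) with polarity unchanged:
#' vessels stay dark.
#'
#' @param image `H x W` or `H x W x 3` numeric grid.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
extract_vessel_channel <- function(image) {
  nd <- length(dim(image))
  if (nd == 3L) {
    if (dim(image)[3L] > 3L) stop_vs("expected at most 3 channels, got %d", dim(image)[3L])
    image <- matrix(image[, , min(2L, dim(image)[3L])],
                    dim(image)[1L], dim(image)[2L])
  } else if (nd != 2L) {
    stop_vs("expected a 2-D or 3-D image grid")
  }
  if (max(image) > 1) image <- image / 255
  image
}

#' Build a matched-filter bank for dark vessel profiles
#'
#' Each kernel models a short straight vessel segment: a negative Gaussian
#' cross-section `-exp(-x^2 / (2 sigma_w^2))` across the vessel, constant
#' along it for `|y| <= length/2`, evaluated analytically in coordinates
#' rotated by each orientation on an odd square support, then mean-subtracted
#' so every kernel sums to zero (zero response on constant regions).
#'
#' @param widths Gaussian profile sigmas in pixels (one per vessel width).
#' @param orientations Kernel orientations in degrees (angle of the vessel
#'   axis; 0 = horizontal line, 90 = vertical line).
#' @param length Kernel support length in pixels (odd).
#' @return A `vs_filter_bank`: `kernels` (list of matrices), per-kernel
#'   `widths` and `orientations`, and `length`.
#' @export
build_filter_bank <- function(widths = c(1, 1.5, 2),
                              orientations = seq(0, 165, by = 15),
                              length = 9L) {
  if (any(widths <= 0)) stop_vs("widths must be positive")
  length <- as.integer(length)
  if (length %% 2L == 0L) stop_vs("kernel length must be odd")
  half <- (length - 1L) / 2
  u <- matrix(-half:half, length, length)            # row offset
  v <- matrix(-half:half, length, length, byrow = TRUE)  # col offset
  kernels <- list(); kw <- numeric(0); ko <- numeric(0)
  for (sw in widths) {
    for (th in orientations) {
      a <- th * pi / 180
      # vessel axis at angle th: y runs along the line, x across it
      y <- v * cos(a) + u * sin(a)
      x <- -v * sin(a) + u * cos(a)
      k <- ifelse(abs(y) <= length / 2, -exp(-x^2 / (2 * sw^2)), 0)
      k <- k - mean(k)
      kernels[[base::length(kernels) + 1L]] <- k
      kw <- c(kw, sw); ko <- c(ko, th)
    }
  }
  structure(list(kernels = kernels, widths = kw, orientations = ko,
                 length = length),
            class = "vs_filter_bank")
}

#' Maximum matched-filter response
#'
#' Cross-correlates the normalized image with every kernel of the bank
#' (reflective boundaries) and records, per pixel, the maximum response and
#' the index of the first kernel attaining it.
#'
#' @param norm A `vs_norm` from [normalize_image()] (or a plain matrix).
#' @param bank A `vs_filter_bank` from [build_filter_bank()].
#' @return A `vs_response`: `values` (`H x W` max response), `kind =
#'   "matched_filter"`, `argmax_index`, plus the `bank`.
#' @export
matched_filter_response <- function(norm, bank) {
  img <- if (inherits(norm, "vs_norm")) norm$values else norm
  if (length(bank$kernels) == 0L) stop_vs("empty filter bank")
  if (bank$length >= min(dim(img))) stop_vs("kernel support exceeds image size")
  best <- matrix(-Inf, nrow(img), ncol(img))
  argk <- matrix(0L, nrow(img), ncol(img))
  for (k in seq_along(bank$kernels)) {
    r <- xcorr2_reflect(img, bank$kernels[[k]])
    upd <- r > best
    best[upd] <- r[upd]
    argk[upd] <- k
  }
  structure(list(values = best, kind = "matched_filter", argmax_index = argk,
                 bank = bank),
            class = "vs_response")
}

#' Hessian-eigenvalue multi-scale line detection (vesselness)
#'
#' For each scale `s`, the image is polarity-inverted (dark vessels become
#' bright ridges), Gaussian-smoothed at `s`, and its scale-normalized Hessian
#' eigenvalues `|lambda1| <= |lambda2|` computed per pixel. Bright tubular
#' structures have strongly negative `lambda2`; the vesselness score there is
#' `exp(-(lambda1/lambda2)^2 / (2 beta^2)) * (1 - exp(-(lambda1^2 +
#' lambda2^2) / (2 c^2)))`, zero where `lambda2 >= 0`. `c` is half the
#' maximum Frobenius norm of the Hessian over the image at that scale. The
#' returned map is the per-pixel maximum over scales.
#'
#' @param norm A `vs_norm` or plain matrix (dark-vessel polarity).
#' @param scales Gaussian scales in pixels (all > 0).
#' @param beta Blobness sensitivity (default 0.5).
#' @return A `vs_response` with `kind = "line_detection"`, `values`,
#'   `argmax_index` (winning scale index), and `per_scale` (list of `L(,,s)`).
#' @export
line_detection_response <- function(norm, scales = c(1, 1.5, 2), beta = 0.5) {
  img <- if (inherits(norm, "vs_norm")) norm$values else norm
  if (length(scales) == 0L) stop_vs("at least one scale is required")
  if (any(scales <= 0)) stop_vs("scales must be positive")
  inv <- -img  # vessels bright after inversion
  best <- matrix(0, nrow(img), ncol(img))
  args <- matrix(0L, nrow(img), ncol(img))
  per_scale <- vector("list", length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    sm <- gaussian_blur(inv, s)
    d <- hessian_central(sm)
    # scale normalization (gamma = 2)
    hxx <- s^2 * d$xx; hyy <- s^2 * d$yy; hxy <- s^2 * d$xy
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    e1 <- (tr + disc) / 2; e2 <- (tr - disc) / 2
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)  # |l1| <= |l2|
    l2 <- ifelse(swap, e1, e2)
    s2 <- hxx^2 + 2 * hxy^2 + hyy^2  # squared Frobenius norm
    cmax <- sqrt(max(s2))
    v <- matrix(0, nrow(img), ncol(img))
    ok <- l2 < 0
    if (any(ok) && cmax > 0) {
      cc <- cmax / 2
      rb2 <- (l1[ok] / l2[ok])^2
      v[ok] <- exp(-rb2 / (2 * beta^2)) *
        (1 - exp(-(l1[ok]^2 + l2[ok]^2) / (2 * cc^2)))
    }
    per_scale[[si]] <- v
    upd <- v > best
    best[upd] <- v[upd]
    args[upd] <- si
  }
  structure(list(values = best, kind = "line_detection", argmax_index = args,
                 scales = scales, per_scale = per_scale),
            class = "vs_response")
}

# Central-difference Hessian with reflective boundaries.
# xx: second derivative along rows (i); yy: along columns (j).
hessian_central <- function(img) {
  p <- pad_reflect(img, 1L, 1L)
  nr <- nrow(img); nc <- ncol(img)
  ctr <- function(dr, dc) p[(2L + dr):(1L + dr + nr), (2L + dc):(1L + dc + nc), drop = FALSE]
  xx <- ctr(1L, 0L) - 2 * img + ctr(-1L, 0L)
  yy <- ctr(0L, 1L) - 2 * img + ctr(0L, -1L)
  xy <- (ctr(1L, 1L) - ctr(1L, -1L) - ctr(-1L, 1L) + ctr(-1L, -1L)) / 4
  list(xx = xx, yy = yy, xy = xy)
}

#' Otsu-thresholded binary mask from an enhancement response
#'
#' Classical front-end baseline: min--max rescales a response map over the
#' FOV and binarizes it at its Otsu level. Useful to verify that the
#' enhancement stages alone are informative about vessel locations.
#'
#' @param resp A `vs_response` or plain matrix.
#' @param fov Binary field-of-view mask.
#' @return Binary `H x W` matrix (zero outside the FOV).
#' @export
otsu_response_mask <- function(resp, fov) {
  v <- if (inherits(resp, "vs_response")) resp$values else resp
  idx <- fov != 0
  lo <- min(v[idx]); hi <- max(v[idx])
  if (hi <= lo) stop_vs("response is constant over the FOV")
  r <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  th <- EBImage::otsu(EBImage::Image(r * idx))
  ((r >= th) & idx) * 1
}

#' Gaussian scale-space stack
#'
#' Progressively Gaussian-blurred copies of the input (reflective
#' boundaries, kernels truncated at 4 sigma). A leading sigma of 0 yields an
#' exact copy of the input.
#'
#' @param norm A `vs_norm` or plain matrix.
#' @param sigmas Ascending blur scales in pixels; the first may be 0.
#' @return A `vs_scale_space`: `images` (list of matrices), `sigmas`.
#' @export
scale_space <- function(norm, sigmas = c(0, 1, 2)) {
  img <- if (inherits(norm, "vs_norm")) norm$values else norm
  if (any(sigmas < 0)) stop_vs("scale-space sigmas must be non-negative")
  if (is.unsorted(sigmas)) stop_vs("scale-space sigmas must be ascending")
  images <- lapply(sigmas, function(s) gaussian_blur(img, s))
  structure(list(images = images, sigmas = sigmas), class = "vs_scale_space")
}

#' Assemble the network's input feature stack
#'
#' Stacks the normalized image, the matched-filter maximum response, the
#' line-detection maximum response and each scale-space image into an
#' `H x W x C` grid. Every channel is min--max rescaled to `[0, 1]` over the
#' field of view; outside-FOV pixels are zeroed. The channel list is
#' configurable: any subset of `"norm"`, `"matched_filter"`,
#' `"line_detection"`, `"scale_space"`.
#'
#' @param norm `vs_norm` from [normalize_image()].
#' @param mf Optional `vs_response` from [matched_filter_response()].
#' @param ld Optional `vs_response` from [line_detection_response()].
#' @param ss Optional `vs_scale_space` from [scale_space()].
#' @param fov Binary `H x W` field-of-view mask.
#' @param channels Character vector selecting and ordering channel groups.
#' @return A `vs_feature_stack`: `channels` (`H x W x C` array),
#'   `channel_names`, `fov_mask`.
#' @export
build_feature_stack <- function(norm, mf = NULL, ld = NULL, ss = NULL, fov,
                                channels = c("norm", "matched_filter",
                                             "line_detection", "scale_space")) {
  hw <- dim(norm$values)
  if (!identical(dim(fov), hw)) stop_vs("FOV shape mismatch")
  mats <- list(); nms <- character(0)
  for (ch in channels) {
    if (ch == "norm") {
      mats <- c(mats, list(norm$values)); nms <- c(nms, "norm")
    } else if (ch == "matched_filter") {
      if (is.null(mf)) stop_vs("channel 'matched_filter' requested but mf is NULL")
      mats <- c(mats, list(mf$values)); nms <- c(nms, "matched_filter")
    } else if (ch == "line_detection") {
      if (is.null(ld)) stop_vs("channel 'line_detection' requested but ld is NULL")
      mats <- c(mats, list(ld$values)); nms <- c(nms, "line_detection")
    } else if (ch == "scale_space") {
      if (is.null(ss)) stop_vs("channel 'scale_space' requested but ss is NULL")
      for (m in seq_along(ss$images)) {
        mats <- c(mats, list(ss$images[[m]]))
        nms <- c(nms, sprintf("scale_%g", ss$sigmas[m]))
      }
    } else {
      stop_vs("unknown channel group '%s'", ch)
    }
  }
  if (length(mats) == 0L) stop_vs("at least one channel is required")
  idx <- fov != 0
  arr <- array(0, dim = c(hw[1L], hw[2L], length(mats)))
  for (c in seq_along(mats)) {
    m <- mats[[c]]
    if (!identical(dim(m), hw)) stop_vs("channel '%s' shape mismatch", nms[c])
    lo <- min(m[idx]); hi <- max(m[idx])
    sc <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    sc[!idx] <- 0
    arr[, , c] <- pmin(pmax(sc, 0), 1)
  }
  structure(list(channels = arr, channel_names = nms, fov_mask = fov * 1),
            class = "vs_feature_stack")
}
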