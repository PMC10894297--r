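#' Read a raster image
#'
#' Decodes a PNG, TIFF, PPM/PGM, or JPEG file into a numeric pixel grid with
#' 0-based conceptual (row i, column j) indexing, row 1 at the top. 8-bit
#' files are returned on the 0--255 integer scale; floating-point TIFFs are
#' returned as stored.
#'
#' @param path Path to an image file.
#' @return An `H x W` matrix (grayscale) or `H x W x 3` array (color).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_vs("image file does not exist: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop_vs("JPEG support requires the 'jpeg' package")
      }
      jpeg::readJPEG(path)
    },
    ppm = ,
    pgm = read_pnm(path),
    stop_vs("unsupported image format '%s' for '%s'", ext, path)
  )
  if (ext %in% c("ppm", "pgm")) return(x)
  # png/jpeg/tiff decoders return [0,1]; restore the 8-bit integer scale.
  x <- x * 255
  if (max(abs(x - round(x))) < 1e-6) x <- round(x)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] == 1L) {
      x <- x[, , 1L]
    } else if (dim(x)[3L] == 2L) {
      x <- x[, , 1L]  # gray + alpha
    } else {
      x <- x[, , seq_len(min(3L, dim(x)[3L])), drop = FALSE]  # drop alpha
    }
  }
  x
}

# Minimal binary/ASCII PPM (P2/P3/P5/P6) and PGM reader; returns 0..maxval.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop_vs("truncated PNM file '%s'", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("^[[:space:]]$", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop_vs("unsupported image format: '%s' is not a P2/P3/P5/P6 PNM", path)
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval < 256L) {
      as.integer(readBin(con, "raw", n = n))
    } else {
      readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    out <- integer(n)
    for (i in seq_len(n)) out[i] <- as.integer(read_token())
    out
  }
  if (length(vals) < n) stop_vs("truncated PNM file '%s'", path)
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, dim = c(h, w, 3L))
    for (c in 1:3) {
      a[, , c] <- matrix(vals[seq(c, n, by = 3L)], nrow = h, ncol = w, byrow = TRUE)
    }
    a
  }
}

#' Read a binary mask
#'
#' Decodes an image and binarizes it. Color inputs are first converted to
#' luminance (Rec. 601 weights). Masks whose maximum pixel value is at most 1
#' are treated as already binary; otherwise pixels with value `>= threshold`
#' map to 1.
#'
#' @param path Path to a mask image (PNG, PGM/PPM, GIF-converted PNG, TIFF).
#' @param threshold Intensity cut on the 0--255 scale (default 128).
#' @return An `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path, threshold = 128) {
  x <- read_image(path)
  if (length(dim(x)) == 3L) {
    x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
  }
  if (max(x) <= 1) {
    m <- (x > 0) * 1
  } else {
    m <- (x >= threshold) * 1
  }
  m
}

#' Write a binary mask as PNG
#'
#' Foreground (1) is stored as pixel value 255, background as 0, so that
#' [read_mask()] recovers the identical grid.
#'
#' @param mask `H x W` matrix with values in `{0, 1}`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  if (!is_binary_grid(mask)) stop_vs("mask must be a binary {0,1} matrix")
  if (any(dim(mask) == 0L)) stop_vs("mask has zero extent; nothing to write")
  storage.mode(mask) <- "double"
  png::writePNG(mask, target = path)
  invisible(path)
}

#' Write a grayscale image as PNG
#'
#' @param image `H x W` matrix with values in `[0, 1]` (real) or `[0, 255]`
#'   (integer scale; divided by 255 before encoding).
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  if (any(dim(image) == 0L)) stop_vs("image has zero extent; nothing to write")
  if (max(image) > 1) image <- image / 255
  storage.mode(image) <- "double"
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

# Write a probability map with 16-bit precision (TIFF); read back with
# read_probability_map. Values are clipped to [0,1].
#' Write / read a probability map (16-bit TIFF)
#'
#' Per-pixel vessel probabilities in `[0,1]` are stored at 16-bit precision
#' so that thresholding the re-read map reproduces the binary decisions made
#' at write time.
#' @param V `H x W` probability matrix in `[0,1]`.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_probability_map <- function(V, path) {
  tiff::writeTIFF(pmin(pmax(V, 0), 1), where = path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

# Quantise probabilities to the 16-bit grid used on disk.
quantize_16bit <- function(V) round(pmin(pmax(V, 0), 1) * 65535) / 65535

#' Resolve a dataset directory into a manifest
#'
#' Builds a deterministic, lexicographically ordered list of samples with
#' train/test assignment from a dataset descriptor. Supported layouts:
#' \describe{
#'   \item{`drive`}{`training/` and `test/` subtrees, each with `images/`,
#'     `1st_manual/` (ground truth) and `mask/` (field of view).}
#'   \item{`flat`, `stare`, `chase`, `hrf`}{a single tree with `images/`,
#'     `masks/` (ground truth) and optional `fov/` directories; the split
#'     comes from `split_file`, a text file listing the training image ids
#'     (basenames without extension), one per line. `stare` requires the
#'     split file; for the others, if it is absent every sample is `test`.}
#' }
#' Ground truth and field-of-view files are matched to images by basename.
#' Missing ground truth produces a warning, not an error.
#'
#' @param config A list (or path to a YAML file) with fields `name`, `layout`
#'   (one of `drive`, `stare`, `chase`, `hrf`, `flat`), `root`, and optionally
#'   `split_file` and `fov_dir`.
#' @return An object of class `vs_manifest`: a list with `name`, `root`,
#'   `samples` (each a `vs_sample_ref` with `id`, `image_path`, `gt_path`,
#'   `fov_path`, `split`), `n_train`, `n_test`.
#' @export
load_manifest <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  layout <- match.arg(config$layout, c("drive", "stare", "chase", "hrf", "flat"))
  root <- config$root
  if (is.null(root) || !dir.exists(root)) {
    stop_vs("dataset root '%s' does not exist", root %||% "<missing>")
  }
  img_exts <- "\\.(png|tif|tiff|jpg|jpeg|ppm|pgm)$"
  list_sorted <- function(dir) {
    if (!dir.exists(dir)) return(character(0))
    f <- list.files(dir, pattern = img_exts, ignore.case = TRUE, full.names = TRUE)
    f[order(basename(f), method = "radix")]
  }
  match_by_id <- function(id, dir) {
    if (is.null(dir) || !dir.exists(dir)) return(NA_character_)
    f <- list_sorted(dir)
    ids <- tools::file_path_sans_ext(basename(f))
    hit <- f[ids == id]
    if (length(hit) == 0L) {
      # DRIVE-style name decorations: 21_training -> 21_manual1 etc.
      stem <- sub("_(training|test)$", "", id)
      hit <- f[startsWith(tools::file_path_sans_ext(basename(f)), stem)]
    }
    if (length(hit) == 0L) NA_character_ else hit[[1L]]
  }
  build_samples <- function(img_dir, gt_dir, fov_dir, split) {
    imgs <- list_sorted(img_dir)
    lapply(imgs, function(p) {
      id <- tools::file_path_sans_ext(basename(p))
      gt <- match_by_id(id, gt_dir)
      if (is.na(gt)) {
        warning(sprintf("no ground truth found for sample '%s'", id), call. = FALSE)
        gt <- NULL
      }
      fov <- match_by_id(id, fov_dir)
      structure(list(id = id, image_path = p,
                     gt_path = gt, fov_path = if (is.na(fov)) NULL else fov,
                     split = split),
                class = "vs_sample_ref")
    })
  }
  if (layout == "drive") {
    samples <- c(
      build_samples(file.path(root, "training", "images"),
                    file.path(root, "training", "1st_manual"),
                    file.path(root, "training", "mask"), "train"),
      build_samples(file.path(root, "test", "images"),
                    file.path(root, "test", "1st_manual"),
                    file.path(root, "test", "mask"), "test")
    )
  } else {
    img_dir <- file.path(root, "images")
    if (!dir.exists(img_dir)) img_dir <- root
    gt_dir <- file.path(root, "masks")
    fov_dir <- config$fov_dir %||% file.path(root, "fov")
    train_ids <- character(0)
    if (!is.null(config$split_file)) {
      sf <- config$split_file
      if (!file.exists(sf)) sf <- file.path(root, config$split_file)
      if (!file.exists(sf)) stop_vs("split_file '%s' not found", config$split_file)
      train_ids <- trimws(readLines(sf, warn = FALSE))
      train_ids <- train_ids[nzchar(train_ids)]
    } else if (layout == "stare") {
      stop_vs("layout 'stare' has no canonical split; a split_file is required")
    }
    samples <- build_samples(img_dir, gt_dir, fov_dir, "test")
    for (i in seq_along(samples)) {
      if (samples[[i]]$id %in% train_ids) samples[[i]]$split <- "train"
    }
  }
  if (length(samples) == 0L) stop_vs("no images found under dataset root '%s'", root)
  n_train <- sum(vapply(samples, function(s) s$split == "train", logical(1)))
  structure(list(
    name = config$name %||% basename(root),
    root = root,
    samples = samples,
    n_train = n_train,
    n_test = length(samples) - n_train
  ), class = "vs_manifest")
}

#' Load the pixel data of a manifest sample
#'
#' Reads the image, ground-truth and field-of-view files referenced by a
#' manifest entry. When no FOV file exists a full-frame mask of ones is
#' synthesized.
#'
#' @param ref A `vs_sample_ref` from [load_manifest()].
#' @return A `vs_fundus_sample`: list with `id`, `image`, `fov_mask`,
#'   `gt_mask` (or `NULL`), `split`, `source_path`.
#' @export
load_sample <- function(ref) {
  img <- read_image(ref$image_path)
  hw <- dim(img)[1:2]
  gt <- if (!is.null(ref$gt_path)) read_mask(ref$gt_path) else NULL
  fov <- if (!is.null(ref$fov_path)) read_mask(ref$fov_path) else
    matrix(1, hw[1L], hw[2L])
  if (!is.null(gt) && !identical(dim(gt), hw)) {
    stop_vs("ground truth shape mismatch for sample '%s'", ref$id)
  }
  if (!identical(dim(fov), hw)) {
    stop_vs("FOV shape mismatch for sample '%s'", ref$id)
  }
  structure(list(id = ref$id, image = img, fov_mask = fov, gt_mask = gt,
                 split = ref$split, source_path = ref$image_path),
            class = "vs_fundus_sample")
}

#' @export
print.vs_manifest <- function(x, ...) {
  cat(sprintf("<vs_manifest> %s: %d samples (%d train / %d test) at %s\n",
              x$name, length(x$samples), x$n_train, x$n_test, x$root))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
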