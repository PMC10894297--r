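#' Parameters for synthetic fundus phantoms
#'
#' A phantom emulates the appearance of a fundus photograph's vessel-bearing
#' channel: dark branching curvilinear vessel trees of varying width on a
#' brighter, vignetted, noisy background inside a circular field of view,
#' with exact ground truth. Widths and intensities are in pixels and
#' normalized intensity units respectively.
#'
#' @param height,width Image size in pixels.
#' @param n_roots Number of root vessels entering from the FOV rim.
#' @param branch_prob Probability per walk step of spawning a child branch.
#' @param max_depth Maximum branching generation (root = 0).
#' @param width_root Root vessel full width in pixels.
#' @param width_decay Multiplicative width factor per generation, in (0, 1].
#' @param tortuosity Angular-noise standard deviation per step (radians).
#' @param vessel_contrast Peak intensity drop at the vessel centerline, in
#'   `[0, background_level]`.
#' @param background_level Background intensity in `[0, 1]`.
#' @param vignette_strength Relative darkening at the FOV rim, in `[0, 1]`.
#' @param noise_sigma Additive Gaussian pixel noise standard deviation.
#' @param fov_radius_frac FOV radius as a fraction of `min(height, width)/2`.
#' @param seed Integer seed; the generator uses a private RNG stream.
#' @return A `vs_phantom_params` list.
#' @export
phantom_params <- function(height = 128L, width = 128L,
                           n_roots = 3L, branch_prob = 0.025, max_depth = 3L,
                           width_root = 3.5, width_decay = 0.8,
                           tortuosity = 0.15,
                           vessel_contrast = 0.45, background_level = 0.75,
                           vignette_strength = 0.3, noise_sigma = 0.03,
                           fov_radius_frac = 0.95, seed = 1L) {
  p <- list(height = as.integer(height), width = as.integer(width),
            n_roots = as.integer(n_roots), branch_prob = branch_prob,
            max_depth = as.integer(max_depth), width_root = width_root,
            width_decay = width_decay, tortuosity = tortuosity,
            vessel_contrast = vessel_contrast,
            background_level = background_level,
            vignette_strength = vignette_strength, noise_sigma = noise_sigma,
            fov_radius_frac = fov_radius_frac, seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "vs_phantom_params")
}

validate_phantom_params <- function(p) {
  if (p$height <= 0L || p$width <= 0L) stop_vs("phantom dimensions must be positive")
  if (p$width_root < 1) stop_vs("width_root must be >= 1 pixel")
  if (p$width_decay <= 0 || p$width_decay > 1) stop_vs("width_decay must be in (0, 1]")
  if (p$vessel_contrast < 0 || p$vessel_contrast > p$background_level ||
      p$background_level > 1) {
    stop_vs("need 0 <= vessel_contrast <= background_level <= 1")
  }
  invisible(p)
}

#' Grow a synthetic vascular tree
#'
#' Each root starts on the FOV rim and performs a correlated random walk
#' inward (heading toward the image centre plus angular noise). At every step
#' a child branch spawns with probability `branch_prob` (up to `max_depth`
#' generations); a child's width is its parent's width times `width_decay`.
#' Deterministic given `params$seed`; the caller's RNG state is untouched.
#'
#' @param params A [phantom_params()] object.
#' @return A list of polylines; each has `xy` (n x 2 matrix of (row, col)
#'   vertex positions), `width` (per-vertex full width, pixels) and `depth`.
#' @export
generate_tree <- function(params) {
  validate_phantom_params(params)
  with_local_rng(params$seed, grow_tree_impl(params))
}

grow_tree_impl <- function(params) {
  h <- params$height; w <- params$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  R <- params$fov_radius_frac * min(h, w) / 2
  step <- 2
  # root walks span roughly one image diameter; each deeper generation
  # walks half as far, which keeps total vessel coverage bounded
  max_steps_root <- ceiling(0.9 * min(h, w) / step)
  polylines <- list()
  # queue of branches to grow: position, heading, width, depth
  queue <- list()
  for (r in seq_len(params$n_roots)) {
    phi <- stats::runif(1, 0, 2 * pi)
    start <- c(cy + R * sin(phi), cx + R * cos(phi))
    heading <- atan2(cy - start[1L], cx - start[2L]) + stats::rnorm(1, 0, 0.3)
    queue[[length(queue) + 1L]] <- list(pos = start, heading = heading,
                                        width = params$width_root, depth = 0L)
  }
  qi <- 1L
  while (qi <= length(queue)) {
    b <- queue[[qi]]; qi <- qi + 1L
    pos <- b$pos; heading <- b$heading
    verts <- matrix(pos, ncol = 2L)
    max_steps <- ceiling(max_steps_root * 0.5^b$depth)
    for (s in seq_len(max_steps)) {
      heading <- heading + stats::rnorm(1, 0, params$tortuosity)
      # weak pull back toward the centre keeps walks inside the FOV
      to_c <- atan2(cy - pos[1L], cx - pos[2L])
      d <- ((to_c - heading + pi) %% (2 * pi)) - pi
      heading <- heading + 0.05 * d
      pos <- pos + step * c(sin(heading), cos(heading))
      if (pos[1L] < 1 || pos[1L] > h || pos[2L] < 1 || pos[2L] > w) break
      verts <- rbind(verts, pos)
      if (b$depth < params$max_depth &&
          stats::runif(1) < params$branch_prob) {
        side <- if (stats::runif(1) < 0.5) -1 else 1
        child_heading <- heading + side * stats::runif(1, pi / 6, pi / 3)
        queue[[length(queue) + 1L]] <- list(
          pos = pos, heading = child_heading,
          width = b$width * params$width_decay, depth = b$depth + 1L)
      }
    }
    if (nrow(verts) >= 2L) {
      polylines[[length(polylines) + 1L]] <- list(
        xy = unname(verts), width = rep(b$width, nrow(verts)), depth = b$depth)
    }
  }
  polylines
}

#' Render a phantom image from a vascular tree
#'
#' The background is `background_level` times a radial vignette falling to
#' `1 - vignette_strength` at the FOV rim. Each vessel is a smooth intensity
#' trough: at distance `d` from a centerline of local full width `w`, the
#' intensity is reduced by `vessel_contrast * exp(-d^2 / (2 (w/2)^2))`
#' (maximum over overlapping vessels). Gaussian pixel noise with standard
#' deviation `noise_sigma` is added and the image clipped to `[0, 1]`. The
#' ground-truth mask is exactly the set of pixels within half the local
#' width of some centerline segment, intersected with the circular FOV.
#'
#' @param tree Polyline list from [generate_tree()].
#' @param params The same [phantom_params()] used to grow the tree.
#' @return A `vs_phantom_sample`: list with `id`, `image`, `gt_mask`,
#'   `fov_mask`, `centerlines`, `params`.
#' @export
render_phantom <- function(tree, params) {
  validate_phantom_params(params)
  h <- params$height; w <- params$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  R <- params$fov_radius_frac * min(h, w) / 2
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- sqrt((rows - cy)^2 + (cols - cx)^2)
  fov <- (rr <= R) * 1
  vignette <- 1 - params$vignette_strength * pmin(rr / R, 1)^2
  img <- params$background_level * vignette

  # per-pixel: min scaled distance to any segment (for gt), max trough depth
  trough <- matrix(0, h, w)
  inside <- matrix(FALSE, h, w)
  for (pl in tree) {
    xy <- pl$xy; wid <- pl$width
    for (s in seq_len(nrow(xy) - 1L)) {
      a <- xy[s, ]; b <- xy[s + 1L, ]
      wseg <- (wid[s] + wid[s + 1L]) / 2
      half <- wseg / 2
      reach <- ceiling(half + 3 * half)  # render tails out to ~3 sigma-ish
      r0 <- max(1L, floor(min(a[1L], b[1L]) - reach))
      r1 <- min(h, ceiling(max(a[1L], b[1L]) + reach))
      c0 <- max(1L, floor(min(a[2L], b[2L]) - reach))
      c1 <- min(w, ceiling(max(a[2L], b[2L]) + reach))
      if (r0 > r1 || c0 > c1) next
      ri <- r0:r1; ci <- c0:c1
      py <- matrix(ri, length(ri), length(ci))
      px <- matrix(ci, length(ri), length(ci), byrow = TRUE)
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) matrix(0, length(ri), length(ci)) else
        pmin(pmax(((py - a[1L]) * ab[1L] + (px - a[2L]) * ab[2L]) / len2, 0), 1)
      dy <- py - (a[1L] + t * ab[1L]); dx <- px - (a[2L] + t * ab[2L])
      d2 <- dy^2 + dx^2
      dep <- params$vessel_contrast * exp(-d2 / (2 * (wseg / 2)^2))
      trough[ri, ci] <- pmax(trough[ri, ci], dep)
      inside[ri, ci] <- inside[ri, ci] | (d2 <= half^2)
    }
  }
  img <- img - trough
  if (params$noise_sigma > 0) {
    noise <- with_local_rng(derive_seed(params$seed, "noise"),
                            stats::rnorm(h * w, 0, params$noise_sigma))
    img <- img + matrix(noise, h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  gt <- (inside * 1) * fov
  structure(list(id = sprintf("phantom_%06d", params$seed),
                 image = img, gt_mask = gt, fov_mask = fov,
                 centerlines = tree, params = params),
            class = c("vs_phantom_sample", "vs_fundus_sample"))
}

#' Generate a seeded phantom dataset
#'
#' Sample `k` (1-based, of `n`) is generated with seed `base_seed + k - 1`,
#' so consecutive datasets can be reproduced and extended deterministically.
#'
#' @param n Number of phantoms (>= 1).
#' @param params Template [phantom_params()]; its `seed` field is overridden.
#' @param base_seed Seed of the first sample.
#' @return List of `vs_phantom_sample`s.
#' @export
generate_dataset <- function(n, params = phantom_params(), base_seed = 1L) {
  if (n < 1) stop_vs("n must be >= 1")
  lapply(seq_len(n), function(k) {
    p <- params
    p$seed <- as.integer(base_seed + k - 1L)
    render_phantom(generate_tree(p), p)
  })
}

#' Export phantoms as an on-disk flat-layout dataset
#'
#' Writes `images/`, `masks/` and `fov/` PNG trees plus a `manifest.yaml`
#' and a `train.txt` split file, so the export round-trips through
#' [load_manifest()].
#'
#' @param samples List of `vs_phantom_sample`s.
#' @param dir Output directory (created if needed).
#' @param n_train Number of leading samples assigned to the training split.
#' @return Invisibly, the manifest config list written to `manifest.yaml`.
#' @export
export_phantom_dataset <- function(samples, dir, n_train = 0L) {
  for (sub in c("images", "masks", "fov")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  ids <- character(length(samples))
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    id <- sprintf("ph%03d", k)
    ids[k] <- id
    write_image(s$image, file.path(dir, "images", paste0(id, ".png")))
    write_mask(s$gt_mask, file.path(dir, "masks", paste0(id, ".png")))
    write_mask(s$fov_mask, file.path(dir, "fov", paste0(id, ".png")))
  }
  writeLines(ids[seq_len(n_train)], file.path(dir, "train.txt"))
  cfg <- list(name = basename(dir), layout = "flat", root = dir,
              split_file = "train.txt")
  yaml::write_yaml(cfg, file.path(dir, "manifest.yaml"))
  invisible(cfg)
}
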