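#' Post-processing parameters
#'
#' @param threshold Probability cut in (0, 1); pixels with `V >= threshold`
#'   become vessel (inclusive, so exact-0.5 outputs are deterministic).
#' @param min_object_px Foreground components smaller than this area are
#'   removed (speckle noise).
#' @param closing_radius Disc radius for morphological closing (0 disables).
#' @param fill_hole_px Background holes smaller than this area are filled.
#' @param connectivity Pixel connectivity for component analysis: 4 or 8.
#' @param order `"threshold_then_morph"` (binary morphology after Eq.-style
#'   thresholding, the default) or `"morph_then_threshold"` (grayscale
#'   closing of the probability map first).
#' @return A `vs_postproc_params` list.
#' @export
postproc_params <- function(threshold = 0.5, min_object_px = 30L,
                            closing_radius = 1L, fill_hole_px = 20L,
                            connectivity = 8L,
                            order = c("threshold_then_morph",
                                      "morph_then_threshold")) {
  if (threshold <= 0 || threshold >= 1) stop_vs("threshold must be strictly inside (0,1)")
  structure(list(threshold = threshold, min_object_px = as.integer(min_object_px),
                 closing_radius = as.integer(closing_radius),
                 fill_hole_px = as.integer(fill_hole_px),
                 connectivity = as.integer(connectivity),
                 order = match.arg(order)),
            class = "vs_postproc_params")
}

# Discrete disc structuring element: pixels with i^2 + j^2 <= r^2
# (radius 1 is a plus shape, not a 3x3 box).
disc_brush <- function(radius) {
  r <- as.integer(radius)
  i <- matrix(-r:r, 2L * r + 1L, 2L * r + 1L)
  (i^2 + t(i)^2 <= r^2) * 1
}

#' Threshold a probability map into a binary mask
#'
#' `B(i,j) = 1` iff `V(i,j) >= t` (inclusive).
#'
#' @param V A `vs_probability_map` or plain `H x W` matrix in `[0,1]`.
#' @param t Threshold strictly inside (0, 1).
#' @return Binary `H x W` matrix.
#' @export
apply_threshold <- function(V, t = 0.5) {
  if (t <= 0 || t >= 1) stop_vs("threshold must be strictly inside (0,1)")
  v <- if (inherits(V, "vs_probability_map")) V$values else V
  (v >= t) * 1
}

#' Morphological refinement of a binary vessel mask
#'
#' In order: (1) morphological closing with a disc of `closing_radius`
#' (bridges small gaps), (2) removal of foreground components with area
#' below `min_object_px` (speckle noise), (3) filling of enclosed background
#' holes with area below `fill_hole_px`. All steps are deterministic.
#'
#' @param B Binary `H x W` matrix.
#' @param params A [postproc_params()].
#' @return Refined binary matrix.
#' @export
morphological_refine <- function(B, params = postproc_params()) {
  if (!is_binary_grid(B)) stop_vs("B must be a binary {0,1} matrix")
  m <- B
  if (params$closing_radius > 0L) {
    m <- as.matrix(EBImage::closing(m, disc_brush(params$closing_radius)))
    m <- (m > 0.5) * 1
  }
  if (params$min_object_px > 0L && any(m > 0)) {
    lab <- label_components(m, params$connectivity)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L])
      keep <- which(areas >= params$min_object_px)
      m <- (lab %in% keep) * 1
      dim(m) <- dim(B)
    }
  }
  if (params$fill_hole_px > 0L) {
    bg <- 1 - m
    # holes are background components not touching the image border;
    # complement connectivity: 8-connected foreground pairs with
    # 4-connected background and vice versa
    bg_conn <- if (params$connectivity == 8L) 4L else 8L
    lab <- label_components(bg, bg_conn)
    if (max(lab) > 0L) {
      border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
      areas <- tabulate(lab[lab > 0L])
      fill <- setdiff(which(areas < params$fill_hole_px), border)
      if (length(fill) > 0L) m[lab %in% fill] <- 1
    }
  }
  m
}

#' Threshold + refine in the configured order
#'
#' @param V Probability map (object or matrix).
#' @param params A [postproc_params()].
#' @return Binary mask after thresholding and morphology.
#' @export
postprocess <- function(V, params = postproc_params()) {
  v <- if (inherits(V, "vs_probability_map")) V$values else V
  if (params$order == "morph_then_threshold") {
    if (params$closing_radius > 0L) {
      v <- as.matrix(EBImage::closing(v, disc_brush(params$closing_radius)))
    }
    B <- apply_threshold(v, params$threshold)
    p2 <- params; p2$closing_radius <- 0L
    morphological_refine(B, p2)
  } else {
    B <- apply_threshold(v, params$threshold)
    morphological_refine(B, params)
  }
}
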