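# Internal numerical utilities shared across modules.

#' Run code with a private RNG stream
#'
#' Saves the caller's `.Random.seed`, seeds a fresh Mersenne-Twister stream,
#' runs `code`, and restores the caller's stream so package functions never
#' perturb user-level random state.
#' @noRd
with_local_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Derive a named substream seed from a master seed; keeps all pipeline RNG
# rooted in one config seed while decorrelating stages. Result < 2^31.
derive_seed <- function(seed, name) {
  h <- utf8ToInt(paste0(name, ":"))
  acc <- as.double(seed %% 2147483647L)
  for (v in h) acc <- (acc * 31 + v) %% 2147483647
  as.integer(acc)
}

# Reflective (mirror, edge not repeated) padding of a matrix by (pr, pc).
pad_reflect <- function(x, pr, pc = pr) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(pr < nr, pc < nc)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

# 2-D cross-correlation with reflective boundary handling.
# EBImage::filter2 performs true convolution (kernel flipped) with circular
# boundaries, so the kernel is rotated 180 degrees and the image padded
# reflectively by the kernel half-support before calling it.
xcorr2_reflect <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  if (hr == 0L && hc == 0L) return(img * kern[1L, 1L])
  kflip <- kern[kr:1, kc:1, drop = FALSE]
  p <- pad_reflect(img, hr, hc)
  out <- EBImage::filter2(p, kflip, boundary = "circular")
  out <- as.matrix(out)
  out[(hr + 1L):(hr + nrow(img)), (hc + 1L):(hc + ncol(img)), drop = FALSE]
}

# 1-D Gaussian kernel truncated at `truncate` sigmas, normalised to sum 1.
gauss_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with reflective boundaries. sigma = 0 is identity.
gaussian_blur <- function(img, sigma, truncate = 4) {
  if (sigma == 0) return(img)
  k <- gauss_kernel_1d(sigma, truncate)
  r <- (length(k) - 1L) %/% 2L
  # rows direction
  p <- pad_reflect(img, r, 0L)
  out <- matrix(0, nrow(img), ncol(img))
  for (o in seq_along(k)) {
    out <- out + k[o] * p[o:(o + nrow(img) - 1L), , drop = FALSE]
  }
  # columns direction
  p <- pad_reflect(out, 0L, r)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (o in seq_along(k)) {
    out2 <- out2 + k[o] * p[, o:(o + ncol(img) - 1L), drop = FALSE]
  }
  out2
}

# Connected-component labelling with selectable connectivity. 4-connected
# labelling comes from EBImage::bwlabel; 8-connectivity merges 4-connected
# labels that touch diagonally via union-find. Label ids are deterministic:
# renumbered by each component's first pixel in column-major order.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  fg <- mask != 0
  if (!any(fg)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- as.matrix(EBImage::bwlabel(fg * 1))
  storage.mode(lab) <- "integer"
  if (connectivity == 8L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # \ diagonal
    a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]   # / diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(max(lab))
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      lab[fg] <- roots[lab[fg]]
    }
  }
  # renumber deterministically by first occurrence
  ids <- lab[fg]
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[fg] <- match(ids, unique(ids))
  out
}

# Population (divide-by-N) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

is_binary_grid <- function(x) {
  is.numeric(x) && length(dim(x)) == 2L && all(x %in% c(0, 1))
}

stop_vs <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
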