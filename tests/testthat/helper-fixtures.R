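# Shared fixtures, all generated in code at test time.

# Small seeded phantom (defaults: 128 x 128).
make_phantom <- function(seed = 11, ...) {
  p <- phantom_params(seed = seed, ...)
  render_phantom(generate_tree(p), p)
}

# Flat-layout dataset directory with n phantom images + masks + fov and a
# split file listing the first n_train ids.
make_flat_dataset <- function(n = 3, n_train = 2, dir = NULL,
                              height = 64, width = 64, base_seed = 1) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  samples <- generate_dataset(n, phantom_params(height = height, width = width),
                              base_seed = base_seed)
  export_phantom_dataset(samples, dir, n_train = n_train)
  list(dir = dir, samples = samples)
}

# Independent reflective-boundary index: mirror without repeating the edge
# pixel (offset k beyond [1, n] reflects to 2 - k or 2n - k).
reflect_idx <- function(k, n) {
  ifelse(k < 1, 2 - k, ifelse(k > n, 2 * n - k, k))
}

# Brute-force cross-correlation oracle with reflective boundaries:
# per-pixel loop, independent of the package's FFT path.
xcorr_oracle <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  hr <- (nrow(kern) - 1) / 2; hc <- (ncol(kern) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- reflect_idx((i - hr):(i + hr), nr)
    for (j in seq_len(nc)) {
      ci <- reflect_idx((j - hc):(j + hc), nc)
      out[i, j] <- sum(img[ri, ci] * kern)
    }
  }
  out
}

# Per-pixel loop oracle for confusion counts and the derived metrics.
metrics_oracle <- function(pred, gt) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  total <- tp + fp + fn + tn
  p_o <- (tp + tn) / total
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       jaccard = tp / (tp + fp + fn),
       recall = tp / (tp + fn),
       precision = tp / (tp + fp),
       f1 = 2 * tp / (2 * tp + fp + fn),
       accuracy = p_o,
       kappa = (p_o - p_e) / (1 - p_e),
       specificity = tn / (tn + fp))
}
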