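#' Assemble a pipeline configuration
#'
#' Bundles the per-phase settings of the three-phase pipeline (enhance ->
#' segment -> post-process) plus dataset, evaluation and seeding options.
#' Any field may be overridden; unspecified fields take package defaults.
#'
#' @param dataset Either a manifest descriptor (see [load_manifest()]) or a
#'   phantom study spec: `list(type = "phantom", n_train =, n_test =,
#'   params = phantom_params(...))`.
#' @param enhance List with `widths`, `orientations`, `kernel_length`,
#'   `vesselness_scales`, `beta`, `scale_space_sigmas`, `channels`.
#' @param model A [net_config()] or plain list of its fields.
#' @param postproc A [postproc_params()] or plain list of its fields.
#' @param eval List with `use_fov` flag.
#' @param seed Master seed; all stage RNG streams derive from it.
#' @param out_dir Output/working directory for caches, checkpoints, masks
#'   and reports.
#' @return A `vs_pipeline_config` list.
#' @export
pipeline_config <- function(dataset = list(type = "phantom", n_train = 20L,
                                           n_test = 5L),
                            enhance = list(), model = list(),
                            postproc = list(), eval = list(),
                            seed = 1L, out_dir = tempfile("vesselseg_run_")) {
  enh <- utils::modifyList(list(
    widths = c(1, 1.5, 2),
    orientations = seq(0, 165, by = 15),
    kernel_length = 9L,
    vesselness_scales = c(1, 1.5, 2),
    beta = 0.5,
    scale_space_sigmas = c(0, 1, 2),
    channels = c("norm", "matched_filter", "line_detection", "scale_space")
  ), enhance)
  n_ch <- feature_channel_count(enh)
  mdl <- if (inherits(model, "vs_net_config")) model else
    do.call(net_config, utils::modifyList(list(input_channels = n_ch,
                                               seed = as.integer(seed)),
                                          model))
  pp <- if (inherits(postproc, "vs_postproc_params")) postproc else
    do.call(postproc_params, postproc)
  ev <- utils::modifyList(list(use_fov = TRUE, calibrate_threshold = TRUE), eval)
  structure(list(dataset = dataset, enhance = enh, model = mdl,
                 postproc = pp, eval = ev, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "vs_pipeline_config")
}

feature_channel_count <- function(enh) {
  n <- 0L
  for (ch in enh$channels) {
    n <- n + if (ch == "scale_space") length(enh$scale_space_sigmas) else 1L
  }
  n
}

#' Read / write a pipeline configuration as YAML
#'
#' The serialization is canonical: writing a loaded config reproduces the
#' file byte-for-byte.
#' @param path YAML file path.
#' @return `load_pipeline_config` returns a `vs_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(dataset = y$dataset %||% list(type = "phantom"),
                  enhance = y$enhance %||% list(),
                  model = y$model %||% list(),
                  postproc = y$postproc %||% list(),
                  eval = y$eval %||% list(),
                  seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% tempfile("vesselseg_run_"))
}

#' @rdname load_pipeline_config
#' @param config A `vs_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- list(dataset = config$dataset, enhance = config$enhance,
            model = unclass(config$model), postproc = unclass(config$postproc),
            eval = config$eval, seed = config$seed, out_dir = config$out_dir)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Resolve the configured dataset to an on-disk manifest, generating and
# exporting phantoms when dataset$type == "phantom".
resolve_dataset <- function(config) {
  ds <- config$dataset
  if (identical(ds$type, "phantom")) {
    n_train <- ds$n_train %||% 20L
    n_test <- ds$n_test %||% 5L
    dir <- file.path(config$out_dir, "dataset")
    params <- if (inherits(ds$params, "vs_phantom_params")) ds$params else
      do.call(phantom_params, ds$params %||% list())
    base_seed <- derive_seed(config$seed, "phantom")
    if (!file.exists(file.path(dir, "manifest.yaml"))) {
      samples <- generate_dataset(n_train + n_test, params, base_seed)
      export_phantom_dataset(samples, dir, n_train = n_train)
    }
    load_manifest(list(name = "phantom", layout = "flat", root = dir,
                       split_file = "train.txt"))
  } else {
    load_manifest(ds)
  }
}

#' Compute the feature stack of one sample
#'
#' Runs the preprocessing chain in order: vessel-channel extraction,
#' z-score normalization over the FOV, matched-filter bank response,
#' Hessian line detection, Gaussian scale space, and channel assembly.
#'
#' @param image Raw image grid (grayscale or color).
#' @param fov Binary field-of-view mask.
#' @param enh Enhance-config list (see [pipeline_config()]).
#' @return A `vs_feature_stack`.
#' @export
compute_feature_stack <- function(image, fov, enh) {
  ch <- extract_vessel_channel(image)
  norm <- normalize_image(ch, domain = fov)
  mf <- NULL; ld <- NULL; ss <- NULL
  if ("matched_filter" %in% enh$channels) {
    bank <- build_filter_bank(enh$widths, enh$orientations, enh$kernel_length)
    mf <- matched_filter_response(norm, bank)
  }
  if ("line_detection" %in% enh$channels) {
    ld <- line_detection_response(norm, enh$vesselness_scales, enh$beta)
  }
  if ("scale_space" %in% enh$channels) {
    ss <- scale_space(norm, enh$scale_space_sigmas)
  }
  build_feature_stack(norm, mf, ld, ss, fov, channels = enh$channels)
}

#' Run the preprocessing phase over a dataset
#'
#' Computes and caches one feature stack per sample. The cache key is the
#' MD5 of the image file content plus the enhance configuration, so reruns
#' with unchanged inputs recompute nothing; per-sample failures are logged
#' and skipped.
#'
#' @param config A `vs_pipeline_config`.
#' @return Invisible list: `manifest`, `stacks` (named by id), `computed`,
#'   `cached`, `failed` (ids).
#' @export
run_preprocess <- function(config) {
  manifest <- resolve_dataset(config)
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_tmp <- tempfile()
  on.exit(unlink(cfg_tmp), add = TRUE)
  saveRDS(config$enhance, cfg_tmp)
  cfg_md5 <- unname(tools::md5sum(cfg_tmp))
  stacks <- list(); computed <- 0L; cached <- 0L; failed <- character(0)
  for (ref in manifest$samples) {
    key <- paste0(unname(tools::md5sum(ref$image_path)), "-", cfg_md5)
    cache_file <- file.path(cache_dir, paste0(ref$id, ".rds"))
    hit <- NULL
    if (file.exists(cache_file)) {
      obj <- readRDS(cache_file)
      if (identical(obj$key, key)) hit <- obj$stack
    }
    if (!is.null(hit)) {
      stacks[[ref$id]] <- hit
      cached <- cached + 1L
      next
    }
    res <- tryCatch({
      sample <- load_sample(ref)
      stack <- compute_feature_stack(sample$image, sample$fov_mask, config$enhance)
      saveRDS(list(key = key, stack = stack), cache_file)
      stack
    }, error = function(e) {
      message(sprintf("preprocess: sample '%s' failed: %s", ref$id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      failed <- c(failed, ref$id)
    } else {
      stacks[[ref$id]] <- res
      computed <- computed + 1L
    }
  }
  invisible(list(manifest = manifest, stacks = stacks, computed = computed,
                 cached = cached, failed = failed))
}

#' Run the training phase
#'
#' Trains the residual U-Net on the cached feature stacks of the training
#' split and writes a checkpoint plus a JSON training history.
#'
#' @param config A `vs_pipeline_config`.
#' @param pre Optional result of [run_preprocess()] (recomputed otherwise).
#' @param verbose Print per-epoch progress.
#' @return Invisible list: `model`, `checkpoint_path`, `history`.
#' @export
run_train <- function(config, pre = NULL, verbose = FALSE) {
  pre <- pre %||% run_preprocess(config)
  manifest <- pre$manifest
  train_refs <- Filter(function(s) s$split == "train", manifest$samples)
  if (length(train_refs) == 0L) stop_vs("no training samples in the dataset")
  samples <- lapply(train_refs, function(ref) {
    if (is.null(ref$gt_path)) {
      stop_vs("training sample '%s' has no ground-truth mask", ref$id)
    }
    stack <- pre$stacks[[ref$id]]
    if (is.null(stack)) stop_vs("no cached feature stack for sample '%s'", ref$id)
    list(stack = stack, gt = read_mask(ref$gt_path), fov = stack$fov_mask)
  })
  model <- build_unet(config$model)
  model <- train_unet(model, samples, config$model, verbose = verbose)
  if (isTRUE(config$eval$calibrate_threshold)) {
    model <- calibrate_threshold(model, samples, postproc = config$postproc)
    if (verbose) message(sprintf("calibrated threshold: %.2f", model$threshold))
  }
  model_dir <- file.path(config$out_dir, "model")
  dir.create(model_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(model_dir, "checkpoint.rds")
  save_checkpoint(model, ckpt)
  jsonlite::write_json(model$history, file.path(model_dir, "history.json"),
                       dataframe = "columns", digits = NA)
  invisible(list(model = model, checkpoint_path = ckpt, history = model$history))
}

#' Run the segmentation phase on the test split
#'
#' For every test sample, writes the probability map `V` (16-bit TIFF) and
#' the post-processed binary mask `B` (PNG). Probabilities are quantised to
#' the on-disk 16-bit grid before thresholding so files and masks agree
#' exactly.
#'
#' @param config A `vs_pipeline_config`.
#' @param checkpoint Path to a checkpoint or a `vs_model`.
#' @param pre Optional result of [run_preprocess()].
#' @return Invisible list: `ids`, `prob_paths`, `mask_paths`, `elapsed`
#'   (seconds per sample).
#' @export
run_segment <- function(config, checkpoint, pre = NULL) {
  model <- if (inherits(checkpoint, "vs_model")) checkpoint else
    load_checkpoint(checkpoint)
  pre <- pre %||% run_preprocess(config)
  test_refs <- Filter(function(s) s$split == "test", pre$manifest$samples)
  out_dir <- file.path(config$out_dir, "predictions")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pp_params <- config$postproc
  if (!is.null(model$threshold) && isTRUE(config$eval$calibrate_threshold)) {
    pp_params$threshold <- model$threshold
  }
  ids <- character(0); pp <- character(0); mp <- character(0); el <- numeric(0)
  for (ref in test_refs) {
    stack <- pre$stacks[[ref$id]]
    if (is.null(stack)) next
    t0 <- proc.time()[["elapsed"]]
    V <- predict_unet(model, stack)
    Vq <- quantize_16bit(V$values)
    B <- postprocess(Vq, pp_params)
    elapsed <- proc.time()[["elapsed"]] - t0
    prob_path <- file.path(out_dir, paste0(ref$id, "_prob.tif"))
    mask_path <- file.path(out_dir, paste0(ref$id, "_mask.png"))
    write_probability_map(Vq, prob_path)
    write_mask(B, mask_path)
    ids <- c(ids, ref$id); pp <- c(pp, prob_path); mp <- c(mp, mask_path)
    el <- c(el, elapsed)
  }
  invisible(list(ids = ids, prob_paths = pp, mask_paths = mp, elapsed = el,
                 postproc = pp_params))
}

#' Run the evaluation phase
#'
#' Matches written predictions to ground truths by id, computes the full
#' metric suite per sample, and writes a per-sample CSV plus an aggregate
#' JSON report.
#'
#' @param config A `vs_pipeline_config`.
#' @param seg Result of [run_segment()] (or a compatible list).
#' @param pre Optional result of [run_preprocess()].
#' @return Invisible list: `reports` (per sample), `aggregate` (data frame),
#'   `csv_path`, `json_path`.
#' @export
run_evaluate <- function(config, seg, pre = NULL) {
  pre <- pre %||% run_preprocess(config)
  test_refs <- Filter(function(s) s$split == "test", pre$manifest$samples)
  names(test_refs) <- vapply(test_refs, `[[`, character(1), "id")
  missing <- setdiff(names(test_refs), seg$ids)
  if (length(missing) > 0L) {
    stop_vs("missing predictions for sample(s): %s", paste(missing, collapse = ", "))
  }
  reports <- list()
  for (i in seq_along(seg$ids)) {
    id <- seg$ids[i]
    ref <- test_refs[[id]]
    if (is.null(ref)) stop_vs("prediction '%s' has no matching test sample", id)
    if (is.null(ref$gt_path)) stop_vs("test sample '%s' has no ground truth", id)
    gt <- read_mask(ref$gt_path)
    fov <- if (isTRUE(config$eval$use_fov)) pre$stacks[[id]]$fov_mask else NULL
    V <- read_probability_map(seg$prob_paths[i])
    rep <- evaluate_sample(V, gt, fov, seg$postproc %||% config$postproc,
                           elapsed = if (length(seg$elapsed) >= i) seg$elapsed[i] else NA_real_)
    reports[[id]] <- rep
  }
  agg <- aggregate_reports(reports)
  rep_dir <- file.path(config$out_dir, "reports")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  per_sample <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(id = id, jaccard = r$jaccard, f1 = r$f1, recall = r$recall,
               precision = r$precision, accuracy = r$accuracy, kappa = r$kappa,
               auc = r$auc, specificity = r$specificity, fps = r$fps)
  }))
  csv_path <- file.path(rep_dir, "per_sample.csv")
  utils::write.csv(per_sample, csv_path, row.names = FALSE)
  json_path <- file.path(rep_dir, "aggregate.json")
  agg_list <- stats::setNames(as.list(agg$mean), agg$metric)
  jsonlite::write_json(agg_list, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(reports = reports, aggregate = agg, csv_path = csv_path,
                 json_path = json_path))
}

#' Run the full pipeline end-to-end
#'
#' Preprocess -> train -> segment -> evaluate on the configured dataset,
#' writing all artifacts under `config$out_dir` together with a resolved
#' run manifest (`run.yaml`) sufficient to reproduce the run.
#'
#' @param config A `vs_pipeline_config`.
#' @param verbose Print stage progress.
#' @return Invisible list: `pre`, `train`, `seg`, `eval`, `aggregate`,
#'   `wall_time` (named seconds per stage).
#' @export
run_all <- function(config, verbose = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pre <- run_preprocess(config)
  times["preprocess"] <- tic() - t0
  if (verbose) message(sprintf("preprocess: %d computed, %d cached, %d failed (%.1fs)",
                               pre$computed, pre$cached, length(pre$failed),
                               times["preprocess"]))
  t0 <- tic()
  tr <- run_train(config, pre, verbose = verbose)
  times["train"] <- tic() - t0
  if (verbose) message(sprintf("train: %d epochs (%.1fs)",
                               nrow(tr$history), times["train"]))
  t0 <- tic()
  seg <- run_segment(config, tr$model, pre)
  times["segment"] <- tic() - t0
  t0 <- tic()
  ev <- run_evaluate(config, seg, pre)
  times["evaluate"] <- tic() - t0
  run_manifest <- list(
    dataset = config$dataset, enhance = config$enhance,
    model = unclass(config$model), postproc = unclass(config$postproc),
    eval = config$eval, seed = config$seed, out_dir = config$out_dir,
    versions = list(
      vesselseg = as.character(utils::packageVersion("vesselseg")),
      r = R.version.string))
  yaml::write_yaml(run_manifest, file.path(config$out_dir, "run.yaml"))
  invisible(list(pre = pre, train = tr, seg = seg, eval = ev,
                 aggregate = ev$aggregate, wall_time = times))
}
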