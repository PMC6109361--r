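# Volume-level I/O and the end-to-end pipeline:
# phantom/ingest -> degrade -> patches -> train -> reconstruct -> evaluate.

#' Read a volume (+ mask) as a `labeled_volume`
#'
#' Intensities are min-max normalized to `[0,1]` on read; the original
#' range is recorded (`intensity_range`) for metric rescaling. Without a
#' mask file the mask is derived by nonzero thresholding (with a warning
#' and a full mask if every voxel is nonzero). Labels are not stored in
#' NIfTI exports; the label array of an ingested volume is the mask.
#'
#' @param path intensity NIfTI (`.nii`/`.nii.gz`)
#' @param mask_path optional companion mask NIfTI
#' @return a `labeled_volume`
#' @export
read_volume <- function(path, mask_path = NULL) {
  nii <- read_nifti(path)
  rng <- range(nii$data)
  intensity <- if (diff(rng) > 0) (nii$data - rng[1]) / diff(rng) else
    nii$data * 0
  if (!is.null(mask_path)) {
    mask <- read_nifti(mask_path)$data > 0
    if (!identical(dim(mask), dim(intensity))) {
      stop("mask and volume dimensions differ")
    }
  } else {
    mask <- nii$data != 0
    if (all(mask)) {
      warning("no mask supplied and volume is all-nonzero; using full mask")
    }
  }
  structure(
    list(intensity = intensity, labels = array(as.integer(mask), dim(mask)),
         mask = mask, spacing = nii$spacing, intensity_range = rng),
    class = "labeled_volume"
  )
}

#' Write a `labeled_volume` as intensity + mask NIfTI files
#'
#' @param vol a `labeled_volume`
#' @param path intensity output (`.nii`/`.nii.gz`)
#' @param mask_path mask output; default derived from `path`
#'   (`*_mask.nii[.gz]`)
#' @export
write_volume <- function(vol, path, mask_path = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (is.null(mask_path)) {
    mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  }
  write_nifti(vol$intensity, path, vol$spacing, "float32")
  write_nifti(array(as.double(vol$mask), dim(vol$mask)), mask_path,
              vol$spacing, "uint8")
  invisible(c(path, mask_path))
}

#' Slice-wise network reconstruction of a volume
#'
#' Each axial slice is (optionally) bicubically pre-upsampled to the target
#' grid and passed through the network whole — fully convolutional, no
#' patch stitching. Output intensities are clipped to `[0,1]` and zeroed
#' outside the mask is NOT enforced (the network output is reported as-is
#' inside the volume; metrics are mask-restricted anyway).
#'
#' @param vol a `labeled_volume` already on the HR grid (the pre-upsampling
#'   convention), or on the LR grid with `pre_upsample = TRUE`
#' @param params trained `network_params`
#' @param spec a [degrade_spec()]; its `scale` sets the upsampling factor
#'   when `pre_upsample` is `TRUE`
#' @param pre_upsample bicubically enlarge slices by `spec$scale` first
#' @return a `labeled_volume` with the reconstructed intensity
#' @export
super_resolve <- function(vol, params, spec = NULL, pre_upsample = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"),
            inherits(params, "network_params"))
  d <- dim(vol$intensity)
  rf <- max(vapply(layer_table(params$spec), function(e) e$layer$size, 0))
  target <- if (pre_upsample) {
    stopifnot(inherits(spec, "degrade_spec"))
    c(d[1:2] * spec$scale, d[3])
  } else {
    d
  }
  if (target[1] < rf || target[2] < rf) {
    stop(sprintf("slice %dx%d smaller than the largest kernel (%d)",
                 target[1], target[2], rf))
  }
  out <- array(0, target)
  mask <- array(FALSE, target)
  for (s in seq_len(d[3])) {
    sl <- vol$intensity[, , s]
    msl <- vol$mask[, , s]
    if (pre_upsample) {
      sl <- clip01(resize_bicubic(sl, target[1:2], antialias = FALSE))
      msl <- resize_bicubic(matrix(as.double(msl), d[1], d[2]),
                            target[1:2], antialias = FALSE) > 0.5
    }
    out[, , s] <- clip01(mfcn_forward(params, sl))
    mask[, , s] <- msl
  }
  structure(
    list(intensity = out, labels = array(as.integer(mask), target),
         mask = mask, spacing = vol$spacing),
    class = "labeled_volume"
  )
}

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory
#' @param input optional path to an input volume NIfTI (with `mask` path);
#'   when `NULL` a phantom cohort is generated
#' @param mask optional mask path for `input`
#' @param phantom a [phantom_spec()] for generated cohorts
#' @param n_subjects cohort size when generating
#' @param n_val held-out subjects for validation
#' @param degrade a [degrade_spec()]
#' @param network an `mfcn_spec`
#' @param training a [train_spec()]
#' @param metrics a [metric_spec()]
#' @param n_patches patch pairs per training slice
#' @param seed global seed; recorded in every artifact
#' @return object of class `run_config`
#' @export
run_config <- function(out_dir, input = NULL, mask = NULL,
                       phantom = phantom_spec(), n_subjects = 4L,
                       n_val = 1L, degrade = degrade_spec(2L),
                       network = reduced_baseline_spec(),
                       training = train_spec(lr = 1e-4, iterations = 200L),
                       metrics = metric_spec(), n_patches = 200L,
                       seed = 1L) {
  if (!is.null(input) && !file.exists(input)) {
    stop(sprintf("input volume not found: %s", input))
  }
  if (!is.null(mask) && !file.exists(mask)) {
    stop(sprintf("mask not found: %s", mask))
  }
  structure(
    list(out_dir = out_dir, input = input, mask = mask, phantom = phantom,
         n_subjects = as.integer(n_subjects), n_val = as.integer(n_val),
         degrade = degrade, network = network, training = training,
         metrics = metrics, n_patches = as.integer(n_patches),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Generates (or ingests) volumes, degrades them, extracts training
#' patches, trains the configured network, reconstructs the held-out
#' volumes and evaluates bicubic vs network reconstruction. Writes a
#' manifest (config hash, seed, spec hashes), the trained network, the
#' training trace CSV and the metric report into `out_dir`. With
#' `scale = 1` and no blur the task is the identity; this is detected and
#' flagged in the manifest.
#'
#' @param config a [run_config()]
#' @return the output directory, invisibly; the metric report is attached
#'   as attribute `"report"` and the trace as `"trace"`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  vols <- pipeline_stage("ingest", {
    if (is.null(config$input)) {
      make_cohort(config$n_subjects, config$phantom, seed = config$seed)
    } else {
      list(read_volume(config$input, config$mask))
    }
  })
  n_val <- min(config$n_val, length(vols) - 1L)
  train_vols <- vols[seq_len(length(vols) - n_val)]
  val_vols <- if (n_val > 0) vols[(length(vols) - n_val + 1):length(vols)]
              else vols[length(vols)]

  degraded <- pipeline_stage("degrade", {
    list(train = lapply(train_vols, degrade_volume, spec = config$degrade),
         val = lapply(val_vols, degrade_volume, spec = config$degrade))
  })

  data <- pipeline_stage("patches", {
    sets <- list()
    for (i in seq_along(degraded$train)) {
      pairs <- degraded$train[[i]]
      mid <- pairs[[ceiling(length(pairs) / 2)]]
      sets[[i]] <- extract_patch_pairs(
        mid, config$n_patches, seed = config$seed + i
      )
    }
    patchset_bind(sets)
  })

  val_pairs <- pipeline_stage("validation-slices", {
    lapply(degraded$val, function(pairs) pairs[[ceiling(length(pairs) / 2)]])
  })

  fit <- pipeline_stage("train", {
    ts <- config$training
    ts$seed <- config$seed
    net <- build_network(config$network, seed = config$seed)
    train(net, data, val_pairs, ts)
  })

  recon <- pipeline_stage("reconstruct", {
    lapply(val_pairs, function(pair) clip01(mfcn_forward(fit$params, pair$lr)))
  })

  report <- pipeline_stage("evaluate", {
    evaluate_methods(
      hr = lapply(val_pairs, `[[`, "hr"),
      reconstructions = list(
        bicubic = lapply(val_pairs, `[[`, "lr"),
        mfcn = recon
      ),
      mask = lapply(val_pairs, `[[`, "mask"),
      spec = config$metrics, scale_factor = config$degrade$scale
    )
  })

  identity_task <- config$degrade$scale == 1L &&
    config$degrade$noise_sigma == 0 && config$degrade$blur == "bicubic"
  if (identity_task) {
    warning("scale = 1 with no blur/noise: degradation is the identity; ",
            "bicubic metrics are sentinels")
  }

  save_network(fit$params, file.path(config$out_dir, "network.rds"))
  write_trace_csv(fit$trace, file.path(config$out_dir, "trace.csv"))
  write_metrics_report(report, file.path(config$out_dir, "metrics"))
  write_mfcn_spec(config$network, file.path(config$out_dir, "network.json"))
  manifest <- list(
    seed = config$seed,
    config_hash = content_hash(config),
    network_hash = content_hash(config$network),
    degrade = unclass(config$degrade),
    iterations = config$training$iterations,
    identity_task = identity_task,
    batch_digest = fit$trace$batch_digest
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- config$out_dir
  attr(out, "report") <- report
  attr(out, "trace") <- fit$trace
  invisible(out)
}

#' Bicubic benchmark on a reference volume
#'
#' Degrades every masked axial slice of the given volume at the requested
#' scales and evaluates the bicubic reconstruction with brain-masked
#' metrics on the 0-255 scale — the protocol behind the published bicubic
#' benchmark rows. Intended for the BrainWeb T1 phantom
#' (181x217x181, 1 mm), which must be downloaded manually; any
#' `labeled_volume` (e.g. a synthetic stand-in) is accepted.
#'
#' @param vol a `labeled_volume`
#' @param scales integer upscale factors (default `c(2, 3, 4)`)
#' @param spec a [metric_spec()]
#' @return data frame with one row per scale: RMSE, SNR, PSNR, SSIM
#'   (mask-weighted means over slices)
#' @export
brainweb_benchmark <- function(vol, scales = c(2L, 3L, 4L),
                               spec = metric_spec()) {
  stopifnot(inherits(vol, "labeled_volume"))
  do.call(rbind, lapply(scales, function(f) {
    pairs <- degrade_volume(vol, degrade_spec(f))
    rep <- evaluate_methods(
      hr = lapply(pairs, `[[`, "hr"),
      reconstructions = list(bicubic = lapply(pairs, `[[`, "lr")),
      mask = lapply(pairs, `[[`, "mask"),
      spec = spec, scale_factor = f
    )
    rep$summary
  }))
}
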