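# The degradation model L = DSH + e and patch-pair extraction. Following the
# pre-upsampling convention, the low-resolution observation is immediately
# interpolated back to the high-resolution grid with a bicubic kernel, so the
# stored `lr` slice doubles as the bicubic-baseline reconstruction.

#' Degradation operator settings
#'
#' The blur `S` is either implicit in an antialiased bicubic downsampler
#' (`"bicubic"`, the SRCNN-lineage convention and the default) or an explicit
#' gaussian (`"gaussian"`) followed by plain bicubic decimation. `D` is
#' decimation by the integer factor `scale`; `e` is optional additive
#' gaussian noise (default 0, matching the simulated experiments).
#'
#' @param scale integer upscale factor f (>= 1; 2, 3 or 4 in practice)
#' @param blur `"bicubic"` or `"gaussian"`
#' @param blur_sigma gaussian sigma in pixels; default `0.5 * scale` when the
#'   gaussian blur is selected
#' @param noise_sigma additive noise sigma in `[0,1]` intensity units
#' @return object of class `degrade_spec`
#' @export
degrade_spec <- function(scale = 3L, blur = c("bicubic", "gaussian"),
                         blur_sigma = NULL, noise_sigma = 0) {
  blur <- match.arg(blur)
  stopifnot_scalar_int(scale, "scale", min = 1)
  if (blur == "gaussian") {
    if (is.null(blur_sigma)) blur_sigma <- 0.5 * scale
    if (blur_sigma <= 0) stop("gaussian blur requires sigma > 0")
  }
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  structure(
    list(
      scale = as.integer(scale), blur = blur, blur_sigma = blur_sigma,
      noise_sigma = noise_sigma, interp = "bicubic"
    ),
    class = "degrade_spec"
  )
}

#' Degrade one slice and re-interpolate to the original grid
#'
#' Applies blur + f-fold downsampling + bicubic upsampling; the result lives
#' on the same grid as `hr` and is the bicubic-baseline reconstruction under
#' the pre-upsampling scheme. With `scale = 1`, bicubic blur and zero noise
#' the operator is the identity.
#'
#' @param hr numeric matrix in `[0,1]`
#' @param mask logical matrix, same shape
#' @param spec a [degrade_spec()]
#' @return a `slice_pair`: list with `hr`, `lr`, `mask`, `spec`
#' @export
degrade_slice <- function(hr, mask, spec) {
  stopifnot(is.matrix(hr), inherits(spec, "degrade_spec"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(hr), ncol(hr))
  stopifnot(identical(dim(hr), dim(mask)))
  f <- spec$scale
  if (f > nrow(hr) || f > ncol(hr)) {
    stop(sprintf("scale %d exceeds image dims %dx%d", f, nrow(hr), ncol(hr)))
  }
  if (min(hr) < -1e-9 || max(hr) > 1 + 1e-9) stop("hr must lie in [0,1]")
  lo_dim <- pmax(1L, as.integer(ceiling(dim(hr) / f)))
  if (spec$blur == "gaussian") {
    blurred <- blur_gaussian(hr, spec$blur_sigma)
    lo <- if (f == 1) blurred else resize_bicubic(blurred, lo_dim,
                                                  antialias = FALSE)
  } else {
    lo <- if (f == 1) hr else resize_bicubic(hr, lo_dim, antialias = TRUE)
  }
  lr <- if (f == 1) lo else resize_bicubic(lo, dim(hr), antialias = FALSE)
  if (spec$noise_sigma > 0) {
    lr <- lr + matrix(rnorm(length(lr), 0, spec$noise_sigma), nrow(lr))
  }
  lr <- clip01(lr)
  structure(list(hr = hr, lr = lr, mask = mask > 0, spec = spec),
            class = "slice_pair")
}

#' Degrade every masked axial slice of a volume
#'
#' @param vol a `labeled_volume`
#' @param spec a [degrade_spec()]
#' @return list of `slice_pair`, one per axial slice intersecting the mask;
#'   each carries its slice index as attribute `"slice"`
#' @export
degrade_volume <- function(vol, spec) {
  stopifnot(inherits(vol, "labeled_volume"))
  keep <- which(apply(vol$mask, 3, any))
  if (!length(keep)) stop("no axial slice intersects the mask")
  lapply(keep, function(s) {
    p <- degrade_slice(vol$intensity[, , s], vol$mask[, , s], spec)
    attr(p, "slice") <- s
    p
  })
}

#' Extract aligned low/high-resolution patch pairs from a slice
#'
#' Samples `n_per_slice` patch centers uniformly with replacement among
#' pixels that lie inside the mask and whose full patch fits inside the
#' image (no padding). Coordinates are centers, 1-based `(row, col)`.
#'
#' @param pair a `slice_pair`
#' @param n_per_slice number of pairs (default 600, the per-slice sampling
#'   density used for training)
#' @param patch_size odd patch side (default 33)
#' @param seed integer seed making the draw reproducible
#' @return a `patch_set`: list with arrays `lr`, `hr`
#'   (`patch_size x patch_size x m`), data frame `coords`
#'   (`slice`, `row`, `col`), `patch_size`, `m`, `seed`
#' @export
extract_patch_pairs <- function(pair, n_per_slice = 600L, patch_size = 33L,
                                seed = 1L) {
  stopifnot(inherits(pair, "slice_pair"))
  stopifnot_scalar_int(n_per_slice, "n_per_slice", min = 1)
  if (patch_size %% 2 == 0) stop("patch_size must be odd")
  hw <- (patch_size - 1L) %/% 2L
  d <- dim(pair$hr)
  if (d[1] < patch_size || d[2] < patch_size) {
    stop("slice smaller than one patch")
  }
  admissible <- pair$mask
  admissible[c(seq_len(hw), (d[1] - hw + 1):d[1]), ] <- FALSE
  admissible[, c(seq_len(hw), (d[2] - hw + 1):d[2])] <- FALSE
  centers <- which(admissible, arr.ind = TRUE)
  if (!nrow(centers)) {
    stop(sprintf(
      "no admissible %dx%d patch center (mask has %d pixels)",
      patch_size, patch_size, sum(pair$mask)
    ))
  }
  pick <- with_seed(seed,
                    sample.int(nrow(centers), n_per_slice, replace = TRUE))
  lr <- array(0, c(patch_size, patch_size, n_per_slice))
  hr <- array(0, c(patch_size, patch_size, n_per_slice))
  for (i in seq_len(n_per_slice)) {
    r <- centers[pick[i], 1]
    cc <- centers[pick[i], 2]
    rows <- (r - hw):(r + hw)
    cols <- (cc - hw):(cc + hw)
    lr[, , i] <- pair$lr[rows, cols]
    hr[, , i] <- pair$hr[rows, cols]
  }
  slice_idx <- attr(pair, "slice")
  if (is.null(slice_idx)) slice_idx <- NA_integer_
  structure(
    list(
      lr = lr, hr = hr,
      coords = data.frame(
        slice = slice_idx, row = centers[pick, 1], col = centers[pick, 2]
      ),
      patch_size = as.integer(patch_size), m = as.integer(n_per_slice),
      seed = as.integer(seed)
    ),
    class = "patch_set"
  )
}

#' Concatenate patch sets
#'
#' @param sets list of `patch_set` objects with a common patch size
#' @return one combined `patch_set`
#' @export
patchset_bind <- function(sets) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "patch_set")))
  ps <- unique(vapply(sets, `[[`, 1L, "patch_size"))
  if (length(ps) != 1) stop("patch sizes differ")
  lr <- array(unlist(lapply(sets, `[[`, "lr"), use.names = FALSE),
              c(ps, ps, sum(vapply(sets, `[[`, 1L, "m"))))
  hr <- array(unlist(lapply(sets, `[[`, "hr"), use.names = FALSE), dim(lr))
  structure(
    list(
      lr = lr, hr = hr, coords = do.call(rbind, lapply(sets, `[[`, "coords")),
      patch_size = ps, m = dim(lr)[3], seed = sets[[1]]$seed
    ),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d pairs of %dx%d patches (seed %d)\n",
              x$m, x$patch_size, x$patch_size, x$seed))
  invisible(x)
}

#' Save / load a patch set as a single file
#'
#' One portable container holding the two stacked patch arrays, the
#' coordinate table and the metadata (R serialization; see the package
#' vignette for the format decision).
#'
#' @param x a `patch_set`
#' @param path file path
#' @return `load_patchset` returns the `patch_set`
#' @export
save_patchset <- function(x, path) {
  stopifnot(inherits(x, "patch_set"))
  saveRDS(unclass(x), path)
  invisible(path)
}

#' @rdname save_patchset
#' @export
load_patchset <- function(path) {
  structure(readRDS(path), class = "patch_set")
}
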