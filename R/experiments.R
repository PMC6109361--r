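# Architecture-analysis harnesses: the published configuration grammar as
# named variants, paired-seed sweeps, the MFCN-vs-plain-CNN convergence
# comparison, and feature-map dumps. Cross-variant comparisons share seeds
# and mini-batch order (the batch RNG stream is independent of the
# initialization stream), so differences are attributable to architecture.

#' The published configuration variants
#'
#' Named `mfcn_spec` objects for the baseline and the ablation grid:
#' kernel-size variants (`s713`, `s957`, `s1159`), kernel-count variants
#' (`n16321`, `n64961`), the 3x3 sub-path variant (`S3`), the two-layer
#' sub-path variant (`L2`), depth variants (`U1`, `U3`) and the
#' ReLU-before-fusion ablation of the baseline (`BL_relu_fusion`). The
#' tables only pin the sub-path grammar for `U1`/`U3`; main paths follow
#' the baseline pattern (see the vignette).
#'
#' @return named list of `mfcn_spec`
#' @export
builtin_variants <- function() {
  mk <- function(mains, subs, recon, relu_fusion = FALSE) {
    mfcn_spec(
      mapply(function(m, s) {
        mfu_spec(m, if (is.null(s)) list() else list(s),
                 relu_before_fusion = relu_fusion)
      }, mains, subs, SIMPLIFY = FALSE, USE.NAMES = FALSE),
      recon = recon
    )
  }
  list(
    MFCN_BL = baseline_spec(),
    s713 = mk(c("7/32", "1/64"), list("1/32", "1/64"), "3/1"),
    s957 = mk(c("9/32", "5/64"), list("1/32", "1/64"), "7/1"),
    s1159 = mk(c("11/32", "5/64"), list("1/32", "1/64"), "9/1"),
    n16321 = mk(c("9/16", "3/32"), list("1/16", "1/32"), "5/1"),
    n64961 = mk(c("9/64", "3/96"), list("1/64", "1/96"), "5/1"),
    S3 = mk(c("9/32", "3/64"), list("3/32", "3/64"), "5/1"),
    L2 = mk(c("9/32", "3/64"),
            list(c("1/32", "1/32"), c("1/64", "1/64")), "5/1"),
    U1 = mk("9/32", list("1/32"), "5/1"),
    U3 = mk(c("9/32", "3/32", "3/64"), list("1/32", "1/32", "1/64"), "5/1"),
    BL_relu_fusion = mk(c("9/32", "3/64"), list("1/32", "1/64"), "5/1",
                        relu_fusion = TRUE)
  )
}

#' Train a grid of variants over shared data and seeds
#'
#' Every `(variant, seed)` pair is trained on identical data with identical
#' mini-batch order per seed. Divergent runs are recorded, not fatal.
#'
#' @param variants named list of `mfcn_spec`
#' @param data a `patch_set`
#' @param val list of `slice_pair` for validation PSNR
#' @param tspec a [train_spec()]; its `seed` field is overridden per run
#' @param seeds integer vector of seeds
#' @param out_dir optional directory; each finished run is saved there
#'   immediately (`<variant>_seed<seed>.rds`), so interrupted sweeps resume
#' @return a `sweep_result`: list with data frame `results` (variant, seed,
#'   parameters, final loss, final/best val PSNR, convergence index,
#'   diverged flag) and `traces` (named list of `train_trace`)
#' @export
run_sweep <- function(variants, data, val, tspec, seeds = 1L,
                      out_dir = NULL) {
  stopifnot(length(variants) >= 1, !is.null(names(variants)))
  rows <- list()
  traces <- list()
  for (vn in names(variants)) {
    for (sd in seeds) {
      key <- sprintf("%s_seed%d", vn, sd)
      cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(key, ".rds"))
      fit <- NULL
      if (!is.null(cache) && file.exists(cache)) fit <- readRDS(cache)
      if (is.null(fit)) {
        ts <- tspec
        ts$seed <- as.integer(sd)
        net <- build_network(variants[[vn]], seed = sd)
        fit <- tryCatch(
          train(net, data, val, ts),
          error = function(e) list(error = conditionMessage(e))
        )
        if (!is.null(cache)) {
          dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
          saveRDS(fit, cache)
        }
      }
      diverged <- !is.null(fit$error)
      rows[[key]] <- data.frame(
        variant = vn, seed = sd,
        parameters = count_parameters(variants[[vn]]),
        final_loss = if (diverged) NA_real_ else tail(fit$trace$loss, 1),
        final_psnr = if (diverged || !nrow(fit$trace$val)) NA_real_ else
          tail(fit$trace$val$psnr, 1),
        best_psnr = if (diverged || !nrow(fit$trace$val)) NA_real_ else
          max(fit$trace$val$psnr),
        convergence = if (diverged || !nrow(fit$trace$val)) NA_integer_ else
          convergence_iteration(fit$trace),
        diverged = diverged
      )
      if (!diverged) traces[[key]] <- fit$trace
    }
  }
  structure(list(results = do.call(rbind, rows), traces = traces),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Paired convergence comparison: MFCN vs its plain-CNN counterpart
#'
#' Trains `spec` and `plain_cnn_spec(spec)` with shared per-seed data,
#' initialization seed and batch order, and reports the convergence index
#' of each (see [convergence_iteration()]) plus the per-seed sign of the
#' difference. Batch-order pairing is audited via the trace batch digests.
#'
#' @param spec an `mfcn_spec` with at least one sub-path
#' @param data a `patch_set`
#' @param val list of `slice_pair`
#' @param tspec a [train_spec()]
#' @param seeds integer vector of seeds
#' @param epsilon plateau tolerance passed to [convergence_iteration()]
#' @return list with data frame `results` (per seed: convergence indices,
#'   final PSNRs, `mfcn_no_slower`, `batch_order_matched`) and the paired
#'   `traces`
#' @export
compare_convergence <- function(spec, data, val, tspec, seeds = 1:3,
                                epsilon = 0.02) {
  stopifnot(inherits(spec, "mfcn_spec"))
  if (!sum(lengths(lapply(spec$units, `[[`, "subpaths")))) {
    stop("spec has no sub-path to remove")
  }
  pl <- plain_cnn_spec(spec)
  rows <- list()
  traces <- list()
  for (sd in seeds) {
    ts <- tspec
    ts$seed <- as.integer(sd)
    fit_m <- train(build_network(spec, seed = sd), data, val, ts)
    fit_p <- train(build_network(pl, seed = sd), data, val, ts)
    ci_m <- convergence_iteration(fit_m$trace, epsilon)
    ci_p <- convergence_iteration(fit_p$trace, epsilon)
    rows[[as.character(sd)]] <- data.frame(
      seed = sd, conv_mfcn = ci_m, conv_plain = ci_p,
      psnr_mfcn = tail(fit_m$trace$val$psnr, 1),
      psnr_plain = tail(fit_p$trace$val$psnr, 1),
      mfcn_no_slower = ci_m <= ci_p,
      batch_order_matched = identical(fit_m$trace$batch_digest,
                                      fit_p$trace$batch_digest)
    )
    traces[[sprintf("mfcn_seed%d", sd)]] <- fit_m$trace
    traces[[sprintf("plain_seed%d", sd)]] <- fit_p$trace
  }
  list(results = do.call(rbind, rows), traces = traces)
}

#' Dump per-layer feature-map montages for one input
#'
#' Writes, per MFU, three plain-text PGM montages: the main-path maps (after
#' ReLU), the summed sub-path maps, and the fused maps, each tile
#' normalized for display. Also returns the raw arrays so the fusion
#' identity (fused = main + sub) can be re-verified numerically.
#'
#' @param params a `network_params`
#' @param image single-channel input matrix
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list per unit with arrays `main`, `sub`, `fused`
#'   and the written file names
#' @export
dump_feature_maps <- function(params, image, out_dir) {
  stopifnot(inherits(params, "network_params"), is.matrix(image))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- params$spec
  layers <- params$layers
  x <- as_batch(image)
  out <- list()
  k <- 1L
  for (i in seq_along(spec$units)) {
    u <- spec$units[[i]]
    main <- conv_fwd(x, layers[[k]], relu = TRUE)
    k <- k + 1L
    sub <- array(0, dim(main))
    for (j in seq_along(u$subpaths)) {
      z <- x
      sp <- u$subpaths[[j]]
      for (l in seq_along(sp)) {
        z <- conv_fwd(z, layers[[k]], relu = sp[[l]]$relu)
        k <- k + 1L
      }
      sub <- sub + z
    }
    fused <- main + sub
    files <- c(
      main = file.path(out_dir, sprintf("mfu%d_main.pgm", i)),
      sub = file.path(out_dir, sprintf("mfu%d_subpath.pgm", i)),
      fused = file.path(out_dir, sprintf("mfu%d_fused.pgm", i))
    )
    write_pgm_montage(main[, , , 1], files["main"])
    write_pgm_montage(sub[, , , 1], files["sub"])
    write_pgm_montage(fused[, , , 1], files["fused"])
    out[[sprintf("mfu%d", i)]] <- list(
      main = main[, , , 1], sub = sub[, , , 1], fused = fused[, , , 1],
      files = files
    )
    x <- fused
  }
  invisible(out)
}
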