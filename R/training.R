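# Euclidean-loss SGD training. The backward pass mirrors mfcn_forward's
# traversal exactly; gradients at a fusion junction flow unchanged into the
# main path (through its ReLU mask) and into every sub-path, and the input
# gradient is their sum.

#' Training settings
#'
#' @param lr learning rate. The default keeps the published recipe value
#'   0.001, but note that under the `1/(2B)` Euclidean loss on 33x33
#'   patches the loss curvature is of order the patch pixel count and SGD
#'   at 0.001 reliably diverges as soon as the fit starts to improve
#'   (see the package vignette); the SRCNN-lineage rate `1e-4` is the
#'   empirically stable choice and is what [run_config()] uses.
#' @param batch mini-batch size (default 32)
#' @param momentum classical momentum coefficient (default 0.9)
#' @param iterations number of SGD iterations (>= 0)
#' @param val_interval evaluate validation PSNR every this many iterations
#' @param seed integer seed driving mini-batch shuffling
#' @return object of class `train_spec`
#' @export
train_spec <- function(lr = 0.001, batch = 32L, momentum = 0.9,
                       iterations = 1000L, val_interval = 100L, seed = 1L,
                       precision = c("single", "double")) {
  if (lr <= 0) stop("learning rate must be > 0")
  stopifnot_scalar_int(batch, "batch", min = 1)
  stopifnot_scalar_int(iterations, "iterations", min = 0)
  stopifnot_scalar_int(val_interval, "val_interval", min = 1)
  precision <- match.arg(precision)
  structure(
    list(lr = lr, batch = as.integer(batch), momentum = momentum,
         iterations = as.integer(iterations),
         val_interval = as.integer(val_interval), seed = as.integer(seed),
         precision = precision, loss = "sum-of-squares / 2B"),
    class = "train_spec"
  )
}

#' Euclidean loss and its gradient
#'
#' `loss = (1 / 2B) * sum_b ||pred_b - target_b||^2` with `B` the batch
#' size (last array dimension; 1 for plain matrices); the gradient with
#' respect to `pred` is `(pred - target) / B`. This is the Caffe
#' EuclideanLoss convention, so reported magnitudes are per-patch
#' half-sum-of-squares.
#'
#' @param pred,target same-shaped numeric arrays
#' @return list with `loss` (scalar) and `grad` (array like `pred`)
#' @export
euclidean_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) {
    stop("pred and target shapes differ")
  }
  B <- if (length(dim(pred)) == 4) dim(pred)[4] else 1L
  d <- pred - target
  list(loss = sum(d^2) / (2 * B), grad = d / B)
}

# Backward pass. `gy` is the loss gradient w.r.t. the network output.
# Returns list(grads = per-layer list(w, b) in layer order, gx).
mfcn_backward <- function(params, fwd, gy) {
  spec <- params$spec
  layers <- params$layers
  nlay <- length(layers)
  grads <- vector("list", nlay)
  bwd <- cpp_conv2d_bwd(fwd$cache$recon_input, layers[[nlay]]$w, gy)
  grads[[nlay]] <- list(w = bwd$gw, b = bwd$gb)
  gcur <- bwd$gx
  k <- nlay - 1L  # walk the flat layer list backwards
  for (i in rev(seq_along(spec$units))) {
    u <- spec$units[[i]]
    uc <- fwd$cache$units[[i]]
    # sub-paths occupy the trailing positions of this unit's block
    nsub_layers <- sum(lengths(u$subpaths))
    main_k <- k - nsub_layers
    gpre <- gcur * (uc$act_main > 0)
    bwd <- cpp_conv2d_bwd(uc$input, layers[[main_k]]$w, gpre)
    grads[[main_k]] <- list(w = bwd$gw, b = bwd$gb)
    ginput <- bwd$gx
    kk <- k
    for (j in rev(seq_along(u$subpaths))) {
      sp <- u$subpaths[[j]]
      sc <- uc$sub[[j]]
      gz <- gcur
      for (l in rev(seq_along(sp))) {
        if (sp[[l]]$relu) gz <- gz * (sc$act[[l]] > 0)
        bwd <- cpp_conv2d_bwd(sc$inputs[[l]], layers[[kk]]$w, gz)
        grads[[kk]] <- list(w = bwd$gw, b = bwd$gb)
        gz <- bwd$gx
        kk <- kk - 1L
      }
      ginput <- ginput + gz
    }
    gcur <- ginput
    k <- main_k - 1L
  }
  list(grads = grads, gx = gcur)
}

#' Flatten network parameters to a numeric vector (and back)
#'
#' Fixed traversal order (per unit: main, then sub-path layers; recon last;
#' kernels before biases within a layer). Used for finite-difference
#' gradient checks and checkpoint diffing.
#'
#' @param params a `network_params`
#' @param v numeric vector of length `count_parameters(spec)`
#' @return `flatten_params`: numeric vector; `unflatten_params`: a
#'   `network_params`
#' @export
flatten_params <- function(params) {
  unlist(lapply(params$layers, function(l) c(as.vector(l$w), l$b)),
         use.names = FALSE)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(params, v) {
  pos <- 0L
  for (i in seq_along(params$layers)) {
    l <- params$layers[[i]]
    nw <- length(l$w)
    nb <- length(l$b)
    params$layers[[i]]$w <- array(v[pos + seq_len(nw)], dim(l$w))
    params$layers[[i]]$b <- v[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  stopifnot(pos == length(v))
  params
}

patchset_batch_arrays <- function(data) {
  ps <- data$patch_size
  list(x = array(data$lr, c(ps, ps, 1L, data$m)),
       y = array(data$hr, c(ps, ps, 1L, data$m)))
}

validation_psnr <- function(params, val, mspec) {
  mean(vapply(val, function(pair) {
    out <- clip01(mfcn_forward(params, pair$lr))
    psnr(pair$hr, out, pair$mask, mspec)
  }, 0))
}

#' Train a network by SGD on a patch set
#'
#' Mini-batches are drawn by seeded epoch-wise shuffling (reshuffled when
#' the set is exhausted). Updates use classical momentum:
#' `v <- momentum * v - lr * g; w <- w + v`. Training aborts with an error
#' naming the iteration if the loss becomes non-finite. Runs are
#' deterministic for a fixed seed and platform (floating-point order is
#' fixed). Two numerically equivalent backends exist: `precision =
#' "single"` (default) runs forward/backward/update in a float32 engine —
#' the precision the Caffe lineage actually trained in — while `"double"`
#' runs the reference R path used by the gradient-correctness tests; both
#' see identical mini-batch sequences for a given seed.
#'
#' @param params initial `network_params` from [build_network()]
#' @param data a `patch_set`
#' @param val list of `slice_pair` held out for validation PSNR (may be
#'   empty)
#' @param spec a [train_spec()]
#' @return list with `params` (trained) and `trace` (class `train_trace`:
#'   per-iteration `loss`, data frame `val` of `(iteration, psnr)`, the
#'   `seed`, `iterations`, and `batch_digest`, a content hash of the
#'   mini-batch index sequence for paired-run audits)
#' @export
train <- function(params, data, val = list(), spec = train_spec()) {
  stopifnot(inherits(params, "network_params"), inherits(data, "patch_set"),
            inherits(spec, "train_spec"))
  if (data$m < 1) stop("empty patch set")
  mspec <- metric_spec()
  losses <- numeric(spec$iterations)
  val_it <- integer(0)
  val_psnr <- numeric(0)
  batch_seq <- integer(0)
  with_seed(spec$seed, {
    # epoch-wise shuffling shared by both precision backends
    perm <- sample.int(data$m)
    pos <- 1L
    next_batch <- function() {
      idx <- integer(0)
      while (length(idx) < spec$batch) {
        take <- min(spec$batch - length(idx), length(perm) - pos + 1L)
        idx <- c(idx, perm[pos:(pos + take - 1L)])
        pos <<- pos + take
        if (pos > length(perm)) {
          perm <<- sample.int(data$m)
          pos <<- 1L
        }
      }
      idx
    }
    # iteration indices after which validation PSNR is evaluated
    val_points <- if (length(val) && spec$iterations > 0) {
      unique(c(seq_len(spec$iterations %/% spec$val_interval) *
                 spec$val_interval, spec$iterations))
    } else if (spec$iterations > 0) {
      spec$iterations
    } else {
      integer(0)
    }

    if (spec$precision == "single") {
      tab <- layer_table(params$spec)
      meta <- lapply(tab, function(e) {
        list(s = e$layer$size, cin = e$cin, cout = e$layer$count,
             relu = e$layer$relu, unit = e$unit, kind = e$kind,
             sub_id = e$sub_id)
      })
      ps <- data$patch_size
      eng <- cpp_trainer_new(meta, params$layers,
                             as.double(data$lr), as.double(data$hr),
                             ps, ps)
      done <- 0L
      for (vp in val_points) {
        k <- vp - done
        idx <- vapply(seq_len(k), function(i) next_batch(),
                      integer(spec$batch))
        idx <- matrix(idx, nrow = spec$batch)
        batch_seq <- c(batch_seq, as.vector(idx))
        res <- cpp_trainer_run(eng, idx, spec$lr, spec$momentum)
        losses[done + seq_len(k)] <- res$losses
        if (res$diverged_at > 0) {
          stop(sprintf(
            "training diverged (non-finite loss) at iteration %d",
            done + res$diverged_at
          ), call. = FALSE)
        }
        done <- vp
        params$layers <- stats::setNames(cpp_trainer_params(eng),
                                         names(params$layers))
        if (length(val)) {
          val_it <- c(val_it, vp)
          val_psnr <- c(val_psnr, validation_psnr(params, val, mspec))
        }
      }
      if (spec$iterations > 0 && done == 0L) {
        # no validation grid: single chunk
        idx <- vapply(seq_len(spec$iterations), function(i) next_batch(),
                      integer(spec$batch))
        idx <- matrix(idx, nrow = spec$batch)
        batch_seq <- c(batch_seq, as.vector(idx))
        res <- cpp_trainer_run(eng, idx, spec$lr, spec$momentum)
        losses[] <- res$losses
        if (res$diverged_at > 0) {
          stop(sprintf(
            "training diverged (non-finite loss) at iteration %d",
            res$diverged_at
          ), call. = FALSE)
        }
        params$layers <- stats::setNames(cpp_trainer_params(eng),
                                         names(params$layers))
      }
    } else {
      arrs <- patchset_batch_arrays(data)
      nlay <- length(params$layers)
      vel <- lapply(params$layers, function(l) {
        list(w = array(0, dim(l$w)), b = numeric(length(l$b)))
      })
      for (it in seq_len(spec$iterations)) {
        idx <- next_batch()
        batch_seq <- c(batch_seq, idx)
        xb <- arrs$x[, , , idx, drop = FALSE]
        yb <- arrs$y[, , , idx, drop = FALSE]
        fwd <- mfcn_forward(params, xb, cache = TRUE)
        ls <- euclidean_loss(fwd$y, yb)
        losses[it] <- ls$loss
        if (!is.finite(ls$loss)) {
          stop(sprintf(
            "training diverged (non-finite loss) at iteration %d", it
          ), call. = FALSE)
        }
        bk <- mfcn_backward(params, fwd, ls$grad)
        for (li in seq_len(nlay)) {
          vel[[li]]$w <- spec$momentum * vel[[li]]$w -
            spec$lr * bk$grads[[li]]$w
          vel[[li]]$b <- spec$momentum * vel[[li]]$b -
            spec$lr * bk$grads[[li]]$b
          params$layers[[li]]$w <- params$layers[[li]]$w + vel[[li]]$w
          params$layers[[li]]$b <- params$layers[[li]]$b + vel[[li]]$b
        }
        if (it %in% val_points && length(val)) {
          val_it <- c(val_it, it)
          val_psnr <- c(val_psnr, validation_psnr(params, val, mspec))
        }
      }
    }
  })
  trace <- structure(
    list(loss = losses, val = data.frame(iteration = val_it, psnr = val_psnr),
         seed = spec$seed, iterations = spec$iterations,
         batch_digest = content_hash(batch_seq)),
    class = "train_trace"
  )
  list(params = params, trace = trace)
}

#' @export
print.train_trace <- function(x, ...) {
  cat(sprintf("<train_trace> %d iterations (seed %d); final loss %.4g",
              x$iterations, x$seed,
              if (x$iterations) x$loss[x$iterations] else NA))
  if (nrow(x$val)) cat(sprintf("; final val PSNR %.2f dB", tail(x$val$psnr, 1)))
  cat("\n")
  invisible(x)
}

#' Export a training trace as CSV
#'
#' @param trace a `train_trace`
#' @param path file path; columns `iteration`, `loss`, `val_psnr` (NA off
#'   the validation grid)
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "train_trace"))
  df <- data.frame(iteration = seq_len(trace$iterations), loss = trace$loss,
                   val_psnr = NA_real_)
  df$val_psnr[match(trace$val$iteration, df$iteration)] <- trace$val$psnr
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Iteration at which a validation series reaches its plateau
#'
#' The plateau is the mean of the last 10% of the series (at least one
#' point); the function returns the earliest 1-based index at which the
#' series reaches `(1 - epsilon)` times the plateau, or the series length
#' if it never does.
#'
#' @param trace a `train_trace` (its validation PSNR series is used) or a
#'   numeric series
#' @param epsilon plateau tolerance as a fraction (default 0.02)
#' @return 1-based integer index into the validation series
#' @export
convergence_iteration <- function(trace, epsilon = 0.02) {
  series <- if (inherits(trace, "train_trace")) trace$val$psnr else trace
  if (!length(series)) stop("empty validation series")
  n <- length(series)
  plateau <- mean(tail(series, max(1L, round(0.1 * n))))
  idx <- which(series >= (1 - epsilon) * plateau)[1]
  if (is.na(idx)) n else as.integer(idx)
}
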