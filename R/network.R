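# Multi-scale fusion networks (MFCNs). A multi-scale fusion unit (MFU)
# combines a main convolution path, f(x, W0) = ReLU(conv(x)), with J
# sub-paths of (usually 1x1) convolutions, fused by elementwise addition:
#
#     x_{i+1} = ReLU(conv_main(x_i)) + sum_j SP_j(x_i)
#
# The final layer of each sub-path carries no ReLU before the addition
# (removing it improves reconstruction, as in pre-activation residual
# units), and no activation follows the fusion. An MFCN stacks MFUs and a
# single-kernel reconstruction convolution. All convolutions use the
# cross-correlation convention with zero same-padding, so fusion of paths
# with different kernel sizes is well-defined and whole slices can be
# processed fully convolutionally.

#' Convolution layer description
#'
#' @param size odd kernel side `s_k`
#' @param count number of kernels `n_k`
#' @param relu apply a ReLU after the convolution
#' @return object of class `conv_layer_spec`
#' @export
conv_layer_spec <- function(size, count, relu = TRUE) {
  stopifnot_scalar_int(size, "size", min = 1)
  stopifnot_scalar_int(count, "count", min = 1)
  if (size %% 2 == 0) stop("kernel size must be odd")
  structure(list(size = as.integer(size), count = as.integer(count),
                 relu = isTRUE(relu)),
            class = "conv_layer_spec")
}

# "9/32" -> conv_layer_spec(9, 32)
parse_layer <- function(txt, relu = TRUE) {
  parts <- as.integer(strsplit(trimws(txt), "/")[[1]])
  if (length(parts) != 2 || anyNA(parts)) {
    stop(sprintf("cannot parse layer notation '%s' (expected 's/n')", txt))
  }
  conv_layer_spec(parts[1], parts[2], relu)
}

layer_txt <- function(l) sprintf("%d/%d", l$size, l$count)

#' Multi-scale fusion unit description
#'
#' @param main `conv_layer_spec` (or `"s/n"` text) of the main path; always
#'   followed by a ReLU
#' @param subpaths list of sub-paths; each sub-path is a list of
#'   `conv_layer_spec` (or a character vector of `"s/n"`). The last layer of
#'   every sub-path must match the main path's kernel count so the fusion
#'   addition is well-defined.
#' @param relu_before_fusion apply a ReLU to the last sub-path layer before
#'   the addition (the ablation variant; default `FALSE`)
#' @return object of class `mfu_spec`
#' @export
mfu_spec <- function(main, subpaths = list(), relu_before_fusion = FALSE) {
  if (is.character(main)) main <- parse_layer(main)
  stopifnot(inherits(main, "conv_layer_spec"))
  main$relu <- TRUE
  subpaths <- lapply(subpaths, function(sp) {
    if (is.character(sp)) sp <- lapply(sp, parse_layer)
    stopifnot(length(sp) >= 1,
              all(vapply(sp, inherits, TRUE, "conv_layer_spec")))
    n <- length(sp)
    for (i in seq_len(n)) sp[[i]]$relu <- i < n || isTRUE(relu_before_fusion)
    if (sp[[n]]$count != main$count) {
      stop(sprintf(
        "sub-path final kernel count %d != main path count %d (fusion)",
        sp[[n]]$count, main$count
      ))
    }
    sp
  })
  structure(list(main = main, subpaths = subpaths,
                 relu_before_fusion = isTRUE(relu_before_fusion)),
            class = "mfu_spec")
}

#' Full network description
#'
#' @param units list of [mfu_spec()] (`nMFU` of them), applied in order to a
#'   single-channel input
#' @param recon reconstruction layer, a `conv_layer_spec` (or `"s/1"` text)
#'   with one kernel and no activation
#' @return object of class `mfcn_spec`
#' @export
mfcn_spec <- function(units, recon = "5/1") {
  if (inherits(units, "mfu_spec")) units <- list(units)
  stopifnot(length(units) >= 1,
            all(vapply(units, inherits, TRUE, "mfu_spec")))
  if (is.character(recon)) recon <- parse_layer(recon, relu = FALSE)
  recon$relu <- FALSE
  if (recon$count != 1) stop("reconstruction layer must have one kernel")
  spec <- structure(list(units = units, recon = recon), class = "mfcn_spec")
  validate_mfcn(spec)
  spec
}

# Channel chaining check; returns per-unit input channel counts.
validate_mfcn <- function(spec) {
  cin <- 1L
  for (i in seq_along(spec$units)) {
    u <- spec$units[[i]]
    for (sp in u$subpaths) {
      # inner sub-path layers may use any width; only the last is pinned
      if (sp[[length(sp)]]$count != u$main$count) {
        stop(sprintf("MFU %d: sub-path output does not match main path", i))
      }
    }
    cin <- u$main$count
  }
  invisible(spec)
}

#' @export
print.mfcn_spec <- function(x, ...) {
  for (i in seq_along(x$units)) {
    u <- x$units[[i]]
    sp <- vapply(u$subpaths, function(s) {
      paste(vapply(s, layer_txt, ""), collapse = ",")
    }, "")
    cat(sprintf("MFU_%d: main %s%s%s\n", i, layer_txt(u$main),
                if (length(sp)) " + sub " else "",
                paste(sprintf("[%s]", sp), collapse = " ")))
  }
  cat(sprintf("recon: %s  (%s parameters)\n", layer_txt(x$recon),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' The baseline MFCN configuration
#'
#' Two MFUs (main 9/32 with sub-path 1/32; main 3/64 with sub-path 1/64)
#' and a 5/1 reconstruction layer: 24,897 parameters.
#'
#' @return an `mfcn_spec`
#' @export
baseline_spec <- function() {
  mfcn_spec(
    list(
      mfu_spec("9/32", list("1/32")),
      mfu_spec("3/64", list("1/64"))
    ),
    recon = "5/1"
  )
}

#' Desk-scale reduced baseline
#'
#' The baseline grammar with kernel counts shrunk for CPU budgets:
#' main 9/8 + sub 1/8; main 3/16 + sub 1/16; recon 5/1.
#'
#' @return an `mfcn_spec`
#' @export
reduced_baseline_spec <- function() {
  mfcn_spec(
    list(
      mfu_spec("9/8", list("1/8")),
      mfu_spec("3/16", list("1/16"))
    ),
    recon = "5/1"
  )
}

#' Plain stacked-CNN counterpart of an MFCN
#'
#' Removes every sub-path (J = 0 per unit), leaving the main-path
#' convolutions and the reconstruction layer: a traditional SRCNN-style
#' stack with identical main-path geometry.
#'
#' @param spec an `mfcn_spec`
#' @return an `mfcn_spec` without sub-paths
#' @export
plain_cnn_spec <- function(spec) {
  stopifnot(inherits(spec, "mfcn_spec"))
  mfcn_spec(
    lapply(spec$units, function(u) mfu_spec(u$main, list())),
    recon = layer_txt(spec$recon)
  )
}

# Flat list of layer descriptors (role, spec, input channels) in a fixed
# traversal order: per unit main then sub-paths, then recon.
layer_table <- function(spec) {
  out <- list()
  cin <- 1L
  for (i in seq_along(spec$units)) {
    u <- spec$units[[i]]
    out[[length(out) + 1]] <- list(role = sprintf("mfu%d.main", i),
                                   layer = u$main, cin = cin,
                                   unit = i, kind = 0L, sub_id = 0L)
    for (j in seq_along(u$subpaths)) {
      sp_cin <- cin
      for (l in seq_along(u$subpaths[[j]])) {
        out[[length(out) + 1]] <- list(
          role = sprintf("mfu%d.sub%d.%d", i, j, l),
          layer = u$subpaths[[j]][[l]], cin = sp_cin,
          unit = i, kind = 1L, sub_id = j
        )
        sp_cin <- u$subpaths[[j]][[l]]$count
      }
    }
    cin <- u$main$count
  }
  out[[length(out) + 1]] <- list(role = "recon", layer = spec$recon,
                                 cin = cin, unit = 0L, kind = 2L,
                                 sub_id = 0L)
  out
}

#' Number of trainable parameters
#'
#' `sum(s_k^2 * c_in * n_k + n_k)` over every convolution layer, sub-paths
#' included.
#'
#' @param spec an `mfcn_spec`
#' @return integer count
#' @export
count_parameters <- function(spec) {
  sum(vapply(layer_table(spec), function(e) {
    e$layer$size^2 * e$cin * e$layer$count + e$layer$count
  }, 0))
}

#' Initialize network parameters
#'
#' Kernels drawn from Gaussian(0, sd = `init_sd`), biases zero; the record
#' of the initialization (distribution, sd, seed) travels with the
#' parameters.
#'
#' @param spec an `mfcn_spec`
#' @param seed integer seed
#' @param init_sd kernel standard deviation (default 0.001)
#' @return `network_params`: list with `spec`, per-layer `layers`
#'   (`w` array `s x s x cin x n_k`, `b` numeric), `init`
#' @export
build_network <- function(spec, seed = 1L, init_sd = 0.001) {
  stopifnot(inherits(spec, "mfcn_spec"))
  tab <- layer_table(spec)
  layers <- with_seed(seed, lapply(tab, function(e) {
    s <- e$layer$size
    nk <- e$layer$count
    list(
      w = array(rnorm(s * s * e$cin * nk, 0, init_sd), c(s, s, e$cin, nk)),
      b = numeric(nk)
    )
  }))
  names(layers) <- vapply(tab, `[[`, "", "role")
  structure(
    list(spec = spec, layers = layers,
         init = list(distribution = "gaussian", sd = init_sd,
                     seed = as.integer(seed))),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> %d layers, %s parameters (init %s sd %g, seed %d)\n",
              length(x$layers),
              format(count_parameters(x$spec), big.mark = ","),
              x$init$distribution, x$init$sd, x$init$seed))
  invisible(x)
}

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4)
  x
}

conv_fwd <- function(x, lay, relu = FALSE) {
  cpp_conv2d_fwd(x, lay$w, lay$b, relu)
}

#' Forward pass through one multi-scale fusion unit
#'
#' `out = ReLU(conv_main(x)) + sum_j SP_j(x)`, with no activation after the
#' addition. Spatial size is preserved (zero same-padding).
#'
#' @param x input feature maps: `H x W` matrix or `(H, W, C, N)` array
#' @param unit an [mfu_spec()]
#' @param params list of this unit's layer parameters in traversal order
#'   (main first, then sub-path layers), as sliced from
#'   [build_network()] output
#' @return `(H, W, n_k, N)` array
#' @export
forward_mfu <- function(x, unit, params) {
  stopifnot(inherits(unit, "mfu_spec"))
  x <- as_batch(x)
  k <- 1L
  if (dim(x)[3] != dim(params[[k]]$w)[3]) {
    stop(sprintf("channel mismatch: input has %d, main path expects %d",
                 dim(x)[3], dim(params[[k]]$w)[3]))
  }
  out <- conv_fwd(x, params[[k]], relu = TRUE)
  k <- k + 1L
  for (j in seq_along(unit$subpaths)) {
    z <- x
    sp <- unit$subpaths[[j]]
    for (l in seq_along(sp)) {
      z <- conv_fwd(z, params[[k]], relu = sp[[l]]$relu)
      k <- k + 1L
    }
    out <- out + z
  }
  out
}

# Slice a unit's parameter sub-list out of the flat layer list.
unit_param_indices <- function(spec, i) {
  roles <- vapply(layer_table(spec), `[[`, "", "role")
  grep(sprintf("^mfu%d\\.", i), roles)
}

#' Forward pass through an MFCN
#'
#' Fully convolutional: accepts 33x33 training patches or whole slices; the
#' output has the spatial size of the input.
#'
#' @param params a `network_params`
#' @param x single-channel image (matrix) or `(H, W, 1, N)` batch
#' @param cache keep intermediate activations for the backward pass
#' @return with `cache = FALSE`, the output in the same form as the input
#'   (matrix in, matrix out); with `cache = TRUE`, a list `(y, cache)`
#' @export
mfcn_forward <- function(params, x, cache = FALSE) {
  stopifnot(inherits(params, "network_params"))
  was_matrix <- is.matrix(x)
  x <- as_batch(x)
  if (!all(is.finite(x))) stop("non-finite values in network input")
  spec <- params$spec
  layers <- params$layers
  k <- 1L
  caches <- list()
  cur <- x
  for (i in seq_along(spec$units)) {
    u <- spec$units[[i]]
    uc <- list(input = cur)
    # ReLU fused into the convolution; act > 0 recovers the backward mask
    out <- conv_fwd(cur, layers[[k]], relu = TRUE)
    uc$act_main <- out
    k <- k + 1L
    uc$sub <- list()
    for (j in seq_along(u$subpaths)) {
      z <- cur
      sp <- u$subpaths[[j]]
      sc <- list(inputs = list(), act = list(), relu = logical(0))
      for (l in seq_along(sp)) {
        sc$inputs[[l]] <- z
        z <- conv_fwd(z, layers[[k]], relu = sp[[l]]$relu)
        sc$act[[l]] <- z
        sc$relu[l] <- sp[[l]]$relu
        k <- k + 1L
      }
      uc$sub[[j]] <- sc
      out <- out + z
    }
    caches[[i]] <- uc
    cur <- out
  }
  recon_input <- cur
  y <- conv_fwd(cur, layers[[k]])
  if (cache) {
    return(list(y = y, cache = list(units = caches,
                                    recon_input = recon_input)))
  }
  if (was_matrix) matrix(y, dim(y)[1], dim(y)[2]) else y
}

#' Save / load network parameters with the embedded spec
#'
#' @param params a `network_params`
#' @param path file path
#' @return `load_network` returns the `network_params`
#' @export
save_network <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  p <- readRDS(path)
  stopifnot(inherits(p, "network_params"))
  p
}

#' Read / write a network spec in the table notation
#'
#' JSON dialect mirroring the configuration tables, e.g.
#' `{"units": [{"main": "9/32", "subpaths": [["1/32"]]}], "recon": "5/1"}`.
#'
#' @param spec an `mfcn_spec`
#' @param path file path
#' @return `read_mfcn_spec` returns an `mfcn_spec`
#' @export
write_mfcn_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mfcn_spec"))
  obj <- list(
    units = lapply(spec$units, function(u) {
      list(
        main = layer_txt(u$main),
        subpaths = lapply(u$subpaths, function(sp) {
          vapply(sp, layer_txt, "")
        }),
        relu_before_fusion = u$relu_before_fusion
      )
    }),
    recon = layer_txt(spec$recon)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mfcn_spec
#' @export
read_mfcn_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  units <- lapply(obj$units, function(u) {
    subpaths <- lapply(u$subpaths, function(sp) unlist(sp, use.names = FALSE))
    mfu_spec(u$main[[1]], subpaths,
             relu_before_fusion = isTRUE(u$relu_before_fusion[[1]]))
  })
  mfcn_spec(units, recon = obj$recon[[1]])
}
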