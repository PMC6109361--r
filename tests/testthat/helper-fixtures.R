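# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_phantom <- function() {
  fixture("tiny_phantom", function() {
    make_phantom(phantom_spec(dim = c(64, 64, 8), n_structures = 4,
                              seed = 11))
  })
}

tiny_slice <- function() {
  v <- tiny_phantom()
  list(hr = v$intensity[, , 4], mask = v$mask[, , 4],
       labels = v$labels[, , 4])
}

tiny_patchset <- function() {
  fixture("tiny_patchset", function() {
    s <- tiny_slice()
    pair <- degrade_slice(s$hr, s$mask, degrade_spec(2))
    extract_patch_pairs(pair, n_per_slice = 64, patch_size = 17, seed = 5)
  })
}

# smallest network that still has an MFU + sub-path + recon
tiny_spec <- function() {
  mfcn_spec(
    list(mfu_spec("3/4", list("1/4")), mfu_spec("3/4", list("1/4"))),
    recon = "3/1"
  )
}

# brute-force zero-padded cross-correlation oracle (single sample)
conv2d_oracle <- function(x, w, b) {
  if (length(dim(x)) == 4) x <- array(x, dim(x)[1:3])
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  s <- dim(w)[1]; Cout <- dim(w)[4]; hw <- (s - 1) / 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      acc <- b[co]
      for (ci in seq_len(Cin)) for (dr in -hw:hw) for (dc in -hw:hw) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) {
          acc <- acc + x[rr, c2, ci] * w[dr + hw + 1, dc + hw + 1, ci, co]
        }
      }
      y[r, cc, co] <- acc
    }
  }
  y
}

# Central finite-difference check of the analytic loss gradient for the
# sampled weight indices. ReLU makes the loss only piecewise smooth: a
# probe whose +/-h interval straddles a kink gives a biased difference
# quotient even when the analytic gradient is exact. The kink-affected
# interval fraction shrinks linearly with h, so probes failing at the
# primary step are re-checked at h/100 — a genuinely wrong gradient fails
# at every step size. Returns the per-probe relative error after the
# refinement.
fd_gradcheck <- function(net, x, y, idx, h = 1e-5, tol = 1e-4) {
  fwd <- mfcn_forward(net, x, cache = TRUE)
  ls <- euclidean_loss(fwd$y, y)
  bk <- mfcnsr:::mfcn_backward(net, fwd, ls$grad)
  analytic <- unlist(lapply(bk$grads, function(g) c(as.vector(g$w), g$b)),
                     use.names = FALSE)
  v0 <- flatten_params(net)
  fd_at <- function(i, hh) {
    vp <- v0
    vp[i] <- vp[i] + hh
    lp <- euclidean_loss(mfcn_forward(unflatten_params(net, vp), x),
                         y)$loss
    vm <- v0
    vm[i] <- vm[i] - hh
    lm <- euclidean_loss(mfcn_forward(unflatten_params(net, vm), x),
                         y)$loss
    (lp - lm) / (2 * hh)
  }
  rel_err <- function(a, n) abs(a - n) / pmax(abs(a) + abs(n), 1e-6)
  numeric_g <- vapply(idx, fd_at, 0, hh = h)
  rel <- rel_err(analytic[idx], numeric_g)
  retry <- which(rel >= tol)
  for (j in retry) {
    rel[j] <- rel_err(analytic[idx[j]], fd_at(idx[j], h / 100))
  }
  rel
}

# total variation (anisotropic, first differences)
total_variation <- function(img) {
  sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
}
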