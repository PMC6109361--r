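test_that("identity degradation reproduces the input bit-for-bit", {
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(1))
  expect_identical(pair$lr, pair$hr)
  expect_identical(pair$hr, s$hr)
})

test_that("constant images pass through degradation unchanged", {
  x <- matrix(0.42, 48, 40)
  for (f in c(2, 3, 4)) {
    pair <- degrade_slice(x, NULL, degrade_spec(f))
    expect_equal(pair$lr, x, tolerance = 1e-12)
  }
  pair <- degrade_slice(x, NULL, degrade_spec(2, blur = "gaussian"))
  expect_equal(pair$lr, x, tolerance = 1e-12)
})

test_that("gaussian blur path realizes the analytic kernel at scale 1", {
  x <- matrix(0, 25, 25)
  x[13, 13] <- 1
  pair <- degrade_slice(x, NULL, degrade_spec(1, blur = "gaussian",
                                              blur_sigma = 1))
  k <- gaussian_kernel2d(1)
  r <- (nrow(k) - 1) / 2
  expect_equal(pair$lr[(13 - r):(13 + r), (13 - r):(13 + r)], unname(k),
               tolerance = 1e-12)
})

test_that("degrade_volume processes exactly the mask-bearing slices", {
  v <- tiny_phantom()
  pairs <- degrade_volume(v, degrade_spec(2))
  expect_length(pairs, sum(apply(v$mask, 3, any)))
  expect_true(all(vapply(pairs, function(p) all(p$lr >= 0 & p$lr <= 1), TRUE)))

  empty <- v
  empty$mask[] <- FALSE
  expect_error(degrade_volume(empty, degrade_spec(2)), "no axial slice")
})

test_that("stronger downsampling increases the masked residual", {
  s <- tiny_slice()
  res <- vapply(c(2, 3), function(f) {
    p <- degrade_slice(s$hr, s$mask, degrade_spec(f))
    mean((p$hr - p$lr)[s$mask]^2)
  }, 0)
  expect_gte(res[2], res[1])
})

test_that("degradation contracts total variation on noiseless phantoms", {
  # asserted for the explicit gaussian blur: the antialiased-bicubic route
  # can raise anisotropic TV by a few percent through ringing at sharp
  # edges (negative kernel lobes), so it is checked with a small ringing
  # allowance instead
  v <- make_phantom(phantom_spec(dim = c(64, 64, 6), noise_sigma = 0,
                                 seed = 21))
  for (sl in c(3, 4)) {
    hr <- v$intensity[, , sl]
    for (f in 2:4) {
      pg <- degrade_slice(hr, v$mask[, , sl],
                          degrade_spec(f, blur = "gaussian"))
      expect_lte(total_variation(pg$lr), total_variation(hr))
      pb <- degrade_slice(hr, v$mask[, , sl], degrade_spec(f))
      expect_lte(total_variation(pb$lr), 1.15 * total_variation(hr))
    }
  }
})

test_that("patch extraction respects count, size, mask and determinism", {
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(2))
  ps <- extract_patch_pairs(pair, 600, 33, seed = 7)
  expect_equal(ps$m, 600)
  expect_equal(dim(ps$lr), c(33, 33, 600))
  expect_equal(dim(ps$hr), c(33, 33, 600))
  # centers in mask and patches fully inside
  expect_true(all(s$mask[cbind(ps$coords$row, ps$coords$col)]))
  expect_true(all(ps$coords$row >= 17 & ps$coords$row <= 64 - 16))

  ps2 <- extract_patch_pairs(pair, 600, 33, seed = 7)
  expect_identical(ps$coords, ps2$coords)

  expect_error(extract_patch_pairs(pair, 10, 32, seed = 1), "odd")
})

test_that("a single admissible center degenerates gracefully", {
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(2))
  pair$mask[] <- FALSE
  pair$mask[32, 32] <- TRUE
  ps <- extract_patch_pairs(pair, 5, 33, seed = 1)
  expect_true(all(ps$coords$row == 32 & ps$coords$col == 32))
  expect_equal(ps$lr[, , 1], ps$lr[, , 5])

  pair$mask[] <- FALSE
  expect_error(extract_patch_pairs(pair, 5, 33, seed = 1),
               "no admissible")
})

test_that("patch pairs are spatially aligned", {
  ps <- tiny_patchset()
  aligned <- shuffled <- numeric(20)
  set.seed(3)
  for (i in 1:20) {
    aligned[i] <- cor(as.vector(ps$lr[, , i]), as.vector(ps$hr[, , i]))
    shuffled[i] <- cor(as.vector(ps$lr[, , i]),
                       sample(as.vector(ps$hr[, , i])))
  }
  expect_gt(mean(aligned), mean(shuffled))
  expect_gt(mean(aligned), 0.8)
})

test_that("patch sets round-trip through the single-file container", {
  ps <- tiny_patchset()
  path <- tempfile(fileext = ".rds")
  save_patchset(ps, path)
  back <- load_patchset(path)
  expect_identical(back$lr, ps$lr)
  expect_identical(back$coords, ps$coords)
  unlink(path)
})
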