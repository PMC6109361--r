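test_that("rmse obeys its closed forms on the 0-255 scale", {
  x <- matrix(0.2, 16, 16)
  m <- matrix(TRUE, 16, 16)
  expect_identical(rmse(x, x, m), 0)
  expect_equal(rmse(x, x + 3 / 255, m), 3, tolerance = 1e-12)
  expect_error(rmse(x, x, m & FALSE), "empty")
})

test_that("snr matches its energy-ratio definition", {
  x <- matrix(1, 8, 8)
  expect_identical(snr(x, x), Inf)
  expect_equal(snr(x, x * 2), 0)  # equal signal and residual energy
  expect_error(snr(x * 0, x), "zero energy")
})

test_that("psnr uses 20*log10(R/RMSE) with the literal form behind a flag", {
  x <- matrix(0.5, 16, 16)
  y <- x + 0.1
  unit <- metric_spec(scale = "unit")
  expect_equal(psnr(x, y, spec = unit), 20, tolerance = 1e-9)
  expect_identical(psnr(x, x), Inf)
  lit <- metric_spec(scale = "unit", psnr_form = "literal")
  expect_equal(psnr(x, y, spec = lit), 10, tolerance = 1e-9)
})

test_that("published bicubic PSNR is consistent with published RMSE at R=255", {
  # benchmark-table worked example: the standard form reproduces the
  # printed PSNR from the printed RMSE at every scale within 0.05 dB
  printed_rmse <- c(2.5077, 4.2038, 5.8490)
  printed_psnr <- c(40.1699, 35.6717, 32.7993)
  expect_true(all(abs(psnr_from_rmse(printed_rmse) - printed_psnr) < 0.05))
  # and the literal factor-10 form does not
  expect_true(all(abs(psnr_from_rmse(printed_rmse, form = "literal") -
                        printed_psnr) > 10))
})

test_that("ssim satisfies identity, symmetry, range and the degenerate form", {
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(3))
  expect_equal(ssim(s$hr, s$hr, s$mask), 1)
  a <- ssim(pair$hr, pair$lr, s$mask)
  b <- ssim(pair$lr, pair$hr, s$mask)
  expect_equal(a, b)
  expect_lte(a, 1)

  # constant images, L = 1: (2*0.08 + 1e-4) / (0.2 + 1e-4)
  unit <- metric_spec(scale = "unit")
  x <- matrix(0.2, 16, 16)
  y <- matrix(0.4, 16, 16)
  expect_equal(ssim(x, y, spec = unit), (2 * 0.08 + 1e-4) / (0.2 + 1e-4),
               tolerance = 1e-12)
  expect_equal(ssim(x, y, spec = metric_spec(scale = "unit",
                                             ssim_form = "global")),
               (2 * 0.08 + 1e-4) / (0.2 + 1e-4), tolerance = 1e-12)
  expect_error(ssim(matrix(1, 4, 4), matrix(1, 4, 4)), "window")
})

test_that("metrics ignore pixels outside the evaluation region", {
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(2))
  m <- s$mask
  base <- c(rmse(pair$hr, pair$lr, m), snr(pair$hr, pair$lr, m),
            psnr(pair$hr, pair$lr, m))
  y2 <- pair$lr
  y2[!m] <- runif(sum(!m))  # corrupt outside the mask
  pert <- c(rmse(pair$hr, y2, m), snr(pair$hr, y2, m),
            psnr(pair$hr, y2, m))
  expect_equal(pert, base)

  # SSIM: corruption beyond the window reach of the mask is invisible
  reach <- 5
  far <- !mfcnsr:::dilate2d(m, 2 * reach)
  y3 <- pair$lr
  y3[far] <- 1
  expect_equal(ssim(pair$hr, y3, m), ssim(pair$hr, pair$lr, m))
})

test_that("evaluate_methods is consistent with the individual operations", {
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(2))
  midpoint <- (pair$lr + pair$hr) / 2
  rep <- evaluate_methods(
    pair$hr,
    list(identity = pair$hr, bicubic = pair$lr, midpoint = midpoint),
    mask = s$mask, scale_factor = 2
  )
  sm <- rep$summary
  idr <- sm[sm$method == "identity", ]
  expect_equal(idr$rmse, 0)
  expect_equal(idr$ssim, 1)
  expect_identical(idr$psnr, Inf)
  expect_identical(idr$snr, Inf)

  # strictly closer method scores strictly better
  expect_lt(sm[sm$method == "midpoint", "rmse"],
            sm[sm$method == "bicubic", "rmse"])
  expect_gt(sm[sm$method == "midpoint", "psnr"],
            sm[sm$method == "bicubic", "psnr"])

  # report rows equal the individual ops
  expect_equal(sm[sm$method == "bicubic", "rmse"],
               rmse(pair$hr, pair$lr, s$mask))
  expect_equal(sm[sm$method == "bicubic", "ssim"],
               ssim(pair$hr, pair$lr, s$mask))

  expect_error(evaluate_methods(pair$hr, list(pair$lr)), "named")
})
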