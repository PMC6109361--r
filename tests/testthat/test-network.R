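test_that("the baseline configuration matches the published grammar", {
  sp <- baseline_spec()
  expect_length(sp$units, 2)
  expect_equal(c(sp$recon$size, sp$recon$count), c(5, 1))
  expect_equal(c(sp$units[[1]]$main$size, sp$units[[1]]$main$count), c(9, 32))
  expect_length(sp$units[[1]]$subpaths, 1)
  expect_equal(c(sp$units[[1]]$subpaths[[1]][[1]]$size,
                 sp$units[[1]]$subpaths[[1]][[1]]$count), c(1, 32))
  expect_equal(c(sp$units[[2]]$main$size, sp$units[[2]]$main$count), c(3, 64))
  expect_equal(count_parameters(sp), 24897)
})

test_that("parameter counting follows s^2 * c_in * n_k + n_k", {
  one <- mfcn_spec(list(mfu_spec("1/1", list())), recon = "1/1")
  # 1x1x1x1 + 1 bias, twice
  expect_equal(count_parameters(one), 4)

  sp <- baseline_spec()
  doubled <- mfcn_spec(
    list(mfu_spec("9/64", list("1/64")), mfu_spec("3/128", list("1/128"))),
    recon = "5/1"
  )
  ratio <- count_parameters(doubled) / count_parameters(sp)
  expect_gt(ratio, 2)
  expect_lt(ratio, 4)
})

test_that("the plain-CNN counterpart drops exactly the sub-paths", {
  pl <- plain_cnn_spec(baseline_spec())
  expect_true(all(lengths(lapply(pl$units, `[[`, "subpaths")) == 0))
  expect_equal(count_parameters(pl), 22721)
  expect_equal(count_parameters(pl), 24897 - 64 - 2112)
})

test_that("initialization is seeded gaussian with zero biases", {
  n1 <- build_network(baseline_spec(), seed = 5)
  n2 <- build_network(baseline_spec(), seed = 5)
  expect_identical(flatten_params(n1), flatten_params(n2))
  expect_false(identical(flatten_params(n1),
                         flatten_params(build_network(baseline_spec(), 6))))
  expect_true(all(vapply(n1$layers, function(l) all(l$b == 0), TRUE)))
  # the 3x3x32x64 = 18,432-weight layer samples the configured sd
  w <- n1$layers[["mfu2.main"]]$w
  expect_length(as.vector(w), 18432)
  expect_gt(sd(as.vector(w)), 0.0008)
  expect_lt(sd(as.vector(w)), 0.0012)
})

test_that("spec validation rejects inconsistent fusion channels", {
  expect_error(mfu_spec("9/32", list("1/16")), "fusion")
  expect_error(mfcn_spec(list(mfu_spec("3/4", list())), recon = "5/2"),
               "one kernel")
  expect_error(conv_layer_spec(4, 8), "odd")
})

test_that("single-layer forward matches the brute-force oracle", {
  set.seed(17)
  cases <- list(c(s = 1, cin = 1, cout = 3), c(s = 3, cin = 2, cout = 2),
                c(s = 5, cin = 3, cout = 1), c(s = 9, cin = 1, cout = 4))
  for (cs in cases) {
    x <- array(rnorm(12 * 11 * cs["cin"]), c(12, 11, cs["cin"], 1))
    w <- array(rnorm(cs["s"]^2 * cs["cin"] * cs["cout"], sd = 0.5),
               c(cs["s"], cs["s"], cs["cin"], cs["cout"]))
    b <- rnorm(cs["cout"])
    got <- mfcnsr:::cpp_conv2d_fwd(x, w, b)
    want <- conv2d_oracle(x[, , , 1, drop = FALSE], w, b)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-6)
  }
})

test_that("forward_mfu implements fusion by addition", {
  set.seed(4)
  net <- build_network(tiny_spec(), seed = 1, init_sd = 0.2)
  unit <- net$spec$units[[1]]
  idx <- mfcnsr:::unit_param_indices(net$spec, 1)
  pars <- net$layers[idx]
  x <- array(abs(rnorm(8 * 8)), c(8, 8, 1, 1))

  out <- forward_mfu(x, unit, pars)
  expect_equal(dim(out), c(8, 8, 4, 1))

  # additive identity: zero sub-path leaves the main path
  pars0 <- pars
  pars0[[2]]$w[] <- 0
  out0 <- forward_mfu(x, unit, pars0)
  main <- pmax(mfcnsr:::cpp_conv2d_fwd(x, pars[[1]]$w, pars[[1]]$b), 0)
  expect_equal(out0, main)

  # fusion linearity: output = main + sub, computed independently
  sub <- mfcnsr:::cpp_conv2d_fwd(x, pars[[2]]$w, pars[[2]]$b)
  expect_equal(out, main + sub)

  # delta main kernel + unit 1x1 sub-path doubles nonnegative input
  dn <- build_network(mfcn_spec(list(mfu_spec("3/1", list("1/1"))), "1/1"),
                      seed = 1)
  dn$layers[[1]]$w[] <- 0
  dn$layers[[1]]$w[2, 2, 1, 1] <- 1  # centered delta
  dn$layers[[2]]$w[] <- 1
  dn$layers[[1]]$b[] <- 0
  dn$layers[[2]]$b[] <- 0
  u <- dn$spec$units[[1]]
  expect_equal(forward_mfu(x, u, dn$layers[1:2]), 2 * x)

  expect_error(forward_mfu(array(1, c(8, 8, 3, 1)), unit, pars),
               "channel mismatch")
})

test_that("network forward equals explicit per-unit composition", {
  set.seed(9)
  net <- build_network(tiny_spec(), seed = 3, init_sd = 0.3)
  x <- matrix(rnorm(64), 8, 8)
  got <- mfcn_forward(net, x)

  h <- as_b <- array(x, c(8, 8, 1, 1))
  h1 <- forward_mfu(as_b, net$spec$units[[1]],
                    net$layers[mfcnsr:::unit_param_indices(net$spec, 1)])
  h2 <- forward_mfu(h1, net$spec$units[[2]],
                    net$layers[mfcnsr:::unit_param_indices(net$spec, 2)])
  recon <- net$layers[[length(net$layers)]]
  want <- mfcnsr:::cpp_conv2d_fwd(h2, recon$w, recon$b)
  expect_equal(got, matrix(want, 8, 8), tolerance = 1e-12)
})

test_that("all-zero parameters map any input to zero; shapes are preserved", {
  net <- build_network(tiny_spec(), seed = 1)
  net <- unflatten_params(net, rep(0, count_parameters(net$spec)))
  s <- tiny_slice()
  out <- mfcn_forward(net, s$hr)
  expect_equal(out, matrix(0, 64, 64))
  expect_error(mfcn_forward(net, matrix(c(NA, rep(1, 63)), 8, 8)),
               "non-finite")
})

test_that("zeroed sub-paths reproduce the plain CNN exactly", {
  spec <- tiny_spec()
  plain <- plain_cnn_spec(spec)
  net <- build_network(spec, seed = 8, init_sd = 0.2)
  pnet <- build_network(plain, seed = 8, init_sd = 0.2)
  # share main-path + recon weights; zero the sub-paths
  roles_p <- names(pnet$layers)
  for (r in roles_p) pnet$layers[[r]] <- net$layers[[r]]
  for (r in setdiff(names(net$layers), roles_p)) {
    net$layers[[r]]$w[] <- 0
    net$layers[[r]]$b[] <- 0
  }
  x <- matrix(runif(10 * 12), 10, 12)
  expect_equal(mfcn_forward(net, x), mfcn_forward(pnet, x),
               tolerance = 1e-12)
})

test_that("every builtin variant preserves spatial shape on a 12x12 input", {
  x <- matrix(runif(144), 12, 12)
  for (v in builtin_variants()) {
    net <- build_network(v, seed = 2)
    out <- mfcn_forward(net, x)
    expect_identical(dim(out), c(12L, 12L))
    expect_true(all(is.finite(out)))
    expect_gt(count_parameters(v), 0)
  }
})

test_that("spec files round-trip through the table notation", {
  for (sp in list(baseline_spec(), builtin_variants()$L2,
                  builtin_variants()$BL_relu_fusion)) {
    path <- tempfile(fileext = ".json")
    write_mfcn_spec(sp, path)
    back <- read_mfcn_spec(path)
    expect_equal(back, sp)
    unlink(path)
  }
})

test_that("the ReLU-before-fusion toggle changes the computation", {
  x <- matrix(runif(100), 10, 10)
  a <- build_network(tiny_spec(), seed = 4, init_sd = 0.3)
  spec_b <- mfcn_spec(
    list(mfu_spec("3/4", list("1/4"), relu_before_fusion = TRUE),
         mfu_spec("3/4", list("1/4"), relu_before_fusion = TRUE)),
    recon = "3/1"
  )
  b <- build_network(spec_b, seed = 4, init_sd = 0.3)
  expect_identical(flatten_params(a), flatten_params(b))
  expect_false(isTRUE(all.equal(mfcn_forward(a, x), mfcn_forward(b, x))))
})
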