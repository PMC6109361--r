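test_that("euclidean loss matches its closed form and gradient contract", {
  p <- array(0.5, c(33, 33, 1, 1))
  t0 <- array(0.5, c(33, 33, 1, 1))
  expect_equal(euclidean_loss(p, t0)$loss, 0)
  # B = 1, difference identically 1 on a 33x33 patch -> 1089/2
  expect_equal(euclidean_loss(p + 1, t0)$loss, 544.5)
  # batch form: loss = sum/(2B), grad = diff/B
  pb <- array(runif(33 * 33 * 2), c(33, 33, 1, 2))
  tb <- array(runif(33 * 33 * 2), c(33, 33, 1, 2))
  ls <- euclidean_loss(pb, tb)
  expect_equal(ls$loss, sum((pb - tb)^2) / 4)
  expect_equal(ls$grad, (pb - tb) / 2)
  expect_error(euclidean_loss(pb, tb[, , , 1, drop = FALSE]), "shapes")
})

test_that("analytic network gradients match central finite differences", {
  set.seed(31)
  net <- build_network(tiny_spec(), seed = 6, init_sd = 0.3)
  x <- array(runif(12 * 12 * 2), c(12, 12, 1, 2))
  y <- array(runif(12 * 12 * 2), c(12, 12, 1, 2))
  idx <- sample(count_parameters(net$spec), 120)
  expect_lt(max(fd_gradcheck(net, x, y, idx)), 1e-4)
})

test_that("zero iterations leaves parameters untouched", {
  ps <- tiny_patchset()
  net <- build_network(tiny_spec(), seed = 2)
  fit <- train(net, ps, list(), train_spec(iterations = 0))
  expect_identical(flatten_params(fit$params), flatten_params(net))
  expect_length(fit$trace$loss, 0)
})

test_that("training is deterministic and backends agree", {
  ps <- tiny_patchset()
  net <- build_network(tiny_spec(), seed = 2)
  ts <- train_spec(lr = 1e-4, iterations = 25, val_interval = 25)
  f1 <- train(net, ps, list(), ts)
  f2 <- train(net, ps, list(), ts)
  expect_identical(f1$trace$loss, f2$trace$loss)
  expect_identical(flatten_params(f1$params), flatten_params(f2$params))
  expect_identical(f1$trace$batch_digest, f2$trace$batch_digest)

  td <- train_spec(lr = 1e-4, iterations = 25, val_interval = 25,
                   precision = "double")
  fd <- train(net, ps, list(), td)
  expect_identical(fd$trace$batch_digest, f1$trace$batch_digest)
  expect_equal(fd$trace$loss, f1$trace$loss, tolerance = 1e-5)

  f3 <- train(net, ps, list(),
              train_spec(lr = 1e-4, iterations = 25, seed = 99))
  expect_false(identical(f3$trace$batch_digest, f1$trace$batch_digest))
})

test_that("a single patch pair is overfit within 500 iterations", {
  ps <- tiny_patchset()
  one <- ps
  one$lr <- ps$lr[, , 1, drop = FALSE]
  one$hr <- ps$hr[, , 1, drop = FALSE]
  one$coords <- ps$coords[1, ]
  one$m <- 1L
  net <- build_network(tiny_spec(), seed = 3)
  ts <- train_spec(lr = 3e-4, batch = 1L, iterations = 500L,
                   val_interval = 500L)
  fit <- train(net, one, list(), ts)
  expect_lt(tail(fit$trace$loss, 1), 0.1 * fit$trace$loss[1])
})

test_that("divergence aborts with the iteration index", {
  ps <- tiny_patchset()
  net <- build_network(tiny_spec(), seed = 2)
  expect_error(
    train(net, ps, list(), train_spec(lr = 10, iterations = 200)),
    "diverged.*iteration [0-9]+"
  )
  expect_error(
    train(net, ps, list(),
          train_spec(lr = 10, iterations = 200, precision = "double")),
    "diverged.*iteration [0-9]+"
  )
})

test_that("training loss decreases on average at the working rate", {
  ps <- tiny_patchset()
  net <- build_network(tiny_spec(), seed = 4)
  fit <- train(net, ps, list(), train_spec(lr = 1e-4, iterations = 200))
  expect_lt(mean(tail(fit$trace$loss, 50)), mean(head(fit$trace$loss, 50)))
})

test_that("convergence_iteration implements the plateau rule", {
  expect_identical(convergence_iteration(rep(30, 6), 0.01), 1L)
  inc <- seq(20, 30, length.out = 8)
  expect_identical(convergence_iteration(inc, 0), 8L)
  expect_identical(convergence_iteration(c(30, 34, 34.9, 35, 35), 0.01), 3L)
  expect_error(convergence_iteration(numeric(0)), "empty")
})

test_that("traces round-trip to CSV", {
  ps <- tiny_patchset()
  s <- tiny_slice()
  pair <- degrade_slice(s$hr, s$mask, degrade_spec(2))
  net <- build_network(tiny_spec(), seed = 2)
  fit <- train(net, ps, list(pair),
               train_spec(lr = 1e-4, iterations = 20, val_interval = 10))
  path <- tempfile(fileext = ".csv")
  write_trace_csv(fit$trace, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 20)
  expect_equal(df$loss, fit$trace$loss)
  expect_equal(df$val_psnr[10], fit$trace$val$psnr[1])
  unlink(path)
})
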