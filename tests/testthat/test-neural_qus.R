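tiny_config <- function(in_channels = 2L)
  qus_net_config(in_channels = in_channels, enc_channels = c(4L, 6L, 8L),
                 dec_channels = c(4L, 3L, 2L, 2L), dropout_keep = 1)

random_fm <- function(H, B, C, seed = 1) {
  withr::with_seed(seed, fm(matrix(rnorm(H * H * B * C), H * H * B, C),
                            H, H, B))
}

test_that("conditional instance normalization matches hand computation", {
  # single channel x = [1,2,3,4], gamma 2, beta 1, population sigma, eps 0
  gt <- matrix(2, 4, 1); bt <- matrix(1, 4, 1)
  y <- conditional_instance_norm(array(1:4, c(2, 2, 1)), "AC", gt, bt,
                                 eps = 0)
  expect_equal(as.numeric(y), c(-1.6833, 0.1056, 1.8944, 3.6833),
               tolerance = 1e-4)
  # identity case: standardized input, unit gamma, zero beta
  x <- array(scale(rnorm(64))[, 1], c(8, 8, 1))
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y2 <- conditional_instance_norm(x, 1, matrix(1, 4, 1), matrix(0, 4, 1),
                                  eps = 1e-12)
  expect_equal(as.numeric(y2), as.numeric(x), tolerance = 1e-5)
  # collapse case: zero gamma returns beta everywhere
  y3 <- conditional_instance_norm(x, "SoS", matrix(0, 4, 1),
                                  matrix(5, 4, 1))
  expect_true(all(y3 == 5))
  expect_error(condition_vector(9), "malformed")
  expect_error(cond_index(c(1, 1, 0, 0)), "one-hot")
  expect_equal(condition_vector("AC")$one_hot, c(1L, 0L, 0L, 0L))
})

test_that("encoder compresses any valid input to the 16 x 16 latent and
           distinct conditions yield distinct features", {
  cfg <- tiny_config()
  net <- init_qus_net(cfg, 2)
  x <- random_fm(128, 1, 2)
  f1 <- qus_net_forward(net, x, 1L)
  expect_equal(c(f1$latent$H, f1$latent$W), c(16L, 16L))
  expect_equal(ncol(f1$latent$x), 8L)
  f2 <- qus_net_forward(net, x, 2L)
  expect_gt(max(abs(f1$latent$x - f2$latent$x)), 0)
  expect_gt(max(abs(f1$final$x - f2$final$x)), 0)
  # deterministic in evaluation mode
  f1b <- qus_net_forward(net, x, 1L)
  expect_identical(f1$final$x, f1b$final$x)
})

test_that("decoder emits the four auxiliary resolutions and a fused map", {
  cfg <- tiny_config()
  net <- init_qus_net(cfg, 3)
  fw <- qus_net_forward(net, random_fm(128, 2, 2), c(1L, 4L))
  sizes <- vapply(fw$aux, function(a) as.integer(a$H), integer(1))
  expect_identical(sizes, c(16L, 32L, 64L, 128L))
  expect_identical(vapply(fw$aux, function(a) as.integer(a$W), integer(1)),
                   sizes)
  expect_equal(c(fw$final$H, fw$final$W), c(128L, 128L))
})

test_that("residual subnetworks start as identities", {
  cfg <- tiny_config()
  net <- init_qus_net(cfg, 4)
  # with the second residual convolution zero-initialized, the block
  # output equals its (non-negative) input
  expect_true(all(net$decoder[[2]]$res2$params$W == 0))
  br <- net$decoder[[2]]
  up <- relu_forward(random_fm(32, 1, 3, seed = 9))$out
  r1 <- conv_forward(br$res1, up)
  rc <- cin_forward(br$res_cin, r1$out, 1L)
  rr <- relu_forward(rc$out)
  r2 <- conv_forward(br$res2, rr$out)
  expect_equal(r2$out$x + up$x, up$x)
})

test_that("loss decomposes exactly into main + auxiliary + L2 terms", {
  t0 <- matrix(rnorm(16), 4, 4)
  aux <- list(matrix(rnorm(4), 2, 2))
  lo0 <- loss_qi(t0, aux, t0, aux)
  expect_equal(lo0$total, 0)
  # off-by-constant prediction on N pixels: c^2 * N under the sum norm
  lo1 <- loss_qi(t0 + 0.3, aux, t0, aux)
  expect_equal(lo1$total, 0.3^2 * 16)
  w <- list(matrix(1, 3, 3))
  lo2 <- loss_qi(t0 + 0.3, aux, t0, aux, conv_w = w, lambda_l2 = 1e-2)
  expect_equal(lo2$total, lo2$main + lo2$lr + lo2$l2)
  expect_equal(lo2$l2, 1e-2 * 9)
  expect_gt(lo2$total, lo1$total)
  expect_error(loss_qi(t0[1:3, ], aux, t0, aux), "mismatch")
})

test_that("backpropagated gradients match finite differences and reach
           every subnetwork", {
  cfg <- tiny_config()
  net <- init_qus_net(cfg, 5)
  x <- random_fm(128, 2, 2, seed = 6)
  cond <- c(1L, 3L)
  withr::with_seed(8, {
    targ <- matrix(rnorm(128 * 128 * 2), ncol = 1)
    aux_t <- lapply(c(16, 32, 64, 128),
                    function(R) matrix(rnorm(R * R * 2), ncol = 1))
  })
  lossfun <- function(n) {
    fw <- qus_net_forward(n, x, cond)
    loss_qi(fw$final$x, lapply(fw$aux, `[[`, "x"), targ, aux_t)$total
  }
  fw <- qus_net_forward(net, x, cond)
  d_final <- fw$final; d_final$x <- 2 * (fw$final$x - targ)
  d_aux <- lapply(1:4, function(r) {
    d <- fw$aux[[r]]; d$x <- 2 * (fw$aux[[r]]$x - aux_t[[r]]); d
  })
  gr <- qus_net_backward(net, fw, d_final, d_aux, cond)

  # finite-difference spot checks across the architecture
  eps <- 1e-5
  spots <- list(
    list(get = function(n) n$encoder[[1]]$conv$params$W,
         set = function(n, v) { n$encoder[[1]]$conv$params$W <- v; n },
         g = gr$encoder[[1]]$conv$W),
    list(get = function(n) n$decoder[[4]]$res1$params$W,
         set = function(n, v) { n$decoder[[4]]$res1$params$W <- v; n },
         g = gr$decoder[[4]]$res1$W),
    list(get = function(n) n$decoder[[1]]$head_cin$params$gamma,
         set = function(n, v) { n$decoder[[1]]$head_cin$params$gamma <- v; n },
         g = gr$decoder[[1]]$head_cin$gamma),
    list(get = function(n) n$bottleneck$params$b,
         set = function(n, v) { n$bottleneck$params$b <- v; n },
         g = gr$bottleneck$b))
  for (sp in spots) {
    p <- sp$get(net)
    i <- which.max(abs(sp$g))          # a parameter with a live gradient
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    num <- (lossfun(sp$set(net, pp)) - lossfun(sp$set(net, pm))) / (2 * eps)
    expect_equal(num, as.numeric(sp$g[i]), tolerance = 1e-4)
  }
  # every decoder branch and encoder stage receives gradient (res1 is
  # legitimately silent while its zero-initialized successor is zero)
  for (r in 1:4) {
    expect_gt(sum(abs(gr$decoder[[r]]$head$W)), 0)
    expect_gt(sum(abs(gr$decoder[[r]]$aux$W)), 0)
    expect_gt(sum(abs(gr$decoder[[r]]$res2$W)), 0)
  }
  for (i in 1:3) expect_gt(sum(abs(gr$encoder[[i]]$conv$W)), 0)
})

test_that("the dataset split reproduces the published 15.5k/1.0k design", {
  sp <- split_dataset(16500, seed = 2)
  expect_equal(length(sp$train), 15500L)
  expect_equal(length(sp$test), 1000L)
  expect_equal(sort(c(sp$train, sp$test)), 1:16500)
  sp2 <- split_dataset(16500, seed = 2)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(64)
  expect_equal(length(sp3$test), 4L)
})

test_that("validation metrics agree with independent implementations", {
  withr::with_seed(13, {
    ref <- matrix(rnorm(1600), 40, 40)
    pred <- ref + 0.1 * matrix(rnorm(1600), 40, 40)
  })
  # PSNR from first principles
  expect_equal(psnr(pred, ref),
               10 * log10(diff(range(ref))^2 / mean((pred - ref)^2)),
               tolerance = 1e-12)
  expect_equal(psnr(ref, ref), Inf)
  expect_equal(mnae(pred, ref),
               mean(abs(pred - ref)) / diff(range(ref)), tolerance = 1e-12)

  # literal textbook SSIM: explicit loops over 11x11 Gaussian windows
  ssim_loops <- function(a, b) {
    L <- diff(range(b)); c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
    w <- outer(dnorm(-5:5, sd = 1.5), dnorm(-5:5, sd = 1.5))
    w <- w / sum(w)
    H <- nrow(a); W <- ncol(a)
    vals <- c()
    for (i in 6:(H - 5)) for (j in 6:(W - 5)) {
      pa <- a[(i - 5):(i + 5), (j - 5):(j + 5)]
      pb <- b[(i - 5):(i + 5), (j - 5):(j + 5)]
      mx <- sum(w * pa); my <- sum(w * pb)
      vx <- sum(w * pa^2) - mx^2; vy <- sum(w * pb^2) - my^2
      cxy <- sum(w * pa * pb) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
    mean(vals)
  }
  expect_equal(ssim(pred, ref), ssim_loops(pred, ref), tolerance = 1e-6)
  expect_equal(ssim(ref, ref), 1, tolerance = 1e-9)
})

test_that("short training on a trivial conditional task reduces the loss", {
  # inputs are uninformative; the optimal strategy is the per-condition
  # mean image, which the conditional normalization must express
  withr::with_seed(31, {
    ds <- lapply(1:16, function(i) {
      ci <- ((i - 1) %% 4) + 1L
      base <- matrix(c(0.2, 0.8, 0.5, 0.35)[ci], 128, 128)
      list(input = array(rnorm(64 * 64 * 2, sd = 0.3), c(64, 64, 2)),
           cond = ci,
           target = base + matrix(rnorm(128 * 128, sd = 0.02), 128, 128))
    })
  })
  cfg <- qus_net_config(in_channels = 2L, enc_channels = c(4L, 8L),
                        dec_channels = c(4L, 3L, 2L, 2L),
                        input_size = 64L, dropout_keep = 1,
                        batch_size = 4L, lr = 0.02)
  st <- train_qus(ds, cfg, seed = 2, epochs = 10)
  h <- st$history
  expect_lt(h$train_loss[nrow(h)], 0.5 * h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  expect_true(all(diff(h$epoch) == 1))
  # identical seeds give identical loss curves
  st2 <- train_qus(ds, cfg, seed = 2, epochs = 2)
  expect_equal(st2$history$train_loss, h$train_loss[1:2], tolerance = 1e-12)
  expect_error(train_qus(list(), cfg), "empty")
})

test_that("prediction requires a trained state and respects conditions", {
  expect_error(predict_qus(array(0, c(64, 64, 2)), "AC", list()),
               "untrained")
})
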