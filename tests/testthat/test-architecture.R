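test_that("configuration invariants are enforced with informative errors", {
  expect_error(unet_config("vgg16", N = 1), "N must be at least 2")
  expect_error(unet_config("vgg16", N = 7), "N in 2..6")
  expect_error(unet_config("vgg16", kernel_size = 4), "odd")
  expect_error(unet_config("resnet34", N = 4), "requires N = 5")
  expect_error(unet_config("vgg16", n = 0), "n must be at least 1")
})

test_that("forward pass returns input-resolution class maps across the depth grid", {
  for (N in 2:6) {
    sz <- 2^(N - 1) * 2
    m <- lfe_unet(unet_config("vgg16", N = N, n = 4), seed = 1)
    x <- array(runif(sz * sz * 3), dim = c(sz, sz, 3, 1))
    p <- predict(m, x, type = "logits")
    expect_equal(dim(p), c(sz, sz, 2, 1))
  }
  for (n in c(8, 16, 32)) {
    m <- lfe_unet(unet_config("vgg16", N = 3, n = n), seed = 1)
    x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
    expect_equal(dim(predict(m, x, type = "prob")), c(16, 16, 2, 2))
  }
  mr <- lfe_unet(unet_config("resnet34", in_channels = 12, classes = 4), seed = 1)
  x <- array(runif(32 * 32 * 12), dim = c(32, 32, 12, 1))
  expect_equal(dim(predict(mr, x)), c(32, 32, 4, 1))
})

test_that("softmax probabilities are a proper distribution over classes", {
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 2)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3, 1))
  p <- predict(m, x, type = "prob")
  expect_true(all(p >= 0))
  expect_equal(apply(p, c(1, 2, 4), sum), array(1, dim = c(16, 16, 1)))
})

test_that("forward pass rejects mismatched channels and indivisible sizes", {
  m <- lfe_unet(unet_config("vgg16", N = 4, n = 4), seed = 1)
  expect_error(predict(m, array(0.5, c(16, 16, 4, 1))), "channels")
  expect_error(predict(m, array(0.5, c(20, 20, 3, 1))), "divisible")
})

test_that("decoder channels mirror the encoder at every level", {
  cfg <- unet_config("vgg16", N = 5, n = 8)
  m <- lfe_unet(cfg, init = "none")
  s <- summary(m)
  for (i in 1:4) {
    theta2 <- s[s$name == sprintf("dec%d_theta2", i), ]
    expect_equal(theta2$out_channels, 8 * 2^(i - 1))
  }
  # doubling n doubles every channel dimension and nothing else
  s2 <- summary(lfe_unet(unet_config("vgg16", N = 5, n = 16), init = "none"))
  expect_identical(s2$name, s$name)
  expect_true(all(s2$out_channels[s2$name != "classifier"] ==
                    2 * s$out_channels[s$name != "classifier"]))
})

test_that("decoder level 2 of the depth-5 network concatenates six branches", {
  cfg <- unet_config("vgg16", N = 5, n = 8)
  expect_equal(lfeunet:::decoder_branch_count(cfg, 2L), 6L)
  expect_equal(lfeunet:::decoder_branch_count(cfg, 4L), 5L)  # bottleneck level
  m <- lfe_unet(cfg, seed = 1)
  feats <- lapply(1:5, function(j)
    feature_map(array(runif(prod(c(32, 32) / 2^(j - 1)) * 8 * 2^(j - 1)),
                      dim = c(32 / 2^(j - 1), 32 / 2^(j - 1), 8 * 2^(j - 1))), j))
  deeper <- feature_map(array(runif(8 * 8 * 32), dim = c(8, 8, 32)), 3)
  out <- decoder_layer_forward(m, feats, deeper, i = 2)
  expect_s3_class(out, "feature_map")
  expect_equal(out$level, 2L)
  expect_equal(out$channels, 16L)  # 2^(i-1) * n mirrored from the encoder
})

test_that("decoder output is non-negative after the fused block's ReLU", {
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 5)
  feats <- lapply(1:3, function(j)
    feature_map(array(0, dim = c(16 / 2^(j - 1), 16 / 2^(j - 1), 4 * 2^(j - 1))), j))
  out <- decoder_layer_forward(m, feats, NULL, i = 2, training = FALSE)
  expect_true(all(out$data >= 0))
})

test_that("decoder layer validates its input levels", {
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 5)
  feats <- lapply(c(1, 3, 2), function(j)  # wrong order: level mismatch
    feature_map(array(0, dim = c(16 / 2^(j - 1), 16 / 2^(j - 1), 4 * 2^(j - 1))), j))
  expect_error(decoder_layer_forward(m, feats, NULL, i = 2), "level")
})

test_that("resampling is identity at equal levels and exact max-pool downwards", {
  f <- feature_map(array(runif(4 * 4 * 2), dim = c(4, 4, 2)), level = 1)
  expect_identical(resample(f, 1), f)
  const <- feature_map(array(7, dim = c(4, 4, 1)), 1)
  down <- resample(const, 2)
  expect_equal(down$data, array(7, dim = c(2, 2, 1, 1)))
  # brute-force per-block maximum oracle
  set.seed(8)
  f2 <- feature_map(array(rnorm(4 * 4 * 3), dim = c(4, 4, 3)), 1)
  d2 <- resample(f2, 2)
  for (c in 1:3) for (i in 1:2) for (j in 1:2)
    expect_equal(d2$data[i, j, c, 1],
                 max(f2$data[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1]))
  expect_error(resample(feature_map(array(0, c(2, 2, 1)), 1), 3), "below 1 pixel")
})

test_that("bilinear upsampling preserves constants and doubles extent", {
  f <- feature_map(array(3.5, dim = c(4, 4, 2)), 2)
  up <- resample(f, 1)
  expect_equal(dim(up$data)[1:2], c(8, 8))
  expect_equal(up$data, array(3.5, dim = c(8, 8, 2, 1)))
})

test_that("backpropagated gradients match finite differences", {
  for (backbone in c("vgg16", "resnet34")) {
    cfg <- if (backbone == "vgg16")
      unet_config("vgg16", N = 3, n = 2, in_channels = 3, classes = 2)
    else unet_config("resnet34", N = 5, n = 2, in_channels = 4, classes = 3)
    sz <- if (backbone == "vgg16") 8L else 16L
    m <- lfe_unet(cfg, seed = 11)
    set.seed(21)
    x <- array(runif(sz * sz * cfg$in_channels * 2),
               dim = c(sz, sz, cfg$in_channels, 2))
    y <- array(sample(0:(cfg$classes - 1), sz * sz * 2, TRUE), dim = c(sz, sz, 2))
    spec <- loss_spec("CE")
    fw <- lfeunet:::unet_forward(m, x, training = TRUE)
    sl <- lfeunet:::score_loss(spec, fw$logits$value, y)
    grads <- lfeunet:::tp_backward(fw$logits, sl$grad)
    lossat <- function(mm)
      lfeunet:::score_loss(spec,
        lfeunet:::unet_forward(mm, x, training = TRUE)$logits$value, y)$loss
    for (nm in sample(names(grads), 4)) {
      r <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      mp <- m; mp$params[[nm]][r] <- mp$params[[nm]][r] + eps
      mn <- m; mn$params[[nm]][r] <- mn$params[[nm]][r] - eps
      num <- (lossat(mp) - lossat(mn)) / (2 * eps)
      expect_equal(grads[[nm]][r], num, tolerance = 1e-4,
                   label = paste("analytic grad of", nm))
    }
  }
})
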