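test_that("all nine losses match the brute-force per-pixel oracle", {
  fx <- loss_fixture()
  spec <- loss_spec()
  for (nm in c("CE", "L2", "SF", "BCL", "DL", "TL", "FL", "KL")) {
    expect_equal(compute_loss(nm, fx$z, fx$y, spec),
                 oracle_loss(nm, fx$z, fx$y),
                 tolerance = 1e-6, label = nm)
  }
  p <- lfeunet:::softmax4(fx$z)  # BCE takes probabilities
  expect_equal(compute_loss("BCE", p, fx$y, spec), oracle_loss("BCE", p, fx$y),
               tolerance = 1e-6)
  # and on a larger seeded multi-class example
  fx4 <- loss_fixture(seed = 77, H = 3, W = 5, C = 4, Nb = 2)
  for (nm in c("CE", "DL", "TL", "FL", "KL", "SF", "L2"))
    expect_equal(compute_loss(nm, fx4$z, fx4$y, spec),
                 oracle_loss(nm, fx4$z, fx4$y),
                 tolerance = 1e-6, label = paste("4-class", nm))
})

test_that("Tversky at alpha = beta = 0.5 reduces to the Dice loss", {
  fx <- loss_fixture(seed = 5, H = 4, W = 4, C = 3)
  s <- loss_spec("TL", alpha = 0.5, beta = 0.5)
  # equality holds up to the overlap-smoothing constant
  expect_equal(compute_loss("TL", fx$z, fx$y, s),
               compute_loss("DL", fx$z, fx$y, s), tolerance = 1e-6)
})

test_that("focal loss with gamma = 0, lambda = 1 reduces to cross entropy", {
  fx <- loss_fixture(seed = 6, H = 4, W = 4, C = 3)
  s <- loss_spec("FL", lambda = 1, gamma = 0)
  expect_equal(compute_loss("FL", fx$z, fx$y, s),
               compute_loss("CE", fx$z, fx$y, s), tolerance = 1e-9)
})

test_that("cross entropy of a uniform prediction is log(C) and Dice of a perfect one is 0", {
  for (C in c(2, 4)) {
    z <- array(0, dim = c(3, 3, C, 1))
    y <- array(sample(0:(C - 1), 9, TRUE), dim = c(3, 3, 1))
    expect_equal(compute_loss("CE", z, y), log(C))
  }
  y <- array(c(0, 1, 1, 0), dim = c(2, 2, 1))
  oh <- lfeunet:::as_one_hot(y, c(2, 2, 2, 1))
  expect_equal(compute_loss("DL", 1e4 * oh - 5e3, y), 0, tolerance = 1e-5)
})

test_that("every loss is non-negative and minimal at the one-hot target", {
  set.seed(9)
  for (rep in 1:5) {
    C <- sample(2:4, 1)
    y <- array(sample(0:(C - 1), 12, TRUE), dim = c(3, 4, 1))
    oh <- lfeunet:::as_one_hot(y, c(3, 4, C, 1))
    sharp <- 50 * oh - 25
    z <- array(rnorm(12 * C), dim = c(3, 4, C, 1))
    for (nm in c("CE", "L2", "SF", "BCL", "DL", "TL", "FL", "KL")) {
      lr <- compute_loss(nm, z, y)
      lp <- compute_loss(nm, sharp, y)
      expect_gte(lr, 0)
      expect_lte(lp, lr + 1e-9)
      expect_lt(lp, 0.01)
    }
    psharp <- pmin(pmax(lfeunet:::softmax4(sharp), 1e-9), 1 - 1e-9)
    expect_lt(compute_loss("BCE", psharp, y), 0.01)
  }
})

test_that("losses are equivariant under permutation of the batch", {
  fx <- loss_fixture(seed = 12, H = 3, W = 3, C = 2, Nb = 4)
  perm <- c(3, 1, 4, 2)
  for (nm in c("CE", "DL", "TL", "FL", "KL", "SF", "L2", "BCL"))
    expect_equal(compute_loss(nm, fx$z, fx$y),
                 compute_loss(nm, fx$z[, , , perm, drop = FALSE],
                              fx$y[, , perm, drop = FALSE]),
                 tolerance = 1e-12, label = nm)
})

test_that("raising the true-class score lowers CE, FL, DL and TL", {
  z <- array(c(0.3, -0.1), dim = c(1, 1, 2, 1))
  y <- array(1L, dim = c(1, 1, 1))   # true class is the second one
  z_hi <- z; z_hi[1, 1, 2, 1] <- z[1, 1, 2, 1] + 0.5
  for (nm in c("CE", "FL", "DL", "TL"))
    expect_lt(compute_loss(nm, z_hi, y), compute_loss(nm, z, y),
              label = nm)
})

test_that("loss input validation identifies the offending input", {
  z <- array(rnorm(8), dim = c(2, 2, 2, 1))
  y <- array(0L, dim = c(2, 2, 1))
  expect_error(compute_loss("BCE", z, y), "probabilities")
  expect_error(compute_loss("XX", z, y), "valid names")
  expect_error(compute_loss("CE", z, array(5L, dim = c(2, 2, 1))), "0..1")
  expect_error(compute_loss("CE", z, array(0L, dim = c(3, 2, 1))), "match")
})

test_that("combinations are weighted sums of their components", {
  fx <- loss_fixture(seed = 20, H = 3, W = 3, C = 2, Nb = 2)
  single <- loss_spec("TL")
  expect_identical(combine_loss(single, fx$z, fx$y),
                   compute_loss("TL", fx$z, fx$y, single))
  dk <- loss_spec(c("DL", "KL"))
  expect_equal(combine_loss(dk, fx$z, fx$y),
               compute_loss("DL", fx$z, fx$y, dk) +
                 compute_loss("KL", fx$z, fx$y, dk),
               tolerance = 1e-12)
  wdk <- loss_spec(c("DL", "KL"), weights = c(2, 0.5))
  expect_equal(combine_loss(wdk, fx$z, fx$y),
               2 * compute_loss("DL", fx$z, fx$y, wdk) +
                 0.5 * compute_loss("KL", fx$z, fx$y, wdk),
               tolerance = 1e-12)
  expect_error(loss_spec(c("DL", "QQ")), "valid names")
  expect_error(loss_spec(c("DL", "KL"), weights = 1), "one entry per")
})

test_that("the DFK preset equals the oracle sum of Dice, focal and KL", {
  fx <- loss_fixture(seed = 31)
  expect_equal(combine_loss(dfk_loss(), fx$z, fx$y),
               oracle_loss("DL", fx$z, fx$y) + oracle_loss("FL", fx$z, fx$y) +
                 oracle_loss("KL", fx$z, fx$y),
               tolerance = 1e-6)
})

test_that("analytic loss gradients match central differences", {
  fx <- loss_fixture(seed = 40, H = 2, W = 3, C = 3, Nb = 2)
  spec <- loss_spec()
  for (nm in c("CE", "L2", "SF", "BCL", "DL", "TL", "FL", "KL")) {
    g <- lfeunet:::loss_grad(nm, fx$z, fx$y, spec)
    for (r in sample(length(fx$z), 4)) {
      eps <- 1e-6
      zp <- fx$z; zp[r] <- zp[r] + eps
      zm <- fx$z; zm[r] <- zm[r] - eps
      num <- (compute_loss(nm, zp, fx$y, spec) -
                compute_loss(nm, zm, fx$y, spec)) / (2 * eps)
      expect_equal(g[r], num, tolerance = 1e-4,
                   label = paste("grad", nm, "entry", r))
    }
  }
})
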