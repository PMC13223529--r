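# a fabricated history data.frame with given validation losses
fake_history <- function(val_loss) {
  data.frame(epoch = seq_along(val_loss), train_loss = NA_real_,
             val_loss = val_loss, val_dice = NA_real_, lr = NA_real_)
}

test_that("the plateau schedule decays the rate to one tenth after 20 stalled epochs", {
  cfg <- train_config(learning_rate = 1e-4, patience = 20)
  # one improving epoch then 20 epochs without improvement
  h <- fake_history(c(1.0, rep(1.0, 20)))
  expect_equal(lr_schedule_step(h, cfg), 1e-5)
  # an improvement at epoch 19 of the stall resets the counter
  h2 <- fake_history(c(1.0, rep(1.0, 18), 0.9, rep(0.95, 10)))
  expect_equal(lr_schedule_step(h2, cfg), 1e-4)
  # two completed stall cycles compose to one hundredth
  h3 <- fake_history(c(1.0, rep(1.0, 40)))
  expect_equal(lr_schedule_step(h3, cfg), 1e-6)
  empty <- data.frame(epoch = integer(0), val_loss = numeric(0))
  expect_error(lr_schedule_step(empty, cfg), "empty")
})

test_that("the learning-rate trace is non-increasing and drops exactly by the factor", {
  cfg <- train_config(learning_rate = 1e-3, patience = 3, lr_decay_factor = 0.1)
  set.seed(2)
  tr <- lfeunet:::lr_trace(cumsum(rnorm(40)) * 0 + runif(40), cfg)
  expect_true(all(diff(tr) <= 0))
  drops <- tr[-1] / tr[-length(tr)]
  expect_true(all(abs(drops - 1) < 1e-12 | abs(drops - 0.1) < 1e-12))
})

tiny_setup <- function(n = 6, seed = 3) {
  cfg <- synthetic_config("liver_binary", n_samples = n, size = 16, seed = seed)
  ds <- generate_liver_like(cfg)
  split_dataset(ds, 2 / 3, seed = seed)
}

test_that("one epoch of training populates a complete history record", {
  sp <- tiny_setup()
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 7)
  fit <- fit_unet(m, sp$train, sp$val,
                  train_config(max_epochs = 1, batch_size = 2, seed = 7))
  h <- fit$history$epochs
  expect_equal(nrow(h), 1L)
  expect_true(all(is.finite(c(h$train_loss, h$val_loss, h$val_dice, h$lr))))
  expect_equal(h$epoch, 1L)
  expect_s3_class(fit, "unet_fit")
  expect_false(is.null(fit$best_params))
})

test_that("identical seeds give identical first-epoch training losses", {
  sp <- tiny_setup()
  cfg <- train_config(max_epochs = 1, batch_size = 2, seed = 13)
  f1 <- fit_unet(lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 9),
                 sp$train, sp$val, cfg)
  f2 <- fit_unet(lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 9),
                 sp$train, sp$val, cfg)
  expect_identical(f1$history$epochs$train_loss, f2$history$epochs$train_loss)
  expect_identical(f1$best_dice, f2$best_dice)
})

test_that("validation never changes the model parameters", {
  sp <- tiny_setup()
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 9)
  before <- m$params
  invisible(lfeunet:::validation_metrics(m, sp$val, loss_spec("CE"), 2L))
  expect_identical(m$params, before)
})

test_that("training rejects incompatible data before any step", {
  sp <- tiny_setup()
  m_wrong <- lfe_unet(unet_config("vgg16", N = 3, n = 4, in_channels = 12,
                                  classes = 4), seed = 1)
  expect_error(fit_unet(m_wrong, sp$train, sp$val, train_config(max_epochs = 1)),
               "channels")
})

test_that("the recorded learning-rate trace only falls, by the decay factor", {
  sp <- tiny_setup()
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), seed = 5)
  fit <- fit_unet(m, sp$train, sp$val,
                  train_config(max_epochs = 8, batch_size = 2, patience = 2,
                               seed = 5, learning_rate = 1e-3))
  lr <- fit$history$epochs$lr
  expect_true(all(diff(lr) <= 0))
  ratio <- lr[-1] / lr[-length(lr)]
  expect_true(all(abs(ratio - 1) < 1e-12 | abs(ratio - 0.1) < 1e-12))
})

test_that("multi-class training records per-region dice columns", {
  cfg <- synthetic_config("brats_multiclass", n_samples = 6, size = 16, seed = 4)
  ds <- generate_brats_like(cfg)
  sp <- split_dataset(ds, 2 / 3, seed = 4)
  m <- lfe_unet(unet_config("vgg16", N = 3, n = 4, in_channels = 12,
                            classes = 4), seed = 2)
  fit <- fit_unet(m, sp$train, sp$val,
                  train_config(max_epochs = 1, batch_size = 2, seed = 2,
                               loss = dfk_loss()))
  expect_true(all(c("dice_wt", "dice_tc", "dice_et") %in%
                    colnames(fit$history$epochs)))
})
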