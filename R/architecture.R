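#' Network configuration for an LFE-UNet
#'
#' Describes a lightweight full-encoder U-shaped segmentation network: a
#' contracting backbone of `N` levels whose level-i feature maps carry
#' `2^(i-1) * n` channels, and `N - 1` decoder levels, each of which
#' aggregates resampled feature maps from *every* encoder level (plus the
#' next-deeper decoder output) before fusing them with a two-convolution
#' block. All convolutions are bias-free and batch normalisation carries no
#' learnable affine terms, so the trainable parameters are exactly the
#' convolution weights.
#'
#' @param backbone `"vgg16"` (two 3x3 convolutions per stage) or `"resnet34"`
#'   (a stride-1 stem plus four stages of residual basic blocks).
#' @param N Number of encoder levels. 2..6 for `"vgg16"`; 5 for `"resnet34"`.
#' @param n Base channel count of the shallowest level.
#' @param in_channels Number of input image channels (3 for a single RGB-coded
#'   slice, 12 for four MRI modalities of three channels each).
#' @param classes Number of output classes.
#' @param kernel_size Odd convolution kernel size for all encoder/decoder
#'   convolutions (the final classifier is always 1x1).
#' @param blocks Residual basic-block counts per stage for the resnet34
#'   backbone (levels 2..5).
#' @return An object of class `"unet_config"`.
#' @export
unet_config <- function(backbone = c("vgg16", "resnet34"), N = 5L, n = 8L,
                        in_channels = 3L, classes = 2L, kernel_size = 3L,
                        blocks = c(3L, 4L, 6L, 3L)) {
  backbone <- match.arg(backbone)
  N <- as.integer(N); n <- as.integer(n)
  if (N < 2L) stop("N must be at least 2 (got ", N, ")")
  if (n < 1L) stop("n must be at least 1 (got ", n, ")")
  if (kernel_size %% 2L != 1L)
    stop("kernel_size must be odd (got ", kernel_size, ")")
  if (backbone == "vgg16" && N > 6L)
    stop("vgg16 backbone supports N in 2..6 (got N = ", N, ")")
  if (backbone == "resnet34") {
    if (N != 5L)
      stop("resnet34 backbone requires N = 5 (got N = ", N, ")")
    if (length(blocks) != 4L)
      stop("resnet34 backbone needs 4 basic-block counts (levels 2..5)")
  }
  structure(list(backbone = backbone, N = N, n = n,
                 in_channels = as.integer(in_channels),
                 classes = as.integer(classes),
                 kernel_size = as.integer(kernel_size),
                 blocks = as.integer(blocks)),
            class = "unet_config")
}

## Channel width of encoder (and mirrored decoder) level i.
level_channels <- function(config, i) config$n * 2L^(i - 1L)

## Enumerate every convolution in construction order.
## Returns a data.frame: name, layer, k, cin, cout, stride.
unet_conv_specs <- function(config) {
  k <- config$kernel_size
  N <- config$N
  n <- config$n
  rows <- list()
  add <- function(name, layer, k, cin, cout, stride = 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, layer = layer, k = k, cin = cin, cout = cout,
      stride = stride, stringsAsFactors = FALSE)

  if (config$backbone == "vgg16") {
    cin <- config$in_channels
    for (i in seq_len(N)) {
      w <- level_channels(config, i)
      add(sprintf("enc%d_conv1", i), sprintf("encoder_%d", i), k, cin, w)
      add(sprintf("enc%d_conv2", i), sprintf("encoder_%d", i), k, w, w)
      cin <- w
    }
  } else {
    add("stem", "encoder_1", k, config$in_channels, n)
    cin <- n
    for (i in 2:5) {
      w <- level_channels(config, i)
      b <- config$blocks[i - 1L]
      add(sprintf("enc%d_b1_conv1", i), sprintf("encoder_%d", i), k, cin, w, 2L)
      add(sprintf("enc%d_b1_conv2", i), sprintf("encoder_%d", i), k, w, w)
      add(sprintf("enc%d_down", i), sprintf("encoder_%d", i), 1L, cin, w, 2L)
      if (b > 1L) for (j in 2:b) {
        add(sprintf("enc%d_b%d_conv1", i, j), sprintf("encoder_%d", i), k, w, w)
        add(sprintf("enc%d_b%d_conv2", i, j), sprintf("encoder_%d", i), k, w, w)
      }
      cin <- w
    }
  }

  for (i in seq(N - 1L, 1L)) {
    d <- level_channels(config, i)
    nb <- decoder_branch_count(config, i)
    src <- decoder_branch_channels(config, i)
    for (b in seq_len(nb))
      add(sprintf("dec%d_gamma%d", i, b), sprintf("decoder_%d", i), k, src[b], d)
    add(sprintf("dec%d_theta1", i), sprintf("decoder_%d", i), k, nb * d, d)
    add(sprintf("dec%d_theta2", i), sprintf("decoder_%d", i), k, d, d)
  }
  add("classifier", "classifier", 1L, n, config$classes)
  do.call(rbind, rows)
}

## Decoder level i aggregates all N encoder levels, plus the level-(i+1)
## decoder output when i < N - 1. At i = N - 1 the subsequent layer is the
## bottleneck, i.e. encoder level N, which already sits among the full-encoder
## branches, so no extra branch is added there.
decoder_branch_count <- function(config, i) {
  if (i < config$N - 1L) config$N + 1L else config$N
}

decoder_branch_channels <- function(config, i) {
  ch <- vapply(seq_len(config$N), function(j) level_channels(config, j), 0)
  if (i < config$N - 1L) ch <- c(ch, level_channels(config, i + 1L))
  ch
}

#' Build an LFE-UNet model
#'
#' Constructs the network described by a [unet_config()]: the backbone
#' encoder, the full-encoder decoder levels and the 1x1 classifier, with
#' Kaiming-initialised weights. With `init = "none"` only the layer shapes
#' are laid out (no memory for weights), which is enough for parameter
#' accounting and summary tables.
#'
#' @param config A [unet_config()], or `NULL` to build one from `...`.
#' @param ... Arguments forwarded to [unet_config()] when `config` is `NULL`.
#' @param init `"kaiming"` (seedable random init) or `"none"` (shapes only).
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `"lfe_unet"` with elements `config`, `shapes`
#'   (named list of weight dims), `params` (named list of weight arrays, or
#'   `NULL`s when uninitialised) and `bn` (running batch-norm statistics).
#' @examples
#' m <- lfe_unet(unet_config("vgg16", N = 3, n = 4), init = "none")
#' n_params(m)
#' @export
lfe_unet <- function(config = NULL, ..., init = c("kaiming", "none"),
                     seed = 1L) {
  init <- match.arg(init)
  if (is.null(config)) config <- unet_config(...)
  if (!inherits(config, "unet_config")) stop("config must be a unet_config")
  specs <- unet_conv_specs(config)
  shapes <- stats::setNames(
    lapply(seq_len(nrow(specs)), function(r)
      c(specs$k[r], specs$k[r], specs$cin[r], specs$cout[r])),
    specs$name)
  params <- stats::setNames(vector("list", nrow(specs)), specs$name)
  if (init == "kaiming") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (nm in names(shapes)) {
      d <- shapes[[nm]]
      fan_in <- d[1] * d[2] * d[3]
      params[[nm]] <- array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), dim = d)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  structure(list(config = config, specs = specs, shapes = shapes,
                 params = params, bn = new.env(parent = emptyenv()),
                 initialized = init == "kaiming"),
            class = "lfe_unet")
}

#' @export
print.lfe_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("LFE-UNet (%s backbone): N = %d encoder levels, n = %d base channels\n",
              cfg$backbone, cfg$N, cfg$n))
  cat(sprintf("  input channels: %d, classes: %d, kernel size: %d\n",
              cfg$in_channels, cfg$classes, cfg$kernel_size))
  cat(sprintf("  trainable parameters: %s (%.3f M)\n",
              format(n_params(x), big.mark = ","), n_params(x) / 1e6))
  invisible(x)
}

#' Total trainable parameter count of a built model
#' @param model An `"lfe_unet"` model.
#' @return Integer count of trainable parameters (convolution weights).
#' @export
n_params <- function(model) {
  sum(vapply(model$shapes, prod, 0))
}

## ---- forward pass -------------------------------------------------------

## Resample a tape node from `from` level to `to` level.
resample_node <- function(tape, x, from, to) {
  if (to == from) return(x)
  if (to > from) return(ly_maxpool(tape, x, 2L^(to - from)))
  d <- dim(x$value)
  f <- 2L^(from - to)
  ly_bilinear(tape, x, d[1] * f, d[2] * f)
}

conv_bn_relu <- function(tape, x, model, name, training, stride = 1L) {
  y <- ly_conv(tape, x, model$params[[name]], name, stride = stride)
  y <- ly_bn(tape, y, model, paste0(name, "_bn"), training)
  ly_relu(tape, y)
}

encoder_forward <- function(tape, model, x, training) {
  cfg <- model$config
  feats <- vector("list", cfg$N)
  if (cfg$backbone == "vgg16") {
    h <- x
    for (i in seq_len(cfg$N)) {
      if (i > 1L) h <- ly_maxpool(tape, h, 2L)
      h <- conv_bn_relu(tape, h, model, sprintf("enc%d_conv1", i), training)
      h <- conv_bn_relu(tape, h, model, sprintf("enc%d_conv2", i), training)
      feats[[i]] <- h
    }
  } else {
    h <- conv_bn_relu(tape, x, model, "stem", training)
    feats[[1L]] <- h
    for (i in 2:5) {
      b <- cfg$blocks[i - 1L]
      for (j in seq_len(b)) {
        if (j == 1L) {
          id <- ly_conv(tape, h, model$params[[sprintf("enc%d_down", i)]],
                        sprintf("enc%d_down", i), stride = 2L, pad = 0L)
          id <- ly_bn(tape, id, model, sprintf("enc%d_down_bn", i), training)
          y <- conv_bn_relu(tape, h, model, sprintf("enc%d_b1_conv1", i),
                            training, stride = 2L)
        } else {
          id <- h
          y <- conv_bn_relu(tape, h, model, sprintf("enc%d_b%d_conv1", i, j),
                            training)
        }
        y <- ly_conv(tape, y, model$params[[sprintf("enc%d_b%d_conv2", i, j)]],
                     sprintf("enc%d_b%d_conv2", i, j))
        y <- ly_bn(tape, y, model, sprintf("enc%d_b%d_conv2_bn", i, j), training)
        h <- ly_relu(tape, ly_add(tape, y, id))
      }
      feats[[i]] <- h
    }
  }
  feats
}

decoder_level_forward <- function(tape, model, feats, deeper, i, training) {
  cfg <- model$config
  branches <- lapply(seq_len(cfg$N), function(j)
    resample_node(tape, feats[[j]], j, i))
  if (i < cfg$N - 1L)
    branches <- c(branches, list(resample_node(tape, deeper, i + 1L, i)))
  adapted <- lapply(seq_along(branches), function(b)
    ly_conv(tape, branches[[b]], model$params[[sprintf("dec%d_gamma%d", i, b)]],
            sprintf("dec%d_gamma%d", i, b)))
  h <- ly_concat(tape, adapted)
  h <- conv_bn_relu(tape, h, model, sprintf("dec%d_theta1", i), training)
  conv_bn_relu(tape, h, model, sprintf("dec%d_theta2", i), training)
}

## Full forward pass. `x` is an array dim c(H, W, C, N) (a lone c(H, W, C)
## image is promoted to a batch of one). Returns list(logits=, tape=).
unet_forward <- function(model, x, training = FALSE) {
  if (!model$initialized)
    stop("model was built with init = \"none\"; rebuild with weights to run it")
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cfg <- model$config
  d <- dim(x)
  if (d[3] != cfg$in_channels)
    stop("input has ", d[3], " channels but the model expects ", cfg$in_channels)
  if (d[1] %% 2L^(cfg$N - 1L) != 0L || d[2] %% 2L^(cfg$N - 1L) != 0L)
    stop("spatial size ", d[1], "x", d[2], " must be divisible by 2^(N-1) = ",
         2L^(cfg$N - 1L))
  tape <- tape_new()
  x0 <- tp_leaf(tape, x)
  feats <- encoder_forward(tape, model, x0, training)
  h <- feats[[cfg$N]]  # bottleneck doubles as the level-N decoder node
  for (i in seq(cfg$N - 1L, 1L))
    h <- decoder_level_forward(tape, model, feats, h, i, training)
  logits <- ly_conv(tape, h, model$params[["classifier"]], "classifier")
  list(logits = logits, tape = tape)
}

#' Run a model on images
#'
#' @param object An `"lfe_unet"` model.
#' @param newdata Array of dim `c(H, W, C)` or `c(H, W, C, batch)` with
#'   channel count matching the model.
#' @param type `"logits"`, `"prob"` (softmax over classes) or `"class"`
#'   (integer label map, classes coded 0..classes-1).
#' @param ... Unused.
#' @return Array of dim `c(H, W, classes, batch)`, or `c(H, W, batch)` class
#'   labels for `type = "class"`.
#' @export
predict.lfe_unet <- function(object, newdata, type = c("prob", "logits", "class"),
                             ...) {
  type <- match.arg(type)
  out <- unet_forward(object, newdata, training = FALSE)$logits$value
  if (type == "logits") return(out)
  p <- softmax4(out)
  if (type == "prob") return(p)
  apply(p, c(1, 2, 4), which.max) - 1L
}

## softmax over the 3rd (class) margin of a c(H,W,C,N) array
softmax4 <- function(x) {
  m <- apply(x, c(1, 2, 4), max)
  d <- dim(x)
  e <- exp(x - aperm(array(m, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)))
  s <- apply(e, c(1, 2, 4), sum)
  e / aperm(array(s, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

## ---- feature maps and the standalone ops of the module surface ----------

#' Multi-channel 2D feature map tagged with its scale level
#'
#' @param data Array dim `c(H, W, C)` or `c(H, W, C, batch)`.
#' @param level Integer scale index; level 1 is full resolution and the
#'   spatial size halves at each deeper level.
#' @return An object of class `"feature_map"`.
#' @export
feature_map <- function(data, level = 1L) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, level >= 1L)
  structure(list(data = data, level = as.integer(level),
                 channels = dim(data)[3]), class = "feature_map")
}

#' Resample a feature map to another scale level
#'
#' Moving to a deeper level applies non-overlapping max pooling with window
#' `2^(target - level)`; moving to a shallower level applies bilinear
#' interpolation (half-pixel centres) by `2^(level - target)`; equal levels
#' return the input unchanged. Channel count is preserved.
#'
#' @param f A [feature_map()].
#' @param target_level Integer level to resample to.
#' @return A [feature_map()] at `target_level`.
#' @export
resample <- function(f, target_level) {
  stopifnot(inherits(f, "feature_map"), target_level >= 1L)
  target_level <- as.integer(target_level)
  if (target_level == f$level) return(f)
  d <- dim(f$data)
  if (target_level > f$level) {
    w <- 2L^(target_level - f$level)
    if (d[1] < w || d[2] < w)
      stop("resampling to level ", target_level, " would shrink a ",
           d[1], "x", d[2], " map below 1 pixel")
    y <- maxpool_fwd_cpp(f$data, w)$y
  } else {
    fct <- 2L^(f$level - target_level)
    y <- bilinear_fwd_cpp(f$data, d[1] * fct, d[2] * fct)
  }
  feature_map(y, target_level)
}

#' Run one decoder level on explicit encoder features
#'
#' Applies the full-encoder aggregation of decoder level `i` using the
#' weights of `model`: every encoder feature map (and, for `i < N - 1`, the
#' deeper decoder output) is resampled to level `i`, adapted by its own
#' single convolution, concatenated, and fused by the two-convolution block.
#'
#' @param model An initialised `"lfe_unet"` model.
#' @param encoder_feats List of `N` [feature_map()]s, element `j` at level `j`.
#' @param deeper The level-`i+1` decoder output as a [feature_map()]; ignored
#'   at `i = N - 1`, where the subsequent layer is the bottleneck (encoder
#'   level `N`), already present among the branches.
#' @param i Decoder level in `1..N-1`.
#' @param training Logical; use batch statistics (TRUE) or running statistics.
#' @return A [feature_map()] at level `i` with `2^(i-1) * n` channels.
#' @export
decoder_layer_forward <- function(model, encoder_feats, deeper = NULL, i,
                                  training = FALSE) {
  cfg <- model$config
  stopifnot(i >= 1L, i <= cfg$N - 1L)
  if (length(encoder_feats) != cfg$N)
    stop("need ", cfg$N, " encoder feature maps, got ", length(encoder_feats))
  for (j in seq_len(cfg$N))
    if (encoder_feats[[j]]$level != j)
      stop("encoder feature ", j, " is at level ", encoder_feats[[j]]$level,
           ", expected level ", j)
  tape <- tape_new()
  feats <- lapply(encoder_feats, function(f) tp_leaf(tape, f$data))
  deeper_node <- NULL
  if (i < cfg$N - 1L) {
    if (is.null(deeper)) stop("decoder level ", i, " needs the level-", i + 1L,
                              " decoder output")
    if (deeper$level != i + 1L)
      stop("deeper input is at level ", deeper$level, ", expected ", i + 1L)
    deeper_node <- tp_leaf(tape, deeper$data)
  }
  out <- decoder_level_forward(tape, model, feats, deeper_node, i, training)
  feature_map(out$value, i)
}
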