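#' Closed-form trainable-parameter count
#'
#' Evaluates the analytic parameter count of an LFE-UNet from the
#' configuration alone, without constructing the network. The counting
#' convention (validated against the constructed network, see
#' [empirical_params()]) is: convolution weights only — convolutions carry no
#' bias and batch normalisation no learnable affine terms.
#'
#' For the vgg16 backbone the encoder contributes
#' \deqn{k_e^2 \sum_{i=1}^{N} \left(c_{i-1} 2^{i-1} n + (2^{i-1} n)^2\right)}
#' (two convolutions per stage, \eqn{c_0 = n_0}); decoder level \eqn{i} with
#' width \eqn{d = 2^{i-1} n} and \eqn{m} branches contributes
#' \eqn{k_e^2 (d \sum_j s_j + m d^2 + d^2)} where \eqn{s_j} are the branch
#' channel counts, and the classifier adds \eqn{n \cdot n_c}.
#'
#' @param config A [unet_config()].
#' @return Integer total parameter count.
#' @examples
#' closed_form_params(unet_config("vgg16", N = 5, n = 8)) / 1e6  # 0.892...
#' @export
closed_form_params <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  k2 <- config$kernel_size^2
  N <- config$N; n <- config$n
  total <- 0
  if (config$backbone == "vgg16") {
    cin <- config$in_channels
    for (i in seq_len(N)) {
      w <- level_channels(config, i)
      total <- total + k2 * (cin * w + w * w)
      cin <- w
    }
  } else {
    total <- total + k2 * config$in_channels * n
    cin <- n
    for (i in 2:5) {
      w <- level_channels(config, i)
      b <- config$blocks[i - 1L]
      total <- total + k2 * (cin * w + w * w) + cin * w +  # first block + 1x1
        (b - 1L) * 2 * k2 * w * w
      cin <- w
    }
  }
  for (i in seq_len(N - 1L)) {
    d <- level_channels(config, i)
    src <- decoder_branch_channels(config, i)
    m <- length(src)
    total <- total + k2 * (d * sum(src) + m * d * d + d * d)
  }
  total + n * config$classes
}

#' Empirical per-layer parameter report
#'
#' Enumerates the trainable parameters of a constructed model layer by layer
#' and cross-checks the total against the closed form.
#'
#' @param model An `"lfe_unet"` model (weights need not be initialised; the
#'   layer shapes are already laid out at construction).
#' @return A list of class `"param_report"` with elements `per_layer`
#'   (data.frame of layer id and count), `total`, `total_M` (millions, 3
#'   decimals) and `formula_total` (the closed-form count).
#' @export
empirical_params <- function(model) {
  stopifnot(inherits(model, "lfe_unet"))
  counts <- vapply(model$shapes, prod, 0)
  per_layer <- stats::aggregate(
    list(count = counts),
    by = list(layer = model$specs$layer), FUN = sum)
  ## keep architectural order
  per_layer <- per_layer[match(unique(model$specs$layer), per_layer$layer), ]
  rownames(per_layer) <- NULL
  total <- sum(counts)
  structure(list(per_layer = per_layer, total = total,
                 total_M = round(total / 1e6, 3),
                 formula_total = closed_form_params(model$config)),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  print(x$per_layer, row.names = FALSE)
  cat(sprintf("total: %s (%.3f M); closed form: %s (%s)\n",
              format(x$total, big.mark = ","), x$total_M,
              format(x$formula_total, big.mark = ","),
              if (x$total == x$formula_total) "agrees" else "DISAGREES"))
  invisible(x)
}

#' Parameter count as a percentage of a reference network
#'
#' @param count_M Parameter count in millions.
#' @param reference_M Reference network's parameter count in millions.
#' @return `100 * count_M / reference_M`, rounded to 2 decimals.
#' @examples
#' param_ratio(0.89, 26.97)  # 3.30
#' @export
param_ratio <- function(count_M, reference_M) {
  if (any(reference_M <= 0)) stop("reference_M must be positive")
  round(100 * count_M / reference_M, 2)
}

#' Parameter grid over encoder depths and base widths
#'
#' Tabulates the closed-form parameter count (in millions) of the
#' vgg16-backbone model over a grid of encoder depths and base channel
#' counts, in the style of the lightweight-design study.
#'
#' @param N Integer vector of encoder depths.
#' @param n Integer vector of base channel counts.
#' @param in_channels,classes Input channels and output classes.
#' @return data.frame with columns `N`, `n`, `params`, `params_M`.
#' @export
param_grid <- function(N = 3:6, n = c(8L, 16L, 32L, 64L),
                       in_channels = 3L, classes = 2L) {
  g <- expand.grid(n = n, N = N)[, c("N", "n")]
  g$params <- mapply(function(N, n)
    closed_form_params(unet_config("vgg16", N = N, n = n,
                                   in_channels = in_channels,
                                   classes = classes)),
    g$N, g$n)
  g$params_M <- round(g$params / 1e6, 3)
  g
}

#' Model summary as a data.frame (and optional JSON/TSV export)
#'
#' @param object An `"lfe_unet"` model.
#' @param ... Unused.
#' @return data.frame with one row per convolution: name, layer group,
#'   output channels and parameter count.
#' @export
summary.lfe_unet <- function(object, ...) {
  s <- object$specs
  data.frame(name = s$name, layer = s$layer, out_channels = s$cout,
             params = s$k^2 * s$cin * s$cout, stringsAsFactors = FALSE)
}

#' Export a model summary to JSON or TSV
#'
#' @param model An `"lfe_unet"` model.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_model_summary <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  s <- summary(model)
  if (format == "tsv") {
    utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(config = unclass(model$config), layers = s,
                              total = n_params(model)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Extract model weights
#'
#' @param object An `"lfe_unet"` model. @param ... Unused.
#' @return Named list of convolution weight arrays.
#' @export
coef.lfe_unet <- function(object, ...) object$params
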