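#' Load a run configuration from YAML
#'
#' Reads a YAML file with any of the sections `network`, `loss`, `train` and
#' `synth`, whose keys map onto the arguments of [unet_config()],
#' [loss_spec()], [train_config()] and [synthetic_config()]. Missing
#' sections fall back to the respective defaults.
#'
#' @param path Path to a YAML file.
#' Because bare `y`/`n` tokens are YAML booleans, the network keys may be
#' spelled `depth` (for `N`) and `base_channels` (for `n`); the quoted forms
#' `"N"`/`"n"` also work.
#'
#' @return List with elements `network`, `loss`, `train`, `synth`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("network:", "  backbone: vgg16", "  N: 5", "  n: 8",
#'              "loss:", "  components: [DL, FL, KL]"), f)
#' cfg <- load_run_config(f)
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$network)) {
    nw <- y$network
    if (!is.null(nw$depth)) { nw$N <- nw$depth; nw$depth <- NULL }
    if (!is.null(nw$base_channels)) { nw$n <- nw$base_channels; nw$base_channels <- NULL }
    y$network <- nw
  }
  loss <- do.call(loss_spec, if (is.null(y$loss)) list() else y$loss)
  train_args <- if (is.null(y$train)) list() else y$train
  train_args$loss <- loss
  list(network = do.call(unet_config,
                         if (is.null(y$network)) list() else y$network),
       loss = loss,
       train = do.call(train_config, train_args),
       synth = if (is.null(y$synth)) NULL else do.call(synthetic_config, y$synth))
}
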