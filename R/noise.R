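#' Noise specification
#'
#' @param kind `"gaussian_image"` (additive zero-mean Gaussian noise on
#'   intensity-normalised images, variance `variance`) or
#'   `"saltpepper_label"` (impulse corruption overwriting a fraction
#'   `variance` of label pixels, half salt, half pepper).
#' @param variance Noise variance `v_r` (Gaussian) or corrupted-pixel
#'   fraction `v_s` (salt-and-pepper, in `[0, 1]`).
#' @param seed Integer seed making the injection reproducible.
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("gaussian_image", "saltpepper_label"),
                       variance, seed = 1L) {
  kind <- match.arg(kind)
  if (variance < 0) stop("variance must be non-negative")
  if (kind == "saltpepper_label" && variance > 1)
    stop("salt-and-pepper fraction must be at most 1")
  structure(list(kind = kind, variance = variance, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add Gaussian noise to an intensity-normalised image
#'
#' Adds i.i.d. zero-mean Gaussian noise of variance `spec$variance` to every
#' pixel/channel, then clips the result back to `[0, 1]`.
#'
#' @param image Numeric array with values in `[0, 1]`.
#' @param spec A [noise_spec()] of kind `"gaussian_image"`.
#' @return Array of the same shape, values in `[0, 1]`.
#' @export
add_gaussian_image_noise <- function(image, spec) {
  stopifnot(inherits(spec, "noise_spec"), spec$kind == "gaussian_image")
  if (any(image < 0 | image > 1))
    stop("image values outside [0, 1]; normalise intensities before adding noise")
  if (spec$variance == 0) return(image)
  noisy <- image + withr_seed(spec$seed, stats::rnorm(length(image),
                                                      sd = sqrt(spec$variance)))
  out <- pmin(pmax(noisy, 0), 1)
  dim(out) <- dim(image)
  out
}

#' Add salt-and-pepper noise to a binary label mask
#'
#' Overwrites a fraction `spec$variance` of the pixels, chosen uniformly
#' without replacement: half are set to 1 (salt; the larger half when the
#' count is odd) and half to 0 (pepper). A chosen pixel counts as overwritten
#' even when the impulse equals its original value.
#'
#' @param label Binary (0/1 or logical) array.
#' @param spec A [noise_spec()] of kind `"saltpepper_label"`.
#' @return Binary array of the same shape.
#' @export
add_saltpepper_label_noise <- function(label, spec) {
  stopifnot(inherits(spec, "noise_spec"), spec$kind == "saltpepper_label")
  if (!all(label %in% c(0, 1)))
    stop("label must be binary (0/1) for salt-and-pepper corruption")
  m <- round(spec$variance * length(label))
  if (m == 0) return(label)
  out <- label
  pos <- withr_seed(spec$seed, sample.int(length(label), m))
  nsalt <- ceiling(m / 2)
  out[pos[seq_len(nsalt)]] <- 1L
  if (m > nsalt) out[pos[(nsalt + 1):m]] <- 0L
  dim(out) <- dim(label)
  out
}

## the seeded positions, exposed so corruption can be audited exactly
saltpepper_positions <- function(n_pixels, variance, seed) {
  m <- round(variance * n_pixels)
  if (m == 0) return(integer(0))
  withr_seed(seed, sample.int(n_pixels, m))
}

#' Degrade a dataset with image or label noise
#'
#' Returns a copy of the dataset with training inputs degraded: Gaussian
#' image noise leaves every label untouched; salt-and-pepper label noise
#' leaves every image untouched and corrupts only samples marked for
#' training (`role == "train"`, or all samples when no roles are set) —
#' validation labels always stay clean, since evaluation is against the true
#' annotation.
#'
#' @param dataset A `"seg_dataset"` (see [generate_liver_like()]).
#' @param spec A [noise_spec()]. Each sample is corrupted with an independent
#'   sub-seed derived from `spec$seed`, so the result is reproducible.
#' @return A degraded copy of the dataset.
#' @export
build_noisy_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "seg_dataset"), inherits(spec, "noise_spec"))
  out <- dataset
  roles <- attr(dataset, "roles")
  for (s in seq_along(dataset$samples)) {
    sub <- noise_spec(spec$kind, spec$variance,
                      seed = (spec$seed + 104729L * s) %% .Machine$integer.max)
    if (spec$kind == "gaussian_image") {
      out$samples[[s]]$image <-
        add_gaussian_image_noise(dataset$samples[[s]]$image, sub)
    } else {
      if (!is.null(roles) && roles[s] != "train") next
      out$samples[[s]]$label <-
        add_saltpepper_label_noise(dataset$samples[[s]]$label, sub)
    }
  }
  out
}

## run expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}
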