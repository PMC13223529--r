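#' Synthetic dataset configuration
#'
#' @param task `"liver_binary"` (3-channel image, one bright organ blob,
#'   binary label) or `"brats_multiclass"` (12-channel image from 4
#'   pseudo-modalities, 4-class label with nested tumor structures).
#' @param n_samples Number of slices to generate.
#' @param size Square slice side in pixels; must be divisible by `2^(N-1)`
#'   for the model depth `N` it feeds (the default 64 serves any `N` up to 6).
#' @param foreground_fraction_range `(lo, hi)` bounds on the foreground
#'   (organ, or whole-tumor) pixel fraction of every generated label.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(task = c("liver_binary", "brats_multiclass"),
                             n_samples = 10L, size = 64L,
                             foreground_fraction_range = NULL, seed = 1L) {
  task <- match.arg(task)
  if (is.null(foreground_fraction_range))
    foreground_fraction_range <-
      if (task == "liver_binary") c(0.10, 0.35) else c(0.06, 0.20)
  fr <- foreground_fraction_range
  if (!(length(fr) == 2 && fr[1] > 0 && fr[2] < 1 && fr[1] < fr[2]))
    stop("foreground_fraction_range must satisfy 0 < lo < hi < 1")
  structure(list(task = task, n_samples = as.integer(n_samples),
                 size = as.integer(size), foreground_fraction_range = fr,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## smooth random blob: elliptical-harmonic boundary r(theta) = r0 (1 + sum a_k cos(k theta + phi_k))
blob_shape <- function(size, center, r0, ak, phik, scale = 1) {
  xs <- matrix(rep(seq_len(size), size), size) - center[1]
  ys <- matrix(rep(seq_len(size), each = size), size) - center[2]
  th <- atan2(ys, xs)
  rr <- sqrt(xs^2 + ys^2)
  bound <- r0 * scale
  for (k in seq_along(ak))
    bound <- bound + r0 * scale * ak[k] * cos((k + 1) * th + phik[k])
  rr <= pmax(bound, 0.5)
}

## grow/shrink the blob radius until its pixel fraction lands inside (lo, hi)
calibrated_blob <- function(size, center, ak, phik, target, lo, hi) {
  frac <- function(r0) mean(blob_shape(size, center, r0, ak, phik))
  r <- size * sqrt(target / pi)
  for (iter in 1:60) {
    f <- frac(r)
    if (f > lo && f < hi) break
    r <- r * sqrt(ifelse(f <= lo, max(target / max(f, 1e-6), 1.05),
                         min(target / f, 0.95)))
  }
  f <- frac(r)
  if (f <= lo || f >= hi)
    stop("could not fit a blob with foreground fraction in (", lo, ", ", hi,
         ") at size ", size)
  list(r0 = r, mask = blob_shape(size, center, r, ak, phik))
}

new_seg_dataset <- function(samples, task, classes, class_names) {
  structure(list(samples = samples, task = task, classes = classes,
                 class_names = class_names), class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  d <- if (length(x$samples)) dim(x$samples[[1]]$image) else c(NA, NA, NA)
  cat(sprintf("seg_dataset: %d samples, task %s, %dx%d px, %d channels, %d classes\n",
              length(x$samples), x$task, d[1], d[2], d[3], x$classes))
  invisible(x)
}

#' @export
length.seg_dataset <- function(x) length(x$samples)

#' Generate liver-like binary segmentation slices
#'
#' Each sample carries a 3-channel image with one smooth, randomly shaped
#' bright blob (the "organ") on a darker textured background, and the binary
#' mask of that blob. The blob boundary is an elliptical-harmonic curve;
#' its area is calibrated into the configured foreground-fraction range.
#' Fixed contrasts (background ~0.25, organ ~0.65, texture noise sd 0.05)
#' keep the task learnable by the smallest network at small image sizes.
#'
#' @param cfg A [synthetic_config()] with `task = "liver_binary"`.
#' @return A `"seg_dataset"`: list of samples with `image` (`c(H, W, 3)`,
#'   values in `[0, 1]`) and `label` (`c(H, W)`, values 0/1).
#' @export
generate_liver_like <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), cfg$task == "liver_binary")
  fr <- cfg$foreground_fraction_range
  samples <- lapply(seq_len(cfg$n_samples), function(s) {
    withr_seed(cfg$seed + 7919L * s, {
      sz <- cfg$size
      center <- sz / 2 + stats::runif(2, -sz * 0.08, sz * 0.08)
      ak <- stats::rnorm(4, sd = 0.10 / seq_len(4))
      phik <- stats::runif(4, 0, 2 * pi)
      target <- stats::runif(1, fr[1], fr[2])
      blob <- calibrated_blob(sz, center, ak, phik, target, fr[1], fr[2])
      mask <- blob$mask
      gx <- matrix(rep(seq_len(sz) / sz, sz), sz)
      base <- 0.22 + 0.06 * gx
      img <- array(0, dim = c(sz, sz, 3))
      for (ch in 1:3) {
        ci <- base + (0.40 + 0.02 * ch) * mask +
          matrix(stats::rnorm(sz * sz, sd = 0.05), sz)
        img[, , ch] <- pmin(pmax(ci, 0), 1)
      }
      list(image = img, label = mask * 1L)
    })
  })
  new_seg_dataset(samples, "liver_binary", 2L, c("background", "liver"))
}

#' Generate brain-tumor-like multi-class slices
#'
#' Each sample carries a 12-channel image — four pseudo-modalities of three
#' channels each, sharing one geometry but with modality-specific contrasts —
#' and a 4-class label (0 background, 1 ET, 2 ED, 3 NET) built from three
#' concentric blob shapes inside a brain-like elliptical foreground: an ET
#' core inside a NET ring inside an ED ring, so the mapped nested regions
#' always satisfy `ET ⊆ TC ⊆ WT`. The whole-tumor pixel fraction is
#' calibrated into the configured range.
#'
#' @param cfg A [synthetic_config()] with `task = "brats_multiclass"`.
#' @return A `"seg_dataset"` with 12-channel images and 4-class labels.
#' @export
generate_brats_like <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), cfg$task == "brats_multiclass")
  fr <- cfg$foreground_fraction_range
  ## per-modality intensity increments for (brain, ED, NET, ET) over background
  contrasts <- rbind(flair = c(0.25, 0.35, 0.30, 0.28),
                     t1    = c(0.35, -0.10, -0.05, 0.05),
                     t1ce  = c(0.30, 0.05, 0.08, 0.40),
                     t2    = c(0.20, 0.40, 0.15, 0.10))
  samples <- lapply(seq_len(cfg$n_samples), function(s) {
    withr_seed(cfg$seed + 7919L * s, {
      sz <- cfg$size
      xs <- matrix(rep(seq_len(sz), sz), sz) / sz - 0.5
      ys <- matrix(rep(seq_len(sz), each = sz), sz) / sz - 0.5
      brain <- (xs / 0.42)^2 + (ys / 0.46)^2 <= 1
      center <- sz / 2 + stats::runif(2, -sz * 0.10, sz * 0.10)
      ak <- stats::rnorm(4, sd = 0.08 / seq_len(4))
      phik <- stats::runif(4, 0, 2 * pi)
      target <- stats::runif(1, fr[1], fr[2])
      blob <- calibrated_blob(sz, center, ak, phik, target, fr[1], fr[2])
      wt <- blob$mask & brain
      if (mean(wt) <= fr[1]) wt <- blob$mask  # keep the fraction contract
      tc <- blob_shape(sz, center, blob$r0, ak, phik, scale = 0.62) & wt
      et <- blob_shape(sz, center, blob$r0, ak, phik, scale = 0.34) & tc
      label <- matrix(0L, sz, sz)
      label[wt] <- 2L   # peritumoral edema
      label[tc] <- 3L   # non-enhancing core
      label[et] <- 1L   # enhancing core
      img <- array(0, dim = c(sz, sz, 12))
      for (m in 1:4) {
        base <- 0.15 + contrasts[m, 1] * brain + contrasts[m, 2] * (label == 2) +
          contrasts[m, 3] * (label == 3) + contrasts[m, 4] * (label == 1)
        for (ch in 1:3) {
          ci <- base * (1 + 0.02 * (ch - 2)) +
            matrix(stats::rnorm(sz * sz, sd = 0.04), sz)
          img[, , (m - 1) * 3 + ch] <- pmin(pmax(ci, 0), 1)
        }
      }
      list(image = img, label = label)
    })
  })
  new_seg_dataset(samples, "brats_multiclass", 4L,
                  c("background", "ET", "ED", "NET"))
}

#' Emulated CT volume of correlated slices
#'
#' Builds a toy "volume": one liver-like blob whose cross-section waxes and
#' wanes across `depth` slices (a lens-like profile), so slice-selection
#' logic can be exercised without real scans.
#'
#' @param cfg A [synthetic_config()] with `task = "liver_binary"`.
#' @param depth Number of slices in the volume.
#' @return List with `images` (`c(H, W, 3, depth)`) and `labels`
#'   (`c(H, W, depth)`).
#' @export
generate_liver_volume <- function(cfg, depth = 8L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fr <- cfg$foreground_fraction_range
  withr_seed(cfg$seed, {
    sz <- cfg$size
    center <- sz / 2 + stats::runif(2, -sz * 0.05, sz * 0.05)
    ak <- stats::rnorm(4, sd = 0.08 / seq_len(4))
    phik <- stats::runif(4, 0, 2 * pi)
    target <- mean(fr)
    blob <- calibrated_blob(sz, center, ak, phik, target, fr[1], fr[2])
    prof <- sin(pi * (seq_len(depth) - 0.5) / depth)  # 0..1..0 lens profile
    images <- array(0, dim = c(sz, sz, 3, depth))
    labels <- array(0L, dim = c(sz, sz, depth))
    gx <- matrix(rep(seq_len(sz) / sz, sz), sz)
    for (d in seq_len(depth)) {
      mask <- if (prof[d] < 0.15) matrix(FALSE, sz, sz) else
        blob_shape(sz, center, blob$r0, ak, phik, scale = prof[d])
      labels[, , d] <- mask * 1L
      for (ch in 1:3)
        images[, , ch, d] <- pmin(pmax(
          0.22 + 0.06 * gx + 0.42 * mask +
            matrix(stats::rnorm(sz * sz, sd = 0.05), sz), 0), 1)
    }
    list(images = images, labels = labels)
  })
}

#' Pick the most prominent slices of a volume by foreground size
#'
#' Returns the indices (1-based) of the `k` slices with the largest
#' foreground pixel counts, in decreasing order of count with ties broken by
#' the lower index. Slices with no foreground are never selected; if fewer
#' than `k` slices are non-empty, all non-empty ones are returned.
#'
#' @param volume_labels Array `c(H, W, depth)` of masks, or a list of masks.
#' @param k Number of slices to select.
#' @return Integer vector of slice indices.
#' @examples
#' v <- array(0, c(2, 2, 4)); v[1, 1, 2] <- 1; v[, , 3] <- 1
#' select_prominent_slices(v, 2)  # 3 then 2
#' @export
select_prominent_slices <- function(volume_labels, k) {
  stopifnot(k >= 1)
  counts <- if (is.list(volume_labels))
    vapply(volume_labels, function(m) sum(m != 0), 0)
  else {
    if (length(dim(volume_labels)) != 3L)
      stop("volume_labels must be a c(H, W, depth) array or a list of masks")
    apply(volume_labels != 0, 3, sum)
  }
  if (length(counts) == 0L) stop("empty slice stack")
  ord <- order(-counts, seq_along(counts))
  ord <- ord[counts[ord] > 0]
  utils::head(ord, k)
}

#' Drop slices with too little enhancing tumor
#'
#' Keeps only the samples whose ET-pixel count (label code 1) is at least
#' `min_et`; mirrors the preprocessing rule that excludes slices with fewer
#' than 20 enhancing-tumor pixels.
#'
#' @param dataset A multi-class `"seg_dataset"`.
#' @param min_et Minimum ET pixel count (default 20).
#' @return The filtered dataset.
#' @export
filter_et_slices <- function(dataset, min_et = 20L) {
  stopifnot(inherits(dataset, "seg_dataset"))
  keep <- vapply(dataset$samples, function(s) sum(s$label == 1L) >= min_et,
                 logical(1))
  dataset$samples <- dataset$samples[keep]
  dataset
}

#' Seeded train/validation split
#'
#' Shuffles the samples with the given seed, assigns the first
#' `round(fraction * n)` to training and the rest to validation; the two
#' parts are disjoint and jointly exhaustive.
#'
#' @param dataset A `"seg_dataset"`.
#' @param fraction Training fraction in (0, 1); 0.9 reproduces a 90/10 split.
#' @param seed Integer seed.
#' @return List with elements `train` and `val`, both `"seg_dataset"`s.
#' @export
split_dataset <- function(dataset, fraction = 0.9, seed = 1L) {
  stopifnot(inherits(dataset, "seg_dataset"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- length(dataset$samples)
  if (n < 2L) stop("need at least 2 samples to split")
  perm <- withr_seed(seed, sample.int(n))
  ntr <- min(max(round(fraction * n), 1L), n - 1L)
  tr <- dataset; tr$samples <- dataset$samples[perm[seq_len(ntr)]]
  va <- dataset; va$samples <- dataset$samples[perm[setdiff(seq_len(n), seq_len(ntr))]]
  list(train = tr, val = va)
}
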