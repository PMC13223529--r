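## Dataset input/output.
##
## png_pairs layout: <dir>/images/<stem>[_m<k>].png, <dir>/labels/<stem>.png,
## plus manifest.tsv pairing them. Images are stored as 8-bit PNG in [0, 1];
## 12-channel samples are split into four 3-channel modality files. Labels
## are stored as integer codes in an 8-bit grayscale PNG (code / 255), which
## round-trips losslessly for up to 256 classes.
##
## nifti_volumes layout: <dir>/images/<stem>.nii(.gz) and
## <dir>/labels/<stem>.nii(.gz); each volume of depth d yields d slice
## samples, sliced along the third (axial) axis. Single-channel image
## volumes are replicated to three channels on read, the way grayscale CT is
## fed to three-channel networks; intensities are min-max normalised to
## [0, 1] and the scaling is recorded in the dataset manifest.

#' Write a segmentation dataset to disk
#'
#' @param dataset A `"seg_dataset"`.
#' @param path Output directory (created if needed).
#' @param layout `"png_pairs"` or `"nifti_volumes"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, layout = c("png_pairs", "nifti_volumes")) {
  layout <- match.arg(layout)
  stopifnot(inherits(dataset, "seg_dataset"))
  dir.create(file.path(path, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "labels"), recursive = TRUE, showWarnings = FALSE)
  if (layout == "png_pairs") {
    rows <- lapply(seq_along(dataset$samples), function(s) {
      smp <- dataset$samples[[s]]
      stem <- sprintf("sample_%04d", s)
      C <- dim(smp$image)[3]
      nmod <- C %/% 3L
      imgs <- character(nmod)
      for (m in seq_len(nmod)) {
        fn <- if (nmod == 1L) paste0(stem, ".png")
              else sprintf("%s_m%d.png", stem, m)
        png::writePNG(smp$image[, , (m - 1L) * 3L + 1:3],
                      file.path(path, "images", fn))
        imgs[m] <- fn
      }
      png::writePNG(smp$label / 255, file.path(path, "labels", paste0(stem, ".png")))
      data.frame(stem = stem, images = paste(imgs, collapse = ";"),
                 label = paste0(stem, ".png"), scale = 1,
                 stringsAsFactors = FALSE)
    })
    man <- do.call(rbind, rows)
    man$task <- dataset$task
    man$classes <- dataset$classes
    utils::write.table(man, file.path(path, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    d1 <- dim(dataset$samples[[1]]$image)
    imgs <- vapply(dataset$samples, function(s) {
      if (!identical(dim(s$image), d1))
        stop("nifti_volumes layout needs samples of identical shape")
      s$image[, , 1]  # channel 1 carries the intensity
    }, matrix(0, d1[1], d1[2]))
    labs <- vapply(dataset$samples, function(s) s$label + 0,
                   matrix(0, d1[1], d1[2]))
    RNifti::writeNifti(imgs, file.path(path, "images", "volume.nii.gz"))
    RNifti::writeNifti(labs, file.path(path, "labels", "volume.nii.gz"))
    utils::write.table(
      data.frame(stem = "volume", task = dataset$task,
                 classes = dataset$classes, scale = 1),
      file.path(path, "manifest.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' Read a segmentation dataset from disk
#'
#' @param path Dataset directory (see the layout notes in this file's
#'   documentation).
#' @param layout `"png_pairs"` or `"nifti_volumes"`.
#' @param classes Number of classes; label values at or above this count are
#'   an error. Read from the manifest when present.
#' @return A `"seg_dataset"`.
#' @export
read_dataset <- function(path, layout = c("png_pairs", "nifti_volumes"),
                         classes = NULL) {
  layout <- match.arg(layout)
  manifest_path <- file.path(path, "manifest.tsv")
  man <- if (file.exists(manifest_path))
    utils::read.table(manifest_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  if (layout == "png_pairs") {
    if (is.null(man)) stop("missing manifest: ", manifest_path)
    task <- man$task[1]
    if (is.null(classes)) classes <- man$classes[1]
    samples <- lapply(seq_len(nrow(man)), function(s) {
      imgs <- strsplit(man$images[s], ";", fixed = TRUE)[[1]]
      chans <- lapply(imgs, function(fn) {
        fp <- file.path(path, "images", fn)
        if (!file.exists(fp)) stop("missing image file: ", fp)
        a <- png::readPNG(fp)
        if (length(dim(a)) == 2L) array(a, dim = c(dim(a), 1L)) else a
      })
      img <- array(0, dim = c(dim(chans[[1]])[1:2],
                              sum(vapply(chans, function(a) dim(a)[3], 0L))))
      at <- 0L
      for (a in chans) {
        img[, , at + seq_len(dim(a)[3])] <- a
        at <- at + dim(a)[3]
      }
      fp <- file.path(path, "labels", man$label[s])
      if (!file.exists(fp)) stop("missing label file: ", fp)
      lab <- round(png::readPNG(fp) * 255)
      if (length(dim(lab)) == 3L) lab <- lab[, , 1]
      if (any(lab >= classes))
        stop("label file ", fp, " contains value(s) >= ", classes)
      if (!identical(dim(lab), dim(img)[1:2]))
        stop("image/label shape mismatch for ", man$stem[s])
      list(image = img, label = array(as.integer(lab), dim = dim(lab)))
    })
    return(new_seg_dataset(samples, task, as.integer(classes),
                           class_names = if (classes == 4L)
                             c("background", "ET", "ED", "NET")
                           else c("background", "foreground")))
  }
  img_files <- sort(list.files(file.path(path, "images"),
                               pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(img_files) == 0L) stop("no NIfTI volumes under ", path)
  if (is.null(classes)) classes <- if (!is.null(man)) man$classes[1] else 2L
  task <- if (!is.null(man)) man$task[1] else "liver_binary"
  samples <- list()
  for (f in img_files) {
    stem <- sub("\\.nii(\\.gz)?$", "", basename(f))
    lf <- file.path(path, "labels", basename(f))
    if (!file.exists(lf))
      stop("missing label volume for ", basename(f))
    vol <- as.array(RNifti::readNifti(f))
    lab <- as.array(RNifti::readNifti(lf))
    if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
    if (length(dim(lab)) == 2L) dim(lab) <- c(dim(lab), 1L)
    if (!identical(dim(vol), dim(lab)))
      stop("image/label volume shape mismatch for ", basename(f))
    rng <- range(vol)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    vol <- (vol - rng[1]) / scale
    for (d in seq_len(dim(vol)[3])) {
      sl <- vol[, , d]
      lb <- lab[, , d]
      if (any(lb >= classes)) stop("label volume ", lf, " has value(s) >= ", classes)
      samples[[length(samples) + 1L]] <-
        list(image = array(rep(sl, 3L), dim = c(dim(sl), 3L)),
             label = array(as.integer(lb), dim = dim(lb)))
    }
  }
  ds <- new_seg_dataset(samples, task, as.integer(classes),
                        class_names = c("background", "foreground"))
  attr(ds, "intensity_scale") <- scale
  ds
}
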