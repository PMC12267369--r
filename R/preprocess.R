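#' Preprocessing configuration
#'
#' The preprocessing pipeline applies, in order: intensity windowing in raw
#' input units (optional), min-max normalization to `[0,1]`, and resizing to
#' a square working resolution. Windowing in raw units must precede
#' normalization to be well defined, which fixes the stage order. The default
#' window of `[-100, 400]` Hounsfield units is a conventional soft-tissue /
#' liver CT window; synthetic phantom data (already in `[0,1]`) disables it.
#'
#' @param target_size pixels per side of the working resolution.
#' @param window length-2 intensity interval `c(lo, hi)` in input units.
#' @param apply_window whether to clamp intensities to `window` first.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 256L, window = c(-100, 400),
                              apply_window = FALSE) {
  if (target_size <= 0) stop("target_size must be positive")
  if (apply_window && window[1] >= window[2])
    stop("window must satisfy lo < hi")
  structure(list(target_size = as.integer(target_size), window = window,
                 apply_window = isTRUE(apply_window)),
            class = "preprocess_config")
}

#' Clamp intensities to a window
#'
#' Every value is replaced by `min(max(x, lo), hi)`; shape is preserved.
#' On CT data this is the usual Hounsfield-unit windowing step.
#'
#' @param image numeric array.
#' @param lo,hi window bounds, `lo < hi`.
#' @return the clamped array.
#' @export
window_clip <- function(image, lo, hi) {
  if (lo >= hi) stop("window_clip requires lo < hi")
  out <- pmin(pmax(image, lo), hi)
  dim(out) <- dim(image)
  out
}

#' Min-max normalization to \[0,1\]
#'
#' Maps `x` to `(x - min) / (max - min)`. A constant image (zero range) maps
#' to all zeros rather than NaN. Non-finite input is rejected.
#'
#' @param image numeric array with finite values.
#' @return array of the same shape with values in `[0,1]`.
#' @export
minmax_normalize <- function(image) {
  if (!all(is.finite(image))) stop("minmax_normalize: non-finite values")
  lo <- min(image); hi <- max(image)
  out <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  dim(out) <- dim(image)
  out
}

#' Resize a slice/mask pair to a square target resolution
#'
#' The image is interpolated bilinearly; the mask is resampled with nearest
#' neighbor so it stays binary.
#'
#' @param pair a `slice_pair` (list with `image` and `mask` matrices).
#' @param target_size pixels per side.
#' @return a `slice_pair` at `target_size` x `target_size`.
#' @export
resize_pair <- function(pair, target_size) {
  if (length(target_size) != 1 || target_size <= 0)
    stop("target_size must be a single positive (square) size")
  img <- pair$image
  msk <- pair$mask
  if (nrow(img) != target_size || ncol(img) != target_size) {
    img <- EBImage::resize(img, w = target_size, h = target_size,
                           filter = "bilinear")
    msk <- EBImage::resize(msk, w = target_size, h = target_size,
                           filter = "none")
    img <- matrix(as.numeric(img), target_size, target_size)
    msk <- matrix(as.numeric(msk), target_size, target_size)
  }
  structure(list(image = img, mask = round(msk)), class = "slice_pair")
}

#' Full preprocessing pipeline for one slice/mask pair
#'
#' Applies [window_clip()] (if enabled), then [minmax_normalize()], then
#' [resize_pair()].
#'
#' @param pair a `slice_pair`.
#' @param config a [preprocess_config()].
#' @return the preprocessed `slice_pair` with image values in `[0,1]`.
#' @export
preprocess_slice <- function(pair, config) {
  stopifnot(inherits(config, "preprocess_config"))
  img <- pair$image
  if (config$apply_window)
    img <- window_clip(img, config$window[1], config$window[2])
  img <- minmax_normalize(img)
  resize_pair(structure(list(image = img, mask = pair$mask),
                        class = "slice_pair"),
              config$target_size)
}

#' Extract axial slice/mask pairs from NIfTI volumes
#'
#' Reads an image volume and a label volume (`.nii` / `.nii.gz`), iterates
#' axial (third-dimension) slices pairing them by index, and binarizes the
#' label against `target_label` (liver = 1 convention in LiTS-style files;
#' labels greater than or equal to `target_label` count as foreground when
#' `at_least` is `TRUE`, useful for liver+tumor label schemes).
#'
#' @param image_path path to the intensity volume.
#' @param label_path path to the segmentation volume.
#' @param target_label integer label treated as foreground.
#' @param at_least if `TRUE`, labels `>= target_label` are foreground.
#' @return list of `slice_pair` objects (raw units, not yet preprocessed).
#' @export
nifti_slice_pairs <- function(image_path, label_path, target_label = 1L,
                              at_least = FALSE) {
  vol <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  if (!all(dim(vol)[1:3] == dim(lab)[1:3]))
    stop("image and label volumes have different dimensions")
  lapply(seq_len(dim(vol)[3]), function(k) {
    m <- lab[, , k]
    m <- if (at_least) (m >= target_label) else (m == target_label)
    structure(list(image = matrix(as.numeric(vol[, , k]), dim(vol)[1]),
                   mask = matrix(as.numeric(m), dim(lab)[1])),
              class = "slice_pair")
  })
}
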