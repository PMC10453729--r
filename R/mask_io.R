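#' Load a segmentation mask from disk
#'
#' Reads a PNG (2-D) or NIfTI (2-D or 3-D) file and binarizes it into a
#' [binary_mask()]. The default rule treats every nonzero value as
#' foreground; alternatively a single label value can be selected as the
#' foreground class (one-vs-rest), e.g. to extract class 2 from a label map.
#'
#' @param path Path to a `.png`, `.nii` or `.nii.gz` file; format is
#'   inferred from the extension.
#' @param binarize Either the string `"nonzero"` (default) or a single
#'   numeric label value: pixels equal to that label become foreground.
#'   For PNG label maps the stored 8-bit integer values are compared.
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, binarize = "nonzero") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  fmt <- mask_format(path)
  values <- if (fmt == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      # RGB(A): accept only if colour channels agree, then use the first
      ch <- dim(img)[3]
      rgb <- img[, , seq_len(min(ch, 3L)), drop = FALSE]
      if (any(apply(rgb, c(1, 2), function(v) length(unique(v))) != 1L)) {
        stop("RGB PNG with non-identical channels is not a mask: ", path)
      }
      img <- img[, , 1]
    }
    round(img * 255)  # back to 8-bit integer labels
  } else {
    as.array(RNifti::readNifti(path))
  }
  if (anyNA(values)) stop("mask file contains missing values: ", path)
  fg <- if (identical(binarize, "nonzero")) {
    values != 0
  } else if (is.numeric(binarize) && length(binarize) == 1L) {
    values == binarize
  } else {
    stop("binarize must be \"nonzero\" or a single label value")
  }
  binary_mask(array(fg, dim = dim(values)))
}

mask_format <- function(path) {
  lower <- tolower(path)
  if (endsWith(lower, ".png")) "png"
  else if (endsWith(lower, ".nii") || endsWith(lower, ".nii.gz")) "nifti"
  else stop("unsupported mask format (expected .png, .nii or .nii.gz): ", path)
}

#' Save a segmentation mask to disk
#'
#' Writes foreground as 1 (255 in 8-bit PNG) and background as 0, so that
#' `load_mask(save_mask(m, path))` round-trips exactly. PNG supports 2-D
#' masks only; NIfTI supports 2-D and 3-D.
#'
#' @param mask A [binary_mask()].
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  m <- as_mask_array(mask)
  fmt <- mask_format(path)
  if (fmt == "png") {
    if (length(dim(m)) != 2L) {
      stop("PNG supports 2-D masks only; use NIfTI for ",
           length(dim(m)), "-D masks")
    }
    png::writePNG(m * 1, path)
  } else {
    RNifti::writeNifti(array(as.integer(m), dim = dim(m)), path)
  }
  invisible(path)
}
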