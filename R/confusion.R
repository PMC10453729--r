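#' Binary segmentation masks
#'
#' A binary mask is an n-dimensional logical array (`TRUE` = foreground, the
#' positive class; `FALSE` = background). Binarization of raw pixel data is
#' the loader's job ([load_mask()]); this constructor only validates.
#'
#' @param data A logical array, matrix or vector, or a numeric array
#'   containing only 0 and 1. Plain vectors are treated as 1-dimensional
#'   masks.
#' @return An object of class `binary_mask`: a logical array with a `dim`
#'   attribute.
#' @examples
#' binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
#' @export
binary_mask <- function(data) {
  if (is.numeric(data)) {
    if (anyNA(data) || !all(data %in% c(0, 1))) {
      stop("numeric mask data must contain only 0 and 1 (binarize at load time)")
    }
    data <- data == 1
  }
  if (!is.logical(data)) {
    stop("mask data must be logical (or strictly 0/1 numeric)")
  }
  if (anyNA(data)) stop("mask data must not contain NA")
  if (length(data) < 1L) stop("mask must contain at least one element")
  if (is.null(dim(data))) dim(data) <- length(data)
  class(data) <- c("binary_mask", class(data))
  data
}

#' @rdname binary_mask
#' @param x Object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

as_mask_array <- function(x) {
  if (is_binary_mask(x)) return(unclass(x))
  unclass(binary_mask(x))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x), collapse = " x "),
      " (", sum(x), " foreground of ", length(x), ")\n", sep = "")
  invisible(x)
}

#' Confusion counts for a binary mask pair
#'
#' The four confusion-matrix cells over all pixels/voxels: TP (foreground
#' predicted foreground), FP (background predicted foreground), TN
#' (background predicted background), FN (foreground predicted background).
#' `P = TP + FN` is the number of actual positives and `N = TN + FP` the
#' number of actual negatives; an image with `P = 0` is a *weak label*
#' (no region of interest in the ground truth).
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts; at least one must be
#'   positive (an all-zero confusion matrix corresponds to an empty image,
#'   which is rejected).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @examples
#' counts_from_cells(tp = 0, fp = 5000, tn = 55000, fn = 0)
#' @export
counts_from_cells <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(cells) || !is.numeric(cells)) stop("cells must be numeric and non-missing")
  if (any(cells < 0)) {
    stop("negative confusion cell(s): ",
         paste(names(cells)[cells < 0], collapse = ", "))
  }
  if (any(cells != round(cells))) stop("confusion cells must be whole numbers")
  if (sum(cells) == 0) stop("all-zero confusion counts correspond to an empty image")
  structure(as.list(as.numeric(cells)[c(1, 2, 3, 4)]) |>
              stats::setNames(c("tp", "fp", "tn", "fn")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g FP=%g TN=%g FN=%g (P=%g, N=%g)\n",
              x$tp, x$fp, x$tn, x$fn, positives(x), negatives(x)))
  invisible(x)
}

#' @rdname counts_from_cells
#' @param c A `confusion_counts` object.
#' @export
positives <- function(c) c$tp + c$fn

#' @rdname counts_from_cells
#' @export
negatives <- function(c) c$tn + c$fp

#' Compute confusion counts from a ground-truth/prediction mask pair
#'
#' @param truth,pred [binary_mask()] objects (or coercible arrays) of
#'   identical shape.
#' @return A [counts_from_cells()] `confusion_counts` object whose four cells
#'   sum to the total element count of the masks.
#' @examples
#' truth <- binary_mask(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE))
#' pred  <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
#' compute_confusion(truth, pred)
#' @export
compute_confusion <- function(truth, pred) {
  t <- as_mask_array(truth)
  p <- as_mask_array(pred)
  if (!identical(dim(t), dim(p))) {
    stop(sprintf("mask shape mismatch: truth is %s, prediction is %s",
                 paste(dim(t), collapse = "x"), paste(dim(p), collapse = "x")))
  }
  counts_from_cells(tp = sum(t & p), fp = sum(!t & p),
                    tn = sum(!t & !p), fn = sum(t & !p))
}
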