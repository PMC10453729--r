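#' Scenario specification for synthetic mask pairs
#'
#' Describes one ground-truth/prediction scenario: an optional disk-shaped
#' "lesion" in the ground truth, and a perturbation that turns the truth
#' into a prediction. A scenario without a lesion is a *weak label*
#' (ground-truth `P = 0`), the control-patient case.
#'
#' @param name Scenario identifier.
#' @param image_shape Integer vector of positive extents (2-D or 3-D).
#' @param lesion `NULL` for a weak label, or `list(center =, radius =)`
#'   with `center` a coordinate vector matching `image_shape` and `radius`
#'   a non-negative pixel radius. The rasterization rule is: a pixel is
#'   foreground iff its integer coordinate lies within Euclidean distance
#'   `radius` of `center`.
#' @param perturbation One of `"none"`, `"dilate"`, `"erode"`, `"shift"`,
#'   `"spurious_blob"`, `"empty_prediction"`, `"full_false_positive"`,
#'   `"invert"`.
#' @param magnitude Non-negative integer pixel magnitude (brush/blob radius
#'   or shift distance); ignored by the parameter-free perturbations.
#' @param seed Integer seed for the randomized perturbations
#'   (`spurious_blob`).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, image_shape = c(64, 64), lesion = NULL,
                          perturbation = "none", magnitude = 0L, seed = 1L) {
  kinds <- c("none", "dilate", "erode", "shift", "spurious_blob",
             "empty_prediction", "full_false_positive", "invert")
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  if (any(image_shape < 1) || any(image_shape != round(image_shape))) {
    stop("image_shape must be positive integers")
  }
  if (!perturbation %in% kinds) {
    stop("unknown perturbation '", perturbation, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  }
  if (magnitude < 0 || magnitude != round(magnitude)) {
    stop("magnitude must be a non-negative integer")
  }
  if (!is.null(lesion)) {
    if (!is.list(lesion) || !all(c("center", "radius") %in% names(lesion))) {
      stop("lesion must be NULL or list(center =, radius =)")
    }
    if (length(lesion$center) != length(image_shape)) {
      stop("lesion center dimensionality must match image_shape")
    }
    if (lesion$radius < 0) stop("lesion radius must be non-negative")
  }
  structure(list(name = name, image_shape = as.integer(image_shape),
                 lesion = lesion, perturbation = perturbation,
                 magnitude = as.integer(magnitude), seed = as.integer(seed)),
            class = "scenario_spec")
}

# logical array with TRUE where the Euclidean distance from `center`
# is <= radius; pixel centers are integer grid coordinates
rasterize_ball <- function(shape, center, radius) {
  zero <- array(0, dim = shape)
  dist2 <- Reduce(`+`, lapply(seq_along(shape), function(d) {
    (slice.index(zero, d) - center[d])^2
  }))
  dist2 <= radius^2
}

#' Generate the ground-truth mask of a scenario
#'
#' A filled disk (2-D) or ball (3-D) at the lesion location, or an
#' all-background mask for a weak-label scenario.
#'
#' @param spec A [scenario_spec()].
#' @return A [binary_mask()].
#' @export
make_truth <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  shape <- spec$image_shape
  if (is.null(spec$lesion)) {
    return(binary_mask(array(FALSE, dim = shape)))
  }
  ctr <- spec$lesion$center
  r <- spec$lesion$radius
  if (any(ctr - r < 1) || any(ctr + r > shape)) {
    stop(sprintf("lesion (center %s, radius %g) overflows image %s",
                 paste(ctr, collapse = ","), r, paste(shape, collapse = "x")))
  }
  binary_mask(array(rasterize_ball(shape, ctr, r), dim = shape))
}

# binary morphology via EBImage disc brushes (2-D only)
morph_2d <- function(mask, op, radius) {
  if (length(dim(mask)) != 2L) {
    stop("dilate/erode perturbations support 2-D masks only")
  }
  if (radius == 0) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- op(EBImage::Image(mask * 1), brush)
  array(as.array(out) > 0.5, dim = dim(mask))
}

shift_axis1 <- function(mask, by) {
  out <- array(FALSE, dim = dim(mask))
  n <- dim(mask)[1]
  if (by < n) {
    idx_src <- seq_len(n - by)
    idx_dst <- idx_src + by
    # build index list for arbitrary dimensionality
    src <- do.call(`[`, c(list(mask), list(idx_src),
                          rep(list(quote(expr = )), length(dim(mask)) - 1L),
                          list(drop = FALSE)))
    do.call(`[<-`, c(list(out), list(idx_dst),
                     rep(list(quote(expr = )), length(dim(mask)) - 1L),
                     list(value = src)))
  } else out
}

#' Generate the predicted mask of a scenario
#'
#' Applies the scenario's perturbation to the ground truth:
#' * `none` — identical copy (a perfect prediction);
#' * `dilate` / `erode` — morphological over-/under-segmentation by a disc
#'   of radius `magnitude` (2-D only);
#' * `shift` — translation by `magnitude` pixels along the first axis,
#'   dropping pixels shifted out of the image (no wrap-around);
#' * `spurious_blob` — the truth plus a disk of radius `magnitude` centred
#'   at a seeded random background pixel (clipped at image borders), the
#'   canonical weak-label false-positive case;
#' * `empty_prediction` — all background;
#' * `full_false_positive` — all foreground;
#' * `invert` — the complement of the truth.
#'
#' @param truth A [binary_mask()] consistent with `spec`.
#' @param spec A [scenario_spec()].
#' @return A [binary_mask()] of the same shape as `truth`.
#' @export
make_prediction <- function(truth, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  t <- as_mask_array(truth)
  shape <- dim(t)
  if (!identical(as.integer(shape), spec$image_shape)) {
    stop("truth shape does not match the scenario's image_shape")
  }
  m <- spec$magnitude
  pred <- switch(spec$perturbation,
    none = t,
    dilate = morph_2d(t, EBImage::dilate, m),
    erode = morph_2d(t, EBImage::erode, m),
    shift = shift_axis1(t, m),
    spurious_blob = {
      bg <- which(!t)
      if (length(bg) == 0) stop("spurious_blob needs at least one background pixel")
      ctr <- withr::with_seed(spec$seed, {
        arrayInd(bg[sample.int(length(bg), 1L)], .dim = shape)[1, ]
      })
      t | rasterize_ball(shape, ctr, m)
    },
    empty_prediction = array(FALSE, dim = shape),
    full_false_positive = array(TRUE, dim = shape),
    invert = !t
  )
  binary_mask(array(pred, dim = shape))
}

#' Deterministic scenario suite
#'
#' A seeded bundle of ground-truth/prediction pairs covering the normal and
#' edge cases relevant to weak-label evaluation: a perfect prediction,
#' under-/over-segmentation, a shifted prediction, an inverted annotation,
#' and weak-label scenarios ranging from a perfect all-background prediction
#' to a fully false-positive one.
#'
#' @param seed Integer seed; the same seed always yields identical masks.
#' @param image_shape 2-D image extents for every scenario.
#' @return A named list of `list(spec, truth, pred)` entries.
#' @export
scenario_suite <- function(seed = 42L, image_shape = c(64, 64)) {
  ctr <- as.integer(floor(image_shape / 2))
  lesion <- list(center = ctr, radius = 10)
  specs <- list(
    scenario_spec("perfect", image_shape, lesion, "none", seed = seed),
    scenario_spec("under_segmentation", image_shape, lesion, "erode", 3L, seed),
    scenario_spec("over_segmentation", image_shape, lesion, "dilate", 3L, seed),
    scenario_spec("shifted", image_shape, lesion, "shift", 8L, seed),
    scenario_spec("inverted", image_shape, lesion, "invert", seed = seed),
    scenario_spec("weak_label_perfect", image_shape, NULL, "empty_prediction",
                  seed = seed),
    scenario_spec("weak_label_small_fp", image_shape, NULL, "spurious_blob",
                  4L, seed),
    scenario_spec("weak_label_large_fp", image_shape, NULL, "spurious_blob",
                  14L, seed + 1L),
    scenario_spec("weak_label_all_fp", image_shape, NULL, "full_false_positive",
                  seed = seed)
  )
  out <- lapply(specs, function(sp) {
    truth <- make_truth(sp)
    list(spec = sp, truth = truth, pred = make_prediction(truth, sp))
  })
  stats::setNames(out, vapply(specs, `[[`, "", "name"))
}

#' Export a scenario suite as a directory tree
#'
#' Writes `<out_dir>/truth/<name>.png` and `<out_dir>/pred/<name>.png` for
#' every scenario, a layout directly consumable by [evaluate_directories()].
#'
#' @param suite A [scenario_suite()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
export_scenarios <- function(suite, out_dir) {
  truth_dir <- file.path(out_dir, "truth")
  pred_dir <- file.path(out_dir, "pred")
  for (d in c(truth_dir, pred_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (name in names(suite)) {
    save_mask(suite[[name]]$truth, file.path(truth_dir, paste0(name, ".png")))
    save_mask(suite[[name]]$pred, file.path(pred_dir, paste0(name, ".png")))
  }
  invisible(out_dir)
}
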