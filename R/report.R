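#' Batch evaluation of mask-pair directories
#'
#' Pairs ground-truth and predicted masks by filename (extension-insensitive,
#' no fuzzy matching), evaluates every requested metric per pair, and
#' aggregates across the dataset.
#'
#' Aggregation is *macro* by default: the per-image mean over defined values,
#' with undefined values excluded and counted separately. Pooling counts
#' across images first (*micro*) is also available, but lets a few
#' large-lesion images drown out weak-label failures — the exact imbalance
#' problem weak-label scoring exists to expose.
#'
#' @param truth_dir,pred_dir Directories of mask files (`.png`, `.nii`,
#'   `.nii.gz`) with matching base names.
#' @param alpha Weighting coefficient in (0, 1).
#' @param metrics Metric keys, see [evaluate_counts()].
#' @param aggregate `"macro"` (per-image mean of defined values) or
#'   `"micro"` (metrics of the pooled confusion counts).
#' @param binarize Binarization rule passed to [load_mask()].
#' @return An `evaluation_report`: list with `per_image` (data.frame of
#'   image, metric, value, undefined), `aggregates` (data.frame of metric,
#'   mean, n_defined, n_undefined), `alpha`, `aggregate`, `n_images`.
#' @export
evaluate_directories <- function(truth_dir, pred_dir, alpha = 0.1,
                                 metrics = c("dsc", "spec", "wspec", "fpr",
                                             "acc", "nmcc", "mism"),
                                 aggregate = c("macro", "micro"),
                                 binarize = "nonzero") {
  aggregate <- match.arg(aggregate)
  check_alpha(alpha)
  pairs <- match_mask_pairs(truth_dir, pred_dir)
  per_image <- NULL
  pooled <- NULL
  results_by_image <- list()
  for (i in seq_len(nrow(pairs))) {
    counts <- tryCatch(
      compute_confusion(load_mask(pairs$truth[i], binarize),
                        load_mask(pairs$pred[i], binarize)),
      error = function(e) stop("pair '", pairs$image[i], "': ",
                               conditionMessage(e), call. = FALSE))
    res <- evaluate_counts(counts, alpha = alpha, metrics = metrics)
    results_by_image[[pairs$image[i]]] <- res
    pooled <- if (is.null(pooled)) counts else {
      counts_from_cells(pooled$tp + counts$tp, pooled$fp + counts$fp,
                        pooled$tn + counts$tn, pooled$fn + counts$fn)
    }
    for (r in res) {
      if (r$undefined) {
        warning("metric ", r$metric, " undefined for image '",
                pairs$image[i], "'", call. = FALSE)
      }
    }
    per_image <- rbind(per_image, data.frame(
      image = pairs$image[i],
      metric = vapply(res, `[[`, "", "metric"),
      value = vapply(res, `[[`, 0, "value"),
      undefined = vapply(res, `[[`, TRUE, "undefined"),
      row.names = NULL))
  }
  labels <- unique(per_image$metric)
  aggregates <- do.call(rbind, lapply(labels, function(lab) {
    vals <- per_image$value[per_image$metric == lab]
    und <- per_image$undefined[per_image$metric == lab]
    mean_val <- if (aggregate == "macro") {
      if (all(und)) NA_real_ else mean(vals[!und])
    } else {
      evaluate_counts(pooled, alpha = alpha,
                      metrics = names(which(vapply(
                        metric_registry(), `[[`, "", "label") == lab)))[[1]]$value
    }
    data.frame(metric = lab, mean = mean_val,
               n_defined = sum(!und), n_undefined = sum(und))
  }))
  structure(list(per_image = per_image, aggregates = aggregates,
                 alpha = alpha, aggregate = aggregate,
                 n_images = nrow(pairs), results = results_by_image),
            class = "evaluation_report")
}

match_mask_pairs <- function(truth_dir, pred_dir) {
  for (d in c(truth_dir, pred_dir)) {
    if (!dir.exists(d)) stop("directory not found: ", d)
  }
  list_masks <- function(d) {
    files <- list.files(d, pattern = "\\.(png|nii|nii\\.gz)$",
                        ignore.case = TRUE)
    stats::setNames(file.path(d, files),
                    sub("\\.(png|nii|nii\\.gz)$", "", files, ignore.case = TRUE))
  }
  truth <- list_masks(truth_dir)
  pred <- list_masks(pred_dir)
  orphans <- c(setdiff(names(truth), names(pred)),
               setdiff(names(pred), names(truth)))
  if (length(orphans) > 0) {
    stop("unmatched mask filenames: ", paste(sort(orphans), collapse = ", "))
  }
  if (length(truth) == 0) stop("no mask files found in ", truth_dir)
  keys <- sort(names(truth))
  data.frame(image = keys, truth = unname(truth[keys]),
             pred = unname(pred[keys]), row.names = NULL)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d image(s), alpha=%g, %s aggregation\n",
              x$n_images, x$alpha, x$aggregate))
  agg <- x$aggregates
  agg$mean <- format_score(agg$mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to CSV or JSON
#'
#' CSV layout: one row per (image, metric) with `scope = "image"`, followed
#' by one aggregate row per metric with `scope = "aggregate"`. Scores are
#' printed with 6 decimal places; undefined values as the literal string
#' `undefined`. Aggregates are means over defined values only, with the
#' defined/undefined counts reported alongside (undefined values are never
#' imputed as 0 — that would recreate the weak-label zero-scoring artifact).
#' JSON output (by `.json` extension) carries the same content structured.
#'
#' @param report An [evaluate_directories()] result.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  if (report$n_images < 1) stop("empty report")
  ext <- tolower(tools::file_ext(path))
  detail <- data.frame(scope = "image",
                       image = report$per_image$image,
                       metric = report$per_image$metric,
                       value = format_score(report$per_image$value),
                       n_defined = "", n_undefined = "")
  agg <- data.frame(scope = "aggregate", image = "",
                    metric = report$aggregates$metric,
                    value = format_score(report$aggregates$mean),
                    n_defined = report$aggregates$n_defined,
                    n_undefined = report$aggregates$n_undefined)
  if (ext == "csv") {
    utils::write.csv(rbind(detail, agg), path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    per_image <- split(report$per_image[c("metric", "value", "undefined")],
                       report$per_image$image)
    per_image <- lapply(per_image, function(d) {
      stats::setNames(lapply(seq_len(nrow(d)), function(i) {
        if (d$undefined[i]) "undefined" else round(d$value[i], 6)
      }), d$metric)
    })
    jsonlite::write_json(
      list(alpha = report$alpha, aggregate = report$aggregate,
           n_images = report$n_images, per_image = per_image,
           aggregates = report$aggregates),
      path, auto_unbox = TRUE, digits = NA, na = "string")
  } else {
    stop("unsupported report extension: .", ext)
  }
  invisible(path)
}
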