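#' Score gradient sweep over the weak-label false-positive ratio
#'
#' Explores how metrics score the weak-label edge case (`P = 0`) as the
#' fraction of the image falsely predicted foreground grows. For each ratio
#' `r` in the grid, confusion counts are `(tp = 0, fn = 0, fp = round(r * n),
#' tn = n - fp)` and each requested metric is evaluated; MISm is evaluated
#' once per `alpha`. Dividing the weighted-specificity formula through by
#' `n` gives the closed form `MISm(alpha, r) = alpha (1 - r) /
#' ((1 - alpha) r + alpha (1 - r))`, which the sweep reproduces with integer
#' counts.
#'
#' @param n_pixels Total pixel count `N` of the simulated weak-label image
#'   (default 60000, a typical slice-sized pixel budget).
#' @param ratios Strictly increasing FP/N grid in \[0, 1\]; default 101
#'   evenly spaced points.
#' @param alphas Weighting coefficients for the MISm curves, each in (0, 1).
#' @param metrics Non-MISm comparator metric keys to include
#'   (see [evaluate_counts()]).
#' @return A `score_table`: data.frame with columns `ratio` (requested),
#'   `realized_ratio` (`fp / n_pixels` after integer rounding), one column
#'   per comparator metric label and one `MISm(alpha=x)` column per alpha.
#'   Undefined scores are `NA`. Attribute `n_pixels` records the scale.
#' @examples
#' tab <- sweep_scores(n_pixels = 60000, ratios = 5000 / 60000, alphas = 0.1)
#' tab[["MISm(alpha=0.1)"]] # 0.55
#' @export
sweep_scores <- function(n_pixels = 60000,
                         ratios = seq(0, 1, length.out = 101),
                         alphas = c(0.05, 0.1, 0.25, 0.5, 0.75),
                         metrics = c("dsc", "acc", "nmcc")) {
  if (!is.numeric(n_pixels) || length(n_pixels) != 1L || n_pixels < 1 ||
      n_pixels != round(n_pixels)) {
    stop("n_pixels must be a positive integer")
  }
  if (length(ratios) < 1L || any(ratios < 0 | ratios > 1)) {
    stop("ratios must lie in [0, 1]")
  }
  if (is.unsorted(ratios, strictly = TRUE) && length(ratios) > 1L) {
    stop("ratios must be strictly increasing")
  }
  for (a in alphas) check_alpha(a)
  reg <- resolve_metrics(metrics)

  fp <- floor(ratios * n_pixels + 0.5)  # half-up rounding to integer counts
  tn <- n_pixels - fp
  rows <- lapply(seq_along(ratios), function(i) {
    counts <- counts_from_cells(tp = 0, fp = fp[i], tn = tn[i], fn = 0)
    base <- vapply(reg, function(m) m$fn(counts, NA)$value, numeric(1))
    mis <- vapply(alphas, function(a) mism(counts, a)$value, numeric(1))
    c(base, mis)
  })
  scores <- do.call(rbind, rows)
  labels <- c(vapply(reg, `[[`, "", "label"),
              sprintf("MISm(alpha=%g)", alphas))
  tab <- data.frame(ratio = ratios, realized_ratio = fp / n_pixels,
                    check.names = FALSE)
  tab[labels] <- scores
  attr(tab, "n_pixels") <- n_pixels
  class(tab) <- c("score_table", "data.frame")
  tab
}

score_columns <- function(table) {
  setdiff(names(table), c("ratio", "realized_ratio"))
}

#' Write a score table as CSV
#'
#' Header `ratio,realized_ratio,<metric1>,...`; scores at 6 decimal places;
#' undefined cells as the literal string `undefined`.
#'
#' @param table A `score_table` from [sweep_scores()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(inherits(table, "score_table"), nrow(table) >= 1)
  out <- data.frame(ratio = sprintf("%.6f", table$ratio),
                    realized_ratio = sprintf("%.6f", table$realized_ratio),
                    check.names = FALSE)
  for (col in score_columns(table)) out[[col]] <- format_score(table[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a score gradient sweep
#'
#' One line per metric column, x = requested FP/N ratio, y = score.
#' Undefined points are omitted; a column that is undefined everywhere is
#' dropped with a warning.
#'
#' @param table A `score_table` from [sweep_scores()].
#' @param out_path Output image path; format chosen by extension (`.png` or
#'   `.pdf`).
#' @return `out_path`, invisibly.
#' @importFrom rlang .data
#' @export
render_sweep <- function(table, out_path) {
  stopifnot(inherits(table, "score_table"), nrow(table) >= 1)
  cols <- score_columns(table)
  all_na <- vapply(cols, function(col) all(is.na(table[[col]])), logical(1))
  if (any(all_na)) {
    warning("omitting all-undefined series: ",
            paste(cols[all_na], collapse = ", "))
    cols <- cols[!all_na]
  }
  if (length(cols) == 0) stop("no defined series to plot")
  long <- do.call(rbind, lapply(cols, function(col) {
    data.frame(ratio = table$ratio, score = table[[col]], metric = col)
  }))
  long <- long[!is.na(long$score), ]
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$ratio, y = .data$score,
                                    colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "false positives / actual negatives (FP/N)",
                  y = "score", colour = NULL,
                  title = "Metric scoring gradients on weak labels (P = 0)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "png") {
    grDevices::png(out_path, width = 7, height = 5, units = "in", res = 150,
                   type = "cairo")
  } else if (ext == "pdf") {
    grDevices::pdf(out_path, width = 7, height = 5)
  } else {
    stop("unsupported plot extension: .", ext)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out_path)
}
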