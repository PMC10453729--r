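#' @title Segmentation metrics with an explicit undefined state
#'
#' @description
#' Each metric maps a [counts_from_cells()] confusion object to a
#' `metric_result`. A metric whose denominator vanishes is *undefined*: this
#' is reported as a first-class state, never silently coerced to 0 — scoring
#' an undefined case as 0 is exactly the weak-label artifact that motivates
#' MISm.
#'
#' The definition gaps are:
#' * Dice (`dsc`): undefined iff `TP = FP = FN = 0` (a completely
#'   true-negative prediction).
#' * Specificity (`specificity`), FPR (`fpr`), weighted specificity
#'   (`weighted_specificity`): undefined iff `TN = FP = 0` (no actual
#'   negatives).
#' * `mism` and `accuracy` are defined for every non-empty image.
#'
#' @param c A `confusion_counts` object.
#' @param alpha Weighting coefficient in the open interval (0, 1); default
#'   0.1, the recommended fixed community value. It down-weights the
#'   (typically dominant) TN count against FP in the weak-label branch.
#' @return A `metric_result`: list with fields `metric` (label), `value`
#'   (numeric, `NA` when undefined), `undefined` (logical), `counts`, and
#'   `alpha` (`NA` for metrics that take none).
#' @name metrics
NULL

metric_result <- function(metric, value, counts, alpha = NA_real_) {
  undefined <- is.null(value)
  structure(list(metric = metric,
                 value = if (undefined) NA_real_ else as.numeric(value),
                 undefined = undefined,
                 counts = counts,
                 alpha = alpha),
            class = "metric_result")
}

#' @rdname metrics
#' @param x Object to test / print.
#' @export
is_undefined <- function(x) {
  stopifnot(inherits(x, "metric_result"))
  x$undefined
}

#' @export
print.metric_result <- function(x, ...) {
  val <- if (x$undefined) "undefined" else format_score(x$value)
  extra <- if (!is.na(x$alpha)) sprintf(" (alpha=%g)", x$alpha) else ""
  cat(sprintf("%s%s = %s\n", x$metric, extra, val))
  invisible(x)
}

# serialization rule shared by reports and sweep CSVs
format_score <- function(v) {
  ifelse(is.na(v), "undefined", sprintf("%.6f", v))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1, got: ",
         deparse(substitute(alpha)), " = ", paste(alpha, collapse = ","))
  }
  invisible(alpha)
}

check_counts <- function(c) {
  if (!inherits(c, "confusion_counts")) stop("expected a confusion_counts object")
  invisible(c)
}

#' @rdname metrics
#' @export
dsc <- function(c) {
  check_counts(c)
  den <- 2 * c$tp + c$fp + c$fn
  metric_result("DSC", if (den > 0) 2 * c$tp / den else NULL, c)
}

#' @rdname metrics
#' @export
fpr <- function(c) {
  check_counts(c)
  n <- negatives(c)
  metric_result("FPR", if (n > 0) c$fp / n else NULL, c)
}

#' @rdname metrics
#' @export
specificity <- function(c) {
  check_counts(c)
  n <- negatives(c)
  metric_result("Spec", if (n > 0) c$tn / n else NULL, c)
}

#' @rdname metrics
#' @export
weighted_specificity <- function(c, alpha = 0.1) {
  check_counts(c)
  check_alpha(alpha)
  den <- (1 - alpha) * c$fp + alpha * c$tn
  metric_result("wSpec", if (den > 0) alpha * c$tn / den else NULL, c, alpha)
}

#' @rdname metrics
#' @details
#' `mism` is the composite metric: the Dice similarity coefficient when the
#' ground truth contains foreground (`P = TP + FN > 0`), and the weighted
#' specificity when the label is weak (`P = 0`). On a non-empty image it is
#' always defined: `P > 0` makes the Dice denominator positive, and `P = 0`
#' forces `TN + FP = N > 0` so the weighted-specificity denominator is
#' positive for any `alpha` in (0, 1).
#' @export
mism <- function(c, alpha = 0.1) {
  check_counts(c)
  check_alpha(alpha)
  r <- if (positives(c) > 0) dsc(c) else weighted_specificity(c, alpha)
  metric_result("MISm", r$value, c, alpha)
}

#' @rdname metrics
#' @export
accuracy <- function(c) {
  check_counts(c)
  total <- c$tp + c$fp + c$tn + c$fn
  metric_result("Acc", (c$tp + c$tn) / total, c)
}

#' @rdname metrics
#' @details
#' `nmcc` is the normalized Matthews correlation coefficient,
#' `(MCC + 1) / 2`, mapping MCC's \[-1, 1\] onto \[0, 1\]: 1 is a perfect
#' prediction, 0 an exactly inverted ground truth, and 0.5 randomness. When
#' any marginal sum is zero the MCC denominator vanishes; the conventional
#' value MCC = 0 is used, so nMCC = 0.5 — the "no information" score.
#' @export
nmcc <- function(c) {
  check_counts(c)
  den2 <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  mcc <- if (den2 > 0) (c$tp * c$tn - c$fp * c$fn) / sqrt(den2) else 0
  metric_result("nMCC", (mcc + 1) / 2, c)
}

# canonical metric registry: CLI keys -> label + function of (counts, alpha)
metric_registry <- function() {
  list(
    dsc   = list(label = "DSC",   fn = function(c, alpha) dsc(c)),
    spec  = list(label = "Spec",  fn = function(c, alpha) specificity(c)),
    wspec = list(label = "wSpec", fn = function(c, alpha) weighted_specificity(c, alpha)),
    fpr   = list(label = "FPR",   fn = function(c, alpha) fpr(c)),
    acc   = list(label = "Acc",   fn = function(c, alpha) accuracy(c)),
    nmcc  = list(label = "nMCC",  fn = function(c, alpha) nmcc(c)),
    mism  = list(label = "MISm",  fn = function(c, alpha) mism(c, alpha))
  )
}

resolve_metrics <- function(metrics) {
  reg <- metric_registry()
  keys <- tolower(metrics)
  bad <- setdiff(keys, names(reg))
  if (length(bad) > 0) {
    stop("unknown metric(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(reg), collapse = ", "))
  }
  reg[keys]
}

#' Evaluate a set of metrics on confusion counts
#'
#' @param c A `confusion_counts` object.
#' @param alpha Weighting coefficient for `wspec`/`mism`, in (0, 1).
#' @param metrics Character vector of metric keys (any of
#'   `r paste(names(metric_registry()), collapse = ", ")`).
#' @return A named list of `metric_result`, named by metric label.
#' @export
evaluate_counts <- function(c, alpha = 0.1,
                            metrics = c("dsc", "spec", "wspec", "fpr",
                                        "acc", "nmcc", "mism")) {
  check_counts(c)
  check_alpha(alpha)
  reg <- resolve_metrics(metrics)
  res <- lapply(reg, function(m) m$fn(c, alpha))
  stats::setNames(res, vapply(res, `[[`, "", "metric"))
}

#' Evaluate all metrics on a ground-truth/prediction mask pair
#'
#' Computes a single confusion matrix for the pair and evaluates every
#' requested metric from it.
#'
#' @param truth,pred [binary_mask()] objects of identical shape.
#' @inheritParams evaluate_counts
#' @return A named list of `metric_result`.
#' @examples
#' truth <- binary_mask(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE))
#' pred  <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
#' evaluate_all(truth, pred)
#' @export
evaluate_all <- function(truth, pred, alpha = 0.1,
                         metrics = c("dsc", "spec", "wspec", "fpr",
                                     "acc", "nmcc", "mism")) {
  evaluate_counts(compute_confusion(truth, pred), alpha = alpha,
                  metrics = metrics)
}
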