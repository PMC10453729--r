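# shared helpers: random masks, independent confusion/metric oracles

random_mask <- function(shape, p = 0.5) {
  binary_mask(array(stats::runif(prod(shape)) < p, dim = shape))
}

# per-pixel nested-loop confusion counter, deliberately naive:
# the independent oracle for compute_confusion
loop_confusion <- function(truth, pred) {
  t <- as.vector(unclass(truth))
  p <- as.vector(unclass(pred))
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(t)) {
    if (t[i] && p[i]) tp <- tp + 1L
    else if (!t[i] && p[i]) fp <- fp + 1L
    else if (t[i] && !p[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# closed form for MISm on the weak-label sweep, derived by dividing the
# weighted-specificity formula through by N (r = FP/N)
mism_closed_form <- function(alpha, r) {
  alpha * (1 - r) / ((1 - alpha) * r + alpha * (1 - r))
}

# brute-force count of integer lattice points within distance `radius`
# of `center` (the rasterization oracle), nested loops on purpose
loop_disk_count <- function(shape, center, radius) {
  n <- 0L
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) n <- n + 1L
    }
  }
  n
}

# every confusion-count vector with cells in 0..k, excluding all-zero
enumerate_counts <- function(k = 6) {
  g <- expand.grid(tp = 0:k, fp = 0:k, tn = 0:k, fn = 0:k)
  g[rowSums(g) > 0, ]
}

cli_path <- function() system.file("cli", "mism.R", package = "mism")

run_cli <- function(args) {
  out <- suppressWarnings(
    system2("Rscript", c(shQuote(cli_path()), args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
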