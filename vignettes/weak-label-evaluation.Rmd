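---
title: "Evaluating segmentation masks with weak labels: the MISm metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating segmentation masks with weak labels: the MISm metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mism)
```

## The model

A binary segmentation prediction is summarized by its confusion matrix over
all pixels or voxels: TP, FP, TN, FN, with P = TP + FN the actual positives
and N = TN + FP the actual negatives. All metrics in this package are pure
functions of these four counts; image geometry, spacing and orientation play
no role. A **weak label** is an image whose ground truth has P = 0 — no
region of interest at all, the typical control-patient case. On weak labels,
TP = FN = 0 necessarily, so:

* DSC = 2TP/(2TP+FP+FN) is 0 for any FP > 0 (uninformative: every imperfect
  prediction scores alike) and 0/0 for FP = 0 (undefined exactly when the
  prediction is perfect);
* specificity TN/(FP+TN) is defined but numerically insensitive, because in
  segmentation the background dwarfs any plausible error.

MISm composes two established metrics to cover both regimes:

$$\mathrm{MISm} = \begin{cases}
  \mathrm{DSC} & \text{if } P > 0\\[2pt]
  \mathrm{wSpec}_\alpha = \dfrac{\alpha\,TN}{(1-\alpha)\,FP + \alpha\,TN}
    & \text{if } P = 0
\end{cases}$$

The weighted specificity deflates TN by $\alpha$ and inflates FP by
$1-\alpha$, restoring a usable scoring gradient on weak labels. On a
non-empty image MISm is always defined: $P > 0$ makes the DSC denominator at
least $P$, and $P = 0$ forces $FP + TN = N > 0$, so the wSpec denominator is
positive for any $\alpha \in (0,1)$. The package proves this exhaustively in
its tests by enumerating all count vectors with cells in $\{0,\dots,6\}$.

## Parameters

The single tunable parameter is the dimensionless weighting coefficient
$\alpha$, default **0.1**, the fixed community value recommended for
comparable quantitative evaluation. Writing $r = FP/N$ for the fraction of
the weak-label image falsely marked foreground, dividing wSpec through by
$N$ gives the closed form

$$\mathrm{MISm}(\alpha, r) = \frac{\alpha (1-r)}{(1-\alpha) r + \alpha (1-r)},$$

a strictly decreasing curve from 1 at $r=0$ to 0 at $r=1$, with $\alpha$
setting how fast early errors are punished: at $\alpha = 0.1$ a 10% false
positive fraction already halves the score, while $\alpha = 0.5$ reduces
wSpec to plain specificity. `sweep_scores()` tabulates these curves against
the comparators (accuracy is exactly $1-r$ there; nMCC is pinned at 0.5;
DSC is 0 everywhere except undefined at $r=0$):

```{r sweep}
tab <- sweep_scores(n_pixels = 60000, ratios = seq(0, 1, 0.125),
                    alphas = c(0.1, 0.5))
tab
```

Although the metric's weight is nominally in $[0,1]$, this implementation
accepts only the open interval: $\alpha = 0$ makes wSpec 0/0 whenever
FP = 0 (the perfect weak-label prediction would be the one undefined case),
and $\alpha = 1$ makes it constantly 1 whenever TN > 0, destroying the
gradient. Both endpoints raise an error.

## Undefined values

Definition gaps are first-class results, not errors and not zeros:
`dsc()` is undefined iff TP = FP = FN = 0, and `specificity()`, `fpr()` and
`weighted_specificity()` iff TN = FP = 0. Reports serialize these as the
literal string `undefined`, and aggregates average over defined values only
while reporting the undefined count — imputing 0 would recreate precisely
the weak-label artifact MISm exists to fix.

Two further conventions:

* **nMCC.** The Matthews correlation coefficient is normalized as
  $(\mathrm{MCC}+1)/2$, so 1 is perfect, 0 is an exactly inverted
  annotation, and 0.5 is chance level. When any marginal sum is zero the MCC
  denominator vanishes; the conventional MCC = 0 is used, so every
  weak-label case collapses to nMCC = 0.5 regardless of FP — one of the
  behaviours the scoring-gradient comparison exposes.
* **Accuracy** uses the standard (TP+TN)/(TP+TN+FP+FN); it is always
  defined but tracks $1-r$ on weak labels, i.e. it inherits the background
  dominance that motivates the weighting.
* **Empty images** (zero pixels) are rejected at construction: every metric
  would be 0/0 and "always defined" is claimed only for non-empty images.

Arithmetic is plain double-precision on exact integer counts; comparisons
against 4-decimal reference values in the tests use an absolute tolerance of
$5\times10^{-5}$ (half a unit in the last printed digit).

## Batch evaluation

`evaluate_directories()` pairs ground-truth and prediction files strictly by
base filename (silent fuzzy matching could mispair patients) and aggregates
**macro** by default — the per-image mean over defined values. Micro
aggregation (pooling counts across images first) is available via
`aggregate = "micro"`, but a few large-lesion images can then mask
weak-label failures, which is the imbalance problem weak-label scoring is
meant to surface; the choice is therefore an explicit flag, not a silent
default. Masks are read from 8/16-bit grayscale PNG (2-D) or NIfTI (2-D/3-D)
with nonzero-is-foreground binarization by default, or one-vs-rest on a
chosen label; NIfTI orientation metadata is preserved on write but ignored
by the metrics, which are orientation-invariant count functions.

## Synthetic scenarios

No external imaging data is needed: `scenario_suite()` generates
deterministic mask pairs spanning the qualitative cases of interest — a
perfect prediction, morphological under- and over-segmentation, a spatially
shifted prediction, an inverted annotation (the nMCC = 0 anchor), and
weak-label cases from a perfect all-background prediction through small and
large spurious blobs to an all-foreground one.

Design choices worth knowing:

* Lesions are rasterized disks/balls: a pixel is foreground iff its integer
  coordinate lies within Euclidean distance *radius* of the center — the
  simplest reproducible rule, frozen against a brute-force lattice-count
  oracle in the tests (a radius-10 disk has 317 pixels).
* Dilation/erosion use disc-shaped structuring elements (EBImage) and are
  2-D; shifting drops pixels at the border rather than wrapping, since
  wrap-around would place false positives at anatomically meaningless
  locations; spurious blobs are centred on a seeded random background pixel
  and clipped at image borders.
* Scenario randomness is confined to a local RNG scope, so generation never
  perturbs the caller's random stream, and identical seeds yield
  byte-identical mask files.

These masks emulate only what the metrics consume — foreground geometry at
realistic class imbalance (a 317-pixel lesion in a 64×64 frame, blobs up to
full-image false positives). They carry no intensity texture, anatomy, or
inter-rater ambiguity, so passing tests demonstrate correctness of the
scoring machinery, not segmentation quality on real MRI; the default sweep
scale of 60000 pixels matches a typical slice-sized budget and is
configurable.

## Known limitations

* Binary (one-vs-rest) evaluation only; no multi-class confusion matrices,
  soft/probabilistic predictions, or distance-based metrics (Hausdorff,
  surface distances).
* Aggregation weights every image equally (macro) or every pixel equally
  (micro); no size-stratified reporting.
* The α default is a community convention, not a fitted constant; studies
  using a different α should report it, since scores across α values are
  not comparable.
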