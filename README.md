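# mism

Evaluation of binary medical image segmentation masks, built around the
composite metric **MISm** and its comparators, with first-class handling of
**weak labels** — images whose ground-truth mask contains no foreground at
all (e.g. scans of control patients).

## The problem

The Dice similarity coefficient (DSC), the de-facto standard overlap score in
medical image segmentation, collapses on weak labels. With the confusion
cells TP, FP, TN, FN computed over all pixels, and P = TP + FN the number of
actual positives:

    DSC = 2·TP / (2·TP + FP + FN)

When P = 0 every prediction with any false positive scores exactly 0 — a
nearly clean prediction and a catastrophic one are indistinguishable — and a
perfect all-background prediction leaves DSC undefined (0/0). Plain
specificity, TN/(FP+TN), is defined there but barely moves: with 5000 of
60000 pixels falsely marked foreground it still returns ≈ 0.9167, because
the huge TN count dominates.

## The metric

MISm scores ordinary images with DSC and weak-label images with a *weighted
specificity* that re-balances TN against FP via a coefficient α ∈ (0, 1):

    wSpec_α = α·TN / ((1−α)·FP + α·TN)

    MISm = DSC      if P > 0
         = wSpec_α  if P = 0          (default α = 0.1)

On the example above, wSpec₀.₁ = 0.55: the same prediction now scores in the
middle of the range instead of ≈ 0.92 or 0. MISm is defined for every
non-empty image, falls strictly from 1 (perfect weak-label prediction) to 0
(everything falsely positive), and equals DSC bit-for-bit whenever the
ground truth contains foreground.

The package also implements the comparators used to study this behaviour:
specificity, false positive rate, accuracy, and the normalized Matthews
correlation coefficient nMCC = (MCC+1)/2, with explicit `undefined` results
wherever a denominator vanishes (never silently 0).

## Worked example

```r
library(mism)

counts <- counts_from_cells(tp = 0, fp = 5000, tn = 55000, fn = 0)
specificity(counts)
#> Spec = 0.916667
weighted_specificity(counts, alpha = 0.1)
#> wSpec (alpha=0.1) = 0.550000
mism(counts, alpha = 0.1)
#> MISm (alpha=0.1) = 0.550000
nmcc(counts)
#> nMCC = 0.500000
```

The specificity of 0.9167 looks like a good prediction although almost a
tenth of the image is falsely foreground; the weighted specificity (and
hence MISm, whose weak-label branch it is) scores it 0.55. nMCC returns 0.5
— its "no information" value — because a marginal sum is zero.

Mask pairs can also be evaluated from files (`load_mask`, `evaluate_all`) or
whole directories (`evaluate_directories`), and a synthetic scenario
generator (`scenario_suite`) produces deterministic tumor-like and
weak-label test cases.

## Command line

```sh
MISM_CLI=$(Rscript -e 'cat(system.file("cli", "mism.R", package = "mism"))')
Rscript $MISM_CLI simulate --seed 42 --out-dir fixtures/
Rscript $MISM_CLI evaluate --truth fixtures/truth --pred fixtures/pred \
    --alpha 0.1 --out report.csv
Rscript $MISM_CLI sweep --n-pixels 60000 --out-csv sweep.csv --out-plot sweep.png
```

`evaluate` pairs masks by filename, reports every metric per image plus
macro aggregates (undefined values excluded and counted, never imputed as
0). `sweep` tabulates each metric against the weak-label false-positive
ratio FP/N, the scoring-gradient comparison that motivates α = 0.1.

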