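---
title: "Gene selection with a non-negative gating layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection with a non-negative gating layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genegate)
```

## The problem

Bulk RNA-seq studies of small surgical cohorts produce expression matrices
with on the order of $10^4$ genes and a dozen samples. Selecting the genes
that drive a binary contrast (tumor vs. normal tissue, better vs. worse
prognosis) from such data is hard: filter methods score genes one at a time
and miss interactions, wrapper methods are combinatorially expensive, and
most embedded methods are tied to linear models. `genegate` implements an
embedded selection method in which a neural network learns, jointly with a
classifier, how much each gene is worth.

## The model

Let $x = (x_1, \dots, x_k)^\top$ be a sample's min–max normalized
expression vector. A *gating layer* with one weight per gene computes the
Hadamard product

$$y = f(W \odot x), \qquad W = (w_1, \dots, w_k)^\top,\; f(x) = x,$$

so $y_i = w_i x_i$ exactly: the layer has no bias and a linear activation.
The gated vector feeds a dense classifier — three 500-unit ReLU layers, each
followed by dropout with probability 0.5, then a softmax output over the
classes — trained with categorical cross-entropy. The gate weights are
constrained to be non-negative by projection (clipping at zero) after every
optimizer update.

Because every input lies in $[0, 1]$ and every gate weight is non-negative,
a gene that does not help minimize the loss can only have its weight decay
toward zero, while genes the classifier relies on keep or grow theirs. After
training, $w_i$ is read as the importance of gene $i$.

### Why the importance is a tally, not a weight

With a dozen samples and $10^4$ genes a single training run is unreliable:
weight initialization and dropout masks change which of several equally
predictive genes the network happens to lean on. The method therefore trains
the network $K$ times with independent seeds, ranks genes by descending gate
weight within each trial, and scores each gene by the number of trials in
which it ranked in the top $N$. The study configuration uses $K = 1000$ and
reports $N = 10$ and $N = 50$ side by side; `tally_table()` computes both
from the same trials in one pass. Counts conserve exactly:
$\sum_g \mathrm{count}_g = \min(N, k)\,K$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_widths` | 500, 500, 500 | classifier capacity |
| `dropout_rate` | 0.5 | regularization of the hidden layers |
| `epochs` | 100 | full-batch Adam epochs per trial |
| `learning_rate` | $10^{-3}$ | Adam step size |
| `K` | 1000 | number of independently seeded trials |
| `N` | 10 and 50 | top-rank cutoff for the tally |

The architecture constants are the study configuration. The optimizer, its
learning rate, the epoch count, and full-batch training are this package's
declared defaults — the method itself fixes none of them; with at most a
dozen samples a batch is the whole dataset, and 100 Adam epochs at
$10^{-3}$ drive training accuracy to 1 on every cohort we generate while
keeping a 1000-trial run tractable. Gate weights are initialized to 1 (the
identity gate): deterministic, and it lets training alone decide which genes
decay. The non-negativity requirement is read strictly as a constraint and
enforced by projection after each update rather than as a soft penalty.
Dropout is placed after each hidden activation. The cross-entropy applies a
probability floor of $10^{-12}$ before the logarithm.

### Normalization

Min–max normalization is applied **per gene across samples**:
$x' = (x - \min)/(\max - \min)$, so every non-constant gene spans $[0, 1]$.
Per-gene scaling is what makes gate weights comparable across genes, which
the tally requires; a whole-matrix variant is available via
`min_max_normalize(m, axis = "global")` for comparison. Constant genes are
kept and mapped to all-zero rows (with a warning) rather than dropped: a
zero input can only let the gene's gate weight decay, which is the correct
fate for an uninformative gene. Normalization is fit on the full dataset —
the method trains on all samples, holding nothing out, because cohorts of
this size leave no room for validation data.

Seeds follow the schedule `base_seed + trial_index`, covering weight
initialization and dropout masks, so an interrupted run can resume from its
checkpoint manifest and any single trial can be reproduced in isolation.
Trials whose loss turns non-finite are excluded from the tally and counted
in the run metadata. Ties in a trial ranking are broken by ascending gene
index; ties in the final count ranking are broken lexicographically by gene
identifier. Both rules are deterministic and data-independent.

## The synthetic-data generator

The study's own RNA-seq data are not deposited, so the package ships a
generator that emulates the relevant geometry: per gene, log-expression is
Normal with a baseline mean drawn from $U(2, 10)$ and SD 1, exponentiated to
a strictly positive CPM-scale value; `m_informative` planted genes shift
their class-1 mean by `effect_delta` SD units on the log scale, with the
shift direction alternating so both up- and down-regulated genes occur.
Presets `"task1"` and `"task2"` reproduce the study's cohort geometry
(11,273 genes; 12 samples as 6 + 6, and 13 samples as 6 + 7).

What the generator does *not* emulate: gene–gene correlation, batch
effects, library-size artifacts, or count-level (negative-binomial) noise —
the method consumes normalized CPM values, so count modeling is upstream of
its contract. Passing tests on this generator therefore show that the
implementation recovers planted marginal class differences under log-normal
noise, not that the method is robust to the covariance structure of real
tumor expression data.

The survival generator draws event times exponentially with hazard
$\lambda \cdot \mathrm{HR}^{\,[x > c]}$ for a subject with expression $x$
and true threshold $c$, with uniform administrative censoring on
$(0, \text{horizon}]$.

## Survival validation

`scan_best_cutpoint()` reimplements the exhaustive Kaplan–Meier scan used to
validate selected genes against an external cohort: every midpoint between
consecutive distinct expression values is a candidate threshold; subjects
with expression strictly above the threshold form the high group; only
splits leaving at least `min_group` subjects (default 8, a declared
convention) per arm are tested; the split minimizing the unweighted
(Mantel–Haenszel) log-rank p-value wins. Minimum-p scanning inflates the
type-I error, so a Bonferroni adjustment over the number of tested
cutpoints is always reported alongside the raw minimum — the adjusted value
is conservative under the null, which the test suite verifies by
simulation.

## Numerical and design notes

* **Determinism.** A trial is a pure function of (data, spec, training
  config, seed). Identical calls produce bitwise-identical weights.
* **Degenerate inputs.** Constant genes normalize to zero rows; cohorts
  with no admissible cutpoint, single-class label files, and negative or
  missing expression values raise located errors.
* **Positional permutation.** Renaming genes in place permutes all outputs
  identically. Physically reordering the rows of the input matrix does
  *not* reproduce the same trained weights under the same seed, because
  dense-layer initialization is drawn from the seeded RNG stream in a fixed
  element order; equivariance under row permutation holds in distribution,
  not bitwise.
* **What the tally's null is not.** Under no planted signal the tally does
  **not** follow the Binomial$(K, N/k)$ law of independent random rankings.
  Within a run, all $K$ trials see the same fixed dataset; genes with the
  largest spurious sample correlation to the labels are promoted in nearly
  every trial, so their counts concentrate far above any binomial
  percentile. The same concentration is what makes the tally informative
  when signal exists — but it means a high count alone is not evidence
  against a no-signal null. Calibrating the tally would require a
  label-permutation null (retraining on permuted labels), which is a
  different experiment. External validation — here, survival analysis on an
  independent cohort — is the appropriate check on selected genes.

## Problem sizes used by the test suite

The packaged checks run scaled-down study conditions chosen to exercise
every property at desk scale: selection runs use $k = 500$ genes, 10
planted genes at $\delta = 2$, $10 + 10$ samples, and $K = 50$ trials;
mechanical properties use smaller fixtures. The log-rank and product-limit
implementations are checked against independent brute-force oracles on
random cohorts; the cutpoint scan's minimum p is compared with an
exhaustive loop. The null-concentration behavior described above is
measured, not assumed.

## Worked example

```{r example, eval = FALSE}
sim <- generate_expression(k_genes = 500, n_per_class = c(10, 10),
                           m_informative = 10, effect_delta = 2, seed = 1)
norm <- min_max_normalize(sim$expression)
run <- run_trials(norm, sim$labels, K = 50, base_seed = 100)
tal <- tally_top_n(run, N = 10)
final_ranking(tal, m = 20)
autoplot(tal)

co <- generate_survival(200, true_cutpoint = 1, hazard_ratio = 4,
                        baseline_hazard = 1/400, seed = 14)
scan_best_cutpoint(co, min_group = 8)
```

## Limitations

* Training is full-batch CPU code aimed at cohorts of tens of samples; it
  is not a general deep-learning framework.
* The tally has no attached significance test; use external validation.
* Gene identifiers are treated as opaque strings — no annotation lookup.
* The `min_group` and adjustment conventions of the original web-based KM
  scanner are not published; both are exposed as configuration here.
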