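---
title: "Methods: the weighted FCNN/DNN ensemble for PPD screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the weighted FCNN/DNN ensemble for PPD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdens)
```

## The problem and the model

Postpartum depression (PPD) screening questionnaires produce small ordinal
feature sets: here, nine integer-coded attributes (an age band plus eight
symptom items such as "Feeling sad or Tearful", each coded 1 = yes,
2 = an intermediate answer, 3 = no) predicting a binary anxiety indicator
used as the PPD proxy (1 = anxious). `ppdens` implements a weighted ensemble
of two backpropagation multilayer perceptrons trained on such data:

* the **FCNN** — a plain fully-connected network, interpretable but prone to
  overfitting;
* the **DNN** — the *same architecture* trained with inverted dropout
  (hidden units zeroed with probability $p$ during training-mode forwards,
  survivors scaled by $1/(1-p)$), better regularized but less interpretable.

Both are instances of one `ppd_network` code path; the FCNN is simply
`dropout_rate = 0`. The forward pass is the classical
$h_j = f(\sum_i w^{1}_{ji} x_i + b^1_j)$,
$y_l = f(\sum_j w^{2}_{lj} h_j + b^2_l)$ with sigmoid $f$, trained by
mini-batch gradient descent on the squared-error loss
$E = \tfrac12 \sum_l (y_l - d_l)^2$ with update
$w \leftarrow w - \eta\, \partial E/\partial w$. The squared-error loss is
kept deliberately (rather than cross-entropy) to match the model family as
published; with one sigmoid output unit it behaves well on this task.

After training, the two members are combined by fixed convex weights derived
from their **training-set accuracies** $a_1, a_2$ and **dropout rates**
$d_1, d_2$:

$$w_1 = \frac{1}{2}\left(\frac{a_1}{a_1+a_2} + \frac{d_1}{d_1+d_2}\right),
\qquad
w_2 = \frac{1}{2}\left(\frac{a_2}{a_1+a_2} + \frac{d_2}{d_1+d_2}\right),$$

and the ensemble probability is $w_1 p_{\mathrm{FCNN}} + w_2 p_{\mathrm{DNN}}$,
thresholded at 0.5 (ties predict positive — the conservative choice for a
screening instrument). $w_1 + w_2 = 1$ is an algebraic identity, so the
ensemble probability always lies between the member probabilities.

Two conventions the formula itself forces us to pick:

* **Zero-dropout limit.** When $d_1 = d_2 = 0$ the dropout share is $0/0$;
  we define both shares as $\tfrac12$, which makes the fully symmetric case
  (identical members) come out at $w_1 = w_2 = \tfrac12$ exactly.
* **Asymmetry.** With the usual configuration $d_1 = 0$ (the FCNN has no
  dropout mechanism) the dropout share contributes its full half-weight to
  the DNN, so $w_2 > w_1$ whenever the accuracies are comparable — e.g.
  accuracies (0.898, 0.902) with dropout (0, 0.5) give
  $(w_1, w_2) \approx (0.24944, 0.75056)$. We implement the formula as
  published and document rather than "correct" this behaviour.

* **Probabilities, not labels.** The weighted average is applied to member
  output probabilities and thresholded afterwards; averaging hard labels
  would discard information and make the convexity property untestable.

* **Accuracy definition.** $a_1, a_2$ are final-epoch training-set
  accuracies (not best-epoch); only "accuracy on the training set" is
  specified by the model family, and the final network is the one actually
  deployed.

## Training defaults and what they mean

| parameter | default | role |
|---|---|---|
| `hidden` | 16 units, one layer | capacity; 9 ordinal inputs need little |
| `activation` | sigmoid | hidden and output transfer |
| `learning_rate` | 0.1 | step size $\eta$ of the update |
| `epochs` | 200 | passes over the training data |
| `batch_size` | 32 | mini-batch size; gradients are batch means |
| `init_scale` | 0.1 | uniform $[-s, s]$ initialisation |
| `dnn_dropout` | 0.5 | hidden-unit drop probability of the DNN |
| `scale_features` | TRUE | min-max scaling of codes to $[0,1]$ |

The architecture is not pinned down by the model family, so these are the
package's own defaults: one hidden layer of 16 sigmoid units trains in
seconds at $n \approx 1500$ and reaches training accuracies around 0.91 on
the default synthetic data. Mini-batch gradients are *averaged* over the
batch (the per-sample update rule does not define batch semantics; the mean
keeps $\eta$ comparable across batch sizes). Dropout applies to hidden
layers only — never input or output — and we use *inverted* dropout so that
inference is mask-free.

One subtlety worth stating precisely: inverted dropout preserves the
expectation of the *masked hidden activations* exactly,
$\mathbb{E}[h \cdot m/(1-p)] = h$. After the next nonlinearity a Jensen gap
of order $f''\cdot\mathrm{Var}$ remains, so the network *output* under
train-mode averaging is only approximately the inference output. The
dropout-expectation test therefore asserts the exact statement (the hidden
layer), not the approximate one.

Numerical choices: training aborts with the epoch index if the loss goes
non-finite; the gradient check uses central differences with relative error
$|a-b|/\max(1,|a|,|b|)$; model JSON serialization stores doubles at 17
significant digits so round trips are bit-exact.

## The synthetic data world

The study dataset (1,503 questionnaire records from a public repository) is
not bundled; instead `generate_ppd()` draws datasets with the reported
structure so the whole pipeline is testable offline:

1. a latent Gaussian vector with unit variances and correlation matrix
   `latent_corr` per record;
2. each coordinate cut at fixed thresholds into the attribute's codes
   (a Gaussian copula with ordinal marginals);
3. a logistic outcome model on the raw codes, with the intercept calibrated
   by root-finding on a seed-derived 100,000-draw sample so the expected
   positive share equals `positive_fraction`.

Defaults state the documented world and are not tuned afterwards:

* `n = 1503`, `positive_fraction = 0.65` (the reported 65/35 split);
* symptom marginals mildly skewed toward "yes" (0.40/0.30/0.30), age bands
  uniform — the source reports no marginal tables, so these are one-time
  realistic choices;
* a weak exchangeable latent correlation of 0.15 among the eight symptom
  items (observed ordinal $r \approx 0.12$, i.e. "weak" $\le 0.2$), age
  independent;
* the "Feeling sad or Tearful" / "Overeating or loss of appetite" pair set
  to latent $\rho = 0.448$, obtained with `calibrate_latent_correlation()`
  so the *observed* Pearson correlation of the thresholded codes is 0.36 —
  thresholding attenuates correlation, which is why $\rho > 0.36$;
* outcome coefficients of $-2$ per symptom code step (code 1 = yes raises
  PPD log-odds), zero for age. This sizes the Bayes accuracy of the world
  at $\approx 0.93$, so a well-tuned classifier can reach the 0.90–0.95
  band — consistent with the published headline accuracy of a comparable
  magnitude.

The calibration routine uses common random numbers: the same latent draws
are reused at every candidate $\rho$, making the observed-correlation
objective smooth and monotone so bisection converges cleanly.

What the generator does **not** emulate: the five discarded questionnaire
columns, any real marginal skew beyond the stated defaults, item
non-response, and whatever higher-order dependence the real data carries
beyond pairwise correlation. A green test on synthetic data therefore
establishes that the machinery is correct under the stated world — it does
not reproduce the published benchmark tables, which require the external
CSV (pass it via `read_ppd()` or the CLI's `--data` flag for a qualitative
comparison).

At $n = 1503$ the observed maximum correlation has a sampling standard
deviation of about 0.022 around its calibrated centre of 0.36; single-seed
summaries typically land within $\pm 0.05$.

## Evaluation protocol

`metric_report()` derives the nine screening metrics (accuracy, precision,
recall, F1, MCC, specificity, NPV, FPR, FNR) from a confusion matrix with
1 = anxious as the positive class. Small test sets can produce empty
margins; any zero-denominator metric is reported as 0 and named in a
`flagged` column rather than silently dropped.

Splits are stratified by default (the 65/35 imbalance makes unstratified
9:1 splits unstable); the test-set size is `round(n * (1 - f))` with ties
rounded half away from zero, so sizes never depend on the seed.

`repeated_runs()` re-runs the model `k = 30` times. The published protocol
does not state whether the 30 runs re-split the data or only re-initialise;
the default re-draws both split and initialisation per run (`"resplit"`),
and `"fixed_split"` varies only the initialisation. `mann_whitney()`
compares two accuracy series two-sided, exact by enumeration when the
pooled size is at most 12 with no ties, otherwise by the tie- and
continuity-corrected normal approximation (delegated to
`stats::wilcox.test` behind this rule). Two caveats we verified by
enumeration: the corrected normal approximation can deviate from the
inclusive exact tail by up to ~0.015 for mid-range U at 6+6 (it is much
closer in the decision-relevant tails), and a fully tied pooled sample has
zero rank variance, for which we define p = 1. The 0.05 significance level
is reported, never auto-asserted.

`ablate()` trains FCNN, DNN and ensemble with shared seeds on one shared
split — the ensemble's members *are* the two single-model rows, so the
comparison isolates the weighting rule. `benchmark()` runs the proposed
model against pluggable baseline adapters (`fit(X, y)` / `predict(state,
X)`); logistic regression and LDA wrap established implementations, k-NN
and categorical naive Bayes are small local ones, and a majority-class
control bounds the floor. Adapter failures are isolated per classifier and
the run continues. SVM, tree/forest, boosting and deep sequence baselines
are not shipped because no suitable implementation is available in the
supported dependency set; the adapter contract accepts user-supplied ones.

## Known limitations

* Single hidden layer by default and plain SGD only (no momentum/Adam);
  the published model family does not use them.
* The ensemble weighting is a fixed convex rule, not learned stacking; with
  `dropout1 = 0` it structurally favours the DNN (see above).
* Synthetic-data realism is limited to schema, class balance and pairwise
  correlation structure.
* Exact Mann–Whitney is only engaged up to pooled size 12; beyond that the
  normal approximation is used, as is standard at 30 runs per classifier.
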