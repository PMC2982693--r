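---
title: "Graph-regularized prediction of drug-target interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-regularized prediction of drug-target interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlaprls)
library(dplyr)
```

## The problem

A gold-standard drug-target dataset consists of three matrices: a binary
interaction matrix $Y \in \{0,1\}^{n_d \times n_p}$ (1 = experimentally
confirmed interaction between drug $i$ and protein $j$), a drug-drug
chemical similarity matrix $S_d$ (substructure-overlap scores such as
SIMCOMP, in $[0,1]$), and a protein-protein sequence similarity matrix
$S_p$ (normalized Smith-Waterman scores, in $[0,1]$). Known interactions
are rare — on the order of 1-10% of all pairs — and, crucially, there are
no confirmed *non*-interactions: every 0 in $Y$ means "unknown". The task
is to rank the unknown pairs so that true interactions concentrate at the
top of the list. This is a semi-supervised regime: a small set of positive
labels, a vast unlabeled remainder, and no negatives at all.

## Models

### Weighted profile (baseline)

The simplest similarity-based predictor scores a pair by averaging the
labels of similar neighbors in one domain:

$$f(d_i, p_j) = \frac{1}{N_{d_i}} \sum_k S_d(d_i, d_k)\, Y_{kj},
\qquad N_{d_i} = \sum_k S_d(d_i, d_k),$$

with the analogous score $f(p_j, d_i)$ computed from $S_p$ on the
transposed label matrix. The combined baseline averages the two:
$\bar f = (f(d_i,p_j) + f(p_j,d_i))/2$. A row with zero total similarity
has no evidence and is scored 0. This is `dti_predict(method =
"weighted_profile")`; the single-space variants are exposed as
`"weighted_profile_drug"` and `"weighted_profile_protein"`.

### LapRLS: graph-regularized least squares

In each domain a similarity graph is built and the score matrix $F$ is fit
by trading label fidelity against smoothness along the graph:

$$F_d^* = \arg\min_{F_d} \; \lVert Y - F_d \rVert_F^2
 + \beta_d\, \mathrm{Trace}(F_d^\top L_d F_d),$$

where $L_d = I - D_d^{-1/2} W_d D_d^{-1/2}$ is the normalized graph
Laplacian of the drug graph ($D_d$ = diagonal of row sums of $W_d$).
Writing $F_d = W_d \alpha_d$ (representer form) gives the closed-form
solution

$$F_d^* = W_d (W_d + \beta_d L_d W_d)^{-1} Y,$$

and symmetrically $F_p^* = W_p (W_p + \beta_p L_p W_p)^{-1} Y^\top$ in the
protein domain. The final prediction averages the two views:
$F^* = (F_d^* + F_p^{*\top})/2$. With $W_d = S_d$ and $W_p = S_p$ this is
plain LapRLS (`method = "laprls"`).

### NetLapRLS: fusing in the interaction network

The known interaction network itself carries similarity information: two
drugs that share many targets are pharmacologically alike. The
shared-partner kernel counts exactly that,
$K_d = Y Y^\top$ and $K_p = Y^\top Y$ (`network_kernel()`), and is fused
with the intrinsic similarity by a normalized linear combination

$$W_d = \frac{\gamma_{d1} S_d + \gamma_{d2} K_d}{\gamma_{d1} + \gamma_{d2}},$$

(`fuse_similarity()`), and likewise for $W_p$. Running the same
closed-form solver on the fused graphs is NetLapRLS (`method =
"netlaprls"`). Setting $\gamma_{d2} = \gamma_{p2} = 0$ reduces it exactly
to LapRLS — the package tests this reduction to $10^{-10}$.

During cross-validation the kernel is rebuilt from each fold's *training*
positives only, so held-out labels can never leak into the fit (a
perturbation test asserts this).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `beta_d`, `beta_p` | 0.3 | smoothness weight per domain; 0 = pure label fit (returns the labels when the graph matrix is nonsingular), large values force graph-constant scores |
| `gamma_d1`, `gamma_p1` | 1 | weight of the intrinsic (chemical / sequence) similarity |
| `gamma_d2`, `gamma_p2` | 0.01 | weight of the shared-partner kernel; calibrated against *raw counts*, which is why it is two orders of magnitude below `gamma1` |
| `ridge_eps` | 1e-8 | jitter added to the linear system; similarity matrices with duplicate rows are rank-deficient and the closed form silently assumes invertibility |

The defaults are the values used in the benchmark study of the four
gold-standard target classes (enzymes, ion channels, GPCRs, nuclear
receptors); they are deliberately not re-tuned here.

Two secondary flags on `normalized_laplacian()` cover readings the
benchmark description leaves open: `zero_diagonal` drops self-similarity
from the degree computation (default keeps it — degrees are plain row
sums), and the kernel is used unscaled by default (a max-normalization
would invalidate the `gamma2 = 0.01` calibration).

## Numerical choices

* The solver solves the general (non-symmetric) linear system
  $(W + \beta L W + \varepsilon I)\,\alpha = Y$ with `solve()` rather than
  forming an inverse; a singular system raises an error carrying the
  reciprocal condition number.
* $L$ is re-symmetrized as $(L + L^\top)/2$ after computation; isolated
  nodes use the pseudo-inverse convention $(D^{-1/2})_k = 0$, giving them
  an identity Laplacian row and no smoothing.
* Similarity matrices with asymmetry at or below $10^{-6}$ (ASCII
  rounding in distributed files) are repaired by averaging with the
  transpose; larger asymmetry is a validation error naming the file and
  cell.
* Everywhere a ranking is materialized, ties break by (drug index,
  protein index) ascending — outputs are bit-identical across platforms.

## Cross-validation protocols and metrics

`make_cv_plan()` implements two schemes. **Pairwise**: the known
interactions are shuffled (seeded) into folds of near-equal size; each
fold's positives are relabeled 0 in the training matrix and the test set
is every pair that is not a training positive. Note the test set is huge
compared to the training set — with 54 drugs, 26 proteins, 90 positives
and folds of 10, each fold trains on 80 positives and tests on the
remaining 1,324 pairs, 10 of them positive. **blm_drug / blm_protein**:
local-model style domain CV — the drugs (proteins) are partitioned, all
pairs touching a held-out drug (protein) are zeroed for training and form
the test set, and held-out drugs are scored by the protein-domain
classifier (and vice versa), since a held-out node has no labels of its
own.

`run_cv()` pools test-pair scores across folds for the headline report
and returns a per-fold table as well (published comparisons use both
presentations); `cross_validate(repeats = r)` reruns with consecutive
seeds and reports mean and standard deviation per metric.

Metrics: `roc_auc()` is the tie-aware rank statistic (normalized
Mann-Whitney $U$); `aupr()` is the step-wise precision-recall area
$\sum_k (R_k - R_{k-1}) P_k$; `threshold_metrics()` computes
sensitivity/specificity/PPV after marking the top-$k$ pairs positive,
where $k$ is either the number of positives in the test set
(`"test_size"` — the only reading of a "same number as the test set"
cutoff that does not mark everything positive) or a top percentile of all
test pairs (`"top_percentile"`, default 1%).

## The synthetic generator

Real gold-standard data cannot be bundled, so `simulate_dti_dataset()`
generates datasets with the structure the models assume: latent clusters
on both sides, within-cluster similarity `within_sim = 0.8` vs
between-cluster `between_sim = 0.2` plus Gaussian noise (sd 0.05,
symmetrized, clipped to $[0,1]$, unit diagonal), and a block-structured
sparse $Y$: each drug cluster is compatible with one uniformly drawn
protein cluster, compatible blocks interact with probability 0.3,
everything else at a 0.005 background rate. With the default 60 drugs,
40 proteins and 4 x 3 clusters this yields a density around 10%, at the
dense end of curated interaction collections. One drug cluster maps to
one protein cluster (rather than a denser random bipartite map) so that
every drug cluster is guaranteed signal; all draws come from a single
seeded stream in a fixed order, so a seed fully determines the dataset.

Problem sizes used in the shipped checks — datasets up to 60 x 40, fold
counts of 5-10, 20 generator seeds, 50 random solver instances with
$n \le 15$ — were chosen so that the entire suite re-runs in well under a
minute while still exercising every code path at sizes where brute-force
oracles are exact.

### What the generator does and does not emulate

It reproduces: similarities in $[0,1]$ with unit diagonal and latent
cluster structure, a sparse block-structured $Y$, and the presence of
network signal (drugs in one cluster share targets). It does **not**
reproduce several features of real chemical/genomic data: heavy-tailed
similarity distributions with most mass near zero, hub drugs and
promiscuous targets, correlated noise between the two domains, or
network information that goes beyond cluster co-membership.

This matters for interpreting the benchmark trend on synthetic data. On
the generated datasets the network-augmented model consistently edges out
plain LapRLS (the shared-partner kernel adds real signal), and the
combined weighted profile consistently beats either single-space profile
— both trends match the published benchmark. But the combined weighted
profile also *beats* plain LapRLS here, the opposite of the published
ordering on real data: under block-structured similarities a one-step
similarity average is already close to the best achievable predictor, so
the extra smoothing that pays off on real, noisy, heavy-tailed similarity
data has nothing left to add. The acceptance checks report this ordering
as computed rather than adjusting the generator until it flips; passing
the other trends on synthetic data shows the machinery is correct, not
that the synthetic regime reproduces every empirical ranking obtained on
curated datasets.

## Worked example

```{r example}
ds <- simulate_dti_dataset(seed = 42)
ds

fit <- dti_predict(ds, "netlaprls")
tidy(fit, top_k = 5)

cv <- run_cv(ds, "netlaprls", plan = make_cv_plan(ds, "pairwise", 10, seed = 42))
glance(cv)
```

```{r roc, fig.width = 5, fig.height = 4}
autoplot(cv, type = "roc")
```

## Known limitations

* The closed form inverts an $n \times n$ system per domain; fine for
  hundreds-to-thousands of nodes, not for chemical libraries of millions.
* No hyperparameter search is shipped; `beta` and `gamma` are taken as
  fixed benchmark values.
* The local-model CV schemes mirror the published comparison protocol at
  the level of detail available; the SVM-based local-model classifier
  itself is out of scope.
* Scores are not calibrated probabilities; only their ranking is
  meaningful.
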