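---
title: "Modeling read-start bias with positional stacking energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling read-start bias with positional stacking energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackbias)
```

## The model

Read starts in an RNA-Seq library are far from uniform along a transcript:
fragmentation chemistry, priming and the synthesis of the new strand all
respond to the local sequence. `stackbias` models the count of reads
starting at position $j$ of transcript $i$ as

$$n_{ij} \sim \mathrm{Poisson}(\mu_{ij}), \qquad
  \log \mu_{ij} = v_i + \alpha + \log \frac{1}{1 + e^{E_{ij}}},$$

where $v_i = \log \mu_i$ is the transcript's log-abundance, $\alpha$ a
global intercept, and $E_{ij}$ the free energy of the $N$-base context
window around the read start,

$$E_{ij} = \sum_{k=1}^{N-1} w_k\, \varepsilon_{b_k, b_{k+1}}.$$

Each of the $N-1$ overlapping dinucleotides $(b_k, b_{k+1})$ contributes
its stacking energy $\varepsilon$ — a nearest-neighbour interaction
strength, one value per ordered dinucleotide — scaled by a positional
weight $w_k$ expressing how much that slot of the window matters. The
logistic complement $1/(1+e^{E})$ is the binding affinity of the window;
because $w, \varepsilon \ge 0$ the energy is non-negative and the affinity
at most $1/2$. The window spans $N/2$ bases upstream through $N/2 - 1$
downstream of (and including) the read-start base; with the default
$N = 40$ that is 20 upstream and 19 downstream, and the model has
$39 + 16 + 1 = 56$ free parameters. Positions too close to a transcript
end to own a full window, and windows containing an ambiguous base, are
excluded everywhere — fitting, prediction and the abundance denominator —
so that no energy ever has to be invented for a partial context.

Only the products $w_k \varepsilon$ enter the energy, so the scale split
between the two groups is not identifiable. We fix it by renormalising
$\sum_k w_k = 1$ after every optimisation block; the uniform
initialisation $w_k = 1/(N-1)$ already satisfies this, and the convention
makes weight and energy profiles comparable across runs.

## Fitting

Writing $y_{ij} = \log n_{ij}$ for observed counts, the parameters solve
the penalized nonlinear least-squares problem

$$\min_{w, \varepsilon, \alpha, v} \;
  \sum_{i,j : n_{ij} \ge 1}
  \bigl(y_{ij} - v_i - \alpha - \log \tfrac{1}{1+e^{E_{ij}}}\bigr)^2
  \;-\; \lambda \Bigl(\sum_k \log w_k + \sum_d \log \varepsilon_d\Bigr),$$

with a logarithmic barrier keeping every $w$ and $\varepsilon$ strictly
positive and $\lambda$ driven towards zero. Zero-count positions cannot
enter this objective (their log count is undefined); they re-enter in the
deviance used for evaluation, which has a well-defined zero branch. We
considered adding a pseudocount instead and rejected it: it changes the
target of the regression at low coverage, while exclusion merely reduces
the training set.

`fit_bias_model()` alternates

1. a damped Newton block update of $w$ with $\varepsilon$ fixed,
2. a damped Newton block update of $\varepsilon$ with $w$ fixed,
3. closed-form updates of $\alpha$ (global mean residual) and of each
   $v_i$ (per-transcript mean residual — the exact least-squares minimiser
   given the other parameters),

renormalising $\sum w_k = 1$ after every block. Newton systems use the
exact block Hessian with an escalating ridge when a Cholesky factorisation
fails, and a normalised gradient step as last resort; every step is
accepted only if it decreases the objective, with backtracking halving.
Iteration stops when the Euclidean distance between consecutive
concatenated $(w, \varepsilon, \alpha)$ vectors falls below the threshold
(default 0.1) or the iteration cap is reached. Because that printed
threshold refers to the whole parameter vector, `fit_config()` also offers
`stop_metric = "rms"`, which divides by $\sqrt{\dim}$ so the same number
remains meaningful for other window sizes.

Two bookkeeping choices matter for reproducibility and are deliberate:

* **Barrier continuation.** Newton directions use the current continuation
  coefficient ($\lambda: 10^{-2} \to 10^{-6}$, factor-10 decay, re-solving
  at each stage), but step acceptance and the recorded `objective_trace`
  always use the barrier at the final $\lambda$. The trace is therefore
  non-increasing by construction — a property the test suite asserts at
  tolerance $10^{-8}$ — while iterates stay strictly interior.
* **Reported abundances.** During descent the $v_i$ are working variables
  of the least-squares objective, which conditions on $n_{ij} \ge 1$ and
  is therefore biased at moderate coverage. The `v` returned in a
  `bias_fit` is instead the closed-form Poisson maximum-likelihood
  estimate under the fitted preferences,
  $\hat v_i = \log \bigl(\sum_j n_{ij} \big/ \sum_j e^{\alpha} a_{ij}\bigr)$
  with $a_{ij}$ the fitted affinity, which uses every eligible position
  including zeros. The same closed form provides null-model abundances,
  held-out abundances in cross-validation, `predict_track()` and
  `estimate_abundance()`; it reduces to the mean-coverage initialisation
  when the preference is constant.

The intercept $\alpha$ is a pure intercept of the log-rate once
$\sum w_k = 1$ is fixed, so it is updated in closed form rather than by
Newton; it remains confounded with a constant shift of all $v_i$ in the
least-squares objective, which is harmless for every quantity the package
reports (rates, deviances, correlations are shift-invariant), but users
comparing $\alpha$ across fits should remember it absorbs the global mean
residual.

## Goodness of fit

Model fit is summarised by the deviance R-squared $R^2 = 1 - d/d_0$, where
$d$ is the Poisson deviance of the fitted model over all eligible
positions (zeros included) and $d_0$ that of the null model: equal
positional weights, the initial stacking-energy table, $\alpha = 0$, and
closed-form abundances. With the default uniform initial table the null
model is exactly the constant-rate-per-transcript Poisson model. The
published nearest-neighbour stacking-energy tables this family of models
descends from are not shipped here; `fit_config(initial_energy = ...)`
accepts any user-supplied table for both initialisation and the null
model, and the uniform fallback equals the optimizer's own starting point.

`cross_validated_r2()` partitions transcripts into five folds (seeded
shuffle, 80/20 splits), refits the global parameters on each training
portion, assigns held-out $v_i$ by the closed form with those parameters
frozen, and pools held-out deviances before forming $1 - \sum d / \sum
d_0$. Pooling, rather than averaging per-fold ratios, keeps transcripts
with few eligible positions from dominating.

## Preprocessing and data import

`counts_from_alignments()` tallies primary, mapped, forward-strand
alignments by their leftmost aligned base on the transcript; everything
else (reverse strand, secondary, supplementary, unmapped, sub-MAPQ) is
excluded and tallied in a skip log. Only transcriptome alignments are
supported — spliced genome coordinates are out of scope. Since
multi-mapping policy differs between aligners, we count one increment per
read via the primary record only.

`preprocess_track()` implements the two standard cleanups as a mask over
positions: trimming a fixed number of bases from each end (20 reproduces
the spike-in protocol) and dropping zero-count positions. The mask is a
view — coordinates never shift, so window extraction stays valid — and
the operation is idempotent. `select_training_set()` ranks transcripts by
mean per-base start count rather than raw totals, so transcript length
does not dominate the ranking, and breaks ties lexicographically for
reproducibility.

## The simulator

`simulate_truth()` / `simulate_counts()` generate i.i.d. nucleotide
sequences with a chosen GC content and draw
$n_{ij} \sim \mathrm{Poisson}(e^{v_i + \alpha} a_{ij})$ at every
full-context position, with edge positions zero. Sequences are i.i.d. by
default so that any structure in the counts is attributable solely to the
planted energy model; a first-order Markov option
(`markov_order = 1`) exists for robustness experiments. Counts are drawn
under `seed + 1` so the count noise is independent of the sequence draw,
and everything is reproducible from the one seed. The default truth
`gc_bias_params()` makes stacking energy grow with the dinucleotide's G/C
content and peaks the positional weights at the read-start base — the
qualitative shape recovered from real libraries.

Default simulation scale is 50 transcripts of 1000 nt with
$v^* \sim U[\log 1, \log 20]$ and $\alpha^* = 0$, sized so a full fit
takes about a minute on one CPU. Two fixed study conditions are used by
the test suite and the acceptance script:

* **Recovery design** — 50 × 1000 nt, constant GC 0.5,
  $v^* \sim U[\log 25, \log 100]$, chosen so mean eligible-position
  coverage is above 5 read starts; at that depth the fitted log-affinity
  profile correlates with the planted one at $r > 0.95$ and recovered
  $v_i$ at $r > 0.99$.
* **Gradient design** — 40 × 500 nt with GC running 0.3 to 0.7 across
  transcripts. Because mean affinity then varies almost threefold with
  composition, naive RPKM ranks are distorted in a way the model can
  correct: the Spearman correlation of the bias-corrected estimator with
  the planted abundances is at least that of RPKM, and cross-validated
  $R^2$ is positive.

What passing these tests shows — and what it does not: the simulator
draws from exactly the model being fitted, with independent positions,
no overdispersion, no read errors, no multi-mapping ambiguity, no
isoform mixtures and no fragment-length effects. Recovery under these
conditions validates the estimator and optimizer, not the adequacy of
the model for any particular real library; on real data the deviance
R-squared, not the recovery correlation, is the relevant diagnostic.

## Numerical notes

* $\log(1 + e^E)$ is computed as $\max(E, 0) + \log(1 + e^{-|E|})$; large
  positive energies underflow the affinity smoothly towards zero.
* The deviance uses the $n \log n \to 0$ limit at $n = 0$; a zero fitted
  rate against a positive count raises an explicit infinite-deviance
  error rather than returning `Inf`.
* All-zero transcripts are excluded from fitting with a warning; in
  evaluation their closed-form abundance is $-\infty$ and their rates 0,
  contributing zero deviance.
* Ties in training-set selection and fold assignment are broken
  deterministically (lexicographic ids; seeded shuffle), so identical
  seeds give bit-identical fits.

## Worked example

```{r example, eval = FALSE}
truth <- simulate_truth(n_transcripts = 20, length = 600, seed = 42,
                        params = gc_bias_params(window_size = 20))
counts <- simulate_counts(truth)
fit <- fit_bias_model(counts, fit_config(window_size = 20, seed = 42))
fit
cross_validated_r2(counts, fit_config(window_size = 20, seed = 42))
head(abundance_table(counts, fit$params))
```

## Limitations

Single-end, transcriptome-aligned reads only; no isoform deconvolution,
no paired-end fragment model, no overdispersion. The least-squares
objective approximates the Poisson likelihood on the log scale and
excludes zero-count positions, so parameter estimates at very low
coverage lean heavily on the closed-form abundance step; the deviance
R-squared remains well-defined throughout.
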