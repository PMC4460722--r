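# stackbias

Read starts in RNA-Seq libraries are strongly non-uniform: the sequence
around a position modulates fragmentation, priming and strand synthesis,
so per-base read-start counts carry a reproducible sequence bias that
distorts naive expression measures such as RPKM. `stackbias` is for
anyone quantifying transcript abundance from single-end, transcriptome-
aligned RNA-Seq who wants that bias modeled explicitly rather than
averaged away.

## The model

The count of reads starting at position *j* of transcript *i* is

    n_ij ~ Poisson(mu_ij),    log mu_ij = v_i + alpha + log( 1 / (1 + exp(E_ij)) )

where `v_i` is the transcript log-abundance, `alpha` an intercept, and

    E_ij = sum_{k=1}^{N-1} w_k * eps(b_k, b_{k+1})

is the free energy of the *N*-base context window around the read start
(default N = 40: 20 bases upstream through 19 downstream of the start,
inclusive): each overlapping dinucleotide contributes a stacking energy
`eps`, scaled by a positional weight `w_k`. The logistic complement of the
energy is the window's binding affinity, the position-specific multiplier
of the transcript rate. The default model has 39 + 16 + 1 = 56 free
parameters.

The package provides:

- `counts_from_alignments()` — per-position read-start counts from
  SAM/BAM against a transcript FASTA, with filtering and a skip log;
- `preprocess_track()`, `select_training_set()` — end trimming,
  zero-position masking and the "top-k highest-expressed single-isoform"
  training-set rule;
- `fit_bias_model()` — alternating penalized Newton least squares over
  the weights, energies and intercept, with a log-barrier keeping both
  parameter groups positive;
- `poisson_deviance()`, `cross_validated_r2()` — goodness of fit as the
  deviance R² = 1 − d/d₀ against the uniform-preference null model,
  pooled over 5 seeded folds;
- `estimate_abundance()` / `abundance_table()` — the closed-form
  bias-corrected abundance MLE, with `rpkm()` as baseline and
  `rank_correlation()` / `filter_low_expression()` for gold-standard
  comparisons;
- `simulate_truth()` / `simulate_counts()` / `make_sam_fixture()` — a
  seeded generative simulator for end-to-end parameter-recovery testing;
- `inst/cli/stackbias.R` — a thin command-line wrapper
  (`counts | fit | predict | quantify | simulate | evaluate`) writing a
  manifest beside every output.

## Worked example

```r
library(stackbias)

truth  <- simulate_truth(n_transcripts = 20, length = 600, seed = 42,
                         v_range = c(log(10), log(40)),
                         params = gc_bias_params(window_size = 20))
counts <- simulate_counts(truth)
fit    <- fit_bias_model(counts, fit_config(window_size = 20, seed = 42))
fit
#> bias_fit: 20 transcripts, 38 outer iterations (converged: TRUE)
#>   deviance 1.335e+04 vs null 1.564e+04; training R^2 = 0.147

cor(truth$v_true[names(fit$v)], fit$v)
#> [1] 0.9945706

head(abundance_table(counts, fit$params), 3)
#>   transcript_id       mu n_positions_used total_counts      rpkm
#> 1         tx001 3.949522              581         2229 134620.96
#> 2         tx002 2.076322              581         1183  71447.55
#> 3         tx003 2.918446              581         1677 101282.79

cross_validated_r2(counts, fit_config(window_size = 20, seed = 42))
#> [1] 0.1391154 (attributes: per-fold deviances)
```

The fitted `bias_fit` holds the model parameters (here 19 + 16 + 1 = 36
for the 20-base window; 56 for the default 40), the per-transcript
log-abundances (`fit$v`, the closed-form MLE under the fitted
preferences), the monotone objective trace, and training deviance against
the null model. The training deviance R² of 0.147 says the sequence
preference explains that share of the null model's deviance, and holds up
out of sample (cross-validated R² 0.139). `mu` is the bias-corrected
expression measure — expected read starts per eligible position once the
sequence preference is divided out. Its scale is relative (the fitted
intercept absorbs a global factor; here the planted abundances 28.0,
14.8, 20.2 are each ≈ 7.1 × `mu`), so it is read as a relative measure:
it recovers the planted abundances at Pearson r = 0.995 on the log scale,
while `rpkm` is the naive baseline.

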