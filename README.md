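# attnms1

Sequence-based prediction of peptide MS1 intensity with an interpretable
attention encoder–decoder.

## The problem

In HPLC-ESI-MS/MS, peptides at identical molar concentrations produce MS1
precursor signals that differ by orders of magnitude, because ionization
efficiency depends on sequence-derived physicochemical properties. Using
equimolar peptide-pool data (where concentration is controlled and the
sequence effect is directly observable), `attnms1` trains a deep model that
predicts a peptide's log MS1 intensity from its amino acid sequence alone
— and, unlike a black box, reports *which residues* the prediction relied
on, so that the learned signal can be related to physicochemical
properties. It is intended for computational proteomics researchers
working toward label-free, sequence-aware quantification.

## The model

A bidirectional-GRU encoder reads the one-hot encoded sequence
(20 residues + padding, padded to length 40) and produces per-position
states `h_j`. An additive attention mechanism scores each state against the
encoder final state `s`,

```
e_j = vᵀ tanh(W s + U h_j + b),    α_j = softmax(e)_j,    c = Σ_j α_j h_j
```

and a single-step bidirectional-GRU decoder consumes `[c ; start]` and a
one-unit dense head to emit the scalar intensity. Training minimises MSE
with Adam defaults; the recurrent forward/backward passes are compiled
(RcppArmadillo). The attention weights `α`, averaged per amino acid across
a dataset, form a 20-value relevance profile that is screened against the
566 AAindex1 physicochemical indices by Pearson correlation (significant
at |PCC| ≥ 0.7, i.e. p < 1e-3 at n = 20).

The package also implements the surrounding workflow: MaxQuant
(`peptides.txt`/`summary.txt`) and SDRF ingestion; PEP/decoy/contaminant/
zero-intensity filtering, replicate merging (median intensity, CV ≤ 0.3)
and enzyme-based segmentation; log/min–max target transforms and 5-fold
splits; synthetic proof-of-concept generators with known per-symbol
contributions; and random-forest / ridge baselines on a positional
840-variable encoding under a shared cross-validation harness.

## Worked example

Train on a synthetic dataset with known ground truth and check that the
attention profile recovers the planted contributions:

```r
library(attnms1)

ds  <- synthetic_generate(poc_preset("POC1", n_sequences = 10000, seed = 1))
cfg <- attn_config(units = 64, max_len = 8, epochs = 30, patience = 3,
                   min_delta = 1e-4, seed = 1)
rep <- crossval(ds, attention_learner(ds$spec$alphabet, cfg),
                k = 5, seed = 1, log_target = FALSE, scale_range = c(0, 30))
s <- rep$summary
cat(sprintf("MAPE %.3f%%  PCC %.4f\n",
            s$mean[s$metric == "mape_log"], s$mean[s$metric == "pcc_log"]))
#> MAPE 0.372%  PCC 0.9987

prof <- mean_attention_per_aa(ds$data$sequence, rep$alpha)
recovery_score(prof, ds$ground_truth)$spearman
#> [1] 0.9878788
```

`mape_log` here is the held-out mean absolute percentage error on the
(identity-scale) targets — about 0.4%, i.e. the model reproduces the
synthetic intensity to a fraction of a percent — and the Spearman
correlation of ~0.99 says the per-symbol mean attention weights rank the
true contributions almost perfectly. On real, filtered repository data the
same protocol is run with `log_target = TRUE` after `filter_cascade()`,
and `rank_significant(prof, parse_aaindex1("aaindex1"))` lists the
physicochemical indices that track the attention profile.

A command-line wrapper covers the same workflow
(`inst/cli/attnms1 simulate|ingest|filter|train|predict|interpret|benchmark`).

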