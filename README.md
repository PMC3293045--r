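# mirstage

Stage-wise miRNA differential-expression and regulatory-network analysis
for tumour progression series.

`mirstage` implements the complete analysis chain used to study how
microRNA expression changes across ordered clinical stages of
nasopharyngeal carcinoma (normal epithelium → stage I-II → III → IV →
lymph-node metastasis), in designs far too small for per-gene variance
estimation to be trusted:

1. **Moderated multi-group screening** — a random-variance-model (RVM)
   F-test. Each feature's inverse residual variance is modelled as
   `1/σ² ~ Gamma(a, scale = b)` across all features; the per-feature
   variance is shrunk to the posterior value
   `σ̃² = ((n−k)s² + 2/b) / ((n−k) + 2a)` and the moderated statistic
   `F̃ = MS_between / σ̃²` is referred to `F(k−1, n−k+2a)`. The prior
   contributes `2a` extra denominator degrees of freedom — the source of
   the method's small-sample power. `(a, b)` are estimated by maximum
   likelihood from the fact that `s²·a·b ~ F(n−k, 2a)` under the model.
   Discoveries are gated at `p < 0.05` and Benjamini–Hochberg
   `FDR < 0.05`, with per-stage up/down calls via a Welch contrast
   against the reference stage.
2. **Stage-trend patterns** — hierarchical clustering (centered Pearson
   distance, average linkage) and classification of stage-mean
   trajectories into six dynamic patterns (gradual loss, early loss,
   down-then-up, up-then-down, gradual gain, metastasis spike).
3. **miRNA–target integration** — predicted target pairs are restricted
   to a tissue-specific gene list, then to pairs whose miRNA and mRNA
   differential directions are *inverse* (the repression signature),
   optionally adding a Pearson anti-correlation filter on paired
   expression.
4. **Enrichment** — hypergeometric over-representation of the retained
   target genes against GMT gene sets (plain or EASE-style), in the
   familiar Term/Count/%/PValue/FDR layout.
5. **Regulatory networks** — the bipartite miRNA–target network with
   degree-≥10 hub calling; IUPAC consensus motif scanning of pre-miRNA
   upstream sequences (both strands, mismatch budget) to build the
   TF–miRNA network with Pearson-correlation edge weights ("regulatory
   ability"); and mining of TF→miRNA→TF **negative feedback loops**,
   where a TF binds the promoter of a miRNA that silences the TF's own
   transcript.
6. **qPCR validation helpers** — comparative-Ct quantification
   (`fold = 2^(−ΔΔCt)`, U6/GAPDH normalizers) and standard-curve
   amplification efficiency `E = 10^(−1/slope) − 1`.
7. **Synthetic data** — a generator that emulates the 22-sample staged
   design (6/4/4/4/4) under exactly the model assumptions above, with
   planted differential features, planted anti-correlated miRNA–target
   pairs and planted promoter motifs, so every stage of the pipeline can
   be benchmarked against known truth.

The study's printed result tables (stage-wise miRNA calls, inverse
miRNA/target pairs, per-stage core transcription factors, feedback
loops) ship as plain-text fixtures and load via `load_fixture_table()`.

## Worked example

```r
library(mirstage)

design <- npc_stage_design()          # 6 normal / 4 / 4 / 4 / 4 MET
sim    <- generate_staged_expression(seed = 42)   # 766 miRNAs, 48 planted

prior <- fit_rvm_prior(pooled_residual_variances(sim$matrix, design),
                       df = 17)
prior
#> rvm_prior: a = 1.908, b = 1.515 (prior df = 2a = 3.82)
#>   fitted on 766 variances (0 excluded), converged: TRUE

diff <- rvm_f_test(sim$matrix, design, prior)
head(diff[order(diff$p_value),
          c("feature_id", "f_raw", "f_rvm", "p_value", "q_value")], 3)
#>       feature_id     f_raw     f_rvm      p_value      q_value
#> 284 syn-miR-0284 235.59549 143.83343 7.570691e-15 5.799149e-12
#> 494 syn-miR-0494 125.03451  96.79909 3.859269e-13 1.478100e-10
#> 410 syn-miR-0410  76.75804  70.16668 8.844480e-12 1.717376e-09

sig <- diff$feature_id[diff$p_value < 0.05 & diff$q_value < 0.05]
length(sig)                                        # 47 called
mean(sim$truth$de$feature_id %in% sig)             # 0.979 of planted 48

calls <- stage_direction_calls(sim$matrix, design, diff)
lengths(calls[["MET"]])                            # down 15, up 15
```

The moderated statistic is visibly shrunk for the top feature
(`f_rvm = 144` vs classical `f_raw = 236`): its observed variance was
luckily small, and the prior pulls it back toward the ensemble. 47 of
766 miRNAs pass the global gate, recovering 97.9% of the 48 planted
ones; at the metastasis stage 30 of them also pass the Welch stage
contrast, 15 in each direction.

Loading the packaged study tables instead of simulations:

```r
t1 <- load_fixture_table("table1")
lengths(t1[["I-II"]])                 # down 7, up 5 -> the printed 12
t6 <- load_fixture_table("table6")
net   <- build_tf_mirna_network(t6[, c("tf", "mirna")])
loops <- find_feedback_loops(net, target_pairs(t6$mirna, t6$target_gene))
unique(loops$tf)                      # "ETS2" "KLF6" "SP1"
```

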