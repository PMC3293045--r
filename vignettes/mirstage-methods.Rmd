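---
title: "mirstage: models, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirstage: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstage)
```

`mirstage` analyses miRNA expression profiled across ordered clinical
stages of a tumour — here the nasopharyngeal carcinoma series normal,
I-II, III, IV, lymph-node metastasis — and follows the signal downstream
into target genes, gene sets and transcription-factor (TF) regulation.
This vignette explains the statistical model of each step, the
parameters that matter, what the synthetic generator does and does not
emulate, and the choices made where the design was genuinely open.

## The random variance model

Staged biopsy studies are small: six controls and four samples per
stage. A per-feature residual variance estimated on `n − k = 17` degrees
of freedom is unreliable, and assuming one common variance for all
features is biologically wrong. The random variance model sits between
these extremes. The reciprocal of each feature's true residual variance
is taken to be drawn from a gamma distribution,

$$ 1/\sigma_g^2 \sim \mathrm{Gamma}(a,\ \mathrm{scale} = b), $$

so that the observed pooled variance satisfies
$s_g^2\,a\,b \sim F(n-k,\ 2a)$. `fit_rvm_prior()` maximizes this
F-likelihood over $(a, b)$ — deterministically: a fixed moment-based
start, BFGS on the log parameters, Nelder–Mead fallback, and a hard
error (never silent success) on degenerate input such as constant
variances. The posterior variance for each feature,

$$ \tilde\sigma_g^2 = \frac{(n-k)\,s_g^2 + 2/b}{(n-k) + 2a}, $$

is a strictly convex combination of the observed variance and the prior
scale $1/(ab)$. The moderated statistic
$\tilde F_g = \mathrm{MS}_{between}/\tilde\sigma_g^2$ is referred to
$F(k-1,\ n-k+2a)$: the ensemble contributes $2a$ extra denominator
degrees of freedom, which is where the small-sample power comes from.
As $a \to 0$ with $2/b \to 0$ the moderated test collapses to the
classical one-way ANOVA F — the test suite checks this limit to
`1e-9`, and checks calibration of the null statistic against its
reference distribution.

Two conventions worth noting. Features with missing values are dropped
from the test with a logged count — missingness is never zero-filled.
Features that are exactly constant in every sample get `p = 1` and a
`zero_variance` flag; they are excluded from prior fitting but retained
in testing, where the prior term alone sets their denominator.

**Multiplicity.** The discovery gate is `p < 0.05` together with
Benjamini–Hochberg `FDR < 0.05` (`bh_fdr()`, a checked wrapper over
`stats::p.adjust`). The FDR procedure was an open choice; BH step-up is
the community default for expression screens of this era and scale.

**Per-stage calls.** No printed rule exists for assigning a
screen-positive feature to particular stages. The default here is the
global gate *plus* a Welch two-sample contrast (stage vs reference,
`p < 0.05`), with direction given by the sign of the stage-mean
difference; an absolute log2-fold-change rule
(`stage_rule = "foldchange"`) is available as the alternative. The
Welch contrast was preferred because it respects the unequal group
sizes (6 vs 4) and needs no fold-change threshold on an arbitrary
intensity scale.

## Stage-trend patterns

Trajectories of stage means are reduced to a trend vector — the sign of
each successive stage difference, with differences of magnitude at most
`eps` (default 0.25 log2 units, roughly the noise floor of stage means
at n = 4) treated as flat. Six patterns are assigned, with the
metastasis-spike pattern taking precedence:

| id | shape | rule |
|----|-------|------|
| 6 | metastasis spike | primary transitions flat, last jump ≥ `delta` (default 1.0 log2) |
| 1 | gradual decrease | non-increasing, still falling at the last transition |
| 2 | early decrease, plateau | non-increasing, flat tail |
| 3 | down-then-up | first sign −, a later + |
| 4 | up-then-down | first sign +, a later − |
| 5 | gradual increase | non-decreasing, at least one rise |

Only patterns 1, 5 and 6 have verbal definitions in the source study;
2–4 are described there only graphically. The table above is this
package's completion of the taxonomy, and `mode = "basic"` disables it,
keeping the broad monotone definitions of 1 and 5 (any non-increasing /
non-decreasing non-flat trajectory) and leaving everything else
unclassified. In the full mode, pattern 1 additionally requires the
final transition to be negative so that 1 and 2 partition the
non-increasing trajectories instead of overlapping. Pattern assignment
is invariant to adding a constant, and patterns 1 and 5 are mutually
exclusive for any non-flat trajectory.

Clustering uses the classic expression metric, `1 − Pearson r`, with
average linkage (`stats::hclust`; complete linkage available). For
*sample* dendrograms each feature is z-scored across samples first —
otherwise between-sample correlations are dominated by the spread of
feature baseline intensities rather than by relative changes. On the
packaged benchmark, cutting the sample tree at five recovers largely
stage-pure subgroups (≥ 80% purity in the test suite).

## Target integration

The data-reduction strategy is three nested restrictions of a predicted
target-pair set, and their order does not matter:

1. `filter_tissue_specific()` — keep pairs whose gene is on the
   tissue-specific list;
2. `coordinate_pairs()` — keep pairs whose miRNA and mRNA differential
   directions are strictly inverse (miRNA up ⇒ target down, and vice
   versa). "Consistent" is read strictly as inverse direction, which
   matches every printed row of the packaged coordinate table;
3. `correlation_filter()` — optional, only when paired matrices share
   ≥ 3 samples: keep pairs with Pearson `r ≤ r_max` (default 0, i.e.
   any anti-correlation), recording `r` on the pair.

The packaged coordinate table assigns a handful of genes opposite
directions in its two halves (e.g. NOTCH2 appears as a down-regulated
target of up-regulated miRNAs *and* as an up-regulated target of a
down-regulated miRNA), so reproducing it exactly requires overlaying
the up-miRNA and down-miRNA halves separately — the test suite does
exactly that.

## Enrichment

`hypergeometric_enrichment()` computes the upper-tail hypergeometric
probability `P(X ≥ count)` per term, with the background defaulting to
the union of all term genes. The EASE variant (`method = "ease"`)
computes the tail at `count − 1` — the conservative jackknifed score of
the DAVID server, offered because the original analysis used that
server without printing a formula. Both BH and Bonferroni corrections
are exposed for the FDR column for the same reason. Terms with fewer
than `min_count = 2` hits are not reported. The reported percent is
`100·count/|list|`, matching the printed tables' convention. The
printed enrichment p-values themselves are *not* reproduction targets:
they depend on a 2011-vintage annotation database.

## Regulatory networks and feedback loops

The miRNA–target network is bipartite with typed, directed edges; hubs
are nodes with degree ≥ 10. The threshold is inclusive (≥) rather than
strict (>) because the table caption defining the published TF lists
uses "degree ≥ 10"; `strict = TRUE` gives the other reading.

Promoter scanning takes the upstream sequences as caller input (the
synthetic generator uses 1000 bp windows; the original window is not
recoverable) and matches IUPAC consensus motifs with a per-window
mismatch budget, on both strands. Matching is delegated to
`Biostrings::matchPattern` with degeneracy expanded on the motif side
only; windows overhanging the sequence ends are discarded so the
semantics equal a naive full-window sliding scan, and the test suite
holds the implementation to exactly that oracle. Minus-strand hits are
reported at the position of the window on the forward sequence, which
makes scanning reverse-complement symmetric. Position-weight-matrix
scoring is deliberately out of scope: the consensus-plus-mismatch model
is the recoverable core of the original alignment-based screen.

A feedback loop is a pair (TF, miRNA) with a `tf_binds_mirna` edge and
the reciprocal `(miRNA, TF)` in the target set — the TF predicted to
repress its own translation through a miRNA it induces. Loop mining is
a set intersection and is tested against the brute-force double loop.
When TF and miRNA expression are available, TF→miRNA edges carry the
Pearson correlation of the two profiles as their "regulatory ability";
no significance test is attached to these weights, as none was defined
for them originally.

## qPCR quantification

`delta_delta_ct()` uses the Livak convention `fold = 2^(−ΔΔCt)`;
positive ΔΔCt means down-regulation. The original text writes the
exponent without the sign, but its reported up/down directions are only
consistent with the negated form; `negate = FALSE` gives the literal
reading. Replicates are summarized by the arithmetic mean of ΔΔCt —
equivalently the geometric mean of folds — with spread reported as the
SD of replicate log2 folds. Standard-curve efficiency is
`E = 10^(−1/slope) − 1`, so 100% efficiency corresponds to a slope of
`−1/log10 2 ≈ −3.32`; the efficiency/slope pair round-trips to 1e-9
over the realistic range E ∈ (0.5, 1.2).

## The synthetic generator

`generate_staged_expression()` draws data under exactly the assumptions
the screen makes: inverse-gamma feature variances, Gaussian log2-scale
noise, equal stage means for nulls, pattern trajectories for planted
features. Defaults are the study's conditions: 766 features, 48
planted, arms of 6/4/4/4/4. The variance prior defaults to
`a = 2, b = 1.5` — mid-range of published random-variance fits to
microarray data. The planted effect span defaults to 3.5 log2 units
(~11-fold): stage-wise array changes of this magnitude are what
validates cleanly by qPCR, and a design-stage power simulation showed
it yields ≥ 90% recovery of planted features at `p, q < 0.05` robustly
across seeds at these arm sizes (mean ≈ 0.97), whereas spans of 2 log2
units leave the screen underpowered (≈ 0.79) at n = 4 per arm. Problem
sizes throughout the test suite (hundreds to a few thousand features,
50-seed property loops) were chosen so the full suite runs in seconds.

`generate_regulome()` plants anti-correlated miRNA–target pairs by
mirroring the (centered) miRNA profile into the gene profile plus noise
at 0.75 of the profile SD, giving a generative Pearson r of about
−0.8; planted promoter motifs are written verbatim into otherwise
i.i.d.-uniform ACGT sequence, and each planted loop adds the TF's gene
to its miRNA's target set. Because background genes never use TF names,
the loop count recovered downstream equals the planted count exactly.
`generate_ct_table()` inverts the comparative-Ct model with Gaussian
cycle noise, so noiseless tables recover the true folds exactly.

What the generator does **not** emulate: probe-level chemistry, batch
and array effects, correlated features, heavy-tailed noise (a flag
exists for none of these; log2-Gaussian is the standard array
assumption), EBV-encoded miRNAs, or the real genomic promoter
landscape. Passing recovery benchmarks therefore demonstrates the
pipeline's correctness under its own model, not performance on raw
array data — reproducing the study's actual 48-miRNA list would
require its unreleased raw intensities and is explicitly not a goal.

## Identifier conventions and degenerate inputs

Identifiers are matched as exact strings everywhere: star species
(`hsa-miR-34b*`), arm suffixes (`-3p`/`-5p`) and even the anomalous
printed token `hsa-miR-17-5p:9.1` are preserved verbatim in the
packaged fixtures, with no alias resolution or miRBase version
remapping. One stage-label normalization is applied: the metastasis
rows of the printed tables are keyed `MET`. Sequence coordinates are
0-based half-open; motif hit positions are 0-based offsets. Degenerate
inputs fail loudly and early: duplicate feature/sample ids, non-numeric
expression cells (with row/column address), malformed GMT lines (with
line number), invalid IUPAC codes (naming the character), slopes ≥ 0,
Ct values outside (0, 50), designs with singleton stages.

## Known limitations

* The exact published miRNA list, enrichment p-values and TF tables are
  database- and raw-data-bound; this package reproduces their *logic*
  and their printed tables, not their provenance.
* The RVM prior fit assumes a common residual degrees-of-freedom `df`
  across features; designs with per-feature missingness get their
  incomplete features dropped rather than refitted at reduced df.
* Pattern classification is sensitive to `eps` when stage means sit
  near the flatness tolerance; on noisy benchmark data roughly a third
  of correctly screened features land in a neighbouring pattern (mostly
  1 vs 2), which is inherent to sign-based trend coding at n = 4.
* Motif scanning has no notion of binding affinity or conservation;
  with short or highly degenerate motifs, hit lists on kilobase windows
  are expectedly dense.
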