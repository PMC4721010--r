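---
title: "Models and methods behind encore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind encore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`encore` analyses a two-group expression study in three stages:
per-gene differential expression, per-set enrichment by several set-based
and network-based methods, and rank combination across methods. This
vignette describes the statistical model of each stage, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic benchmark generator does and does not emulate.

## Data model and assumptions

The expression matrix is genes × samples: log2 intensities for
`data_type = "microarray"`, non-negative integer counts for
`data_type = "rnaseq"`. The sample classification is binary (0 = control,
1 = case), optionally with a block column for 1:1 paired designs. Gene
identifiers are opaque, case-sensitive strings; no identifier mapping is
attempted beyond the optional probe-to-gene summarization step. Missing
values are rejected at parse time rather than imputed, because none of the
downstream statistics define a principled NA treatment. The groups file is
the authority on sample order: results are invariant to the column order
of the matrix file by construction.

Gene sets may contain genes absent from the data; they are kept at parse
time and filtered to measured genes at analysis time, so the same GMT file
can serve multiple datasets. At analysis time a set-size window (default
5–500 measured genes, configurable per call) removes sets too small for a
stable statistic or too broad to be interpretable; a message reports when
the window bites.

## Differential expression

Per gene the log2 fold change is the case-minus-control mean difference,
the test statistic an ordinary pooled-variance two-sample t (df
`n0 + n1 − 2`), or a one-sample t on within-block differences in the
paired design. RNA-seq counts are first transformed to
`log2(CPM + 0.5)`; the pseudo-count of 0.5 keeps zero counts finite and is
the conventional magnitude for library sizes in the millions. An
empirical-Bayes moderated variance is a possible extension; the ordinary t
was chosen because everything downstream consumes the statistic
generically, and a plain t keeps the permutation null exact rather than
approximately exchangeable.

Zero pooled variance is a real degenerate case in simulated and truncated
data. The convention: equal means give `stat = 0, p = 1`; unequal means
give `stat = ±Inf` with the smallest representable positive p-value, and a
warning. P-values are two-sided from the t distribution. Adjustment
defaults to Benjamini–Hochberg; Bonferroni, Holm, Benjamini–Yekutieli and
`none` are available through `adjust_pvalues()`. BH is the default because
the per-gene report feeds ORA's significant-gene count, where family-wise
control would be needlessly conservative at genome scale.

Probe summarization (`summarize_probes()`) offers the two standard
policies: per-sample mean over a gene's probes, or keeping verbatim the
probe with the largest |t| between the groups ("most discriminating").

## The permutation engine

SAFE-style, GSEA and SAMGS-type statistics share one engine
(`safe_run()`): per-gene local statistics `|t|` are recomputed for the
observed labels and for each of `B` sample-label permutations — within
blocks (sign flips of paired differences) when `paired = TRUE`. Gene rows
are ordered stably by gene id before ranking so that input order never
changes a result.

Random-permutation p-values are `(b + 1)/(B + 1)`, where `b` counts
permuted global statistics at least as large as the observed one; this
estimator is strictly positive, which matters because permutation
p-values of exactly zero misstate the evidence and break p-value-based
ranking. With `exhaustive = TRUE` the engine enumerates all
`choose(n, n1)` distinct relabelings (all `2^blocks` sign patterns when
paired) and reports the exact count `b/B`, the observed labeling being
part of the enumeration. When `n_perm` exceeds the number of distinct
relabelings the engine warns and allows duplicates rather than silently
switching modes. Default `n_perm = 1000` balances p-value granularity
(1/1001) against runtime.

Global statistics, all one-sided towards "members have larger local
statistics" (the natural alternative for |t|):

- **wilcoxon** (method `safe`): rank-sum of member statistics among all
  genes, mid-ranks for ties.
- **ks** (method `gsea`): the running-sum enrichment score. Hits
  increment by `|t|^q` normalized over members, misses decrement by
  `1/(N − N_hit)`; the score is the signed maximum deviation from zero,
  ties between the positive and negative extreme resolving to the
  positive one (a measure-zero event on continuous data, fixed for
  determinism). `q = 1` is the default weighted form in wide use; `q = 0`
  is the classic Kolmogorov–Smirnov statistic and is exposed by flag.
- **sum_sq** (method `samgs`): the sum of squared member statistics.
  This is the diagonal-covariance reduction of Hotelling's T²; the full
  multivariate form needs a stable covariance estimate that 5–10 samples
  per group cannot provide, so it is deliberately out of scope.

ORA needs no permutation: with universe `N` (measured genes in the DE
result), `K` significant genes (adjusted p < α by default; a flag
switches to raw p), `n` measured members and `k` significant members, the
p-value is the upper hypergeometric tail. α defaults to 0.05. With zero
significant genes all sets get p = 1 and a warning — an informative
outcome, not an error.

## Network-based scoring

A regulatory network is a list of signed directed edges
(activation/inhibition). Each edge's consistency with the observed
expression changes is `tanh(lfc_reg) · tanh(lfc_tgt)`, negated for
inhibition. The tanh squashing gives saturation (a 5-unit and a 10-unit
shift are equally "maximal") and the product gives sign agreement:
consistency is +1 exactly when both genes are strongly de-regulated the
way the edge predicts, −1 when maximally contradicted, 0 when either gene
is unchanged. This functional form is this package's own reconstruction
of consistency scoring from its stated semantics — sign agreement with
the interaction type plus saturation — not a port of any published
implementation.

A set's raw score sums consistencies over its *induced* edges — by
default every measured edge with at least one endpoint in the set
(`edges = "adjacent"`), so regulators outside the set still contribute
mechanism; `edges = "within"` restricts to both endpoints. The normalized
score divides by the edge count and lies in [−1, 1]. Significance comes
from the shared permutation engine applied to the raw score, with fold
changes recomputed per relabeling. Both scores are reported and the
p-value is computed on the raw score, which preserves the size signal
that normalization removes. Sets with no induced edges get score 0,
p = 1, and a flag column rather than being dropped: absence of network
evidence is information.

One numerical consequence worth knowing: the raw score is invariant under
swapping the two group labels wholesale (tanh is odd, so both factors of
every product flip sign), so the smallest attainable permutation p-value
is governed by how often the complement labeling is drawn, not by
`1/(B + 1)`.

External enrichment methods join through the plug-in contract: a function
`(data, gene_sets, alpha, network)` returning one p-value per set, in
collection order. The wrapper validates length and range and builds a
ranking with `score = −p`, so combination and reporting treat plug-ins
exactly like native methods. The names `spia`, `nea` and `pathnet` are
reserved for the corresponding published methods.

## Rank combination

Each method's ranking is reduced to per-set ranks of a chosen statistic
(p-value ascending by default, score descending as the alternative):

- *absolute*: dense ranks 1..`N_D` over distinct values (`N_D` = number
  of distinct values), tied sets sharing a rank;
- *relative*: `absolute/N_D · 100`;
- *competitive*: the percentage of sets whose statistic is at least as
  extreme, inclusive of the set itself.

Competitive ranks are the default because permutation p-values tie
heavily: a method returning the same p for 80 % of sets yields absolute
ranks that look deceptively good. Inclusive counting keeps every
competitive rank strictly positive (a t-way tie at the top ranks
`100·t/N_GS`), consistent with the never-zero convention of the
permutation p-values; exclusive counting would rank a unique top set 0 %.
Competitive ranks are invariant under strictly monotone transforms of the
statistic, so they compare coarse and fine-grained methods on one scale.

Ranks are computed per method on that method's full ranking *before* any
support restriction, then aggregated by sum (default), mean, median, min,
or a user-supplied function. Default support is the intersection of the
rankings; under union support a set missing from a method is penalized
with that method's worst rank (100 for relative/competitive, `N_D` for
absolute) — a deliberate artifact convention, reported via message. The
final order is ascending in the combined value, ties broken by the best
single-method rank and then lexicographic set id (another artifact
convention chosen for determinism).

## Synthetic benchmark generator

`simulate_study()` draws background genes i.i.d. Normal(baseline, σ²) in
both groups (microarray path) or negative binomial with dispersion 0.1
and a log-linear group effect (rnaseq path), spikes the genes of one or
more sets by ±δ in cases (per-gene direction recorded in the truth
table), assembles disjoint gene sets over a shuffled gene space, and
draws a within-set regulatory network (a chain plus random extra pairs,
24 edges per 25-gene set by default) whose edge signs match the simulated
directions at rate ρ for spiked sets and are random for background sets.

Defaults — 2000 genes, 6+6 samples, 20 sets of 25, one spiked set, δ = 2,
σ = 1, ρ = 1 — are the package's benchmark condition: an effect of two
noise SDs with six samples per group sits at the edge where genome-wide
per-gene significance is rare but set-level signal is strong, which is
exactly the regime enrichment analysis exists for. These sizes also keep
the full five-method benchmark (B = 1000 permutations) under ten seconds,
which is why the test suite and the acceptance script use them as stated
problem sizes.

What the generator does *not* emulate: gene–gene correlation within and
across sets, overlap and crosstalk between sets, batch effects, library
size variation, and realistic network topology. Passing benchmarks on
these fixtures therefore demonstrate correctness of the statistical
machinery and sensible relative behavior of the methods — not performance
on real tissue data, where set overlap and correlation structure can
change both calibration and power.

## Reporting

The HTML report is deliberately static and deterministic: no timestamps,
fixed number formatting, hand-assembled SVG for the volcano plot, p-value
histogram and expression heatmaps (average-linkage hierarchical ordering
of rows and columns — one standard choice among several, fixed for
reproducibility). Identical inputs re-render byte-identically, which
makes report bundles diffable and cacheable. Interactivity is limited to
client-side column sorting; every table is also written as TSV next to
its page.

## Known limitations

- The moderated-variance t and count-model local statistics (voom/edgeR/
  DESeq2 style) are not implemented; the log-CPM + pooled-t path is a
  documented simplification.
- Paired designs beyond perfect 1:1 blocks are rejected.
- GSEA-style normalized enrichment scores and gene-permutation nulls are
  not provided; significance is always by sample permutation.
- The GGEA-style consistency is a reconstruction (see above), and its
  p-values inherit the complement-invariance granularity limit.
- Union-support penalties and final tie-breaks are artifact conventions;
  they are stated here and in the function documentation rather than
  derived from any published rule.
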