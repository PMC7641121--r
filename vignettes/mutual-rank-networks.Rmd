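---
title: "Mutual-rank co-expression networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-rank co-expression networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gene co-expression networks are a standard instrument for annotating
genes in organisms without a reference genome: genes whose expression
profiles track each other across tissues tend to act in the same process,
so an unannotated gene inherits hypotheses from its network neighbors.
`coexmr` implements this workflow for multi-tissue FPKM expression
matrices — the typical product of a de novo transcriptome study with a
handful of tissues and a few biological replicates each.

# The model

## Correlation and mutual rank

For genes $x$ and $y$ with FPKM values $x_i, y_i$ over $n$ samples, the
similarity measure is Pearson's correlation coefficient,

$$
r_{xy} = \frac{\sum_{i=1}^n (x_i - \bar x)(y_i - \bar y)}
  {\sqrt{\sum_{i=1}^n (x_i - \bar x)^2 \sum_{i=1}^n (y_i - \bar y)^2}.}
$$

Raw correlations are a poor edge criterion on their own: a promiscuous
gene can be moderately correlated with thousands of partners.  The
mutual rank corrects for this by asking how each gene ranks *in the
other's* partner list.  With $\mathrm{rank}(A \to B)$ the 1-based
position of $B$ when $A$'s partners are sorted by decreasing $|r|$,

$$
\mathrm{MR}(A,B) = \sqrt{\mathrm{rank}(A \to B)\,\mathrm{rank}(B \to A)}.
$$

MR is symmetric, at least 1, and small only when the attraction is
mutual.

## Edge selection

An unordered pair becomes an edge when
$|r| \ge \texttt{pcc\_cutoff}$ **and** it is admitted by one of two MR
routes: $\mathrm{MR} \le \texttt{mr\_cutoff}$, or one endpoint is among
the other's `top_k` partners by MR.  Defaults are `pcc_cutoff = 0.7`,
`mr_cutoff = 30`, `top_k = 3` — the strict "MR top 3 + MR ≤ 30" regime.
Edges carry their sign: positive when $r > 0$, negative when $r < 0$,
and per-sign subnetworks are available via `positive_network()` /
`negative_network()`.

Three points here were genuinely open and are resolved as follows:

* **Ranking uses $|r|$, not signed $r$.**  Ranking by signed correlation
  would push every anti-correlated pair to the bottom of the partner
  lists and make a negative subnetwork built on MR thresholds
  unreachable.  Since the method's output explicitly includes a negative
  network, partner lists are ordered by $|r|$ and the PCC cutoff is
  applied to $|r|$ as well.
* **"top 3 + MR ≤ 30" is a union of admission routes**, not an
  intersection: the top-k route guarantees each well-correlated gene a
  minimum of connectivity even when its MR exceeds the global bound,
  which is what keeps node coverage high on real transcriptomes.  The
  PCC cutoff remains a conjunct over everything.
* **Correlation runs over all replicate samples by default** (tissue
  medians are available via `use_tissue_medians = TRUE`), and on raw
  FPKM (a `log_transform` option applies $\log_2(\mathrm{FPKM}+1)$, off
  by default).

Tie-breaks in ranking (exactly equal $|r|$, which happens with
zero-noise synthetic data) are resolved by ascending gene id, making
ranks, MRs and networks fully reproducible.

## Expression calling and filtering

Replicates are summarized per tissue by the **median** (the midpoint of
the two central values for even counts), and a gene is called expressed
in a tissue when its median FPKM exceeds **0.3, strictly** — a median of
exactly 0.3 is not expressed.  Genes expressed in fewer than
`min_expressed_tissues` tissues (default 1) are excluded from the
network entirely, as are zero-variance genes, whose correlations are
undefined (the package reports them as flagged exclusions, never as
silent zeros).  Whether the 0.3 call should apply to tissue medians or
to individual samples is ambiguous in practice; this package applies it
to medians and exposes a per-sample variant (`call_expressed()`).

## Neighborhood queries and overlays

`neighborhood()` extracts the subnetwork around query genes bounded by
an MR ceiling (common choices: 30 or 50).  Induced edges *among*
neighbors are included — displayed co-expression neighborhoods show
inter-neighbor links, not just spokes — and the query's MR bound is
applied uniformly to those induced edges.  Overlays annotate nodes
without touching topology: `overlay_tissue()` marks each node
expressed/not-expressed in one tissue, and `overlay_deg()` attaches
up/down/ns classes from a differential-expression table
(`padj < 0.05` and `|log2FC| > 1` by default, strict inequalities, with
the stricter `|log2FC| > 2` variant available; genes absent from the
table are `ns`).  Fitting the differential model itself is out of scope:
DEG tables are consumed, not computed.

## Enrichment

Gene-set enrichment of a query list is the one-sided Fisher exact
(hypergeometric upper-tail) test.  With universe size $N$, query size
$n$, set size $K$ and overlap $k$, the point probability is

$$
P(k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},
$$

computed in log space so transcriptome-scale binomials do not overflow,
and significance is the tail $\sum_{k' \ge k} P(k')$ — a point
probability alone is not a significance level, so the tail is what
`gsea()` reports, with the pmf exposed separately.  FDR control is
Benjamini–Hochberg, applied within each annotation category when the
collection carries category labels (GO and pathway FDRs are
conventionally reported separately), across all tested sets otherwise.
The universe defaults to the collection's stated gene universe — for
network queries, the network's genes — and is configurable, since the
appropriate $N$ (all genes vs annotated genes) is a study-level choice.

# The synthetic-data generator

`simulate_expression()` emulates the study design the package targets:
**10 tissues × 3 biological replicates** of non-negative FPKM values,
with planted structure so that every downstream stage has ground truth:

* Each of the `n_modules` (default 20) planted modules gets a latent
  per-tissue activity vector drawn uniformly on $[0.05, 1]$; a member
  gene's tissue mean is `expression_scale` (default 50 FPKM) times the
  latent value.  A `frac_negative` fraction of members uses the profile
  reflected about its maximum, which gives correlation exactly $-1$ at
  zero noise — an analytic anchor for sign tests.
* Replicate noise is multiplicative log-normal: tissue mean times
  $2^\varepsilon$, $\varepsilon \sim N(0, \texttt{noise\_sd})$ (default
  0.2 on the log2 scale).  This mimics RNA-seq abundance dispersion
  while keeping values non-negative without clipping.
* Background genes (default 100) follow independent latent vectors;
  silent genes (default 50) are uniform on $[0, 0.3]$ per sample, so
  they are never called expressed at the 0.3 floor.
* Module archetypes are drawn by rejection so that no two archetypes
  correlate beyond $|r| = 0.45$.  Planted modules are meant to be
  *identifiable* ground truth; without a separation bound, two "distinct"
  modules can be nearly collinear by chance in a 10-dimensional tissue
  space, and noise fluctuation then pushes cross-module gene pairs over
  the 0.7 edge cutoff, merging modules that the truth labels as
  different.  The bound is kept well below the edge cutoff to leave
  margin for that fluctuation.  The draw restarts when a candidate
  cannot be placed, and fails loudly for infeasible requests (many
  modules over very few tissues).
* `frac_negative` defaults to 0: the package's recovery guarantee is
  that connected components of the **positive** network reproduce
  planted membership, which is only coherent when a planted module is a
  positively coherent program.  Anti-correlated members are opt-in for
  studying signed networks, where they split each planted module into a
  majority and a reflected minority by construction.
* Planted DEGs (default 50 genes) get true $|log2FC| \in [1.5, 4]$ and
  simulated adjusted p below 0.01; all other non-silent genes get
  $|log2FC| < 0.5$ and adjusted p above 0.05, so the standard
  classification rule recovers exactly the planted set.
* Every operation draws from its own RNG stream keyed by (seed,
  operation name), so adding an operation never perturbs fixtures
  generated by another.

What the generator does **not** emulate: count-level sampling noise and
its mean–variance relationship, library-size and length biases baked
into FPKM, correlated replicate batch effects, partially overlapping or
hierarchically nested modules, and annotation noise in gene sets.
Passing tests therefore demonstrate algorithmic correctness on data
with planted truth, not robustness to every artifact of real RNA-seq.

# Numerical choices and degenerate inputs

* Undefined correlations (zero variance) are `NA` with an explicit
  flag/reason, never coerced to 0.
* Exact rank ties → ascending gene id, everywhere (partner lists and
  top-k selection), so outputs are byte-reproducible.
* `hypergeom_pmf`/`fisher_enrichment_p` validate their bounds and
  evaluate in log space with a log-sum-exp reduction; the tail at
  $k = 0$ (or below the support minimum) is exactly 1.
* BH adjustment delegates to the standard step-up implementation in
  base R; the test suite checks it against an independent transcription
  of the definition.
* Empty matrices, unknown query genes, unknown tissues, p-values
  outside $[0,1]$ and malformed TSV/GMT input all raise immediate,
  named errors.

# Problem sizes used by the test suite

The suite exercises oracle equivalence (naive all-pairs reference) at
200 genes; module recovery at the default 650-gene, 30-sample
configuration over five seeds; enrichment recovery over twenty seeds
against 50 decoy sets; and exhaustive enumeration of all
$\binom{20}{6}$ query draws for the enrichment tail.  These sizes were
chosen as the smallest at which the checked properties are
non-trivial while keeping the default test run fast.

# Known limitations

* All-pairs correlation and ranking are dense $O(G^2)$ in genes; the
  implementation targets the tens-of-thousands scale at most, not
  approximate nearest-neighbor shortcuts.
* Scale-free behaviour is assessed by a least-squares log–log fit of
  the degree histogram — the conventional quick check, not a rigorous
  power-law test.  On small synthetic networks with a few planted
  clique-like modules the degree histogram is dominated by the module
  size and the fitted slope can be positive; the negative-slope decay
  expected of transcriptome-scale networks only emerges with many
  modules of varying size.
* The positive/negative split assigns sign by the PCC sign of each
  edge; genes can participate in both subnetworks.
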