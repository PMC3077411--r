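---
title: "Literature cohesion of gene sets: model, calibration, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature cohesion of gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(litcohesion)
```

# The model

`litcohesion` scores the functional cohesion of a gene set from the
literature alone. The chain is:

gene–citation links → per-gene documents → log-entropy weighted
term-by-gene matrix → truncated SVD (LSI) → gene–gene cosine matrix →
empirically calibrated edge threshold → Fisher's exact test on edge
counts → the literature p-value (LPv).

## Gene documents

A gene's document is the concatenation of the title and abstract of every
citation linked to it. Two corrections are applied before concatenation:

* **Promiscuous citations** — citations linked to *strictly more than*
  `max_genes_per_citation` (default 10) distinct genes are removed
  entirely. These are almost always genome-scale papers (screens, array
  studies) whose link to any single gene carries no functional
  information. The boundary is deliberately strict-greater: a citation
  linked to exactly 10 genes is kept.
* **Ortholog merging** — citation sets of orthologous genes are unioned,
  and every member gene of a group receives the union. The alternative
  (one merged document per group) would discard per-organism genes;
  replicating the shared literature to each member keeps per-gene
  documents while pooling evidence. The promiscuity filter runs *before*
  merging, so merging can never push a citation over the threshold; the
  opposite order would silently change filter semantics.

Concatenation is in ascending `citation_id` order. Downstream is a
bag-of-words model, so the order is immaterial for results; fixing it
makes outputs byte-stable, which the tests rely on.

Tokenization (lowercase, purely alphabetic tokens, minimum length 3, a
small fixed stop-list, no stemming) is the simplest fully reproducible
rule set; every piece is configurable through `tokenize_rules()`. Nothing
downstream depends on linguistic sophistication here — log-entropy
weighting already suppresses undiscriminative tokens.

## Log-entropy weighting

For counts $f_{ij}$ (term $i$, gene $j$, $n$ genes),

$$w_{ij} = g_i\, l_{ij},\qquad l_{ij} = \log_2(1+f_{ij}),\qquad
  g_i = 1 + \frac{\sum_j p_{ij} \log_2 p_{ij}}{\log_2 n},\qquad
  p_{ij} = \frac{f_{ij}}{\sum_j f_{ij}}.$$

$g_i$ is one minus the normalized entropy of term $i$'s distribution
across gene documents: a term confined to one gene has $g = 1$, a term
spread evenly over all genes has $g = 0$ and is effectively deleted. The
logarithm base cancels in $g$ and rescales $l$ uniformly, so cosines are
base-invariant; base 2 is used throughout. Two numerical choices:

* $0 \log 0 := 0$ (by summing over nonzero entries only);
* a computed $g$ within $10^{-12}$ of 0 is snapped to exactly 0, so the
  invariant "$w_{ij} = 0$ iff $f_{ij} = 0$ or $g_i = 0$" holds exactly
  for analytically-uniform terms instead of up to float noise.

A single-gene matrix is rejected ($g$ is undefined for $n = 1$).

## LSI and cosines

The weighted matrix is factorized with a dense SVD and truncated to rank
$k$ (default 300, following common practice for large document
collections; capped at the matrix rank so small corpora degrade
gracefully — an *explicit* $k$ beyond the rank is an error). The gene
vector is the gene-side factor row scaled by the singular values
($V_k S_k$), the standard LSI document representation; `fit_lsi(...,
scale_gene_vectors = FALSE)` gives unscaled $V_k$. At full rank the
cosine of two gene vectors equals the cosine of the corresponding raw
weighted columns — this equivalence is tested to $10^{-8}$ and is the
main guard against factorization bugs.

Zero gene vectors (possible when $k$ is small or a gene's terms all have
$g = 0$) get cosine 0 with a warning: such genes simply contribute no
edges rather than poisoning the matrix with NaN.

## Threshold calibration

`calibrate_threshold()` draws `n_sets` random gene sets with sizes
uniform over an inclusive range (defaults 1000 sets of 50–400 genes,
mirroring the scale of the original procedure), pools all within-set
pairwise cosines, and returns the **nearest-rank** percentile (default
95): the pooled score at ascending rank $\lceil p/100 \cdot M \rceil$.
Nearest-rank (rather than an interpolated quantile) was chosen because it
is unambiguous, returns an observed score, and is trivially
oracle-checkable. By construction the fraction of pooled scores strictly
above the threshold can never exceed $(100-p)\%$; ties can only push it
lower. The result records the seed, the pooled count $M$, the
above-threshold count $K$, and per-set above-threshold fractions as a
diagnostic (in a real collection these hover just above 5 %).

## The LPv

For a resolved gene set of $n$ genes ($m = n(n-1)/2$ pairs, $k$ strictly
above threshold — strict inequality matches the "edges are cosines
> threshold" convention), the LPv is the one-sided (enrichment) Fisher's
exact p-value of the table $[[k, m-k], [K, M-K]]$, i.e. the
hypergeometric tail $P(X \ge k)$ with population $m+M$, successes $m$,
draws $k+K$. Design choices:

* **Background row = actual calibration counts** $(K, M)$, not an
  idealized 5 % proportion: Fisher's test needs integer counts and the
  calibration already measured them. A fixed-proportion background
  (`background_proportion` with `background_total`) is available when a
  threshold is supplied without calibration.
* **One-sided**: cohesion is directional — only an *excess* of edges is
  evidence of functional relatedness. A two-sided variant is available
  via `alternative = "two.sided"`.
* Duplicate inputs are collapsed and unknown/unmodeled identifiers
  dropped before pair counting, with full bookkeeping (`n_input` vs
  `n_with_abstracts`, per-identifier status report).
* A fingerprint stored in both model and calibration artifacts makes
  mixing artifacts from different runs a hard error.

# The synthetic world

`generate_corpus()` produces corpora whose *statistical shape* matches a
real mammalian gene-document collection, with known ground truth:

* **Abstracts per gene**: a discretized lognormal truncated at
  `abstracts_min` (default 1). The defaults (`meanlog = log 3`,
  `sdlog = 1.1`) give median ≈ 3, ~25 % single-abstract genes, and a long
  right tail — the documented shape of real collections (median 3–5,
  thousands of single-abstract genes, maxima in the thousands).
* **Topics**: genes are assigned round-robin to `n_topics` disjoint topic
  vocabularies; each abstract draws `background_mix` (default 0.3) of its
  words from a shared background vocabulary and the rest from its topic.
* **Co-citation** (`cocitation_rate`, default 0.3): a paper describing a
  gene also cites up to `cocitation_max` same-topic genes, which *spend
  one of their own abstract slots* on the shared citation — so the
  abstracts-per-gene marginal is preserved exactly. Co-citation is
  essential realism: in real link data most sparsely-studied genes share
  their few papers with other genes (two genes with identical citation
  sets have cosine 1.0), which is why low-count genes have *high* top
  neighbors in real collections.
* **Well-studied genes** (`wellstudied_fraction`): their abstract counts
  are multiplied by `wellstudied_boost` and each abstract's topic is
  drawn from the gene's own random subset of `wellstudied_topics` topics.
  Early experiments drew each abstract's topic uniformly from *all*
  topics; that makes every well-studied document converge to the same
  global topic mixture, so well-studied genes form a tight mutual cluster
  and their top-neighbor cosines come out *high* — the opposite of the
  real phenomenon, where well-studied genes span *different* pathway
  subsets. Per-gene subsets restore the real direction.
* **Promiscuous citations**: a configurable number of extra citations
  linked to more than ten genes each, with background-only text —
  exactly what the promiscuity filter is meant to remove.
* One master seed expands into per-stage substreams, so adding a
  generator stage never perturbs earlier draws, and identical specs give
  byte-identical corpora.

What the generator deliberately does **not** emulate: real English text,
MeSH/term correlation structure, citation dates, organism specifics. A
green test on synthetic data establishes that the *pipeline and statistic
behave as designed under a known topic model* — not that any particular
biological collection will yield a particular LPv.

# Acceptance worlds and their rationale

The acceptance tests fix specific synthetic worlds; the parameters encode
deliberate scaling arguments, not tuning:

* **Type-I error** runs on an *exchangeable* null: topic-free, uniform
  5 abstracts per gene, a sparse 3000-word vocabulary, no co-citation.
  The Fisher null is "every pair has the same edge probability"; this
  world satisfies it, and the measured false-positive rate is nominal.
  Under heterogeneous abstract counts the method is **anti-conservative**
  (measured 0.13–0.25 at nominal 0.05): genes with long documents become
  similarity hubs, overdispersing pair counts relative to the
  hypergeometric. This is a genuine property of the method — the same
  mechanism as the documented well-studied-gene bias — and users should
  treat LPv's near the significance boundary with caution when a set
  contains disproportionately well-studied genes.
* **Power** runs at topic purity 0.8, ≥ 5 abstracts per gene, on 300
  genes over 15 topics with cohesive sets of 15. The geometry matters: a
  real collection has tens of thousands of genes over (effectively)
  thousands of themes, so random sets contain almost no same-topic pairs.
  Desk-scale worlds with few coarse topics break that geometry — random
  sets then carry highly variable numbers of same-topic pairs, inflating
  null-set rejections — so the world uses the finest topic structure that
  still leaves room for size-15 within-topic sets.
* **The well-studied diagnostic** (negative rank correlation between a
  gene's abstract count and its mean top-10 neighbor cosine) uses long
  abstracts (150 words) and a modest count spread among normal genes.
  With very short documents the *opposite* correlation dominates: a
  single 40-word abstract is a noisy sample of its topic vocabulary, so
  low-count genes land far from everyone, including their own topic — a
  small-sample artifact of the generator, not the phenomenon of
  interest. The well-studied-vs-normal gap itself (≈ 0.64 vs 0.86 mean
  top-10 cosine) is robust across all worlds examined.

# Numerical and degenerate-input policy

* Fisher tails are computed by `phyper` (verified against direct
  `lchoose` pmf summation over the full grid $m \le 40$, $M \le 400$ at
  $10^{-12}$ relative, and against exact rational enumeration for frozen
  representative tables); $k = 0$ returns exactly 1.
* `fit_lsi` requires $1 \le k \le \min(\text{terms}, \text{genes})$;
  cosines are clamped to $[-1, 1]$; the similarity matrix is symmetrized
  ($S \leftarrow (S + S^\top)/2$) to kill asymmetric rounding.
* Fewer than two resolved genes is an error carrying the full resolution
  report; empty link collections, empty token bags, and dangling
  citations follow a skip-and-report policy rather than failing.
* Sparse and dense weighting paths produce identical results (the
  weighting worker converts through one sparse route regardless of input
  class).

# Known limitations

* LPv treats gene pairs as exchangeable draws; any gene-level
  heterogeneity in edge propensity (well-studied genes, hub vocabulary)
  makes the test anti-conservative. Interpret borderline LPv's
  accordingly; the annotation table's abstract counts are provided
  precisely so users can see when a set is dominated by well-studied
  genes.
* No multiple-testing correction is applied across gene sets.
* The default rank of 300 is a convention from large document
  collections; for small corpora the rank cap makes the model exact
  rather than reduced, which is the right behavior for testing but means
  "LSI smoothing" effects only appear at realistic scale.
* The 0.6-style threshold is corpus-specific: it must be recalibrated
  for every model artifact, which is why calibration results embed a
  model fingerprint and the CLI refuses mismatched artifacts.
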