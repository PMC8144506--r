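---
title: "Inferring lncRNA-driven miRNA-sponge networks: models and choices"
author: "spongenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-driven miRNA-sponge networks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Competing endogenous RNAs (ceRNAs) de-repress each other by sequestering a
shared pool of miRNAs: a long non-coding RNA that binds the same miRNAs as
an mRNA acts as a sponge, and the two transcripts co-vary positively even
though neither regulates the other directly. spongenet reconstructs such
lncRNA-driven sponge networks from two ingredients that are routinely
available for a patient-tissue cohort: a gene x sample expression matrix
(long-RNA sequencing, in which miRNAs are unobserved) and tables of
validated miRNA-target interactions.

The procedure has four stages, each exposed as package functions and
driven end-to-end by `run_pipeline()`:

1. **Expression filtering.** Transcripts whose total count over all
   samples is strictly below `min_total` (default 100) are removed; a
   transcript summing exactly to the threshold is kept. A `log2(x + 1)`
   transform is applied by default; simulated Gaussian-scale input uses
   `transform = none`, under which `min_total = 0` is an exact identity.
2. **Shared-miRNA enrichment.** For a lncRNA targeted by $n$ miRNAs and
   an mRNA targeted by $K$ miRNAs out of a universe of $N$ miRNAs with
   any evidence, the observed overlap $k$ is referred to the
   hypergeometric upper tail
   $P(X \ge k) = \sum_{x=k}^{\min(n,K)} \binom{K}{x}\binom{N-K}{n-x}/\binom{N}{n}$,
   evaluated through the survival function (log-space available) so deep
   tails never round to an exact zero for $k < n$. p-values are
   Benjamini-Hochberg adjusted across all enumerated pairs and pairs with
   $q < 0.05$ become candidates.
3. **Causal-effect estimation.** A CPDAG over the union of candidate
   genes is learned with PC-stable (Fisher-z Gaussian conditional
   independence tests), then local IDA collects, for each pair, the
   multiset of total-effect estimates over all locally valid adjustment
   sets around the lncRNA, summarized by the signed minimum-absolute
   element — the standard IDA lower bound.
4. **Edge calling and hubs.** Each candidate's Pearson correlation $r$ on
   the same transformed matrix is tested with the Fisher z-transform,
   $z = \sqrt{n-3}\,\operatorname{atanh}(r)$ (the corPvalueFisher
   convention); after a joint BH adjustment, pairs with $q < 0.05$ and
   $r > 0$ form the bipartite sponge network. Hub lncRNAs are the top
   20% of lncRNA nodes by degree, $\max(1, \lfloor 0.2 L \rfloor)$ of
   them, ties broken by identifier — with 24 lncRNA nodes this yields 4.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_total` | 100 | row-sum floor (counts) for the expression filter |
| `transform` | `log2p1` | expression transform; `none` for Gaussian-scale input |
| `min_shared` | 1 | smallest shared-miRNA count enumerated |
| `sharing_q_max` | 0.05 | BH cutoff on the hypergeometric test |
| `alpha` | 0.01 | per-test level of the PC conditional-independence tests |
| `max_cond_size` | 3 | largest conditioning set the skeleton search explores |
| `edge_q_max` | 0.05 | BH cutoff on the correlation test |
| `effect_min` | $-\infty$ | causal-effect floor for edges (annotation-only by default) |
| `require_positive_r` | true | ceRNA theory predicts positive correlation |
| `hub_fraction` | 0.2 | fraction of lncRNA nodes reported as hubs |

`alpha = 0.01` with `max_cond_size = 3` keeps skeletons sparse and runs
desk-scale while giving the v-structure phase enough separators to work
with; both are exposed because no single choice suits every cohort size.
The miRNA universe of the enrichment test is pooled over both target
classes: a sponge pair competes for miRNAs regardless of which class a
given interaction was curated against, and both evidence tables are
merged before pair identification.

**Why effects annotate edges instead of gating them.** The IDA summary is
exactly 0 for any pair whose lncRNA-mRNA edge is left undirected in the
CPDAG: one compatible orientation makes the mRNA a cause of the lncRNA,
its adjustment set then contains the mRNA, and the convention scores that
set as a zero effect, which the min-abs summary propagates. Under latent
miRNA confounding at cohort-scale sample sizes, sponge edges are
essentially never orientable, so a positive-effect gate would empty the
network of precisely the pairs the method is designed to find. Edge
membership is therefore decided by the BH-adjusted correlation test, with
`effect_min` available for users who want the stricter behavior.

## The synthetic sponge system

`sponge_system_spec()` describes a linear-Gaussian structural equation
model: exogenous miRNA regulators, coefficients drawn around
`repression_strength` (default $-0.8$, sd $0.1$), unit Gaussian noise,
and 22 samples by default — the sample count of a typical congenital
heart disease cohort. The default sharing plan places lncRNA$_i$-mRNA$_i$
pairs on a diagonal with 0-5 shared regulators (summing to 30, exactly
the default miRNA pool); `plant_sponge_pairs()` replaces the plan with a
small number of strong pairs (8 shared miRNAs each — heavy sharing at
desk scale, mirroring flagship sponge pairs that share dozens of miRNAs
against universes of hundreds). For a pair sharing $s$ miRNAs with equal
coefficients $b$ and unit noise the population correlation is
$s b^2 / (s b^2 + 1)$, which the property tests verify at $n = 2000$.

Three deliberate constructions keep the truth interpretable:

* shared-regulator sets are drawn **without replacement across pairs**,
  so sponging pools are disjoint and the true sponge pairs are exactly
  the support of the sharing matrix (total demand above the pool size is
  an error);
* private regulators are also drawn without replacement, so an "all-null"
  system is truly null — this is why the null calibration uses a pool of
  40 miRNAs: 32 transcripts each need a distinct private regulator;
* miRNA rows are **not** emitted in the expression matrix, mirroring
  rRNA-depleted long-RNA data in which the confounders are latent.

Evidence tables are corrupted at configurable rates: each true record is
deleted with probability `fn_rate` and `round(fp_rate * n_true)` spurious
records per class are drawn uniformly from the non-edges (defaults 5%
each). Every generator output is a pure function of the spec, including
its seed; the global RNG state is saved and restored.

What the generator does *not* emulate: count noise (expression is
delivered on the Gaussian scale the inference stack assumes; a
negative-binomial layer would add assumptions the tests cannot isolate),
library-size or batch effects, miRNA-expression dynamics, and database
identifier drift. Passing tests therefore demonstrate correctness of the
statistical machinery under the model's own assumptions, not robustness
to everything real RNA-seq data can do.

## Numerical and algorithmic choices

* **Order independence.** PC-stable freezes adjacency sets per level,
  which makes the skeleton order-independent — but the *separating sets*
  recorded by the classic first-found rule are not, and a flipped sepset
  flips v-structures. spongenet therefore evaluates every candidate
  subset at the removal level (both adjacency sides) and records the
  maximum-p separator, ties broken by sorted gene names; collider triples
  are applied in canonical name order. The whole CPDAG is then invariant
  to gene input order, which a property test asserts by permutation.
* **Orientation rules.** Closure uses Meek rules R1-R3, which are
  complete when orientations arise solely from v-structures; the
  background-knowledge-only rule R4 can never fire in this setting and
  is deliberately omitted.
* **Conflicting colliders** (possible under near-unfaithful data) never
  erase an edge: the first orientation in canonical order wins and the
  conflict is left as oriented, preserving the invariant that an edge is
  directed or undirected but never both.
* **IDA tie-breaks.** Sibling subsets are enumerated by size, then
  lexicographically; the summary takes the first subset attaining the
  minimum absolute effect, making results deterministic.
* **Saturations.** $|r| = 1$ yields $p = 0$ (dependent) in both the CI
  test and the correlation test; a collinear conditioning set raises an
  error naming the problem; rank-deficient IDA regressions are excluded,
  with an error only if every adjustment set fails.
* **Degenerate inputs.** An empty candidate list flows through the whole
  pipeline (empty network, header-only hub table); an empty evidence file
  or a filter that removes every gene is an error.

## Problem sizes

The validation studies run at sizes chosen to finish on a laptop while
leaving the statistics meaningful: CPDAG recovery uses 100 replicates of
a 5-node linear-Gaussian DAG at $n = 5000$ ($\alpha = 0.01$); IDA
recovery uses 50 seeds for each effect size $\beta \in \{0.5, 1, 2\}$;
the local-IDA oracle check enumerates all 543 DAGs on 4 labeled nodes
(185 equivalence classes, 2220 ordered pairs); the null and planted
calibrations each run the full pipeline over 20 seeded systems at the
default 22-sample design. The recovery DAG (a collider $a \to c \leftarrow b$
plus an isolated $d \to e$ pair) was chosen so that every true separator
of every nonadjacent pair contains the blocking node: class recovery then
depends only on test errors, not on which separator happens to be found.
Parameterizations in which a collider's descendant nearly cancels a
common-cause correlation (population partial correlation below $0.01$)
are effectively unfaithful at these sample sizes and are avoided on
principle — any constraint-based method would misorient them.

## Known limitations

* Causal sufficiency is knowingly violated: miRNAs are latent common
  causes by construction. IDA effect summaries are screening scores, not
  unbiased causal estimates; the package is faithful to the method, which
  carries the same caveat.
* Identifier matching is exact string equality after whitespace trimming;
  database-version harmonization and identifier liftover are out of
  scope and must happen upstream.
* The CPDAG is built over candidate-pair genes only, not the full
  transcriptome; effects are conditional on that scope.
* No library-size normalization is performed; callers supplying raw
  counts should pre-normalize if their design requires it.
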