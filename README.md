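# spongenet

Inference of lncRNA-driven miRNA-sponge (ceRNA) regulatory networks from
long-RNA expression profiles and validated miRNA-target interaction
evidence.

Competing endogenous RNAs de-repress each other by competing for a shared
pool of miRNAs: a lncRNA that binds the same miRNAs as an mRNA acts as a
sponge, producing a positive expression correlation without direct
regulation. Given a gene x sample expression matrix and miRNA-target
tables, spongenet

1. removes low-expression transcripts (row total < `min_total`, default
   100, strictly) and log-transforms the matrix;
2. scores every lncRNA-mRNA pair for shared-miRNA enrichment with the
   hypergeometric upper tail `P(X >= k)` for `k` shared of `n` (lncRNA)
   and `K` (mRNA) miRNAs in a pooled universe of `N`, BH-adjusted
   (`q < 0.05`);
3. learns a CPDAG over the candidate genes with the PC-stable algorithm
   (Fisher-z conditional-independence tests, `alpha = 0.01`) and computes
   per-pair causal-effect multisets with local IDA, summarized by the
   signed minimum-absolute effect;
4. calls sponge edges by Fisher z-transform correlation significance,
   `z = sqrt(n - 3) * atanh(r)`, BH-adjusted across all candidates
   (`q < 0.05`, positive `r`), and reports hub lncRNAs — the top 20% of
   lncRNA nodes by degree (with 24 lncRNA nodes: exactly 4 hubs).

A linear-Gaussian sponge-system simulator (latent miRNA regulators,
configurable sharing plan, corruptible evidence tables) generates
ground-truth systems for calibration, so the whole pipeline is testable
without any external download.

## Worked example

The numbered scripts under `analysis/` run the whole study; tables land
under `results/`. From the repository root:

```sh
Rscript analysis/01_simulate.R       # synthetic input bundles
Rscript analysis/02_candidates.R     # shared-miRNA enrichment
Rscript analysis/03_causal_effects.R # PC-stable + local IDA
Rscript analysis/04_network_hubs.R   # edge calling + hub selection
Rscript analysis/05_calibration.R    # 20-seed null / planted studies
```

`02_candidates.R` prints, for the system with three planted strong
sponge pairs (8 shared miRNAs each, 22 samples):

```
5 pairs share >= 1 miRNA; 3 are enriched at BH q < 0.05
  lnc_id mrna_id k_shared n_lnc K_mrna      p_hyper      q_hyper
1  lnc01  mRNA01        8     8      8 2.039509e-06 5.098773e-06
3  lnc02  mRNA02        8     8      8 2.039509e-06 5.098773e-06
4  lnc03  mRNA03        7     7      7 4.079019e-06 6.798365e-06
```

(the third pair lost one evidence record to the simulated 5%
false-negative rate). `04_network_hubs.R` then calls the final network:

```
  lnc_id mrna_id         r        p_cor        q_cor k_shared
1  lnc01  mRNA01 0.8290918 2.388093e-07 3.582139e-07        8
2  lnc02  mRNA02 0.8080153 1.020899e-06 1.020899e-06        8
3  lnc03  mRNA03 0.9041129 7.341852e-11 2.202555e-10        7
recovery vs truth: recall 1.00, 0 false edge(s)
top-20% rule on a 24-lncRNA network selects 4 hubs
```

All three planted pairs are recovered with strong positive correlations
and no false edges, and the degree rule reproduces the 4-hub count at
the reference network size. `05_calibration.R` repeats both studies over
20 seeds (null systems: 20/20 empty networks; planted systems: 20/20
full recall with <= 1 false edge).

Programmatic use mirrors the scripts:

```r
library(spongenet)
spec  <- plant_sponge_pairs(sponge_system_spec(seed = 1), n_pairs = 3, n_shared = 8)
paths <- end_to_end_fixture(spec, "bundle")
res   <- run_pipeline(paths$config, out_dir = "bundle/out")
res$network          # called sponge edges with r, p, q, effect summaries
res$hubs             # top-degree lncRNAs
score_network(res$network, generate_truth(spec))
```

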