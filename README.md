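# survbalance

Selection of compositional microbiome **balances** for right-censored
**time-to-event outcomes**.

## What problem does this solve?

Microbiome relative abundances are compositional: only ratios are
interpretable. A *balance* condenses the antagonism between two disjoint
sets of taxa into a single scale-invariant feature — the normalized
log-ratio of their geometric means,

```
B_i = sqrt(k+ k- / (k+ + k-)) * log[ gmean(X_i, I+) / gmean(X_i, I-) ]
```

where `I+` (`k+` taxa) and `I-` (`k-` taxa) index the two sets. In many
clinical microbiome studies the endpoint is a censored survival time
(overall survival, time to relapse or disease onset), so `survbalance`
searches for the pair `(I+, I-)` whose balance is most associated with
the outcome under either

* a **Cox proportional-hazards model**
  `h(t|B,Z) = h0(t) exp(γB + Z'β)` — the plus set is hazard-increasing, or
* a **Weibull AFT model** `log T = μ + γ'B + Z'β' + σε` — the plus set is
  survival-time-increasing,

using a greedy step-wise search (best 1-vs-1 pair, then one taxon added
per step while the model log-likelihood improves by more than `tol`).
Because a greedy selector always returns something, every run is gated by
a community-level kernel association pre-test (Bray-Curtis and Jaccard
kernels, martingale-residual permutation p-values, Cauchy-combination
omnibus): when the omnibus p-value is ≥ α the result carries a **caution
flag** — selection proceeds, interpretation should be careful.

Intended users: statisticians and bioinformaticians analyzing 16S/shotgun
profiles against survival endpoints, who want an interpretable two-set
taxon signature rather than per-taxon tests.

## Worked example

Simulate a 120-sample, 10-taxon cohort whose hazard is driven by the
planted balance of taxa {T1, T2} (hazard-increasing) versus {T3}
(hazard-decreasing), then run the full pipeline on the written TSV pair:

```r
library(survbalance)
cfg <- simulation_config(n_samples = 120, n_taxa = 10,
                         planted_plus = c(1, 2), planted_minus = 3,
                         gamma_true = 1.2, seed = 20)
sim <- simulate_dataset(cfg)
paths <- write_simulated_dataset(sim, "demo/in")

cfgr <- run_config(paths[["counts"]], paths[["metadata"]], "time", "event",
                   model = "cox", filter_mode = "remove_rare",
                   filter_threshold = 1e-4, n_permutations = 999,
                   seed = 11, out_dir = "demo/out")
res <- run_pipeline(cfgr)
print(res)
#> selected balance (cox model)
#>   plus  (k+ = 2): T2, T1
#>   minus (k- = 1): T3
#>   gamma = 1.1066, LRT p = 1.99e-44
#>   community omnibus p = 0.0016; caution = FALSE
```

The planted sets are recovered exactly. `gamma = 1.1066` estimates the
log-hazard increase per unit of balance (truth 1.2; the 95% CI in the
report is [0.92, 1.29] — the pseudocount slightly attenuates the latent
effect); the LRT p-value tests `γ = 0`; the omnibus p-value (0.0016)
says the community-level association is itself significant, so no
caution flag. `demo/out/` now contains `report.json` (selection, fit,
community test, echoed configuration), `balance.tsv`, the two distance
matrices, `trace.tsv` (one row per accepted greedy step), and
`curves.tsv` with predicted survival at the first/third quartiles of the
selected balance (here Q1 = −1.58, Q3 = 1.48; the Q3 curve lies below
the Q1 curve because `gamma > 0`). Add `plot = TRUE` for a PNG figure,
or `by_covariate = "sex"` for per-level curve panels.

The same pipeline runs from the shell:

```sh
exec/survbalance run --counts demo/in/counts.tsv --metadata demo/in/metadata.tsv \
    --time-col time --event-col event --model cox --seed 11 --out demo/out
exec/survbalance simulate --out demo/sim --n 100 --taxa 20 --gamma 1.5
exec/survbalance test-community --counts demo/in/counts.tsv \
    --metadata demo/in/metadata.tsv --time-col time --event-col event
```

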