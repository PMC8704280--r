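# pollinet

Analysis of bipartite plant–pollinator interaction networks sampled along
environmental (e.g. elevational) gradients, for community ecologists who
work with specimen-level visitation records: one row per captured insect,
carrying the habitat zone, site, sampling period, pollinator taxon and host
plant.

The package covers the full workflow of a gradient network study:

* **Data model** — aggregate records into site-level plant × pollinator
  count matrices, pool sites into zone-level networks
  (`build_site_networks()`, `pool_zone()`, `zones_from_records()`), and
  read/write both the long-format records CSV and labelled matrix CSV.
* **Network indices** on a count matrix `A = (a_ij)` with total `m`:
  * *Weighted connectance* `C = LD_w / (P + Q)`, where
    `LD_w = ½ [ Σ_j (a_·j/m) 2^{H_j} + Σ_i (a_i·/m) 2^{H_i} ]` is the
    entropy-based weighted linkage density (`weighted_connectance()`).
  * *Nestedness* NODF — percent overlap between species pairs with strictly
    decreasing marginal totals, averaged over all row and column pairs,
    0–100 (`nodf()`).
  * *Specialization* `H2' = (H2max − H2) / (H2max − H2min)` standardizing
    the two-dimensional Shannon entropy between its marginal-constrained
    extremes (`h2_prime()`).
  * *Modularity* — Barber bipartite
    `Q = (1/m) Σ_ij [a_ij − a_i· a_·j / m] δ(g_i, g_j)`, maximized by label
    propagation with agglomerative merging and Kernighan–Lin refinement,
    deterministic given a seed (`modularity_bipartite()`).
  * *Robustness* `R` — area under the attack-tolerance curve when plants
    are removed in random order and pollinator survival is tracked
    (`robustness_pollinators()`); `(2P−1)/(2P)` on a complete network.
* **Core generalists** — the degree z-score
  `Gc_i = (k_i − k̄) / σ_k`, where `k_i` is the mean per-site count of
  distinct plant partners; species with `Gc > 1` form the network core
  (`gc_scores()`, `core_generalists()`), plus nested ranks
  (`nested_rank()`) and singleton shares (`singleton_share()`).
* **Extinction simulation** — targeted removal of named pollinators from
  every site of a zone with before/after NODF bookkeeping
  (`simulate_removal()`, `rank_removal_sweep()`).
* **Community statistics** — per-event richness/abundance summaries and
  GLM group comparisons (gaussian / poisson / quasipoisson) with
  Tukey-adjusted pairwise marginal-mean contrasts (`summarize_events()`,
  `compare_groups()`).
* **Synthetic communities** — a seeded trait-matching generator
  (`synth_params()`, `generate_zone()`, `preset_gradient()`) reproducing
  the statistical structure such surveys assume, so the entire pipeline is
  testable without field data.

## Worked example

Simulate the three-zone elevational preset, analyse the high-elevation
zone, and remove its top three generalists:

```r
library(pollinet)

sim <- preset_gradient(seed = 42)
zc  <- zones_from_records(sim$SF$records, zone = "SF")

zone_metrics(zc, replicates = 100, seed = 42)$means
#> connectance_w  nodf  modularity_q  h2_prime  robustness_r  ...
#>         0.097 21.21         0.371     0.541         0.591

gt <- gc_scores(zc)
head(gt[, c("pollinator", "group", "k_i", "gc", "is_core")], 3)
#>   pollinator       group   k_i    gc is_core
#> 1   poll_001         fly 10.17 7.577    TRUE
#> 2   poll_095         bee  4.83 3.277    TRUE
#> 3   poll_041 lepidoptera  2.00 0.993   FALSE

rank_removal_sweep(zc, 1:3)$combined
#> removal_result: {poll_001, poll_095, poll_041}
#>   mean NODF 21.21 -> 12.93 (-39.03%)
```

Read: the simulated spruce-fir-like zone averages NODF ≈ 21 and H2′ ≈ 0.54
across its six sites; one hyperabundant generalist fly (`poll_001`,
mean 10.2 distinct partners per site, Gc = 7.6) anchors the core, and
deleting the three top-ranked generalists collapses mean nestedness by
~39% — the signature of generalist-dependent network stability. Removing
three bottom-ranked species instead changes it only marginally (try
`rank_removal_sweep` with bottom ranks).

The same analyses are scriptable end to end:

```sh
./exec/pollinet simulate --seed 42 --out run/
./exec/pollinet metrics --records run/records.csv --zone SF --seed 42 --out run/
./exec/pollinet generalists --records run/records.csv --zone SF --out run/
./exec/pollinet remove --records run/records.csv --zone SF --ranks 1,2,3 --out run/
```

or as one configured pipeline (`run_pipeline()` /
`./exec/pollinet run --config cfg.yaml`), with YAML or JSON configuration:

```yaml
simulate: {preset: gradient}
seed: 42
metrics: {replicates: 100, restarts: 10}
removal: {zone: SF, ranks: [1, 2, 3]}
stats:
  - {response: pollinator_richness, family: poisson}
  - {response: flower_abundance, family: quasipoisson}
output: run/
```

## Vignette

`vignettes/pollinet-methods.Rmd` documents the models, the numerical
choices (H2′ extremes, modularity optimizer, tie-breaking), what the
synthetic generator does and does not emulate, and known limitations.
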