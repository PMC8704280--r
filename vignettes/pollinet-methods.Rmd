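---
title: "Models and methods behind pollinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pollinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

# The analysis problem

Gradient studies of pollination ask how the *structure* of the bipartite
plant–pollinator network — not just species counts — changes across
habitat zones, and which pollinator species hold that structure together.
The raw material is a specimen table: one row per insect captured on a
flower, with zone, site, sampling period, pollinator and host-plant taxon.
`pollinet` turns such tables into site-level interaction-count matrices
(rows = plants, columns = pollinators; cell $a_{ij}$ = specimens of
pollinator $j$ caught on plant $i$, summed over periods and years), pools
them per zone, and computes the standard battery of indices plus
generalist-core and extinction-simulation analyses.

Two aggregation conventions are fixed throughout and worth stating once:
rows are always plants ("lower level") and columns pollinators ("higher
level"); and rows or columns whose marginal total is zero are trimmed when
a matrix is constructed, so every index sees strictly positive marginals.
Label matching is exact string equality after whitespace trimming —
taxonomic reconciliation is out of scope.

# The five network indices

**Weighted connectance.** Plain connectance ($L/PQ$) overweights rare,
weak links. The weighted version divides the entropy-based weighted
linkage density by total species count:
$$LD_w = \tfrac12\Big[\sum_j \frac{a_{\cdot j}}{m}2^{H_j} +
\sum_i \frac{a_{i\cdot}}{m}2^{H_i}\Big], \qquad C_w = \frac{LD_w}{P+Q},$$
with $H_i$ the base-2 Shannon entropy of row $i$'s interaction
distribution, so $2^{H_i}$ is species $i$'s effective partner number.
$C_w \in (0, 0.5]$, with 0.5 attained exactly on uniform complete
matrices. Because the gradient literature often describes connectance on a
0–100 scale that no weighted formula attains, `network_metrics()` reports
both the fraction and 100× it; no rescaling to a "percent of possible" is
attempted because none is well defined for the weighted quantity.

**NODF.** For each ordered pair within an axis whose marginal totals
*strictly* decrease, the paired term is $100\times$ (shared presences) /
(presences of the poorer member); equal totals contribute zero. NODF is
the mean over all $P(P-1)/2 + Q(Q-1)/2$ pairs. The default binarizes
counts — the decreasing-fill definition is a binary concept — and this is
what the reference pipeline uses everywhere (removals, acceptance
properties). A quantitative variant (`weighted = TRUE`, counting cells of
the poorer member that are strictly smaller than the richer member's) is
provided for sensitivity analysis but deliberately not wired into any
default. NODF is invariant to permutations, 100 on strictly nested
triangular fills, 0 on permutation matrices; the tests verify all three
and check random matrices against both a brute-force pairwise oracle and
`vegan::nestednodf`.

**H2′.** Observed selectiveness is the two-dimensional entropy
$H_2 = -\sum p_{ij}\ln p_{ij}$, $p_{ij} = a_{ij}/m$. It is standardized
between the entropy of the *outer product of marginal frequencies*
($H_{2max}$, purely opportunistic partner use) and a *minimum-entropy
integer fill* of the marginals ($H_{2min}$):
$H_2' = (H_{2max}-H_2)/(H_{2max}-H_{2min})$, clipped into $[0,1]$.
Reference implementations differ in how they approximate the two extremes;
we chose a real-valued $H_{2max}$ (no integer constraint) and a fully
deterministic greedy fill for $H_{2min}$ — repeatedly place
$\min(\text{row remainder}, \text{column remainder})$ in the admissible
cell where that minimum is largest, ties broken by lowest row then lowest
column index. The rationale is reproducibility and checkability: the
greedy fill is oracle-verified against exhaustive enumeration of all
integer matrices with the same marginals (at $m \le 12$, where enumeration
is feasible), and it makes $H_2'$ a pure function of the matrix with no
hidden randomness. The integer-constrained $H_{2max}$ variant would change
values in the third decimal at typical sizes; it is noted as an option,
not implemented, to keep one canonical definition.

**Modularity.** Barber's bipartite
$Q = \frac1m \sum_{ij}\big[a_{ij} - a_{i\cdot}a_{\cdot j}/m\big]
\delta(g_i, g_j)$ is maximized by a label-propagation scheme with
agglomerative merging, in the LPAwb+ family, rather than simulated
annealing: it is deterministic given `(matrix, seed, restarts)`, fast at
survey scale, and verifiable. Three move types alternate to a joint
fixpoint: (1) greedy single-node reassignment sweeps, (2) best-pair module
merges, and (3) Kernighan–Lin chains — every node is forced through its
best single move once, negative gains allowed, and the best prefix of the
chain is kept. The KL stage matters: plain propagation + merging has
strong attractors that all restarts can fall into; the chains escape
them. Restart 1 starts from each plant in its own module; later restarts
scatter both sides over a random number of labels to diversify basins.
Q of the single-module partition is exactly 0; results are never clipped
and the documented range is $[-0.5, 1]$. On networks with $\le 10$–$12$
species the optimizer is tested against exhaustive search over all set
partitions; at survey scale it is, like every modularity maximizer, a
heuristic.

**Robustness.** Plants are removed one at a time in uniformly random
order; a pollinator survives while it retains at least one link. With
$y_k$ the surviving fraction after $k$ of $P$ removals, $R$ is the
trapezoid integral of the curve $(k/P, y_k)$, averaged over replicates
(default 100, seeded). The removal order is random because the underlying
study design named none; degree-ascending and degree-descending orders are
available behind the `order` argument. The complete network gives the
closed form $(2P-1)/(2P)$ and toys are tested against the exact mean over
all $P!$ orders.

**Zone reporting.** All five indices are computed per site and averaged
arithmetically across a zone's sites; pooled matrices are used only where
the method demands pooling (Gc, nested ranks, singleton shares).

# Core generalists, ranks, removals

$Gc_i = (k_i - \bar k)/\sigma_k$, where $k_i$ is pollinator $i$'s mean
per-site count of distinct plant partners. The source formula is printed
ambiguously in parts of the literature ("$k_i - k_{mean}/\sigma$"); it is
read with standard z-score precedence, consistent with its cited uses.
Two resolved ambiguities are exposed as arguments rather than hidden:

* **Absent sites.** By default a site where the species was never caught
  contributes $k = 0$ (six-site averaging is what distinguishes Gc from a
  pooled degree z-score and is why two species with equal pooled degree
  can differ in Gc); `include_absent_sites = FALSE` averages occupied
  sites only.
* **Standard deviation.** Sample ($n-1$, default) or population.

$\sum_i Gc_i = 0$ by construction (tested), Gc depends only on
distinct-link structure (invariant to uniform count scaling, tested), and
core sets shrink monotonically in the threshold. "Singletons" have two
senses in field usage — one captured individual, or one unique link — so
`singleton_share()` makes the definition an explicit argument with
`one_individual` as default.

Nested ranks order pollinators by decreasing pooled degree, ties broken by
decreasing abundance, then alphabetically (a deterministic tie-break keeps
removal experiments reproducible). Extinction simulations delete the named
species from every site, trim orphaned plant rows, and recompute NODF per
site; sites never holding the species keep their original value in the
"after" mean (the zone mean is over *all* sites, matching the averaging
convention of the study design; `absent_sites = "skip"` is available for
sensitivity). Percent change is computed on the zone mean, not as a mean
of per-site percent changes. Ranks are assigned once, from the intact
network, and not re-derived between removals. A site whose matrix falls
below the size where NODF is defined is excluded from both means, with a
warning — preferring an honest exclusion over an arbitrary imputed zero.

# Group comparisons

`compare_groups()` fits `response ~ zone` by `stats::glm` under a
caller-specified family — the per-response choices (Poisson for pollinator
richness/abundance, Gaussian for plant richness, quasi-Poisson for
overdispersed flower counts) mirror standard practice and are config keys,
with no automatic normality testing. The overall test is an F test on the
deviance drop when dispersion is estimated (gaussian, quasipoisson) and a
deviance $\chi^2$ for poisson. Pairwise contrasts are formed on the link
scale from the estimated marginal means with Tukey adjustment via the
studentized range (`ptukey` at the residual df, or its large-df limit for
z statistics) — the same machinery the `emmeans` package applies; the
multiplicity adjustment is an assumption recorded here, as the source
methods name the package but not the adjustment. An all-constant response
returns a flagged degenerate result (statistic 0, p = 1) instead of an
error, so batch pipelines survive pathological subsets.

# The synthetic generator: what it does and does not emulate

`generate_zone()` simulates the survey design: `n_sites` (6) sites ×
`n_periods` (9) periods, Bernoulli($\psi$) site occupancy per species,
log-normal plant abundances $f_i$ and pollinator activities $g_j$, uniform
plant traits $t_i$ and pollinator optima $u_j$, log-normal niche breadths
$b_j$, Gaussian trait matching
$w_{ij} = \exp(-(t_i-u_j)^2/2b_j^2)$, and Poisson visit counts with mean
$\lambda f_i g_j w_{ij}$ per occupied (site, period) cell. One record per
specimen is emitted. The kernel-with-heterogeneous-breadths choice is
scaffolding, not biology inferred from data: it is the simplest generative
model whose two knobs produce the structures the metrics are supposed to
detect — breadth heterogeneity yields nestedness, trait clustering yields
modules, and the mean breadth moves H2′.

`preset_gradient()` encodes a three-zone elevational world whose
magnitudes were calibrated once, during development, to the published
totals of a montane survey of this design (≈340 / 730 / 630 specimens and
≈67 / 101 / 72 observed pollinator species for the low / middle / high
zone; 27 / 32 / 20 plants; one high-zone fly holding roughly a third of
individuals; ≈60–70k flowers per zone, log-normal per site × period ×
plant). Latent species pools are larger than observed richness because
narrow-niche rare species go uncaptured — the calibration targets are the
*observed* tables. Niche breadths widen with elevation
($e^{\mu_b}$ = 0.055 → 0.085 → 0.15), so zone-mean H2′ declines and NODF
rises on average; these parameters were fixed before the recovery tests
were run and are not tuned against them.

What the generator does **not** emulate: phenological turnover within a
season (periods are exchangeable), intraspecific trait variation,
plant-side activity differences beyond abundance, spatial autocorrelation
among sites, and observation effects other than Poisson sampling
(no detection bias by taxon, no weather-cancelled visits). A green
synthetic-recovery test therefore establishes that the pipeline detects
trait-matching structure under idealized sampling — not that any
particular field system matches the preset.

# Numerical choices and degenerate inputs

* H2′ is clipped into $[0,1]$ after standardization; matrices whose
  marginals admit a single configuration (e.g. $1\times n$) raise a
  degenerate-input error, as do 1×1 matrices for NODF.
* The greedy $H_{2min}$ tie-break (lowest row, then column index) and the
  nested-rank tie-break (abundance, then label) are fixed so results are
  bit-reproducible.
* All Monte-Carlo routines (`robustness_pollinators`,
  `modularity_bipartite` restarts) take explicit seeds, set them locally,
  and restore the caller's RNG state.
* Gc requires ≥2 pollinator species with non-identical $k$; identical
  degrees everywhere is reported as degenerate rather than returning NaN.
* The modularity optimizer tracks Q incrementally but every exported
  partition satisfies `q == barber_q(M, partition)` (tested), so no
  accumulation drift can reach the user.

# Known limitations

* Modularity above ~12 species is a heuristic optimum; restarts and KL
  chains reduce but cannot eliminate the chance of a local maximum.
* NODF's weighted variant is provided but has no oracle of comparable
  strength; treat it as exploratory.
* The extinction simulation models one trophic step only — no plant
  coextinction cascades, no rewiring.
* Null-model significance testing of indices (Patefield shuffles etc.) is
  deliberately out of scope; the indices are descriptive here.
* The acceptance specification for this package lists no numeric targets
  (the motivating study's raw data have no public accession), so
  quantitative acceptance is carried entirely by the oracle-backed test
  suite; the data-conditional reproduction tier would activate only if a
  compatible specimen file were supplied.
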