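---
title: "Methods: tiered core diagnosis and partition-aware assembly analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered core diagnosis and partition-aware assembly analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `coretier`, the
assumptions each stage makes, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
numerical conventions the implementation commits to.

## 1. Data model

A *community table* is a tibble whose first column `sample_id` identifies
samples and whose remaining numeric columns are taxa — a samples-by-taxa
feature table. Metadata carries `sample_id, host, site, latitude, longitude`.
A *subcommunity* (local community) is the set of samples of one host at one
site; a *meta-community* pools one host's samples across sites.

Standard preprocessing (`filter_table()`) removes taxa with total count at
most `drop_max_total = 2` (singletons and doubletons — most likely
sequencing artifacts) and then samples below `min_depth = 1000` reads, in
that order: rare-taxon removal can push a borderline sample below the depth
cut, so the depth rule is applied to the cleaned table. The
Hellinger transform (`hellinger()`) — the square root of within-sample
relative abundance — gives unit-L2 sample rows and tempers the dominance of
abundant taxa before ordination and correlation work.

## 2. Two-level core diagnosis

At threshold `thres ∈ [0, 1)` a taxon is **core′** in a subcommunity of
`N_samp` samples when its occurrence fraction is *strictly* greater than the
threshold:

    core' = { tax_i | occurrence_i / N_samp > thres }

and **core** in the meta-community of `N_comm` subcommunities when it is
core′ in a strictly greater fraction of them than the same threshold:

    core  = { tax_i | n(tax_i ∈ core'_j) / N_comm > thres }

Both inequalities are strict, and a single threshold is used at both levels.
The second level is what distinguishes a host-associated core from a
site-local bloom: a taxon saturating one of five sites is core′ in 1/5 of
subcommunities and is denied at any threshold ≥ 0.2, however abundant it is.

### Threshold sweep and tiers

A fixed threshold is arbitrary, so the diagnosis is run at every integer
percent 0–99 (`threshold_sweep()`), twice: once on the real site
subcommunities, once on simulated subcommunities (`simulate_subcommunities()`,
default `reps = 100` views of `subsample = 30` samples drawn without
replacement from the pooled meta-community). The simulated views answer
"what would the core look like if site structure were an artifact of
sampling?" Agreement is measured by the Jaccard index of the two core sets,
with the convention `J(∅, ∅) = 1`: at very high thresholds both sides are
empty, which counts as agreement, but empty sets never form tiers.

A **tier** (`identify_tiers()`) is a maximal contiguous threshold run where
`J = 1`, the (shared) core set is constant, and the set is nonempty.
Scanning from 99% downward, tiers are numbered 1, 2, …; strict-threshold
filters make core sets nested, so every lower tier's set contains every
higher tier's. A later run reproducing an already-seen set is merged into
that tier's interval record rather than numbered separately — the set, not
the interval, is the scientific object; the interval multiplicity is kept in
the `intervals` list column.

`select_tier()` picks the tier whose cumulative relative abundance (summed
Hellinger mass of its taxa over the whole table) is closest to
`target_abundance = 0.5`. The 50% working point selects a core that is
simultaneously compact and representative — a "half the community by mass"
summary; exact ties break toward the higher tier (more stringent
thresholds). The result is a two-class partition (core / noncore) of the
full taxon universe.

## 3. Sloan neutral community model

For the neutral fit the Hellinger table is scaled back to integers
(`scale_round()`, `factor = 1000` — three significant digits preserves the
transform's resolution while giving the model a defensible "reads" scale).
With community size `N` (mean scaled row sum), migration probability `m`,
and detection limit `d = 1/N`, the neutral expectation for the occurrence
frequency of a taxon with mean relative abundance `p` is

    f(p) = 1 − BetaCDF(d; N·m·p, N·m·(1−p))

`fit_ncm()` estimates `m` by least squares over taxa in untransformed
frequency space (`optimize()` on (1e−8, 1−1e−8), tolerance 1e−9 — the
objective is smooth and unimodal in practice, so golden-section search
suffices). `R² = 1 − SSE/SST` summarizes fit quality. Uncertainty comes
from a percentile bootstrap over taxa (`n_boot = 1000`): a 95% interval for
`m` and a 95% band around the prediction curve; a Wilson score band over
the binomial sampling error of frequency is available via
`band_method = "wilson"`. The bootstrap band is clamped to contain the
point prediction so on-curve data can never be labelled non-neutral by
bootstrap noise. Taxa are labelled `above` / `neutral` / `below` by strict
comparison of observed frequency with the band; never-observed taxa are
excluded from the fit but reported with `NA` labels.
`partition_proportions()` crosses these labels with the core set at every
sweep threshold, showing how deviation from neutrality distributes over the
core/noncore split.

Caveat: because `p` is estimated from detection-truncated observed
abundances, the estimator carries a small upward bias that grows with `m`
(visible in the package's own recovery study); the bootstrap interval
quantifies sampling noise, not this bias.

## 4. Dissimilarity–overlap curves

For every unordered sample pair sharing at least one taxon, `doc_points()`
computes overlap — the average total relative abundance invested in shared
taxa, `Σ_{i∈S}(x_i + y_i)/2` — and dissimilarity — the root Jensen–Shannon
divergence (log base 2, hence in [0, 1]) of the compositions renormalized
on the shared support. Pairs with disjoint support are skipped and counted.

`fit_doc()` LOWESS-smooths dissimilarity on overlap (`lowess_frac = 2/3`,
the conventional span; evaluated on a 50-point grid over the observed
overlap range) and bootstraps the curve over *samples*, not pairs
(`n_boot = 100`): pair observations sharing a sample are dependent, so
resampling samples and weighting pairs by joint multiplicity is the honest
resampling unit. The **change point** is the smallest grid overlap from
which the smoothed slope stays negative through the maximum observed
overlap; if the terminal slope is nonnegative there is none (`NA`,
conventionally drawn at the rightmost overlap). A negative terminal slope
at high overlap is the universal-dynamics signature; it is compared against
`doc_null()` curves in which every taxon's abundance vector is permuted
across samples independently (preserving each taxon's marginal distribution
while destroying the overlap–dissimilarity coupling), via the 2.5th
percentile of null terminal slopes.

## 5. Co-occurrence networks and the D-measure

`spearman_network()` computes Spearman's rho (average ranks) between all
taxon pairs of a subcommunity and keeps edges with `|rho| > 0.8` *and*
two-sided `p < 0.001`, both strict, with raw (uncorrected) p-values — the
frequency-combination step below is the multiplicity control. P-values use
the exact permutation null (via `cor.test()`) for ≤ 9 samples and the t
approximation otherwise. Constant taxa are dropped (and counted) first.

`combine_networks()` counts each unordered edge across the `reps = 100`
simulated subcommunity networks and keeps edges present in strictly more
than `min_freq = 20` of them — "recurs in over a fifth of bootstrap views"
— which suppresses single-view flukes far more aggressively than any
per-test correction. `node_metrics()` reports degree, Wasserman–Faust
component-corrected closeness `((c−1)/Σd)·((c−1)/(N−1))` (isolated vertices
get 0), and Brandes betweenness.

`graph_dissimilarity()` implements the three-term weighted D-measure with
weights `(0.45, 0.45, 0.10)`:

    D = w1·sqrt(JS(μ1, μ2)/log 2)
      + w2·|sqrt(NND1) − sqrt(NND2)|
      + (w3/2)·[sqrt(JS(Pα(g1), Pα(g2))/log 2) + sqrt(JS(Pα(ḡ1), Pα(ḡ2))/log 2)]

where μ is a graph's mean node-distance distribution (distance bins 1…N
with bin N collecting unreachable pairs), NND the network node dispersion
(Jensen–Shannon divergence of the per-node distance distributions,
normalized by log(diameter + 1), defined 0 for edgeless graphs), Pα the
sorted α-centrality distribution scaled by N² with the remaining mass
appended, and ḡ the complement graph. Two conventions needed fixing where
the published description leaves latitude: α is set to `1/N` with exogenous
term `degree/(N−1)` (always below the reciprocal spectral radius of a
simple graph, since λmax ≤ N−1, and numerically stable), and distributions
of graphs of unequal order are zero-padded at the tail before the
Jensen–Shannon step. With weights summing to 1, D is symmetric, 0 for
identical graphs and bounded by 1; the test suite checks it against an
independent second transcription of the algorithm. `network_ordination()`
NMDS-ordinates a set of networks by pairwise D, flagging all-identical
inputs as degenerate rather than feeding a zero matrix to the solver.

## 6. The synthetic generator

`simulate_metacommunity()` emulates the *occupancy architecture* the
diagnosis targets, not sequence-level reality:

- **Planted core**: `n_core = 5` taxa present in every site at per-sample
  prevalence `core_prevalence = 0.9` with high abundance weight (60).
- **Epidemic taxa**: `n_epidemic = 3` taxa at prevalence 0.95 in
  `epidemic_sites = 1` home site and 0.02 elsewhere — the adversarial case
  the two-level definition must reject.
- **Rare tail**: `n_rare = 200` taxa whose per-taxon occupancy is drawn
  from a Beta(0.7, b) with mean `rare_occupancy_mean = 0.08`, *truncated*
  at `rare_occupancy_max = 0.25` by inverse-CDF sampling. The untruncated
  Beta reproduces the L-shaped occupancy curve of real tables but lets a
  substantial minority of "rare" taxa reach intermediate-to-high occupancy,
  making the ground-truth labels incoherent; truncation at the conventional
  rare/intermediate boundary keeps a rare label meaning rare.
- Conditional on presence, abundances are log-normal around per-taxon
  weights (`abundance_sdlog = 0.5`); counts are multinomial at a
  negative-binomial depth (`depth_mean = 5000`, `depth_dispersion = 5`,
  truncated at ≥ 1) mimicking uneven library sizes.

Not emulated: reads, chimeras, taxonomy error, phylogenetic structure,
between-taxon interactions (except via `plant_correlated_pairs()`, which
rewrites one column as an exact monotone or anti-monotone image of another
for network-recovery fixtures), and any real abundance-distribution family —
the log-normal is a configurable stand-in.

`simulate_ncm_community()` inverts the neutral model's sampling
distribution: per sample and taxon, a relative abundance is drawn from
`Beta(Nm·p, Nm·(1−p))`; a draw at or below the detection limit `1/n_reads`
is undetected, a draw above it yields a nonzero binomial count. This makes
the realized occurrence frequencies converge exactly to the fitted curve —
a plain binomial read-out would detect taxa the model deems undetectable
and systematically inflate recovered `m`.

`simulate_doc_regimes()` produces the two DOC ground truths. In the
`universal` regime all samples are noisy subsets of one shared composition
and the per-sample noise amplitude shrinks as the sample's richness (hence
its overlap with everything) grows — so high-overlap pairs are reliably
more similar, guaranteeing the negative terminal slope without an ODE
simulation. In the `independent` regime samples are drawn independently
and no overlap–dissimilarity coupling exists.

## 7. Pipeline and reproducibility

`run_pipeline()` sequences filter → Hellinger → sweep → tiers → selection →
neutral fit → partition proportions → per-partition DOC with nulls →
combined network with node metrics. `pipeline_config()` requires a root
seed; per-stage seeds are spawned from it deterministically (all below
2^31) and recorded in the report, so any stage can be replayed in
isolation. Stage failures raise a classed error naming the stage and
carrying the partial report. `write_report()` serializes every tabular
output as CSV plus a JSON summary; identical configurations produce
byte-identical files. A DOC stage that cannot run on a partition (for
example a core of two taxa giving too few pairs) is recorded as `NULL` with
a message rather than failing the run.

## 8. Limitations

- The tier machinery requires *perfect* (J = 1) agreement; on noisy tables
  with many borderline taxa, tiers can be short or absent (an empty tier
  table with a warning). The sweep output remains useful diagnostically.
- At threshold extremes the diagnosis is structurally permissive: at 0%
  every observed taxon is core on both real and simulated sides, so the
  lowest tier is always the full observed universe. Interpretation should
  focus on intermediate thresholds; `select_tier()`'s abundance target does
  this implicitly.
- The neutral fit inherits the detection-truncation bias of
  abundance-estimated `p` (Section 3); its bootstrap interval is a noise
  interval, not a bias interval.
- Spearman networks on compositional data can reflect closure effects;
  the Hellinger transform and the frequency cut mitigate but do not remove
  this.
- DOC change-point detection depends on the LOWESS span; the default 2/3
  favours smooth global trends over local wiggles, so short terminal
  descents may be missed at small sample counts.
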