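# Shared expensive fixtures, computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# 20 seeded planted-core runs: simulate, sweep, tiers, selected partition
recovery_runs <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  runs <- lapply(1:20, function(seed) {
    sim <- simulate_metacommunity(metacommunity_spec(seed = seed))
    hell <- hellinger(sim$counts)
    real <- subcommunity_views(sim$counts, sim$metadata)
    sims <- simulate_subcommunities(sim$counts, n_samples = 30, reps = 100,
                                    seed = seed + 1000)
    sweep <- threshold_sweep(real, sims, hell)
    tiers <- identify_tiers(sweep)
    partition <- select_tier(tiers)
    list(truth = sim$truth, sweep = sweep, tiers = tiers,
         partition = partition)
  })
  .fixture_cache$recovery <- runs
  runs
}

# thresholds where real core equals the planted core set with J = 1
planted_thresholds <- function(run) {
  planted <- run$truth$labels$taxon_id[run$truth$labels$label == "core"]
  core_real <- attr(run$sweep, "core_real")
  hit <- run$sweep$jaccard == 1 &
    vapply(core_real, function(s) setequal(s, planted), logical(1))
  run$sweep$threshold[hit]
}

# build a tier_table by hand (for selection-rule tests)
manual_tier_table <- function(abundances, universe = sprintf("t%02d", 1:10)) {
  n <- length(abundances)
  taxa <- lapply(seq_len(n), function(i) universe[seq_len(i + 1)])
  out <- tibble::tibble(
    tier = seq_len(n),
    threshold_lo = rev(seq(10, by = 10, length.out = n)),
    threshold_hi = rev(seq(15, by = 10, length.out = n)),
    intervals = lapply(seq_len(n), function(i) list(c(0L, 0L))),
    n_taxa = lengths(taxa),
    abundance = abundances,
    taxa = taxa
  )
  structure(out, taxa = universe, class = c("tier_table", class(out)))
}
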