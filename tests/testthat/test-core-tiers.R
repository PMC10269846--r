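make_presence_table <- function(presence, prefix = "tax") {
  m <- presence * 1.0
  dimnames(m) <- list(sprintf("s%02d", seq_len(nrow(m))),
                      sprintf("%s%d", prefix, seq_len(ncol(m))))
  as_community_tibble(m)
}

test_that("core_prime keeps taxa strictly above the prevalence threshold", {
  # taxa 3, 4, 5 occur in > 80% of 10 samples; taxa 1, 2 do not
  pres <- cbind(
    tax1 = c(rep(1, 4), rep(0, 6)),
    tax2 = c(rep(1, 8), rep(0, 2)), # exactly 0.8: excluded at 0.8
    tax3 = c(rep(1, 9), 0),
    tax4 = rep(1, 10),
    tax5 = c(rep(1, 9), 0)
  )
  tb <- make_presence_table(pres)
  names(tb) <- c("sample_id", paste0("tax", 1:5))
  expect_setequal(core_prime(tb, 0.80), c("tax3", "tax4", "tax5"))
  expect_false("tax2" %in% core_prime(tb, 0.80)) # boundary is strict
  expect_setequal(core_prime(tb, 0), paste0("tax", 1:5))
})

test_that("core_set denies site-local (epidemic-like) taxa and keeps ubiquitous ones", {
  # taxon "everywhere" is core' in all 5 subcommunities; "local" in 1 of 5
  subs <- lapply(1:5, function(k) {
    tibble::tibble(
      sample_id = sprintf("site%d_s%d", k, 1:4),
      everywhere = c(1, 1, 1, 1),
      local = if (k == 1) c(1, 1, 1, 1) else c(0, 0, 0, 0)
    )
  })
  expect_setequal(core_set(subs, 0.5), "everywhere")
  for (th in c(0, 0.3, 0.7, 0.99)) {
    expect_true("everywhere" %in% core_set(subs, th))
  }
  expect_error(core_set(list(), 0.5), "nonempty")
})

test_that("core_set equals the exhaustive double-loop oracle on random fixtures", {
  for (fixture_seed in 1:10) {
    set.seed(fixture_seed)
    n_subs <- sample(2:4, 1)
    n_taxa <- sample(4:12, 1)
    subs <- lapply(seq_len(n_subs), function(k) {
      n_samp <- sample(3:8, 1)
      m <- matrix(rbinom(n_samp * n_taxa, 1, runif(1, 0.2, 0.8)), n_samp)
      dimnames(m) <- list(sprintf("c%d_s%d", k, seq_len(n_samp)),
                          sprintf("t%02d", seq_len(n_taxa)))
      as_community_tibble(m)
    })
    for (th in (0:99) / 100) {
      expect_identical(core_set(subs, th), bf_core_set(subs, th))
    }
  }
})

test_that("sample order never changes a core set", {
  sim <- simulate_metacommunity(metacommunity_spec(
    n_sites = 3, samples_per_site = 12, n_rare = 40, seed = 6))
  subs <- subcommunity_views(sim$counts, sim$metadata)
  shuffled <- lapply(subs, function(s) s[sample.int(nrow(s)), ])
  for (th in c(0, 0.25, 0.5, 0.8)) {
    expect_setequal(core_set(subs, th), core_set(shuffled, th))
  }
})

test_that("simulate_subcommunities draws seeded views without replacement", {
  tb <- random_count_table(40, 6, seed = 14)
  views <- simulate_subcommunities(tb, n_samples = 30, reps = 100, seed = 5)
  expect_length(views, 100)
  for (v in views[c(1, 50, 100)]) {
    expect_identical(nrow(v), 30L)
    expect_false(anyDuplicated(v$sample_id) > 0)
    expect_true(all(v$sample_id %in% tb$sample_id))
  }
  expect_identical(views,
                   simulate_subcommunities(tb, 30, 100, seed = 5))
  expect_error(simulate_subcommunities(tb, n_samples = 41, reps = 2, seed = 1),
               "exceeds")
  with_rep <- simulate_subcommunities(tb, n_samples = 41, reps = 2, seed = 1,
                                      replace = TRUE)
  expect_identical(nrow(with_rep[[1]]), 41L)
})

test_that("jaccard_index follows the definition and the empty-set convention", {
  expect_equal(jaccard_index(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(jaccard_index(c("a", "b"), c("b", "a")), 1)
  expect_equal(jaccard_index(character(0), character(0)), 1)
  expect_equal(jaccard_index(character(0), "a"), 0)
})

test_that("threshold_sweep covers 0..99 with monotone core sizes", {
  run <- recovery_runs()[[1]]
  sw <- run$sweep
  expect_identical(sw$threshold, 0:99)
  expect_true(all(diff(sw$n_core_real) <= 0))
  expect_true(all(diff(sw$n_core_sim) <= 0))
  expect_true(all(sw$jaccard >= 0 & sw$jaccard <= 1))
  expect_true(all(sw$abund_real >= 0 & sw$abund_real <= 1))
  # at the top threshold cores are typically empty on both sides: J = 1
  expect_identical(sw$n_core_real[100], 0L)
  expect_identical(sw$n_core_sim[100], 0L)
  expect_equal(sw$jaccard[100], 1)
})

test_that("identify_tiers finds maximal constant-set J=1 runs", {
  # constructed sweep: J = 1 everywhere, core set changes twice -> 3 tiers
  pres <- cbind(
    t1 = rep(1, 10),                   # occupancy 1
    t2 = c(rep(1, 7), 0, 0, 0),        # occupancy 0.7
    t3 = c(rep(1, 3), rep(0, 7))       # occupancy 0.3
  )
  tb <- make_presence_table(pres, prefix = "t")
  names(tb) <- c("sample_id", c("t1", "t2", "t3"))
  subs <- list(tb) # one subcommunity: real and "simulated" identical
  sweep <- threshold_sweep(subs, subs, tb)
  expect_true(all(sweep$jaccard == 1))
  tiers <- identify_tiers(sweep)
  expect_identical(nrow(tiers), 3L)
  expect_setequal(tiers$taxa[[1]], "t1")
  expect_setequal(tiers$taxa[[2]], c("t1", "t2"))
  expect_setequal(tiers$taxa[[3]], c("t1", "t2", "t3"))
  # tier 1 holds the highest thresholds; intervals don't overlap downward
  expect_true(tiers$threshold_lo[1] > tiers$threshold_hi[2])
  expect_true(tiers$threshold_lo[2] > tiers$threshold_hi[3])
})

test_that("sweeps that never reach a nonempty J=1 set yield no tiers, with a warning", {
  # constructed sweep: real and simulated cores disagree while nonempty and
  # agree only once both are empty -- the empty-set convention never forms a tier
  core_real <- c(rep(list(c("t1", "t2")), 50), rep(list(character(0)), 50))
  core_sim <- c(rep(list("t1"), 50), rep(list(character(0)), 50))
  base <- tibble::tibble(
    threshold = 0:99,
    n_core_real = lengths(core_real), abund_real = 0.5,
    n_core_sim = lengths(core_sim), abund_sim = 0.3,
    jaccard = mapply(jaccard_index, core_real, core_sim)
  )
  sweep <- structure(base, core_real = core_real, core_sim = core_sim,
                     taxa = c("t1", "t2"),
                     class = c("core_sweep", class(base)))
  expect_warning(tiers <- identify_tiers(sweep), "[Nn]o t")
  expect_identical(nrow(tiers), 0L)
  expect_error(select_tier(tiers), "Empty tier table")
})

test_that("tier sets are nested on real planted runs", {
  for (run in recovery_runs()[1:5]) {
    tiers <- run$tiers
    if (nrow(tiers) < 2) next
    for (i in seq_len(nrow(tiers) - 1)) {
      expect_true(all(tiers$taxa[[i]] %in% tiers$taxa[[i + 1]]))
    }
    expect_true(all(diff(tiers$n_taxa) >= 0))
  }
})

test_that("select_tier picks the abundance closest to the target with a high tie-break", {
  tiers <- manual_tier_table(c(0.12, 0.55, 0.81))
  part <- select_tier(tiers, 0.5)
  expect_identical(attr(part, "tier")$tier, 2L)
  expect_setequal(part$taxon_id[part$class == "core"], tiers$taxa[[2]])
  expect_identical(sort(unique(part$class)), c("core", "noncore"))

  single <- manual_tier_table(0.9)
  expect_identical(attr(select_tier(single), "tier")$tier, 1L)

  tie <- manual_tier_table(c(0.4, 0.6))
  expect_identical(attr(select_tier(tie, 0.5), "tier")$tier, 1L)
})

test_that("the selected tier recovers the planted core and rejects epidemics", {
  runs <- recovery_runs()
  ok <- vapply(runs, function(run) {
    planted <- run$truth$labels$taxon_id[run$truth$labels$label == "core"]
    got <- run$partition$taxon_id[run$partition$class == "core"]
    epi <- run$truth$labels$taxon_id[run$truth$labels$label == "epidemic"]
    setequal(got, planted) && !any(epi %in% got)
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("the planted-core threshold interval spans the working range", {
  runs <- recovery_runs()
  covers <- vapply(runs, function(run) {
    all(40:75 %in% planted_thresholds(run))
  }, logical(1))
  expect_gte(sum(covers), 18)
})

test_that("epidemic taxa stay out of every tier in the working threshold range", {
  for (run in recovery_runs()[1:20]) {
    epi <- run$truth$labels$taxon_id[run$truth$labels$label == "epidemic"]
    tiers <- run$tiers
    high <- tiers[tiers$threshold_hi >= 20, ]
    for (i in seq_len(nrow(high))) {
      expect_false(any(epi %in% high$taxa[[i]]))
    }
  }
})
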