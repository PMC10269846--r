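#' Split a meta-community into site subcommunities
#'
#' A subcommunity (local community) is the set of samples of one host at one
#' site. Given a count table and metadata, returns one count-table tibble
#' per site, optionally restricted to a single host.
#'
#' @param x A count table tibble.
#' @param metadata Sample metadata tibble.
#' @param host Optional host label to select.
#' @return A named list of count-table tibbles, one per site.
#' @export
subcommunity_views <- function(x, metadata, host = NULL) {
  validate_count_table(x)
  validate_sample_metadata(metadata, counts = x)
  md <- metadata[match(x$sample_id, metadata$sample_id), ]
  if (!is.null(host)) {
    keep <- md$host == host
    x <- x[keep, , drop = FALSE]
    md <- md[keep, , drop = FALSE]
    if (nrow(x) == 0) abort(paste0("No samples for host ", host))
  }
  split(x, md$site)
}

#' Within-subcommunity core' set
#'
#' The core' (core-prime) members of a local community are the taxa whose
#' occurrence fraction across its samples strictly exceeds the threshold:
#' `{tax_i | occurrence_i / N_samp > thres}`.
#'
#' @param x A count-table tibble for one subcommunity.
#' @param thres Prevalence threshold in `[0, 1)`.
#' @return Character vector of core' taxon ids (table column order).
#' @export
core_prime <- function(x, thres) {
  stopifnot(thres >= 0, thres < 1)
  m <- as_community_matrix(x)
  if (nrow(m) < 1) abort("Subcommunity must contain at least one sample.")
  frac <- colMeans(m > 0)
  names(frac)[frac > thres]
}

#' Meta-community core set
#'
#' A taxon is a core member of the meta-community when it is core' in a
#' fraction of subcommunities strictly greater than the (shared) threshold:
#' `{tax_i | n(tax_i in core'_j) / N_comm > thres}`.
#'
#' @param subs A nonempty list of subcommunity count tables sharing one
#'   taxon universe.
#' @param thres Threshold in `[0, 1)`, used at both levels.
#' @return Character vector of core taxon ids.
#' @export
core_set <- function(subs, thres) {
  if (length(subs) == 0) abort("`subs` must be a nonempty list of subcommunities.")
  occ <- occurrence_fractions(subs)
  core_set_from_occ(occ, thres)
}

occurrence_fractions <- function(subs) {
  taxa <- taxon_ids(subs[[1]])
  occ <- vapply(subs, function(s) {
    stopifnot(identical(taxon_ids(s), taxa))
    colMeans(as_community_matrix(s) > 0)
  }, numeric(length(taxa)))
  t(matrix(occ, nrow = length(taxa), dimnames = list(taxa, NULL)))
}

core_set_from_occ <- function(occ, thres) {
  prime_frac <- colMeans(occ > thres)
  colnames(occ)[prime_frac > thres]
}

#' Bootstrap-simulated subcommunities
#'
#' Pools the meta-community's samples and draws `reps` simulated
#' subcommunities of `n_samples` samples each, uniformly without replacement
#' (with replacement behind `replace = TRUE`); deterministic given `seed`.
#'
#' @param x The pooled meta-community count table.
#' @param n_samples Samples per simulated subcommunity (default 30).
#' @param reps Number of simulated subcommunities (default 100).
#' @param seed Integer seed.
#' @param replace Draw with replacement (default FALSE).
#' @return A list of `reps` count-table tibbles.
#' @export
simulate_subcommunities <- function(x, n_samples = 30, reps = 100, seed,
                                    replace = FALSE) {
  validate_count_table(x)
  if (missing(seed)) abort("`seed` is mandatory.")
  n <- nrow(x)
  if (!replace && n_samples > n) {
    abort("`n_samples` exceeds the number of available samples.")
  }
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    x[sample.int(n, n_samples, replace = replace), , drop = FALSE]
  })
}

#' Jaccard index between taxon sets
#'
#' `|a intersect b| / |a union b|`, with the convention that two empty sets
#' agree perfectly (`J = 1`): at very high prevalence thresholds both the
#' real and the simulated core sets are empty, which counts as agreement,
#' though empty sets never form tiers.
#'
#' @param a,b Character vectors of taxon ids.
#' @return The Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Threshold sweep of real versus simulated core sets
#'
#' For every integer threshold percent 0..99, computes the meta-community
#' core set from the real site subcommunities and from the bootstrap
#' simulated subcommunities (same threshold at both levels of the
#' definition), records their sizes, their cumulative relative abundances in
#' the supplied abundance table, and the Jaccard agreement between them.
#'
#' @param real_subs List of real (site) subcommunity count tables.
#' @param sim_subs List of simulated subcommunity count tables (e.g. from
#'   [simulate_subcommunities()]).
#' @param abundance Meta-community abundance table (typically Hellinger
#'   transformed) used for the cumulative-abundance columns; its grand total
#'   is the denominator, so passing a pooled multi-host table yields pooled
#'   shares.
#' @return A `core_sweep` tibble with columns `threshold` (percent),
#'   `n_core_real`, `abund_real`, `n_core_sim`, `abund_sim`, `jaccard`, and
#'   attributes `core_real`, `core_sim` (lists of taxon-id vectors) and
#'   `taxa` (the taxon universe).
#' @export
threshold_sweep <- function(real_subs, sim_subs, abundance) {
  if (!length(real_subs) || !length(sim_subs)) {
    abort("Both subcommunity lists must be nonempty.")
  }
  occ_real <- occurrence_fractions(real_subs)
  occ_sim <- occurrence_fractions(sim_subs)
  stopifnot(identical(colnames(occ_real), colnames(occ_sim)))
  share <- abundance_share(abundance)
  stopifnot(identical(names(share), colnames(occ_real)))

  thresholds <- 0:99
  core_real <- core_sim <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[i] / 100
    core_real[[i]] <- core_set_from_occ(occ_real, th)
    core_sim[[i]] <- core_set_from_occ(occ_sim, th)
  }
  out <- tibble::tibble(
    threshold = thresholds,
    n_core_real = lengths(core_real),
    abund_real = vapply(core_real, function(s) sum(share[s]), numeric(1)),
    n_core_sim = lengths(core_sim),
    abund_sim = vapply(core_sim, function(s) sum(share[s]), numeric(1)),
    jaccard = mapply(jaccard_index, core_real, core_sim)
  )
  structure(
    out,
    core_real = core_real, core_sim = core_sim,
    taxa = colnames(occ_real),
    class = c("core_sweep", class(out))
  )
}

abundance_share <- function(abundance) {
  am <- as_community_matrix(abundance)
  tot <- colSums(am)
  tot / sum(tot)
}

#' Identify core tiers from a threshold sweep
#'
#' Scanning thresholds from 99% downward, every maximal contiguous run where
#' the real and simulated core sets agree perfectly (`J = 1`), the (shared)
#' set is constant across the run, and the set is nonempty becomes a tier.
#' Tiers are numbered 1, 2, ... from the highest threshold down; a later run
#' that reproduces an already-seen set is merged into that tier's interval
#' record. By the nestedness of strict-threshold core sets, every lower
#' tier's set contains every higher tier's set.
#'
#' @param sweep A `core_sweep` from [threshold_sweep()].
#' @return A `tier_table` tibble with columns `tier`, `threshold_lo`,
#'   `threshold_hi` (bounds of the tier's highest interval), `intervals`
#'   (list of all `[lo, hi]` runs yielding this set), `n_taxa`, `abundance`,
#'   `taxa` (list column); attribute `taxa` carries the universe. Empty
#'   (with a warning) when no threshold qualifies.
#' @export
identify_tiers <- function(sweep) {
  stopifnot(inherits(sweep, "core_sweep"))
  core_real <- attr(sweep, "core_real")
  share <- NULL
  ok <- sweep$jaccard == 1 & sweep$n_core_real > 0
  ord <- order(sweep$threshold, decreasing = TRUE)

  tiers <- list() # each: list(taxa, intervals = list(c(lo, hi)), abundance)
  run_set <- NULL
  run_lo <- run_hi <- NA_integer_
  flush_run <- function() {
    if (is.null(run_set)) return()
    key <- which(vapply(tiers, function(t) setequal(t$taxa, run_set), logical(1)))
    if (length(key)) {
      tiers[[key[1]]]$intervals <<- c(tiers[[key[1]]]$intervals,
                                      list(c(run_lo, run_hi)))
    } else {
      tiers[[length(tiers) + 1]] <<- list(taxa = run_set,
                                          intervals = list(c(run_lo, run_hi)))
    }
    run_set <<- NULL
  }
  for (i in ord) {
    th <- sweep$threshold[i]
    if (!ok[i]) { flush_run(); next }
    set_i <- core_real[[i]]
    if (!is.null(run_set) && setequal(set_i, run_set)) {
      run_lo <- th
    } else {
      flush_run()
      run_set <- set_i
      run_lo <- run_hi <- th
    }
  }
  flush_run()

  if (length(tiers) == 0) {
    warn("No threshold interval with J = 1 and a nonempty core set; no tiers.")
    out <- tibble::tibble(
      tier = integer(), threshold_lo = integer(), threshold_hi = integer(),
      intervals = list(), n_taxa = integer(), abundance = numeric(),
      taxa = list()
    )
  } else {
    abund_at <- function(set) {
      i <- which(vapply(core_real, function(s) setequal(s, set), logical(1)))[1]
      sweep$abund_real[i]
    }
    out <- tibble::tibble(
      tier = seq_along(tiers),
      threshold_lo = vapply(tiers, function(t) t$intervals[[1]][1], numeric(1)),
      threshold_hi = vapply(tiers, function(t) t$intervals[[1]][2], numeric(1)),
      intervals = lapply(tiers, function(t) t$intervals),
      n_taxa = vapply(tiers, function(t) length(t$taxa), integer(1)),
      abundance = vapply(tiers, function(t) abund_at(t$taxa), numeric(1)),
      taxa = lapply(tiers, function(t) t$taxa)
    )
  }
  structure(out, taxa = attr(sweep, "taxa"),
            class = c("tier_table", class(out)))
}

#' Select a tier and partition the taxon universe
#'
#' Chooses the tier whose cumulative relative abundance is closest to
#' `target_abundance` (default 50%, the paper-style working point); exact
#' ties break toward the higher tier (higher thresholds, smaller tier
#' number). Returns the induced two-class partition of the full taxon
#' universe.
#'
#' @param tiers A `tier_table` from [identify_tiers()].
#' @param target_abundance Target cumulative relative abundance in `[0, 1]`
#'   (default 0.5).
#' @return A `core_partition` tibble with columns `taxon_id` and `class`
#'   (`"core"` / `"noncore"`); attributes `tier` (the chosen row) and
#'   `target_abundance`.
#' @export
select_tier <- function(tiers, target_abundance = 0.5) {
  stopifnot(inherits(tiers, "tier_table"))
  if (nrow(tiers) == 0) abort("Empty tier table: no tier to select.")
  gap <- abs(tiers$abundance - target_abundance)
  best <- which(gap == min(gap))
  chosen <- tiers[min(best), ] # smaller tier number = higher threshold
  universe <- attr(tiers, "taxa")
  out <- tibble::tibble(
    taxon_id = universe,
    class = ifelse(universe %in% chosen$taxa[[1]], "core", "noncore")
  )
  structure(out, tier = chosen, target_abundance = target_abundance,
            class = c("core_partition", class(out)))
}
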