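#' Specify a synthetic meta-community
#'
#' Collects the parameters of the synthetic meta-community generator: a host
#' meta-community split into site subcommunities, with a small planted core
#' (high prevalence at every site), a few "epidemic" taxa (high prevalence at
#' a subset of sites only), and a large tail of rare taxa whose per-taxon
#' occupancy is Beta-distributed, reproducing the L-shaped occupancy curve of
#' real endophyte tables. Sequencing depth is negative-binomial to mimic
#' uneven library sizes.
#'
#' @param n_sites Number of site subcommunities (default 5).
#' @param samples_per_site Samples per site (default 30).
#' @param n_core Number of planted core taxa (default 5).
#' @param core_prevalence Per-site presence probability of core taxa
#'   (default 0.9).
#' @param n_epidemic Number of epidemic taxa (default 3).
#' @param epidemic_sites Number of sites where each epidemic taxon is
#'   prevalent (default 1).
#' @param epidemic_prevalence Presence probability of an epidemic taxon in
#'   its home site(s) (default 0.95).
#' @param epidemic_background Presence probability elsewhere (default 0.02).
#' @param n_rare Number of rare taxa (default 200).
#' @param rare_occupancy_mean Mean of the (untruncated) Beta distribution of
#'   per-taxon rare occupancy (default 0.08).
#' @param rare_occupancy_max Upper truncation of rare occupancy (default
#'   0.25): a taxon labelled rare is, by construction, genuinely rare, so
#'   the ground-truth labels stay coherent with realized occupancies.
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters
#'   (mean and size; defaults 5000 and 5), truncated at depth >= 1.
#' @param core_weight,epidemic_weight,rare_weight_meanlog,rare_weight_sdlog
#'   Log-normal abundance weights: core and epidemic taxa have fixed base
#'   weights; rare taxa draw per-taxon weights from
#'   `rlnorm(rare_weight_meanlog, rare_weight_sdlog)`.
#' @param abundance_sdlog Per-sample log-normal noise on conditional
#'   abundances (default 0.5).
#' @param seed Mandatory integer seed.
#' @return A `metacommunity_spec` list.
#' @export
metacommunity_spec <- function(n_sites = 5, samples_per_site = 30,
                               n_core = 5, core_prevalence = 0.9,
                               n_epidemic = 3, epidemic_sites = 1,
                               epidemic_prevalence = 0.95,
                               epidemic_background = 0.02,
                               n_rare = 200, rare_occupancy_mean = 0.08,
                               rare_occupancy_max = 0.25,
                               depth_mean = 5000, depth_dispersion = 5,
                               core_weight = 60, epidemic_weight = 10,
                               rare_weight_meanlog = log(5),
                               rare_weight_sdlog = 1,
                               abundance_sdlog = 0.5,
                               seed) {
  if (missing(seed)) abort("`seed` is mandatory for the generator.")
  spec <- as.list(environment())
  with(spec, {
    stopifnot(n_sites >= 1, samples_per_site >= 1,
              n_core >= 0, n_epidemic >= 0, n_rare >= 0,
              epidemic_sites >= 0, epidemic_sites <= n_sites,
              core_prevalence > 0, core_prevalence <= 1,
              epidemic_prevalence > 0, epidemic_prevalence <= 1,
              rare_occupancy_mean > 0, rare_occupancy_mean < 1,
              rare_occupancy_max > 0, rare_occupancy_max <= 1,
              depth_mean >= 1, depth_dispersion > 0)
  })
  if (spec$n_core + spec$n_epidemic + spec$n_rare == 0) {
    abort("Spec implies zero taxa.")
  }
  structure(spec, class = "metacommunity_spec")
}

#' Simulate a meta-community with planted core, epidemic and rare taxa
#'
#' Draws, per sample, taxon presence as Bernoulli trials at the planted
#' per-site prevalence; conditional on presence, latent abundances are
#' log-normal around per-taxon base weights; integer counts are multinomial
#' at a negative-binomially drawn depth. The generator is a pure function of
#' the spec (including its seed).
#'
#' @param spec A [metacommunity_spec()].
#' @return A list with `counts` (count table tibble), `metadata` (sample
#'   metadata tibble) and `truth` (list: `labels` tibble of taxon_id/label
#'   in core/epidemic/rare, `prevalence` long tibble of planted per-site
#'   prevalences, `weights` per-taxon base abundance weights).
#' @export
simulate_metacommunity <- function(spec) {
  stopifnot(inherits(spec, "metacommunity_spec"))
  set.seed(spec$seed)
  n_taxa <- spec$n_core + spec$n_epidemic + spec$n_rare
  taxa <- c(
    if (spec$n_core) sprintf("core_%02d", seq_len(spec$n_core)),
    if (spec$n_epidemic) sprintf("epi_%02d", seq_len(spec$n_epidemic)),
    if (spec$n_rare) sprintf("rare_%03d", seq_len(spec$n_rare))
  )
  label <- rep(c("core", "epidemic", "rare"),
               c(spec$n_core, spec$n_epidemic, spec$n_rare))

  # per-taxon base abundance weights
  weights <- c(
    rep(spec$core_weight, spec$n_core),
    rep(spec$epidemic_weight, spec$n_epidemic),
    rlnorm(spec$n_rare, spec$rare_weight_meanlog, spec$rare_weight_sdlog)
  )

  # rare occupancy: Beta(a, b) with mean rare_occupancy_mean (L-shaped tail),
  # truncated at rare_occupancy_max by inverse-CDF sampling
  a <- 0.7
  b <- a * (1 - spec$rare_occupancy_mean) / spec$rare_occupancy_mean
  rare_occ <- if (spec$n_rare) {
    u <- runif(spec$n_rare, 0, pbeta(spec$rare_occupancy_max, a, b))
    stats::qbeta(u, a, b)
  } else numeric(0)

  # epidemic home sites, cycled over the site list
  epi_home <- lapply(seq_len(spec$n_epidemic), function(e) {
    ((e - 1 + seq_len(spec$epidemic_sites) - 1) %% spec$n_sites) + 1
  })

  prevalence <- matrix(0, spec$n_sites, n_taxa,
                       dimnames = list(NULL, taxa))
  for (k in seq_len(spec$n_sites)) {
    prev <- numeric(n_taxa)
    prev[label == "core"] <- spec$core_prevalence
    if (spec$n_epidemic) {
      at_home <- vapply(epi_home, function(h) k %in% h, logical(1))
      prev[label == "epidemic"] <- ifelse(at_home, spec$epidemic_prevalence,
                                          spec$epidemic_background)
    }
    prev[label == "rare"] <- rare_occ
    prevalence[k, ] <- prev
  }

  n_samples <- spec$n_sites * spec$samples_per_site
  depth <- rnbinom(n_samples, size = spec$depth_dispersion, mu = spec$depth_mean)
  depth <- pmax(depth, 1)

  counts <- matrix(0L, n_samples, n_taxa)
  site_of <- rep(seq_len(spec$n_sites), each = spec$samples_per_site)
  for (s in seq_len(n_samples)) {
    prev <- prevalence[site_of[s], ]
    present <- runif(n_taxa) < prev
    latent <- numeric(n_taxa)
    if (any(present)) {
      latent[present] <- rlnorm(sum(present), log(weights[present]),
                                spec$abundance_sdlog)
    } else {
      latent[which.max(weights)] <- 1
    }
    counts[s, ] <- rmultinom(1, depth[s], latent)[, 1]
  }
  sample_ids <- sprintf("site%d_s%02d", site_of,
                        rep(seq_len(spec$samples_per_site), spec$n_sites))
  dimnames(counts) <- list(sample_ids, taxa)

  metadata <- tibble::tibble(
    sample_id = sample_ids,
    host = "hostA",
    site = sprintf("site%d", site_of),
    latitude = 31.5 + site_of * 0.45,
    longitude = 34.8 + site_of * 0.25
  )
  truth <- list(
    labels = tibble::tibble(taxon_id = taxa, label = label),
    prevalence = tibble::tibble(
      taxon_id = rep(taxa, each = spec$n_sites),
      site = rep(sprintf("site%d", seq_len(spec$n_sites)), n_taxa),
      prevalence = as.numeric(prevalence)
    ),
    weights = setNames(weights, taxa)
  )
  list(counts = as_community_tibble(counts), metadata = metadata, truth = truth)
}

#' Simulate a neutrally assembled community
#'
#' Inverts the Sloan neutral model's sampling distribution: for each sample
#' and taxon `i`, the per-sample relative abundance is drawn from
#' `Beta(N*m*p_i, N*m*(1-p_i))` where `p_i` is the source (meta-community)
#' relative abundance and `N = n_reads`, `m` the migration probability.
#' Detection follows the model's detection limit `d = 1/n_reads`: a
#' proportion at or below `d` is undetected (count 0), a proportion above
#' `d` yields a nonzero Binomial(`n_reads`, proportion) count. The
#' occurrence frequency of taxon `i` across samples therefore converges
#' (large `n_samples`) to `1 - pbeta(1/n_reads, N*m*p_i, N*m*(1-p_i))`,
#' exactly the curve the model fit expects.
#'
#' @param m Migration probability in (0, 1).
#' @param n_reads Reads per sample (also the community size `N`).
#' @param source_abundances Strictly positive vector summing to 1.
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed.
#' @return A count table tibble (`n_samples` rows).
#' @export
simulate_ncm_community <- function(m, n_reads, source_abundances, n_samples, seed) {
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m >= 1) {
    abort("`m` must lie strictly within (0, 1).")
  }
  p <- source_abundances
  if (any(p <= 0)) abort("`source_abundances` must be strictly positive.")
  p <- p / sum(p)
  set.seed(seed)
  Nm <- n_reads * m
  d <- 1 / n_reads
  n_taxa <- length(p)
  counts <- matrix(0L, n_samples, n_taxa)
  for (s in seq_len(n_samples)) {
    prop <- rbeta(n_taxa, Nm * p, Nm * (1 - p))
    detected <- prop > d
    counts[s, detected] <- pmax(1L, rbinom(sum(detected), n_reads, prop[detected]))
  }
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n_samples)),
                           sprintf("tax_%04d", seq_len(n_taxa)))
  as_community_tibble(counts)
}

#' Simulate universal- or independent-dynamics compositions
#'
#' Generates relative-abundance tables for dissimilarity-overlap analysis.
#' In the `universal` regime all samples are noisy views of one shared
#' composition: each sample carries a random subset of taxa at the shared
#' relative proportions, and samples carrying more of the shared community
#' (higher overlap with it, hence with each other) are perturbed less — so
#' pairs at high overlap are also more similar, the signature of universal
#' dynamics. In the `independent` regime each sample's composition is drawn
#' independently and no such coupling exists.
#'
#' @param regime `"universal"` or `"independent"`.
#' @param n_samples,n_taxa Table dimensions (`n_taxa >= 10`).
#' @param noise Multiplicative log-scale noise amplitude (default 0.6).
#' @param seed Integer seed.
#' @return An abundance table tibble whose rows sum to 1.
#' @export
simulate_doc_regimes <- function(regime = c("universal", "independent"),
                                 n_samples = 60, n_taxa = 80, noise = 0.6,
                                 seed = 1) {
  regime <- rlang::arg_match(regime)
  if (n_taxa < 10) abort("`n_taxa` must be at least 10.")
  set.seed(seed)
  vals <- matrix(0, n_samples, n_taxa)
  if (regime == "universal") {
    g <- rlnorm(n_taxa, 0, 1)
    g <- g / sum(g)
    richness <- runif(n_samples, 0.5, 1)
    for (s in seq_len(n_samples)) {
      present <- runif(n_taxa) < richness[s]
      if (!any(present)) present[which.max(g)] <- TRUE
      eta <- noise * (1 - richness[s])
      v <- g[present] * exp(eta * rnorm(sum(present)))
      vals[s, present] <- v / sum(v)
    }
  } else {
    for (s in seq_len(n_samples)) {
      present <- runif(n_taxa) < 0.75
      if (!any(present)) present[1] <- TRUE
      v <- rlnorm(sum(present), 0, 1)
      vals[s, present] <- v / sum(v)
    }
  }
  dimnames(vals) <- list(sprintf("s%03d", seq_len(n_samples)),
                         sprintf("tax_%04d", seq_len(n_taxa)))
  as_community_tibble(vals)
}

#' Plant correlated taxon pairs into a count table
#'
#' Rewrites the second member of each pair as a monotone (sign `"+"`) or
#' anti-monotone (sign `"-"`) noisy integer function of the first across
#' samples, leaving all other columns untouched; a fixture builder for
#' co-occurrence network recovery.
#'
#' @param x A count table tibble.
#' @param pairs A data frame with columns `taxon_a`, `taxon_b`, `sign`
#'   (`"+"` or `"-"`).
#' @param noise Noise standard deviation as a fraction of `sd(taxon_a)`
#'   (default 0).
#' @param seed Integer seed.
#' @return The modified count table.
#' @export
plant_correlated_pairs <- function(x, pairs, noise = 0, seed = 1) {
  validate_count_table(x)
  m <- as_community_matrix(x)
  missing_taxa <- setdiff(c(pairs$taxon_a, pairs$taxon_b), colnames(m))
  if (length(missing_taxa)) {
    abort(paste0("Pair references missing taxon/taxa: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  set.seed(seed)
  for (i in seq_len(nrow(pairs))) {
    a <- m[, pairs$taxon_a[i]]
    base <- if (pairs$sign[i] == "-") max(a) - a else a
    eps <- if (noise > 0) rnorm(length(a), 0, noise * max(sd(a), 1)) else 0
    m[, pairs$taxon_b[i]] <- pmax(0, round(base + eps))
  }
  as_community_tibble(m)
}
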