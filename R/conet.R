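#' Spearman co-occurrence network of one subcommunity
#'
#' Computes Spearman's rho (average-rank ties) between every taxon pair
#' across samples and keeps an edge when `|rho| > rho_min` and the two-sided
#' p-value `< p_max`, both strict, with raw (uncorrected) p-values. P-values
#' use the exact null distribution (via [stats::cor.test()]) when the
#' subcommunity has 9 or fewer samples and the t approximation otherwise.
#' Taxa with constant abundance (including all-zero taxa) are dropped before
#' correlation and counted.
#'
#' @param x A community tibble (abundances) for one subcommunity; at least
#'   5 samples and 2 taxa.
#' @param rho_min Absolute-correlation threshold, exclusive (default 0.8).
#' @param p_max P-value threshold, exclusive (default 0.001).
#' @return A `taxa_network`: list with `edges` (tibble `taxon_a`, `taxon_b`,
#'   `rho`, `p`), `taxa` (the full taxon universe of `x`), `n_samples`,
#'   `n_constant` (taxa dropped as constant).
#' @export
spearman_network <- function(x, rho_min = 0.8, p_max = 0.001) {
  m <- as_community_matrix(x)
  n <- nrow(m)
  if (n < 5) abort("Co-occurrence network needs at least 5 samples.")
  if (ncol(m) < 2) abort("Co-occurrence network needs at least 2 taxa.")
  universe <- colnames(m)
  keep <- apply(m, 2, function(v) length(unique(v)) > 1)
  n_constant <- sum(!keep)
  m <- m[, keep, drop = FALSE]
  edges <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                          rho = numeric(), p = numeric())
  if (ncol(m) >= 2) {
    ranks <- apply(m, 2, rank)
    rho <- suppressWarnings(cor(ranks))
    idx <- which(upper.tri(rho) & abs(rho) > rho_min, arr.ind = TRUE)
    if (nrow(idx)) {
      r <- rho[idx]
      if (n <= 9) {
        p <- vapply(seq_len(nrow(idx)), function(k) {
          suppressWarnings(cor.test(m[, idx[k, 1]], m[, idx[k, 2]],
                                    method = "spearman",
                                    exact = TRUE)$p.value)
        }, numeric(1))
      } else {
        tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
        p <- 2 * pt(-abs(tval), df = n - 2)
        p[abs(r) >= 1] <- 0
      }
      sel <- p < p_max
      edges <- tibble::tibble(
        taxon_a = colnames(m)[idx[sel, 1]],
        taxon_b = colnames(m)[idx[sel, 2]],
        rho = r[sel], p = p[sel]
      )
    }
  }
  structure(list(edges = edges, taxa = universe, n_samples = n,
                 n_constant = n_constant),
            class = "taxa_network")
}

#' Combine co-occurrence networks by edge frequency
#'
#' Counts, for each unordered taxon pair, how many source networks contain
#' that edge, and keeps edges whose frequency is strictly greater than
#' `min_freq` ("present in more than `min_freq` subcommunities"). The full
#' pre-cut edge-frequency histogram is kept as an attribute.
#'
#' @param nets A nonempty list of `taxa_network`s over a common universe.
#' @param min_freq Frequency cut, exclusive (default 20).
#' @return A `combined_network`: list with `edges` (tibble `taxon_a`,
#'   `taxon_b`, `frequency`), `taxa`, `n_networks`, and `histogram` (tibble
#'   `frequency`, `n_edges` over all observed edges before the cut).
#' @export
combine_networks <- function(nets, min_freq = 20) {
  if (!length(nets)) abort("`nets` must be a nonempty list.")
  universe <- nets[[1]]$taxa
  keys <- unlist(lapply(nets, function(nw) {
    if (!identical(nw$taxa, universe)) {
      abort("All networks must share one taxon universe.")
    }
    e <- nw$edges
    if (!nrow(e)) return(character(0))
    paste(pmin(e$taxon_a, e$taxon_b), pmax(e$taxon_a, e$taxon_b), sep = "\r")
  }))
  freq <- table(keys)
  histogram <- if (length(freq)) {
    tibble::as_tibble(table(frequency = as.integer(freq)), n = "n_edges") |>
      dplyr::mutate(frequency = as.integer(.data$frequency))
  } else {
    tibble::tibble(frequency = integer(), n_edges = integer())
  }
  kept <- freq[freq > min_freq]
  parts <- strsplit(names(kept), "\r", fixed = TRUE)
  edges <- tibble::tibble(
    taxon_a = vapply(parts, `[`, character(1), 1),
    taxon_b = vapply(parts, `[`, character(1), 2),
    frequency = as.integer(kept)
  )
  structure(list(edges = edges, taxa = universe, n_networks = length(nets),
                 histogram = histogram),
            class = "combined_network")
}

#' Convert a taxa network to an igraph graph
#'
#' @param x A `taxa_network` or `combined_network` (igraph objects pass
#'   through).
#' @param include_isolated Keep taxa without edges as isolated vertices
#'   (default TRUE).
#' @return An undirected simple igraph graph.
#' @export
net_as_igraph <- function(x, include_isolated = TRUE) {
  if (igraph::is_igraph(x)) return(x)
  stopifnot(inherits(x, c("taxa_network", "combined_network")))
  verts <- if (include_isolated) x$taxa else unique(c(x$edges$taxon_a, x$edges$taxon_b))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Node centralities
#'
#' Degree, closeness and betweenness for every vertex. Closeness is computed
#' within each vertex's connected component and scaled by the component's
#' share of the graph (the Wasserman-Faust correction):
#' `((c-1)/sum_d) * ((c-1)/(N-1))` for component size `c`; isolated vertices
#' get closeness 0. Betweenness is Brandes shortest-path betweenness with
#' fractional splitting over tied geodesics.
#'
#' @param net A `taxa_network`, `combined_network` or igraph graph.
#' @return A tibble with `taxon_id`, `degree`, `closeness`, `betweenness`.
#' @export
node_metrics <- function(net) {
  g <- net_as_igraph(net)
  N <- igraph::vcount(g)
  comp <- igraph::components(g)
  dm <- igraph::distances(g)
  clo <- vapply(seq_len(N), function(v) {
    members <- which(comp$membership == comp$membership[v])
    c_size <- length(members)
    if (c_size < 2) return(0)
    sum_d <- sum(dm[v, members])
    ((c_size - 1) / sum_d) * ((c_size - 1) / max(N - 1, 1))
  }, numeric(1))
  tibble::tibble(
    taxon_id = igraph::V(g)$name %||% as.character(seq_len(N)),
    degree = as.integer(igraph::degree(g)),
    closeness = clo,
    betweenness = unname(igraph::betweenness(g, directed = FALSE))
  )
}

# per-node shortest-path-length distributions: bins 1..N where j < N counts
# nodes at distance j and bin N collects unreachable nodes; rows sum to 1.
node_distance_distributions <- function(g) {
  N <- igraph::vcount(g)
  dm <- igraph::distances(g)
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    di <- dm[i, -i]
    di[is.infinite(di)] <- N
    P[i, ] <- tabulate(di, nbins = N) / (N - 1)
  }
  P
}

# generalized Jensen-Shannon divergence (natural log) of distribution rows
js_rows <- function(P) {
  mu <- colMeans(P)
  tot <- 0
  for (i in seq_len(nrow(P))) {
    pos <- P[i, ] > 0
    tot <- tot + sum(P[i, pos] * log(P[i, pos] / mu[pos]))
  }
  tot / nrow(P)
}

js_two <- function(p, q) {
  len <- max(length(p), length(q))
  p <- c(p, rep(0, len - length(p)))
  q <- c(q, rep(0, len - length(q)))
  js_rows(rbind(p, q))
}

# network node dispersion: JS divergence among the node-distance
# distributions, normalized by log(diameter + 1)
network_node_dispersion <- function(g) {
  P <- node_distance_distributions(g)
  dm <- igraph::distances(g)
  finite <- dm[is.finite(dm)]
  diam <- max(finite)
  if (diam < 1) return(list(nnd = 0, mu = colMeans(P)))
  list(nnd = js_rows(P) / log(diam + 1), mu = colMeans(P))
}

# sorted alpha-centrality distribution of g (alpha = 1/N, exogenous term
# degree/(N-1)), scaled by N^2 with the remaining mass appended
alpha_centrality_distribution <- function(g) {
  N <- igraph::vcount(g)
  r <- igraph::alpha_centrality(g, alpha = 1 / N,
                                exo = igraph::degree(g) / (N - 1))
  r <- sort(r) / N^2
  c(r, max(0, 1 - sum(r)))
}

#' Weighted graph dissimilarity (D-measure)
#'
#' Three-term structural dissimilarity between two simple undirected graphs:
#' `D = w1 * sqrt(JS(mu1, mu2)/log 2)
#'    + w2 * |sqrt(NND(g1)) - sqrt(NND(g2))|
#'    + (w3/2) * (sqrt(JS(Pa(g1), Pa(g2))/log 2) +
#'                sqrt(JS(Pa(comp(g1)), Pa(comp(g2)))/log 2))`,
#' where `mu` is the graph's mean node-distance distribution (with a
#' dedicated bin for unreachable pairs), `NND` the network node dispersion
#' (Jensen-Shannon divergence of the node-distance distributions normalized
#' by `log(diameter + 1)`), and `Pa` the sorted alpha-centrality
#' distribution of a graph (`comp` = graph complement). Distributions of
#' graphs of unequal order are zero-padded at the tail. `D` is symmetric,
#' zero for identical graphs, and bounded by 1 when the weights sum to 1.
#'
#' @param g1,g2 igraph graphs (or `taxa_network`s), each with at least two
#'   vertices.
#' @param w Numeric weights `(w1, w2, w3)`, nonnegative, summing to 1;
#'   default `c(0.45, 0.45, 0.10)`.
#' @return The dissimilarity, a single number in `[0, 1]`.
#' @export
graph_dissimilarity <- function(g1, g2, w = c(0.45, 0.45, 0.10)) {
  stopifnot(length(w) == 3, all(w >= 0), abs(sum(w) - 1) < 1e-9)
  g1 <- net_as_igraph(g1)
  g2 <- net_as_igraph(g2)
  if (igraph::vcount(g1) < 2 || igraph::vcount(g2) < 2) {
    abort("Both graphs need at least two vertices.")
  }
  n1 <- network_node_dispersion(g1)
  n2 <- network_node_dispersion(g2)
  term1 <- sqrt(js_two(n1$mu, n2$mu) / log(2))
  term2 <- abs(sqrt(n1$nnd) - sqrt(n2$nnd))
  term3 <- 0
  if (w[3] > 0) {
    pa1 <- alpha_centrality_distribution(g1)
    pa2 <- alpha_centrality_distribution(g2)
    pc1 <- alpha_centrality_distribution(igraph::complementer(g1))
    pc2 <- alpha_centrality_distribution(igraph::complementer(g2))
    term3 <- sqrt(js_two(pa1, pa2) / log(2)) + sqrt(js_two(pc1, pc2) / log(2))
  }
  w[1] * term1 + w[2] * term2 + w[3] / 2 * term3
}

#' Ordinate a set of networks by pairwise D-measure
#'
#' Computes the pairwise [graph_dissimilarity()] matrix over a list of
#' networks and ordinates it with [nmds_ordinate()]. Lists of effectively
#' identical graphs (all distances ~0) are flagged as degenerate and
#' returned as an all-zero configuration.
#'
#' @param nets A list of at least 4 networks (igraph or `taxa_network`).
#' @param w D-measure weights (default `c(0.45, 0.45, 0.10)`).
#' @param seed Integer seed for the NMDS restarts.
#' @param k Ordination dimensionality (default 2).
#' @return An `nmds_ordination` with the D matrix attached as attribute
#'   `distances`.
#' @export
network_ordination <- function(nets, w = c(0.45, 0.45, 0.10), seed = 1, k = 2) {
  if (length(nets) < 4) abort("Need at least 4 networks to ordinate.")
  n <- length(nets)
  ids <- names(nets) %||% sprintf("net%02d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- graph_dissimilarity(nets[[i]], nets[[j]], w)
  }
  if (max(D) < 1e-12) {
    warn("All pairwise network dissimilarities are zero; ordination is degenerate.")
    ord <- structure(
      list(coordinates = dplyr::bind_cols(
             tibble::tibble(sample_id = ids),
             tibble::as_tibble(matrix(0, n, k, dimnames = list(NULL, paste0("axis", seq_len(k)))))),
           stress = 0, k = k, n_restarts = 0, seed = seed, converged = NA),
      class = "nmds_ordination"
    )
  } else {
    ord <- nmds_ordinate(D, k = k, seed = seed)
  }
  attr(ord, "distances") <- D
  ord
}

#' @export
print.taxa_network <- function(x, ...) {
  cat("Spearman co-occurrence network: ", length(x$taxa), " taxa, ",
      nrow(x$edges), " edges (", x$n_samples, " samples, ",
      x$n_constant, " constant taxa dropped)\n", sep = "")
  invisible(x)
}

#' @export
print.combined_network <- function(x, ...) {
  cat("Combined co-occurrence network: ", length(x$taxa), " taxa, ",
      nrow(x$edges), " edges kept from ", x$n_networks, " source networks\n",
      sep = "")
  invisible(x)
}
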