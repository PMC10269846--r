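# Independent brute-force oracles used to validate the package's own
# implementations. Everything here is written from the definitions, without
# reusing package internals.

# random small count table
random_count_table <- function(n_samples, n_taxa, lambda = 4, seed = 1,
                               prefix = "tax") {
  set.seed(seed)
  m <- matrix(as.numeric(rpois(n_samples * n_taxa, lambda)), n_samples, n_taxa)
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("%s%02d", prefix, seq_len(n_taxa)))
  as_community_tibble(m)
}

# Bray-Curtis from the definition
bf_bray_curtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}

# haversine great-circle distance (km), IUGG mean Earth radius
bf_haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# two-level core definition, exhaustive double loop over taxa and
# subcommunities (strict > at both levels)
bf_core_set <- function(subs, thres) {
  taxa <- names(subs[[1]])[-1]
  core <- character(0)
  for (tx in taxa) {
    n_prime <- 0L
    for (s in subs) {
      v <- s[[tx]]
      if (sum(v > 0) / length(v) > thres) n_prime <- n_prime + 1L
    }
    if (n_prime / length(subs) > thres) core <- c(core, tx)
  }
  core
}

# Spearman edges from the definition: average ranks, strict cuts,
# t-approximation p-value (n > 9), exact for small n via cor.test
bf_spearman_edges <- function(m, rho_min = 0.8, p_max = 0.001) {
  keep <- apply(m, 2, function(v) length(unique(v)) > 1)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  out <- list()
  cols <- colnames(m)
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    rx <- rank(m[, i]); ry <- rank(m[, j])
    r <- cor(rx, ry)
    if (!is.finite(r) || abs(r) <= rho_min) next
    if (n <= 9) {
      p <- suppressWarnings(cor.test(m[, i], m[, j], method = "spearman",
                                     exact = TRUE)$p.value)
    } else if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
    if (p < p_max) {
      out[[length(out) + 1]] <- data.frame(taxon_a = cols[i], taxon_b = cols[j],
                                           rho = r, p = p)
    }
  }
  if (!length(out)) {
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      rho = numeric(), p = numeric()))
  }
  do.call(rbind, out)
}

# rJSD from the definition (log base 2) for two positive compositions
bf_rjsd <- function(p, q) {
  mid <- (p + q) / 2
  kl <- function(a, b) sum(a * log2(a / b))
  sqrt(0.5 * kl(p, mid) + 0.5 * kl(q, mid))
}

# dissimilarity-overlap points from the definition
bf_doc_points <- function(m) {
  m <- m / rowSums(m)
  out <- list()
  n <- nrow(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- m[i, ] > 0 & m[j, ] > 0
    if (!any(shared)) next
    x <- m[i, shared]; y <- m[j, shared]
    out[[length(out) + 1]] <- data.frame(
      id_a = rownames(m)[i], id_b = rownames(m)[j],
      overlap = sum(x + y) / 2,
      dissimilarity = bf_rjsd(x / sum(x), y / sum(y))
    )
  }
  do.call(rbind, out)
}

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
bf_fw <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- D[i, k] + D[k, ]
    upd <- nd < D[i, ]
    D[i, upd] <- nd[upd]
  }
  D
}

# geodesic counts from s: sigma[u] = number of shortest s-u paths
bf_geodesic_counts <- function(A, D, s) {
  n <- nrow(A)
  sigma <- numeric(n)
  sigma[s] <- 1
  for (dist in seq_len(max(D[s, is.finite(D[s, ])]))) {
    for (u in which(D[s, ] == dist)) {
      preds <- which(A[, u] > 0 & D[s, ] == dist - 1)
      sigma[u] <- sum(sigma[preds])
    }
  }
  sigma
}

# shortest-path betweenness by direct enumeration of geodesic counts
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_fw(A)
  sig <- lapply(seq_len(n), function(s) bf_geodesic_counts(A, D, s))
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + sig[[s]][v] * sig[[v]][t] / sig[[s]][t]
      }
    }
    btw[v] <- tot
  }
  btw
}

# component-corrected closeness from the definition
bf_closeness <- function(A) {
  n <- nrow(A)
  D <- bf_fw(A)
  vapply(seq_len(n), function(v) {
    members <- which(is.finite(D[v, ]))
    cs <- length(members)
    if (cs < 2) return(0)
    ((cs - 1) / sum(D[v, members])) * ((cs - 1) / (n - 1))
  }, numeric(1))
}

# independent transcription of the three-term graph dissimilarity, built on
# Floyd-Warshall distances and a direct linear solve for alpha centrality
d_measure_ref <- function(A1, A2, w = c(0.45, 0.45, 0.10)) {
  ndd <- function(A) {
    n <- nrow(A)
    D <- bf_fw(A)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      di <- D[i, -i]
      di[is.infinite(di)] <- n
      for (j in di) P[i, j] <- P[i, j] + 1
      P[i, ] <- P[i, ] / (n - 1)
    }
    P
  }
  jsr <- function(P) {
    mu <- colMeans(P)
    tot <- 0
    for (i in seq_len(nrow(P))) {
      pos <- P[i, ] > 0
      tot <- tot + sum(P[i, pos] * log(P[i, pos] / mu[pos]))
    }
    tot / nrow(P)
  }
  js2 <- function(p, q) {
    L <- max(length(p), length(q))
    p <- c(p, rep(0, L - length(p)))
    q <- c(q, rep(0, L - length(q)))
    jsr(rbind(p, q))
  }
  nnd <- function(A) {
    P <- ndd(A)
    D <- bf_fw(A)
    dm <- max(D[is.finite(D)])
    list(nnd = if (dm < 1) 0 else jsr(P) / log(dm + 1), mu = colMeans(P))
  }
  acd <- function(A) {
    n <- nrow(A)
    alpha <- 1 / n
    ex <- rowSums(A) / (n - 1)
    x <- solve(diag(n) - alpha * t(A), ex)
    r <- sort(x) / n^2
    c(r, max(0, 1 - sum(r)))
  }
  comp <- function(A) {
    C <- 1 - A
    diag(C) <- 0
    C
  }
  n1 <- nnd(A1); n2 <- nnd(A2)
  t1 <- sqrt(js2(n1$mu, n2$mu) / log(2))
  t2 <- abs(sqrt(n1$nnd) - sqrt(n2$nnd))
  t3 <- sqrt(js2(acd(A1), acd(A2)) / log(2)) +
    sqrt(js2(acd(comp(A1)), acd(comp(A2))) / log(2))
  w[1] * t1 + w[2] * t2 + w[3] / 2 * t3
}

# small named graph fixtures for the dissimilarity tests
graph_fixtures <- function() {
  set.seed(42)
  list(
    path4 = igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE),
    star4 = igraph::make_star(4, mode = "undirected"),
    cycle5 = igraph::make_ring(5),
    full5 = igraph::make_full_graph(5),
    bull = igraph::make_graph("Bull"),
    two_comp = igraph::make_graph(c(1, 2, 2, 3, 4, 5), directed = FALSE),
    gnp8a = igraph::sample_gnp(8, 0.4),
    gnp8b = igraph::sample_gnp(8, 0.6)
  )
}
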