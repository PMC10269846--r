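test_that("planted monotone pairs produce rho = +/-1 edges", {
  tb <- random_count_table(30, 8, lambda = 30, seed = 2)
  pairs <- data.frame(taxon_a = c("tax01", "tax03"),
                      taxon_b = c("tax02", "tax04"),
                      sign = c("+", "-"))
  planted <- plant_correlated_pairs(tb, pairs)
  net <- spearman_network(planted)
  key <- paste(pmin(net$edges$taxon_a, net$edges$taxon_b),
               pmax(net$edges$taxon_a, net$edges$taxon_b))
  expect_true("tax01 tax02" %in% key)
  expect_true("tax03 tax04" %in% key)
  expect_equal(net$edges$rho[key == "tax01 tax02"], 1)
  expect_equal(net$edges$rho[key == "tax03 tax04"], -1)
  expect_true(all(net$edges$p[key %in% c("tax01 tax02", "tax03 tax04")] < 1e-12))
})

test_that("the |rho| cut is strict at the boundary", {
  # ranks chosen so Spearman's rho is exactly 0.8
  tb <- tibble::tibble(sample_id = sprintf("s%d", 1:5),
                       a = c(10, 20, 30, 40, 50),
                       b = c(1, 3, 2, 5, 4) * 10)
  expect_equal(cor(rank(tb$a), rank(tb$b)), 0.8)
  net <- spearman_network(tb, rho_min = 0.8, p_max = 1)
  expect_identical(nrow(net$edges), 0L)
  net2 <- spearman_network(tb, rho_min = 0.79, p_max = 1)
  expect_identical(nrow(net2$edges), 1L)
})

test_that("the p-value cut is strict at the boundary", {
  set.seed(13)
  n <- 20
  a <- rnorm(n)
  b <- rank(a) + rnorm(n, 0, 2.2)
  tb <- tibble::tibble(sample_id = sprintf("s%d", 1:n), a = a, b = b)
  r <- cor(rank(a), rank(b))
  expect_gt(abs(r), 0.5) # deterministic fixture; guards the cut below
  expect_lt(abs(r), 1)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p_exact <- 2 * pt(-abs(tval), df = n - 2)
  at_boundary <- spearman_network(tb, rho_min = 0.5, p_max = p_exact)
  expect_identical(nrow(at_boundary$edges), 0L) # p == p_max excluded
  above <- spearman_network(tb, rho_min = 0.5, p_max = p_exact * 1.0001)
  expect_identical(nrow(above$edges), 1L)
  expect_equal(above$edges$p, p_exact, tolerance = 1e-12)
})

test_that("retained edges match the brute-force all-pairs oracle", {
  set.seed(29)
  tb <- random_count_table(30, 12, lambda = 15, seed = 29)
  # mix in some correlated structure so edges exist
  m <- as_community_matrix(tb)
  m[, 2] <- m[, 1] + rpois(30, 2)
  m[, 7] <- pmax(0, 60 - m[, 6] + rpois(30, 1))
  tb <- as_community_tibble(m)
  net <- spearman_network(tb, rho_min = 0.6, p_max = 0.01)
  ref <- bf_spearman_edges(m, rho_min = 0.6, p_max = 0.01)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(net$edges$taxon_a, net$edges$taxon_b),
                  key(ref$taxon_a, ref$taxon_b))
  ord <- order(net$edges$taxon_a, net$edges$taxon_b)
  ord_ref <- order(ref$taxon_a, ref$taxon_b)
  expect_equal(net$edges$rho[ord], ref$rho[ord_ref], tolerance = 1e-12)
  expect_equal(net$edges$p[ord], ref$p[ord_ref], tolerance = 1e-12)
})

test_that("small subcommunities use the exact permutation p-value", {
  tb <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                       a = c(1, 2, 3, 4, 5, 6),
                       b = c(2, 4, 6, 8, 10, 12))
  net <- spearman_network(tb, rho_min = 0.8, p_max = 0.01)
  p_ref <- suppressWarnings(cor.test(tb$a, tb$b, method = "spearman",
                                     exact = TRUE)$p.value)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$p, p_ref)
})

test_that("constant taxa are dropped and counted before correlation", {
  tb <- tibble::tibble(sample_id = sprintf("s%d", 1:10),
                       a = 1:10, b = 10:1, flat = rep(3, 10),
                       zero = rep(0, 10))
  net <- spearman_network(tb)
  expect_identical(net$n_constant, 2L)
  expect_setequal(net$taxa, c("a", "b", "flat", "zero")) # universe intact
  expect_identical(nrow(net$edges), 1L)
})

test_that("combine_networks keeps edges strictly above the frequency cut", {
  universe <- c("x", "y", "z")
  make_net <- function(edges) {
    structure(list(edges = edges, taxa = universe, n_samples = 30,
                   n_constant = 0L), class = "taxa_network")
  }
  edge_xy <- tibble::tibble(taxon_a = "x", taxon_b = "y", rho = 1, p = 0)
  edge_yz <- tibble::tibble(taxon_a = "z", taxon_b = "y", rho = -1, p = 0)
  none <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                         rho = numeric(), p = numeric())
  # xy in 25 of 100 nets, yz in exactly 20, nothing else
  nets <- c(
    lapply(1:20, function(i) make_net(dplyr::bind_rows(edge_xy, edge_yz))),
    lapply(1:5, function(i) make_net(edge_xy)),
    lapply(1:75, function(i) make_net(none))
  )
  comb <- combine_networks(nets, min_freq = 20)
  expect_identical(nrow(comb$edges), 1L)
  expect_identical(comb$edges$taxon_a, "x")
  expect_identical(comb$edges$frequency, 25L)
  expect_identical(comb$n_networks, 100L)
  # the pre-cut histogram still sees both edges
  expect_setequal(comb$histogram$frequency, c(20L, 25L))
  expect_true(all(comb$histogram$n_edges == 1L))
  # at min_freq 19 the 20-frequency edge enters (strictly greater than)
  comb19 <- combine_networks(nets, min_freq = 19)
  expect_identical(nrow(comb19$edges), 2L)
  expect_error(combine_networks(list()), "nonempty")
})

test_that("node metrics match brute-force centralities on small graphs", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- sprintf("v%d", 1:6)
  met <- node_metrics(star)
  expect_identical(met$degree[1], 5L)
  expect_true(all(met$degree[-1] == 1L))
  expect_equal(met$betweenness[1], choose(5, 2))
  expect_true(all(met$betweenness[-1] == 0))
  expect_equal(met$closeness[1], 1) # center: distance 1 to all, full component

  set.seed(33)
  g <- igraph::sample_gnp(12, 0.3)
  igraph::V(g)$name <- sprintf("n%02d", 1:12)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  met2 <- node_metrics(g)
  expect_equal(met2$betweenness, bf_betweenness(A), tolerance = 1e-9)
  expect_equal(met2$closeness, bf_closeness(A), tolerance = 1e-12)
  expect_equal(met2$degree, as.integer(rowSums(A)))
})

test_that("isolated vertices get zero closeness and betweenness", {
  net <- structure(list(
    edges = tibble::tibble(taxon_a = "a", taxon_b = "b", rho = 1, p = 0),
    taxa = c("a", "b", "lonely"), n_samples = 30, n_constant = 0L
  ), class = "taxa_network")
  met <- node_metrics(net)
  lonely <- met[met$taxon_id == "lonely", ]
  expect_identical(lonely$degree, 0L)
  expect_identical(lonely$closeness, 0)
  expect_identical(lonely$betweenness, 0)
  # connected pair: closeness carries the component-share correction (1/2)
  expect_equal(met$closeness[met$taxon_id == "a"], 1 * (1 / 2))
})

test_that("independent taxa essentially never produce combined edges", {
  spurious <- vapply(1:100, function(seed) {
    set.seed(seed)
    m <- matrix(rpois(30 * 50, 10), 30, 50)
    dimnames(m) <- list(sprintf("s%02d", 1:30), sprintf("t%02d", 1:50))
    nrow(spearman_network(as_community_tibble(m))$edges)
  }, numeric(1))
  expect_gte(mean(spurious <= 1), 0.95)
})

test_that("graph dissimilarity is zero on identity, symmetric, and bounded", {
  gs <- graph_fixtures()
  for (g in gs) {
    expect_equal(graph_dissimilarity(g, g), 0, tolerance = 1e-12)
  }
  set.seed(8)
  picks <- t(combn(length(gs), 2))
  for (r in seq_len(nrow(picks))) {
    g1 <- gs[[picks[r, 1]]]
    g2 <- gs[[picks[r, 2]]]
    d12 <- graph_dissimilarity(g1, g2)
    d21 <- graph_dissimilarity(g2, g1)
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_gte(d12, 0)
    expect_lte(d12, 1)
  }
  expect_gt(graph_dissimilarity(gs$path4, gs$star4), 0)
})

test_that("graph dissimilarity matches an independent transcription", {
  gs <- graph_fixtures()
  adj <- lapply(gs, function(g) as.matrix(igraph::as_adjacency_matrix(g)))
  picks <- t(combn(length(gs), 2))
  for (r in seq_len(nrow(picks))) {
    i <- picks[r, 1]; j <- picks[r, 2]
    expect_equal(graph_dissimilarity(gs[[i]], gs[[j]]),
                 d_measure_ref(adj[[i]], adj[[j]]), tolerance = 1e-9)
  }
  expect_error(graph_dissimilarity(gs$path4, gs$star4, w = c(1, 1, 1)))
})

test_that("network ordination separates graph families and flags degeneracy", {
  set.seed(19)
  dense <- lapply(1:4, function(i) igraph::sample_gnp(15, 0.7))
  sparse <- lapply(1:4, function(i) igraph::sample_gnp(15, 0.1))
  ord <- network_ordination(c(dense, sparse), seed = 2)
  D <- attr(ord, "distances")
  within <- c(D[1:4, 1:4][upper.tri(diag(4))], D[5:8, 5:8][upper.tri(diag(4))])
  between <- as.vector(D[1:4, 5:8])
  expect_gt(mean(between), 2 * mean(within))
  ord2 <- network_ordination(c(dense, sparse), seed = 2)
  expect_identical(ord$coordinates, ord2$coordinates)

  same <- lapply(1:4, function(i) igraph::make_ring(6))
  expect_warning(flat <- network_ordination(same), "degenerate")
  expect_true(all(flat$coordinates$axis1 == 0))
  expect_error(network_ordination(dense[1:3]), "at least 4")
})
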