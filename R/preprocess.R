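#' Filter rare taxa and shallow samples
#'
#' Applies the standard amplicon-table clean-up in a single pass: taxa whose
#' total count across all samples is at most `drop_max_total` (singletons and
#' doubletons by default) are removed first, then samples whose remaining
#' depth falls below `min_depth` reads are removed. Surviving row and column
#' order is preserved.
#'
#' @param x A count table tibble.
#' @param min_depth Minimum post-filter sample depth to retain (default 1000).
#' @param drop_max_total Remove taxa with total count `<=` this value
#'   (default 2, i.e. singletons and doubletons).
#' @return The filtered count table.
#' @export
filter_table <- function(x, min_depth = 1000, drop_max_total = 2) {
  validate_count_table(x)
  m <- as_community_matrix(x)
  keep_tax <- colSums(m) > drop_max_total
  m <- m[, keep_tax, drop = FALSE]
  if (ncol(m) == 0) abort("Filtering removed every taxon.")
  keep_samp <- rowSums(m) >= min_depth
  m <- m[keep_samp, , drop = FALSE]
  if (nrow(m) == 0) abort("Filtering removed every sample.")
  as_community_tibble(m)
}

#' Hellinger transformation
#'
#' Transforms counts to the square root of within-sample relative abundance,
#' `sqrt(count / depth)`, via [vegan::decostand()]. Each nonzero sample row
#' of the result has unit L2 norm; squared values are relative abundances.
#'
#' @param x A count table tibble with strictly positive row sums.
#' @return An abundance table tibble of the same shape.
#' @export
hellinger <- function(x) {
  validate_count_table(x)
  m <- as_community_matrix(x)
  if (any(rowSums(m) == 0)) {
    abort("Zero-sum sample row(s); run `filter_table()` first.")
  }
  h <- vegan::decostand(m, method = "hellinger")
  as_community_tibble(h)
}

#' Scale abundances back to integers
#'
#' Multiplies transformed abundances by `factor` and rounds, producing the
#' integer pseudo-count table that integer-based model fits (such as the
#' neutral community model) consume. Taxa whose column becomes all zero are
#' retained and reported via a message.
#'
#' @param x An abundance table tibble.
#' @param factor Positive integer scale (default 1000).
#' @return A count table tibble of rounded integers.
#' @export
scale_round <- function(x, factor = 1000) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    abort("`factor` must be a single positive number.")
  }
  m <- round(as_community_matrix(x) * factor)
  zeroed <- colSums(m) == 0
  if (any(zeroed)) {
    inform(paste0(sum(zeroed), " taxon/taxa became all-zero after scaling and were retained."))
  }
  as_community_tibble(m)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarity
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between sample rows via
#' [vegan::vegdist()].
#'
#' @param x An abundance (or count) table tibble with at least two samples.
#' @return A symmetric matrix with zero diagonal, samples as dimnames.
#' @export
bray_curtis <- function(x) {
  m <- as_community_matrix(x)
  if (nrow(m) < 2) abort("Need at least two samples.")
  if (any(rowSums(m) == 0)) abort("All-zero sample row(s) make Bray-Curtis undefined.")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Ordinates a dissimilarity matrix with [vegan::metaMDS()] (monoMDS engine,
#' Kruskal stress-1), keeping the lowest-stress configuration over random
#' restarts. Deterministic for a fixed `seed`.
#'
#' @param d A symmetric dissimilarity matrix with dimnames (e.g. from
#'   [bray_curtis()]), or a `dist` object.
#' @param k Number of ordination dimensions (default 2).
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Integer seed.
#' @return An object of class `nmds_ordination`: list with `coordinates`
#'   (tibble of `sample_id` and axis scores), `stress`, `k`, `n_restarts`,
#'   `seed`.
#' @export
nmds_ordinate <- function(d, k = 2, n_restarts = 20, seed = 1) {
  d <- stats::as.dist(d)
  if (k >= attr(d, "Size")) abort("`k` must be smaller than the number of points.")
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  ))
  coords <- tibble::as_tibble(fit$points, .name_repair = ~ paste0("axis", seq_along(.x)))
  coords <- dplyr::bind_cols(
    tibble::tibble(sample_id = attr(d, "Labels") %||% as.character(seq_len(nrow(fit$points)))),
    coords
  )
  structure(
    list(coordinates = coords, stress = fit$stress, k = k,
         n_restarts = n_restarts, seed = seed, converged = fit$converged),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$coordinates), " points, k = ", x$k,
      ", stress = ", format(x$stress, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius), through [geosphere::distHaversine()].
#'
#' @param lon1,lat1,lon2,lat2 Coordinate vectors in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

#' Distance-decay linear model
#'
#' Pairs every two samples' community dissimilarity with the great-circle
#' distance (km) between their sites and fits an ordinary least squares
#' line. Same-site pairs (0 km) are included. By default every sample pair
#' contributes one point; with `level = "site"` pairs of site centroids
#' (mean dissimilarity between site members) are used instead.
#'
#' @param d A dissimilarity matrix with sample ids as dimnames.
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @param level `"sample"` (default) or `"site"`.
#' @return A `distance_decay_fit`: list with `slope` (dissimilarity per km),
#'   `intercept`, `r_squared`, `n_pairs`, and the underlying `pairs` tibble.
#' @export
distance_decay <- function(d, metadata, level = c("sample", "site")) {
  level <- rlang::arg_match(level)
  d <- as.matrix(d)
  ids <- rownames(d)
  validate_sample_metadata(metadata)
  md <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(md$sample_id)) abort("Every sample in `d` needs a metadata row.")
  if (level == "site") {
    site_of <- md$site
    sites <- unique(site_of)
    n <- length(sites)
    dd <- matrix(0, n, n, dimnames = list(sites, sites))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dd[i, j] <- mean(d[site_of == sites[i], site_of == sites[j], drop = FALSE])
    }
    d <- dd
    md <- md[match(sites, md$site), ]
    ids <- sites
  }
  idx <- which(upper.tri(d), arr.ind = TRUE)
  km <- haversine_km(md$longitude[idx[, 1]], md$latitude[idx[, 1]],
                     md$longitude[idx[, 2]], md$latitude[idx[, 2]])
  pairs <- tibble::tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    distance_km = as.numeric(km), dissimilarity = d[idx]
  )
  if (all(pairs$distance_km == 0)) {
    abort("All pairs are at zero geographic distance; distance-decay design is degenerate.")
  }
  fit <- lm(dissimilarity ~ distance_km, data = pairs)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n_pairs = nrow(pairs),
         pairs = pairs, level = level),
    class = "distance_decay_fit"
  )
}

#' @export
print.distance_decay_fit <- function(x, ...) {
  cat("Distance-decay fit (", x$level, " level): slope = ",
      format(x$slope, digits = 4), " per km, R^2 = ",
      format(x$r_squared, digits = 4), ", n_pairs = ", x$n_pairs, "\n", sep = "")
  invisible(x)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth via
#' [vegan::rrarefy()]; used as an alternative input for ordination when an
#' even-depth table is preferred over the Hellinger route.
#'
#' @param x A count table tibble.
#' @param depth Target depth; defaults to the minimum sample depth.
#' @param seed Integer seed.
#' @return A rarefied count table tibble.
#' @export
rarefy_table <- function(x, depth = NULL, seed = 1) {
  m <- as_community_matrix(x)
  depth <- depth %||% min(rowSums(m))
  if (any(rowSums(m) < depth)) abort("Some samples are shallower than `depth`.")
  set.seed(seed)
  as_community_tibble(vegan::rrarefy(m, depth))
}
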