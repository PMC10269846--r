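#' Dissimilarity-overlap points
#'
#' For every unordered sample pair with at least one shared taxon, computes
#' the pair's overlap — the average total relative abundance the two samples
#' invest in their shared taxa, `sum_{i in S} (x_i + y_i) / 2` — and their
#' dissimilarity — the root Jensen-Shannon divergence (log base 2, so
#' rJSD is in `[0, 1]`) of the two compositions restricted to the shared
#' taxa and renormalized. Pairs with empty shared support are skipped and
#' counted.
#'
#' @param x An abundance table tibble (e.g. a partition-restricted slice);
#'   at least 3 samples.
#' @param renormalize Renormalize rows to sum 1 first (default TRUE;
#'   required for compositions restricted to a partition's taxa).
#' @param drop_empty Silently drop all-zero sample rows instead of erroring
#'   (default FALSE).
#' @return A `doc_points` tibble with columns `id_a`, `id_b`, `overlap`,
#'   `dissimilarity`; attribute `n_skipped` counts disjoint-support pairs,
#'   `sample_ids` the samples used.
#' @export
doc_points <- function(x, renormalize = TRUE, drop_empty = FALSE) {
  m <- as_community_matrix(x)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    if (drop_empty) {
      m <- m[rs > 0, , drop = FALSE]
      rs <- rowSums(m)
    } else {
      abort("All-zero sample row(s); drop or filter them first.")
    }
  }
  if (nrow(m) < 3) abort("DOC needs at least 3 samples.")
  if (renormalize) m <- m / rs
  ids <- rownames(m)
  n <- nrow(m)
  np <- n * (n - 1) / 2
  id_a <- id_b <- character(np)
  ov <- dis <- rep(NA_real_, np)
  k <- 0L
  skipped <- 0L
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      yj <- m[j, ]
      shared <- xi > 0 & yj > 0
      if (!any(shared)) { skipped <- skipped + 1L; next }
      k <- k + 1L
      id_a[k] <- ids[i]
      id_b[k] <- ids[j]
      xs <- xi[shared]; ys <- yj[shared]
      ov[k] <- sum(xs + ys) / 2
      xs <- xs / sum(xs); ys <- ys / sum(ys)
      dis[k] <- rjsd(xs, ys)
    }
  }
  out <- tibble::tibble(id_a = id_a[seq_len(k)], id_b = id_b[seq_len(k)],
                        overlap = ov[seq_len(k)], dissimilarity = dis[seq_len(k)])
  structure(out, n_skipped = skipped, sample_ids = ids,
            class = c("doc_points", class(out)))
}

# root Jensen-Shannon divergence, log base 2, of two positive compositions
rjsd <- function(p, q) {
  mid <- (p + q) / 2
  jsd <- 0.5 * sum(p * log2(p / mid)) + 0.5 * sum(q * log2(q / mid))
  sqrt(max(0, jsd))
}

doc_grid <- function(overlap, n_grid = 50) {
  seq(min(overlap), max(overlap), length.out = n_grid)
}

lowess_on_grid <- function(overlap, dissimilarity, grid, lowess_frac) {
  lw <- lowess(overlap, dissimilarity, f = lowess_frac)
  approx(lw$x, lw$y, xout = grid, rule = 2, ties = mean)$y
}

# change point = smallest grid overlap from which the smoothed curve's slope
# stays negative through the maximum observed overlap; NA when the curve
# never turns downward (rendered at the right edge).
find_change_point <- function(grid, y) {
  slopes <- diff(y) / diff(grid)
  if (slopes[length(slopes)] >= 0) return(NA_real_)
  neg <- slopes < 0
  k <- max(which(!neg), 0) + 1
  grid[k]
}

#' Fit a dissimilarity-overlap curve
#'
#' LOWESS-smooths dissimilarity on overlap, bootstraps the curve over
#' samples (not pairs) for a 95% band, and locates the change point: the
#' smallest overlap from which the smoothed curve's slope is negative all
#' the way to the maximum observed overlap. When no such suffix exists the
#' change point is `NA` ("none") and is conventionally drawn at the
#' rightmost overlap.
#'
#' @param points A `doc_points` tibble.
#' @param lowess_frac LOWESS span (default 2/3).
#' @param n_boot Bootstrap replicates over samples (default 100).
#' @param seed Integer seed.
#' @param n_grid Evaluation grid size (default 50).
#' @return A `doc_fit`: list with `curve` (tibble `overlap`,
#'   `dissimilarity`, `band_lo`, `band_hi`), `change_point` (`NA` = none),
#'   `terminal_slope` (least-squares slope of the smoothed curve past the
#'   change point, or over the top overlap quartile when there is none),
#'   `fraction_negative_slope` (fraction of data points beyond the change
#'   point), `n_pairs`, `n_boot`, `lowess_frac`, `seed`, and the `points`.
#' @export
fit_doc <- function(points, lowess_frac = 2/3, n_boot = 100, seed = 1,
                    n_grid = 50) {
  stopifnot(inherits(points, "doc_points"))
  if (nrow(points) < 20) abort("DOC fit needs at least 20 pairs.")
  grid <- doc_grid(points$overlap, n_grid)
  y <- lowess_on_grid(points$overlap, points$dissimilarity, grid, lowess_frac)
  cp <- find_change_point(grid, y)
  ts <- doc_terminal_slope(tibble::tibble(overlap = grid, dissimilarity = y),
                           from = if (is.na(cp)) NULL else cp)
  frac_neg <- if (is.na(cp)) 0 else mean(points$overlap > cp)

  ids <- attr(points, "sample_ids")
  set.seed(seed)
  boot_curves <- matrix(NA_real_, n_boot, n_grid)
  for (b in seq_len(n_boot)) {
    draw <- table(sample(ids, length(ids), replace = TRUE))
    na <- draw[points$id_a]
    nb <- draw[points$id_b]
    w <- ifelse(is.na(na), 0, as.numeric(na)) * ifelse(is.na(nb), 0, as.numeric(nb))
    keep <- w > 0
    if (sum(keep) < 5) { next }
    ov <- rep(points$overlap[keep], w[keep])
    ds <- rep(points$dissimilarity[keep], w[keep])
    boot_curves[b, ] <- lowess_on_grid(ov, ds, grid, lowess_frac)
  }
  band_lo <- apply(boot_curves, 2, quantile, probs = 0.025, na.rm = TRUE)
  band_hi <- apply(boot_curves, 2, quantile, probs = 0.975, na.rm = TRUE)

  structure(
    list(
      curve = tibble::tibble(overlap = grid, dissimilarity = y,
                             band_lo = band_lo, band_hi = band_hi),
      change_point = cp, terminal_slope = ts,
      fraction_negative_slope = frac_neg,
      n_pairs = nrow(points), n_boot = n_boot,
      lowess_frac = lowess_frac, seed = seed, points = points
    ),
    class = "doc_fit"
  )
}

#' Terminal slope of a smoothed DOC curve
#'
#' Ordinary least-squares slope of the curve over overlaps at or beyond
#' `from` (defaults to the top quartile of the curve's overlap range); the
#' statistic compared between real and null curves.
#'
#' @param curve A tibble with `overlap` and `dissimilarity`.
#' @param from Left edge of the window (default: 75th percentile of range).
#' @return The slope (dissimilarity per unit overlap).
#' @export
doc_terminal_slope <- function(curve, from = NULL) {
  rng <- range(curve$overlap)
  from <- from %||% (rng[1] + 0.75 * diff(rng))
  sub <- curve[curve$overlap >= from, ]
  if (nrow(sub) < 2) sub <- utils::tail(curve, 2)
  unname(coef(lm(dissimilarity ~ overlap, data = sub))[2])
}

#' Permutation null curves for the DOC
#'
#' Each replicate independently permutes every taxon's abundance vector
#' across samples (destroying any coupling between overlap and
#' dissimilarity while preserving each taxon's value multiset), recomputes
#' the dissimilarity-overlap points and the LOWESS curve.
#'
#' @param x The abundance table the real DOC was computed from.
#' @param reps Number of null replicates.
#' @param seed Integer seed.
#' @param lowess_frac LOWESS span (default 2/3).
#' @param n_grid Evaluation grid size (default 50).
#' @return A list of `reps` curve tibbles (`overlap`, `dissimilarity`).
#' @export
doc_null <- function(x, reps, seed = 1, lowess_frac = 2/3, n_grid = 50) {
  m <- as_community_matrix(x)
  set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    perm <- apply(m, 2, function(col) col[sample.int(nrow(m))])
    rownames(perm) <- rownames(m)
    pts <- doc_points(as_community_tibble(perm), drop_empty = TRUE)
    grid <- doc_grid(pts$overlap, n_grid)
    y <- lowess_on_grid(pts$overlap, pts$dissimilarity, grid, lowess_frac)
    out[[r]] <- tibble::tibble(overlap = grid, dissimilarity = y)
  }
  out
}

#' @export
print.doc_fit <- function(x, ...) {
  cp <- if (is.na(x$change_point)) "none (rightmost)" else format(x$change_point, digits = 4)
  cat("Dissimilarity-overlap curve fit over ", x$n_pairs, " pairs\n",
      "  change point: ", cp,
      "\n  terminal slope: ", format(x$terminal_slope, digits = 4),
      "\n  fraction of points past change point: ",
      format(x$fraction_negative_slope, digits = 4), "\n", sep = "")
  invisible(x)
}
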