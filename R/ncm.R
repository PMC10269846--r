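#' Fit the Sloan neutral community model
#'
#' Fits the neutral expectation that a taxon's occurrence frequency across
#' samples is determined by its mean relative abundance: with community size
#' `N` (the mean per-sample total after integer scaling), migration
#' probability `m`, and detection limit `d = 1/N`, the predicted frequency
#' of a taxon at mean relative abundance `p` is
#' `1 - pbeta(d, N*m*p, N*m*(1-p))`. `m` is estimated by least squares over
#' taxa in frequency space (untransformed residuals). 95% intervals for `m`
#' and a 95% band around the prediction curve come from a percentile
#' bootstrap over taxa (Wilson score bands over the binomial sampling error
#' of frequency are available with `band_method = "wilson"`). Taxa never
#' observed (`f = 0`) are excluded from the fit but retained in the
#' per-taxon report with `NA` labels.
#'
#' @param x An integer count table tibble, typically from [scale_round()] of
#'   a Hellinger table; needs `>= 5` samples and `>= 10` taxa with nonzero
#'   totals.
#' @param seed Integer seed for the bootstrap.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param band_method `"bootstrap"` (default) or `"wilson"`.
#' @return An `ncm_fit` object: list with `m`, `N`, `Nm`, `d`,
#'   `r_squared` (1 - SSE/SST, can be negative for terrible fits), `m_ci`,
#'   `band_method`, `n_boot`, `seed`, `n_samples`, and `taxa` — a tibble of
#'   per-taxon `p` (mean relative abundance), `f` (observed frequency),
#'   `predicted`, `band_lo`, `band_hi`, `fitted` flag and `label` in
#'   above/neutral/below.
#' @export
fit_ncm <- function(x, seed, n_boot = 1000,
                    band_method = c("bootstrap", "wilson")) {
  band_method <- rlang::arg_match(band_method)
  if (missing(seed)) abort("`seed` is mandatory.")
  m0 <- as_community_matrix(x)
  if (nrow(m0) < 5) abort("NCM fit needs at least 5 samples.")
  if (sum(colSums(m0) > 0) < 10) abort("NCM fit needs at least 10 nonzero taxa.")
  depth <- rowSums(m0)
  if (any(depth == 0)) abort("Zero-depth sample row(s); filter first.")
  N <- mean(depth)
  d <- 1 / N
  rel <- sweep(m0, 1, depth, "/")
  p_all <- colMeans(rel)
  f_all <- colMeans(m0 > 0)
  fitted_mask <- f_all > 0
  p <- pmin(p_all[fitted_mask], 1 - 1e-12)
  f <- f_all[fitted_mask]
  if (all(f == 1) || sd(f) == 0) {
    abort("Degenerate occurrence data (no frequency variation); NCM fit undefined.")
  }

  predict_freq <- function(p, m) ncm_predict(p, m, N, d)
  fit_m <- function(p, f) fit_ncm_curve(p, f, N, d)
  m_hat <- fit_m(p, f)
  pred <- predict_freq(p, m_hat)
  sse <- sum((f - pred)^2)
  sst <- sum((f - mean(f))^2)
  r2 <- 1 - sse / sst

  set.seed(seed)
  n_fit <- length(p)
  m_boot <- numeric(n_boot)
  pred_boot <- matrix(NA_real_, n_boot, n_fit)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_fit, n_fit, replace = TRUE)
    mb <- fit_m(p[idx], f[idx])
    m_boot[b] <- mb
    pred_boot[b, ] <- predict_freq(p, mb)
  }
  m_ci <- unname(quantile(m_boot, c(0.025, 0.975)))
  if (band_method == "bootstrap") {
    band_lo <- apply(pred_boot, 2, quantile, probs = 0.025)
    band_hi <- apply(pred_boot, 2, quantile, probs = 0.975)
    # the point prediction is kept inside its own band
    band_lo <- pmin(band_lo, pred)
    band_hi <- pmax(band_hi, pred)
  } else {
    w <- wilson_band(pred, nrow(m0))
    band_lo <- w$lo
    band_hi <- w$hi
  }

  taxa <- tibble::tibble(
    taxon_id = names(f_all),
    p = unname(p_all),
    f = unname(f_all),
    predicted = NA_real_,
    band_lo = NA_real_,
    band_hi = NA_real_,
    fitted = fitted_mask
  )
  taxa$predicted[fitted_mask] <- pred
  taxa$band_lo[fitted_mask] <- band_lo
  taxa$band_hi[fitted_mask] <- band_hi

  out <- structure(
    list(m = m_hat, N = N, Nm = N * m_hat, d = d, r_squared = r2,
         m_ci = m_ci, m_boot = m_boot, band_method = band_method,
         n_boot = n_boot, seed = seed, n_samples = nrow(m0), taxa = taxa),
    class = "ncm_fit"
  )
  out$taxa$label <- classify_taxa(out)$label
  out
}

#' Neutral-model occurrence-frequency prediction
#'
#' The Sloan model's predicted occurrence frequency for a taxon of mean
#' relative abundance `p` in a community of size `N` with migration
#' probability `m` and detection limit `d`:
#' `1 - pbeta(d, N*m*p, N*m*(1-p))`.
#'
#' @param p Mean relative abundance(s) in (0, 1).
#' @param m Migration probability in (0, 1).
#' @param N Community size (individuals or scaled reads per sample).
#' @param d Detection limit (default `1/N`).
#' @return Predicted frequency(ies) in `[0, 1]`.
#' @export
ncm_predict <- function(p, m, N, d = 1 / N) {
  1 - pbeta(d, N * m * p, N * m * (1 - p))
}

# least-squares migration estimate in frequency space
fit_ncm_curve <- function(p, f, N, d = 1 / N) {
  opt <- optimize(function(m) sum((f - ncm_predict(p, m, N, d))^2),
                  interval = c(1e-8, 1 - 1e-8), tol = 1e-9)
  opt$minimum
}

wilson_band <- function(p_hat, n, z = 1.959964) {
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

#' Classify taxa against the neutral prediction band
#'
#' Recompares each fitted taxon's observed frequency with the fit's stored
#' 95% band: `above` when `f > band_hi`, `below` when `f < band_lo`,
#' `neutral` otherwise; taxa excluded from the fit get `NA`.
#'
#' @param fit An `ncm_fit`.
#' @return A tibble with `taxon_id` and `label`.
#' @export
classify_taxa <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  tx <- fit$taxa
  label <- rep(NA_character_, nrow(tx))
  fb <- tx$fitted
  label[fb] <- dplyr::case_when(
    tx$f[fb] > tx$band_hi[fb] ~ "above",
    tx$f[fb] < tx$band_lo[fb] ~ "below",
    TRUE ~ "neutral"
  )
  tibble::tibble(taxon_id = tx$taxon_id, label = label)
}

#' Neutral-fit label proportions by core/noncore partition across thresholds
#'
#' For every threshold of a core sweep, splits the labelled taxa by the
#' real core set at that threshold and reports the proportions of
#' above/neutral/below labels within the core and within the noncore
#' partition (the stacked-proportion view of how deviation from neutrality
#' concentrates in the core).
#'
#' @param labels A tibble with `taxon_id` and `label` (e.g. from
#'   [classify_taxa()]), or an `ncm_fit`.
#' @param sweep A `core_sweep` from [threshold_sweep()].
#' @return A tibble with columns `threshold`, `partition`, `n`,
#'   `prop_above`, `prop_neutral`, `prop_below`, `empty` (TRUE when the
#'   partition holds no labelled taxa, in which case proportions are NaN).
#' @export
partition_proportions <- function(labels, sweep) {
  if (inherits(labels, "ncm_fit")) labels <- classify_taxa(labels)
  stopifnot(inherits(sweep, "core_sweep"))
  labels <- labels[!is.na(labels$label), ]
  core_real <- attr(sweep, "core_real")
  res <- purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    in_core <- labels$taxon_id %in% core_real[[i]]
    purrr::map_dfr(c(core = TRUE, noncore = FALSE), function(side) {
      lab <- labels$label[in_core == side]
      n <- length(lab)
      tibble::tibble(
        n = n,
        prop_above = sum(lab == "above") / n,
        prop_neutral = sum(lab == "neutral") / n,
        prop_below = sum(lab == "below") / n,
        empty = n == 0
      )
    }, .id = "partition") |>
      dplyr::mutate(threshold = sweep$threshold[i], .before = 1)
  })
  dplyr::select(res, "threshold", "partition", "n",
                "prop_above", "prop_neutral", "prop_below", "empty")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat("  m  = ", format(x$m, digits = 4),
      "  [", format(x$m_ci[1], digits = 4), ", ",
      format(x$m_ci[2], digits = 4), "] (95% bootstrap)\n", sep = "")
  cat("  N  = ", format(x$N, digits = 6), ",  Nm = ",
      format(x$Nm, digits = 5), "\n", sep = "")
  cat("  R^2 = ", format(x$r_squared, digits = 4),
      " over ", sum(x$taxa$fitted), " taxa, ", x$n_samples, " samples\n", sep = "")
  lab <- table(x$taxa$label)
  cat("  labels:", paste(names(lab), lab, collapse = ", "), "\n")
  invisible(x)
}
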