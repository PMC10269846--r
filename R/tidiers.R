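#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-unit table underlying an
#' object (per taxon, per tier, per pair, per grid point); `glance()` a
#' one-row summary of the fit.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name coretier-tidiers
NULL

#' @rdname coretier-tidiers
#' @method tidy ncm_fit
#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @rdname coretier-tidiers
#' @method glance ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, m_lo = x$m_ci[1], m_hi = x$m_ci[2],
    N = x$N, Nm = x$Nm, d = x$d, r_squared = x$r_squared,
    n_taxa = nrow(x$taxa), n_taxa_fitted = sum(x$taxa$fitted),
    n_samples = x$n_samples, n_boot = x$n_boot, band_method = x$band_method
  )
}

#' @rdname coretier-tidiers
#' @method tidy doc_fit
#' @export
tidy.doc_fit <- function(x, ...) x$curve

#' @rdname coretier-tidiers
#' @method glance doc_fit
#' @export
glance.doc_fit <- function(x, ...) {
  tibble::tibble(
    change_point = x$change_point,
    terminal_slope = x$terminal_slope,
    fraction_negative_slope = x$fraction_negative_slope,
    n_pairs = x$n_pairs, n_boot = x$n_boot, lowess_frac = x$lowess_frac
  )
}

#' @rdname coretier-tidiers
#' @method tidy tier_table
#' @export
tidy.tier_table <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(tier = integer(), threshold_lo = integer(),
                          threshold_hi = integer(), abundance = numeric(),
                          taxon_id = character()))
  }
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "tier", "threshold_lo",
                  "threshold_hi", "abundance", taxon_id = "taxa"),
    "taxon_id"
  )
}

#' @rdname coretier-tidiers
#' @method tidy nmds_ordination
#' @export
tidy.nmds_ordination <- function(x, ...) x$coordinates

#' @rdname coretier-tidiers
#' @method glance nmds_ordination
#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n_restarts = x$n_restarts,
                 converged = isTRUE(x$converged))
}

#' @rdname coretier-tidiers
#' @method tidy taxa_network
#' @export
tidy.taxa_network <- function(x, ...) x$edges

#' @rdname coretier-tidiers
#' @method glance taxa_network
#' @export
glance.taxa_network <- function(x, ...) {
  tibble::tibble(n_taxa = length(x$taxa), n_edges = nrow(x$edges),
                 n_samples = x$n_samples, n_constant = x$n_constant)
}

#' @rdname coretier-tidiers
#' @method tidy combined_network
#' @export
tidy.combined_network <- function(x, ...) x$edges

#' @rdname coretier-tidiers
#' @method glance combined_network
#' @export
glance.combined_network <- function(x, ...) {
  tibble::tibble(n_taxa = length(x$taxa), n_edges = nrow(x$edges),
                 n_networks = x$n_networks)
}

#' @rdname coretier-tidiers
#' @method tidy distance_decay_fit
#' @export
tidy.distance_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "distance_km"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname coretier-tidiers
#' @method glance distance_decay_fit
#' @export
glance.distance_decay_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_pairs = x$n_pairs)
}
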