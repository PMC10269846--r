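#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with defaults
#' at the study's working values: depth filter 1000 reads, singleton and
#' doubleton removal, 30-sample subcommunities resampled 100 times, the
#' closest-to-50%-abundance tier, x1000 integer scaling for the neutral
#' fit with 1000 bootstrap replicates, Spearman cuts |rho| > 0.8 and
#' p < 0.001, edge-frequency cut "more than 20 of 100", and D-measure
#' weights (0.45, 0.45, 0.10).
#'
#' @param seed Mandatory root seed; per-stage seeds are spawned from it
#'   deterministically and recorded in the report.
#' @param min_depth,drop_max_total Filtering (see [filter_table()]).
#' @param subsample,reps Simulated-subcommunity size and count.
#' @param target_abundance Tier selection target (see [select_tier()]).
#' @param scale_factor Integer scaling for the NCM (see [scale_round()]).
#' @param ncm_boot,band_method NCM bootstrap settings (see [fit_ncm()]).
#' @param doc_frac,doc_boot,doc_null_reps DOC settings (see [fit_doc()],
#'   [doc_null()]).
#' @param rho_min,p_max,min_edge_freq Network cuts (see
#'   [spearman_network()], [combine_networks()]).
#' @param dmeasure_w D-measure weights.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            min_depth = 1000, drop_max_total = 2,
                            subsample = 30, reps = 100,
                            target_abundance = 0.5,
                            scale_factor = 1000,
                            ncm_boot = 1000,
                            band_method = "bootstrap",
                            doc_frac = 2 / 3, doc_boot = 100,
                            doc_null_reps = 100,
                            rho_min = 0.8, p_max = 0.001,
                            min_edge_freq = 20,
                            dmeasure_w = c(0.45, 0.45, 0.10)) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory: every stochastic stage must be seeded.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full per-host analysis pipeline
#'
#' Sequences the stages: depth/rarity filtering, Hellinger transformation,
#' real (site) and bootstrap-simulated subcommunities, the core threshold
#' sweep, tier identification and selection, the Sloan neutral model fit
#' with per-taxon classification and per-threshold partition proportions,
#' dissimilarity-overlap curves (with permutation nulls) for the core and
#' noncore partitions, and the combined co-occurrence network over the
#' simulated subcommunities with node centralities. A stage failure halts
#' the run with an error naming the stage and carrying the partial report
#' in its `report` field. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param counts A count table tibble.
#' @param metadata Sample metadata tibble.
#' @param config A [pipeline_config()].
#' @param host Optional host label selecting one meta-community.
#' @param out_dir Optional directory; when given, every tabular stage output
#'   is written as CSV/JSON beneath it.
#' @return A `coretier_report` list with elements `config`, `seeds`,
#'   `filter`, `sweep`, `tiers`, `partition`, `ncm`, `ncm_by_threshold`,
#'   `doc` (per partition: `fit`, `null_slopes`), `network` (combined
#'   network, histogram, node metrics).
#' @export
run_pipeline <- function(counts, metadata, config, host = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, 6)
  names(seeds) <- c("subsample", "ncm", "doc_core", "doc_noncore",
                    "doc_null", "ordination")
  report <- list(config = config, seeds = seeds)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "coretier_pipeline_error", report = report)
    })
  }

  filtered <- run_stage("filter", {
    validate_sample_metadata(metadata, counts = counts)
    if (!is.null(host)) {
      keep <- metadata$sample_id[metadata$host == host]
      counts <- counts[counts$sample_id %in% keep, , drop = FALSE]
    }
    filter_table(counts, config$min_depth, config$drop_max_total)
  })
  report$filter <- list(
    n_samples_in = nrow(counts), n_taxa_in = ncol(counts) - 1,
    n_samples_kept = nrow(filtered), n_taxa_kept = ncol(filtered) - 1
  )
  hell <- run_stage("hellinger", hellinger(filtered))

  report$sweep <- run_stage("core_sweep", {
    real_subs <- subcommunity_views(filtered, metadata, host = host)
    sim_subs <- simulate_subcommunities(filtered, n_samples = config$subsample,
                                        reps = config$reps,
                                        seed = seeds[["subsample"]])
    threshold_sweep(real_subs, sim_subs, hell)
  })
  report$tiers <- run_stage("tiers", identify_tiers(report$sweep))
  report$partition <- run_stage("partition",
    select_tier(report$tiers, config$target_abundance))

  report$ncm <- run_stage("ncm", {
    scaled <- suppressMessages(scale_round(hell, config$scale_factor))
    fit_ncm(scaled, seed = seeds[["ncm"]], n_boot = config$ncm_boot,
            band_method = config$band_method)
  })
  report$ncm_by_threshold <- run_stage("ncm_partition_proportions",
    partition_proportions(report$ncm, report$sweep))

  rel <- as_community_matrix(filtered)
  rel <- rel / rowSums(rel)
  report$doc <- run_stage("doc", {
    out <- list()
    for (cls in c("core", "noncore")) {
      taxa_cls <- report$partition$taxon_id[report$partition$class == cls]
      sub <- as_community_tibble(rel[, taxa_cls, drop = FALSE])
      res <- tryCatch({
        pts <- doc_points(sub, drop_empty = TRUE)
        fit <- fit_doc(pts, lowess_frac = config$doc_frac,
                       n_boot = config$doc_boot,
                       seed = seeds[[paste0("doc_", cls)]])
        nulls <- doc_null(sub, reps = config$doc_null_reps,
                          seed = seeds[["doc_null"]],
                          lowess_frac = config$doc_frac)
        from <- if (is.na(fit$change_point)) NULL else fit$change_point
        list(fit = fit,
             null_slopes = vapply(nulls, doc_terminal_slope, numeric(1),
                                  from = from))
      }, error = function(e) {
        inform(paste0("DOC skipped for ", cls, " partition: ",
                      conditionMessage(e)))
        NULL
      })
      out[[cls]] <- res
    }
    out
  })

  report$network <- run_stage("network", {
    sim_subs <- simulate_subcommunities(filtered, n_samples = config$subsample,
                                        reps = config$reps,
                                        seed = seeds[["subsample"]])
    nets <- lapply(sim_subs, function(s)
      spearman_network(hellinger(s), config$rho_min, config$p_max))
    combined <- combine_networks(nets, config$min_edge_freq)
    list(combined = combined, histogram = combined$histogram,
         metrics = node_metrics(combined))
  })

  report <- structure(report, class = "coretier_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Serializes every tabular stage output of a `coretier_report` as CSV and
#' the scalar summaries (config, seeds, fit statistics, change points) as
#' JSON; the same report always produces byte-identical files.
#'
#' @param report A `coretier_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_csv(tibble::as_tibble(report$sweep), p("core_sweep.csv"))
  tiers_flat <- dplyr::mutate(
    tibble::as_tibble(report$tiers),
    intervals = vapply(.data$intervals, function(v)
      paste(vapply(v, paste, character(1), collapse = "-"), collapse = ";"),
      character(1)),
    taxa = vapply(.data$taxa, paste, character(1), collapse = ";")
  )
  readr::write_csv(tiers_flat, p("tiers.csv"))
  readr::write_csv(tibble::as_tibble(report$partition), p("partition.csv"))
  readr::write_csv(report$ncm$taxa, p("ncm_taxa.csv"))
  readr::write_csv(report$ncm_by_threshold, p("ncm_by_threshold.csv"))
  for (cls in names(report$doc)) {
    if (is.null(report$doc[[cls]])) next
    readr::write_csv(report$doc[[cls]]$fit$curve, p(paste0("doc_curve_", cls, ".csv")))
    readr::write_csv(tibble::as_tibble(report$doc[[cls]]$fit$points),
                     p(paste0("doc_points_", cls, ".csv")))
  }
  readr::write_csv(report$network$combined$edges, p("network_edges.csv"))
  readr::write_csv(report$network$histogram, p("network_edge_histogram.csv"))
  readr::write_csv(report$network$metrics, p("network_node_metrics.csv"))
  summary <- list(
    config = unclass(report$config),
    seeds = as.list(report$seeds),
    filter = report$filter,
    ncm = list(m = report$ncm$m, N = report$ncm$N, Nm = report$ncm$Nm,
               r_squared = report$ncm$r_squared, m_ci = report$ncm$m_ci),
    doc = lapply(report$doc, function(d) {
      if (is.null(d)) return(NULL)
      list(change_point = d$fit$change_point,
           terminal_slope = d$fit$terminal_slope,
           fraction_negative_slope = d$fit$fraction_negative_slope)
    })
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.coretier_report <- function(x, ...) {
  cat("coretier pipeline report\n")
  cat("  filter: ", x$filter$n_samples_kept, "/", x$filter$n_samples_in,
      " samples, ", x$filter$n_taxa_kept, "/", x$filter$n_taxa_in,
      " taxa kept\n", sep = "")
  cat("  tiers: ", nrow(x$tiers), "; selected tier ",
      attr(x$partition, "tier")$tier, " (",
      attr(x$partition, "tier")$n_taxa, " taxa, ",
      round(100 * attr(x$partition, "tier")$abundance, 2),
      "% abundance)\n", sep = "")
  cat("  NCM: m = ", format(x$ncm$m, digits = 4), ", Nm = ",
      format(x$ncm$Nm, digits = 5), ", R^2 = ",
      format(x$ncm$r_squared, digits = 4), "\n", sep = "")
  for (cls in names(x$doc)) {
    if (is.null(x$doc[[cls]])) next
    cp <- x$doc[[cls]]$fit$change_point
    cat("  DOC ", cls, ": change point ",
        if (is.na(cp)) "none" else format(cp, digits = 4), "\n", sep = "")
  }
  cat("  combined network: ", nrow(x$network$combined$edges), " edges over ",
      length(x$network$combined$taxa), " taxa\n", sep = "")
  invisible(x)
}
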