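#' Community tables
#'
#' Throughout the package a community table is a tibble whose first column,
#' `sample_id`, holds unique sample identifiers and whose remaining columns
#' are numeric taxon abundances (integer read counts or transformed
#' abundances), one column per taxon. This mirrors a samples-by-taxa feature
#' table as produced by amplicon pipelines, in tidy wide form so the usual
#' dplyr verbs apply.
#'
#' @param x A community tibble.
#' @return `as_community_matrix()` returns a base numeric matrix with sample
#'   ids as row names and taxon ids as column names;
#'   `as_community_tibble()` the inverse.
#' @examples
#' tb <- tibble::tibble(sample_id = c("s1", "s2"), taxA = c(3, 0), taxB = c(1, 9))
#' m <- as_community_matrix(tb)
#' all.equal(as_community_tibble(m), tb)
#' @export
as_community_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "sample_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x$sample_id)
  m
}

#' @rdname as_community_matrix
#' @export
as_community_tibble <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  out <- tibble::as_tibble(x, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), out)
}

taxon_ids <- function(x) names(x)[-1]

validate_count_table <- function(x, call = rlang::caller_env()) {
  if (!is.data.frame(x) || ncol(x) < 2 || names(x)[1] != "sample_id") {
    abort("A count table must be a data frame with first column `sample_id` and at least one taxon column.", call = call)
  }
  if (anyDuplicated(x$sample_id)) {
    abort("Duplicate sample ids in count table.", call = call)
  }
  if (anyDuplicated(names(x))) {
    abort("Duplicate taxon ids in count table.", call = call)
  }
  m <- as_community_matrix(x)
  if (anyNA(m)) abort("Count table contains missing values.", call = call)
  if (any(m < 0)) abort("Count table contains negative values.", call = call)
  invisible(x)
}

#' Read and write samples-by-taxa count tables
#'
#' Reads a feature table either from a tab-separated file (header row of
#' taxon ids, first column of sample ids, or the transpose with
#' `orientation = "taxa"`) or from a dense BIOM JSON file (via the biomformat
#' package, in which rows are observations/taxa as per the BIOM convention).
#' The returned table is always oriented rows = samples and validated:
#' non-negative numeric cells, no duplicate ids.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"` (dense BIOM JSON).
#' @param orientation For TSV input, whether rows of the file are
#'   `"samples"` (default) or `"taxa"`.
#' @return A count table tibble (see [as_community_matrix()]).
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             orientation = c("samples", "taxa")) {
  format <- rlang::arg_match(format)
  orientation <- rlang::arg_match(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "biom") {
    rlang::check_installed("biomformat", reason = "to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b))) # biom rows are taxa
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
    ids <- as.character(df[[1]])
    num <- df[, -1, drop = FALSE]
    bad <- which(!vapply(num, is.numeric, logical(1)))
    if (length(bad)) {
      abort(paste0("Non-numeric cells in column(s): ",
                   paste(names(num)[bad], collapse = ", ")))
    }
    m <- as.matrix(num)
    rownames(m) <- ids
    if (orientation == "taxa") m <- t(m)
  }
  out <- as_community_tibble(m)
  validate_count_table(out)
  out
}

#' @rdname read_count_table
#' @param x A count table tibble.
#' @export
write_count_table <- function(x, path) {
  validate_count_table(x)
  df <- as.data.frame(x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata is a CSV with columns `sample_id, host, site, latitude,
#' longitude`; each sample of any analysed table must have exactly one row.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the five metadata columns.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE)
  validate_sample_metadata(md)
  md
}

validate_sample_metadata <- function(md, counts = NULL, call = rlang::caller_env()) {
  need <- c("sample_id", "host", "site", "latitude", "longitude")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    abort(paste0("Metadata is missing column(s): ", paste(miss, collapse = ", ")), call = call)
  }
  if (anyDuplicated(md$sample_id)) abort("Duplicate sample ids in metadata.", call = call)
  if (any(abs(md$latitude) > 90, na.rm = TRUE)) abort("latitude out of [-90, 90].", call = call)
  if (any(abs(md$longitude) > 180, na.rm = TRUE)) abort("longitude out of [-180, 180].", call = call)
  if (!is.null(counts)) {
    missing_samples <- setdiff(counts$sample_id, md$sample_id)
    if (length(missing_samples)) {
      abort(paste0(length(missing_samples), " sample(s) lack metadata rows, e.g. ",
                   head(missing_samples, 1)), call = call)
    }
  }
  invisible(md)
}
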