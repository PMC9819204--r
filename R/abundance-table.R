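#' Construct a sample-by-taxon abundance table
#'
#' The central data container: a nonnegative numeric matrix with samples in
#' rows and taxa in columns, an abundance mode flag, an optional taxonomy map
#' and optional per-sample metadata. Relative-abundance rows must sum to 1
#' over the taxa present in the table (conversion is expected to happen
#' *after* any prevalence filtering, so row sums are over retained taxa).
#'
#' @param values numeric matrix, samples x taxa, with unique dimnames.
#' @param mode `"counts"` or `"relative"`.
#' @param taxonomy optional data.frame with columns `taxon_id`, `phylum`,
#'   `family`, `genus` (extra columns such as `species` are kept). Every
#'   taxon in `values` must appear; missing ranks may be `"unclassified"`.
#' @param metadata optional data.frame of per-sample covariates/outcomes,
#'   either with a `sample_id` column or with sample ids as row names.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("counts", "relative"),
                            taxonomy = NULL, metadata = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("taxon_", seq_len(ncol(values)))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing cell at sample '", rownames(values)[idx[1]],
         "', taxon '", colnames(values)[idx[2]], "'")
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample '", rownames(values)[idx[1]],
         "', taxon '", colnames(values)[idx[2]], "'")
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad))
      stop("relative-mode rows must sum to 1 (within 1e-6); offending sample: '",
           rownames(values)[bad[1]], "' (sum ", format(rs[bad[1]]), ")")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    need <- c("taxon_id", "phylum", "family", "genus")
    if (!all(need %in% names(taxonomy)))
      stop("taxonomy must have columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(values), taxonomy$taxon_id)
    if (length(missing))
      stop("taxonomy missing entries for: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ...")
    taxonomy <- taxonomy[match(colnames(values), taxonomy$taxon_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if ("sample_id" %in% names(metadata)) {
      rownames(metadata) <- metadata$sample_id
      metadata$sample_id <- NULL
    }
    missing <- setdiff(rownames(values), rownames(metadata))
    if (length(missing))
      stop("metadata missing entries for samples: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ...")
    metadata <- metadata[rownames(values), , drop = FALSE]
  }
  structure(list(values = values, mode = mode,
                 taxonomy = taxonomy, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa (", x$mode, "mode )\n")
  zf <- colMeans(x$values == 0)
  cat("  per-taxon zero fraction: median", round(stats::median(zf), 3),
      " range [", round(min(zf), 3), ",", round(max(zf), 3), "]\n")
  if (!is.null(x$taxonomy))
    cat("  taxonomy:", length(unique(x$taxonomy$genus)), "genera,",
        length(unique(x$taxonomy$phylum)), "phyla\n")
  if (!is.null(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from delimited text or BIOM-JSON
#'
#' TSV/CSV input is a header-ed numeric table; `orientation` says whether
#' rows are samples or taxa (the returned table is always samples x taxa).
#' BIOM input must be the JSON dialect (HDF5 BIOM is not supported).
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"biom-json"`.
#' @param orientation `"samples-rows"` or `"taxa-rows"` (ignored for BIOM,
#'   whose observations are taxa by convention).
#' @param mode abundance mode of the stored values.
#' @param taxonomy_path optional TSV sidecar with columns
#'   `taxon_id`, `phylum`, `family`, `genus`.
#' @param metadata_path optional CSV sidecar keyed by a `sample_id` column.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 format = c("tsv", "csv", "biom-json"),
                                 orientation = c("samples-rows", "taxa-rows"),
                                 mode = c("counts", "relative"),
                                 taxonomy_path = NULL, metadata_path = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") {
    b <- biomformat::read_biom(path)
    values <- t(as.matrix(biomformat::biom_data(b)))  # biom rows are observations
  } else {
    sep <- if (format == "tsv") "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    for (j in seq_along(raw)) {
      col <- raw[[j]]
      if (!is.numeric(col)) {
        num <- suppressWarnings(as.numeric(col))
        if (anyNA(num)) {
          i <- which(is.na(num))[1]
          stop("malformed numeric cell at row '", rownames(raw)[i],
               "', column '", colnames(raw)[j], "': '", col[i], "'")
        }
        raw[[j]] <- num
      }
    }
    values <- as.matrix(raw)
    if (orientation == "taxa-rows") values <- t(values)
  }
  taxonomy <- if (!is.null(taxonomy_path))
    utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  metadata <- if (!is.null(metadata_path))
    utils::read.csv(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  abundance_table(values, mode = mode, taxonomy = taxonomy, metadata = metadata)
}

#' Write an abundance table to delimited text
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_abundance_table <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "abundance_table"))
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop rare taxa by prevalence
#'
#' Retains exactly the taxa whose abundance is nonzero in at least
#' `min_nonzero_fraction` of samples. The default 0.10 reproduces the usual
#' data-reduction step of dropping taxa absent from more than 90% of
#' samples, which also guarantees enough nonzero values to form positive
#' tertiles downstream.
#'
#' @param table an [abundance_table()].
#' @param min_nonzero_fraction required fraction of samples with nonzero
#'   abundance, in (0, 1].
#' @return the filtered [abundance_table()]; taxon order preserved.
#' @export
prevalence_filter <- function(table, min_nonzero_fraction = 0.10) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(min_nonzero_fraction) || min_nonzero_fraction <= 0 ||
      min_nonzero_fraction > 1)
    stop("min_nonzero_fraction must be in (0, 1]")
  # compare on counts with a tiny slack so exact boundaries (e.g. 21/210 at
  # threshold 0.10) are kept regardless of floating-point division
  keep <- colSums(table$values > 0) >=
    min_nonzero_fraction * nrow(table$values) - 1e-9
  if (!any(keep))
    stop("prevalence filter at ", min_nonzero_fraction,
         " removes all taxa; lower the threshold")
  values <- table$values[, keep, drop = FALSE]
  taxonomy <- if (!is.null(table$taxonomy))
    table$taxonomy[keep, , drop = FALSE]
  out <- table
  out$values <- values
  out$taxonomy <- taxonomy
  # relative rows no longer sum to 1 after dropping columns; re-close them
  if (table$mode == "relative") {
    out$mode <- "counts"
    out <- to_relative_abundance(out)
  }
  out
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its row sum (closure over the taxa currently in
#' the table). Idempotent on relative-mode input. Conversion is intended to
#' run after [prevalence_filter()], so proportions are relative to the
#' retained taxa.
#'
#' @param table an [abundance_table()].
#' @return the table in relative mode.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative") return(table)
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop("all-zero sample row(s): ",
         paste(utils::head(rownames(table$values)[rs == 0], 5), collapse = ", "))
  out <- table
  out$values <- table$values / rs
  out$mode <- "relative"
  out
}
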