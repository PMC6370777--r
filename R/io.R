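#' Read a sample x feature count table
#'
#' Two on-disk dialects are supported: plain TSV (header row of feature ids,
#' first column sample ids, integer cells) and BIOM v1 JSON (sparse or dense;
#' parsed with the biomformat package). Supplementary tables from sequencing
#' studies are sometimes stored transposed (samples in columns); with
#' `orientation = "auto"` the reader matches ids against `metadata` to decide,
#' otherwise the declared orientation is trusted.
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @param orientation `"samples-in-rows"` (default), `"samples-in-columns"`,
#'   or `"auto"` (requires `metadata`). BIOM files are observation x sample by
#'   definition and ignore this argument.
#' @param metadata Optional [sample_metadata()] used for `"auto"` orientation.
#' @param rank Feature rank label to attach, default `"otu"`.
#' @return A [count_matrix()], samples as rows.
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom-json"),
                             orientation = c("samples-in-rows",
                                             "samples-in-columns", "auto"),
                             metadata = NULL, rank = "otu") {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "biom-json") {
    b <- biomformat::read_biom(path)
    m <- methods::as(biomformat::biom_data(b), "matrix") # observations x samples
    m <- t(m)
    return(count_matrix(check_integral(m, path), rank = rank))
  }
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 1) stop("malformed count table: ", path, call. = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "auto") {
    if (is.null(metadata)) {
      stop("orientation = \"auto\" requires `metadata`", call. = FALSE)
    }
    hit_rows <- length(intersect(rownames(m), metadata$sample_id))
    hit_cols <- length(intersect(colnames(m), metadata$sample_id))
    orientation <- if (hit_cols > hit_rows) "samples-in-columns"
                   else "samples-in-rows"
  }
  if (orientation == "samples-in-columns") m <- t(m)
  count_matrix(check_integral(m, path), rank = rank)
}

# validate cells read from disk, naming the offending entry
check_integral <- function(m, path) {
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count in %s at row '%s', column '%s'",
      path, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  m
}

#' Write a count table
#'
#' The TSV dialect writes a header of feature ids, one row per sample, tab
#' separated, unquoted, UTF-8, `\n` line endings — byte-stable for a fixed
#' matrix. The BIOM dialect writes BIOM v1 JSON via biomformat with a pinned
#' generation date so repeated writes are identical.
#'
#' @param x A [count_matrix()].
#' @param path Output file.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  x <- count_matrix(as.matrix(unclass_counts(x)), rank = count_rank(x))
  if (any(grepl("\t", c(rownames(x), colnames(x))))) {
    stop("tabs are not allowed in sample or feature ids", call. = FALSE)
  }
  if (dialect == "biom-json") {
    b <- biomformat::make_biom(data = t(unclass_counts(x)))
    b$date <- "1970-01-01T00:00:00"
    b$id <- "graftmicrobe"
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  header <- paste(c("sample_id", colnames(x)), collapse = "\t")
  body <- if (nrow(x) > 0) {
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], format(x[i, ], scientific = FALSE,
                                     trim = TRUE)),
            collapse = "\t")
    }, character(1))
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `variety`, `location`, `line`.
#'
#' @inheritParams sample_metadata
#' @param path TSV file.
#' @return Validated [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path, variety_levels = NULL,
                                 location_levels = NULL, line_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  sample_metadata(df, variety_levels = variety_levels,
                  location_levels = location_levels,
                  line_levels = line_levels)
}

#' Write sample metadata to TSV
#' @param metadata A [sample_metadata()] data frame.
#' @param path Output file.
#' @export
write_sample_metadata <- function(metadata, path) {
  write_tsv(data.frame(lapply(metadata, as.character),
                       stringsAsFactors = FALSE), path)
}

#' Read a taxonomy table
#'
#' TSV with columns `feature_id` and `lineage` (semicolon-delimited,
#' kingdom..genus, short lineages padded with `"unidentified"`), or the six
#' rank columns spelled out.
#'
#' @param path TSV file.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  if ("lineage" %in% names(df)) {
    parse_lineage(df$feature_id, df$lineage)
  } else {
    taxonomy_table(df)
  }
}

#' Write a taxonomy table as feature_id + lineage TSV
#' @param taxonomy A [taxonomy_table()].
#' @param path Output file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_tsv(data.frame(feature_id = taxonomy$feature_id,
                       lineage = format_lineage(taxonomy),
                       stringsAsFactors = FALSE), path)
}

#' Write and read generic result tables
#'
#' Plain TSV serialization for result data frames (PERMANOVA, ANOVA,
#' preference reports); `read_result_table(write_result_table(df))`
#' round-trips column names and cell values.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `read_result_table` returns a data frame.
#' @export
write_result_table <- function(df, path) {
  write_tsv(df, path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    quote = "", check.names = FALSE, fileEncoding = "UTF-8")
}

# deterministic unquoted TSV writer used by all table outputs
write_tsv <- function(df, path) {
  has_tab <- vapply(df, function(col) any(grepl("\t", as.character(col))),
                    logical(1))
  if (any(has_tab)) {
    stop("tabs are not allowed inside TSV cells", call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0) {
               do.call(paste, c(lapply(df, function(col) {
                 if (is.numeric(col)) format(col, scientific = FALSE,
                                             trim = TRUE, digits = 15)
                 else as.character(col)
               }), sep = "\t"))
             })
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Align counts, metadata and taxonomy to their shared identifiers
#'
#' Restricts the count matrix to samples present in the metadata and features
#' present in the taxonomy (when supplied), preserving the matrix's own
#' ordering, and subsets metadata/taxonomy to match. Ids dropped from any side
#' are reported.
#'
#' @param counts A [count_matrix()].
#' @param metadata A [sample_metadata()] data frame.
#' @param taxonomy Optional [taxonomy_table()]; `NULL` skips feature
#'   alignment.
#' @return List with elements `counts`, `metadata`, `taxonomy`, and `dropped`
#'   (lists of sample/feature ids removed from each input).
#' @export
align_dataset <- function(counts, metadata, taxonomy = NULL) {
  keep_s <- intersect(rownames(counts), metadata$sample_id)
  if (length(keep_s) == 0) {
    stop("no samples shared between counts and metadata", call. = FALSE)
  }
  keep_f <- colnames(counts)
  if (!is.null(taxonomy)) {
    keep_f <- intersect(colnames(counts), taxonomy$feature_id)
    if (length(keep_f) == 0) {
      stop("no features shared between counts and taxonomy", call. = FALSE)
    }
  }
  dropped <- list(
    samples_from_counts = setdiff(rownames(counts), keep_s),
    samples_from_metadata = setdiff(metadata$sample_id, keep_s),
    features_from_counts = setdiff(colnames(counts), keep_f),
    features_from_taxonomy =
      if (is.null(taxonomy)) character(0)
      else setdiff(taxonomy$feature_id, keep_f)
  )
  out_counts <- count_matrix(
    unclass_counts(counts)[keep_s, keep_f, drop = FALSE],
    rank = count_rank(counts))
  out_meta <- metadata[match(keep_s, metadata$sample_id), , drop = FALSE]
  out_meta <- droplevels(out_meta)
  rownames(out_meta) <- out_meta$sample_id
  out_tax <- if (is.null(taxonomy)) NULL
             else taxonomy[match(keep_f, taxonomy$feature_id), , drop = FALSE]
  list(counts = out_counts, metadata = out_meta, taxonomy = out_tax,
       dropped = dropped)
}
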