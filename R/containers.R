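#' @keywords internal
"_PACKAGE"

# Ranks of the lineage strings handled throughout, coarsest first.
TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

# Sentinel for ranks without an assignment.
UNIDENTIFIED <- "unidentified"

#' Construct a validated count matrix
#'
#' A count matrix holds non-negative integer read counts with samples as rows
#' and features (OTUs or collapsed taxa) as columns. Row and column names are
#' the sample and feature identifiers and must be unique. The `rank` attribute
#' records what the columns are ("otu" for uncollapsed tables, or a taxonomic
#' rank such as "genus" after collapsing).
#'
#' @param counts Numeric matrix of non-negative integers with unique rownames
#'   (sample ids) and colnames (feature ids).
#' @param rank Label for the feature axis, e.g. "otu", "genus", "order".
#' @return The matrix with class `count_matrix` and a `rank` attribute.
#' @export
count_matrix <- function(counts, rank = "otu") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("`counts` must have rownames (sample ids)", call. = FALSE)
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("`counts` must have colnames (feature ids)", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be non-negative integers; first offender at sample '",
         rownames(counts)[bad[1, 1]], "', feature '",
         colnames(counts)[bad[1, 2]], "'", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  structure(counts, rank = rank, class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d samples x %d features (rank: %s)\n",
              nrow(x), ncol(x), count_rank(x)))
  cat(sprintf("  total reads: %s; sample totals %s-%s\n",
              format(sum(x), big.mark = ","),
              format(min(rowSums(x))), format(max(rowSums(x)))))
  invisible(x)
}

#' Feature rank label of a count matrix
#' @param x A `count_matrix` (or plain matrix, in which case "otu" is assumed).
#' @return Character scalar.
#' @export
count_rank <- function(x) {
  r <- attr(x, "rank")
  if (is.null(r)) "otu" else r
}

# Strip the class for arithmetic, keep dimnames.
unclass_counts <- function(x) {
  attr(x, "rank") <- NULL
  class(x) <- NULL
  x
}

#' Construct validated per-sample metadata
#'
#' Metadata records the experimental design of each sample: the rootstock
#' `variety` (including ungrafted and self-grafted controls), the replicate-set
#' `location` in the field, and the planting `line`. Level sets may be declared
#' explicitly to catch typos; otherwise they are inferred from the data.
#'
#' @param df Data frame with columns `sample_id`, `variety`, `location`,
#'   `line`.
#' @param variety_levels,location_levels,line_levels Optional declared level
#'   sets; values outside them are an error.
#' @return Data frame with factor columns and unique `sample_id`.
#' @export
sample_metadata <- function(df, variety_levels = NULL, location_levels = NULL,
                            line_levels = NULL) {
  need <- c("sample_id", "variety", "location", "line")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  check_levels <- function(x, declared, what) {
    x <- as.character(x)
    if (!is.null(declared)) {
      bad <- setdiff(unique(x), declared)
      if (length(bad) > 0) {
        stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      factor(x, levels = declared)
    } else {
      factor(x)
    }
  }
  df$variety <- check_levels(df$variety, variety_levels, "variety")
  df$location <- check_levels(df$location, location_levels, "location")
  df$line <- check_levels(df$line, line_levels, "line")
  rownames(df) <- df$sample_id
  df
}

#' Construct a validated taxonomy table
#'
#' One row per feature, with the six lineage ranks kingdom..genus. Unassigned
#' ranks carry the sentinel `"unidentified"`; once a rank is unassigned all
#' lower ranks must be unassigned too (no gaps in the lineage).
#'
#' @param df Data frame with column `feature_id` plus the rank columns
#'   `kingdom`, `phylum`, `class`, `order`, `family`, `genus`.
#' @return Validated data frame (character columns).
#' @export
taxonomy_table <- function(df) {
  need <- c("feature_id", TAXONOMY_RANKS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("taxonomy is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature ids in taxonomy", call. = FALSE)
  }
  lin <- as.matrix(df[TAXONOMY_RANKS])
  unid <- lin == UNIDENTIFIED
  # cascade invariant: unassigned at rank r => unassigned below r
  gap <- which(unid[, -ncol(unid), drop = FALSE] & !unid[, -1, drop = FALSE],
               arr.ind = TRUE)
  if (length(gap) > 0) {
    stop("taxonomy lineage has an assigned rank below an unidentified one ",
         "(feature '", df$feature_id[gap[1]], "')", call. = FALSE)
  }
  rownames(df) <- df$feature_id
  df
}

#' Parse semicolon-delimited lineage strings
#'
#' Splits strings such as `"Bacteria;Proteobacteria;...;Sphingomonas"` into
#' the six canonical ranks, padding missing trailing ranks with
#' `"unidentified"`.
#'
#' @param feature_id Character vector of feature identifiers.
#' @param lineage Character vector of `;`-delimited lineages (up to 6 ranks).
#' @return A [taxonomy_table()].
#' @export
parse_lineage <- function(feature_id, lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == "" | is.na(p)] <- UNIDENTIFIED
    length(p) <- length(TAXONOMY_RANKS)
    p[is.na(p)] <- UNIDENTIFIED
    p
  }, character(length(TAXONOMY_RANKS))))
  colnames(mat) <- TAXONOMY_RANKS
  taxonomy_table(data.frame(feature_id = as.character(feature_id), mat,
                            stringsAsFactors = FALSE))
}

# Collapse a taxonomy row set back to "k;p;c;o;f;g" strings.
format_lineage <- function(taxonomy) {
  apply(as.matrix(taxonomy[TAXONOMY_RANKS]), 1, paste, collapse = ";")
}
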