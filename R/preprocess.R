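#' Preprocessing configuration
#'
#' Bundles the parameters of the standard preprocessing cascade applied to a
#' raw OTU table before community analysis: per-sample low-abundance cell
#' filtering, rarefaction to a common depth, optional taxonomic collapsing,
#' and an occurrence filter.
#'
#' @param cell_filter_fraction Cells below this fraction of their sample's
#'   total are zeroed (default 0.001, i.e. 0.1%).
#' @param rarefaction_depth Reads per sample after rarefaction (default 500);
#'   shallower samples are discarded.
#' @param occurrence_min_samples Features must be present (nonzero) in at
#'   least this many samples to be kept (default 30).
#' @param collapse_rank Taxonomic rank to collapse OTUs to (`"genus"`,
#'   `"order"`, ...) or `NULL` to stay at OTU level.
#' @param seed Master seed for the rarefaction subsampling.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(cell_filter_fraction = 0.001,
                              rarefaction_depth = 500,
                              occurrence_min_samples = 30,
                              collapse_rank = NULL,
                              seed = 1) {
  if (cell_filter_fraction < 0 || cell_filter_fraction >= 1) {
    stop("cell_filter_fraction must be in [0, 1)", call. = FALSE)
  }
  if (rarefaction_depth < 1) stop("rarefaction_depth must be >= 1",
                                  call. = FALSE)
  if (occurrence_min_samples < 0) stop("occurrence_min_samples must be >= 0",
                                       call. = FALSE)
  if (!is.null(collapse_rank) &&
      !collapse_rank %in% TAXONOMY_RANKS[-1]) {
    stop("unknown collapse_rank: ", collapse_rank, call. = FALSE)
  }
  structure(list(cell_filter_fraction = cell_filter_fraction,
                 rarefaction_depth = rarefaction_depth,
                 occurrence_min_samples = occurrence_min_samples,
                 collapse_rank = collapse_rank,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Zero low-abundance cells of a count table
#'
#' Cells whose read count is less than `fraction` of the sample's total read
#' count are set to zero, a standard guard against PCR and index-hopping
#' artefacts. The rule is strict (`count < fraction * total`) and single-pass:
#' thresholds use each sample's total *before* any cell is zeroed, which makes
#' the operation exactly idempotent only in the sense that re-running it on
#' its own output (with totals recomputed) can zero further cells; the
#' single-pass form is the one applied here. Features that become all-zero
#' are retained.
#'
#' @param x A [count_matrix()].
#' @param fraction Proportion threshold in `[0, 1)`, default 0.001.
#' @return Filtered [count_matrix()].
#' @export
filter_low_abundance_cells <- function(x, fraction = 0.001) {
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  m <- unclass_counts(x)
  thr <- fraction * rowSums(m)
  m[m < thr] <- 0          # thr recycles down columns: thr[i] for m[i, j]
  count_matrix(m, rank = count_rank(x))
}

# Deterministic per-sample RNG stream: polynomial hash of the sample id
# folded with the master seed, mod the Mersenne prime 2^31 - 1. Dropping or
# reordering samples never shifts another sample's subsample.
seed_for_sample <- function(master, sample_id) {
  p <- 2147483647
  h <- as.numeric(master) %% p
  for (code in utf8ToInt(sample_id)) h <- (h * 31 + code) %% p
  as.integer(h)
}

#' Rarefy a count table to fixed depth
#'
#' Each sample is subsampled uniformly at random *without replacement* to
#' exactly `depth` reads (multivariate hypergeometric); samples with fewer
#' than `depth` reads are discarded. Each sample draws from its own RNG
#' stream seeded by `(seed, sample id)`, so subsetting the matrix does not
#' change the subsample of the remaining samples. The caller's RNG state is
#' left untouched.
#'
#' @param x A [count_matrix()].
#' @param depth Target reads per sample (default 500).
#' @param seed Master seed.
#' @return List with `counts` (rarefied [count_matrix()]) and `discarded`
#'   (character vector of dropped sample ids).
#' @export
rarefy_counts <- function(x, depth = 500, seed = 1) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  m <- unclass_counts(x)
  totals <- rowSums(m)
  discarded <- rownames(m)[totals < depth]
  keep <- rownames(m)[totals >= depth]
  out <- matrix(0, length(keep), ncol(m),
                dimnames = list(keep, colnames(m)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  for (s in keep) {
    row <- m[s, ]
    total <- sum(row)
    if (total == depth) {
      out[s, ] <- row
      next
    }
    set.seed(seed_for_sample(seed, s))
    reads <- rep.int(seq_along(row), row)
    picked <- reads[sample.int(total, depth)]
    out[s, ] <- tabulate(picked, nbins = ncol(m))
  }
  list(counts = count_matrix(out, rank = count_rank(x)),
       discarded = discarded)
}

#' Collapse an OTU table to a higher taxonomic rank
#'
#' OTUs sharing the full lineage prefix down to `rank` are summed into one
#' bin. OTUs unassigned at `rank` fall into a bin labelled
#' `"unidentified <deepest assigned name>"`, one bin per distinct parent
#' lineage. Per-sample totals are conserved. Only OTU-rank matrices can be
#' collapsed (the taxonomy is keyed by OTU); collapsing an already collapsed
#' matrix is an error.
#'
#' @param x A [count_matrix()] at rank `"otu"`.
#' @param taxonomy A [taxonomy_table()] covering every feature of `x`.
#' @param rank Target rank, one of `"phylum"` .. `"genus"`.
#' @param drop_unidentified If `TRUE`, bins unassigned at `rank` are dropped
#'   after collapsing (default `FALSE`).
#' @return Collapsed [count_matrix()] with `rank` attribute set.
#' @export
collapse_to_rank <- function(x, taxonomy, rank, drop_unidentified = FALSE) {
  if (!rank %in% TAXONOMY_RANKS[-1]) {
    stop("unknown rank: ", rank, call. = FALSE)
  }
  if (count_rank(x) != "otu") {
    stop("collapse_to_rank needs an OTU-rank matrix; got rank '",
         count_rank(x), "' (collapsing must refine from OTUs)", call. = FALSE)
  }
  miss <- setdiff(colnames(x), taxonomy$feature_id)
  if (length(miss) > 0) {
    stop("features without taxonomy: ", paste(utils::head(miss, 5),
                                              collapse = ", "), call. = FALSE)
  }
  tax <- taxonomy[match(colnames(x), taxonomy$feature_id), , drop = FALSE]
  upto <- seq_len(match(rank, TAXONOMY_RANKS))
  lin <- as.matrix(tax[TAXONOMY_RANKS[upto]])
  is_unid <- lin[, length(upto)] == UNIDENTIFIED
  key <- apply(lin, 1, paste, collapse = ";")
  label <- lin[, length(upto)]
  if (any(is_unid)) {
    deepest <- apply(lin[is_unid, -length(upto), drop = FALSE], 1, function(r) {
      assigned <- r[r != UNIDENTIFIED]
      if (length(assigned) == 0) UNIDENTIFIED else assigned[length(assigned)]
    })
    label[is_unid] <- paste(UNIDENTIFIED, deepest)
  }
  # first-appearance order of bins; disambiguate label collisions across
  # distinct lineage prefixes
  keys <- unique(key)
  labels <- label[match(keys, key)]
  labels <- make.unique(labels, sep = " #")
  grp <- factor(key, levels = keys)
  collapsed <- t(rowsum(t(unclass_counts(x)), grp))
  colnames(collapsed) <- labels
  if (drop_unidentified) {
    keep <- !startsWith(labels, UNIDENTIFIED)
    collapsed <- collapsed[, keep, drop = FALSE]
  }
  count_matrix(collapsed, rank = rank)
}

#' Keep features occurring in enough samples
#'
#' A feature "occurs" in a sample when its count is nonzero. Features present
#' in fewer than `min_samples` samples are removed; samples are untouched.
#'
#' @param x A [count_matrix()].
#' @param min_samples Minimum number of samples with nonzero count
#'   (default 30).
#' @return Filtered [count_matrix()].
#' @export
filter_by_occurrence <- function(x, min_samples = 30) {
  if (min_samples < 0) stop("min_samples must be >= 0", call. = FALSE)
  occ <- colSums(unclass_counts(x) > 0)
  count_matrix(unclass_counts(x)[, occ >= min_samples, drop = FALSE],
               rank = count_rank(x))
}

#' Convert counts to relative abundances
#'
#' @param x A [count_matrix()].
#' @return Numeric matrix of per-sample proportions (rows sum to 1).
#' @export
to_relative_abundance <- function(x) {
  m <- unclass_counts(x)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  m / totals
}

#' Run the full preprocessing cascade
#'
#' Applies, in order: low-abundance cell filter, rarefaction (discarding
#' shallow samples), optional collapsing to `collapse_rank`, and the
#' occurrence filter at the analyzed rank.
#'
#' @param x Raw [count_matrix()] at OTU rank.
#' @param taxonomy A [taxonomy_table()]; required when `collapse_rank` is
#'   set.
#' @param config A [preprocess_config()].
#' @return List with `counts` (analysis-ready matrix), `rarefied` (OTU-level
#'   rarefied matrix before collapsing/occurrence filtering), `discarded`
#'   (sample ids dropped at rarefaction), and `config`.
#' @export
preprocess_counts <- function(x, taxonomy = NULL,
                              config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  filtered <- filter_low_abundance_cells(x, config$cell_filter_fraction)
  rar <- rarefy_counts(filtered, depth = config$rarefaction_depth,
                       seed = config$seed)
  out <- rar$counts
  if (!is.null(config$collapse_rank)) {
    if (is.null(taxonomy)) {
      stop("collapse_rank set but no taxonomy supplied", call. = FALSE)
    }
    out <- collapse_to_rank(out, taxonomy, config$collapse_rank)
  }
  out <- filter_by_occurrence(out, config$occurrence_min_samples)
  list(counts = out, rarefied = rar$counts, discarded = rar$discarded,
       config = config)
}
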