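#' Observed per-variety mean counts
#'
#' Cell (i, j) is the arithmetic mean of taxon i's read counts over the
#' samples of variety j — the observed statistic of the host-genotype
#' preference test.
#'
#' @param x A [count_matrix()] (rarefied, so counts are comparable across
#'   samples).
#' @param metadata A [sample_metadata()] data frame.
#' @return Taxa x variety numeric matrix.
#' @export
observed_group_means <- function(x, metadata) {
  miss <- setdiff(rownames(x), metadata$sample_id)
  if (length(miss) > 0) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md <- metadata[match(rownames(x), metadata$sample_id), , drop = FALSE]
  g <- md$variety
  empty <- levels(g)[tabulate(g, nlevels(g)) == 0]
  if (length(empty) > 0) {
    stop("variety level(s) with no samples: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  nj <- tabulate(g, nlevels(g))
  means <- rowsum(unclass_counts(x), as.integer(g)) / nj
  rownames(means) <- levels(g)
  t(means)
}

#' Host-genotype preference randomization test
#'
#' For every (taxon, variety) pair the preference index is the z-score
#'
#' \deqn{(N_{obs}(i,j) - \mathrm{Mean}(N_{rand}(i,j))) /
#'       \mathrm{SD}(N_{rand}(i,j))}
#'
#' where \eqn{N_{obs}(i,j)} is the mean read count of taxon i over the
#' samples of variety j and the null moments are taken over permutations in
#' which the variety labels of all samples are shuffled jointly — one shuffle
#' per iteration, shared across taxa, preserving group sizes and cross-taxon
#' dependence. Significance is decided on the upper-tail empirical p-value
#' `(1 + #\{permuted mean >= observed\}) / (1 + n_perm)` (ties count as
#' exceedances), Bonferroni-corrected across the variety conditions of each
#' taxon (`alpha / n_varieties`). Cross-taxon multiplicity is reported but
#' not corrected. The z-scores are descriptive; significance is based on the
#' empirical p, not a normal approximation.
#'
#' @param x A rarefied [count_matrix()] at the rank under test (genus or
#'   OTU).
#' @param metadata A [sample_metadata()] data frame.
#' @param n_perm Number of label permutations (default 999; published
#'   analyses of this design use 100000).
#' @param seed Seed for the shuffles; `NULL` leaves the RNG alone.
#' @param min_occurrence Taxa present in fewer samples are excluded before
#'   testing (default 30).
#' @param alpha Family-wise significance level (default 0.05).
#' @param tail `"preference"` tests for enrichment (upper tail, default);
#'   `"avoidance"` tests the lower tail.
#' @return A `preference_result` list: `N_observed`, `null_mean`, `null_sd`,
#'   `preference` (z-scores), `p_empirical`, `significant` (all taxa x
#'   variety matrices), plus the test settings. Null SD of exactly zero
#'   yields z = 0 and p = 1 by convention.
#' @export
preference_analysis <- function(x, metadata, n_perm = 999, seed = NULL,
                                min_occurrence = 30, alpha = 0.05,
                                tail = c("preference", "avoidance")) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  x <- filter_by_occurrence(x, min_occurrence)
  if (ncol(x) == 0) {
    stop("no taxa pass the occurrence filter (min_occurrence = ",
         min_occurrence, ")", call. = FALSE)
  }
  miss <- setdiff(rownames(x), metadata$sample_id)
  if (length(miss) > 0) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md <- metadata[match(rownames(x), metadata$sample_id), , drop = FALSE]
  g <- droplevels(md$variety)
  nlev <- nlevels(g)
  nj <- tabulate(g, nlev)
  if (any(nj < 1)) {
    stop("variety level(s) with no samples: ",
         paste(levels(g)[nj < 1], collapse = ", "), call. = FALSE)
  }
  m <- unclass_counts(x)
  n <- nrow(m)
  gi <- as.integer(g)
  obs <- rowsum(m, gi) / nj          # varieties x taxa

  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(seed)
  }
  acc <- matrix(0, nlev, ncol(m))     # running sum of permuted means
  acc2 <- matrix(0, nlev, ncol(m))    # running sum of squares
  exceed <- matrix(0L, nlev, ncol(m))
  for (b in seq_len(n_perm)) {
    perm_means <- rowsum(m, gi[sample.int(n)]) / nj
    acc <- acc + perm_means
    acc2 <- acc2 + perm_means^2
    exceed <- exceed + if (tail == "preference") (perm_means >= obs)
                       else (perm_means <= obs)
  }
  null_mean <- acc / n_perm
  null_sd <- sqrt(pmax(acc2 / n_perm - null_mean^2, 0))  # population SD
  z <- (obs - null_mean) / null_sd
  p <- (1 + exceed) / (1 + n_perm)
  degenerate <- null_sd <= .Machine$double.eps^0.5 * pmax(null_mean, 1)
  z[degenerate] <- 0
  p[degenerate] <- 1
  sig <- p < alpha / nlev

  shape <- function(mat) {
    mat <- t(mat)
    dimnames(mat) <- list(colnames(m), levels(g))
    mat
  }
  structure(list(taxa = colnames(m), varieties = levels(g),
                 N_observed = shape(obs), null_mean = shape(null_mean),
                 null_sd = shape(null_sd), preference = shape(z),
                 p_empirical = shape(p), significant = shape(sig),
                 n_permutations = n_perm, seed = seed, alpha = alpha,
                 m_comparisons = nlev, tail = tail,
                 min_occurrence = min_occurrence),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf(
    "Host-genotype preference test: %d taxa x %d varieties, %d permutations\n",
    length(x$taxa), length(x$varieties), x$n_permutations))
  cat(sprintf("  %d significant pair(s) at alpha = %g / %d\n",
              sum(x$significant), x$alpha, x$m_comparisons))
  invisible(x)
}

#' Tabulate significant host-genotype preferences
#'
#' One row per Bonferroni-significant (taxon, variety) pair, sorted by
#' ascending empirical p, with the taxon's lineage attached when a taxonomy
#' is supplied. With no significant pairs an empty table with headers is
#' returned.
#'
#' @param result A [preference_analysis()] result.
#' @param taxonomy Optional [taxonomy_table()] keyed by the result's taxa.
#' @return Data frame `taxon`, `preferred_variety`, `preference`,
#'   `p_empirical` (+ lineage columns `phylum` .. `genus` if taxonomy given).
#' @export
preference_report <- function(result, taxonomy = NULL) {
  stopifnot(inherits(result, "preference_result"))
  hits <- which(result$significant, arr.ind = TRUE)
  out <- data.frame(taxon = result$taxa[hits[, 1]],
                    preferred_variety = result$varieties[hits[, 2]],
                    preference = result$preference[hits],
                    p_empirical = result$p_empirical[hits],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_empirical, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(taxonomy)) {
    ranks <- setdiff(TAXONOMY_RANKS, "kingdom")
    idx <- match(out$taxon, taxonomy$feature_id)
    for (r in ranks) out[[r]] <- taxonomy[[r]][idx]
  }
  out
}
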