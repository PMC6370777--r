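#' Raup-Crick dissimilarity
#'
#' Presence-absence beta-diversity expressed as the probability, under a null
#' assembly model, that two samples share more species than observed. For a
#' pair with observed shared richness s, the dissimilarity is
#' `(#\{null shared > s\} + 0.5 * #\{null shared = s\}) / n_sim`, so chance
#' expectation sits at 0.5, values near 1 mean less shared than expected, and
#' values near 0 mean more shared than expected.
#'
#' The `"null-model"` variant fixes each sample's richness and assembles null
#' samples by drawing species without replacement with probability
#' proportional to their occurrence frequency across samples. The
#' `"analytic"` variant replaces simulation by the closed-form hypergeometric
#' tail under an equiprobable species pool; the two agree on equiprobable
#' pools as `n_sim` grows.
#'
#' @param x A [count_matrix()]; counts are binarized internally.
#' @param variant `"null-model"` (default) or `"analytic"`.
#' @param n_sim Number of null assemblages for the null-model variant
#'   (default 999).
#' @param seed Seed for the null simulation; `NULL` leaves the RNG alone.
#' @return A `dist` object with entries in `[0, 1]`.
#' @export
raup_crick <- function(x, variant = c("null-model", "analytic"),
                       n_sim = 999, seed = NULL) {
  variant <- match.arg(variant)
  pa <- unclass_counts(x) > 0
  richness <- rowSums(pa)
  if (any(richness == 0)) {
    stop("sample(s) with zero richness: ",
         paste(rownames(pa)[richness == 0], collapse = ", "), call. = FALSE)
  }
  freq <- colSums(pa)
  in_pool <- freq > 0
  pa <- pa[, in_pool, drop = FALSE]
  freq <- freq[in_pool]
  n <- nrow(pa)
  pool <- ncol(pa)
  storage.mode(pa) <- "double"
  shared_obs <- tcrossprod(pa)

  if (variant == "analytic") {
    d <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        s <- shared_obs[i, j]
        a <- richness[i]
        b <- richness[j]
        d[i, j] <- d[j, i] <-
          stats::phyper(s, a, pool - a, b, lower.tail = FALSE) +
          0.5 * stats::dhyper(s, a, pool - a, b)
      }
    }
    return(stats::as.dist(d))
  }

  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(seed)
  }
  gt <- matrix(0, n, n)
  eq <- matrix(0, n, n)
  sim <- matrix(0, n, pool)
  for (b in seq_len(n_sim)) {
    sim[] <- 0
    for (i in seq_len(n)) {
      sim[i, sample.int(pool, richness[i], prob = freq)] <- 1
    }
    shared_sim <- tcrossprod(sim)
    gt <- gt + (shared_sim > shared_obs)
    eq <- eq + (shared_sim == shared_obs)
  }
  d <- (gt + 0.5 * eq) / n_sim
  diag(d) <- 0
  dimnames(d) <- list(rownames(pa), rownames(pa))
  stats::as.dist(d)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Sequential (order-of-entry) partitioning of the Gower-centered distance
#' sum of squares over the listed metadata factors, with significance by free
#' permutation of sample labels. Computed with [vegan::adonis2()]
#' (`by = "terms"`); the permutation p-value follows the
#' `(1 + exceedances) / (1 + permutations)` convention.
#'
#' @param d A `dist` with sample labels (e.g. from [raup_crick()]).
#' @param metadata A [sample_metadata()] data frame covering all samples of
#'   `d`.
#' @param terms Factor names in order of entry, default
#'   `c("variety", "location")`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutations; `NULL` leaves the RNG alone.
#' @return A `permanova_result` data frame: one row per term plus Residual
#'   and Total, with columns `term`, `df`, `SS`, `R2`, `pseudo_F`, `p`.
#' @export
community_permanova <- function(d, metadata, terms = c("variety", "location"),
                                n_perm = 10000, seed = NULL) {
  if (length(terms) == 0) stop("`terms` must be non-empty", call. = FALSE)
  labs <- attr(d, "Labels")
  if (is.null(labs)) stop("`d` must carry sample labels", call. = FALSE)
  miss <- setdiff(labs, metadata$sample_id)
  if (length(miss) > 0) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (all(d == 0)) stop("degenerate distances", call. = FALSE)
  md <- metadata[match(labs, metadata$sample_id), , drop = FALSE]
  md <- droplevels(md)
  if (!is.null(seed)) set.seed(seed)
  f <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  fit <- vegan::adonis2(f, data = md, permutations = n_perm, by = "terms")
  out <- data.frame(term = rownames(fit),
                    df = fit$Df,
                    SS = fit$SumOfSqs,
                    R2 = fit$R2,
                    pseudo_F = fit$F,
                    p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_perm = n_perm, seed = seed,
            class = c("permanova_result", "data.frame"))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", attr(x, "n_perm"), "permutations)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-taxon two-way ANOVA
#'
#' For each taxon, fits a fixed-effects ANOVA of its per-sample relative
#' abundance on `variety` then `location` (sequential type-I sums of squares,
#' no interaction) and reports the parametric F tests. Taxa with a constant
#' response are flagged `degenerate` with `NA` statistics rather than
#' raising.
#'
#' @param props Samples x taxa matrix of proportions (see
#'   [to_relative_abundance()]).
#' @param metadata A [sample_metadata()] data frame covering all samples.
#' @param min_occurrence If > 0, taxa with nonzero abundance in fewer samples
#'   are dropped first (default 0: assume prefiltered).
#' @param terms Explanatory factors in order of entry.
#' @return An `anova_result` data frame, one row per taxon.
#' @export
taxon_anova <- function(props, metadata, min_occurrence = 0,
                        terms = c("variety", "location")) {
  miss <- setdiff(rownames(props), metadata$sample_id)
  if (length(miss) > 0) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (min_occurrence > 0) {
    occ <- colSums(props > 0)
    props <- props[, occ >= min_occurrence, drop = FALSE]
  }
  md <- droplevels(metadata[match(rownames(props), metadata$sample_id), ,
                            drop = FALSE])
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  rows <- lapply(colnames(props), function(taxon) {
    y <- props[, taxon]
    base <- list(taxon = taxon)
    if (stats::var(y) == 0) {
      for (tm in terms) {
        base[[paste0(tm, "_df")]] <- NA_integer_
        base[[paste0(tm, "_F")]] <- NA_real_
        base[[paste0(tm, "_p")]] <- NA_real_
      }
      base$residual_df <- NA_integer_
      base$degenerate <- TRUE
      return(as.data.frame(base, stringsAsFactors = FALSE))
    }
    tab <- stats::anova(stats::lm(f, data = cbind(md, y = y)))
    for (tm in terms) {
      base[[paste0(tm, "_df")]] <- tab[tm, "Df"]
      base[[paste0(tm, "_F")]] <- tab[tm, "F value"]
      base[[paste0(tm, "_p")]] <- tab[tm, "Pr(>F)"]
    }
    base$residual_df <- tab["Residuals", "Df"]
    base$degenerate <- FALSE
    as.data.frame(base, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("anova_result", "data.frame"))
}

#' Rarefaction and sample-accumulation curves
#'
#' Per-sample rarefaction curves use the exact hypergeometric expectation of
#' richness at subsampled depths ([vegan::rarefy()]); the sample-accumulation
#' curve is the mean richness over sample orderings
#' ([vegan::specaccum()], method `"exact"` averages over all orderings
#' analytically, `"random"` over `n_perm` random orderings).
#'
#' @param x A [count_matrix()].
#' @param step Depth increment of the rarefaction curves (default 25).
#' @param method Accumulation method, `"exact"` (default) or `"random"`.
#' @param n_perm Random orderings when `method = "random"`.
#' @param seed Seed used for `method = "random"`.
#' @return List with data frames `rarefaction` (`sample_id`, `depth`,
#'   `expected_richness`) and `accumulation` (`n_samples`, `richness`, `sd`).
#' @export
diversity_curves <- function(x, step = 25, method = c("exact", "random"),
                             n_perm = 100, seed = NULL) {
  method <- match.arg(method)
  m <- unclass_counts(x)
  totals <- rowSums(m)
  if (step > min(totals)) {
    stop("step (", step, ") exceeds the smallest sample total (",
         min(totals), ")", call. = FALSE)
  }
  rar <- do.call(rbind, lapply(rownames(m), function(s) {
    depths <- unique(c(seq(step, totals[s], by = step), totals[s]))
    data.frame(sample_id = s, depth = depths,
               expected_richness =
                 as.vector(suppressWarnings(
                   vegan::rarefy(m[s, , drop = FALSE], sample = depths))),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(seed)) set.seed(seed)
  acc <- suppressWarnings(vegan::specaccum(m, method = method,
                                           permutations = n_perm))
  accumulation <- data.frame(n_samples = acc$sites, richness = acc$richness,
                             sd = if (is.null(acc$sd)) NA_real_ else acc$sd)
  list(rarefaction = rar, accumulation = accumulation)
}

#' Per-variety community composition summary
#'
#' For each variety, the pooled read proportion of each taxon (taxon reads
#' summed over the variety's samples, divided by those samples' total reads)
#' and, secondarily, the mean of the per-sample proportions.
#'
#' @param x A [count_matrix()] at the rank of interest.
#' @param metadata A [sample_metadata()] data frame.
#' @return Data frame `variety`, `taxon`, `pooled_proportion`,
#'   `mean_proportion`.
#' @export
composition_summary <- function(x, metadata) {
  al <- align_dataset(x, metadata)
  m <- unclass_counts(al$counts)
  md <- al$metadata
  props <- to_relative_abundance(al$counts)
  out <- do.call(rbind, lapply(levels(md$variety), function(v) {
    rows <- md$variety == v
    pooled <- colSums(m[rows, , drop = FALSE]) / sum(m[rows, , drop = FALSE])
    data.frame(variety = v, taxon = colnames(m),
               pooled_proportion = as.vector(pooled),
               mean_proportion = as.vector(colMeans(props[rows, ,
                                                          drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
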