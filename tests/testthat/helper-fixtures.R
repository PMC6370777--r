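# Small programmatic fixtures and independent oracles shared across tests.

random_counts <- function(n_samples, n_features, seed, lambda = 5,
                          rank = "otu") {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_features, lambda), n_samples, n_features,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("f%02d", seq_len(n_features))))
  count_matrix(m, rank = rank)
}

balanced_metadata <- function(n_varieties = 9, n_locations = 15,
                              per_cell = 1) {
  grid <- expand.grid(variety = sprintf("V%d", seq_len(n_varieties)),
                      location = sprintf("L%02d", seq_len(n_locations)),
                      rep = seq_len(per_cell), stringsAsFactors = FALSE)
  sample_metadata(data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(grid))),
    variety = grid$variety, location = grid$location,
    line = sprintf("line%d", ((match(grid$location,
                                     unique(grid$location)) - 1) %/%
                              max(1, ceiling(n_locations / 3))) + 1),
    stringsAsFactors = FALSE))
}

toy_taxonomy <- function(feature_ids, genus, order = NULL) {
  n <- length(feature_ids)
  if (is.null(order)) order <- rep("OrderA", n)
  taxonomy_table(data.frame(
    feature_id = feature_ids, kingdom = "K", phylum = "P", class = "C",
    order = order, family = paste0("Fam_", genus), genus = genus,
    stringsAsFactors = FALSE))
}

# Exact upper-tail permutation p-values for the preference statistic by full
# enumeration of all label permutations (feasible for <= 8 samples).
# Returns a taxa x variety matrix of P(permuted group mean >= observed).
exact_preference_p <- function(counts, variety) {
  g <- factor(variety)
  n <- length(g)
  stopifnot(n <= 8, nrow(counts) == n)
  nj <- tabulate(g, nlevels(g))
  obs <- rowsum(unclass(counts), as.integer(g)) / nj
  perms <- all_permutations(n)
  hits <- matrix(0, nlevels(g), ncol(counts))
  for (k in seq_len(nrow(perms))) {
    pm <- rowsum(unclass(counts), as.integer(g)[perms[k, ]]) / nj
    hits <- hits + (pm >= obs)
  }
  p <- t(hits / nrow(perms))
  dimnames(p) <- list(colnames(counts), levels(g))
  p
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Exact Raup-Crick dissimilarity for two samples under the equiprobable null
# (closed hypergeometric form), used as the enumeration-backed oracle.
exact_raup_crick_pair <- function(shared, rich_a, rich_b, pool) {
  p_gt <- phyper(shared, rich_a, pool - rich_a, rich_b, lower.tail = FALSE)
  p_eq <- dhyper(shared, rich_a, pool - rich_a, rich_b)
  p_gt + 0.5 * p_eq
}

# Textbook two-way ANOVA F statistics for a *balanced* design, from group
# means only (orthogonal factors, so sequential and marginal SS coincide).
oracle_balanced_anova <- function(y, a, b) {
  grand <- mean(y)
  ss_for <- function(f) sum(tapply(y, f, length) *
                            (tapply(y, f, mean) - grand)^2)
  ss_a <- ss_for(a)
  ss_b <- ss_for(b)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_a - ss_b
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_res <- length(y) - 1 - df_a - df_b
  list(F_a = (ss_a / df_a) / (ss_res / df_res),
       F_b = (ss_b / df_b) / (ss_res / df_res),
       df_res = df_res)
}
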