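#' Configuration of the synthetic field-experiment generator
#'
#' Describes a grafted-plant field design (varieties x replicate-set
#' locations), a compositional community model, and a sequencing-depth model:
#'
#' * each taxon gets a log-normal baseline relative abundance;
#' * variety-preference and location effects multiply the expected relative
#'   abundance of chosen taxa before renormalization;
#' * the realized composition of a sample is Dirichlet with concentration
#'   `overdispersion` times the expected composition (Dirichlet-multinomial
#'   counts, the minimal overdispersed model for amplicon data);
#' * sequencing depth is log-normal, truncated at `low_depth_cutoff`; a
#'   fraction `low_depth_fraction` of samples is instead given a depth below
#'   the cutoff, so that rarefaction at that cutoff drops them.
#'
#' @param n_varieties Number of rootstock varieties (default 9).
#' @param n_locations Number of replicate-set locations (default 15).
#' @param samples_per_cell Samples per variety x location cell (default 1,
#'   giving 135 samples).
#' @param n_taxa Number of taxa / OTUs (default 150).
#' @param baseline_log_sd SD of the log-normal baseline relative abundances
#'   (default 1.5).
#' @param preference_effects Data frame (`taxon`, `variety`, `fold`) of
#'   multiplicative variety effects, or `NULL`.
#' @param location_effects Data frame (`taxon`, `location`, `fold`) of
#'   multiplicative location effects, or `NULL`.
#' @param overdispersion Dirichlet concentration parameter (sum of the
#'   Dirichlet weights; larger = less compositional noise; default 200).
#' @param depth_meanlog,depth_sdlog Log-scale mean and SD of the sequencing
#'   depth distribution (defaults `log(5000)` and 0.5).
#' @param low_depth_fraction Probability that a sample's depth is forced
#'   below `low_depth_cutoff` (default 0.07).
#' @param low_depth_cutoff Rarefaction cutoff the low-depth samples fall
#'   under (default 500).
#' @param unassigned_genus_fraction Fraction of taxa left unidentified at
#'   genus rank in the synthetic taxonomy (default 0.1).
#' @param seed Master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_varieties = 9, n_locations = 15,
                             samples_per_cell = 1, n_taxa = 150,
                             baseline_log_sd = 1.5,
                             preference_effects = NULL,
                             location_effects = NULL,
                             overdispersion = 200,
                             depth_meanlog = log(5000), depth_sdlog = 0.5,
                             low_depth_fraction = 0.07,
                             low_depth_cutoff = 500,
                             unassigned_genus_fraction = 0.1,
                             seed = 1) {
  check_effects <- function(eff, key) {
    if (is.null(eff) || nrow(eff) == 0) {
      out <- data.frame(taxon = character(0), key = character(0),
                        fold = numeric(0), stringsAsFactors = FALSE)
      names(out) <- c("taxon", key, "fold")
      return(out)
    }
    eff <- as.data.frame(eff)
    stopifnot(all(c("taxon", key, "fold") %in% names(eff)))
    if (any(eff$fold <= 0)) stop("fold-changes must be > 0", call. = FALSE)
    eff[c("taxon", key, "fold")]
  }
  if (overdispersion <= 0) stop("overdispersion must be > 0", call. = FALSE)
  if (low_depth_fraction < 0 || low_depth_fraction > 1) {
    stop("low_depth_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_varieties >= 1, n_locations >= 1, samples_per_cell >= 1,
            n_taxa >= 2, baseline_log_sd >= 0, depth_sdlog >= 0,
            low_depth_cutoff >= 2,
            unassigned_genus_fraction >= 0, unassigned_genus_fraction < 1)
  structure(list(n_varieties = n_varieties, n_locations = n_locations,
                 samples_per_cell = samples_per_cell, n_taxa = n_taxa,
                 baseline_log_sd = baseline_log_sd,
                 preference_effects = check_effects(preference_effects,
                                                    "variety"),
                 location_effects = check_effects(location_effects,
                                                  "location"),
                 overdispersion = overdispersion,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 low_depth_fraction = low_depth_fraction,
                 low_depth_cutoff = low_depth_cutoff,
                 unassigned_genus_fraction = unassigned_genus_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Convenience constructors for synthetic configurations
#'
#' `null_config()` has no planted effects (the calibration condition);
#' `planted_config()` records the supplied preference effects.
#'
#' @param effects Data frame (`taxon`, `variety`, `fold`) of planted variety
#'   preferences.
#' @param ... Passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
null_config <- function(...) synthetic_config(preference_effects = NULL, ...)

#' @rdname null_config
#' @export
planted_config <- function(effects, ...) {
  synthetic_config(preference_effects = effects, ...)
}

#' Deterministic synthetic taxonomy
#'
#' Assigns `n_taxa` taxa round-robin to `ceiling(n_taxa / 3)` genera spread
#' over 10 orders (several taxa per genus, to exercise collapsing); the last
#' `unassigned_genus_fraction` of taxa are left `"unidentified"` at genus
#' rank. Purely deterministic in the config's sizes (no RNG), so the same
#' taxa keep the same lineage across seeds.
#'
#' @param config A [synthetic_config()].
#' @return A [taxonomy_table()].
#' @export
synthetic_taxonomy <- function(config) {
  n <- config$n_taxa
  ids <- sprintf("t%03d", seq_len(n))
  n_gen <- max(1, ceiling(n / 3))
  n_ord <- min(10, n_gen)
  gen_idx <- rep_len(seq_len(n_gen), n)
  ord_idx <- ((gen_idx - 1) %% n_ord) + 1
  df <- data.frame(
    feature_id = ids,
    kingdom = "SynKingdom",
    phylum = sprintf("Phylum%02d", ((ord_idx - 1) %% 4) + 1),
    class = sprintf("Class%02d", ((ord_idx - 1) %% 6) + 1),
    order = sprintf("Order%02d", ord_idx),
    family = sprintf("Family%02d", gen_idx),
    genus = sprintf("Genus%02d", gen_idx),
    stringsAsFactors = FALSE)
  n_unassigned <- floor(config$unassigned_genus_fraction * n)
  if (n_unassigned > 0) {
    unid <- seq(n - n_unassigned + 1, n)
    df$genus[unid] <- UNIDENTIFIED
  }
  taxonomy_table(df)
}

#' Expected sample composition under a synthetic configuration
#'
#' The analytic expectation used by the generator and by its tests: baseline
#' abundances times the variety/location fold-changes, renormalized.
#'
#' @param baseline Numeric vector of baseline (unnormalized) abundances.
#' @param config A [synthetic_config()].
#' @param variety,location Labels of the sample's design cell.
#' @return Probability vector over taxa.
#' @export
expected_composition <- function(baseline, config, variety, location) {
  w <- baseline
  pe <- config$preference_effects
  sel <- pe$variety == variety
  if (any(sel)) {
    i <- match(pe$taxon[sel], names(baseline))
    w[i] <- w[i] * pe$fold[sel]
  }
  le <- config$location_effects
  sel <- le$location == location
  if (any(sel)) {
    i <- match(le$taxon[sel], names(baseline))
    w[i] <- w[i] * le$fold[sel]
  }
  w / sum(w)
}

#' Generate a synthetic field-experiment dataset
#'
#' Draws a full dataset under the model described in [synthetic_config()]:
#' balanced variety x location design, log-normal taxon baselines,
#' multiplicative planted effects, Dirichlet-multinomial counts, and variable
#' sequencing depth. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `counts` (a [count_matrix()], rank `"otu"`),
#'   `metadata` (a [sample_metadata()]), `taxonomy` (a [taxonomy_table()]),
#'   and `baseline` (the drawn baseline relative abundances).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  varieties <- c("ungrafted",
                 sprintf("variety%02d", seq_len(config$n_varieties - 1)))
  locations <- sprintf("loc%02d", seq_len(config$n_locations))
  grid <- expand.grid(variety = varieties, location = locations,
                      rep = seq_len(config$samples_per_cell),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  # three planting lines of equal location blocks, as in a lined field layout
  line_of <- ceiling(match(grid$location, locations) /
                     max(1, ceiling(config$n_locations / 3)))
  metadata <- sample_metadata(data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    variety = grid$variety,
    location = grid$location,
    line = sprintf("line%d", line_of),
    stringsAsFactors = FALSE))

  taxonomy <- synthetic_taxonomy(config)
  taxa <- taxonomy$feature_id
  baseline <- stats::setNames(
    stats::rlnorm(config$n_taxa, meanlog = 0,
                  sdlog = config$baseline_log_sd), taxa)
  baseline <- baseline / sum(baseline)

  unknown <- setdiff(c(config$preference_effects$taxon,
                       config$location_effects$taxon), taxa)
  if (length(unknown) > 0) {
    stop("effects reference unknown taxa: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_var <- setdiff(config$preference_effects$variety, varieties)
  if (length(bad_var) > 0) {
    stop("effects reference unknown varieties: ",
         paste(bad_var, collapse = ", "), call. = FALSE)
  }

  depths <- integer(n)
  low <- stats::runif(n) < config$low_depth_fraction
  depths[low] <- sample.int(config$low_depth_cutoff - 1, sum(low),
                            replace = TRUE)
  n_hi <- sum(!low)
  if (n_hi > 0) {
    d <- stats::rlnorm(n_hi, config$depth_meanlog, config$depth_sdlog)
    # truncate at the cutoff so only the designated fraction falls below it
    while (any(d < config$low_depth_cutoff)) {
      redo <- d < config$low_depth_cutoff
      d[redo] <- stats::rlnorm(sum(redo), config$depth_meanlog,
                               config$depth_sdlog)
    }
    depths[!low] <- round(d)
  }

  counts <- matrix(0, n, config$n_taxa,
                   dimnames = list(metadata$sample_id, taxa))
  for (i in seq_len(n)) {
    p <- expected_composition(baseline, config, metadata$variety[i],
                              metadata$location[i])
    gam <- stats::rgamma(config$n_taxa,
                         shape = config$overdispersion * p, rate = 1)
    if (sum(gam) == 0) gam[which.max(p)] <- 1
    counts[i, ] <- stats::rmultinom(1, depths[i], gam / sum(gam))
  }
  list(counts = count_matrix(counts, rank = "otu"), metadata = metadata,
       taxonomy = taxonomy, baseline = baseline)
}

#' Serialize and restore synthetic configurations
#'
#' YAML round-trip for [synthetic_config()] objects; effect tables are stored
#' as lists of records.
#'
#' @param config A [synthetic_config()].
#' @param path YAML file path.
#' @return `read_synthetic_config()` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  obj <- unclass(config)
  obj$preference_effects <- df_to_records(config$preference_effects)
  obj$location_effects <- df_to_records(config$location_effects)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$preference_effects <- records_to_df(obj$preference_effects,
                                          c("taxon", "variety", "fold"))
  obj$location_effects <- records_to_df(obj$location_effects,
                                        c("taxon", "location", "fold"))
  do.call(synthetic_config, obj)
}

df_to_records <- function(df) {
  if (nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

records_to_df <- function(records, cols) {
  if (length(records) == 0) return(NULL)
  do.call(rbind, lapply(records, function(r) {
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
}
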