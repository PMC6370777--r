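#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: input locations (or a synthetic
#' configuration), preprocessing parameters, permutation counts for each
#' test, and the output directory. Every stochastic stage derives its own
#' stream from the master `seed`, so a run is fully reproducible.
#'
#' @param counts_path,metadata_path,taxonomy_path Input TSV paths; ignored
#'   when `synthetic` is given.
#' @param synthetic Optional [synthetic_config()]; when set, the input
#'   dataset is generated rather than read.
#' @param preprocess A [preprocess_config()].
#' @param permanova_terms,permanova_n_perm PERMANOVA factors and permutation
#'   count (default 10000).
#' @param raup_crick_n_sim Null assemblages per Raup-Crick matrix
#'   (default 999).
#' @param preference_n_perm Preference-test permutations (default 100000;
#'   use 999 for quick runs).
#' @param min_occurrence Occurrence filter for the per-taxon tests
#'   (default 30).
#' @param alpha Significance level for the preference test (default 0.05).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL, synthetic = NULL,
                            preprocess = preprocess_config(),
                            permanova_terms = c("variety", "location"),
                            permanova_n_perm = 10000,
                            raup_crick_n_sim = 999,
                            preference_n_perm = 100000,
                            min_occurrence = 30, alpha = 0.05,
                            out_dir = "graftmicrobe-out", seed = 1) {
  if (is.null(synthetic) &&
      (is.null(counts_path) || is.null(metadata_path))) {
    stop("either `synthetic` or counts_path + metadata_path are required",
         call. = FALSE)
  }
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 taxonomy_path = taxonomy_path, synthetic = synthetic,
                 preprocess = preprocess,
                 permanova_terms = permanova_terms,
                 permanova_n_perm = permanova_n_perm,
                 raup_crick_n_sim = raup_crick_n_sim,
                 preference_n_perm = preference_n_perm,
                 min_occurrence = min_occurrence, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a dataset before analysis
#'
#' Checks id agreement between the three inputs, metadata factor levels, and
#' count integrality. Problems are reported as rows, not thrown.
#'
#' @param counts A [count_matrix()] or a matrix.
#' @param metadata A [sample_metadata()] data frame.
#' @param taxonomy Optional [taxonomy_table()].
#' @return Data frame with columns `level` ("error"/"warning") and
#'   `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(counts, metadata, taxonomy = NULL) {
  issues <- list()
  note <- function(level, msg) {
    issues[[length(issues) + 1]] <<- data.frame(level = level,
                                                message = msg,
                                                stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    count_matrix(as.matrix(counts), rank = count_rank(counts)); TRUE
  }, error = function(e) {
    note("error", conditionMessage(e)); FALSE
  })
  need <- c("sample_id", "variety", "location", "line")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    note("error", paste("metadata missing column(s):",
                        paste(miss, collapse = ", ")))
  }
  if (ok && length(miss) == 0) {
    unmatched <- setdiff(rownames(counts), metadata$sample_id)
    if (length(unmatched) > 0) {
      note("warning", paste("samples absent from metadata:",
                            paste(unmatched, collapse = ", ")))
    }
    extra <- setdiff(metadata$sample_id, rownames(counts))
    if (length(extra) > 0) {
      note("warning", paste("metadata samples absent from counts:",
                            paste(extra, collapse = ", ")))
    }
    if (!is.null(taxonomy)) {
      no_tax <- setdiff(colnames(counts), taxonomy$feature_id)
      if (length(no_tax) > 0) {
        note("warning", paste("features without taxonomy:",
                              paste(no_tax, collapse = ", ")))
      }
    }
  }
  if (length(issues) == 0) {
    data.frame(level = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) a dataset, applies the preprocessing cascade, and
#' writes the standard result tables: a retained-sample report, order- and
#' genus-level composition summaries, Raup-Crick + PERMANOVA tables at both
#' ranks, per-genus ANOVA, and genus- and OTU-level preference tables with a
#' significant-pair report. A JSON manifest records versions, seeds, the
#' configuration, and a per-stage log. Result tables are byte-identical
#' across reruns with the same inputs and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log[[length(log) + 1]] <<- list(stage = name,
                                    elapsed_s = round(proc.time()[["elapsed"]]
                                                      - t0, 3))
    res
  }
  stage_seed <- function(name) seed_for_sample(config$seed, name)
  out_path <- function(name) file.path(config$out_dir, name)
  paths <- character(0)
  emit <- function(df, name) {
    write_result_table(df, out_path(name))
    paths <<- c(paths, out_path(name))
  }

  dataset <- stage("load", {
    if (!is.null(config$synthetic)) {
      generate_dataset(config$synthetic)
    } else {
      counts <- read_count_table(config$counts_path)
      metadata <- read_sample_metadata(config$metadata_path)
      taxonomy <- if (!is.null(config$taxonomy_path)) {
        read_taxonomy(config$taxonomy_path)
      }
      list(counts = counts, metadata = metadata, taxonomy = taxonomy)
    }
  })
  al <- stage("align", align_dataset(dataset$counts, dataset$metadata,
                                     dataset$taxonomy))

  pp <- config$preprocess
  pp$seed <- stage_seed("rarefy")
  pre <- stage("preprocess", {
    filtered <- filter_low_abundance_cells(al$counts,
                                           pp$cell_filter_fraction)
    rarefy_counts(filtered, depth = pp$rarefaction_depth, seed = pp$seed)
  })
  rarefied <- pre$counts
  md <- al$metadata[al$metadata$sample_id %in% rownames(rarefied), ,
                    drop = FALSE]
  md <- droplevels(md)
  emit(data.frame(sample_id = rownames(al$counts),
                  retained = !(rownames(al$counts) %in% pre$discarded),
                  stringsAsFactors = FALSE),
       "retained_samples.tsv")

  results <- list(discarded = pre$discarded, rarefied = rarefied)
  ranked <- list()
  for (rank in c("order", "genus")) {
    ranked[[rank]] <- stage(paste0("collapse_", rank),
                            collapse_to_rank(rarefied, al$taxonomy, rank))
    emit(composition_summary(ranked[[rank]], md),
         paste0("composition_", rank, ".tsv"))
    perm <- stage(paste0("permanova_", rank), {
      d <- raup_crick(ranked[[rank]], variant = "null-model",
                      n_sim = config$raup_crick_n_sim,
                      seed = stage_seed(paste0("raupcrick_", rank)))
      community_permanova(d, md, terms = config$permanova_terms,
                          n_perm = config$permanova_n_perm,
                          seed = stage_seed(paste0("permanova_", rank)))
    })
    results[[paste0("permanova_", rank)]] <- perm
    emit(as.data.frame(perm), paste0("permanova_", rank, ".tsv"))
  }

  anova_res <- stage("anova_genus", {
    genus_kept <- filter_by_occurrence(ranked$genus, config$min_occurrence)
    taxon_anova(to_relative_abundance(count_matrix(
      unclass_counts(ranked$genus)[, colnames(genus_kept), drop = FALSE],
      rank = "genus")), md)
  })
  results$anova_genus <- anova_res
  emit(as.data.frame(anova_res), "anova_genus.tsv")

  pref <- list()
  for (rank in c("genus", "otu")) {
    mat <- if (rank == "otu") rarefied else ranked$genus
    pref[[rank]] <- stage(paste0("preference_", rank), {
      preference_analysis(mat, md, n_perm = config$preference_n_perm,
                          seed = stage_seed(paste0("preference_", rank)),
                          min_occurrence = config$min_occurrence,
                          alpha = config$alpha)
    })
    res <- pref[[rank]]
    emit(data.frame(taxon = res$taxa,
                    as.data.frame(res$preference, check.names = FALSE),
                    stringsAsFactors = FALSE, check.names = FALSE),
         paste0("preference_", rank, "_z.tsv"))
    emit(data.frame(taxon = res$taxa,
                    as.data.frame(res$p_empirical, check.names = FALSE),
                    stringsAsFactors = FALSE, check.names = FALSE),
         paste0("preference_", rank, "_p.tsv"))
    emit(preference_report(res,
                           taxonomy = if (rank == "otu") al$taxonomy),
         paste0("preference_", rank, "_report.tsv"))
  }
  results$preference <- pref

  manifest <- list(
    package = "graftmicrobe",
    package_version = as.character(utils::packageVersion("graftmicrobe")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = serialize_config(config),
    config_hash = config_hash(config),
    stages = log,
    outputs = basename(paths))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, paths = c(paths,
                                              out_path("manifest.json")),
                 out_dir = config$out_dir))
}

# config as plain lists for the manifest
serialize_config <- function(config) {
  obj <- unclass(config)
  obj$preprocess <- unclass(obj$preprocess)
  if (!is.null(obj$synthetic)) {
    syn <- unclass(obj$synthetic)
    syn$preference_effects <- df_to_records(syn$preference_effects)
    syn$location_effects <- df_to_records(syn$location_effects)
    obj$synthetic <- syn
  }
  obj
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
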