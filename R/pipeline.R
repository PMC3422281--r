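#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: 1.2-fold
#' down-regulation and a 1.1-fold control band for target calling,
#' independence thresholds of 10 heterozygote reads and 1.5-fold
#' down-regulation, 7-nt words analysed in growing steps of 500 with
#' order-4 Markov correction and alpha 0.01, 40000 GSEA permutations,
#' k-NN reduction at k = 100 and MCL inflations 1.3 / 2.0.
#'
#' @param rng_seed global seed fanned out to per-stage child seeds.
#' @return named list of class `mirdep_config`.
#' @export
default_config <- function(rng_seed = 1L) {
  structure(list(
    rng_seed = as.integer(rng_seed),
    fold_change_min = 1.2,
    adjusted_p_max = 0.05,
    control_band = 1.1,
    independence_min_het_mean = 10,
    independence_max_down_fold = 1.5,
    word_k = 7,
    grow = 500,
    markov_m = 4,
    alpha = 0.01,
    gsea_n_perm = 40000,
    knn_k = 100,
    coarse_inflation = 1.3,
    fine_inflation = 2.0,
    # synthetic-data stage parameters
    n_per_class = 5,
    mirna_depletion = 0.02,
    library_depth = 20000,
    n_transcripts = 1000,
    fraction_planted = 0.1,
    effect_log2fc = -1,
    noise_sd = 0.25,
    n_replicates = 5,
    network_cluster_sizes = c(30, 25, 20, 15),
    network_p_in = 0.6,
    network_p_out = 0.02,
    network_n_hubs = 2
  ), class = "mirdep_config")
}

#' Validate (and complete) a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list), injects defaults for
#' missing keys, rejects unknown keys and collects type errors.
#'
#' @param config path to a YAML file, or a named list (possibly partial).
#' @return `mirdep_config` list, or an error carrying all problems found.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- default_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, sprintf("unknown keys: %s",
                                paste(unknown, collapse = ", ")))
  }
  out <- defaults
  for (k in intersect(names(config), names(defaults))) {
    v <- config[[k]]
    if (!is.numeric(v)) {
      errors <- c(errors, sprintf("`%s` must be numeric", k))
      next
    }
    out[[k]] <- v
  }
  check_pos <- c("fold_change_min", "control_band", "knn_k", "grow",
                 "gsea_n_perm", "library_depth", "n_transcripts")
  for (k in check_pos) {
    if (out[[k]] < 1) errors <- c(errors, sprintf("`%s` must be >= 1", k))
  }
  if (out$coarse_inflation <= 1 || out$fine_inflation <= 1) {
    errors <- c(errors, "inflations must be > 1")
  }
  if (length(errors) > 0) {
    abort(paste(c("invalid configuration:", errors), collapse = "\n  "))
  }
  structure(out, class = "mirdep_config")
}

#' Save a configuration to YAML
#'
#' @param config `mirdep_config` list.
#' @param path output path.
#' @return `path`, invisibly. `validate_config(save_config(cfg))`
#'   round-trips losslessly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order on synthetic data: small-RNA
#' simulation, quantification and normalization, Dgcr8-independence
#' calling; transfection simulation, differential expression, seed
#' scanning, target calling and quality statistics; word-enrichment
#' landscape with Bonferroni calls; preranked GSEA of the target list; and
#' the network stage (triangle weighting, k-NN reduction, two-level MCL,
#' influence support). All intermediate tables are written as TSV under
#' `out_dir` and a machine-readable JSON report is produced. Deterministic
#' given the seed.
#'
#' @param config `mirdep_config` (see [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return the run report (list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempdir()) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  seeds <- derive_seeds(config$rng_seed, 10)
  report <- list(parameters = unclass(config),
                 software_version = as.character(utils::packageVersion("mirdep")),
                 stages = list())

  ## stage 1: small-RNA libraries -> independence calls
  panel <- generate_reference_panel(config$n_per_class, rng_seed = seeds[1])
  mir_ids <- panel$id[panel$class_label == "miRNA" & panel$in_catalog]
  independent <- utils::head(sort(mir_ids), 2)
  genos <- dplyr::bind_rows(
    genotype_spec("WT", 1, independent, config$library_depth),
    genotype_spec("het", 0.6, independent, config$library_depth),
    genotype_spec("homo", config$mirna_depletion, independent,
                  config$library_depth)
  )
  sim <- simulate_small_rna_libraries(panel, genos, rng_seed = seeds[2],
                                      dir = out_dir)
  quants <- purrr::map(seq_len(nrow(sim$libraries)), function(i) {
    quantify_library(sim$libraries$fastq[i], panel,
                     adapter3 = genos$adapter3[i],
                     library_id = sim$libraries$genotype[i],
                     genotype = sim$libraries$genotype[i])
  })
  class_depths <- purrr::list_rbind(purrr::map(quants, "class_depths"))
  norm <- normalize_class_depths(class_depths, "WT")
  depths <- purrr::list_rbind(purrr::map(seq_along(quants), function(i) {
    sf <- norm$scale_factors$scale_factor[
      norm$scale_factors$library_id == sim$libraries$genotype[i]]
    mirna_depths(quants[[i]]$hits, quants[[i]]$library, panel, sf)
  }))
  calls <- call_dgcr8_independent(depths, "het", "homo",
                                  config$independence_min_het_mean,
                                  config$independence_max_down_fold)
  write_tsv_plain(norm$normalized, file.path(out_dir, "class_depths.tsv"))
  write_tsv_plain(depths, file.path(out_dir, "mirna_depths.tsv"))
  write_tsv_plain(calls, file.path(out_dir, "independence_calls.tsv"))
  report$stages$smallrna <- list(
    libraries = nrow(sim$libraries),
    reads_per_library = config$library_depth,
    candidates = calls$mirna_id[calls$candidate],
    planted_independent = independent
  )

  ## stage 2: transfection -> target list + quality
  focal <- panel$sequence[match(mir_ids[1], panel$id)]
  focal <- substr(focal, panel$mature_start[match(mir_ids[1], panel$id)],
                  panel$mature_end[match(mir_ids[1], panel$id)])
  tf <- simulate_transfection_experiment(
    focal, n_transcripts = config$n_transcripts,
    fraction_planted = config$fraction_planted,
    effect_log2fc = config$effect_log2fc, noise_sd = config$noise_sd,
    n_replicates = config$n_replicates, rng_seed = seeds[3], dir = out_dir)
  de <- differential_expression(tf$expression, tf$samples,
                                control = "control", treatment = "mimic")
  utrs <- preprocess_utrs(tf$utrs)
  profiles <- scan_seed_matches(utrs, tf$truth$seeds)
  targets <- call_target_list(de, profiles, config$fold_change_min,
                              config$adjusted_p_max, mirna_id = "focal")
  quality <- signal_to_noise(de, profiles, config$fold_change_min,
                             config$adjusted_p_max, config$control_band)
  write_tsv_plain(de, file.path(out_dir, "de_table.tsv"))
  write_tsv_plain(as_tibble(targets), file.path(out_dir, "target_list.tsv"))
  write_tsv_plain(quality, file.path(out_dir, "target_quality.tsv"))
  tp <- length(intersect(targets$transcript_id, tf$truth$planted_targets))
  report$stages$targets <- list(
    n_targets = nrow(targets),
    recall = tp / length(tf$truth$planted_targets),
    precision = if (nrow(targets) > 0) tp / nrow(targets) else NA,
    signal_to_noise = quality$signal_to_noise,
    sensitivity_above_chance = quality$sensitivity_above_chance
  )

  ## stage 3: word-enrichment landscape
  set.seed(seeds[4])
  decoys <- tibble(
    mirna_id = sprintf("decoy_%02d", 1:8),
    sequence = vapply(1:8, function(i)
      paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = ""),
      character(1)))
  universe_words <- build_word_universe(dplyr::bind_rows(
    tibble(mirna_id = "focal", sequence = focal), decoys))
  ranked_ids <- de$transcript_id[order(de$log2_fold_change)]
  ranked_ids <- intersect(ranked_ids, utrs$id)
  wc <- count_words(utrs, universe_words$word, m = config$markov_m)
  landscape <- enrichment_landscape(ranked_ids, wc, grow = config$grow)
  sig <- landscape_significance(landscape, alpha = config$alpha)
  write_tsv_plain(landscape, file.path(out_dir, "landscape.tsv"))
  report$stages$words <- list(
    n_words = nrow(universe_words),
    threshold = sig$threshold,
    n_significant_points = nrow(sig$calls)
  )

  ## stage 4: preranked GSEA of the target list
  ranked <- de |>
    filter(.data$transcript_id %in% utrs$id) |>
    arrange(.data$log2_fold_change) |>
    transmute(id = .data$transcript_id, metric = .data$log2_fold_change)
  gsea <- gsea_preranked(ranked, targets$transcript_id,
                         n_perm = min(config$gsea_n_perm, 40000),
                         rng_seed = seeds[5], set_id = "focal_targets")
  report$stages$gsea <- list(es = gsea$es, nes = gsea$nes,
                             p_perm = gsea$p_perm, n_perm = gsea$n_perm)

  ## stage 5: network influence
  netsim <- simulate_interaction_network(
    config$network_cluster_sizes, config$network_p_in, config$network_p_out,
    n_hubs = config$network_n_hubs, rng_seed = seeds[6], dir = out_dir)
  net <- build_network(netsim$edges) |>
    triangle_weights() |>
    knn_reduce(k = config$knn_k)
  clustering <- two_level_clustering(net, config$coarse_inflation,
                                     config$fine_inflation)
  planted <- netsim$truth$cluster_assignment
  c1_nodes <- planted$node[!is.na(planted$cluster) & planted$cluster == 1]
  lists <- list(list_a = c1_nodes[seq(1, length(c1_nodes), by = 2)],
                list_b = c1_nodes[seq(2, length(c1_nodes), by = 2)])
  support <- influence_support(net, clustering |> select("node", cluster = "fine"),
                               lists)
  write_tsv_plain(clustering, file.path(out_dir, "clustering.tsv"))
  write_tsv_plain(support, file.path(out_dir, "support_matrix.tsv"))
  report$stages$network <- list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    max_degree_after_knn = graph_summary(net)$max_degree,
    n_coarse = length(unique(clustering$coarse)),
    n_fine = length(unique(clustering$fine)),
    support_matrix = file.path(out_dir, "support_matrix.tsv")
  )

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  report$digests <- as.list(tools::md5sum(outputs))
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
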