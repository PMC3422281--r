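#' Generate a synthetic ncRNA reference panel
#'
#' Builds a small reference panel emulating a catalogue of mouse non-coding
#' RNAs (miRNA hairpins plus the other small ncRNA classes used for
#' normalization). Every miRNA record carries a mature region of 20--24 nt
#' inside its hairpin, and a stated fraction of miRNAs is flagged as absent
#' from the reference catalogue (`in_catalog = FALSE`), emulating
#' predicted-but-unconfirmed hairpins.
#'
#' @param n_per_class number of records per ncRNA class.
#' @param length_ranges named list mapping class to `c(min, max)` sequence
#'   length; classes missing from the list use built-in defaults.
#' @param frac_non_catalog fraction of miRNA records flagged
#'   `in_catalog = FALSE` (default 0.2).
#' @param rng_seed integer seed; the panel is a pure function of the seed
#'   and parameters.
#' @return tibble with columns `id`, `class_label`, `sequence`,
#'   `mature_start`, `mature_end` (NA unless miRNA; 1-based inclusive)
#'   and `in_catalog`.
#' @export
generate_reference_panel <- function(n_per_class,
                                     length_ranges = list(),
                                     frac_non_catalog = 0.2,
                                     rng_seed = 1L) {
  n_per_class <- check_positive_int(n_per_class, "n_per_class")
  defaults <- list(
    tRNA = c(70, 90), snRNA = c(100, 180), snoRNA = c(60, 160),
    rRNA = c(110, 180), Mt_tRNA = c(65, 75), Mt_rRNA = c(110, 180),
    misc_RNA = c(80, 160), miRNA = c(60, 90)
  )
  for (cl in names(length_ranges)) defaults[[cl]] <- length_ranges[[cl]]
  bad <- vapply(defaults, function(r) any(r < 1) || r[2] < r[1], logical(1))
  if (any(bad)) abort("length ranges must be positive with min <= max")

  set.seed(rng_seed)
  recs <- purrr::map(NCRNA_CLASSES, function(cl) {
    rng <- defaults[[cl]]
    lens <- sample(rng[1]:rng[2], n_per_class, replace = TRUE)
    tibble(
      id = sprintf("%s_%02d", cl, seq_len(n_per_class)),
      class_label = cl,
      sequence = vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1))
    )
  }) |> purrr::list_rbind()

  recs$mature_start <- NA_integer_
  recs$mature_end <- NA_integer_
  is_mir <- recs$class_label == "miRNA"
  for (i in which(is_mir)) {
    L <- nchar(recs$sequence[i])
    ml <- sample(20:24, 1)
    s <- sample(seq_len(L - ml + 1), 1)
    recs$mature_start[i] <- s
    recs$mature_end[i] <- s + ml - 1L
  }
  n_out <- round(frac_non_catalog * sum(is_mir))
  out_ids <- if (n_out > 0) sample(recs$id[is_mir], n_out) else character(0)
  recs |>
    mutate(in_catalog = ifelse(is_mir, !(.data$id %in% out_ids), TRUE)) |>
    select("id", "class_label", "sequence", "mature_start", "mature_end",
           "in_catalog")
}

#' Specify a genotype for small-RNA library simulation
#'
#' @param name genotype label (e.g. "WT", "het", "homo").
#' @param mirna_depletion multiplicative factor in (0, 1] applied to the
#'   abundance of canonical (catalogued, Dgcr8-dependent) miRNAs.
#' @param independent_ids miRNA ids exempt from depletion
#'   (Dgcr8-independent).
#' @param library_depth total read count of the library.
#' @param error_rate per-base substitution probability.
#' @param adapter3 3' adapter sequence appended to each insert.
#' @return one-row tibble describing the genotype.
#' @export
genotype_spec <- function(name, mirna_depletion = 1, independent_ids = character(0),
                          library_depth = 1e5, error_rate = 0.001,
                          adapter3 = "TCGTATGCCGTCTTCTGCTTG") {
  if (mirna_depletion <= 0 || mirna_depletion > 1) {
    abort("`mirna_depletion` must be in (0, 1]")
  }
  if (library_depth < 1) abort("`library_depth` must be positive")
  tibble(name = name, mirna_depletion = mirna_depletion,
         independent_ids = list(independent_ids),
         library_depth = as.integer(library_depth),
         error_rate = error_rate, adapter3 = as_dna(adapter3))
}

#' Simulate multi-genotype small-RNA sequencing libraries
#'
#' Emulates small-RNA libraries from wild-type, heterozygous and
#' Dgcr8-depleted cells: per-record abundances are drawn once from a
#' log-normal (shared across genotypes), canonical miRNA abundance is
#' multiplied by each genotype's depletion factor except for flagged
#' independent miRNAs, and reads are drawn multinomially. miRNA reads start
#' at position 1 or 2 of the mature region; other reads start at position
#' 1 or 2 of the feature. Raw reads are fixed `read_length` nt with 3'
#' adapter read-through, exercising adapter trimming downstream.
#'
#' @param panel reference panel from [generate_reference_panel()].
#' @param genotypes tibble of genotype rows from [genotype_spec()]
#'   (bind rows for several genotypes).
#' @param rng_seed integer seed.
#' @param read_length raw read length (default 36 nt).
#' @param dir directory in which FASTQ files are written (default
#'   `tempdir()`).
#' @return list with `libraries` (tibble: genotype, fastq path) and
#'   `truth` (tibble: genotype, id, class_label, expected_proportion,
#'   expected_depth).
#' @export
simulate_small_rna_libraries <- function(panel, genotypes, rng_seed = 1L,
                                         read_length = 36L, dir = tempdir()) {
  if (nrow(panel) == 0) abort("panel must be non-empty")
  mir_ids <- panel$id[panel$class_label == "miRNA"]
  all_ind <- unique(unlist(genotypes$independent_ids))
  if (!all(all_ind %in% mir_ids)) {
    abort(sprintf("independent ids not in panel: %s",
                  paste(setdiff(all_ind, mir_ids), collapse = ", ")))
  }
  set.seed(rng_seed)
  base_abund <- stats::rlnorm(nrow(panel), meanlog = 0, sdlog = 1)
  names(base_abund) <- panel$id

  libs <- list(); truths <- list()
  for (g in seq_len(nrow(genotypes))) {
    gt <- genotypes[g, ]
    dep <- gt$mirna_depletion
    ind <- gt$independent_ids[[1]]
    ab <- base_abund
    canonical <- panel$class_label == "miRNA" & !(panel$id %in% ind)
    ab[canonical] <- ab[canonical] * dep
    prop <- ab / sum(ab)
    depth <- gt$library_depth
    counts <- as.vector(stats::rmultinom(1, depth, prop))

    seqs <- character(depth); pos <- 1L
    for (i in seq_len(nrow(panel))) {
      if (counts[i] == 0) next
      rec <- panel[i, ]
      if (rec$class_label == "miRNA") {
        starts <- rec$mature_start + sample(0:1, counts[i], replace = TRUE)
        ends <- pmin(rec$mature_end, nchar(rec$sequence))
        ins <- substring(rec$sequence, starts, ends)
      } else {
        starts <- sample(1:2, counts[i], replace = TRUE)
        lens <- sample(20:28, counts[i], replace = TRUE)
        ends <- pmin(starts + lens - 1L, nchar(rec$sequence))
        ins <- substring(rec$sequence, starts, ends)
      }
      raw <- substr(paste0(ins, gt$adapter3, strrep("A", read_length)),
                    1, read_length)
      seqs[pos:(pos + counts[i] - 1L)] <- raw
      pos <- pos + counts[i]
    }
    seqs <- seqs[seq_len(pos - 1L)]
    if (gt$error_rate > 0) {
      seqs <- inject_substitutions(seqs, gt$error_rate)
    }
    seqs <- sample(seqs)  # shuffle read order
    path <- file.path(dir, paste0("library_", gt$name, ".fastq"))
    write_fastq_tbl(tibble(
      id = sprintf("%s_read_%d", gt$name, seq_along(seqs)),
      sequence = seqs, quality = strrep("I", nchar(seqs))
    ), path)
    libs[[g]] <- tibble(genotype = gt$name, fastq = path)
    truths[[g]] <- tibble(genotype = gt$name, id = panel$id,
                          class_label = panel$class_label,
                          abundance = ab,
                          expected_proportion = prop,
                          expected_depth = prop * depth)
  }
  list(libraries = purrr::list_rbind(libs), truth = purrr::list_rbind(truths))
}

inject_substitutions <- function(seqs, rate) {
  nc <- nchar(seqs)
  total <- sum(nc)
  n_err <- stats::rbinom(1, total, rate)
  if (n_err == 0) return(seqs)
  pos <- sample.int(total, n_err)
  offsets <- c(0, cumsum(nc))
  for (p in pos) {
    r <- findInterval(p, offsets, left.open = TRUE)
    j <- p - offsets[r]
    old <- substr(seqs[r], j, j)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(seqs[r], j, j) <- new
  }
  seqs
}

#' Simulate a miRNA mimic transfection experiment
#'
#' Emulates a two-condition expression experiment in which a miRNA mimic is
#' transfected into miRNA-depleted cells: a stated fraction of transcripts
#' carries 1--3 planted seed sites (a mix of 7mer(1A), 7mer(2) and
#' 8mer(1A)) in their 3' UTR and is down-regulated by `effect_log2fc` on
#' average; all other UTRs are rejection-sampled to contain no focal seed.
#' Replicate noise is i.i.d. normal on the log2 scale.
#'
#' @param mirna_seq focal miRNA sequence (RNA or DNA, 5' to 3', >= 9 nt).
#' @param n_transcripts number of transcripts.
#' @param fraction_planted fraction of transcripts carrying planted sites,
#'   in (0, 1).
#' @param effect_log2fc planned mean log2 fold change (mimic vs control) of
#'   planted targets; negative for down-regulation.
#' @param noise_sd replicate noise standard deviation (log2 scale).
#' @param n_replicates replicates per condition (>= 2).
#' @param rng_seed integer seed.
#' @param fraction_silent fraction of transcripts given one seed site but
#'   no expression effect (non-functional chance seed carriers; keeps the
#'   signal-to-noise control set non-degenerate). Default 0.05.
#' @param utr_length_range `c(min, max)` UTR length.
#' @param dir optional directory; when given, the UTR FASTA and expression
#'   TSV are written there.
#' @return list with `utrs` (tibble id, sequence), `expression` (tibble:
#'   transcript_id then one column per sample, log2 scale), `samples`
#'   (tibble: sample, condition) and `truth` (list: planted ids, effect,
#'   noise_sd, seeds).
#' @export
simulate_transfection_experiment <- function(mirna_seq, n_transcripts = 1000,
                                             fraction_planted = 0.1,
                                             effect_log2fc = -1,
                                             noise_sd = 0.25,
                                             n_replicates = 5,
                                             rng_seed = 1L,
                                             fraction_silent = 0.05,
                                             utr_length_range = c(200, 600),
                                             dir = NULL) {
  if (fraction_planted <= 0 || fraction_planted >= 1) {
    abort("`fraction_planted` must be in (0, 1)")
  }
  if (n_replicates < 2) abort("`n_replicates` must be >= 2")
  if (!is.finite(effect_log2fc) || !is.finite(noise_sd) || noise_sd < 0) {
    abort("`effect_log2fc` and `noise_sd` must be finite (noise_sd >= 0)")
  }
  seeds <- derive_seed_set(mirna_seq)
  gate <- c(seeds$s7mer1A, seeds$s7mer2, seeds$s8mer1A)

  set.seed(rng_seed)
  n_planted <- round(fraction_planted * n_transcripts)
  ids <- sprintf("tx_%04d", seq_len(n_transcripts))
  planted <- sort(sample(ids, n_planted))
  n_silent <- round(fraction_silent * n_transcripts)
  silent <- if (n_silent > 0)
    sort(sample(setdiff(ids, planted), n_silent)) else character(0)

  lens <- sample(utr_length_range[1]:utr_length_range[2], n_transcripts,
                 replace = TRUE)
  utr <- character(n_transcripts)
  for (i in seq_len(n_transcripts)) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
                 collapse = "")
      if (!any(vapply(gate, function(w) grepl(w, s, fixed = TRUE),
                      logical(1)))) break
    }
    utr[i] <- s
  }
  # plant 1-3 sites into planted UTRs (one site into silent carriers) at
  # non-overlapping positions
  site_pool <- c(seeds$s7mer1A, seeds$s7mer2, seeds$s8mer1A)
  for (id in c(planted, silent)) {
    i <- match(id, ids)
    n_sites <- if (id %in% silent) 1L else sample(1:3, 1)
    words <- sample(site_pool, n_sites, replace = TRUE)
    s <- utr[i]
    taken <- integer(0)
    for (w in words) {
      repeat {
        p <- sample(seq_len(nchar(s) - nchar(w) + 1), 1)
        span <- p:(p + nchar(w) - 1)
        if (!any(span %in% taken)) break
      }
      substr(s, p, p + nchar(w) - 1) <- w
      taken <- c(taken, p:(p + nchar(w) - 1))
    }
    utr[i] <- s
  }

  base <- stats::rnorm(n_transcripts, mean = 8, sd = 1.5)
  is_planted <- ids %in% planted
  samples <- tibble(
    sample = c(sprintf("control_%d", seq_len(n_replicates)),
               sprintf("mimic_%d", seq_len(n_replicates))),
    condition = rep(c("control", "mimic"), each = n_replicates)
  )
  expr <- matrix(NA_real_, n_transcripts, nrow(samples),
                 dimnames = list(ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- base + if (samples$condition[j] == "mimic")
      effect_log2fc * is_planted else 0
    expr[, j] <- mu + stats::rnorm(n_transcripts, 0, noise_sd)
  }
  utrs <- tibble(id = ids, sequence = utr)
  expression <- bind_cols(tibble(transcript_id = ids), as_tibble(expr))
  if (!is.null(dir)) {
    write_fasta_tbl(utrs, file.path(dir, "utrs.fasta"))
    write_tsv_plain(expression, file.path(dir, "expression.tsv"))
  }
  list(utrs = utrs, expression = expression, samples = samples,
       truth = list(planted_targets = planted, silent_carriers = silent,
                    effect_log2fc = effect_log2fc,
                    noise_sd = noise_sd, n_replicates = n_replicates,
                    seeds = seeds))
}

#' Simulate a planted-partition interaction network with hubs
#'
#' Generates a simple undirected graph with triangle-rich planted clusters
#' (within-cluster edge probability `p_in`, between-cluster `p_out`) plus
#' optional hub nodes wired uniformly at random to a stated fraction of all
#' nodes, emulating the high-degree hubs of curated molecular interaction
#' networks that defeat naive clustering.
#'
#' @param cluster_sizes integer vector of planted cluster sizes (each >= 3).
#' @param p_in within-cluster edge probability.
#' @param p_out between-cluster edge probability (< `p_in`).
#' @param n_hubs number of extra hub nodes.
#' @param hub_fraction fraction of all other nodes each hub connects to.
#' @param rng_seed integer seed.
#' @param dir optional directory; when given, the edge list TSV is written.
#' @return list with `edges` (tibble from, to) and `truth` (list:
#'   cluster_assignment tibble, hub_nodes, p_in, p_out).
#' @export
simulate_interaction_network <- function(cluster_sizes, p_in = 0.8,
                                         p_out = 0.02, n_hubs = 0,
                                         hub_fraction = 0.5, rng_seed = 1L,
                                         dir = NULL) {
  if (p_in <= p_out) abort("`p_in` must exceed `p_out`")
  if (any(cluster_sizes < 3)) abort("cluster sizes must be >= 3")
  set.seed(rng_seed)
  n_c <- sum(cluster_sizes)
  nodes <- sprintf("n%03d", seq_len(n_c))
  assign <- rep(seq_along(cluster_sizes), cluster_sizes)
  pairs <- utils::combn(n_c, 2)
  same <- assign[pairs[1, ]] == assign[pairs[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- tibble(from = nodes[pairs[1, keep]], to = nodes[pairs[2, keep]])

  hub_nodes <- character(0)
  if (n_hubs > 0) {
    hub_nodes <- sprintf("hub%02d", seq_len(n_hubs))
    n_all <- n_c + n_hubs
    for (h in seq_len(n_hubs)) {
      others <- c(nodes, hub_nodes[-h])
      k <- round(hub_fraction * (n_all - 1))
      targets <- sample(others, k)
      edges <- bind_rows(edges, tibble(from = hub_nodes[h], to = targets))
    }
    # dedupe hub-hub duplicates
    key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                  paste(edges$to, edges$from))
    edges <- edges[!duplicated(key), ]
  }
  truth <- list(
    cluster_assignment = tibble(node = c(nodes, hub_nodes),
                                cluster = c(assign, rep(NA_integer_, n_hubs))),
    hub_nodes = hub_nodes, p_in = p_in, p_out = p_out
  )
  if (!is.null(dir)) write_tsv_plain(edges, file.path(dir, "network_edges.tsv"))
  list(edges = edges, truth = truth)
}

#' Generate random gene sets, optionally with one enriched set
#'
#' Samples gene sets from a universe (standing in for KEGG/GO annotation).
#' When `enriched_in` is given, the first set is seeded to overlap it at
#' `overlap_rate`.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of sets.
#' @param size_range `c(min, max)` set size.
#' @param enriched_in optional id vector the first set should overlap.
#' @param overlap_rate fraction of `enriched_in` included in the seeded set.
#' @param rng_seed integer seed.
#' @param path optional GMT output path.
#' @return tibble with columns `set_id`, `name`, `members` (list column).
#' @export
generate_gene_sets <- function(universe, n_sets = 10, size_range = c(10, 50),
                               enriched_in = NULL, overlap_rate = 1,
                               rng_seed = 1L, path = NULL) {
  if (length(universe) == 0) abort("universe must be non-empty")
  if (size_range[2] > length(universe)) {
    abort("set size exceeds universe size")
  }
  set.seed(rng_seed)
  sets <- purrr::map(seq_len(n_sets), function(i) {
    size <- sample(size_range[1]:size_range[2], 1)
    sort(sample(universe, size))
  })
  if (!is.null(enriched_in)) {
    core <- sample(enriched_in, round(overlap_rate * length(enriched_in)))
    if (overlap_rate >= 1) core <- enriched_in
    fill_n <- max(0, size_range[1] - length(core))
    fill <- sample(setdiff(universe, core), fill_n)
    sets[[1]] <- sort(unique(c(core, fill)))
  }
  out <- tibble(set_id = sprintf("SET%03d", seq_len(n_sets)),
                name = sprintf("synthetic set %d", seq_len(n_sets)),
                members = sets)
  if (!is.null(path)) write_gmt(out, path)
  out
}
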