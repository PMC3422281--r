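#' Filter and adapter-trim raw small-RNA reads
#'
#' Applies the small-RNA preprocessing chain: 3' adapter removal (longest
#' read suffix exactly matching a prefix of the adapter, minimum 6 nt
#' overlap, no mismatches; untrimmed reads pass through to the length
#' filter unchanged), removal of reads with ambiguous-base runs (three Ns
#' in any window of five bases, or any N within 2 bases of the read end),
#' a low-complexity filter removing reads consisting mostly (>= 80% of the
#' read) of runs of identical nucleotides, di-nucleotides or
#' tri-nucleotides, and a 16--30 nt length filter.
#'
#' @param reads tibble with a `sequence` column (e.g. from
#'   [read_fastq_tbl()]), or a path to a FASTQ file, or a character vector
#'   of sequences.
#' @param adapter3 3' adapter sequence (non-empty).
#' @param min_overlap minimum adapter suffix/prefix overlap (default 6 nt).
#' @return tibble with column `sequence` of retained, trimmed reads.
#' @export
preprocess_reads <- function(reads, adapter3, min_overlap = 6) {
  if (is.null(adapter3) || nchar(adapter3) == 0) abort("adapter must be non-empty")
  adapter3 <- as_dna(adapter3)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq_tbl(reads)
  }
  if (is.character(reads)) reads <- tibble(sequence = reads)
  seqs <- toupper(reads$sequence)

  seqs <- trim_adapter(seqs, adapter3, min_overlap)
  # cheap prefilters: the detailed window scans only run on candidates
  has_n <- grepl("N", seqs, fixed = TRUE)
  keep_n <- !has_n
  keep_n[has_n] <- !vapply(seqs[has_n], has_n_run, logical(1))
  lc_candidate <- grepl("(.)\\1{10,}|(..)\\2{4,}|(...)\\3{2,}", seqs)
  keep_lc <- !lc_candidate
  keep_lc[lc_candidate] <- !vapply(seqs[lc_candidate], is_low_complexity_read,
                                   logical(1))
  seqs <- seqs[keep_n & keep_lc]
  len <- nchar(seqs)
  tibble(sequence = seqs[len >= 16 & len <= 30])
}

# longest suffix of each read equal to a prefix of the adapter
# (>= min_overlap, no mismatches); vectorized over reads
trim_adapter <- function(seqs, adapter, min_overlap) {
  n <- nchar(seqs)
  trimmed_at <- rep(0L, length(seqs))
  for (L in seq(min(max(n), nchar(adapter)), min_overlap, by = -1)) {
    if (L < min_overlap) break
    cand <- trimmed_at == 0L & n >= L
    if (!any(cand)) next
    hit <- cand & substr(seqs, n - L + 1, n) == substr(adapter, 1, L)
    trimmed_at[hit] <- L
  }
  ifelse(trimmed_at > 0, substr(seqs, 1, n - trimmed_at), seqs)
}

has_n_run <- function(s) {
  n <- nchar(s)
  if (n == 0) return(FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  is_n <- ch == "N"
  if (n >= 2 && any(is_n[max(1, n - 1):n])) return(TRUE)  # N within 2 of end
  if (n < 2 && any(is_n)) return(TRUE)
  if (n >= 5) {
    win <- vapply(seq_len(n - 4), function(i) sum(is_n[i:(i + 4)]), integer(1))
    if (any(win >= 3)) return(TRUE)
  } else if (sum(is_n) >= 3) return(TRUE)
  FALSE
}

# read removed when a maximal periodic run (period 1, 2 or 3) spans >= 80%
is_low_complexity_read <- function(s, frac = 0.8) {
  n <- nchar(s)
  if (n == 0) return(TRUE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in 1:3) {
    if (n <= p) next
    i <- 1L
    while (i + p <= n) {
      j <- i
      while (j + p <= n && ch[j + p] == ch[j]) j <- j + 1L
      if ((j + p - i) >= frac * n) return(TRUE)
      i <- max(j, i + 1L)
    }
  }
  FALSE
}

#' Collapse filtered reads into unique sequences with depths
#'
#' @param reads tibble with a `sequence` column (filtered reads), or a
#'   character vector.
#' @param library_id library label.
#' @param genotype genotype label.
#' @return tibble with columns `library_id`, `genotype`, `sequence`,
#'   `depth`; total depth equals the number of input reads.
#' @export
collapse_reads <- function(reads, library_id = "lib", genotype = NA_character_) {
  if (is.character(reads)) reads <- tibble(sequence = reads)
  if (nrow(reads) == 0) {
    return(tibble(library_id = character(0), genotype = character(0),
                  sequence = character(0), depth = integer(0)))
  }
  reads |>
    count(.data$sequence, name = "depth") |>
    mutate(library_id = library_id, genotype = genotype) |>
    select("library_id", "genotype", "sequence", "depth") |>
    arrange(desc(.data$depth), .data$sequence)
}

# Allowed alignment start positions on a reference feature: positions 1 and
# 2 of the feature; for miRNA hairpins additionally positions 1 and 2 of the
# mature region, so that mature-region reads are mappable.
allowed_starts <- function(rec) {
  st <- c(1L, 2L)
  if (rec$class_label == "miRNA" && !is.na(rec$mature_start)) {
    st <- sort(unique(c(st, rec$mature_start, rec$mature_start + 1L)))
  }
  st
}

#' Map collapsed reads against a reference panel
#'
#' Ungapped, forward-strand alignment of each unique read against every
#' panel record. A valid alignment requires >= 90% identity over the
#' aligned region, an aligned length of >= 16 bases covering >= 75% of the
#' read, and a 5' start at position 1 or 2 of the reference feature (for
#' miRNA hairpins, position 1 or 2 of the mature region is also accepted).
#' The 3' end is unconstrained: read bases extending past the reference
#' (e.g. untrimmed adapter or non-templated additions) only reduce
#' coverage.
#'
#' @param library tibble from [collapse_reads()].
#' @param panel reference panel from [generate_reference_panel()] or
#'   [read_panel()].
#' @param min_identity minimum identity (default 0.90).
#' @param min_length minimum aligned length (default 16).
#' @param min_coverage minimum fraction of the read aligned (default 0.75).
#' @return tibble of hits: `sequence`, `reference_id`, `class_label`,
#'   `start` (1-based on the reference), `aligned_length`, `identity`,
#'   `coverage`. Reads with no hit are absent (recorded as unmapped).
#' @export
map_reads <- function(library, panel, min_identity = 0.90,
                      min_length = 16, min_coverage = 0.75) {
  if (nrow(panel) == 0) abort("panel must be non-empty")
  if (nrow(library) == 0) {
    return(tibble(sequence = character(0), reference_id = character(0),
                  class_label = character(0), start = integer(0),
                  aligned_length = integer(0), identity = double(0),
                  coverage = double(0)))
  }
  reads <- library$sequence
  rl <- nchar(reads)
  max_rl <- max(rl)
  # reads as a padded character matrix, one row per position
  read_mat <- matrix("", nrow = max_rl, ncol = length(reads))
  split_reads <- strsplit(reads, "", fixed = TRUE)
  for (i in seq_along(reads)) read_mat[seq_len(rl[i]), i] <- split_reads[[i]]

  hits <- list(); h <- 0L
  for (r in seq_len(nrow(panel))) {
    rec <- panel[r, ]
    ref_ch <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
    ref_len <- length(ref_ch)
    best <- NULL
    for (st in allowed_starts(rec)) {
      if (st > ref_len) next
      avail <- ref_len - st + 1L
      alen <- pmin(rl, avail)
      ok_len <- alen >= min_length & alen / rl >= min_coverage
      if (!any(ok_len)) next
      L <- min(max_rl, avail)
      ref_block <- ref_ch[st:(st + L - 1L)]
      eq <- read_mat[seq_len(L), , drop = FALSE] == ref_block
      # matches within each read's aligned region
      cum <- apply(eq, 2, cumsum)
      matches <- cum[cbind(pmin(alen, L), seq_along(reads))]
      ident <- matches / alen
      ok <- ok_len & ident >= min_identity
      if (any(ok)) {
        h <- h + 1L
        hits[[h]] <- tibble(
          sequence = reads[ok], reference_id = rec$id,
          class_label = rec$class_label, start = st,
          aligned_length = alen[ok], identity = ident[ok],
          coverage = alen[ok] / rl[ok]
        )
      }
    }
  }
  if (h == 0) {
    return(tibble(sequence = character(0), reference_id = character(0),
                  class_label = character(0), start = integer(0),
                  aligned_length = integer(0), identity = double(0),
                  coverage = double(0)))
  }
  out <- purrr::list_rbind(hits)
  # keep the best start per (read, reference): highest identity, earliest start
  out |>
    group_by(.data$sequence, .data$reference_id) |>
    arrange(desc(.data$identity), .data$start, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Classify mapped reads into ncRNA classes
#'
#' A read mapping to exactly one ncRNA class is assigned that class; reads
#' mapping to more than one class form the `mixed_mapping` group. Reads in
#' the miRNA class are subdivided: `miRNA` when an alignment to a
#' catalogued hairpin overlaps the mature region by at least half the read,
#' `miRNA_non_mature` when all catalogued-hairpin alignments fall outside
#' the mature region, and `miRNA_non_catalog` when the read maps only to
#' hairpins absent from the reference catalogue.
#'
#' @param hits tibble from [map_reads()].
#' @param library tibble from [collapse_reads()] (provides depths).
#' @param panel reference panel.
#' @param mature_overlap_frac minimum fraction of the read overlapping the
#'   mature region to count as mature (default 0.5).
#' @return list with `read_classes` (tibble: sequence, depth, class) and
#'   `class_depths` (tibble: library_id, genotype, class, depth — raw
#'   depth per class, including `unmapped`).
#' @export
classify_alignments <- function(hits, library, panel,
                                mature_overlap_frac = 0.5) {
  unknown <- setdiff(hits$reference_id, panel$id)
  if (length(unknown) > 0) {
    abort(sprintf("hits reference unknown panel ids: %s",
                  paste(unknown, collapse = ", ")))
  }
  pan <- panel |>
    select("id", mature_start_ref = "mature_start",
           mature_end_ref = "mature_end", in_catalog_ref = "in_catalog")
  hx <- hits |> left_join(pan, by = c(reference_id = "id"))

  class_of_read <- hx |>
    group_by(.data$sequence) |>
    summarise(classes = list(unique(.data$class_label)), .groups = "drop")

  mir_detail <- hx |>
    filter(.data$class_label == "miRNA") |>
    mutate(
      ov = pmax(0, pmin(.data$start + .data$aligned_length - 1,
                        .data$mature_end_ref) -
                  pmax(.data$start, .data$mature_start_ref) + 1),
      read_len = .data$aligned_length / .data$coverage,
      mature_hit = .data$in_catalog_ref &
        .data$ov >= mature_overlap_frac * .data$read_len,
      catalog_hit = .data$in_catalog_ref
    ) |>
    group_by(.data$sequence) |>
    summarise(any_mature = any(.data$mature_hit),
              any_catalog = any(.data$catalog_hit), .groups = "drop")

  read_classes <- class_of_read |>
    mutate(class = vapply(.data$classes, function(cl)
      if (length(cl) > 1) "mixed_mapping" else cl, character(1))) |>
    left_join(mir_detail, by = "sequence") |>
    mutate(class = case_when(
      .data$class != "miRNA" ~ .data$class,
      .data$any_mature ~ "miRNA",
      .data$any_catalog ~ "miRNA_non_mature",
      TRUE ~ "miRNA_non_catalog"
    )) |>
    select("sequence", "class")

  lib <- library |>
    left_join(read_classes, by = "sequence") |>
    mutate(class = ifelse(is.na(.data$class), "unmapped", .data$class))

  class_depths <- lib |>
    group_by(.data$library_id, .data$genotype, .data$class) |>
    summarise(depth = sum(.data$depth), .groups = "drop") |>
    tidyr::complete(class = c(DEPTH_CLASSES, "unmapped"),
                    fill = list(depth = 0)) |>
    tidyr::fill("library_id", "genotype", .direction = "downup") |>
    filter(!is.na(.data$library_id))

  list(read_classes = lib |> select("sequence", "depth", "class"),
       class_depths = class_depths)
}

#' Normalize class depth tables across libraries
#'
#' Scales every library to the reference library using the total depth of
#' reads mapping to non-miRNA, non-mixed ncRNA classes as the anchor
#' (miRNA, miRNA_non_mature, miRNA_non_catalog and mixed_mapping depths are
#' miRNA-derived or ambiguous and are excluded from the anchor):
#' `scale_factor = anchor(reference) / anchor(library)`. All class depths
#' are multiplied by the library's scale factor.
#'
#' @param class_depths tibble binding the `class_depths` of several
#'   libraries (columns library_id, genotype, class, depth).
#' @param reference_library id of the reference (e.g. WT) library.
#' @return list with `normalized` (same shape, depths scaled, plus
#'   `scale_factor`) and `scale_factors` (tibble: library_id,
#'   scale_factor).
#' @export
normalize_class_depths <- function(class_depths, reference_library) {
  if (!reference_library %in% class_depths$library_id) {
    abort(sprintf("reference library '%s' not present", reference_library))
  }
  anchors <- class_depths |>
    filter(.data$class %in% ANCHOR_CLASSES) |>
    group_by(.data$library_id) |>
    summarise(anchor = sum(.data$depth), .groups = "drop")
  ref_anchor <- anchors$anchor[anchors$library_id == reference_library]
  if (any(anchors$anchor <= 0)) {
    abort("zero anchor depth: cannot normalize (degenerate input)")
  }
  sf <- anchors |>
    mutate(scale_factor = ref_anchor / .data$anchor) |>
    select("library_id", "scale_factor")
  normalized <- class_depths |>
    left_join(sf, by = "library_id") |>
    mutate(depth = .data$depth * .data$scale_factor)
  list(normalized = normalized, scale_factors = sf)
}

#' Per-miRNA normalized mature-read depths
#'
#' Aggregates mature miRNA read depth per hairpin per library and applies
#' the library scale factors from [normalize_class_depths()].
#'
#' @param hits tibble from [map_reads()] (one library).
#' @param library tibble from [collapse_reads()].
#' @param panel reference panel.
#' @param scale_factor the library's scale factor.
#' @param mature_overlap_frac as in [classify_alignments()].
#' @return tibble: `library_id`, `genotype`, `mirna_id`, `depth`
#'   (normalized mature-read depth).
#' @export
mirna_depths <- function(hits, library, panel, scale_factor = 1,
                         mature_overlap_frac = 0.5) {
  pan <- panel |>
    filter(.data$class_label == "miRNA") |>
    select("id", mature_start_ref = "mature_start",
           mature_end_ref = "mature_end")
  mature_hits <- hits |>
    filter(.data$class_label == "miRNA") |>
    inner_join(pan, by = c(reference_id = "id")) |>
    mutate(
      ov = pmax(0, pmin(.data$start + .data$aligned_length - 1,
                        .data$mature_end_ref) -
                  pmax(.data$start, .data$mature_start_ref) + 1),
      read_len = .data$aligned_length / .data$coverage
    ) |>
    filter(.data$ov >= mature_overlap_frac * .data$read_len)
  lib_info <- library |> distinct(.data$library_id, .data$genotype)
  mature_hits |>
    inner_join(library |> select("sequence", "depth"), by = "sequence") |>
    group_by(mirna_id = .data$reference_id) |>
    summarise(depth = sum(.data$depth) * scale_factor, .groups = "drop") |>
    tidyr::complete(mirna_id = pan$id, fill = list(depth = 0)) |>
    mutate(library_id = lib_info$library_id[1],
           genotype = lib_info$genotype[1]) |>
    select("library_id", "genotype", "mirna_id", "depth")
}

#' Call Dgcr8-independent miRNAs
#'
#' A miRNA is a Dgcr8-independence candidate when its mean normalized depth
#' across heterozygote libraries exceeds `min_het_mean` reads (strictly)
#' and its expression is down-regulated less than `max_down_fold` between
#' heterozygous and homozygous-mutant libraries, i.e. the
#' homozygote/heterozygote depth ratio is at least `1 / max_down_fold`
#' (up-regulation also passes).
#'
#' @param depths tibble binding [mirna_depths()] rows for all libraries.
#' @param het_library_ids heterozygote library ids.
#' @param homo_library_ids homozygous-mutant library ids.
#' @param min_het_mean abundance threshold (default 10 reads; "more than").
#' @param max_down_fold maximum tolerated down-regulation (default 1.5).
#' @return tibble: `mirna_id`, `het_mean_depth`, `homo_mean_depth`,
#'   `fold_change` (homo/het), `abundance_pass`, `candidate`.
#' @export
call_dgcr8_independent <- function(depths, het_library_ids, homo_library_ids,
                                   min_het_mean = 10, max_down_fold = 1.5) {
  if (length(het_library_ids) == 0 || length(homo_library_ids) == 0) {
    abort("both library id lists must be non-empty")
  }
  het <- depths |>
    filter(.data$library_id %in% het_library_ids) |>
    group_by(.data$mirna_id) |>
    summarise(het_mean_depth = mean(.data$depth), .groups = "drop")
  homo <- depths |>
    filter(.data$library_id %in% homo_library_ids) |>
    group_by(.data$mirna_id) |>
    summarise(homo_mean_depth = mean(.data$depth), .groups = "drop")
  het |>
    full_join(homo, by = "mirna_id") |>
    mutate(
      fold_change = ifelse(.data$het_mean_depth > 0,
                           .data$homo_mean_depth / .data$het_mean_depth,
                           ifelse(.data$homo_mean_depth > 0, Inf, NaN)),
      abundance_pass = .data$het_mean_depth > min_het_mean,
      candidate = .data$abundance_pass &
        is.finite(.data$fold_change) &
        .data$fold_change >= 1 / max_down_fold
    ) |>
    arrange(desc(.data$candidate), desc(.data$het_mean_depth))
}

#' Quantify one small-RNA library end to end
#'
#' Convenience wrapper: preprocess, collapse, map and classify a FASTQ
#' library against a panel.
#'
#' @param fastq path to the library FASTQ.
#' @param panel reference panel.
#' @param adapter3 3' adapter sequence.
#' @param library_id,genotype labels.
#' @return list with `library`, `hits`, `read_classes`, `class_depths`.
#' @export
quantify_library <- function(fastq, panel, adapter3,
                             library_id = basename(fastq),
                             genotype = NA_character_) {
  filtered <- preprocess_reads(fastq, adapter3)
  library <- collapse_reads(filtered, library_id = library_id,
                            genotype = genotype)
  hits <- map_reads(library, panel)
  cls <- classify_alignments(hits, library, panel)
  c(list(library = library, hits = hits), cls)
}
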