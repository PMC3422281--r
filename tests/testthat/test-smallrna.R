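ADAPTER <- "TCGTATGCCGTCTTCTGCTTG"

test_that("read preprocessing applies the published filter chain", {
  insert22 <- "ACGTTGCAGGTCAATCGGATCA"
  read <- substr(paste0(insert22, ADAPTER), 1, 36)
  out <- preprocess_reads(read, ADAPTER)
  expect_equal(out$sequence, insert22)

  # ambiguous-base rules
  expect_equal(nrow(preprocess_reads(
    "ACGTACGTNCNNAACGTACGTACGT", ADAPTER)), 0)  # 3 Ns in a 5-base window
  expect_equal(nrow(preprocess_reads(
    "ACGTACGTACGTACGTACGTN", ADAPTER)), 0)      # N within 2 of the end
  # low complexity
  expect_equal(nrow(preprocess_reads("ACACACACACACACACAC", ADAPTER)), 0)
  expect_equal(nrow(preprocess_reads(strrep("A", 20), ADAPTER)), 0)
  expect_equal(nrow(preprocess_reads(strrep("AGT", 7), ADAPTER)), 0)
  # length boundaries, 16-30 inclusive
  ins15 <- "ACGTTGCAGGTCAAT"
  ins16 <- "ACGTTGCAGGTCAATG"
  expect_equal(nrow(preprocess_reads(paste0(ins15, ADAPTER), ADAPTER)), 0)
  expect_equal(preprocess_reads(paste0(ins16, ADAPTER), ADAPTER)$sequence,
               ins16)
  # untrimmed reads just meet the length filter
  expect_equal(nrow(preprocess_reads(strrep("ACGTTGCAG", 4), ADAPTER)), 0)

  expect_error(preprocess_reads("ACGT", ""), "adapter")
})

test_that("preprocessing is idempotent on simulated libraries", {
  panel <- generate_reference_panel(3, rng_seed = 11)
  gts <- genotype_spec("WT", 1, library_depth = 3000)
  sim <- simulate_small_rna_libraries(panel, gts, rng_seed = 12,
                                      dir = withr::local_tempdir())
  once <- preprocess_reads(sim$libraries$fastq[1], ADAPTER)
  twice <- preprocess_reads(once, ADAPTER)
  expect_identical(once$sequence, twice$sequence)
})

test_that("read collapsing conserves depth", {
  reads <- c("AACGT", "AACGT", "GGTAC")
  lib <- collapse_reads(reads, "libA")
  expect_equal(sort(lib$depth), c(1, 2))
  expect_equal(sum(lib$depth), 3)
  expect_equal(nrow(collapse_reads(character(0))), 0)
})

test_that("mapping enforces the published alignment thresholds", {
  panel <- tibble::tibble(
    id = c("tRNA_x", "miRNA_x"),
    class_label = c("tRNA", "miRNA"),
    sequence = c("ACGTACGTTGCAGGTCAATCGGATCAGGCATGCAAT",
                 paste0(strrep("G", 9), "ACGTTGCAGGTCAATCGGATCA",
                        strrep("C", 20))),
    mature_start = c(NA, 10L), mature_end = c(NA, 31L),
    in_catalog = c(TRUE, TRUE))

  # perfect prefix read: identity 1, coverage 1, start 1
  lib <- collapse_reads(substr(panel$sequence[1], 1, 22))
  hits <- map_reads(lib, panel)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1)
  expect_equal(hits$coverage, 1)
  expect_equal(hits$start, 1)

  # 3 mismatches in 22 nt: identity 19/22 < 0.90, no hit
  flip <- function(x, pos) {
    for (p in pos) substr(x, p, p) <- chartr("ACGT", "CGTA",
                                             substr(x, p, p))
    x
  }
  r <- flip(substr(panel$sequence[1], 1, 22), c(5, 11, 19))
  expect_equal(nrow(map_reads(collapse_reads(r), panel)), 0)
  # 2 mismatches: 20/22 = 0.909 >= 0.90, hit survives
  r2 <- flip(substr(panel$sequence[1], 1, 22), c(5, 11))
  expect_equal(nrow(map_reads(collapse_reads(r2), panel)), 1)

  # read matching only at reference position 3: rejected
  expect_equal(nrow(map_reads(
    collapse_reads(substr(panel$sequence[1], 3, 24)), panel)), 0)
  # reverse-complement-only match: unmapped
  rc <- reverse_complement(substr(panel$sequence[1], 1, 22))
  expect_equal(nrow(map_reads(collapse_reads(rc), panel)), 0)
  # mature-region read maps to the miRNA hairpin at the mature anchor
  mat <- substr(panel$sequence[2], 10, 31)
  hmat <- map_reads(collapse_reads(mat), panel)
  expect_true("miRNA_x" %in% hmat$reference_id)
  expect_equal(hmat$start[hmat$reference_id == "miRNA_x"], 10)
})

test_that("mapping agrees with an exhaustive per-position oracle", {
  panel <- generate_reference_panel(4, rng_seed = 21)
  gts <- genotype_spec("WT", 1, library_depth = 400, error_rate = 0.01)
  sim <- simulate_small_rna_libraries(panel, gts, rng_seed = 22,
                                      dir = withr::local_tempdir())
  lib <- collapse_reads(preprocess_reads(sim$libraries$fastq[1], ADAPTER))
  lib <- lib[seq_len(min(150, nrow(lib))), ]
  hits <- map_reads(lib, panel)
  for (i in seq_len(nrow(lib))) {
    for (r in seq_len(nrow(panel))) {
      got <- hits[hits$sequence == lib$sequence[i] &
                    hits$reference_id == panel$id[r], ]
      want <- naive_map_read(lib$sequence[i], panel[r, ])
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), 1)
        expect_equal(got$identity, want$identity, tolerance = 1e-12)
        expect_equal(got$aligned_length, want$aligned_length)
      }
    }
  }
})

test_that("classification separates classes, mixed and miRNA subtypes", {
  panel <- tibble::tibble(
    id = c("tRNA_a", "rRNA_a", "snoRNA_a", "miRNA_a", "miRNA_b"),
    class_label = c("tRNA", "rRNA", "snoRNA", "miRNA", "miRNA"),
    sequence = c("ACGTACGTTGCAGGTCAATCGGATCAGGCA",
                 "TTGCCGGAACGTTAGCCGGATTCAGGCAAT",
                 "TTGCCGGAACGTTAGCCGGATTCAGGCAAT",  # same as rRNA_a -> mixed
                 paste0("GGCCATTGCAGGTCAATCGGAGCCA", strrep("T", 30)),
                 paste0("CCGGAATTCAGGCAATTGCAGGACG", strrep("T", 30))),
    mature_start = c(NA, NA, NA, 31L, 31L),
    mature_end = c(NA, NA, NA, 52L, 52L),
    in_catalog = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  panel$sequence[4] <- paste0(substr(panel$sequence[4], 1, 30),
                              "ACGGTCAATCGAGTCCAGTTAC", "GGG")
  panel$sequence[5] <- paste0(substr(panel$sequence[5], 1, 30),
                              "TTCCAGGACTAGCAGTCAGGTA", "GGG")

  reads <- c(substr(panel$sequence[1], 1, 22),   # tRNA only
             substr(panel$sequence[2], 1, 22),   # rRNA + snoRNA -> mixed
             substr(panel$sequence[4], 31, 52),  # mature catalogued miRNA
             substr(panel$sequence[4], 1, 22),   # hairpin arm -> non mature
             substr(panel$sequence[5], 31, 52))  # mature, not in catalogue
  lib <- collapse_reads(reads)
  hits <- map_reads(lib, panel)
  cls <- classify_alignments(hits, lib, panel)
  got <- cls$read_classes
  expect_equal(got$class[got$sequence == reads[1]], "tRNA")
  expect_equal(got$class[got$sequence == reads[2]], "mixed_mapping")
  expect_equal(got$class[got$sequence == reads[3]], "miRNA")
  expect_equal(got$class[got$sequence == reads[4]], "miRNA_non_mature")
  expect_equal(got$class[got$sequence == reads[5]], "miRNA_non_catalog")
  # class depths sum to the mapped total
  expect_equal(sum(cls$class_depths$depth), sum(lib$depth))
  expect_error(
    classify_alignments(dplyr::mutate(hits, reference_id = "ghost"),
                        lib, panel),
    "unknown panel ids")
})

test_that("normalization anchors the non-miRNA ncRNA depth", {
  cd <- tibble::tibble(
    library_id = rep(c("WT", "mut"), each = 4),
    genotype = rep(c("WT", "mut"), each = 4),
    class = rep(c("tRNA", "rRNA", "miRNA", "mixed_mapping"), 2),
    depth = c(6000, 4000, 300, 50,
              3000, 2000, 400, 10))
  norm <- normalize_class_depths(cd, "WT")
  sf <- norm$scale_factors
  expect_equal(sf$scale_factor[sf$library_id == "WT"], 1)
  expect_equal(sf$scale_factor[sf$library_id == "mut"], 2)  # 10000 / 5000
  mut <- norm$normalized[norm$normalized$library_id == "mut", ]
  expect_equal(mut$depth[mut$class == "miRNA"], 800)
  anchors <- norm$normalized |>
    dplyr::filter(!class %in% c("miRNA", "mixed_mapping")) |>
    dplyr::group_by(library_id) |>
    dplyr::summarise(a = sum(depth))
  expect_lt(diff(range(anchors$a)), 1e-9)
  expect_error(normalize_class_depths(cd, "absent"), "not present")
  cd0 <- dplyr::mutate(cd, depth = ifelse(library_id == "mut", 0, depth))
  expect_error(normalize_class_depths(cd0, "WT"), "zero anchor")
})

test_that("independence calling reproduces the printed rule boundaries", {
  depths <- tibble::tibble(
    library_id = rep(c("het1", "homo1"), each = 5),
    genotype = rep(c("het", "homo"), each = 5),
    mirna_id = rep(c("mir_pass", "mir_fail", "mir_low", "mir_up", "mir_edge"), 2),
    depth = c(100, 100, 10, 100, 100,             # het means
              68.8, 64.5, 10, 432.4, 100 * 2 / 3) # homo means
  )
  calls <- call_dgcr8_independent(depths, "het1", "homo1")
  get <- function(id, col) calls[[col]][calls$mirna_id == id]
  # 0.688 down-regulation passes (1/0.688 = 1.45 < 1.5)
  expect_true(get("mir_pass", "candidate"))
  expect_equal(get("mir_pass", "fold_change"), 0.688)
  # 0.645 fails (1/0.645 = 1.55 > 1.5)
  expect_false(get("mir_fail", "candidate"))
  # het mean exactly 10 fails the strict "more than 10 reads" rule
  expect_false(get("mir_low", "abundance_pass"))
  expect_false(get("mir_low", "candidate"))
  # strong up-regulation (4.324) still passes
  expect_true(get("mir_up", "candidate"))
  # ratio exactly 2/3 is at the threshold and passes
  expect_true(get("mir_edge", "candidate"))
  # zero heterozygote depth: +Inf sentinel, no abundance pass
  d0 <- tibble::tibble(library_id = c("het1", "homo1"),
                       genotype = c("het", "homo"),
                       mirna_id = "m", depth = c(0, 5))
  c0 <- call_dgcr8_independent(d0, "het1", "homo1")
  expect_equal(c0$fold_change, Inf)
  expect_false(c0$abundance_pass)
  expect_false(c0$candidate)
  expect_error(call_dgcr8_independent(depths, character(0), "homo1"),
               "non-empty")
})
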