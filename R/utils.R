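#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

NCRNA_CLASSES <- c("tRNA", "snRNA", "snoRNA", "rRNA",
                   "Mt_tRNA", "Mt_rRNA", "misc_RNA", "miRNA")

# classes used as the normalization anchor: everything that is not
# miRNA-derived and not ambiguously mapped
ANCHOR_CLASSES <- setdiff(NCRNA_CLASSES, "miRNA")

DEPTH_CLASSES <- c(NCRNA_CLASSES, "mixed_mapping",
                   "miRNA_non_mature", "miRNA_non_catalog")

#' Convert an RNA or mixed-case sequence to the internal DNA alphabet
#'
#' All sequences are stored internally over \{A, C, G, T\}; RNA input is
#' accepted and U is mapped to T on ingestion.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over the DNA alphabet, uppercase.
#' @export
as_dna <- function(x) {
  chartr("uU", "tT", x) |> toupper()
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, length, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, length, replace = TRUE), collapse = "")
  }, character(1))
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer, got %s",
                  name, paste(x, collapse = ",")))
  }
  as.integer(x)
}

#' Read a FASTA file into a tibble
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return tibble with columns `id` and `sequence` (DNA alphabet).
#' @export
read_fasta_tbl <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)),
         sequence = as.character(ss))
}

#' Write a tibble of sequences to FASTA
#'
#' @param x tibble with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x$sequence)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path path to an (uncompressed) FASTQ file.
#' @return tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq_tbl <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4", length(lines)))
  }
  idx <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[idx], "@"))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d: header does not start with '@'", bad[1]))
  }
  tibble(id = sub("^@", "", lines[idx]),
         sequence = toupper(lines[idx + 1]),
         quality = lines[idx + 3])
}

write_fastq_tbl <- function(x, path) {
  qual <- x$quality %||% strrep("I", nchar(x$sequence))
  writeLines(rbind(paste0("@", x$id), x$sequence, "+", qual), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path path to a GMT file (set id, description, then member ids,
#'   tab separated).
#' @return tibble with columns `set_id`, `name`, `members` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("malformed GMT line %d: fewer than 3 fields", short[1]))
  }
  tibble(
    set_id = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, `[`, character(1), 2),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write gene sets to GMT
#'
#' @param sets tibble with columns `set_id`, `name`, `members` (list column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$name[i], sets$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

# Derive independent child seeds from one global seed, staying below 2^31.
derive_seeds <- function(seed, n) {
  old <- .Random.seed_exists()
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  s
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read a reference panel from FASTA plus annotation TSV
#'
#' @param fasta FASTA of panel sequences.
#' @param annotation TSV with columns `id`, `class`, `mature_start`,
#'   `mature_end`, `in_catalog` (1-based inclusive coordinates).
#' @return panel tibble as produced by [generate_reference_panel()].
#' @export
read_panel <- function(fasta, annotation) {
  seqs <- read_fasta_tbl(fasta)
  ann <- read_tsv_plain(annotation)
  names(ann)[names(ann) == "class"] <- "class_label"
  out <- dplyr::inner_join(seqs, ann, by = "id")
  out$in_catalog <- as.logical(out$in_catalog)
  tibble::as_tibble(out[, c("id", "class_label", "sequence",
                            "mature_start", "mature_end", "in_catalog")])
}

#' Write a reference panel to FASTA plus annotation TSV
#'
#' @param panel panel tibble.
#' @param fasta,annotation output paths.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, fasta, annotation) {
  write_fasta_tbl(panel, fasta)
  write_tsv_plain(panel[, c("id", "class_label", "mature_start",
                            "mature_end", "in_catalog")] |>
                    dplyr::rename(class = "class_label"), annotation)
  invisible(c(fasta, annotation))
}
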