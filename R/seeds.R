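#' Derive target-strand seed-match strings from a miRNA sequence
#'
#' Computes the four canonical seed-site classes on the target (mRNA sense)
#' strand, read 5' to 3':
#' \describe{
#'   \item{7mer(1A)}{reverse complement of miRNA positions 2--7 followed by
#'     an A at the position pairing miRNA position 1.}
#'   \item{7mer(2)}{reverse complement of miRNA positions 2--8.}
#'   \item{8mer(1A)}{the union of the two, i.e. 7mer(2) followed by A.}
#'   \item{7mer(3)}{reverse complement of miRNA positions 3--9 (the shifted
#'     seed).}
#' }
#'
#' @param mirna_seq miRNA sequence, 5' to 3', RNA or DNA, length >= 9.
#' @param mirna_id optional id carried through to the result.
#' @return one-row tibble with columns `mirna_id`, `s7mer1A`, `s7mer2`,
#'   `s7mer3`, `s8mer1A` (uppercase DNA).
#' @export
derive_seed_set <- function(mirna_seq, mirna_id = "miRNA") {
  s <- as_dna(mirna_seq)
  if (nchar(s) < 9) abort("miRNA sequence must be >= 9 nt (7mer(3) undefined)")
  if (grepl("[^ACGT]", s)) abort("miRNA sequence contains non-nucleotide characters")
  s7mer2 <- reverse_complement(substr(s, 2, 8))
  s7mer1A <- paste0(reverse_complement(substr(s, 2, 7)), "A")
  s8mer1A <- paste0(s7mer2, "A")
  s7mer3 <- reverse_complement(substr(s, 3, 9))
  tibble(mirna_id = mirna_id, s7mer1A = s7mer1A, s7mer2 = s7mer2,
         s7mer3 = s7mer3, s8mer1A = s8mer1A)
}

#' Mask low-complexity stretches in a nucleotide sequence
#'
#' Masks (to lower case) every maximal run in which a 1-, 2- or 3-mer
#' repeats to span at least `min_span` nucleotides. Masked bases are
#' skipped by seed scanning and word counting: a match must lie wholly in
#' unmasked sequence.
#'
#' @param x character vector of DNA sequences.
#' @param min_span minimum repeated-unit span to mask (default 15 nt).
#' @return character vector with masked stretches in lower case.
#' @export
mask_low_complexity <- function(x, min_span = 15) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    mask <- logical(n)
    for (p in 1:3) {
      if (n < min_span) next
      i <- 1L
      while (i + p <= n) {
        j <- i
        while (j + p <= n && ch[j + p] == ch[j]) j <- j + 1L
        run_len <- (j + p) - i        # span covered by the periodic run
        if (run_len >= min_span) mask[i:(j + p - 1L)] <- TRUE
        i <- max(j, i + 1L)
      }
    }
    ch[mask] <- tolower(ch[mask])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Preprocess 3' UTR sequences before seed scanning and word counting
#'
#' Collapses exact duplicate sequences to one representative (first id
#' kept), masks low-complexity stretches and drops empty or fully masked
#' sequences.
#'
#' @param utrs tibble with columns `id` and `sequence`, or a path to a
#'   FASTA file.
#' @param min_span low-complexity span passed to [mask_low_complexity()].
#' @return tibble with columns `id`, `sequence` (masked bases lower case)
#'   plus attribute `dropped`, a tibble mapping dropped duplicate ids to
#'   their retained representative.
#' @export
preprocess_utrs <- function(utrs, min_span = 15) {
  if (is.character(utrs) && length(utrs) == 1) utrs <- read_fasta_tbl(utrs)
  bad <- grepl("[^ACGTNacgtn]", utrs$sequence)
  if (any(bad)) {
    abort(sprintf("non-nucleotide characters in UTRs: %s",
                  paste(utrs$id[bad], collapse = ", ")))
  }
  up <- toupper(utrs$sequence)
  dup <- duplicated(up)
  dropped <- tibble(dropped_id = utrs$id[dup],
                    kept_id = utrs$id[match(up[dup], up)])
  kept <- utrs[!dup, ]
  kept$sequence <- mask_low_complexity(toupper(kept$sequence),
                                       min_span = min_span)
  unmasked <- nchar(gsub("[a-zn]", "", kept$sequence))
  kept <- kept[unmasked > 0 & nchar(kept$sequence) > 0, ]
  attr(kept, "dropped") <- dropped
  kept
}

# Count overlapping occurrences of `word` in `s`, where a match must lie
# wholly in unmasked (uppercase, non-N) sequence.
count_occurrences <- function(s, word) {
  n <- nchar(s); k <- nchar(word)
  if (n < k) return(0L)
  hits <- gregexpr(paste0("(?=", word, ")"), s, perl = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}

#' Scan a 3' UTR for seed-class matches
#'
#' Counts overlapping occurrences of each seed class independently (nested
#' counting: an 8mer(1A) site also contributes to 7mer(1A) and 7mer(2)).
#' Masked (lower-case or N) bases break matches. With
#' `exclude_adjacent = TRUE`, 7mer occurrences that abut another seed word
#' into a longer composite site are not counted for the exclusive 7mer(3)
#' analysis.
#'
#' @param utrs tibble with columns `id`, `sequence` (from
#'   [preprocess_utrs()] or raw), or a single sequence string.
#' @param seeds one-row tibble from [derive_seed_set()].
#' @param exclude_adjacent whether to flag transcripts whose only sites are
#'   isolated 7mer(3) sites (no adjacent composite).
#' @return tibble with one row per transcript: `transcript_id`, counts
#'   `n_7mer1A`, `n_7mer2`, `n_7mer3`, `n_8mer1A`,
#'   `any_7mer1A_or_7mer2`, and `exclusive_7mer3_only`.
#' @export
scan_seed_matches <- function(utrs, seeds, exclude_adjacent = TRUE) {
  if (is.character(utrs)) utrs <- tibble(id = "utr", sequence = utrs)
  words <- c(n_7mer1A = seeds$s7mer1A, n_7mer2 = seeds$s7mer2,
             n_7mer3 = seeds$s7mer3, n_8mer1A = seeds$s8mer1A)
  # masked bases break matches: split on any lowercase/N character
  segments <- strsplit(gsub("[a-zN]+", "", utrs$sequence), "",
                       fixed = TRUE)
  counts <- vapply(seq_len(nrow(utrs)), function(i) {
    segs <- segments[[i]]
    vapply(words, function(w) sum(vapply(segs, count_occurrences, integer(1),
                                         word = w)), integer(1))
  }, integer(4))
  counts <- t(counts)
  out <- bind_cols(tibble(transcript_id = utrs$id), as_tibble(counts))
  out$any_7mer1A_or_7mer2 <- out$n_7mer1A > 0 | out$n_7mer2 > 0
  if (exclude_adjacent) {
    excl <- vapply(seq_len(nrow(utrs)), function(i) {
      segs <- segments[[i]]
      has3 <- sum(vapply(segs, count_occurrences, integer(1),
                         word = seeds$s7mer3)) > 0
      if (!has3 || out$any_7mer1A_or_7mer2[i]) return(FALSE)
      # composite: a 7mer(3) site extended by an abutting seed word into a
      # longer match (e.g. the extended 8mer shared by shifted seeds)
      composite <- paste0(seeds$s7mer3, "A")
      has_comp <- sum(vapply(segs, count_occurrences, integer(1),
                             word = composite)) > 0
      !has_comp
    }, logical(1))
    out$exclusive_7mer3_only <- excl
  } else {
    out$exclusive_7mer3_only <- NA
  }
  out
}
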