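#' Build the 7-mer seed word universe from miRNA sequences
#'
#' For every retained miRNA, the two 7-nt windows of its 8mer(1A) target
#' string are added to the universe: the complement of miRNA positions 2--8
#' (the 7mer(2) string) and the complement of positions 1--7 with a forced
#' A at the position pairing miRNA position 1 (the 7mer(1A) string). Words
#' are deduplicated and their contributing miRNAs recorded.
#'
#' @param mirnas tibble with columns `mirna_id`, `sequence` and optionally
#'   `expressed` (logical filter; only expressed miRNAs contribute).
#' @return tibble with columns `word` and `mirna_ids` (list column).
#' @export
build_word_universe <- function(mirnas) {
  if ("expressed" %in% names(mirnas)) mirnas <- mirnas[mirnas$expressed, ]
  entries <- purrr::map(seq_len(nrow(mirnas)), function(i) {
    ss <- derive_seed_set(mirnas$sequence[i], mirnas$mirna_id[i])
    tibble(word = c(ss$s7mer2, ss$s7mer1A), mirna_id = mirnas$mirna_id[i])
  }) |> purrr::list_rbind()
  entries |>
    group_by(.data$word) |>
    summarise(mirna_ids = list(unique(.data$mirna_id)), .groups = "drop")
}

#' Count words and k-mer composition in preprocessed UTRs
#'
#' Counts overlapping occurrences of each word in each sequence (masked
#' bases, lower case or N, break matches) and stores the per-sequence
#' composition tables of orders `m` and `m - 1` needed for Markov
#' correction.
#'
#' @param utrs tibble with `id`, `sequence` (from [preprocess_utrs()]).
#' @param words character vector of words (all the same length `k`).
#' @param m Markov correction order (composition word length, default 4;
#'   0 disables correction).
#' @return list of class `mirdep_word_counts`: `ids`, `counts`
#'   (sequences x words integer matrix), `n_positions` (word windows per
#'   sequence), `comp_m`, `comp_m1` (composition count matrices), `k`, `m`.
#' @export
count_words <- function(utrs, words, m = 4) {
  k <- unique(nchar(words))
  if (length(k) != 1) abort("all words must have the same length")
  # masked bases -> N so fixed-pattern matching cannot cross them
  seq_n <- gsub("[a-z]", "N", utrs$sequence)
  ss <- Biostrings::DNAStringSet(seq_n)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  counts <- t(Biostrings::vcountPDict(pd, ss))
  dimnames(counts) <- list(utrs$id, words)
  # word windows wholly in unmasked sequence
  win <- Biostrings::oligonucleotideFrequency(ss, width = k)
  n_positions <- as.integer(rowSums(win))
  out <- list(ids = utrs$id, counts = counts, n_positions = n_positions,
              comp_m = NULL, comp_m1 = NULL, k = k, m = m)
  if (m >= 1) {
    out$comp_m <- Biostrings::oligonucleotideFrequency(ss, width = m)
    out$comp_m1 <- if (m >= 2)
      Biostrings::oligonucleotideFrequency(ss, width = m - 1) else NULL
    rownames(out$comp_m) <- utrs$id
    if (!is.null(out$comp_m1)) rownames(out$comp_m1) <- utrs$id
  }
  class(out) <- "mirdep_word_counts"
  out
}

#' Markov-chain word probability from composition tables
#'
#' Per-position probability of `word` under an order `m - 1` Markov chain
#' with transition frequencies estimated from a sequence's observed m-mer
#' (and (m-1)-mer) composition: the product of the frequencies of all
#' m-windows of the word divided by the product of the frequencies of its
#' interior (m-1)-windows.
#'
#' @param comp_m named numeric vector (or 1-row matrix) of m-mer counts.
#' @param comp_m1 named numeric vector of (m-1)-mer counts (NULL for m=1).
#' @param word the word.
#' @param m composition order.
#' @return list: `p` (per-position probability) and `degenerate` (TRUE when
#'   a zero denominator frequency forced p = 0).
#' @export
markov_word_probability <- function(comp_m, comp_m1, word, m) {
  comp_m <- drop(as.matrix(comp_m))
  k <- nchar(word)
  if (m < 1 || m > k) abort("`m` must be in 1..nchar(word)")
  tot_m <- sum(comp_m)
  if (tot_m == 0) return(list(p = 0, degenerate = TRUE))
  num_words <- substring(word, 1:(k - m + 1), m:k)
  f_num <- comp_m[num_words] / tot_m
  if (anyNA(f_num)) f_num[is.na(f_num)] <- 0
  if (m == 1) return(list(p = prod(f_num), degenerate = FALSE))
  comp_m1 <- drop(as.matrix(comp_m1))
  tot_m1 <- sum(comp_m1)
  den_words <- if (k - m + 1 >= 2)
    substring(word, 2:(k - m + 1), m:(k - 1)) else character(0)
  if (length(den_words) == 0) return(list(p = prod(f_num), degenerate = FALSE))
  f_den <- comp_m1[den_words] / tot_m1
  if (anyNA(f_den) || any(f_den == 0)) {
    return(list(p = 0, degenerate = TRUE))
  }
  list(p = prod(f_num) / prod(f_den), degenerate = FALSE)
}

# per-sequence expected counts and corrected (composition-rescaled) counts
corrected_counts <- function(wc) {
  counts <- wc$counts
  if (wc$m == 0) return(counts)
  n_seq <- nrow(counts)
  words <- colnames(counts)
  p <- matrix(0, n_seq, length(words), dimnames = dimnames(counts))
  for (j in seq_along(words)) {
    for (i in seq_len(n_seq)) {
      if (counts[i, j] == 0 && wc$n_positions[i] == 0) next
      pr <- markov_word_probability(wc$comp_m[i, ], wc$comp_m1[i, ],
                                    words[j], wc$m)
      p[i, j] <- pr$p
    }
  }
  expected <- p * wc$n_positions
  pbar <- colSums(expected) / sum(wc$n_positions)  # library-wide rate
  corr <- counts
  for (j in seq_along(words)) {
    r <- ifelse(p[, j] > 0, pbar[j] / p[, j], 1)
    corr[, j] <- counts[, j] * r
  }
  corr
}

#' Ranked-list word enrichment landscape
#'
#' For each word, computes a signed log10 hypergeometric enrichment score
#' at growing leading-bin cutoffs of a ranked UTR list: at cutoff c the
#' word's (Markov-corrected) count in the first c sequences is compared to
#' the count in the remainder via one-sided hypergeometric tests over word
#' windows. Positive scores indicate enrichment before the cutoff. With
#' `m >= 1`, per-sequence observed counts are rescaled into corrected count
#' units (library-wide expected rate over sequence-specific Markov rate)
#' and rounded half away from zero for the hypergeometric urn; `m = 0`
#' disables correction and reproduces the exact hypergeometric.
#'
#' @param ranked_ids sequence ids in ranking order (e.g. sorted by log2
#'   fold change).
#' @param word_counts `mirdep_word_counts` from [count_words()].
#' @param grow cutoff step (default 500 sequences).
#' @return tibble of class `mirdep_landscape`: `word`, `cutoff`, `score`
#'   (signed log10 p), plus attributes `params`.
#' @export
enrichment_landscape <- function(ranked_ids, word_counts, grow = 500) {
  wc <- word_counts
  idx <- match(ranked_ids, wc$ids)
  if (anyNA(idx)) abort("ranked ids missing from word counts")
  N <- length(idx)
  if (grow > N) grow <- N
  cutoffs <- seq(grow, N, by = grow)
  if (cutoffs[length(cutoffs)] < N) cutoffs <- c(cutoffs, N)

  corr <- corrected_counts(wc)[idx, , drop = FALSE]
  pos <- wc$n_positions[idx]
  cum_counts <- apply(corr, 2, cumsum)
  cum_pos <- cumsum(pos)
  T_pos <- cum_pos[N]
  M_all <- round_half_away(cum_counts[N, ])

  rows <- list()
  for (ci in seq_along(cutoffs)) {
    c0 <- cutoffs[ci]
    q <- round_half_away(cum_counts[c0, ])
    n1 <- cum_pos[c0]
    M <- M_all
    q <- pmin(q, M, n1)
    p_over <- stats::phyper(q - 1, M, T_pos - M, n1, lower.tail = FALSE)
    p_under <- stats::phyper(q, M, T_pos - M, n1, lower.tail = TRUE)
    score <- ifelse(p_over <= p_under, -log10(pmax(p_over, 1e-320)),
                    log10(pmax(p_under, 1e-320)))
    if (c0 == N) score <- rep(0, length(score))
    rows[[ci]] <- tibble(word = colnames(corr), cutoff = c0,
                         score = unname(score))
  }
  out <- purrr::list_rbind(rows)
  attr(out, "params") <- list(k = wc$k, grow = grow, markov_order_m = wc$m,
                              n_sequences = N)
  class(out) <- c("mirdep_landscape", class(out))
  out
}

#' Bonferroni-thresholded significant landscape points
#'
#' @param landscape tibble from [enrichment_landscape()].
#' @param alpha family-wise significance level (default 0.01).
#' @param scope Bonferroni correction scope: over `"words"` (default) or
#'   `"words_by_cutoffs"`.
#' @return list: `threshold` (on the -log10 scale) and `calls` (landscape
#'   rows beyond the threshold).
#' @export
landscape_significance <- function(landscape, alpha = 0.01,
                                   scope = c("words", "words_by_cutoffs")) {
  scope <- match.arg(scope)
  n_words <- length(unique(landscape$word))
  n_tests <- if (scope == "words") n_words
  else n_words * length(unique(landscape$cutoff))
  if (n_tests == 0) {
    return(list(threshold = Inf, calls = landscape[0, ]))
  }
  threshold <- -log10(alpha / n_tests)
  list(threshold = threshold,
       calls = landscape |> filter(abs(.data$score) > threshold))
}
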