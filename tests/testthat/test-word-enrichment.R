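test_that("word universe holds the two 7-windows of each 8mer(1A)", {
  wu <- build_word_universe(tibble::tibble(mirna_id = "miR-106a-like",
                                           sequence = "AAAAGUGCUUAC"))
  expect_setequal(wu$word, c("GCACTTT", "CACTTTA"))
  # identical first 8 nt -> the words deduplicate
  wu2 <- build_word_universe(tibble::tibble(
    mirna_id = c("a", "b"),
    sequence = c("AAAAGUGCUUAC", "AAAAGUGCUGGG")))
  expect_equal(nrow(wu2), 2)
  expect_setequal(wu2$mirna_ids[[1]], c("a", "b"))
  # n miRNAs contribute at most 2n words
  set.seed(3)
  mir <- tibble::tibble(mirna_id = sprintf("m%d", 1:20),
                        sequence = vapply(1:20, function(i)
                          paste(sample(c("A", "C", "G", "U"), 21,
                                       replace = TRUE), collapse = ""),
                          character(1)))
  expect_lte(nrow(build_word_universe(mir)), 40)
})

test_that("word counting matches a naive scan, with overlaps and masking", {
  utrs <- tibble::tibble(id = "s1", sequence = "AAAAAA")
  wc <- count_words(utrs, "AAAA", m = 0)
  expect_equal(unname(wc$counts[1, 1]), 3)   # overlapping occurrences

  set.seed(5)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T", "a"), 200, replace = TRUE,
                 prob = c(0.28, 0.24, 0.24, 0.2, 0.04)), collapse = ""),
    character(1))
  utrs <- tibble::tibble(id = sprintf("u%02d", 1:30), sequence = seqs)
  words <- c("ACGTGCA", "AAAACCC", "GCACTTA", "TTTTTTT")
  wc <- count_words(utrs, words, m = 4)
  for (i in 1:30) {
    for (w in words) {
      expect_equal(unname(wc$counts[i, w]), naive_word_count(seqs[i], w))
    }
  }
  # absent word counts zero everywhere
  expect_true(all(wc$counts[, "TTTTTTT"] >= 0))
})

test_that("Markov word probability reproduces analytic limits", {
  # uniform i.i.d. composition: P(word) = (1/4)^7
  comp4 <- stats::setNames(rep(1, 4^4),
                           mkAllMers(4))
  comp3 <- stats::setNames(rep(1, 4^3), mkAllMers(3))
  p <- markov_word_probability(comp4, comp3, "GCACTTA", 4)
  expect_equal(p$p, (1 / 4)^7, tolerance = 1e-12)
  expect_false(p$degenerate)

  # degenerate single-letter sequence: P(AAAAAAA) = 1
  ss <- Biostrings::DNAStringSet(strrep("A", 50))
  c4 <- Biostrings::oligonucleotideFrequency(ss, 4)[1, ]
  c3 <- Biostrings::oligonucleotideFrequency(ss, 3)[1, ]
  pA <- markov_word_probability(c4, c3, "AAAAAAA", 4)
  expect_equal(pA$p, 1)
  # zero-frequency interior word flags a degenerate result
  pG <- markov_word_probability(c4, c3, "GGGGGGG", 4)
  expect_true(pG$p == 0)

  # hand-built 2-letter Markov chain: probabilities of all 7-mers over the
  # chain's support sum to 1 (brute-force enumeration over 2^7 words)
  # chain on {A, C}: stationary AA/AC/CA/CC composition from a long sample
  set.seed(11)
  chain <- paste(sample(c("A", "C"), 20000, replace = TRUE,
                        prob = c(0.7, 0.3)), collapse = "")
  cs <- Biostrings::DNAStringSet(chain)
  c4 <- Biostrings::oligonucleotideFrequency(cs, 4)[1, ]
  c3 <- Biostrings::oligonucleotideFrequency(cs, 3)[1, ]
  all7 <- mkAllMers(7, c("A", "C"))
  tot <- sum(vapply(all7, function(w)
    markov_word_probability(c4, c3, w, 4)$p, double(1)))
  expect_equal(tot, 1, tolerance = 0.01)
  expect_error(markov_word_probability(c4, c3, "ACACACA", 9), "m")
})

test_that("landscape with m = 0 equals the enumeration hypergeometric", {
  # word planted once in each of the top 5 of 10 sequences, absent below
  set.seed(2)
  word <- "GCACTTA"
  mk <- function(with_word) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
      if (naive_word_count(s, word) == 0) break
    }
    if (with_word) substr(s, 20, 26) <- word
    s
  }
  utrs <- tibble::tibble(id = sprintf("u%02d", 1:10),
                         sequence = c(vapply(1:5, \(i) mk(TRUE), character(1)),
                                      vapply(1:5, \(i) mk(FALSE), character(1))))
  wc <- count_words(utrs, word, m = 0)
  ls <- enrichment_landscape(utrs$id, wc, grow = 5)
  at5 <- ls$score[ls$cutoff == 5]
  # oracle: 5 occurrences among the window positions of the leading 5
  n1 <- sum(wc$n_positions[1:5]); Tn <- sum(wc$n_positions)
  qq <- sum(wc$counts[1:5, 1]); KK <- sum(wc$counts[, 1])
  expect_equal(qq, 5)   # one planted site per leading sequence
  p_or <- hyper_upper_tail(qq, KK, Tn, n1)
  expect_gt(at5, 0)
  expect_equal(at5, -log10(p_or), tolerance = 1e-9)
  # terminal cutoff scores zero by convention
  expect_equal(ls$score[ls$cutoff == 10], 0)

  # random landscapes agree with the oracle at every point
  set.seed(8)
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
    character(1))
  utrs <- tibble::tibble(id = sprintf("r%02d", 1:40), sequence = seqs)
  words <- c("ACGT", "GGCA", "TTAA")
  wc <- count_words(utrs, words, m = 0)
  ls <- enrichment_landscape(utrs$id, wc, grow = 10)
  for (i in seq_len(nrow(ls))) {
    c0 <- ls$cutoff[i]
    if (c0 == 40) next
    K <- sum(wc$counts[, ls$word[i]])
    q <- sum(wc$counts[1:c0, ls$word[i]])
    n1 <- sum(wc$n_positions[1:c0]); Tn <- sum(wc$n_positions)
    po <- hyper_upper_tail(q, K, Tn, n1)
    pu <- hyper_lower_tail(q, K, Tn, n1)
    want <- if (po <= pu) -log10(po) else log10(pu)
    expect_equal(ls$score[i], want, tolerance = 1e-9)
  }
  # a word absent everywhere scores zero at every cutoff
  wz <- count_words(utrs, "AAAAAAAAAA", m = 0)
  lz <- enrichment_landscape(utrs$id, wz, grow = 10)
  expect_true(all(lz$score == 0))
})

test_that("reversing the ranking mirrors the landscape (m = 0)", {
  set.seed(13)
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1))
  utrs <- tibble::tibble(id = sprintf("s%02d", 1:40), sequence = seqs)
  wc <- count_words(utrs, c("ACGTA", "GGTTC"), m = 0)
  fwd <- enrichment_landscape(utrs$id, wc, grow = 10)
  rev_ls <- enrichment_landscape(rev(utrs$id), wc, grow = 10)
  for (c0 in c(10, 20, 30)) {
    f <- fwd[fwd$cutoff == c0, ]
    r <- rev_ls[rev_ls$cutoff == 40 - c0, ]
    m <- r$score[match(f$word, r$word)]
    expect_equal(abs(f$score), abs(m), tolerance = 1e-9)
    # signs flip except at an exact two-tail tie, where the enrichment
    # branch is taken on both sides by convention
    expect_true(all(abs(f$score + m) < 1e-9 | abs(f$score - m) < 1e-9))
  }
})

test_that("uniform-composition limit: m = 4 tracks m = 0", {
  deltas <- c()
  for (s in 1:20) {
    set.seed(s)
    seqs <- vapply(1:30, function(i)
      paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
            collapse = ""), character(1))
    utrs <- tibble::tibble(id = sprintf("q%02d", 1:30), sequence = seqs)
    words <- c("ACGTGCA", "TGCATGC")
    l0 <- enrichment_landscape(utrs$id, count_words(utrs, words, m = 0),
                               grow = 10)
    l4 <- enrichment_landscape(utrs$id, count_words(utrs, words, m = 4),
                               grow = 10)
    deltas <- c(deltas, abs(l0$score - l4$score))
  }
  expect_gte(mean(deltas <= 0.5), 0.95)
})

test_that("family-wise error of Bonferroni calls is controlled on nulls", {
  set.seed(21)
  seqs <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1))
  utrs <- tibble::tibble(id = sprintf("n%02d", 1:60), sequence = seqs)
  words <- c("ACGTGCA", "GGATCCA", "TTGCAAC", "CACGTGA")
  wc <- count_words(utrs, words, m = 0)
  alpha <- 0.05
  fwer <- vapply(1:200, function(i) {
    perm <- sample(utrs$id)
    ls <- enrichment_landscape(perm, wc, grow = 20)
    nrow(landscape_significance(ls, alpha = alpha,
                                scope = "words_by_cutoffs")$calls) > 0
  }, logical(1))
  # family-wise error at most alpha, within 3 binomial SD
  expect_lte(mean(fwer), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
})

test_that("Bonferroni threshold arithmetic matches the printed convention", {
  fake <- tibble::tibble(word = rep(sprintf("w%03d", 1:568), each = 2),
                         cutoff = rep(c(500, 1000), 568),
                         score = 0)
  thr <- landscape_significance(fake, alpha = 0.01)$threshold
  expect_equal(thr, -log10(0.01 / 568), tolerance = 1e-12)
  expect_equal(round(thr, 3), 4.754)
  one <- tibble::tibble(word = "w", cutoff = 500, score = 0)
  expect_equal(landscape_significance(one, alpha = 0.01)$threshold, 2)
  empty <- fake[0, ]
  expect_equal(nrow(landscape_significance(empty)$calls), 0)
})
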