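#' Per-transcript differential expression (plain two-sample test)
#'
#' Row-wise Welch two-sample t-test on log2 expression values with
#' Benjamini-Hochberg adjustment. The log2 fold change is
#' treatment minus control. Externally fitted DE tables with the same
#' columns are accepted everywhere a DE table is consumed.
#'
#' @param expression tibble: `transcript_id` plus one column per sample
#'   (log2 scale).
#' @param samples tibble with columns `sample`, `condition`.
#' @param control,treatment condition labels (defaults: the first and
#'   second level observed).
#' @return DE table tibble: `transcript_id`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`, `mean_expression`.
#' @export
differential_expression <- function(expression, samples,
                                    control = NULL, treatment = NULL) {
  conds <- unique(samples$condition)
  control <- control %||% conds[1]
  treatment <- treatment %||% conds[2]
  s_ctl <- samples$sample[samples$condition == control]
  s_trt <- samples$sample[samples$condition == treatment]
  if (length(s_ctl) < 2 || length(s_trt) < 2) {
    abort("at least 2 replicates per group are required")
  }
  x <- as.matrix(expression[, s_ctl, drop = FALSE])
  y <- as.matrix(expression[, s_trt, drop = FALSE])
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  tibble(
    transcript_id = expression$transcript_id,
    log2_fold_change = m2 - m1,
    p_value = p,
    adjusted_p = stats::p.adjust(p, method = "BH"),
    mean_expression = (m1 * n1 + m2 * n2) / (n1 + n2)
  )
}

#' Call a seed-gated miRNA target list
#'
#' A transcript is a target when it is significantly down-regulated at
#' least `fold_change_min`-fold (log2 fold change at or below
#' `-log2(fold_change_min)`), its adjusted p-value is at or below
#' `adjusted_p_max`, and its 3' UTR carries at least one 7mer(2) or
#' 7mer(1A) seed site. Transcripts without a seed profile (no annotated
#' UTR) are ineligible.
#'
#' @param de DE table (see [differential_expression()]).
#' @param profiles seed-match profiles from [scan_seed_matches()].
#' @param fold_change_min minimum linear down-regulation (default 1.2).
#' @param adjusted_p_max adjusted p cutoff (0.05 for the more sensitive
#'   array version in the original design, 0.10 otherwise).
#' @param mirna_id label attached to the list.
#' @return tibble of target rows (transcript_id, log2_fold_change,
#'   adjusted_p, seed counts) with attributes `mirna_id` and `thresholds`.
#' @export
call_target_list <- function(de, profiles, fold_change_min = 1.2,
                             adjusted_p_max = 0.05, mirna_id = "miRNA") {
  joined <- de |> inner_join(profiles, by = "transcript_id")
  out <- joined |>
    filter(.data$log2_fold_change <= -log2(fold_change_min),
           .data$adjusted_p <= adjusted_p_max,
           .data$any_7mer1A_or_7mer2)
  attr(out, "mirna_id") <- mirna_id
  attr(out, "thresholds") <- list(fold_change_min = fold_change_min,
                                  adjusted_p_max = adjusted_p_max,
                                  seed_gate = c("7mer1A", "7mer2"))
  class(out) <- c("mirdep_target_list", class(out))
  out
}

target_quality_internal <- function(de, profiles, fold_change_min,
                                    adjusted_p_max, control_band) {
  joined <- de |> inner_join(profiles, by = "transcript_id")
  sig <- joined |>
    filter(.data$log2_fold_change <= -log2(fold_change_min),
           .data$adjusted_p <= adjusted_p_max)
  ctl <- joined |> filter(abs(.data$log2_fold_change) < log2(control_band))
  if (nrow(sig) == 0) abort("no significantly down-regulated transcripts")
  if (nrow(ctl) == 0) abort("empty control set (no unchanged transcripts)")
  prop_sig <- mean(sig$any_7mer1A_or_7mer2)
  prop_ctl <- mean(ctl$any_7mer1A_or_7mer2)
  if (prop_ctl == 0) abort("zero seed proportion in the control set")
  tibble(
    n_significant_down = nrow(sig),
    n_control = nrow(ctl),
    seed_prop_signal = prop_sig,
    seed_prop_control = prop_ctl,
    signal_to_noise = prop_sig / prop_ctl,
    sensitivity_above_chance =
      sum(sig$any_7mer1A_or_7mer2) - nrow(sig) * prop_ctl
  )
}

#' Target-list signal-to-noise ratio
#'
#' The proportion of significantly down-regulated transcripts carrying a
#' 7mer(2) or 7mer(1A) seed in their 3' UTR divided by the same proportion
#' among transcripts whose expression changed less than `control_band`-fold
#' (the control set). Transcripts without an annotated UTR are excluded
#' from both sets.
#'
#' @inheritParams call_target_list
#' @param control_band linear fold-change bound defining the unchanged
#'   control set (default 1.1).
#' @return one-row tibble of quality metrics (see
#'   [sensitivity_above_chance()] for the companion statistic).
#' @export
signal_to_noise <- function(de, profiles, fold_change_min = 1.2,
                            adjusted_p_max = 0.05, control_band = 1.1) {
  target_quality_internal(de, profiles, fold_change_min, adjusted_p_max,
                          control_band)
}

#' Target-list sensitivity above chance
#'
#' The number of significantly down-regulated, seed-bearing transcripts
#' beyond the number expected from the control set's seed proportion:
#' `observed_with_seed - n_significant_down * seed_prop_control`. May be
#' negative; not clamped.
#'
#' @inheritParams signal_to_noise
#' @return the sensitivity-above-chance value (a single number).
#' @export
sensitivity_above_chance <- function(de, profiles, fold_change_min = 1.2,
                                     adjusted_p_max = 0.05,
                                     control_band = 1.1) {
  target_quality_internal(de, profiles, fold_change_min, adjusted_p_max,
                          control_band)$sensitivity_above_chance
}

#' Pairwise target-list overlaps with hypergeometric significance
#'
#' For every pair of target lists, reports the overlap count, the overlap
#' as a percentage of the smaller list, a one-sided over-representation
#' hypergeometric p-value given the universe, and the Bonferroni-corrected
#' p (factor = number of pairwise comparisons in the batch).
#'
#' @param lists named list of transcript id vectors.
#' @param universe transcript id universe (all lists must be contained).
#' @return tibble: `list_a`, `list_b`, `n_a`, `n_b`, `overlap_count`,
#'   `percent_of_smaller`, `hypergeometric_p`, `bonferroni_p`.
#' @export
target_overlap <- function(lists, universe) {
  bad <- names(lists)[!vapply(lists, function(l) all(l %in% universe),
                              logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("lists not contained in universe: %s",
                  paste(bad, collapse = ", ")))
  }
  nm <- names(lists)
  pairs <- utils::combn(length(lists), 2)
  n_comp <- ncol(pairs)
  U <- length(unique(universe))
  rows <- purrr::map(seq_len(n_comp), function(j) {
    a <- unique(lists[[pairs[1, j]]]); b <- unique(lists[[pairs[2, j]]])
    k <- length(intersect(a, b))
    p <- stats::phyper(k - 1, length(a), U - length(a), length(b),
                       lower.tail = FALSE)
    tibble(list_a = nm[pairs[1, j]], list_b = nm[pairs[2, j]],
           n_a = length(a), n_b = length(b), overlap_count = k,
           percent_of_smaller = 100 * k / min(length(a), length(b)),
           hypergeometric_p = p)
  })
  purrr::list_rbind(rows) |>
    mutate(bonferroni_p = pmin(1, .data$hypergeometric_p * n_comp))
}

#' Collapse multiple rows per transcript by maximal spread
#'
#' Utility for probe-level tables: keeps, per transcript, the row whose
#' expression values have the largest inter-quartile range.
#'
#' @param expression tibble: `transcript_id` plus sample columns.
#' @return tibble with one row per transcript.
#' @export
collapse_by_iqr <- function(expression) {
  vals <- as.matrix(expression[, setdiff(names(expression), "transcript_id")])
  iqr <- apply(vals, 1, stats::IQR)
  expression |>
    mutate(.iqr = iqr) |>
    group_by(.data$transcript_id) |>
    arrange(desc(.data$.iqr), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".iqr")
}
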