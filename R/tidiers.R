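#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a preranked GSEA result
#'
#' @param x `mirdep_gsea` object.
#' @param ... unused.
#' @return tibble with one row per ranked position: `position`,
#'   `running_score`, `hit`.
#' @export
tidy.mirdep_gsea <- function(x, ...) {
  tibble(position = seq_len(x$n),
         running_score = x$running_score,
         hit = seq_len(x$n) %in% x$hit_positions)
}

#' One-row summary of a preranked GSEA result
#'
#' @param x `mirdep_gsea` object.
#' @param ... unused.
#' @return one-row tibble: `set_id`, `es`, `nes`, `p_perm`, `set_size`,
#'   `n`, `n_perm`.
#' @export
glance.mirdep_gsea <- function(x, ...) {
  tibble(set_id = x$set_id, es = x$es, nes = x$nes, p_perm = x$p_perm,
         set_size = x$set_size, n = x$n, n_perm = x$n_perm)
}

#' Tidy a target list (plain tibble of member rows)
#'
#' @param x `mirdep_target_list`.
#' @param ... unused.
#' @return tibble of target rows with the miRNA id as a column.
#' @export
tidy.mirdep_target_list <- function(x, ...) {
  as_tibble(x) |> mutate(mirna_id = attr(x, "mirna_id"), .before = 1)
}

#' One-row summary of a target list
#'
#' @param x `mirdep_target_list`.
#' @param ... unused.
#' @return one-row tibble: `mirna_id`, `n_targets`, thresholds.
#' @export
glance.mirdep_target_list <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(mirna_id = attr(x, "mirna_id"), n_targets = nrow(x),
         fold_change_min = th$fold_change_min,
         adjusted_p_max = th$adjusted_p_max)
}

#' Tidy an enrichment landscape (already long format)
#'
#' @param x `mirdep_landscape`.
#' @param ... unused.
#' @return the landscape as a plain tibble.
#' @export
tidy.mirdep_landscape <- function(x, ...) as_tibble(x)

#' One-row-per-word summary of an enrichment landscape
#'
#' @param x `mirdep_landscape`.
#' @param ... unused.
#' @return tibble: `word`, `peak_score` (signed, maximum magnitude),
#'   `peak_cutoff`.
#' @export
glance.mirdep_landscape <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$word) |>
    summarise(peak_score = .data$score[which.max(abs(.data$score))],
              peak_cutoff = .data$cutoff[which.max(abs(.data$score))],
              .groups = "drop") |>
    arrange(desc(abs(.data$peak_score)))
}
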