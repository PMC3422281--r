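#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric over-representation test of a query id list
#' against each gene set, after universe filtering: ids without any set
#' annotation are removed from the universe and the query (mirroring the
#' removal of genes with no pathway annotation), set members are restricted
#' to the universe, and duplicates are dropped.
#'
#' @param query character vector of gene ids (e.g. a target list).
#' @param sets tibble with `set_id`, `name`, `members` (list column), e.g.
#'   from [read_gmt()] or [generate_gene_sets()].
#' @param universe id universe (all interrogated genes).
#' @param alpha significance cutoff for the `significant` flag
#'   (default 0.01).
#' @param filter_unannotated drop universe/query ids not annotated to any
#'   set (default TRUE).
#' @return tibble: `set_id`, `name`, `set_size`, `query_size`, `overlap`,
#'   `p_value`, `significant`, sorted by p.
#' @export
hypergeometric_enrichment <- function(query, sets, universe, alpha = 0.01,
                                      filter_unannotated = TRUE) {
  universe <- unique(universe)
  if (filter_unannotated) {
    annotated <- unique(unlist(sets$members))
    universe <- intersect(universe, annotated)
  }
  if (length(universe) == 0) abort("empty universe after filtering")
  query <- intersect(unique(query), universe)
  U <- length(universe)
  nq <- length(query)
  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    mem <- intersect(unique(sets$members[[i]]), universe)
    k <- length(intersect(query, mem))
    p <- stats::phyper(k - 1, length(mem), U - length(mem), nq,
                       lower.tail = FALSE)
    tibble(set_id = sets$set_id[i], name = sets$name[i],
           set_size = length(mem), query_size = nq, overlap = k,
           p_value = p)
  })
  purrr::list_rbind(rows) |>
    mutate(significant = .data$p_value < alpha) |>
    arrange(.data$p_value)
}

#' Running enrichment score along a ranked gene list
#'
#' Walking down the ranked list, member genes ("hits") increment the
#' running score by `|metric|^weight_exponent` normalized to sum to 1 over
#' the members, and non-members decrement it by `1 / (N - set size)`. The
#' enrichment score (ES) is the signed maximum-magnitude deviation from
#' zero.
#'
#' @param ranked tibble with columns `id` and `metric`, already sorted in
#'   ranking order.
#' @param members character vector of member ids (subset of `ranked$id`,
#'   non-empty, not the whole list).
#' @param weight_exponent 1 (weighted, default) or 0 (classic
#'   Kolmogorov-Smirnov-like statistic).
#' @return list: `running_score` (numeric vector over ranked positions),
#'   `es`, `es_position`, `hit_positions`.
#' @export
running_enrichment_score <- function(ranked, members, weight_exponent = 1) {
  ids <- ranked$id
  if (anyDuplicated(ids)) abort("ranked ids must be unique")
  N <- length(ids)
  if (!all(members %in% ids)) abort("member set must be contained in the ranking")
  hit <- ids %in% members
  s <- sum(hit)
  if (s == 0 || s == N) abort("member set must be a non-empty strict subset")
  w <- abs(ranked$metric)^weight_exponent
  inc <- ifelse(hit, w, 0)
  if (sum(inc) == 0) inc <- as.numeric(hit)   # all-zero metrics: fall back
  inc <- inc / sum(inc)
  dec <- ifelse(hit, 0, 1 / (N - s))
  running <- cumsum(inc - dec)
  i_max <- which.max(abs(running))
  list(running_score = running, es = running[i_max], es_position = i_max,
       hit_positions = which(hit))
}

# ES of a permuted member set given precomputed weights, by evaluating the
# running score only at hit positions
es_at_positions <- function(idx, w, N) {
  s <- length(idx)
  wh <- w[idx]
  tot <- sum(wh)
  if (tot == 0) { wh <- rep(1, s); tot <- s }
  cum_hit <- cumsum(wh) / tot
  miss <- (idx - seq_len(s)) / (N - s)   # misses before and incl. gap
  after <- cum_hit - miss                # value just after each hit
  before <- c(0, cum_hit[-s]) - miss     # value just before each hit
  hi <- max(after); lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment with permutation significance
#'
#' Computes the running enrichment score of a member set in a ranked list
#' and estimates significance from `n_perm` random member sets of equal
#' size drawn without replacement. The plain estimator
#' `p = #(direction-matched |ES_null| >= |ES|) / n_perm` is used by
#' default, giving a minimum detectable p of `1 / n_perm`; a +1-smoothed
#' estimator is available. NES is ES divided by the mean |null ES| of the
#' same sign.
#'
#' @inheritParams running_enrichment_score
#' @param n_perm number of permutations (default 40000).
#' @param rng_seed integer seed.
#' @param smoothed use the (count+1)/(n_perm+1) estimator (default FALSE).
#' @param set_id label for the result.
#' @return object of class `mirdep_gsea`: list with `set_id`, `es`, `nes`,
#'   `p_perm`, `running_score`, `hit_positions`, `n_perm`, `rng_seed`,
#'   `n`, `set_size`.
#' @export
gsea_preranked <- function(ranked, members, n_perm = 40000, rng_seed = 1L,
                           weight_exponent = 1, smoothed = FALSE,
                           set_id = "set") {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  res <- running_enrichment_score(ranked, members, weight_exponent)
  N <- nrow(ranked)
  s <- length(res$hit_positions)
  w <- abs(ranked$metric)^weight_exponent
  set.seed(rng_seed)
  es_null <- vapply(seq_len(n_perm), function(i) {
    es_at_positions(sort(sample.int(N, s)), w, N)
  }, double(1))
  same_sign <- if (res$es >= 0) es_null >= 0 else es_null < 0
  count <- sum(same_sign & abs(es_null) >= abs(res$es))
  p <- if (smoothed) (count + 1) / (n_perm + 1) else max(count, 1) / n_perm
  denom <- mean(abs(es_null[same_sign]))
  nes <- if (is.finite(denom) && denom > 0) res$es / denom else NA_real_
  structure(list(set_id = set_id, es = res$es, nes = nes, p_perm = p,
                 running_score = res$running_score,
                 hit_positions = res$hit_positions,
                 n_perm = n_perm, rng_seed = rng_seed,
                 n = N, set_size = s),
            class = "mirdep_gsea")
}

#' @export
print.mirdep_gsea <- function(x, ...) {
  cat(sprintf(
    "Preranked GSEA: set '%s' (%d of %d genes)\n  ES = %.3f  NES = %.3f  p_perm = %.3g (%d permutations)\n",
    x$set_id, x$set_size, x$n, x$es, x$nes, x$p_perm, x$n_perm))
  invisible(x)
}

#' Intersect ranked lists across platforms before GSEA
#'
#' When a target list comes from a different array version than the
#' ranking, only ids interrogated by both are retained.
#'
#' @param ranked tibble with `id`, `metric`.
#' @param members member id vector.
#' @param shared ids present on both platforms.
#' @return list with filtered `ranked` and `members`.
#' @export
reconcile_platforms <- function(ranked, members, shared) {
  list(ranked = ranked |> filter(.data$id %in% shared),
       members = intersect(members, shared))
}
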