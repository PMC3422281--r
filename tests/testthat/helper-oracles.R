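# Independent oracles used to pin the package's statistics and algorithms.
# These deliberately share no code with the implementations they check.

# one-sided hypergeometric upper tail by explicit enumeration of the pmf:
# P(X >= k) with K white balls, N total, n drawn
hyper_upper_tail <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  js <- max(k, 0):min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

hyper_lower_tail <- function(k, K, N, n) {
  lo <- max(0, n - (N - K))
  if (k < lo) return(0)
  js <- lo:min(k, K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# literal subset enumeration: probability that a random n-subset of a
# universe of size N overlaps a fixed K-set in >= k elements
hyper_upper_by_subsets <- function(k, K, N, n) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)   # the K-set is taken as 1..K
  mean(hits >= k)
}

# naive overlapping substring count, one position at a time, skipping any
# window containing a masked (lower case or N) base
naive_word_count <- function(s, word) {
  k <- nchar(word)
  n <- nchar(s)
  if (n < k) return(0L)
  cnt <- 0L
  for (i in seq_len(n - k + 1)) {
    win <- substr(s, i, i + k - 1)
    if (grepl("[a-zN]", win)) next
    if (win == word) cnt <- cnt + 1L
  }
  cnt
}

# exhaustive ungapped alignment of one read against one reference record,
# applying the published thresholds position by position
naive_map_read <- function(read, rec, min_identity = 0.90, min_length = 16,
                           min_coverage = 0.75) {
  starts <- c(1L, 2L)
  if (rec$class_label == "miRNA" && !is.na(rec$mature_start)) {
    starts <- sort(unique(c(starts, rec$mature_start, rec$mature_start + 1L)))
  }
  rl <- nchar(read)
  best <- NULL
  for (st in starts) {
    if (st > nchar(rec$sequence)) next
    alen <- min(rl, nchar(rec$sequence) - st + 1L)
    if (alen < min_length || alen / rl < min_coverage) next
    matches <- 0L
    for (i in seq_len(alen)) {
      if (substr(read, i, i) == substr(rec$sequence, st + i - 1, st + i - 1)) {
        matches <- matches + 1L
      }
    }
    ident <- matches / alen
    if (ident >= min_identity) {
      if (is.null(best) || ident > best$identity) {
        best <- list(start = st, identity = ident, aligned_length = alen)
      }
    }
  }
  best
}

# textbook dense MCL, no pruning, written independently of the package's
# sparse implementation; shares only the declared parameters (self-loop =
# max incident weight, expansion power 2)
reference_mcl <- function(adj, inflation, max_iter = 300, tol = 1e-8) {
  stopifnot(is.matrix(adj), !is.null(rownames(adj)))
  loops <- apply(adj, 1, max)
  loops[loops == 0] <- 1
  diag(adj) <- loops
  M <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    Mp <- M
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - Mp)) < tol) break
  }
  S <- (M + t(M)) > 1e-5
  diag(S) <- FALSE
  n <- nrow(S)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cur <- cur + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cur
      queue <- c(queue, which(S[u, ] & comp == 0))
    }
  }
  split(rownames(adj), comp)
}

# canonical form of a partition for comparison: sorted list of sorted groups
partition_canonical <- function(groups) {
  unname(lapply(groups, function(g) sort(as.character(g)))) |>
    (\(x) x[order(vapply(x, `[`, character(1), 1))])()
}

partition_from_tibble <- function(cl) {
  partition_canonical(split(cl$node, cl$cluster))
}

# dense adjacency matrix (weights) from an igraph, for the reference MCL
dense_adjacency <- function(net) {
  w <- igraph::E(net)$weight
  A <- as.matrix(igraph::as_adjacency_matrix(
    net, attr = if (!is.null(w)) "weight" else NULL, sparse = FALSE))
  A
}

# quick helper: planted-partition igraph via the package generator
planted_net <- function(sizes, p_in, p_out, seed, n_hubs = 0) {
  sim <- simulate_interaction_network(sizes, p_in, p_out, n_hubs = n_hubs,
                                      rng_seed = seed)
  list(net = build_network(sim$edges), truth = sim$truth)
}

# all k-mers over an alphabet (order irrelevant; used for composition tables)
mkAllMers <- function(k, alphabet = c("A", "C", "G", "T")) {
  do.call(paste0, expand.grid(rep(list(alphabet), k),
                              stringsAsFactors = FALSE))
}
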