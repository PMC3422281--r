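#' Build an undirected weighted network from an edge list
#'
#' Drops self-loops, merges duplicate edges (keeping the first weight; an
#' unweighted input gets weight 1 everywhere) and returns an igraph object.
#'
#' @param edges tibble with two node columns (`from`, `to`; or the first
#'   two columns) and an optional `weight` column, or a path to a TSV/SIF
#'   edge-list file.
#' @return undirected simple igraph with edge attribute `weight` and graph
#'   attribute `provenance = "raw"`.
#' @export
build_network <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    lines <- readLines(edges)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    header <- tolower(paste(parts[[1]], collapse = " "))
    start <- if (grepl("from|node|source", header)) 2L else 1L
    bad <- which(nf[start:length(nf)] < 2)
    if (length(bad) > 0) {
      abort(sprintf("malformed edge-list line %d: fewer than 2 fields",
                    bad[1] + start - 1L))
    }
    get <- function(j) vapply(parts[start:length(parts)], `[`, character(1), j)
    if (nf[min(length(nf), start)] >= 3 && grepl("^sif$", tools::file_ext(edges))) {
      edges <- tibble(from = get(1), to = get(3))  # SIF: node type node
    } else {
      edges <- tibble(from = get(1), to = get(2))
      w <- suppressWarnings(as.numeric(vapply(
        parts[start:length(parts)],
        function(p) if (length(p) >= 3) p[3] else NA_character_,
        character(1))))
      if (!all(is.na(w))) edges$weight <- ifelse(is.na(w), 1, w)
    }
  }
  edges <- as_tibble(edges)
  if (ncol(edges) < 2) abort("edge list needs two node columns")
  names(edges)[1:2] <- c("from", "to")
  if (!"weight" %in% names(edges)) edges$weight <- 1
  all_nodes <- unique(c(edges$from, edges$to))
  edges <- edges |> filter(.data$from != .data$to)
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                paste(edges$to, edges$from))
  edges <- edges[!duplicated(key), ]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = all_nodes)
  g$provenance <- "raw"
  g
}

#' Average node degree of a graph summary
#'
#' @param n_nodes,n_edges node and edge counts of a simple undirected
#'   graph.
#' @return `2 * n_edges / n_nodes`.
#' @export
average_degree <- function(n_nodes, n_edges) 2 * n_edges / n_nodes

#' Summarise a network
#'
#' @param net igraph object.
#' @return one-row tibble: `n_nodes`, `n_edges`, `average_degree`,
#'   `max_degree`.
#' @export
graph_summary <- function(net) {
  tibble(n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
         average_degree = average_degree(igraph::vcount(net),
                                         igraph::ecount(net)),
         max_degree = if (igraph::vcount(net) > 0)
           max(igraph::degree(net)) else 0)
}

#' Promote edges by triangle participation
#'
#' Adds to each edge weight `alpha` times the number of triangles the edge
#' participates in (the number of common neighbours of its endpoints). A
#' simple network with unit weights becomes weightable for k-NN reduction:
#' edges inside densely connected regions are promoted, edges to isolated
#' hubs are not.
#'
#' @param net igraph with `weight` edge attribute.
#' @param alpha proportionality constant (default 1).
#' @return igraph with updated weights and `provenance =
#'   "triangle_weighted"`; the edge set is unchanged.
#' @export
triangle_weights <- function(net, alpha = 1) {
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A@x[] <- 1   # topology only
  A2 <- A %*% A
  el <- igraph::as_edgelist(net, names = FALSE)
  tri <- A2[cbind(el[, 1], el[, 2])]
  w0 <- igraph::E(net)$weight
  if (is.null(w0)) w0 <- rep(1, nrow(el))
  igraph::E(net)$weight <- w0 + alpha * tri
  igraph::E(net)$triangles <- tri
  net$provenance <- "triangle_weighted"
  net
}

#' k-nearest-neighbour edge reduction
#'
#' Keeps an edge only if its weight ranks within the top `k` incident edge
#' weights of both endpoints. Ranking is a total order: weight descending,
#' neighbour id ascending on ties, so the reduced network has maximum
#' degree at most `k`.
#'
#' @param net weighted igraph.
#' @param k neighbourhood size (default 100).
#' @return reduced igraph (`provenance = "knn_reduced"`, attribute `k`).
#' @export
knn_reduce <- function(net, k = 100) {
  if (k < 1) abort("`k` must be >= 1")
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  long <- tibble(
    node = c(el[, 1], el[, 2]),
    neighbor = c(el[, 2], el[, 1]),
    weight = rep(w, 2),
    edge_id = rep(seq_len(nrow(el)), 2)
  )
  ranked <- long |>
    group_by(.data$node) |>
    arrange(desc(.data$weight), .data$neighbor, .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  keep_ids <- ranked |>
    group_by(.data$edge_id) |>
    summarise(keep = all(.data$rank <= k), .groups = "drop") |>
    filter(.data$keep) |>
    pull(.data$edge_id)
  out <- igraph::subgraph_from_edges(net, keep_ids, delete.vertices = FALSE)
  out$provenance <- "knn_reduced"
  out$k <- k
  out
}

# column-normalize a sparse matrix
col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov cluster algorithm (MCL)
#'
#' Clusters a weighted graph by alternating expansion (matrix squaring) and
#' inflation (entrywise power followed by column renormalization) on the
#' column-stochastic transition matrix until convergence. Self-loops are
#' added with weight equal to each node's maximum incident weight; entries
#' below `prune` are dropped (with renormalization) after each inflation.
#' Clusters are the connected components of the converged attractor
#' structure, numbered in descending size order.
#'
#' @param net weighted igraph.
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param max_iter maximum iterations (default 200).
#' @param prune entry pruning threshold (default 1e-5).
#' @param conv_tol convergence tolerance on the maximum entry change
#'   (default 1e-8).
#' @return tibble with columns `node`, `cluster` (integer ids, 1 =
#'   largest).
#' @export
mcl_cluster <- function(net, inflation, max_iter = 200, prune = 1e-5,
                        conv_tol = 1e-8) {
  if (inflation <= 1) abort("`inflation` must be > 1")
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  if (n == 0) return(tibble(node = character(0), cluster = integer(0)))
  A <- igraph::as_adjacency_matrix(net, attr =
    if (!is.null(igraph::E(net)$weight)) "weight" else NULL, sparse = TRUE)
  A <- A * 1
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1  # isolated nodes self-attract
  Matrix::diag(A) <- loop
  M <- col_normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_prev <- M
    M <- M %*% M                       # expansion
    M@x <- M@x^inflation               # inflation
    M <- col_normalize(M)
    M@x[M@x < prune] <- 0              # pruning
    M <- Matrix::drop0(M)
    M <- col_normalize(M)
    delta <- max(abs(M - M_prev))
    if (delta < conv_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("MCL did not converge in %d iterations (last delta %.3g)",
                  max_iter, delta))
  }
  S <- (M + Matrix::t(M)) > 0
  comp_graph <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                                    diag = FALSE)
  comp <- igraph::components(comp_graph)$membership
  sizes <- table(comp)
  ord <- rank(-as.vector(sizes), ties.method = "first")
  cluster <- ord[comp]
  tibble(node = nodes, cluster = as.integer(cluster)) |>
    arrange(.data$cluster, .data$node)
}

#' Two-level nested MCL clustering
#'
#' A coarse clustering at low inflation followed by subclustering of the
#' network restricted to each coarse cluster at higher inflation. Every
#' fine cluster is nested in exactly one coarse cluster by construction.
#'
#' @param net weighted igraph (typically k-NN reduced).
#' @param coarse_inflation inflation of the coarse pass (default 1.3).
#' @param fine_inflation inflation of the subclustering pass (default 2.0).
#' @param ... passed to [mcl_cluster()].
#' @return tibble: `node`, `coarse`, `fine` (both numbered by descending
#'   size).
#' @export
two_level_clustering <- function(net, coarse_inflation = 1.3,
                                 fine_inflation = 2.0, ...) {
  coarse <- mcl_cluster(net, coarse_inflation, ...)
  fine_parts <- list()
  for (cid in sort(unique(coarse$cluster))) {
    sub_nodes <- coarse$node[coarse$cluster == cid]
    sub <- igraph::induced_subgraph(net, sub_nodes)
    fine <- mcl_cluster(sub, fine_inflation, ...)
    fine$coarse <- cid
    fine_parts[[length(fine_parts) + 1]] <- fine
  }
  fine_all <- purrr::list_rbind(fine_parts) |>
    mutate(key = paste(.data$coarse, .data$cluster))
  sizes <- fine_all |> count(.data$key, sort = TRUE)
  fine_all |>
    mutate(fine = match(.data$key, sizes$key)) |>
    select("node", "coarse", "fine") |>
    arrange(.data$fine, .data$node)
}

#' Per-list per-cluster influence (support) scores
#'
#' The support of a node for a cluster is the fraction of the node's total
#' incident edge weight (in the k-NN reduced network) carried by edges into
#' that cluster; a node outside the cluster can therefore support it via
#' its neighbours. The support of a target list for a cluster is the sum of
#' its nodes' supports, normalized by cluster size. Cells also report the
#' number of genes shared between list and cluster.
#'
#' @param net weighted igraph (the k-NN reduced network).
#' @param clustering tibble with `node` and a cluster id column (`cluster`
#'   or `fine`).
#' @param lists named list of node id vectors (target lists); ids absent
#'   from the network are dropped with a warning.
#' @return tibble of class `mirdep_support`: `cluster`, `list_id`,
#'   `support`, `shared_count`, `cluster_size`.
#' @export
influence_support <- function(net, clustering, lists) {
  cl_col <- if ("cluster" %in% names(clustering)) "cluster" else "fine"
  clustering <- clustering |> select("node", cluster = dplyr::all_of(cl_col))
  nodes <- igraph::V(net)$name
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(net))
  el <- igraph::as_edgelist(net, names = TRUE)
  cl_of <- stats::setNames(clustering$cluster, clustering$node)
  strength <- stats::setNames(rep(0, length(nodes)), nodes)
  agg <- tibble(node = c(el[, 1], el[, 2]),
                other = c(el[, 2], el[, 1]),
                weight = rep(w, 2)) |>
    mutate(other_cluster = cl_of[.data$other])
  st <- agg |> group_by(.data$node) |>
    summarise(strength = sum(.data$weight), .groups = "drop")
  strength[st$node] <- st$strength
  # s(v, C) for all v with an edge into C
  svc <- agg |>
    group_by(.data$node, .data$other_cluster) |>
    summarise(w_in = sum(.data$weight), .groups = "drop") |>
    mutate(s = .data$w_in / strength[.data$node])

  cl_sizes <- clustering |> count(.data$cluster, name = "cluster_size")
  rows <- purrr::imap(lists, function(members, list_id) {
    present <- intersect(members, nodes)
    if (length(present) < length(members)) {
      rlang::warn(sprintf("list '%s': %d ids absent from the network",
                          list_id, length(members) - length(present)))
    }
    sup <- svc |>
      filter(.data$node %in% present) |>
      group_by(cluster = .data$other_cluster) |>
      summarise(total_s = sum(.data$s), .groups = "drop")
    cl_sizes |>
      left_join(sup, by = "cluster") |>
      mutate(
        list_id = list_id,
        support = dplyr::coalesce(.data$total_s, 0) / .data$cluster_size,
        shared_count = vapply(.data$cluster, function(cc)
          length(intersect(present,
                           clustering$node[clustering$cluster == cc])),
          integer(1))
      ) |>
      select("cluster", "list_id", "support", "shared_count", "cluster_size")
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("mirdep_support", class(out))
  out
}

#' Annotate clusters by gene-set over-representation
#'
#' Labels each cluster with its best-scoring enriched terms: the two best
#' terms concatenated when the combined label stays within `max_label`
#' characters, otherwise the best term only.
#'
#' @param clustering tibble with `node` and cluster column.
#' @param sets gene-set tibble (`set_id`, `name`, `members`).
#' @param universe id universe.
#' @param max_label maximum combined label length (default 50 characters).
#' @return tibble: `cluster`, `label`, `best_p`.
#' @export
annotate_clusters <- function(clustering, sets, universe, max_label = 50) {
  cl_col <- if ("cluster" %in% names(clustering)) "cluster" else "fine"
  ids <- sort(unique(clustering[[cl_col]]))
  rows <- purrr::map(ids, function(cid) {
    members <- clustering$node[clustering[[cl_col]] == cid]
    enr <- hypergeometric_enrichment(members, sets, universe)
    top <- utils::head(enr, 2)
    lab <- paste(top$name, collapse = "; ")
    if (nchar(lab) > max_label) lab <- top$name[1]
    tibble(cluster = cid, label = lab, best_p = top$p_value[1])
  })
  purrr::list_rbind(rows)
}
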