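#' Collaboration strength between two coauthors
#'
#' The non-normalized variant is the raw number of coauthored publications
#' `M_xy` (on molecules interacting with the query). The normalized variant
#' discounts prolific authors:
#' \deqn{w = M_{xy} / \sqrt{N_x N_y}}
#' where `N_x`, `N_y` are the authors' total publication counts.
#'
#' @param M_xy number of coauthored publications on the related molecules.
#' @param N_x,N_y total publication counts of the two authors (required >= 1
#'   for the normalized variant).
#' @param variant `"norm"` or `"nonnorm"`.
#' @return the edge weight.
#' @export
collaboration_weight <- function(M_xy, N_x, N_y, variant = c("norm", "nonnorm")) {
  variant <- match.arg(variant)
  if (any(M_xy < 0)) abort_domain("M_xy must be >= 0")
  if (variant == "nonnorm") return(M_xy)
  if (any(N_x < 1) || any(N_y < 1))
    abort_domain("N_x and N_y must be >= 1 for the normalized weight")
  M_xy / sqrt(N_x * N_y)
}

#' Build the query-specific coauthorship subnetwork
#'
#' Nodes are the authors with at least one publication mentioning at least
#' one related molecule of the query. An edge joins authors x and y iff they
#' coauthored at least one such publication; `M_xy` counts distinct
#' publications (a publication mentioning two related molecules still counts
#' once). Edge weights follow [collaboration_weight()], with `N` the
#' author's total publication count in the loaded corpus.
#'
#' @param net a [multilayer_network()].
#' @param query molecule name or alias.
#' @param variant `"norm"` or `"nonnorm"`.
#' @return an undirected [igraph::graph] with vertex attributes `name` and
#'   `N`, edge attributes `M` and `weight`. Empty (0-node) graph when no
#'   author qualifies.
#' @export
build_coauthor_subnetwork <- function(net, query, variant = c("norm", "nonnorm")) {
  variant <- match.arg(variant)
  rel <- related_molecules(net, query)
  rel_pubs <- unique(net$mentions$pub_id[net$mentions$molecule %in% rel])
  au <- net$authorship[net$authorship$pub_id %in% rel_pubs, c("pub_id", "author_key")]
  nodes <- sort(unique(au$author_key))
  totals <- total_pub_counts(net)
  if (length(nodes) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))

  pairs <- do.call(rbind, lapply(split(au$author_key, au$pub_id), function(as) {
    as <- sort(unique(as))
    if (length(as) < 2) return(NULL)
    cmb <- utils::combn(as, 2)
    data.frame(x = cmb[1, ], y = cmb[2, ], stringsAsFactors = FALSE)
  }))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes, N = unname(totals[nodes]))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    agg <- stats::aggregate(list(M = rep(1L, nrow(pairs))), pairs[c("x", "y")], sum)
    w <- collaboration_weight(agg$M, totals[agg$x], totals[agg$y], variant)
    g <- igraph::add_edges(g, rbind(agg$x, agg$y),
                           M = agg$M, weight = unname(w))
  }
  g
}

#' PageRank configuration
#'
#' @param damping probability of following an edge rather than teleporting;
#'   in (0,1). Default 0.85, the canonical choice.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @return a list of class `pagerank_config`.
#' @export
pagerank_config <- function(damping = 0.85, tol = 1e-10, max_iter = 200) {
  if (damping <= 0 || damping >= 1) abort_domain("damping must be in (0,1)")
  if (tol <= 0 || max_iter < 1) abort_domain("tol > 0 and max_iter >= 1 required")
  structure(list(damping = damping, tol = tol, max_iter = max_iter),
            class = "pagerank_config")
}

#' Weighted PageRank by power iteration
#'
#' Random-surfer scores on a weighted undirected graph: at each step the
#' surfer follows an incident edge with probability `damping` (choosing a
#' neighbor with probability proportional to the edge weight) or teleports
#' to a uniformly random node. Mass on dangling (isolated) nodes is
#' redistributed uniformly, so isolated nodes end up with teleport-only
#' scores. An optional personalization vector replaces the uniform teleport
#' distribution.
#'
#' @param graph an [igraph::graph] with an edge attribute `weight`
#'   (unweighted graphs are treated as weight 1).
#' @param config a [pagerank_config()].
#' @param personalization optional non-negative vector (named by vertex or
#'   in vertex order); normalized internally.
#' @return named numeric vector of scores summing to 1.
#' @export
pagerank <- function(graph, config = pagerank_config(), personalization = NULL) {
  n <- igraph::vcount(graph)
  if (n == 0) mc_abort("pagerank needs a graph with at least one node", "mc_empty_input")
  names_v <- igraph::V(graph)$name
  if (is.null(names_v)) names_v <- as.character(seq_len(n))
  A <- as.matrix(igraph::as_adjacency_matrix(
    graph, attr = if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = TRUE))
  s <- rowSums(A)
  v <- if (is.null(personalization)) rep(1 / n, n) else {
    p <- if (!is.null(names(personalization))) personalization[names_v] else personalization
    p <- as.numeric(p)
    if (any(is.na(p) | p < 0) || sum(p) <= 0)
      abort_domain("personalization must be non-negative with positive sum")
    p / sum(p)
  }
  d <- config$damping
  p <- rep(1 / n, n)
  dangling <- s == 0
  for (it in seq_len(config$max_iter)) {
    walk <- numeric(n)
    if (any(!dangling)) {
      contrib <- p[!dangling] / s[!dangling]
      walk <- as.numeric(crossprod(A[!dangling, , drop = FALSE], contrib))
    }
    p_new <- (1 - d) * v + d * (walk + sum(p[dangling]) * v)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < config$tol) break
  }
  stats::setNames(p / sum(p), names_v)
}

#' Top coauthor pairs on a single molecule
#'
#' The divide-and-conquer prefilter step: restricted to publications
#' mentioning one given molecule, rank coauthor pairs by the number of
#' publications they coauthored there.
#'
#' @param net a [multilayer_network()].
#' @param molecule molecule name or alias.
#' @param k_pairs number of pairs to keep (>= 1).
#' @return data.frame with columns `x`, `y` (x < y lexicographically), `M`,
#'   sorted by `M` descending then (x, y) lexicographically; at most
#'   `k_pairs` rows.
#' @export
per_molecule_top_pairs <- function(net, molecule, k_pairs) {
  if (k_pairs < 1) abort_domain("k_pairs must be >= 1")
  m <- resolve_molecule(net, molecule)
  pubs <- publications_mentioning(net, m)
  au <- net$authorship[net$authorship$pub_id %in% pubs, c("pub_id", "author_key")]
  pairs <- do.call(rbind, lapply(split(au$author_key, au$pub_id), function(as) {
    as <- sort(unique(as))
    if (length(as) < 2) return(NULL)
    cmb <- utils::combn(as, 2)
    data.frame(x = cmb[1, ], y = cmb[2, ], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(data.frame(x = character(0), y = character(0), M = integer(0),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(M = rep(1L, nrow(pairs))), pairs[c("x", "y")], sum)
  agg <- agg[order(-agg$M, c_order_key(agg$x), c_order_key(agg$y)), , drop = FALSE]
  rownames(agg) <- NULL
  utils::head(agg, k_pairs)
}

#' Recommend collaborators for a query molecule by weighted PageRank
#'
#' Builds the query-specific coauthorship subnetwork, optionally prefilters
#' it to the union over related molecules of each molecule's top coauthor
#' pairs (a speed optimization; disabled by default), runs [pagerank()],
#' and reports the top authors with their scores and a per-related-molecule
#' publication breakdown formatted `"MOL(count), ..."`.
#'
#' @param net a [multilayer_network()].
#' @param query molecule name or alias.
#' @param variant `"norm"` or `"nonnorm"` collaboration weights.
#' @param top_n number of rows to return (default 120).
#' @param config a [pagerank_config()].
#' @param prefilter_k 0 (disabled) or the per-molecule number of top pairs
#'   to retain before building the subnetwork.
#' @return data.frame with columns `rank`, `author_key`, `score`,
#'   `n_distinct_molecules`, `breakdown`; possibly zero rows.
#' @export
recommend_pagerank <- function(net, query, variant = c("norm", "nonnorm"),
                               top_n = 120, config = pagerank_config(),
                               prefilter_k = 0) {
  variant <- match.arg(variant)
  g <- build_coauthor_subnetwork(net, query, variant)
  if (igraph::vcount(g) == 0)
    return(data.frame(rank = integer(0), author_key = character(0),
                      score = numeric(0), n_distinct_molecules = integer(0),
                      breakdown = character(0), stringsAsFactors = FALSE))
  if (prefilter_k > 0) {
    rel <- related_molecules(net, query)
    keep <- unique(unlist(lapply(rel, function(m) {
      tp <- per_molecule_top_pairs(net, m, prefilter_k)
      c(tp$x, tp$y)
    })))
    keep <- intersect(igraph::V(g)$name, keep)
    g <- igraph::induced_subgraph(g, keep)
    if (igraph::vcount(g) == 0)
      return(data.frame(rank = integer(0), author_key = character(0),
                        score = numeric(0), n_distinct_molecules = integer(0),
                        breakdown = character(0), stringsAsFactors = FALSE))
  }
  scores <- pagerank(g, config)
  stats <- compute_author_stats(net, query, mode = "sum")
  ord <- order(-scores, c_order_key(names(scores)))
  keys <- names(scores)[ord]
  idx <- match(keys, stats$author_key)
  res <- data.frame(
    rank = seq_along(keys), author_key = keys, score = unname(scores[ord]),
    n_distinct_molecules = ifelse(is.na(idx), 0L, stats$n_distinct_molecules[idx]),
    breakdown = vapply(idx, function(i)
      if (is.na(i)) "" else format_breakdown(stats$per_molecule[[i]]), ""),
    stringsAsFactors = FALSE)
  utils::head(res, top_n)
}
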