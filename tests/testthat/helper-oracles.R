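# Independent oracles used to check the implementation.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) samples from a population with K successes.
hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  pop <- c(rep(1, K), rep(0, N - K))
  samples <- utils::combn(N, n)
  succ <- colSums(matrix(pop[samples], nrow = n))
  mean(succ >= k)
}

# All upper-tail probabilities for one (N, K, n): enumerate once, threshold
# at every k in 0..n.
hyper_enum_all_k <- function(N, K, n) {
  if (n == 0) return(c(1))
  pop <- c(rep(1, K), rep(0, N - K))
  samples <- utils::combn(N, n)
  succ <- colSums(matrix(pop[samples], nrow = n))
  vapply(0:n, function(k) mean(succ >= k), numeric(1))
}

# PageRank by direct solution of the stationarity linear system
#   p = (1-d)/n * 1 + d * (T' p),
# where T is the row-stochastic transition matrix (dangling rows uniform).
pagerank_solve <- function(graph, damping = 0.85) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(
    graph, attr = if ("weight" %in% igraph::edge_attr_names(graph))
      "weight" else NULL, sparse = TRUE))
  s <- rowSums(A)
  T <- matrix(1 / n, n, n)
  nz <- s > 0
  T[nz, ] <- A[nz, , drop = FALSE] / s[nz]
  p <- solve(diag(n) - damping * t(T), rep((1 - damping) / n, n))
  stats::setNames(p / sum(p), igraph::V(graph)$name)
}

# Two-sided Fisher p-value by enumerating every table with the observed
# margins and summing the probabilities of those no more probable than the
# observed table.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; tot <- a + b + c + d
  lo <- max(0, c1 - (tot - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, tot - c1, r1)
  p_obs <- stats::dhyper(a, c1, tot - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random small weighted graph for PageRank property tests
random_small_graph <- function(n, p_edge = 0.45) {
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 5)
  g
}
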