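test_that("collaboration strength follows the normalized and raw definitions", {
  expect_equal(collaboration_weight(0, 5, 5, "norm"), 0)
  expect_equal(collaboration_weight(1, 1, 1, "norm"), 1)
  expect_equal(collaboration_weight(1, 3, 3, "norm"), 1 / 3, tolerance = 1e-12)
  expect_equal(collaboration_weight(7, 3, 3, "nonnorm"), 7)
  expect_error(collaboration_weight(1, 0, 3, "norm"), class = "mc_domain_error")
})

test_that("the query-specific coauthorship subnetwork has the enumerated topology", {
  g <- build_coauthor_subnetwork(TOY, "A", "norm")
  expect_setequal(igraph::V(g)$name, c("X", "Y", "Z"))
  ed <- igraph::as_data_frame(g, "edges")
  ed <- ed[order(ed$from, ed$to), ]
  expect_equal(ed$from, c("X", "Y"))
  expect_equal(ed$to, c("Y", "Z"))
  expect_equal(ed$M, c(1, 1))  # P1 mentions only the query, so X-Y has M=1
  expect_equal(ed$weight, c(1 / sqrt(9), 1 / sqrt(6)), tolerance = 1e-12)

  gn <- build_coauthor_subnetwork(TOY, "A", "nonnorm")
  expect_equal(sort(igraph::E(gn)$weight), c(1, 1))

  iso <- toy_with_isolated()
  expect_equal(igraph::vcount(build_coauthor_subnetwork(iso, "E", "norm")), 0)
})

test_that("power-iteration PageRank matches symmetry and the linear-system oracle", {
  two <- igraph::make_graph(c("a", "b"), directed = FALSE)
  igraph::E(two)$weight <- 3.7
  expect_equal(unname(pagerank(two)), c(0.5, 0.5), tolerance = 1e-9)

  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(pagerank(tri)), rep(1 / 3, 3), tolerance = 1e-9)

  g <- build_coauthor_subnetwork(TOY, "A", "norm")
  p <- pagerank(g)
  expect_equal(unname(p[c("X", "Y", "Z")]), c(0.236, 0.486, 0.278),
               tolerance = 5e-3)
  expect_equal(p, pagerank_solve(g), tolerance = 1e-8)

  expect_error(pagerank(igraph::make_empty_graph(0, directed = FALSE)),
               class = "mc_empty_input")
})

test_that("PageRank properties hold on random small graphs", {
  set.seed(42)
  for (i in 1:12) {
    g <- random_small_graph(sample(2:10, 1))
    p <- pagerank(g)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(p, pagerank_solve(g), tolerance = 1e-8)
    # weight-scale invariance
    g2 <- g
    if (igraph::ecount(g2) > 0)
      igraph::E(g2)$weight <- igraph::E(g2)$weight * 1234.5
    expect_equal(pagerank(g2), p, tolerance = 1e-9)
    # independent cross-check against igraph's implementation
    expect_equal(p, igraph::page_rank(g, damping = 0.85)$vector,
                 tolerance = 1e-6)
  }
  # isolated vertices get teleport-only mass
  g <- igraph::make_graph(c("a", "b"), directed = FALSE) +
    igraph::vertices("lone")
  igraph::E(g)$weight <- 1
  p <- pagerank(g)
  expect_equal(p, pagerank_solve(g), tolerance = 1e-8)
  expect_lt(p[["lone"]], p[["a"]])
})

test_that("per-molecule top pairs rank by coauthored publications with lexicographic ties", {
  expect_equal(per_molecule_top_pairs(TOY, "B", 5),
               data.frame(x = "Y", y = "Z", M = 1L))
  # D's only publication is single-authored
  expect_equal(nrow(per_molecule_top_pairs(TOY, "D", 5)), 0)
  # C: (X,Y) from P5 and (Y,Z) from P3 tie at M=1; lexicographic keeps (X,Y)
  top1 <- per_molecule_top_pairs(TOY, "C", 1)
  expect_equal(top1$x, "X")
  expect_equal(top1$y, "Y")
  expect_error(per_molecule_top_pairs(TOY, "C", 0), class = "mc_domain_error")
})

test_that("the PageRank recommender orders, truncates and annotates correctly", {
  rec <- recommend_pagerank(TOY, "A", "norm", top_n = 3)
  expect_equal(rec$author_key, c("Y", "Z", "X"))
  expect_equal(rec$score, c(0.486, 0.278, 0.236), tolerance = 5e-3)
  expect_equal(rec$breakdown[1], "B(1), C(2)")

  expect_equal(nrow(recommend_pagerank(TOY, "A", "norm", top_n = 1)), 1)
  expect_equal(recommend_pagerank(TOY, "A", "norm", top_n = 1)$author_key, "Y")

  # disabled prefilter is a no-op; a generous prefilter keeps everyone
  expect_equal(recommend_pagerank(TOY, "A", "norm", 10, prefilter_k = 0),
               recommend_pagerank(TOY, "A", "norm", 10))
  expect_equal(recommend_pagerank(TOY, "A", "norm", 10, prefilter_k = 100),
               recommend_pagerank(TOY, "A", "norm", 10))

  iso <- toy_with_isolated()
  expect_equal(nrow(recommend_pagerank(iso, "E", "norm")), 0)
})

test_that("normalization favors authors with fewer total publications (two-pair construction)", {
  # two coauthor pairs with equal M; the a-side has small N, the b-side
  # large N; a shared collaborator c bridges both with equal M
  build <- function(variant) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(c("a1", "a2", "b1", "b2", "c"))
    N <- c(a1 = 3, a2 = 3, b1 = 9, b2 = 9, c = 2)
    add <- function(g, x, y, M) igraph::add_edges(
      g, c(x, y), weight = collaboration_weight(M, N[[x]], N[[y]], variant))
    g <- add(g, "a1", "a2", 2)
    g <- add(g, "b1", "b2", 2)
    g <- add(g, "a1", "c", 1)
    add(g, "b1", "c", 1)
  }
  p_non <- pagerank(build("nonnorm"))
  expect_equal(p_non[["a1"]], p_non[["b1"]], tolerance = 1e-9)
  expect_equal(p_non[["a2"]], p_non[["b2"]], tolerance = 1e-9)
  p_norm <- pagerank(build("norm"))
  expect_gt(p_norm[["a1"]], p_norm[["b1"]])
  expect_gt(p_norm[["a2"]], p_norm[["b2"]])
})
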