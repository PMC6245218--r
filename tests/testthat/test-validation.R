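test_that("interest profiles count token occurrences with multiplicity", {
  px <- author_top_molecules(TOY, "X")
  expect_equal(px$molecule, c("A", "B", "C"))
  expect_equal(px$freq, c(1L, 1L, 1L))

  py <- author_top_molecules(TOY, "Y", m = 1)
  expect_equal(py, data.frame(molecule = "C", freq = 2L))

  # author with no molecule mentions
  net <- multilayer_network(
    "APP",
    publications = data.frame(pub_id = "P1", title = "nothing relevant",
                              abstract = ""),
    authorship = data.frame(pub_id = "P1", author_key = "Solo"))
  expect_equal(nrow(author_top_molecules(net, "Solo")), 0)
  expect_error(author_top_molecules(TOY, "nobody"), class = "mc_unknown_author")

  # multiplicity: repeated tokens in one abstract all count
  net2 <- multilayer_network(
    c("APP", "GRN"),
    publications = data.frame(pub_id = "P1", title = "APP",
                              abstract = "APP APP and GRN"),
    authorship = data.frame(pub_id = "P1", author_key = "Solo"),
    mentions = data.frame(pub_id = "P1", molecule = c("APP", "GRN")))
  expect_equal(author_top_molecules(net2, "Solo")$freq, c(3L, 1L))
})

test_that("top coauthors rank by shared publications over the whole corpus", {
  expect_equal(top_coauthors(TOY, "Y"),
               data.frame(coauthor = c("X", "Z"), n_shared = c(2L, 1L)))
  expect_equal(top_coauthors(TOY, "Y", c = 1)$coauthor, "X")
  solo <- multilayer_network(
    "APP",
    publications = data.frame(pub_id = "P1", title = "APP", abstract = ""),
    authorship = data.frame(pub_id = "P1", author_key = "Solo"),
    mentions = data.frame(pub_id = "P1", molecule = "APP"))
  expect_equal(nrow(top_coauthors(solo, "Solo")), 0)
})

test_that("coauthor molecule pairs are the cross product after dropping shared interests", {
  p <- coauthor_pair_molecules(c("A", "B"), c("C", "D"))
  expect_equal(nrow(p), 4)
  expect_setequal(paste(p$mol_a, p$mol_b),
                  c("A C", "A D", "B C", "B D"))
  expect_equal(nrow(coauthor_pair_molecules(c("A", "B"), c("A", "B"))), 0)
  p2 <- coauthor_pair_molecules(c("A", "B", "C"), c("C", "D"))
  expect_setequal(paste(p2$mol_a, p2$mol_b), c("A D", "B D"))
})

test_that("the random-pair null draws all ordered pairs of the sampled molecules", {
  net <- generate_network(synth_config(n_molecules = 30, n_publications = 0,
                                       n_authors = 0, seed = 5))
  pr <- sample_random_molecule_pairs(net, n_mol = 7, seed = 9)
  expect_equal(nrow(pr), 49)
  expect_equal(sum(pr$mol_a == pr$mol_b), 7)  # self-pairs included
  expect_identical(pr, sample_random_molecule_pairs(net, n_mol = 7, seed = 9))
  one <- sample_random_molecule_pairs(net, n_mol = 1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$mol_a, one$mol_b)
  expect_error(sample_random_molecule_pairs(net, n_mol = 31, seed = 1),
               class = "mc_insufficient_data")
})

test_that("the validation table matches an exhaustive hand count on the toy network", {
  # All 3 authors qualify at min_pubs = 1; profiles are X:{A,B,C},
  # Y:{C,A,B}, Z:{B,C,D}; relations X->Y, Y->X (identical profiles, 0
  # pairs), Y->Z and Z->Y each contribute the single non-neighbor pair
  # (A,D)/(D,A). Random side: all 16 ordered pairs of the 4 molecules,
  # 8 of which are neighbor pairs.
  tab <- build_validation_table(TOY, n_authors = 3, min_pubs = 1,
                                c = 5, m = 5, n_mol = 4, seed = 123)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(0, 2, 8, 8))
  # reproducibility
  tab2 <- build_validation_table(TOY, n_authors = 3, min_pubs = 1,
                                 c = 5, m = 5, n_mol = 4, seed = 123)
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d),
               c(tab$a, tab$b, tab$c, tab$d))
  expect_error(build_validation_table(TOY, n_authors = 250, seed = 1),
               class = "mc_insufficient_data")

  # no molecular edges anywhere -> no neighbor pairs on either side
  bare <- multilayer_network(
    LETTERS[1:4],
    publications = TOY$publications, authorship = TOY$authorship,
    mentions = TOY$mentions)
  tab0 <- build_validation_table(bare, n_authors = 3, min_pubs = 1,
                                 c = 5, m = 5, n_mol = 4, seed = 1)
  expect_equal(tab0$a, 0)
  expect_equal(tab0$c, 0)
})

test_that("odds ratio follows the cross-product formula with inversion symmetry", {
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1)), 1)
  expect_equal(odds_ratio(contingency_table(2, 1, 1, 2)), 4)
  expect_error(odds_ratio(contingency_table(1, 0, 1, 1)),
               class = "mc_domain_error")
  set.seed(7)
  for (i in 1:10) {
    cells <- sample(1:50, 4, replace = TRUE)
    t1 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_table(cells[2], cells[1], cells[4], cells[3])
    expect_equal(odds_ratio(t1) * odds_ratio(t2), 1, tolerance = 1e-12)
  }
})

test_that("the exact association test agrees with full margin enumeration", {
  expect_equal(association_test(contingency_table(5, 5, 5, 5)), 1)
  expect_equal(association_test(contingency_table(3, 1, 1, 3)), 34 / 70,
               tolerance = 1e-10)
  expect_error(association_test(contingency_table(0, 0, 3, 3)),
               class = "mc_domain_error")
  set.seed(11)
  for (i in 1:25) {
    repeat {
      cells <- stats::rmultinom(1, sample(8:40, 1), rep(1 / 4, 4))[, 1]
      m <- matrix(cells, 2, 2, byrow = TRUE)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    expect_equal(association_test(tab),
                 fisher_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("rank comparison pairs positions and computes Pearson correlation", {
  r <- c("u", "v", "w")
  expect_equal(compare_rankings(r, r)$correlation, 1)
  expect_equal(compare_rankings(r, rev(r))$correlation, -1)
  expect_equal(compare_rankings(c("a", "b", "c"), c("b", "a", "c"))$correlation,
               0.5, tolerance = 1e-12)
  # absent authors get position |rank_b| + 1
  cmp <- compare_rankings(c("a", "b", "zz"), c("b", "a"), top_k = 3)
  expect_equal(cmp$pairs$pos_b, c(2L, 1L, 3L))
  # top_k truncation
  expect_equal(nrow(compare_rankings(letters, letters, top_k = 5)$pairs), 5)
  expect_error(compare_rankings(character(0), r), class = "mc_empty_input")
})
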