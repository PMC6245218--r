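mol_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
pub_file <- function(lines) {
  f <- tempfile(fileext = ".jsonl")
  writeLines(lines, f)
  f
}

test_that("molecular edge-list parsing collapses duplicates and reports bad rows", {
  net <- load_molecular_layer(mol_file(c("A\tB\t1.0", "B\tA\t2.0")))
  expect_equal(nrow(net$mol_edges), 1)
  expect_equal(net$mol_edges$weight, 2.0)

  empty <- load_molecular_layer(mol_file(character(0)))
  expect_equal(length(empty$molecules), 0)
  expect_equal(nrow(empty$mol_edges), 0)

  cmt <- load_molecular_layer(mol_file(c("# header", "A\tB\t0.5")))
  expect_equal(cmt$mol_edges$weight, 0.5)

  err <- expect_error(load_molecular_layer(mol_file(c("A\tB\t1", "A\tB"))),
                      class = "mc_parse_error")
  expect_match(conditionMessage(err), "line 2")
  expect_error(load_molecular_layer(mol_file("A\tB\tnope")),
               class = "mc_parse_error")
  expect_error(load_molecular_layer(mol_file("A\tB\t0")),
               class = "mc_parse_error")
})

test_that("publication records load in order with id uniqueness enforced", {
  one <- load_publications(pub_file(
    '{"pub_id":"P1","title":"t","abstract":"x","keywords":["k"],"authors":["Jane Doe"],"year":2020}'))
  expect_length(one, 1)
  expect_equal(one[[1]]$authors[[1]]$name, "Jane Doe")
  expect_equal(one[[1]]$year, 2020L)

  expect_length(load_publications(pub_file(character(0))), 0)

  expect_error(load_publications(pub_file(c(
    '{"pub_id":"P1","title":"a","authors":[]}',
    '{"pub_id":"P1","title":"b","authors":[]}'))),
    class = "mc_duplicate_id")
  err <- expect_error(load_publications(pub_file(c(
    '{"pub_id":"P1","authors":[]}', "{not json"))),
    class = "mc_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("mention matching is whole-token, case-insensitive and set-valued", {
  mols <- multilayer_network(c("TREM2", "APP", "GRN"),
                             aliases = data.frame(name = "TREM2",
                                                  alias = "TREM-2"))
  rec <- function(title = "", abstract = "", keywords = character(0))
    list(list(pub_id = "P1", title = title, abstract = abstract,
              keywords = keywords, authors = list(), year = NA_integer_))

  hit <- link_mentions(rec(title = "Role of TREM2 in microglia"), mols)
  expect_equal(hit$molecule, "TREM2")

  # word boundaries: no substring matches
  expect_equal(nrow(link_mentions(rec(abstract = "apples and APPLES"), mols)), 0)
  expect_equal(nrow(link_mentions(rec(abstract = "APP-knockout mice"), mols)), 0)

  # hyphenated alias is one token
  expect_equal(link_mentions(rec(abstract = "trem-2 signalling"), mols)$molecule,
               "TREM2")

  # duplicate mentions across fields still give one edge
  dup <- link_mentions(rec(abstract = "GRN and GRN again", keywords = "grn"),
                       mols)
  expect_equal(nrow(dup), 1)

  # keyword match is exact, not tokenized
  expect_equal(link_mentions(rec(keywords = "APP pathway"), mols)$molecule,
               character(0))
  expect_equal(link_mentions(rec(keywords = " app "), mols)$molecule, "APP")
})

test_that("link_mentions is idempotent and order-independent", {
  recs <- list(
    list(pub_id = "P1", title = "GRN story", abstract = "", keywords = character(0),
         authors = list(), year = NA_integer_),
    list(pub_id = "P2", title = "APP and GRN", abstract = "", keywords = character(0),
         authors = list(), year = NA_integer_))
  mols <- multilayer_network(c("APP", "GRN"))
  a <- link_mentions(recs, mols)
  b <- link_mentions(rev(recs), mols)
  expect_equal(a[order(a$pub_id, a$molecule), ], b[order(b$pub_id, b$molecule), ],
               ignore_attr = TRUE)
  expect_equal(link_mentions(recs, mols), a)
})

test_that("canonical dumps round-trip into an identical network", {
  for (net in list(toy_fixture(),
                   generate_network(synth_config(n_molecules = 40,
                                                 n_authors = 15,
                                                 n_publications = 30,
                                                 seed = 11)))) {
    dir <- tempfile("dump")
    write_network(net, dir)
    back <- read_network(dir)
    expect_equal(back$molecules, net$molecules)
    expect_equal(back$mol_edges, net$mol_edges)
    expect_equal(back$mentions[order(back$mentions$pub_id, back$mentions$molecule), ],
                 net$mentions[order(net$mentions$pub_id, net$mentions$molecule), ],
                 ignore_attr = TRUE)
    expect_equal(back$authorship, net$authorship)
    expect_equal(back$publications$pub_id, net$publications$pub_id)
    expect_equal(back$publications$title, net$publications$title)
    expect_equal(sort(back$alias_tab$alias), sort(net$alias_tab$alias))
  }
})

test_that("GraphML export writes a loadable graph", {
  f <- tempfile(fileext = ".graphml")
  export_graphml(TOY, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 12)
  expect_equal(igraph::ecount(g), 18)
})
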