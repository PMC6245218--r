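#' The TOY1 worked fixture
#'
#' A four-molecule, five-publication, three-author network small enough to
#' enumerate by hand, used throughout the documentation and tests:
#' molecules A, B, C, D with molecular edges A-B (1), A-C (2), B-C (1),
#' C-D (1); publications P1 (mentions A; authors X, Y), P2 (B; X),
#' P3 (B, C; Y, Z), P4 (D; Z), P5 (C; X, Y). Mention edges are derived by
#' the real keyword matcher from generated titles, not injected directly.
#'
#' @return a [multilayer_network()].
#' @export
toy_fixture <- function() {
  base <- multilayer_network(
    molecules = c("A", "B", "C", "D"),
    mol_edges = data.frame(from = c("A", "A", "B", "C"),
                           to = c("B", "C", "C", "D"),
                           weight = c(1, 2, 1, 1)))
  titles <- c(P1 = "Profiling of A in cortical tissue",
              P2 = "Expression changes of B under stress",
              P3 = "Crosstalk between B and C",
              P4 = "Regulatory roles of D",
              P5 = "Signaling downstream of C")
  author_sets <- list(P1 = c("X", "Y"), P2 = "X", P3 = c("Y", "Z"),
                      P4 = "Z", P5 = c("X", "Y"))
  records <- lapply(names(titles), function(id) list(
    pub_id = id, title = unname(titles[id]), abstract = "",
    keywords = character(0),
    authors = lapply(author_sets[[id]], function(a)
      list(name = a, affiliation = NA_character_)),
    year = NA_integer_))
  network_from_records(base, records)
}

#' Configuration for the synthetic network generator
#'
#' @param n_molecules number of molecules in the interaction layer.
#' @param molecular_graph_model `"preferential-attachment"` (default; scale
#'   free degree distribution, as molecular interaction networks are) or
#'   `"random-uniform"` (Erdos-Renyi).
#' @param density for `"random-uniform"`, the edge probability; for
#'   `"preferential-attachment"`, the number of edges each new node brings
#'   (rounded, >= 1).
#' @param n_authors size of the author pool.
#' @param n_publications number of publications to generate.
#' @param author_productivity Pareto tail exponent of the author-productivity
#'   weights; smaller means heavier tail. Default 2.5, the classic range
#'   observed for scientific productivity.
#' @param mentions_per_publication integer range (length-2 vector) of
#'   molecules mentioned per publication.
#' @param interest_coupling in \[0, 1\]: probability that a publication's
#'   molecules are drawn from the lead author's home-molecule neighborhood
#'   and its coauthors from authors with adjacent home molecules, rather
#'   than uniformly. 0 decouples interests from the molecular graph
#'   entirely; near 1 plants the adjacency structure the validation
#'   analysis is designed to detect.
#' @param planted_expert optional list with elements `coverage` (fraction of
#'   the query's neighbors the planted author must publish on, in (0, 1\])
#'   and optionally `query` (molecule name; default the highest-degree
#'   molecule) and `author` (display name of the planted author).
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output files.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 300,
                         molecular_graph_model = c("preferential-attachment",
                                                   "random-uniform"),
                         density = 2,
                         n_authors = 120,
                         n_publications = 400,
                         author_productivity = 2.5,
                         mentions_per_publication = c(1, 3),
                         interest_coupling = 0,
                         planted_expert = NULL,
                         seed = 1) {
  molecular_graph_model <- match.arg(molecular_graph_model)
  stopifnot(n_molecules >= 0, n_authors >= 0, n_publications >= 0,
            author_productivity > 1,
            length(mentions_per_publication) == 2,
            interest_coupling >= 0, interest_coupling <= 1)
  if (!is.null(planted_expert)) {
    if (is.null(planted_expert$coverage) || planted_expert$coverage <= 0 ||
          planted_expert$coverage > 1)
      abort_domain("planted_expert$coverage must be in (0, 1]")
  }
  structure(list(n_molecules = n_molecules,
                 molecular_graph_model = molecular_graph_model,
                 density = density, n_authors = n_authors,
                 n_publications = n_publications,
                 author_productivity = author_productivity,
                 mentions_per_publication = mentions_per_publication,
                 interest_coupling = interest_coupling,
                 planted_expert = planted_expert, seed = seed),
            class = "synth_config")
}

# one generation attempt; returns list(records, base, planted_author)
generate_attempt <- function(config, seed) {
  set.seed(seed)
  n_mol <- config$n_molecules
  mols <- sprintf("M%04d", seq_len(n_mol))
  g <- if (config$molecular_graph_model == "preferential-attachment")
    igraph::sample_pa(n_mol, m = max(1, round(config$density)),
                      directed = FALSE)
  else igraph::sample_gnp(n_mol, config$density)
  # names are assigned to graph nodes in shuffled order so that label order
  # carries no information about topology (preferential attachment grows
  # high-degree nodes first, and downstream tie-breaks are lexicographic)
  mols <- sample(mols)
  el <- igraph::as_edgelist(g)
  ed <- if (nrow(el) > 0)
    data.frame(from = mols[el[, 1]], to = mols[el[, 2]],
               weight = round(stats::runif(nrow(el), 0.5, 2), 3),
               stringsAsFactors = FALSE) else NULL
  base <- multilayer_network(molecules = mols, mol_edges = ed)
  adj <- lapply(seq_len(n_mol), function(i)
    mols[as.integer(igraph::neighbors(g, i))])
  names(adj) <- mols

  records <- list()
  authors <- character(0)
  if (config$n_authors > 0 && config$n_publications > 0) {
    authors <- sprintf("Author %03d", seq_len(config$n_authors))
    # Pareto(1, alpha-1) weights give heavy-tailed publication counts
    alpha <- config$author_productivity
    wts <- (1 - stats::runif(config$n_authors))^(-1 / (alpha - 1))
    home <- stats::setNames(sample(mols, config$n_authors, replace = TRUE),
                            authors)
    rng <- config$mentions_per_publication
    for (p in seq_len(config$n_publications)) {
      lead <- sample(authors, 1, prob = wts)
      coupled <- stats::runif(1) < config$interest_coupling
      hood <- unique(c(home[[lead]], adj[[home[[lead]]]]))
      n_ment <- sample(seq(rng[1], rng[2]), 1)
      pool <- if (coupled) hood else mols
      ment <- sample(pool, min(n_ment, length(pool)))
      n_co <- sample(0:3, 1, prob = c(0.2, 0.4, 0.3, 0.1))
      co <- character(0)
      if (n_co > 0) {
        cand <- setdiff(authors, lead)
        if (coupled) {
          near <- cand[home[cand] %in% hood]
          if (length(near) > 0) cand <- near
        }
        co <- sample(cand, min(n_co, length(cand)),
                     prob = wts[match(cand, authors)])
      }
      records[[p]] <- list(
        pub_id = sprintf("PUB%05d", p),
        title = paste("Characterization of", paste(ment, collapse = " and ")),
        abstract = paste("We investigate", paste(ment, collapse = " together with "),
                         "in a controlled model system."),
        keywords = character(0),
        authors = lapply(c(lead, co), function(a)
          list(name = a, affiliation = NA_character_)),
        year = sample(2000:2024, 1))
    }
  }

  planted_author <- NULL
  if (!is.null(config$planted_expert)) {
    pe <- config$planted_expert
    query <- if (!is.null(pe$query)) pe$query else
      mols[which.max(igraph::degree(g))]
    nb <- adj[[query]]
    need <- ceiling(pe$coverage * length(nb))
    if (need < 1)
      mc_abort(sprintf("infeasible planted expert: query '%s' has no neighbors",
                       query), "mc_infeasible_config")
    planted_author <- if (!is.null(pe$author)) pe$author else "Planted Expert"
    cover <- sample(nb, need)
    for (i in seq_along(cover)) {
      records[[length(records) + 1]] <- list(
        pub_id = sprintf("PUBX%04d", i),
        title = paste("Focused analysis of", cover[i]),
        abstract = paste("Dedicated study of", cover[i], "function."),
        keywords = character(0),
        authors = list(list(name = planted_author, affiliation = NA_character_)),
        year = 2024L)
    }
    attr(planted_author, "query") <- query
  }
  list(records = records, base = base, planted_author = planted_author)
}

#' Generate a synthetic multilayer network and its input files
#'
#' Realizes a [synth_config()]: draws the molecular graph, assigns each
#' author a home molecule and a heavy-tailed productivity weight, and emits
#' publication records whose titles/abstracts embed molecule names — the
#' mention cross-layer is then produced by the same keyword matcher used for
#' real inputs, never injected directly. With a planted expert, extra
#' sole-authored publications guarantee the designated author covers
#' `ceiling(coverage * deg(query))` distinct neighbors of the query and has
#' strictly more distinct related molecules than anyone else (verified
#' post-hoc; generation retries with an incremented sub-seed on the rare
#' tie, retry count recorded in the manifest).
#'
#' The exact ingestion inputs are written to `dir`: `molecular.tsv`,
#' `aliases.tsv`, `publications.jsonl` and `manifest.json` (config, seed,
#' retries). The returned network is loaded back from those files, so
#' generated files round-trip by construction.
#'
#' @param config a [synth_config()].
#' @param dir output directory; defaults to a fresh temporary directory.
#' @return a [multilayer_network()] with attributes `dir`, `manifest` and
#'   (when planted) `planted_author` / `planted_query`.
#' @export
generate_network <- function(config, dir = tempfile("synthnet")) {
  max_attempts <- 20
  attempt <- 0
  repeat {
    res <- generate_attempt(config, config$seed + attempt)
    ok <- TRUE
    if (!is.null(res$planted_author)) {
      net0 <- network_from_records(res$base, res$records)
      query <- attr(res$planted_author, "query")
      st <- compute_author_stats(net0, query)
      pl <- st$n_distinct_molecules[st$author_key == res$planted_author]
      others <- st$n_distinct_molecules[st$author_key != res$planted_author]
      ok <- length(pl) == 1 &&
        (length(others) == 0 || pl > max(others))
    }
    if (ok || attempt >= max_attempts) break
    attempt <- attempt + 1
  }
  if (!ok) mc_abort("planted-expert guarantee not met after retries",
                    "mc_infeasible_config")

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed <- res$base$mol_edges
  writeLines(c("# molecular interaction layer: from<TAB>to<TAB>weight",
               sprintf("%s\t%s\t%s", ed$from, ed$to, format(ed$weight))),
             file.path(dir, "molecular.tsv"))
  al <- res$base$alias_tab
  utils::write.table(al, file.path(dir, "aliases.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pub_lines <- vapply(res$records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, na = "null")), "")
  writeLines(pub_lines, file.path(dir, "publications.jsonl"), useBytes = TRUE)
  manifest <- list(config = unclass(config), retries = attempt)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  net <- load_network(file.path(dir, "molecular.tsv"),
                      file.path(dir, "publications.jsonl"),
                      file.path(dir, "aliases.tsv"))
  attr(net, "dir") <- dir
  attr(net, "manifest") <- manifest
  if (!is.null(res$planted_author)) {
    attr(net, "planted_author") <- as.character(res$planted_author)
    attr(net, "planted_query") <- attr(res$planted_author, "query")
  }
  net
}
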