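# Shared fixtures, built in code at test time.

TOY <- toy_fixture()

# TOY1 plus an isolated molecule E (no molecular edges, no mentions)
toy_with_isolated <- function() {
  net <- toy_fixture()
  multilayer_network(
    molecules = c(net$molecules, "E"),
    mol_edges = net$mol_edges,
    publications = net$publications,
    authorship = net$authorship,
    mentions = net$mentions)
}

# write TOY1 ingestion inputs (molecular TSV + publications JSONL) to dir
write_toy_inputs <- function(dir = tempfile("toyin")) {
  dir.create(dir, showWarnings = FALSE)
  net <- toy_fixture()
  dump <- write_network(net, file.path(dir, "dump"))
  list(mol = file.path(dump, "molecule_edges.tsv"),
       pubs = file.path(dump, "publications.jsonl"),
       aliases = file.path(dump, "aliases.tsv"))
}

# network realizing given per-molecule publication counts for named authors:
# counts is a named list author -> named integer vector molecule -> count;
# every listed molecule becomes a neighbor of `query`.
net_from_counts <- function(query, counts) {
  mols <- sort(unique(c(query, unlist(lapply(counts, names)))))
  ed <- data.frame(from = query, to = setdiff(mols, query), weight = 1)
  recs <- list(); i <- 0
  for (author in names(counts)) {
    per <- counts[[author]]
    for (mol in names(per)) for (j in seq_len(per[[mol]])) {
      i <- i + 1
      recs[[i]] <- list(pub_id = sprintf("P%04d", i),
                        title = paste("Study of", mol),
                        abstract = "", keywords = character(0),
                        authors = list(list(name = author,
                                            affiliation = NA_character_)),
                        year = NA_integer_)
    }
  }
  base <- multilayer_network(molecules = mols, mol_edges = ed)
  molcollab:::network_from_records(base, recs)
}
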