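#' Load the molecular interaction layer from a tab-separated edge list
#'
#' The edge file has three tab-separated columns: source name, target name,
#' positive weight. Lines starting with `#` and blank lines are skipped.
#' Duplicate undirected edges collapse keeping the maximum weight. The
#' optional alias table is a two-column TSV (canonical name, alias); an
#' alias shared by two molecules is a load-time error. Canonical names that
#' appear only in the alias table become isolated molecule nodes, which is
#' also how isolated molecules survive a round trip through
#' [write_network()].
#'
#' @param path path to the molecular edge-list TSV.
#' @param alias_path optional path to the alias TSV.
#' @return a [multilayer_network()] containing only the molecular layer.
#' @export
load_molecular_layer <- function(path, alias_path = NULL) {
  if (!file.exists(path)) abort_domain(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3)
      abort_parse(path, ln, sprintf("expected 3 tab-separated fields, found %d",
                                    length(fields)))
    w <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(w) || w <= 0)
      abort_parse(path, ln, sprintf("weight '%s' is not a positive number", fields[3]))
    rows[[i]] <- data.frame(from = trimws(fields[1]), to = trimws(fields[2]),
                            weight = w, stringsAsFactors = FALSE)
  }
  ed <- if (length(rows) > 0) do.call(rbind, rows) else NULL

  aliases <- NULL
  if (!is.null(alias_path)) {
    al <- utils::read.delim(alias_path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE,
                            col.names = c("name", "alias"))
    aliases <- al
  }
  mols <- sort(unique(c(ed$from, ed$to, aliases$name)))
  multilayer_network(molecules = mols, mol_edges = ed, aliases = aliases)
}

#' Load publication records from a line-delimited JSON file
#'
#' One self-contained JSON object per line with fields `pub_id` (required),
#' `title`, `abstract`, `keywords` (array of strings), `authors` (array of
#' strings or of objects `{name, affiliation}`), and optional `year`.
#'
#' @param path path to the JSONL file.
#' @return a list of publication records (each a named list) in file order.
#' @export
load_publications <- function(path) {
  if (!file.exists(path)) abort_domain(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- vector("list", 0)
  seen <- character(0)
  for (ln in seq_along(lines)) {
    if (!nzchar(trimws(lines[ln]))) next
    rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
                    error = function(e) abort_parse(path, ln, conditionMessage(e)))
    if (is.null(rec$pub_id) || !nzchar(as.character(rec$pub_id)))
      abort_parse(path, ln, "missing pub_id")
    id <- as.character(rec$pub_id)
    if (id %in% seen)
      mc_abort(sprintf("duplicate pub_id '%s' at line %d of '%s'", id, ln, path),
               "mc_duplicate_id")
    seen <- c(seen, id)
    authors <- lapply(rec$authors, function(a) {
      if (is.list(a)) list(name = as.character(a$name),
                           affiliation = if (is.null(a$affiliation))
                             NA_character_ else as.character(a$affiliation))
      else list(name = as.character(a), affiliation = NA_character_)
    })
    records[[length(records) + 1]] <- list(
      pub_id = id,
      title = if (is.null(rec$title)) "" else as.character(rec$title),
      abstract = if (is.null(rec$abstract)) "" else as.character(rec$abstract),
      keywords = vapply(rec$keywords, as.character, ""),
      authors = authors,
      year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year))
  }
  records
}

# --- tokenization ----------------------------------------------------------
# A token is a maximal run of alphanumeric characters possibly joined by
# internal hyphens, so "TREM-2" is a single token and "APP" does not match
# inside "APPLE" or "APP-knockout". Lowercased for case-insensitive matching.
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[[:alnum:]]+(-[[:alnum:]]+)*", text)
  tolower(regmatches(text, m)[[1]])
}

# Occurrence counts of each canonical molecule in one record's
# title + abstract + keyword list. Token occurrences are counted with
# multiplicity; each keyword entry equal to an alias counts once.
count_record_mentions <- function(title, abstract, keywords, alias_tab) {
  toks <- c(tokenize(title), tokenize(abstract))
  al <- tolower(alias_tab$alias)
  counts <- stats::setNames(numeric(0), character(0))
  bump <- function(mol, k) {
    counts[mol] <<- (if (mol %in% names(counts)) counts[[mol]] else 0) + k
  }
  single <- !grepl("[[:space:]]", alias_tab$alias)
  if (length(toks) > 0 && any(single)) {
    idx <- match(toks, al[single])
    hit <- idx[!is.na(idx)]
    if (length(hit) > 0) {
      tb <- table(alias_tab$name[single][hit])
      for (mol in names(tb)) bump(mol, as.integer(tb[[mol]]))
    }
  }
  # multi-word aliases: match their token sequence as a sliding window
  for (j in which(!single)) {
    at <- tokenize(alias_tab$alias[j])
    k <- length(at)
    if (k == 0 || length(toks) < k) next
    n_hit <- sum(vapply(seq_len(length(toks) - k + 1), function(s)
      all(toks[s:(s + k - 1)] == at), logical(1)))
    if (n_hit > 0) bump(alias_tab$name[j], n_hit)
  }
  kw <- tolower(trimws(as.character(keywords)))
  if (length(kw) > 0) {
    idx <- match(kw, al)
    hit <- idx[!is.na(idx)]
    for (mol in alias_tab$name[hit]) bump(mol, 1)
  }
  counts
}

#' Derive publication-molecule mention edges by keyword matching
#'
#' A mention edge (publication, molecule) is created iff any alias of the
#' molecule occurs as a whole token (case-insensitive; internal hyphens are
#' part of a token) in the title or abstract, or equals one of the record's
#' keywords (case-insensitive exact match). The result is a set: multiple
#' occurrences still yield one edge.
#'
#' @param records list of publication records as from [load_publications()].
#' @param net a network whose molecular layer supplies names and aliases.
#' @return data.frame with columns `pub_id`, `molecule` (canonical names).
#' @export
link_mentions <- function(records, net) {
  out <- lapply(records, function(r) {
    counts <- count_record_mentions(r$title, r$abstract, r$keywords, net$alias_tab)
    if (length(counts) == 0) return(NULL)
    data.frame(pub_id = r$pub_id, molecule = names(counts),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_mentions() else unique(res[order(res$pub_id, res$molecule), ,
                                                   drop = FALSE])
}

#' Assemble a full multilayer network from layer inputs
#'
#' Convenience wrapper: loads the molecular layer, the publication records,
#' links mentions by keyword matching, and returns the complete network.
#'
#' @param mol_path molecular edge-list TSV.
#' @param pub_path line-delimited publication records.
#' @param alias_path optional alias TSV.
#' @return a [multilayer_network()].
#' @export
load_network <- function(mol_path, pub_path, alias_path = NULL) {
  base <- load_molecular_layer(mol_path, alias_path)
  records <- load_publications(pub_path)
  network_from_records(base, records)
}

# build the publication/author layers of `base` from parsed records
network_from_records <- function(base, records) {
  if (length(records) == 0) return(base)
  pubs <- data.frame(
    pub_id = vapply(records, `[[`, "", "pub_id"),
    title = vapply(records, `[[`, "", "title"),
    abstract = vapply(records, `[[`, "", "abstract"),
    year = vapply(records, `[[`, NA_integer_, "year"),
    stringsAsFactors = FALSE)
  pubs$keywords <- lapply(records, `[[`, "keywords")
  auth <- do.call(rbind, lapply(records, function(r) {
    if (length(r$authors) == 0) return(NULL)
    data.frame(pub_id = r$pub_id,
               author_key = vapply(r$authors, `[[`, "", "name"),
               affiliation = vapply(r$authors, `[[`, NA_character_, "affiliation"),
               stringsAsFactors = FALSE)
  }))
  mentions <- link_mentions(records, base)
  multilayer_network(
    molecules = base$molecules,
    mol_edges = base$mol_edges,
    publications = pubs,
    authorship = auth,
    mentions = mentions,
    aliases = base$alias_tab[base$alias_tab$name != base$alias_tab$alias, ,
                             drop = FALSE])
}

#' Write the canonical plain-text dump of a network
#'
#' Writes five files into `dir`: `molecule_edges.tsv` (from, to, weight),
#' `aliases.tsv` (canonical name, alias; self-aliases included so isolated
#' molecules survive), `mention_edges.tsv`, `authorship_edges.tsv` (pub_id,
#' author_key, position, affiliation) and `publications.jsonl`. The dump
#' round-trips through [read_network()] into an identical network.
#'
#' @param net a [multilayer_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f, comment = NULL) {
    con <- file.path(dir, f)
    if (!is.null(comment)) {
      # comment header keeps the file directly loadable by the ingest layer
      writeLines(comment, con)
      suppressWarnings(utils::write.table(
        d, con, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE, fileEncoding = "UTF-8", append = TRUE))
    } else {
      utils::write.table(d, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE,
                         fileEncoding = "UTF-8")
    }
  }
  tsv(net$mol_edges, "molecule_edges.tsv", "# from\tto\tweight")
  tsv(net$alias_tab, "aliases.tsv", "# name\talias")
  tsv(net$mentions, "mention_edges.tsv")
  tsv(net$authorship, "authorship_edges.tsv")
  pub_lines <- vapply(seq_len(nrow(net$publications)), function(i) {
    p <- net$publications[i, ]
    au <- net$authorship[net$authorship$pub_id == p$pub_id, , drop = FALSE]
    au <- au[order(au$position), , drop = FALSE]
    jsonlite::toJSON(list(
      pub_id = p$pub_id, title = p$title, abstract = p$abstract,
      keywords = p$keywords[[1]],
      authors = lapply(seq_len(nrow(au)), function(j)
        if (is.na(au$affiliation[j])) list(name = au$author_key[j])
        else list(name = au$author_key[j], affiliation = au$affiliation[j])),
      year = p$year[[1]]), auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(pub_lines, file.path(dir, "publications.jsonl"), useBytes = TRUE)
  invisible(dir)
}

#' Read a network back from its canonical dump
#'
#' @param dir directory written by [write_network()].
#' @return a [multilayer_network()] identical to the one dumped.
#' @export
read_network <- function(dir) {
  tsv <- function(f) utils::read.delim(file.path(dir, f),
                                       stringsAsFactors = FALSE,
                                       colClasses = "character")
  bare <- function(f, cols) {
    d <- tryCatch(
      utils::read.delim(file.path(dir, f), header = FALSE,
                        comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character", col.names = cols),
      error = function(e) NULL)  # only-comments file: no data rows
    if (is.null(d))
      d <- stats::setNames(as.data.frame(rep(list(character(0)), length(cols)),
                                         stringsAsFactors = FALSE), cols)
    d
  }
  ed <- bare("molecule_edges.tsv", c("from", "to", "weight"))
  if (nrow(ed) > 0) ed$weight <- as.numeric(ed$weight)
  al <- bare("aliases.tsv", c("name", "alias"))
  records <- load_publications(file.path(dir, "publications.jsonl"))
  mentions <- tsv("mention_edges.tsv")
  mols <- sort(unique(c(ed$from, ed$to, al$name)))
  pubs <- NULL; auth <- NULL
  if (length(records) > 0) {
    pubs <- data.frame(
      pub_id = vapply(records, `[[`, "", "pub_id"),
      title = vapply(records, `[[`, "", "title"),
      abstract = vapply(records, `[[`, "", "abstract"),
      year = vapply(records, `[[`, NA_integer_, "year"),
      stringsAsFactors = FALSE)
    pubs$keywords <- lapply(records, `[[`, "keywords")
    auth <- do.call(rbind, lapply(records, function(r) {
      if (length(r$authors) == 0) return(NULL)
      data.frame(pub_id = r$pub_id,
                 author_key = vapply(r$authors, `[[`, "", "name"),
                 affiliation = vapply(r$authors, `[[`, NA_character_, "affiliation"),
                 stringsAsFactors = FALSE)
    }))
  }
  multilayer_network(
    molecules = mols,
    mol_edges = if (nrow(ed) > 0) ed else NULL,
    publications = pubs, authorship = auth,
    mentions = if (nrow(mentions) > 0) mentions else NULL,
    aliases = al[al$name != al$alias, , drop = FALSE])
}

#' Export the flattened network as GraphML
#'
#' @param net a [multilayer_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
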