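#' Heterogeneous multilayer molecule-publication-author network
#'
#' The central container of the package: three typed node layers (molecules,
#' publications, authors), one weighted undirected intra-layer edge set on the
#' molecular layer, and two cross-layers (publication--molecule mentions and
#' publication--author authorship). There are deliberately no intra-layer
#' edges among publications or authors; coauthorship is always derived on the
#' fly from the authorship cross-layer.
#'
#' @param molecules character vector of canonical molecule names, or a
#'   data.frame with a `name` column. Names must be non-empty and unique
#'   case-insensitively.
#' @param mol_edges data.frame with columns `from`, `to`, `weight` giving the
#'   undirected weighted molecular interaction layer. Self-loops are
#'   rejected; duplicate undirected edges collapse keeping the maximum
#'   weight. Weights must be positive.
#' @param publications data.frame with columns `pub_id`, `title`, `abstract`,
#'   optional `year`, and an optional list-column `keywords`. `pub_id` must
#'   be unique.
#' @param authorship data.frame with columns `pub_id`, `author_key` (one row
#'   per author position, in author-list order) and optional `affiliation`.
#'   Author keys are normalized: trimmed, internal whitespace collapsed,
#'   case preserved.
#' @param mentions data.frame with columns `pub_id`, `molecule` linking
#'   publications to the molecules they mention. Molecule values may be
#'   aliases; they are resolved to canonical names. Stored as a set.
#' @param aliases optional data.frame with columns `name` (canonical) and
#'   `alias`. Every molecule is always an alias of itself. An alias mapping
#'   to two different molecules (case-insensitively) is a load-time error.
#'
#' @return an object of class `multilayer_network`.
#' @export
multilayer_network <- function(molecules,
                               mol_edges = NULL,
                               publications = NULL,
                               authorship = NULL,
                               mentions = NULL,
                               aliases = NULL) {
  if (is.data.frame(molecules)) molecules <- molecules$name
  molecules <- as.character(molecules)
  if (any(is.na(molecules) | !nzchar(molecules)))
    abort_domain("molecule names must be non-empty strings")
  if (anyDuplicated(tolower(molecules)))
    abort_domain("molecule names must be unique (case-insensitive)")

  alias_tab <- data.frame(name = molecules, alias = molecules,
                          stringsAsFactors = FALSE)
  if (!is.null(aliases) && nrow(aliases) > 0) {
    extra <- data.frame(name = as.character(aliases$name),
                        alias = as.character(aliases$alias),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(tolower(extra$name), tolower(molecules))
    if (length(unknown) > 0)
      abort_domain(sprintf("alias table refers to unknown molecule(s): %s",
                           paste(unknown, collapse = ", ")))
    # map canonical spelling
    extra$name <- molecules[match(tolower(extra$name), tolower(molecules))]
    alias_tab <- rbind(alias_tab, extra)
  }
  alias_tab <- unique(alias_tab)
  key <- tolower(alias_tab$alias)
  clash <- tapply(alias_tab$name, key, function(x) length(unique(x)))
  if (any(clash > 1)) {
    bad <- names(clash)[clash > 1][1]
    mc_abort(sprintf("ambiguous alias '%s' maps to multiple molecules", bad),
             "mc_ambiguous_alias")
  }
  lookup <- alias_tab$name
  names(lookup) <- key

  net <- structure(list(
    molecules = molecules,
    alias_tab = alias_tab,
    mol_lookup = lookup,
    mol_edges = empty_mol_edges(),
    publications = empty_publications(),
    authors = character(0),
    authorship = empty_authorship(),
    mentions = empty_mentions()
  ), class = "multilayer_network")

  if (!is.null(mol_edges) && nrow(mol_edges) > 0) {
    from <- vapply(as.character(mol_edges$from), resolve_molecule, "", net = net)
    to <- vapply(as.character(mol_edges$to), resolve_molecule, "", net = net)
    w <- as.numeric(mol_edges$weight)
    if (any(!is.finite(w) | w <= 0))
      abort_domain("molecular edge weights must be positive finite numbers")
    if (any(from == to))
      abort_domain("molecular self-loops are not allowed")
    a <- pmin(from, to); b <- pmax(from, to)
    ed <- data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE)
    # undirected duplicates collapse to the maximum weight
    ed <- ed[order(ed$from, ed$to, -ed$weight), , drop = FALSE]
    ed <- ed[!duplicated(ed[c("from", "to")]), , drop = FALSE]
    rownames(ed) <- NULL
    net$mol_edges <- ed
  }

  if (!is.null(publications) && nrow(publications) > 0) {
    pubs <- data.frame(pub_id = as.character(publications$pub_id),
                       title = as.character(publications$title),
                       abstract = as.character(publications$abstract),
                       stringsAsFactors = FALSE)
    pubs$year <- if ("year" %in% names(publications))
      as.integer(publications$year) else NA_integer_
    pubs$keywords <- if ("keywords" %in% names(publications))
      lapply(publications$keywords, as.character) else
      rep(list(character(0)), nrow(pubs))
    if (anyDuplicated(pubs$pub_id))
      mc_abort("duplicate publication id(s)", "mc_duplicate_id")
    pubs$title[is.na(pubs$title)] <- ""
    pubs$abstract[is.na(pubs$abstract)] <- ""
    rownames(pubs) <- NULL
    net$publications <- pubs
  }

  if (!is.null(authorship) && nrow(authorship) > 0) {
    au <- data.frame(pub_id = as.character(authorship$pub_id),
                     author_key = normalize_author(as.character(authorship$author_key)),
                     stringsAsFactors = FALSE)
    au$affiliation <- if ("affiliation" %in% names(authorship))
      as.character(authorship$affiliation) else NA_character_
    missing_pub <- setdiff(au$pub_id, net$publications$pub_id)
    if (length(missing_pub) > 0)
      abort_domain(sprintf("authorship refers to unknown publication(s): %s",
                           paste(utils::head(missing_pub, 3), collapse = ", ")))
    au <- au[!duplicated(au[c("pub_id", "author_key")]), , drop = FALSE]
    au$position <- stats::ave(seq_len(nrow(au)), au$pub_id, FUN = seq_along)
    rownames(au) <- NULL
    net$authorship <- au
    net$authors <- sort(unique(au$author_key))
  }

  if (!is.null(mentions) && nrow(mentions) > 0) {
    me <- data.frame(pub_id = as.character(mentions$pub_id),
                     molecule = vapply(as.character(mentions$molecule),
                                       resolve_molecule, "", net = net),
                     stringsAsFactors = FALSE)
    missing_pub <- setdiff(me$pub_id, net$publications$pub_id)
    if (length(missing_pub) > 0)
      abort_domain(sprintf("mention refers to unknown publication(s): %s",
                           paste(utils::head(missing_pub, 3), collapse = ", ")))
    me <- unique(me)
    rownames(me) <- NULL
    net$mentions <- me
  }

  net
}

empty_mol_edges <- function()
  data.frame(from = character(0), to = character(0), weight = numeric(0),
             stringsAsFactors = FALSE)
empty_publications <- function() {
  d <- data.frame(pub_id = character(0), title = character(0),
                  abstract = character(0), year = integer(0),
                  stringsAsFactors = FALSE)
  d$keywords <- list()
  d
}
empty_authorship <- function()
  data.frame(pub_id = character(0), author_key = character(0),
             affiliation = character(0), position = integer(0),
             stringsAsFactors = FALSE)
empty_mentions <- function()
  data.frame(pub_id = character(0), molecule = character(0),
             stringsAsFactors = FALSE)

#' Normalize an author name into its identity key
#'
#' Trims leading/trailing whitespace and collapses internal runs of
#' whitespace to a single space; case is preserved. No further
#' disambiguation is attempted: two people publishing under the same
#' normalized name string are one author node.
#'
#' @param x character vector of raw author names.
#' @return character vector of author keys.
#' @export
normalize_author <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Resolve a molecule name or alias to its canonical name
#'
#' Lookup is case-insensitive over canonical names and all aliases.
#'
#' @param net a [multilayer_network()].
#' @param name a single molecule name or alias.
#' @return the canonical molecule name.
#' @export
resolve_molecule <- function(net, name) {
  stopifnot(length(name) == 1)
  hit <- net$mol_lookup[tolower(as.character(name))]
  if (is.na(hit)) abort_unknown_molecule(as.character(name))
  unname(hit)
}

#' Molecules one hop away from a query molecule
#'
#' The "related molecules" of a query: its direct neighbors in the molecular
#' interaction layer. The query itself is never included.
#'
#' @inheritParams resolve_molecule
#' @param query molecule name or alias.
#' @return sorted character vector of canonical neighbor names (possibly
#'   empty).
#' @export
related_molecules <- function(net, query) {
  q <- resolve_molecule(net, query)
  ed <- net$mol_edges
  nb <- c(ed$to[ed$from == q], ed$from[ed$to == q])
  sort(unique(nb))
}

#' Test molecular-layer adjacency
#'
#' @inheritParams resolve_molecule
#' @param a,b molecule names or aliases.
#' @return `TRUE` iff an undirected molecular edge joins `a` and `b`. A
#'   molecule is never a neighbor of itself.
#' @export
are_neighbors <- function(net, a, b) {
  ca <- resolve_molecule(net, a)
  cb <- resolve_molecule(net, b)
  if (ca == cb) return(FALSE)
  lo <- pmin(ca, cb); hi <- pmax(ca, cb)
  any(net$mol_edges$from == lo & net$mol_edges$to == hi)
}

#' Publications mentioning a molecule
#'
#' @inheritParams resolve_molecule
#' @param molecule molecule name or alias.
#' @return sorted character vector of publication ids.
#' @export
publications_mentioning <- function(net, molecule) {
  m <- resolve_molecule(net, molecule)
  sort(unique(net$mentions$pub_id[net$mentions$molecule == m]))
}

#' Authors of a publication, in stored order
#'
#' @inheritParams resolve_molecule
#' @param pub_id publication identifier.
#' @return character vector of author keys in author-list order.
#' @export
authors_of <- function(net, pub_id) {
  if (!pub_id %in% net$publications$pub_id) abort_unknown_publication(pub_id)
  au <- net$authorship[net$authorship$pub_id == pub_id, , drop = FALSE]
  au$author_key[order(au$position)]
}

# vectorized adjacency test on canonical names; self-pairs are FALSE
neighbors_mask <- function(net, x, y) {
  keys <- paste(net$mol_edges$from, net$mol_edges$to, sep = "\r")
  lo <- pmin(x, y); hi <- pmax(x, y)
  x != y & paste(lo, hi, sep = "\r") %in% keys
}

# publication ids authored by `author_key` (unordered)
pubs_of_author <- function(net, author_key) {
  if (!author_key %in% net$authors) abort_unknown_author(author_key)
  unique(net$authorship$pub_id[net$authorship$author_key == author_key])
}

# per-author count of distinct publications that mention >= 1 molecule
molecule_linked_pub_counts <- function(net) {
  linked <- unique(net$mentions$pub_id)
  au <- net$authorship[net$authorship$pub_id %in% linked, , drop = FALSE]
  tab <- table(unique(au[c("author_key", "pub_id")])$author_key)
  stats::setNames(as.integer(tab), names(tab))
}

# per-author count of all publications in the corpus
total_pub_counts <- function(net) {
  tab <- table(unique(net$authorship[c("author_key", "pub_id")])$author_key)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("<multilayer_network>\n")
  cat(sprintf("  molecules:    %d nodes, %d undirected weighted edges\n",
              length(x$molecules), nrow(x$mol_edges)))
  cat(sprintf("  publications: %d nodes\n", nrow(x$publications)))
  cat(sprintf("  authors:      %d nodes\n", length(x$authors)))
  cat(sprintf("  cross-layers: %d mention edges, %d authorship edges\n",
              nrow(x$mentions), nrow(x$authorship)))
  invisible(x)
}

#' Flatten the multilayer network into a single igraph object
#'
#' Node layers are distinguished by a `layer` vertex attribute
#' (`"molecule"`, `"publication"`, `"author"`); edge sets by an `etype`
#' edge attribute (`"interacts"`, `"mentions"`, `"authored"`). Molecular
#' edge weights are kept in `weight`; cross-layer edges get weight 1.
#'
#' @param net a [multilayer_network()].
#' @return an undirected [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  # layer prefixes keep ids unique across layers
  vm <- paste0("mol:", net$molecules)
  vp <- paste0("pub:", net$publications$pub_id)
  va <- paste0("aut:", net$authors)
  verts <- data.frame(
    name = c(vm, vp, va),
    layer = c(rep("molecule", length(vm)), rep("publication", length(vp)),
              rep("author", length(va))),
    label = c(net$molecules, net$publications$pub_id, net$authors),
    stringsAsFactors = FALSE)
  ed <- rbind(
    data.frame(from = paste0("mol:", net$mol_edges$from),
               to = paste0("mol:", net$mol_edges$to),
               weight = net$mol_edges$weight, etype = "interacts",
               stringsAsFactors = FALSE),
    data.frame(from = paste0("pub:", net$mentions$pub_id),
               to = paste0("mol:", net$mentions$molecule),
               weight = 1, etype = "mentions", stringsAsFactors = FALSE),
    data.frame(from = paste0("pub:", net$authorship$pub_id),
               to = paste0("aut:", net$authorship$author_key),
               weight = 1, etype = "authored", stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}
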