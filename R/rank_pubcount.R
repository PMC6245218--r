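#' Per-author publication statistics for a query molecule
#'
#' For a query molecule, finds its related molecules (one-hop neighbors in
#' the molecular layer) and, for every author with at least one publication
#' mentioning at least one related molecule, tallies:
#' \describe{
#'   \item{per_molecule}{named count vector: for each related molecule, the
#'     number of that author's publications with a mention edge to it. A
#'     publication mentioning several related molecules contributes to each
#'     of their counts.}
#'   \item{n_PC}{publication count on related molecules. In `"sum"` mode
#'     (the default, following the literal merge rule of summing the
#'     per-molecule counts) a multi-molecule publication is counted once per
#'     molecule, so `n_PC` can exceed the number of distinct publications.
#'     In `"distinct"` mode it is the number of distinct publications
#'     mentioning at least one related molecule.}
#'   \item{n_TOTAL}{the author's total count of molecule-linked
#'     publications (publications mentioning any molecule, related or not).}
#'   \item{n_distinct_molecules}{number of related molecules with count >= 1.}
#'   \item{r_PC}{normalized publication count `n_PC / n_TOTAL`.}
#'   \item{k_distinct}{distinct publications on related molecules; this is
#'     the `k` used by the hypergeometric test regardless of `mode`, so the
#'     sampling model stays valid (`k <= n_TOTAL`).}
#' }
#' Publications mentioning only the query molecule itself contribute to
#' `n_TOTAL` but not to `n_PC`; an author with no publication on any related
#' molecule is absent from the result.
#'
#' @param net a [multilayer_network()].
#' @param query molecule name or alias.
#' @param mode `"sum"` (default) or `"distinct"`; see above.
#' @return data.frame, one row per author (sorted by `author_key`), with a
#'   `per_molecule` list-column of named integer vectors.
#' @export
compute_author_stats <- function(net, query, mode = c("sum", "distinct")) {
  mode <- match.arg(mode)
  rel <- related_molecules(net, query)
  out <- data.frame(author_key = character(0), n_distinct_molecules = integer(0),
                    n_PC = integer(0), n_TOTAL = integer(0),
                    k_distinct = integer(0), r_PC = numeric(0),
                    stringsAsFactors = FALSE)
  out$per_molecule <- list()
  if (length(rel) == 0) return(out)

  rel_ment <- net$mentions[net$mentions$molecule %in% rel, , drop = FALSE]
  if (nrow(rel_ment) == 0) return(out)
  am <- merge(rel_ment, net$authorship[c("pub_id", "author_key")], by = "pub_id")
  if (nrow(am) == 0) return(out)

  totals <- molecule_linked_pub_counts(net)
  keys <- sort(unique(am$author_key))
  rows <- lapply(keys, function(a) {
    mine <- am[am$author_key == a, , drop = FALSE]
    per <- table(mine$molecule)
    per <- stats::setNames(as.integer(per), names(per))
    per <- per[order(names(per))]
    k_dist <- length(unique(mine$pub_id))
    n_pc <- if (mode == "sum") sum(per) else k_dist
    n_tot <- unname(totals[a])
    d <- data.frame(author_key = a,
                    n_distinct_molecules = length(per),
                    n_PC = as.integer(n_pc), n_TOTAL = as.integer(n_tot),
                    k_distinct = as.integer(k_dist),
                    r_PC = n_pc / n_tot, stringsAsFactors = FALSE)
    d$per_molecule <- list(per)
    d
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Normalized publication count
#'
#' The ratio of an author's publication count on the related molecules of
#' the query to their total publication count, `r_PC = n_PC / n_TOTAL`.
#'
#' @param n_PC publication count on related molecules.
#' @param n_TOTAL total publication count; must be >= 1.
#' @return `n_PC / n_TOTAL`.
#' @export
r_pc <- function(n_PC, n_TOTAL) {
  if (any(n_TOTAL < 1)) abort_domain("n_TOTAL must be >= 1")
  if (any(n_PC < 0)) abort_domain("n_PC must be >= 0")
  n_PC / n_TOTAL
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k_success` or more successes when drawing
#' `n_sample` publications without replacement from a population of `N_pop`
#' publications of which `K_pop` are on the related molecules of the query:
#' `P[X >= k_success]` (inclusive upper tail).
#'
#' @param N_pop population size (all publications in the corpus).
#' @param K_pop successes in the population (distinct publications
#'   mentioning at least one related molecule).
#' @param n_sample the author's sample size (`n_TOTAL`).
#' @param k_success successes in the sample.
#' @return probability in \[0, 1\].
#' @export
hypergeom_pvalue <- function(N_pop, K_pop, n_sample, k_success) {
  if (K_pop > N_pop || K_pop < 0) abort_domain("need 0 <= K_pop <= N_pop")
  if (n_sample > N_pop || n_sample < 0) abort_domain("need 0 <= n_sample <= N_pop")
  if (k_success > n_sample || k_success < 0)
    abort_domain("need 0 <= k_success <= n_sample")
  stats::phyper(k_success - 1, K_pop, N_pop - K_pop, n_sample,
                lower.tail = FALSE)
}

#' Population context for the hypergeometric ranking
#'
#' @param net a [multilayer_network()].
#' @param query molecule name or alias.
#' @return list with `N_pop` (all publications in the corpus) and `K_pop`
#'   (distinct publications mentioning at least one related molecule).
#' @export
ranking_context <- function(net, query) {
  rel <- related_molecules(net, query)
  K <- length(unique(net$mentions$pub_id[net$mentions$molecule %in% rel]))
  list(N_pop = nrow(net$publications), K_pop = K)
}

#' Rank authors by a publication-count measure
#'
#' Three measures are available:
#' \describe{
#'   \item{`"nonnorm"`}{sort by number of related molecules published on
#'     (descending), ties broken by `n_PC` descending. Favors prolific
#'     authors who cover the query's neighborhood widely.}
#'   \item{`"norm"`}{same primary key, ties broken by the normalized count
#'     `r_PC` descending. Favors authors publishing exclusively on the
#'     related molecules, typically earlier-career ones.}
#'   \item{`"hypergeom"`}{sort by the upper-tail hypergeometric p-value
#'     ascending, using `k_distinct` as the sample successes. Favors
#'     authors whose output is improbably concentrated on the neighborhood,
#'     regardless of how many related molecules they span.}
#' }
#' All methods apply a final deterministic tie-break: `author_key`
#' ascending lexicographically (C collation).
#'
#' @param stats data.frame from [compute_author_stats()].
#' @param context list from [ranking_context()]; required for
#'   `method = "hypergeom"`.
#' @param method one of `"nonnorm"`, `"norm"`, `"hypergeom"`.
#' @return `stats` reordered, with a leading `rank` column and (for
#'   `"hypergeom"`) a `p_value` column.
#' @export
rank_authors <- function(stats, context = NULL,
                         method = c("nonnorm", "norm", "hypergeom")) {
  method <- match.arg(method)
  if (nrow(stats) == 0) mc_abort("empty author statistics", "mc_empty_input")
  key_lex <- c_order_key(stats$author_key)
  ord <- switch(method,
    nonnorm = order(-stats$n_distinct_molecules, -stats$n_PC, key_lex),
    norm = order(-stats$n_distinct_molecules, -stats$r_PC, key_lex),
    hypergeom = {
      if (is.null(context)) abort_domain("hypergeom ranking needs a context")
      p <- mapply(hypergeom_pvalue, context$N_pop, context$K_pop,
                  stats$n_TOTAL, stats$k_distinct)
      stats$p_value <- p
      order(p, key_lex)
    })
  res <- stats[ord, , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

# locale-independent lexicographic sort key
c_order_key <- function(x) {
  xtfrm(factor(x, levels = sort(unique(x), method = "radix")))
}

#' Format a per-molecule breakdown as "MOL(count), ..."
#'
#' @param per named integer vector of per-molecule publication counts.
#' @return a single string, molecules in alphabetical order.
#' @export
format_breakdown <- function(per) {
  if (length(per) == 0) return("")
  per <- per[order(names(per), method = "radix")]
  paste(sprintf("%s(%d)", names(per), as.integer(per)), collapse = ", ")
}
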