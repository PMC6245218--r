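#' Molecular interest profile of an author
#'
#' The molecules an author most commonly mentions: token occurrences of each
#' molecule's aliases across the titles, abstracts and keyword lists of all
#' the author's publications, counted with multiplicity (unlike the binary
#' mention edges), top `m` by frequency with lexicographic tie-break.
#'
#' @param net a [multilayer_network()].
#' @param author author key.
#' @param m profile size (default 5).
#' @return data.frame with columns `molecule`, `freq`, at most `m` rows,
#'   frequencies non-increasing.
#' @export
author_top_molecules <- function(net, author, m = 5) {
  pubs <- pubs_of_author(net, author)
  counts <- stats::setNames(numeric(0), character(0))
  for (pid in pubs) {
    p <- net$publications[net$publications$pub_id == pid, ]
    cc <- count_record_mentions(p$title, p$abstract, p$keywords[[1]], net$alias_tab)
    for (mol in names(cc))
      counts[mol] <- (if (mol %in% names(counts)) counts[[mol]] else 0) + cc[[mol]]
  }
  if (length(counts) == 0)
    return(data.frame(molecule = character(0), freq = integer(0),
                      stringsAsFactors = FALSE))
  d <- data.frame(molecule = names(counts), freq = as.integer(counts),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$freq, c_order_key(d$molecule)), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, m)
}

#' Most frequent coauthors of an author
#'
#' Coauthors over all publications (not restricted to any query), ranked by
#' the number of coauthored publications, ties lexicographic.
#'
#' @param net a [multilayer_network()].
#' @param author author key.
#' @param c number of coauthors to keep (default 5).
#' @return data.frame with columns `coauthor`, `n_shared`.
#' @export
top_coauthors <- function(net, author, c = 5) {
  pubs <- pubs_of_author(net, author)
  others <- net$authorship[net$authorship$pub_id %in% pubs &
                             net$authorship$author_key != author, , drop = FALSE]
  if (nrow(others) == 0)
    return(data.frame(coauthor = character(0), n_shared = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(unique(others[c("pub_id", "author_key")])$author_key)
  d <- data.frame(coauthor = names(tab), n_shared = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$n_shared, c_order_key(d$coauthor)), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, c)
}

#' Molecule pairs contributed by one author-coauthor relation
#'
#' Molecules present in both interest profiles are removed from each side;
#' the remaining molecules form the full cross product (author-side molecule
#' crossed with coauthor-side molecule).
#'
#' @param profile_a,profile_b interest profiles as from
#'   [author_top_molecules()] (or character vectors of molecules).
#' @return data.frame with columns `mol_a`, `mol_b` (possibly zero rows).
#' @export
coauthor_pair_molecules <- function(profile_a, profile_b) {
  ma <- if (is.data.frame(profile_a)) profile_a$molecule else as.character(profile_a)
  mb <- if (is.data.frame(profile_b)) profile_b$molecule else as.character(profile_b)
  shared <- intersect(ma, mb)
  ma <- setdiff(ma, shared)
  mb <- setdiff(mb, shared)
  if (length(ma) == 0 || length(mb) == 0)
    return(data.frame(mol_a = character(0), mol_b = character(0),
                      stringsAsFactors = FALSE))
  g <- expand.grid(mol_b = mb, mol_a = ma, stringsAsFactors = FALSE)
  data.frame(mol_a = g$mol_a, mol_b = g$mol_b, stringsAsFactors = FALSE)
}

#' Null sample of random molecule pairs
#'
#' Draws `n_mol` molecules uniformly without replacement and returns all
#' `n_mol^2` ordered pairs, self-pairs included (self-pairs count as
#' non-neighbors downstream, since a molecule is never its own neighbor).
#'
#' @param net a [multilayer_network()].
#' @param n_mol number of molecules to draw (default 500, giving 250,000
#'   pairs).
#' @param seed RNG seed for the draw.
#' @return data.frame with columns `mol_a`, `mol_b` and `n_mol^2` rows.
#' @export
sample_random_molecule_pairs <- function(net, n_mol = 500, seed = 1) {
  mols <- net$molecules
  if (length(mols) < n_mol)
    abort_insufficient("molecules", n_mol, length(mols))
  set.seed(seed)
  picked <- sample(mols, n_mol)
  g <- expand.grid(mol_b = picked, mol_a = picked, stringsAsFactors = FALSE)
  data.frame(mol_a = g$mol_a, mol_b = g$mol_b, stringsAsFactors = FALSE)
}

#' Contingency table of neighbor proximity: coauthor pairs vs random pairs
#'
#' The validation analysis: if molecular interactions among scientists'
#' interests influence collaboration, the molecule pairs derived from
#' coauthors' interest profiles should be molecular-network neighbors more
#' often than random molecule pairs. The procedure:
#' 1. sample `n_authors` authors with at least `min_pubs` molecule-linked
#'    publications;
#' 2. for each, take the `c` most frequent coauthors;
#' 3. for each author-coauthor relation, build both `m`-molecule interest
#'    profiles, drop shared molecules, and cross the remainders into
#'    molecule pairs;
#' 4. classify every pair as neighbor / non-neighbor (cells a / b);
#' 5. compare against all ordered pairs of `n_mol` random molecules
#'    (cells c / d).
#'
#' @param net a [multilayer_network()].
#' @param n_authors number of authors to sample (default 250).
#' @param min_pubs minimum molecule-linked publications to qualify
#'   (default 5).
#' @param c coauthors per author (default 5).
#' @param m interest-profile size (default 5).
#' @param n_mol random molecules for the null (default 500).
#' @param seed RNG seed; the whole table is reproducible from it.
#' @return a `contingency_table` object; see [contingency_table()].
#' @export
build_validation_table <- function(net, n_authors = 250, min_pubs = 5,
                                   c = 5, m = 5, n_mol = 500, seed = 1) {
  linked <- molecule_linked_pub_counts(net)
  qualified <- sort(names(linked)[linked >= min_pubs])
  if (length(qualified) < n_authors)
    abort_insufficient("authors", n_authors, length(qualified))
  if (length(net$molecules) < n_mol)
    abort_insufficient("molecules", n_mol, length(net$molecules))
  set.seed(seed)
  chosen <- sample(qualified, n_authors)
  mol_seed <- sample.int(.Machine$integer.max, 1)

  profiles <- new.env(parent = emptyenv())
  get_profile <- function(a) {
    if (is.null(profiles[[a]])) profiles[[a]] <- author_top_molecules(net, a, m)
    profiles[[a]]
  }
  a_cnt <- 0L; b_cnt <- 0L
  for (au in chosen) {
    co <- top_coauthors(net, au, c)
    pa <- get_profile(au)
    for (cb in co$coauthor) {
      pairs <- coauthor_pair_molecules(pa, get_profile(cb))
      if (nrow(pairs) == 0) next
      nb <- neighbors_mask(net, pairs$mol_a, pairs$mol_b)
      a_cnt <- a_cnt + sum(nb)
      b_cnt <- b_cnt + sum(!nb)
    }
  }
  rnd <- sample_random_molecule_pairs(net, n_mol, seed = mol_seed)
  nb <- neighbors_mask(net, rnd$mol_a, rnd$mol_b)
  contingency_table(a = a_cnt, b = b_cnt, c = sum(nb), d = sum(!nb),
                    params = list(n_authors = n_authors, min_pubs = min_pubs,
                                  c = c, m = m, n_mol = n_mol, seed = seed))
}

#' 2x2 neighbor-proximity contingency table
#'
#' Cell layout: `a` = coauthor-derived neighbor pairs, `b` = coauthor-derived
#' non-neighbor pairs, `c` = random neighbor pairs, `d` = random non-neighbor
#' pairs.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param params optional list of sampling parameters, kept for reporting.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, params = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    abort_domain("contingency cells must be non-negative integers")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d), params = params),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Validation contingency table\n")
  m <- matrix(c(x$c, x$a, x$d, x$b), 2, 2, byrow = TRUE,
              dimnames = list(c("Neighbors", "Non Neighbors"),
                              c("Random pairs", "Coauthor pairs")))
  print(m)
  or <- tryCatch(odds_ratio(x), error = function(e) NA_real_)
  p <- tryCatch(association_test(x), error = function(e) NA_real_)
  cat(sprintf("odds ratio: %.4g\n", or))
  # conventional reporting floor used for vanishingly small p-values
  cat(sprintf("p-value: %s\n",
              if (!is.na(p) && p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4)))
  invisible(x)
}

#' Odds ratio of a 2x2 contingency table
#'
#' `(a/b) / (c/d) = a*d / (b*c)`: the odds of being molecular neighbors for
#' coauthor-derived molecule pairs relative to random pairs.
#'
#' @param table a [contingency_table()].
#' @return the sample odds ratio.
#' @export
odds_ratio <- function(table) {
  if (table$b * table$c == 0)
    abort_domain("odds ratio undefined: b*c = 0")
  (table$a * table$d) / (table$b * table$c)
}

#' Two-sided exact association test for a 2x2 table
#'
#' Fisher's exact test: conditioning on the margins, the p-value sums the
#' probabilities of all tables at least as extreme as (probability no larger
#' than) the observed one.
#'
#' @param table a [contingency_table()].
#' @return two-sided p-value.
#' @export
association_test <- function(table) {
  m <- matrix(c(table$a, table$b, table$c, table$d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort_domain("degenerate margins: a row or column total is zero")
  stats::fisher.test(m)$p.value
}

#' Compare two author rankings by paired positions
#'
#' Takes the top `top_k` authors of `rank_a`, pairs each with its position
#' in `rank_b` (authors absent from `rank_b` get position
#' `length(rank_b) + 1`), and computes the Pearson correlation of the two
#' position vectors — the machinery behind rank-scatter comparisons of the
#' ranking methods.
#'
#' @param rank_a,rank_b ordered character vectors of author keys (or
#'   data.frames with an `author_key` column).
#' @param top_k number of leading authors of `rank_a` to compare
#'   (default 120).
#' @return list with `pairs` (data.frame `author_key`, `pos_a`, `pos_b`) and
#'   `correlation` (Pearson; `NA` when fewer than 2 pairs or a vector is
#'   constant).
#' @export
compare_rankings <- function(rank_a, rank_b, top_k = 120) {
  if (is.data.frame(rank_a)) rank_a <- rank_a$author_key
  if (is.data.frame(rank_b)) rank_b <- rank_b$author_key
  if (length(rank_a) == 0 || length(rank_b) == 0)
    mc_abort("empty ranking", "mc_empty_input")
  top <- utils::head(rank_a, top_k)
  pos_b <- match(top, rank_b)
  pos_b[is.na(pos_b)] <- length(rank_b) + 1L
  pairs <- data.frame(author_key = top, pos_a = seq_along(top), pos_b = pos_b,
                      stringsAsFactors = FALSE)
  corr <- if (nrow(pairs) >= 2 && stats::sd(pairs$pos_a) > 0 &&
                stats::sd(pairs$pos_b) > 0)
    stats::cor(pairs$pos_a, pairs$pos_b) else NA_real_
  list(pairs = pairs, correlation = corr)
}

#' Scatter plot of paired ranks
#'
#' @param comparison result of [compare_rankings()].
#' @param ... passed to [graphics::plot()].
#' @return the comparison, invisibly.
#' @export
plot_rank_comparison <- function(comparison, ...) {
  p <- comparison$pairs
  graphics::plot(p$pos_a, p$pos_b, xlab = "rank (method A)",
                 ylab = "rank (method B)", pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(comparison)
}
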