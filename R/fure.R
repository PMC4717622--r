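# Functional-redundancy scoring: graph-based (Wang) semantic similarity of
# the two genes' ontology annotations, combined by best-match average. A
# truly synthetic lethal pair should be functionally redundant, so a high
# similarity supports the candidate.

# Wang S-values: every ancestor of `term` (including itself, weight 1)
# receives the maximum over paths of the product of edge contribution
# factors along the path. Iterative relaxation; terminates on a DAG with
# weights < 1.
term_svalues <- function(term, g) {
  if (!term %in% g$terms) stop_("unknown term: %s", term)
  s <- stats::setNames(1, term)
  queue <- term
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]
    pa <- g$parents[[t]]
    if (is.null(pa) || nrow(pa) == 0) next
    for (i in seq_len(nrow(pa))) {
      cand <- s[[t]] * pa$weight[i]
      p <- pa$parent[i]
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity between two ontology terms
#'
#' Propagates contribution-weighted S-values over each term's ancestor
#' closure (the term itself weighted 1; an ancestor gets the maximum over
#' paths of the product of edge factors), then scores
#' `sum over shared ancestors of (S1 + S2) / (sum(S1) + sum(S2))`.
#' Identical terms score 1; terms with no shared ancestor score 0.
#'
#' @param t1,t2 Term identifiers present in `g`.
#' @param g An [ontology_graph()].
#' @return Similarity in `[0, 1]`.
#' @export
term_similarity <- function(t1, t2, g) {
  s1 <- term_svalues(t1, g)
  s2 <- term_svalues(t2, g)
  shared <- intersect(names(s1), names(s2))
  if (length(shared) == 0) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

bma <- function(simmat) {
  mean(c(apply(simmat, 1, max), apply(simmat, 2, max)))
}

#' Functional-redundancy score of a gene pair
#'
#' Best-match-average combination of the term-by-term [term_similarity()]
#' matrix over the two genes' annotation sets: the mean of the row maxima
#' and column maxima pooled together. When the annotation carries ontology
#' aspects, similarity is computed per aspect and averaged over aspects in
#' which both genes have at least one term. Genes lacking any known
#' annotation yield `NA` (missing, not zero).
#'
#' @param a,b Gene identifiers.
#' @param ann Annotation data frame (`gene`, `term`, optional `aspect`),
#'   e.g. from [read_annotation()]; unknown terms are dropped with a warning.
#' @param g An [ontology_graph()].
#' @return List of class `"fure_score"`: `gene_a`, `gene_b`, `similarity`
#'   (in `[0, 1]` or `NA`), `n_terms_a`, `n_terms_b`.
#' @export
gene_pair_similarity <- function(a, b, ann, g) {
  ann <- prune_annotation(ann, g)
  ta <- ann[ann$gene == a, , drop = FALSE]
  tb <- ann[ann$gene == b, , drop = FALSE]
  res <- structure(list(gene_a = a, gene_b = b, similarity = NA_real_,
                        n_terms_a = length(unique(ta$term)),
                        n_terms_b = length(unique(tb$term))),
                   class = "fure_score")
  if (nrow(ta) == 0 || nrow(tb) == 0) return(res)
  use_aspects <- !all(is.na(ann$aspect))
  aspect_sim <- function(terms_a, terms_b) {
    simmat <- outer(terms_a, terms_b,
                    Vectorize(function(x, y) term_similarity(x, y, g)))
    bma(matrix(simmat, length(terms_a), length(terms_b)))
  }
  if (!use_aspects) {
    res$similarity <- aspect_sim(unique(ta$term), unique(tb$term))
  } else {
    aspects <- intersect(unique(ta$aspect), unique(tb$aspect))
    aspects <- aspects[!is.na(aspects)]
    if (length(aspects) == 0) return(res)
    sims <- vapply(aspects, function(as)
      aspect_sim(unique(ta$term[ta$aspect == as]),
                 unique(tb$term[tb$aspect == as])), 0)
    res$similarity <- mean(sims)
  }
  res
}

#' @export
print.fure_score <- function(x, ...) {
  cat(sprintf("Functional redundancy %s / %s: %s (%d vs %d terms)\n",
              x$gene_a, x$gene_b,
              if (is.na(x$similarity)) "NA (unannotated gene)"
              else sprintf("%.3f", x$similarity),
              x$n_terms_a, x$n_terms_b))
  invisible(x)
}

#' Annotate a candidate pair list with functional-redundancy scores
#'
#' Appends a `similarity` column (plus per-gene annotated-term counts) to a
#' pair table from [memu()], [bigee()] or [beem()], preserving the input
#' ranking. Pairs with an unannotated gene get `NA` and are kept unless a
#' similarity floor is requested.
#'
#' @param pairs Data frame whose first two character columns (or the columns
#'   named in `gene_cols`) identify the pair.
#' @param ann Annotation data frame (`gene`, `term`, optional `aspect`).
#' @param g An [ontology_graph()].
#' @param min_similarity Optional floor; pairs scoring below it (NA kept)
#'   are dropped.
#' @param gene_cols Length-2 character vector naming the pair columns;
#'   defaults to the first two columns.
#' @return `pairs` with `similarity`, `n_terms_a`, `n_terms_b` appended.
#' @export
fure <- function(pairs, ann, g, min_similarity = NULL, gene_cols = NULL) {
  if (nrow(pairs) == 0) stop_("empty pair list")
  if (is.null(gene_cols)) gene_cols <- names(pairs)[1:2]
  ann <- prune_annotation(ann, g)
  ga <- as.character(pairs[[gene_cols[1]]])
  gb <- as.character(pairs[[gene_cols[2]]])
  # score each distinct pair once
  keys <- pair_key(ga, gb)
  uk <- !duplicated(keys)
  cache <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    sc <- suppressWarnings(gene_pair_similarity(ga[i], gb[i], ann, g))
    assign(keys[i], sc, envir = cache)
  }
  scores <- lapply(keys, get, envir = cache)
  pairs$similarity <- vapply(scores, `[[`, 0, "similarity")
  pairs$n_terms_a <- vapply(scores, `[[`, 0L, "n_terms_a")
  pairs$n_terms_b <- vapply(scores, `[[`, 0L, "n_terms_b")
  if (!is.null(min_similarity))
    pairs <- pairs[is.na(pairs$similarity) |
                     pairs$similarity >= min_similarity, , drop = FALSE]
  pairs
}
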