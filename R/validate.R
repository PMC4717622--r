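# Evaluation statistics: permutation enrichment of candidate pairs against
# a reference synthetic-lethal pair set, gene-set Fisher enrichment, and the
# knock-down dependency (rank-sum) test.

#' Permutation test for enrichment of candidate pairs in a reference set
#'
#' Counts how many candidate pairs hit the reference, then draws the same
#' number of unordered gene pairs uniformly at random from the universe
#' `n_perm` times to build the null overlap distribution. The p-value uses
#' the add-one rule `p = (#\{null >= observed\} + 1) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)` and p is never exactly zero.
#'
#' @param candidates Two-column data frame (or matrix) of candidate gene
#'   pairs.
#' @param reference Two-column data frame of reference pairs (`mode =
#'   "pair"`), or for `mode = "partial"` any table whose genes form the
#'   reference gene set.
#' @param universe Character vector of genes pairs are drawn from; must
#'   cover the candidate genes.
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param mode `"pair"` counts candidates matching a reference pair
#'   (unordered); `"partial"` counts candidates with at least one gene in
#'   the reference gene set.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Object of class `"enrichment_result"`: list with
#'   `observed_overlap`, `null_overlaps` (length `n_perm`), `p`,
#'   `n_permutations`, `n_candidates`, `mode`.
#' @export
permutation_enrichment <- function(candidates, reference, universe,
                                   n_perm = 10000,
                                   mode = c("pair", "partial"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  reference <- as.data.frame(reference, stringsAsFactors = FALSE)
  if (nrow(reference) == 0) stop_("reference pair list is empty")
  if (nrow(candidates) == 0) stop_("candidate pair list is empty")
  if (n_perm < 100) stop_("n_perm must be >= 100")
  universe <- unique(as.character(universe))
  ca <- as.character(candidates[[1]]); cb <- as.character(candidates[[2]])
  miss <- setdiff(c(ca, cb), universe)
  if (length(miss) > 0)
    stop_("universe does not cover candidate gene(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  n_cand <- length(ca)
  if (mode == "pair") {
    ref_keys <- unique(pair_key(as.character(reference[[1]]),
                                as.character(reference[[2]])))
    observed <- sum(pair_key(ca, cb) %in% ref_keys)
    count <- function(a, b) sum(pair_key(a, b) %in% ref_keys)
  } else {
    ref_genes <- unique(c(as.character(reference[[1]]),
                          as.character(reference[[2]])))
    observed <- sum(ca %in% ref_genes | cb %in% ref_genes)
    count <- function(a, b) sum(a %in% ref_genes | b %in% ref_genes)
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      a <- sample(universe, n_cand, replace = TRUE)
      b <- sample(universe, n_cand, replace = TRUE)
      while (any(same <- a == b))  # pairs are of two distinct genes
        b[same] <- sample(universe, sum(same), replace = TRUE)
      count(a, b)
    }, 0L)
  })
  structure(list(observed_overlap = observed, null_overlaps = nulls,
                 p = (sum(nulls >= observed) + 1) / (n_perm + 1),
                 n_permutations = n_perm, n_candidates = n_cand,
                 mode = mode),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment (%s mode): %d/%d candidates overlap reference\n  null mean %.2f over %d permutations; p = %.4g\n",
    x$mode, x$observed_overlap, x$n_candidates, mean(x$null_overlaps),
    x$n_permutations, x$p))
  invisible(x)
}

#' Fisher enrichment of a functional gene set among paired genes
#'
#' Tabulates the gene universe by membership in the candidate pairs versus
#' membership in a functional gene set and applies the two-tailed Fisher
#' exact test.
#'
#' @param pairs Two-column data frame of candidate pairs.
#' @param geneset Character vector of functional genes.
#' @param universe Character vector of all genes considered.
#' @return List with `odds_ratio` (sample ad/bc), `p`, `table`.
#' @export
geneset_enrichment <- function(pairs, geneset, universe) {
  universe <- unique(as.character(universe))
  geneset <- unique(as.character(geneset))
  if (length(geneset) == 0 || length(universe) == 0)
    stop_("geneset and universe must be nonempty")
  if (length(intersect(geneset, universe)) == 0)
    stop_("geneset is disjoint from the universe")
  pair_genes <- unique(c(as.character(pairs[[1]]), as.character(pairs[[2]])))
  in_pairs <- universe %in% pair_genes
  in_set <- universe %in% geneset
  tab <- matrix(c(sum(in_pairs & in_set), sum(in_pairs & !in_set),
                  sum(!in_pairs & in_set), sum(!in_pairs & !in_set)),
                2, 2, byrow = TRUE,
                dimnames = list(pairs = c("in", "out"),
                                geneset = c("in", "out")))
  list(odds_ratio = sample_odds_ratio(tab), p = fisher_p(tab), table = tab)
}

#' Knock-down dependency test for candidate pairs
#'
#' For each candidate pair and each orientation (knock-down target versus
#' partner), splits the screened cell lines by loss of the partner gene and
#' compares the target's phenotype scores between the partner-lost and
#' partner-intact groups with a Wilcoxon rank-sum test. With the screen's
#' convention that a lower phenotype score means greater dependency, the
#' one-sided alternative `"less"` (default) tests that partner loss
#' increases dependency on the target. Multiple knock-down solutions per
#' gene (duplicate rows of `pheno`) are tested separately.
#'
#' @param pheno Numeric matrix of phenotype scores, rows = knock-down
#'   solutions (row names = gene, duplicates allowed), columns = cell lines.
#' @param pairs Two-column data frame of candidate gene pairs.
#' @param loss Logical (or `"loss"`/`"MUT"` character) matrix, genes x
#'   samples: `TRUE` where the gene is lost (low expression, mutated or
#'   deleted, per the caller's label source).
#' @param alternative Wilcoxon alternative for the loss group (default
#'   `"less"`: lower scores, i.e. greater dependency, under partner loss).
#' @param p_threshold Significance flag cut (default 0.05).
#' @return Data frame with one row per (target solution, partner)
#'   orientation: `target_gene`, `partner_gene`, `solution`, `n_lost`,
#'   `n_intact`, `p`, `significant`, `skipped`, `reason`.
#' @export
dependency_test <- function(pheno, pairs, loss,
                            alternative = c("less", "greater", "two.sided"),
                            p_threshold = 0.05) {
  alternative <- match.arg(alternative)
  if (is.character(loss)) {
    loss <- matrix(loss %in% c("loss", "MUT", "low", "TRUE"),
                   nrow(loss), ncol(loss), dimnames = dimnames(loss))
  }
  samples <- intersect(colnames(pheno), colnames(loss))
  if (length(samples) == 0)
    stop_("empty sample intersection between phenotype and loss data")
  rows <- list()
  add <- function(target, partner, solution, n_lost, n_intact, p,
                  skipped, reason) {
    rows[[length(rows) + 1]] <<- data.frame(
      target_gene = target, partner_gene = partner, solution = solution,
      n_lost = n_lost, n_intact = n_intact, p = p,
      significant = !skipped && !is.na(p) && p < p_threshold,
      skipped = skipped, reason = reason, stringsAsFactors = FALSE)
  }
  test_orientation <- function(target, partner) {
    sol_rows <- which(rownames(pheno) == target)
    if (length(sol_rows) == 0) {
      add(target, partner, NA_integer_, 0L, 0L, NA_real_, TRUE,
          "target not in phenotype data")
      return(invisible())
    }
    if (!partner %in% rownames(loss)) {
      add(target, partner, NA_integer_, 0L, 0L, NA_real_, TRUE,
          "partner not in loss data")
      return(invisible())
    }
    lost <- loss[partner, samples]
    for (r in sol_rows) {
      sc <- pheno[r, samples]
      ok <- is.finite(sc)
      s_lost <- sc[ok & lost]; s_int <- sc[ok & !lost]
      if (length(s_lost) == 0) {
        add(target, partner, r, 0L, length(s_int), NA_real_, TRUE,
            "no loss samples")
      } else if (length(s_int) == 0) {
        add(target, partner, r, length(s_lost), 0L, NA_real_, TRUE,
            "no intact samples")
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(s_lost, s_int,
                             alternative = alternative)$p.value)
        add(target, partner, r, length(s_lost), length(s_int), p,
            FALSE, "")
      }
    }
  }
  for (i in seq_len(nrow(pairs))) {
    a <- as.character(pairs[[1]][i]); b <- as.character(pairs[[2]][i])
    test_orientation(a, b)
    test_orientation(b, a)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
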