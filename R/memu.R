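# Genetic-only workflow: mutually exclusive mutation calls between gene
# pairs, tested with the two-tailed Fisher exact test.

#' Filter a mutation matrix by population mutation rate
#'
#' Retains genes whose `MUT` fraction is at least `min_rate` (inclusive,
#' default 5%).
#'
#' @param m `"WT"`/`"MUT"` matrix, genes x samples.
#' @param min_rate Minimum MUT fraction in `(0, 1]`.
#' @return The filtered matrix (possibly zero rows, with a warning).
#' @export
mutation_rate_filter <- function(m, min_rate = 0.05) {
  if (!is.numeric(min_rate) || length(min_rate) != 1 ||
      min_rate <= 0 || min_rate > 1)
    stop_("min_rate must be in (0, 1]")
  keep <- rowMeans(m == "MUT") >= min_rate
  if (!any(keep)) warn_("no genes reach mutation rate %.3f", min_rate)
  m[keep, , drop = FALSE]
}

#' Fisher exact test for mutual exclusivity of two binary loss profiles
#'
#' Builds the 2x2 table `[both-MUT, a-only; b-only, both-WT]` and tests it
#' with the two-tailed Fisher exact test. On this orientation mutual
#' exclusivity depresses the both-MUT cell, driving the sample odds ratio
#' `(both-MUT * both-WT) / (a-only * b-only)` toward 0, while co-occurrence
#' drives it above 1. Conventions: a zero numerator gives `odds_ratio = 0`;
#' a zero denominator with nonzero numerator gives `+Inf`. Degenerate
#' margins (e.g. one gene all-WT) carry no exclusivity information and are
#' returned flagged with `p = 1`, `odds_ratio = 1`.
#'
#' @param a,b Logical (or 0/1) vectors of equal length >= 2; `TRUE` = MUT.
#' @return List with `odds_ratio`, `p`, `table` (2x2 counts), `degenerate`.
#' @export
fisher_exclusivity <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b) || length(a) < 2)
    stop_("a and b must have equal length >= 2")
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE,
                dimnames = list(a = c("MUT", "WT"), b = c("MUT", "WT")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  list(odds_ratio = if (degenerate) 1 else sample_odds_ratio(tab),
       p = fisher_p(tab),
       table = tab,
       degenerate = degenerate)
}

#' Mine a mutation matrix for mutually exclusive gene pairs
#'
#' Tests every unordered pair of genes passing the mutation-rate filter with
#' [fisher_exclusivity()], applies Benjamini-Hochberg FDR over all tested
#' pairs, and keeps pairs with `odds_ratio < or_threshold`,
#' `p < p_threshold` and `q < q_threshold`. Pairs with no exclusive calls at
#' all (both off-diagonal cells zero) carry no exclusivity signal and are
#' excluded before testing. Gene order within a pair is canonical
#' (lexicographic), so the output is invariant to the input row order.
#'
#' @param m `"WT"`/`"MUT"` matrix, genes x samples.
#' @param min_rate Mutation-rate filter (default 0.05, inclusive).
#' @param or_threshold Odds-ratio cut, `odds_ratio < or_threshold`
#'   (default 2.5) on the both-MUT orientation of [fisher_exclusivity()].
#' @param p_threshold Fisher p cut (default 0.05).
#' @param q_threshold BH FDR cut (default 0.1).
#' @param keep_all Return every tested pair with a `pass` column instead of
#'   only the passing pairs (diagnostics / null calibration).
#' @return Data frame of class `c("memu_pairs", "data.frame")`, ranked by
#'   `p` ascending, with columns `gene_a`, `gene_b`, `n_both_mut`,
#'   `n_a_only`, `n_b_only`, `n_both_wt`, `odds_ratio`, `p`, `q`
#'   (and `pass` when `keep_all = TRUE`).
#' @export
memu <- function(m, min_rate = 0.05, or_threshold = 2.5,
                 p_threshold = 0.05, q_threshold = 0.1, keep_all = FALSE) {
  m <- mutation_rate_filter(m, min_rate)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      n_both_mut = integer(0), n_a_only = integer(0),
                      n_b_only = integer(0), n_both_wt = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("memu_pairs", "data.frame")
  if (nrow(m) < 2) {
    warn_("fewer than 2 genes after the mutation-rate filter")
    return(empty)
  }
  mut <- m == "MUT"
  mut <- mut[order(rownames(mut)), , drop = FALSE]  # canonical pair order
  genes <- rownames(mut)
  idx <- utils::combn(length(genes), 2)
  n11 <- integer(ncol(idx)); n10 <- integer(ncol(idx))
  n01 <- integer(ncol(idx)); n00 <- integer(ncol(idx))
  or <- numeric(ncol(idx)); p <- numeric(ncol(idx))
  tested <- logical(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    a <- mut[idx[1, k], ]; b <- mut[idx[2, k], ]
    n11[k] <- sum(a & b); n10[k] <- sum(a & !b)
    n01[k] <- sum(!a & b); n00[k] <- sum(!a & !b)
    if (n10[k] == 0 && n01[k] == 0) next  # no exclusivity signal possible
    tested[k] <- TRUE
    ft <- fisher_exclusivity(a, b)
    or[k] <- ft$odds_ratio; p[k] <- ft$p
  }
  out <- data.frame(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
                    n_both_mut = n11, n_a_only = n10, n_b_only = n01,
                    n_both_wt = n00, odds_ratio = or, p = p,
                    stringsAsFactors = FALSE)[tested, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$pass <- out$odds_ratio < or_threshold & out$p < p_threshold &
    out$q < q_threshold
  out <- out[order(out$p, out$gene_a, out$gene_b), , drop = FALSE]
  if (!keep_all) {
    out <- out[out$pass, , drop = FALSE]
    out$pass <- NULL
  }
  rownames(out) <- NULL
  class(out) <- c("memu_pairs", "data.frame")
  out
}
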