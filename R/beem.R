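# Integrated-genomic workflow: mutation calls enriched in (or exclusive to)
# the high expression mode of a bimodal partner gene.

#' Test bimodal genes against mutation profiles for high-mode enrichment
#'
#' For every (bimodal expression gene, mutation gene) pair over the sample
#' intersection of the two matrices, counts MUT/WT calls inside the low and
#' high expression modes (window samples excluded from both) and tests
#' enrichment of MUT in the high mode with a one-sided Fisher exact test.
#' Pairs are retained when `p < p_threshold` and the mutation frequency in
#' the high mode exceeds that in the low mode; the liberal default
#' `p_threshold = 0.25` maximizes inclusion of mutually exclusive pairs
#' whose low expression mode is small. A pair is flagged `exclusive` when
#' the low mode contains no MUT call at all. No multiple-testing adjustment
#' is applied; confidence is deferred to downstream validation.
#'
#' @param fit A `"bisep"` object from [bisep()] on the expression matrix.
#' @param mut `"WT"`/`"MUT"` matrix, genes x samples; samples must intersect
#'   the expression samples.
#' @param min_mut_rate Population frequency filter applied to the mutation
#'   genes over the intersected samples (default 0.05).
#' @param p_threshold Retention cut on the Fisher p (default 0.25).
#' @param alternative `"greater"` (default) tests one-sided enrichment of
#'   MUT in the high mode; `"two.sided"` is available for symmetric use.
#' @param keep_all Return every tested pair with a `pass` column
#'   (diagnostics / null calibration).
#' @return Data frame of class `c("beem_pairs", "data.frame")`, ranked by
#'   `p` ascending, with columns `expr_gene`, `mut_gene`, `n_high_mut`,
#'   `n_high_wt`, `n_low_mut`, `n_low_wt`, `freq_mut_high`, `freq_mut_low`,
#'   `p`, `exclusive` (and `pass` when `keep_all = TRUE`).
#' @export
beem <- function(fit, mut, min_mut_rate = 0.05, p_threshold = 0.25,
                 alternative = c("greater", "two.sided"), keep_all = FALSE) {
  stopifnot(inherits(fit, "bisep"))
  alternative <- match.arg(alternative)
  samples <- intersect(colnames(fit$expr), colnames(mut))
  if (length(samples) == 0)
    stop_("empty sample intersection between expression and mutation data")
  mut <- mutation_rate_filter(mut[, samples, drop = FALSE], min_mut_rate)
  empty <- data.frame(expr_gene = character(0), mut_gene = character(0),
                      n_high_mut = integer(0), n_high_wt = integer(0),
                      n_low_mut = integer(0), n_low_wt = integer(0),
                      freq_mut_high = numeric(0), freq_mut_low = numeric(0),
                      p = numeric(0), exclusive = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("beem_pairs", "data.frame")
  expr_genes <- bimodal_genes(fit)
  if (length(expr_genes) == 0 || nrow(mut) == 0) {
    warn_("no bimodal expression genes or no mutation genes to test")
    return(empty)
  }
  labs <- fit$labels[expr_genes, samples, drop = FALSE]
  is_mut <- mut == "MUT"
  rows <- vector("list", length(expr_genes) * nrow(mut))
  k <- 0L
  for (i in seq_along(expr_genes)) {
    hi <- labs[i, ] == "high"
    lo <- labs[i, ] == "low"
    for (j in seq_len(nrow(mut))) {
      if (expr_genes[i] == rownames(mut)[j]) next  # self-pair
      mj <- is_mut[j, ]
      tab <- matrix(c(sum(hi & mj), sum(hi & !mj),
                      sum(lo & mj), sum(lo & !mj)),
                    2, 2, byrow = TRUE)
      nh <- sum(tab[1, ]); nl <- sum(tab[2, ])
      if (nh == 0 || nl == 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        expr_gene = expr_genes[i], mut_gene = rownames(mut)[j],
        n_high_mut = tab[1, 1], n_high_wt = tab[1, 2],
        n_low_mut = tab[2, 1], n_low_wt = tab[2, 2],
        freq_mut_high = tab[1, 1] / nh,
        freq_mut_low = tab[2, 1] / nl,
        p = fisher_p(tab, alternative),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(k)])
  out$exclusive <- out$n_low_mut == 0L & out$n_high_mut > 0L
  out$pass <- out$p < p_threshold & out$freq_mut_high > out$freq_mut_low
  out <- out[order(out$p, out$expr_gene, out$mut_gene), , drop = FALSE]
  if (!keep_all) {
    out <- out[out$pass, , drop = FALSE]
    out$pass <- NULL
  }
  rownames(out) <- NULL
  class(out) <- c("beem_pairs", "data.frame")
  out
}
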