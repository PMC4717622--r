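# Expression-only workflow: bimodal gene pairs (almost) never low together,
# ranked by a separation score.

#' Mine bimodal genes for mutually exclusive low expression
#'
#' Evaluates every unordered pair of genes passing the bimodality filter.
#' Each gene's midpoint partitions samples into low/high quadrants (window
#' samples stay unassigned and are excluded from the denominator); pairs in
#' which fewer than `max_low_low` of the samples classifiable for both genes
#' are low-low are retained as candidate synthetic lethal. Admission is the
#' exclusivity rule itself; the score only ranks. The score is the plain sum
#' of both genes' minority-mode proportion, bimodality index and
#' standardized separation:
#' `S = pi_x + pi_y + BI_x + BI_y + delta_x + delta_y`
#' (`pi` taken as `min(pi, 1 - pi)` so that better balance and wider
#' separation both increase S).
#'
#' @param fit A `"bisep"` object from [bisep()].
#' @param max_low_low Maximum tolerated fraction of doubly-low samples
#'   (default 0.01, strict `<`).
#' @return Data frame of class `c("bigee_pairs", "data.frame")`, ranked by
#'   `s_score` descending (ties lexicographic), with quadrant counts
#'   (`n_low_low`, `n_low_high`, `n_high_low`, `n_high_high`),
#'   `n_classifiable`, `frac_low_low`, the six score components and
#'   `s_score`. Gene order within a pair is canonical (lexicographic).
#' @export
bigee <- function(fit, max_low_low = 0.01) {
  stopifnot(inherits(fit, "bisep"))
  if (!is.numeric(max_low_low) || max_low_low <= 0 || max_low_low > 1)
    stop_("max_low_low must be in (0, 1]")
  empty <- data.frame(gene_x = character(0), gene_y = character(0),
                      n_low_low = integer(0), n_low_high = integer(0),
                      n_high_low = integer(0), n_high_high = integer(0),
                      n_classifiable = integer(0), frac_low_low = numeric(0),
                      pi_x = numeric(0), pi_y = numeric(0),
                      bi_x = numeric(0), bi_y = numeric(0),
                      delta_x = numeric(0), delta_y = numeric(0),
                      s_score = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("bigee_pairs", "data.frame")
  genes <- sort(bimodal_genes(fit))
  if (length(genes) < 2) {
    warn_("fewer than 2 bimodal genes; nothing to pair")
    return(empty)
  }
  stats_df <- fit$fits[match(genes, fit$fits$gene), ]
  labs <- fit$labels[genes, , drop = FALSE]
  low <- labs == "low"
  high <- labs == "high"
  idx <- utils::combn(length(genes), 2)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    cls <- (low[i, ] | high[i, ]) & (low[j, ] | high[j, ])
    n_cls <- sum(cls)
    if (n_cls == 0) next
    ll <- sum(low[i, ] & low[j, ])
    if (ll / n_cls >= max_low_low) next
    pim_i <- min(stats_df$pi[i], 1 - stats_df$pi[i])
    pim_j <- min(stats_df$pi[j], 1 - stats_df$pi[j])
    rows[[k]] <- data.frame(
      gene_x = genes[i], gene_y = genes[j],
      n_low_low = ll,
      n_low_high = sum(low[i, ] & high[j, ] & cls),
      n_high_low = sum(high[i, ] & low[j, ] & cls),
      n_high_high = sum(high[i, ] & high[j, ] & cls),
      n_classifiable = n_cls,
      frac_low_low = ll / n_cls,
      pi_x = pim_i, pi_y = pim_j,
      bi_x = stats_df$bi[i], bi_y = stats_df$bi[j],
      delta_x = stats_df$delta[i], delta_y = stats_df$delta[j],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$s_score <- out$pi_x + out$pi_y + out$bi_x + out$bi_y +
    out$delta_x + out$delta_y
  out <- out[order(-out$s_score, out$gene_x, out$gene_y), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bigee_pairs", "data.frame")
  out
}
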