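# Diagnostic plots: per-gene expression density with the midpoint call,
# paired expression scatter with midpoint crosshairs, and a mutation
# overlay on a bimodal partner's distribution.

#' Plot one gene's expression density with its midpoint
#'
#' @param x A `"bisep"` object.
#' @param gene Gene to plot (any gene present in the input matrix).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.bisep <- function(x, gene, ...) {
  if (missing(gene)) gene <- bimodal_genes(x)[1]
  if (!gene %in% rownames(x$expr)) stop_("gene %s not in matrix", gene)
  v <- x$expr[gene, ]
  d <- stats::density(v)
  row <- x$fits[x$fits$gene == gene, ]
  graphics::plot(d, main = sprintf("%s (BI = %.2f, delta = %.2f)",
                                   gene, row$bi, row$delta),
                 xlab = "log2 expression", ...)
  graphics::rug(v)
  if (is.finite(row$midpoint))
    graphics::abline(v = row$midpoint, lty = 2, col = "firebrick")
  invisible(x)
}

#' Scatter plot of a candidate pair with midpoint crosshairs
#'
#' The four quadrants around the crosshairs are the low/high mode
#' combinations; a mutually exclusive pair has an empty low-low quadrant.
#'
#' @param fit A `"bisep"` object.
#' @param gene_x,gene_y The pair to plot (must both pass the filter).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `fit`.
#' @export
plot_pair_expression <- function(fit, gene_x, gene_y, ...) {
  stopifnot(inherits(fit, "bisep"))
  for (g in c(gene_x, gene_y))
    if (!g %in% rownames(fit$expr)) stop_("gene %s not in matrix", g)
  vx <- fit$expr[gene_x, ]; vy <- fit$expr[gene_y, ]
  graphics::plot(vx, vy, xlab = gene_x, ylab = gene_y,
                 main = sprintf("%s vs %s", gene_x, gene_y), pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  mx <- fit$fits$midpoint[fit$fits$gene == gene_x]
  my <- fit$fits$midpoint[fit$fits$gene == gene_y]
  graphics::abline(v = mx, h = my, lty = 2, col = "firebrick")
  invisible(fit)
}

#' Expression density of a bimodal gene with mutated samples marked
#'
#' Visualizes an integrated-genomic candidate: the partner's MUT samples
#' should sit in the high expression mode.
#'
#' @param fit A `"bisep"` object.
#' @param mut `"WT"`/`"MUT"` matrix.
#' @param expr_gene Bimodal expression gene.
#' @param mut_gene Mutation partner gene.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `fit`.
#' @export
plot_mutation_overlay <- function(fit, mut, expr_gene, mut_gene, ...) {
  stopifnot(inherits(fit, "bisep"))
  samples <- intersect(colnames(fit$expr), colnames(mut))
  v <- fit$expr[expr_gene, samples]
  is_mut <- mut[mut_gene, samples] == "MUT"
  d <- stats::density(v)
  graphics::plot(d, main = sprintf("%s expression, %s mutation",
                                   expr_gene, mut_gene),
                 xlab = "log2 expression", ...)
  graphics::rug(v[!is_mut], col = "grey50")
  graphics::rug(v[is_mut], col = "black", lwd = 2)
  mid <- fit$fits$midpoint[fit$fits$gene == expr_gene]
  if (length(mid) == 1 && is.finite(mid))
    graphics::abline(v = mid, lty = 2, col = "firebrick")
  invisible(fit)
}
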