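# Synthetic multi-omic data with planted ground truth. Expression values are
# drawn from the same distributional families the detection model assumes
# (one Gaussian for unimodal genes, a two-component Gaussian mixture for
# bimodal genes), with an optional heavy-tail contamination fraction to
# stress the midpoint search's tail-exclusion band. Planted synthetic-lethal
# structure realizes each workflow's exclusivity pattern exactly:
# disjoint low-mode sample sets (expression-expression), MUT calls confined
# to a partner's high mode (expression-mutation), and disjoint MUT sample
# sets (mutation-mutation). All randomness flows from one explicit seed.

#' Generate an expression matrix with known bimodal structure
#'
#' Unimodal genes draw from one Gaussian with mean uniform on
#' `baseline_range`; bimodal genes draw from a two-component mixture with
#' low-mode weight `pi ~ U(pi_range)`, standardized separation
#' `delta ~ U(delta_range)` and shared within-mode `sigma`, so
#' `mu_high = mu_low + delta * sigma`. Per-sample mode membership is
#' recorded as ground truth.
#'
#' @param n_genes Total genes (default 500).
#' @param n_samples Samples (default 300).
#' @param n_bimodal Number of bimodal genes (default 50; must be
#'   `<= n_genes`).
#' @param delta_range,pi_range Ranges for the true separation and low-mode
#'   weight (defaults `[4, 12]` and `[0.2, 0.5]`).
#' @param sigma Shared within-mode standard deviation in log2 units
#'   (default 0.4, a typical within-mode spread for normalized array data).
#' @param baseline_range Range of unimodal means / bimodal low-mode means
#'   (default `[3, 9]` log2 units).
#' @param contamination Fraction of values replaced by heavy-tailed
#'   (scaled t, 3 df) outliers (default 0).
#' @param seed Optional integer seed.
#' @return List with `expr` (matrix, genes x samples) and `truth`: list with
#'   `bimodal` (data frame `gene`, `mu_low`, `mu_high`, `sigma`, `pi`,
#'   `midpoint`), `low_membership` (logical matrix bimodal genes x samples,
#'   `TRUE` = low mode), `params`, `seed`.
#' @export
generate_expression <- function(n_genes = 500, n_samples = 300,
                                n_bimodal = 50,
                                delta_range = c(4, 12),
                                pi_range = c(0.2, 0.5),
                                sigma = 0.4, baseline_range = c(3, 9),
                                contamination = 0, seed = NULL) {
  if (n_bimodal > n_genes) stop_("n_bimodal must be <= n_genes")
  if (diff(range(delta_range)) < 0 || diff(range(pi_range)) < 0 ||
      length(delta_range) != 2 || length(pi_range) != 2)
    stop_("delta_range and pi_range must be length-2 ranges")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- sprintf("s%03d", seq_len(n_samples))
    expr <- matrix(NA_real_, n_genes, n_samples,
                   dimnames = list(genes, samples))
    bidx <- seq_len(n_bimodal)
    mu_low <- stats::runif(n_bimodal, baseline_range[1], baseline_range[2])
    pi_true <- stats::runif(n_bimodal, pi_range[1], pi_range[2])
    delta_true <- stats::runif(n_bimodal, delta_range[1], delta_range[2])
    mu_high <- mu_low + delta_true * sigma
    membership <- matrix(FALSE, n_bimodal, n_samples,
                         dimnames = list(genes[bidx], samples))
    for (i in bidx) {
      lowmode <- stats::runif(n_samples) < pi_true[i]
      # keep both modes populated so the planted pair is well-defined
      if (!any(lowmode)) lowmode[sample.int(n_samples, 1)] <- TRUE
      if (all(lowmode)) lowmode[sample.int(n_samples, 1)] <- FALSE
      membership[i, ] <- lowmode
      expr[i, ] <- stats::rnorm(n_samples,
                                ifelse(lowmode, mu_low[i], mu_high[i]),
                                sigma)
    }
    if (n_genes > n_bimodal) {
      uni <- (n_bimodal + 1):n_genes
      mu_uni <- stats::runif(length(uni), baseline_range[1],
                             baseline_range[2])
      for (k in seq_along(uni))
        expr[uni[k], ] <- stats::rnorm(n_samples, mu_uni[k], sigma)
    }
    if (contamination > 0) {
      n_out <- round(contamination * length(expr))
      pos <- sample.int(length(expr), n_out)
      expr[pos] <- expr[pos] + sigma * stats::rt(n_out, df = 3) * 3
    }
    truth <- list(
      bimodal = data.frame(gene = genes[bidx], mu_low = mu_low,
                           mu_high = mu_high,
                           sigma = rep(sigma, n_bimodal), pi = pi_true,
                           midpoint = (mu_low + mu_high) / 2,
                           stringsAsFactors = FALSE),
      low_membership = membership,
      params = list(n_genes = n_genes, n_samples = n_samples,
                    n_bimodal = n_bimodal, delta_range = delta_range,
                    pi_range = pi_range, sigma = sigma,
                    baseline_range = baseline_range,
                    contamination = contamination),
      seed = seed)
    list(expr = expr, truth = truth)
  })
}

#' Plant a mutually exclusive loss pair into a synthetic dataset
#'
#' Rewrites the relevant rows of a dataset from [generate_sl_dataset()] (or
#' a compatible list) so that one gene pair carries the exclusivity
#' structure of a chosen mechanism:
#' * `"expression-expression"`: both genes' low-mode sample sets are
#'   redrawn disjoint (and their expression re-simulated), so no sample is
#'   low in both;
#' * `"expression-mutation"`: the mutation gene's MUT calls are confined to
#'   the high mode of the bimodal partner, at `mut_rate` within that mode;
#' * `"mutation-mutation"`: both genes' MUT sample sets are redrawn at
#'   `mut_rate` each over disjoint samples.
#' The planted pair is appended to `dataset$truth$pairs`.
#'
#' @param dataset List with `expr`, `mut`, `truth` as built by
#'   [generate_sl_dataset()].
#' @param mechanism One of the three mechanism tags above.
#' @param genes Length-2 character vector naming the two genes (expression
#'   gene first for `"expression-mutation"`).
#' @param pi_pair For `"expression-expression"`: the two low-mode fractions
#'   (their sum must be < 1 to host disjoint low sets).
#' @param mut_rate MUT fraction used by the mutation-bearing mechanisms
#'   (default 0.2; for two disjoint mutation genes `2 * mut_rate` must be
#'   <= 1).
#' @param seed Optional integer seed.
#' @return The updated dataset.
#' @export
plant_exclusive_pair <- function(dataset,
                                 mechanism = c("expression-expression",
                                               "expression-mutation",
                                               "mutation-mutation"),
                                 genes, pi_pair = c(0.3, 0.3),
                                 mut_rate = 0.2, seed = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(genes) == 2)
  with_seed(seed, {
    n <- ncol(dataset$expr)
    samples <- colnames(dataset$expr)
    tr <- dataset$truth
    if (mechanism == "expression-expression") {
      if (sum(pi_pair) >= 1)
        stop_("requested low fractions sum to >= 1; cannot be disjoint")
      bi <- tr$bimodal
      ridx <- match(genes, bi$gene)
      if (anyNA(ridx)) stop_("genes must be planted bimodal genes")
      n1 <- max(1L, round(pi_pair[1] * n))
      n2 <- max(1L, round(pi_pair[2] * n))
      ord <- sample.int(n)
      low1 <- logical(n); low1[ord[seq_len(n1)]] <- TRUE
      low2 <- logical(n); low2[ord[n1 + seq_len(n2)]] <- TRUE
      for (k in 1:2) {
        g <- genes[k]
        i <- ridx[k]
        lowmode <- if (k == 1) low1 else low2
        tr$bimodal$pi[i] <- mean(lowmode)
        tr$low_membership[g, ] <- lowmode
        dataset$expr[g, ] <- stats::rnorm(
          n, ifelse(lowmode, bi$mu_low[i], bi$mu_high[i]), bi$sigma[i])
      }
    } else if (mechanism == "expression-mutation") {
      eg <- genes[1]; mg <- genes[2]
      if (!eg %in% rownames(tr$low_membership))
        stop_("expression gene must be a planted bimodal gene")
      high <- !tr$low_membership[eg, ]
      calls <- rep("WT", n)
      hit <- which(high)[stats::runif(sum(high)) < mut_rate]
      if (length(hit) == 0) hit <- which(high)[1]
      calls[hit] <- "MUT"
      dataset$mut <- upsert_row(dataset$mut, mg, calls, samples)
    } else {
      if (2 * mut_rate > 1)
        stop_("requested loss fractions sum to > 1; cannot be disjoint")
      m <- max(1L, round(mut_rate * n))
      ord <- sample.int(n)
      for (k in 1:2) {
        calls <- rep("WT", n)
        calls[ord[(k - 1) * m + seq_len(m)]] <- "MUT"
        dataset$mut <- upsert_row(dataset$mut, genes[k], calls, samples)
      }
    }
    pair <- data.frame(gene_a = genes[1], gene_b = genes[2],
                       mechanism = mechanism, stringsAsFactors = FALSE)
    tr$pairs <- rbind(tr$pairs, pair)
    dataset$truth <- tr
    dataset
  })
}

upsert_row <- function(m, gene, values, samples) {
  if (is.null(m)) {
    m <- matrix(values, 1, length(samples),
                dimnames = list(gene, samples))
  } else if (gene %in% rownames(m)) {
    m[gene, ] <- values
  } else {
    m <- rbind(m, matrix(values, 1, ncol(m),
                         dimnames = list(gene, colnames(m))))
  }
  m
}

#' Generate a full synthetic multi-omic dataset with planted pairs
#'
#' Builds an expression matrix via [generate_expression()], a background
#' mutation matrix of independent genes, and plants `n_pairs` mutually
#' exclusive pairs per mechanism via [plant_exclusive_pair()].
#'
#' @inheritParams generate_expression
#' @param n_pairs Planted pairs per mechanism (default 5).
#' @param n_mut_genes Background mutation genes (default 60).
#' @param mut_rate_range Range of independent background MUT rates
#'   (default `[0.02, 0.15]`).
#' @param planted_mut_rate MUT rate of planted mutation genes (default 0.2).
#' @param seed Optional integer seed.
#' @return List with `expr`, `mut`, `truth` (as in [generate_expression()],
#'   plus `truth$pairs`: data frame `gene_a`, `gene_b`, `mechanism`).
#' @export
generate_sl_dataset <- function(n_genes = 500, n_samples = 300,
                                n_bimodal = 50, n_pairs = 5,
                                n_mut_genes = 60,
                                mut_rate_range = c(0.02, 0.15),
                                planted_mut_rate = 0.2,
                                delta_range = c(4, 12),
                                pi_range = c(0.2, 0.5), sigma = 0.4,
                                contamination = 0, seed = NULL) {
  if (3 * n_pairs > n_bimodal)
    stop_("need n_bimodal >= 3 * n_pairs bimodal genes to host the planted pairs")
  with_seed(seed, {
    gen <- generate_expression(n_genes = n_genes, n_samples = n_samples,
                               n_bimodal = n_bimodal,
                               delta_range = delta_range,
                               pi_range = pi_range, sigma = sigma,
                               contamination = contamination)
    samples <- colnames(gen$expr)
    mut_genes <- sprintf("m%04d", seq_len(n_mut_genes))
    rates <- stats::runif(n_mut_genes, mut_rate_range[1], mut_rate_range[2])
    mut <- matrix("WT", n_mut_genes, n_samples,
                  dimnames = list(mut_genes, samples))
    for (j in seq_len(n_mut_genes))
      mut[j, stats::runif(n_samples) < rates[j]] <- "MUT"
    ds <- list(expr = gen$expr, mut = mut, truth = gen$truth)
    ds$truth$pairs <- data.frame(gene_a = character(0),
                                 gene_b = character(0),
                                 mechanism = character(0),
                                 stringsAsFactors = FALSE)
    bg <- ds$truth$bimodal$gene
    ee_genes <- bg[seq_len(2 * n_pairs)]
    em_genes <- bg[2 * n_pairs + seq_len(n_pairs)]
    for (k in seq_len(n_pairs)) {
      ds <- plant_exclusive_pair(
        ds, "expression-expression",
        genes = ee_genes[c(2 * k - 1, 2 * k)],
        pi_pair = stats::runif(2, 0.2, 0.45))
    }
    for (k in seq_len(n_pairs)) {
      ds <- plant_exclusive_pair(
        ds, "expression-mutation",
        genes = c(em_genes[k], sprintf("pm%03d", k)),
        mut_rate = 0.3)
    }
    for (k in seq_len(n_pairs)) {
      ds <- plant_exclusive_pair(
        ds, "mutation-mutation",
        genes = sprintf("pp%03d_%d", k, 1:2),
        mut_rate = planted_mut_rate)
    }
    ds
  })
}

#' Generate an ontology fixture with known branch structure
#'
#' Builds a rooted `is_a` tree of the given depth and branching factor,
#' annotates genes to leaf terms, and records which gene pairs share a
#' branch (children of the same depth-1 subtree) versus sit on disjoint
#' branches. Shared-branch pairs must score strictly higher functional
#' redundancy than disjoint-branch pairs.
#'
#' @param depth Tree depth (>= 2; root = depth 0).
#' @param branching Children per internal term (default 2).
#' @param n_genes Genes to annotate (default 16; assigned round-robin to
#'   leaves).
#' @param seed Optional integer seed (annotation assignment).
#' @return List with `graph` (an [ontology_graph()]), `annotation` (data
#'   frame `gene`, `term`, `aspect = NA`), and `truth` (data frame
#'   `gene_a`, `gene_b`, `type` in `same_branch`/`disjoint_branch`).
#' @export
generate_ontology_fixture <- function(depth = 3, branching = 2,
                                      n_genes = 16, seed = NULL) {
  if (depth < 2) stop_("depth must be >= 2")
  with_seed(seed, {
    counter <- 0L
    new_term <- function() {
      counter <<- counter + 1L
      sprintf("T%04d", counter)
    }
    root <- new_term()
    child <- character(0); parent <- character(0)
    level <- list(root)
    branch_of <- stats::setNames(character(0), character(0))
    for (d in seq_len(depth)) {
      nxt <- list()
      for (p in unlist(level)) {
        for (b in seq_len(branching)) {
          t <- new_term()
          child <- c(child, t); parent <- c(parent, p)
          branch_of[t] <- if (d == 1) t else branch_of[[p]]
          nxt <- c(nxt, t)
        }
      }
      level <- nxt
    }
    leaves <- unlist(level)
    g <- ontology_graph(c(root, child),
                        data.frame(child = child, parent = parent,
                                   relation = "is_a",
                                   stringsAsFactors = FALSE))
    genes <- sprintf("gene%02d", seq_len(n_genes))
    leaf_for <- leaves[(seq_len(n_genes) - 1) %% length(leaves) + 1]
    annotation <- data.frame(gene = genes, term = leaf_for,
                             aspect = rep(NA_character_, n_genes),
                             stringsAsFactors = FALSE)
    truth <- data.frame(gene_a = character(0), gene_b = character(0),
                        type = character(0), stringsAsFactors = FALSE)
    if (n_genes >= 2) {
      pairs <- utils::combn(n_genes, 2)
      same <- branch_of[leaf_for[pairs[1, ]]] ==
        branch_of[leaf_for[pairs[2, ]]]
      truth <- data.frame(gene_a = genes[pairs[1, ]],
                          gene_b = genes[pairs[2, ]],
                          type = ifelse(same, "same_branch",
                                        "disjoint_branch"),
                          stringsAsFactors = FALSE)
    }
    list(graph = g, annotation = annotation, truth = truth)
  })
}

#' Write a synthetic dataset's files to a directory
#'
#' Emits `expression.tsv`, `mutations.tsv`, `go.obo`, `anno.tsv` and
#' `truth.json` so every workflow can be exercised from files alone.
#'
#' @param dataset Result of [generate_sl_dataset()].
#' @param dir Output directory (created if needed).
#' @param ontology Optional result of [generate_ontology_fixture()].
#' @return `dir`, invisibly.
#' @export
write_sl_dataset <- function(dataset, dir, ontology = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(dataset$expr, file.path(dir, "expression.tsv"))
  write_matrix(dataset$mut, file.path(dir, "mutations.tsv"))
  if (!is.null(ontology)) {
    write_obo(ontology$graph, file.path(dir, "go.obo"))
    utils::write.table(ontology$annotation[, c("gene", "term")],
                       file.path(dir, "anno.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  truth <- dataset$truth
  truth$low_membership <- NULL  # large; pairs + bimodal table suffice
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
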