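# Readers, writers and deterministic preprocessing for the matrices the
# toolkit consumes: log2 expression (genes x samples), discrete WT/MUT
# mutation calls and loss/normal copy-number calls, all tab-delimited with
# genes as rows and a header row of sample identifiers.

validate_ids <- function(ids, what, path = NULL) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop_("duplicate %s identifier(s): %s%s", what,
          paste(utils::head(dup, 5), collapse = ", "),
          if (is.null(path)) "" else paste0(" in ", path))
  invisible(ids)
}

read_table_raw <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (file.size(path) == 0) stop_("parse error: empty file %s", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop_("parse error: %s has no data rows or no sample columns", path)
  genes <- as.character(df[[1]])
  samples <- colnames(df)[-1]
  validate_ids(genes, "gene", path)
  validate_ids(samples, "sample", path)
  list(genes = genes, samples = samples, body = df[, -1, drop = FALSE])
}

#' Read a log2 gene-by-sample expression matrix
#'
#' Expects tab-delimited text with gene identifiers in the first column and a
#' header row of sample identifiers. Row and column order are preserved;
#' duplicate identifiers and non-numeric cells are fatal errors that name the
#' offending gene/sample.
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default tab).
#' @return A numeric matrix (genes x samples) in log2 units with gene row
#'   names and sample column names.
#' @seealso [rescale_expression()], [read_mutation_matrix()]
#' @export
read_expression <- function(path, delimiter = "\t") {
  raw <- read_table_raw(path, delimiter)
  body <- raw$body
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(raw$genes, raw$samples))
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0)
      stop_("non-numeric value '%s' at gene %s, sample %s in %s",
            col[bad[1]], raw$genes[bad[1]], raw$samples[j], path)
    if (anyNA(num))
      stop_("missing value at gene %s, sample %s in %s",
            raw$genes[which(is.na(num))[1]], raw$samples[j], path)
    m[, j] <- num
  }
  if (ncol(m) < 2) stop_("expression matrix needs at least 2 samples")
  m
}

read_discrete_matrix <- function(path, levels, delimiter = "\t") {
  raw <- read_table_raw(path, delimiter)
  m <- as.matrix(raw$body)
  dimnames(m) <- list(raw$genes, raw$samples)
  bad <- which(!m %in% levels)
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop_("invalid call '%s' at gene %s, sample %s (expected one of: %s)",
          m[bad[1]], raw$genes[rc[1]], raw$samples[rc[2]],
          paste(levels, collapse = ", "))
  }
  m
}

#' Read a discrete WT/MUT mutation-call matrix
#'
#' @inheritParams read_expression
#' @return Character matrix of `"WT"`/`"MUT"` calls, genes x samples.
#' @export
read_mutation_matrix <- function(path, delimiter = "\t") {
  read_discrete_matrix(path, c("WT", "MUT"), delimiter)
}

#' Read a discrete loss/normal copy-number call matrix
#'
#' @inheritParams read_expression
#' @return Character matrix of `"loss"`/`"normal"` calls, genes x samples.
#' @export
read_copy_number <- function(path, delimiter = "\t") {
  read_discrete_matrix(path, c("loss", "normal"), delimiter)
}

#' Write a gene-by-sample matrix as tab-delimited text
#'
#' Inverse of the readers: first column `gene`, header row of sample
#' identifiers, full numeric precision.
#'
#' @param m Matrix with gene row names and sample column names.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = "\t") {
  if (is.numeric(m)) {
    body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                   dimnames = dimnames(m))  # round-trips doubles exactly
  } else {
    body <- m
  }
  df <- data.frame(gene = rownames(m), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rescale an expression matrix to a 1-100 linear dynamic range
#'
#' Unlogs the matrix (`2^x`), affinely maps the global minimum to 1 and the
#' global maximum to 100, and re-logs. The output range is exactly
#' `[0, log2(100)]`. The map is global (one min/max over the whole matrix),
#' preserving cross-gene comparability of the standardized separation
#' thresholds; it is idempotent after the first application.
#'
#' @param m Numeric log2 expression matrix.
#' @return Rescaled log2 matrix with the same dimnames.
#' @export
rescale_expression <- function(m) {
  lin <- 2^m
  mn <- min(lin)
  mx <- max(lin)
  if (!is.finite(mn) || !is.finite(mx) || mx - mn < .Machine$double.eps)
    stop_("degenerate dynamic range: matrix is constant")
  log2(1 + 99 * (lin - mn) / (mx - mn))
}

#' Build a WT/MUT call matrix from a variant table
#'
#' Constructs a discrete mutation matrix from per-variant records. Silent
#' variants are removed; any remaining record marks its (gene, sample) cell
#' `MUT` (idempotently -- repeated records collapse to one call); everything
#' else is `WT`. Zygosity is not retained: any non-silent variant yields a
#' `MUT` call. No frequency filtering happens here; that is the workflows'
#' job (see [mutation_rate_filter()]).
#'
#' @param variants Data frame with columns `gene`, `sample`, `consequence`
#'   (or the names given in `column_map`).
#' @param samples Ordered character vector of sample identifiers defining the
#'   matrix columns. Records naming a sample outside this list are fatal.
#' @param genes Optional gene universe for the rows; defaults to all genes
#'   observed in `variants` (including genes whose only variants are silent,
#'   which come out all-WT).
#' @param silent_labels Consequence values (case-insensitive) treated as
#'   silent and dropped. Default `"silent"`.
#' @param column_map Optional named character vector mapping the expected
#'   column roles to the table's actual names, accommodating MAF dialects,
#'   e.g. `c(gene = "Hugo_Symbol", sample = "Tumor_Sample_Barcode",
#'   consequence = "Variant_Classification")`.
#' @return Character matrix of `"WT"`/`"MUT"` calls, genes x samples.
#' @export
build_mutation_matrix <- function(variants, samples, genes = NULL,
                                  silent_labels = "silent",
                                  column_map = NULL) {
  if (!is.null(column_map)) {
    for (role in names(column_map)) {
      if (!column_map[[role]] %in% names(variants))
        stop_("column '%s' (mapped to role '%s') not in variant table",
              column_map[[role]], role)
      names(variants)[names(variants) == column_map[[role]]] <- role
    }
  }
  need <- c("gene", "sample", "consequence")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0)
    stop_("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  validate_ids(samples, "sample")
  bad <- setdiff(unique(as.character(variants$sample)), samples)
  if (length(bad) > 0)
    stop_("variant record names sample(s) absent from the sample list: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(as.character(variants$gene)))
  validate_ids(genes, "gene")
  keep <- !(tolower(as.character(variants$consequence)) %in%
              tolower(silent_labels))
  v <- variants[keep, , drop = FALSE]
  m <- matrix("WT", length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(v) > 0) {
    gi <- match(as.character(v$gene), genes)
    if (anyNA(gi))
      stop_("variant record names gene(s) absent from the gene list: %s",
            paste(utils::head(unique(v$gene[is.na(gi)]), 5), collapse = ", "))
    m[cbind(gi, match(as.character(v$sample), samples))] <- "MUT"
  }
  m
}

#' Merge copy-number loss calls into a mutation matrix
#'
#' A cell of the merged matrix is `MUT` iff the gene is mutated and/or shows
#' copy-number loss in that sample (element-wise OR). Gene and sample
#' universes are intersected before merging: samples or genes lacking either
#' data type carry no combined loss-of-function information.
#'
#' @param mut `"WT"`/`"MUT"` matrix from [read_mutation_matrix()] or
#'   [build_mutation_matrix()].
#' @param cn `"loss"`/`"normal"` matrix from [read_copy_number()].
#' @return Merged `"WT"`/`"MUT"` matrix over the intersected universes.
#' @export
merge_copy_number <- function(mut, cn) {
  samples <- intersect(colnames(mut), colnames(cn))
  if (length(samples) == 0)
    stop_("empty sample intersection between mutation and copy-number data")
  genes <- intersect(rownames(mut), rownames(cn))
  if (length(genes) == 0)
    stop_("empty gene intersection between mutation and copy-number data")
  lost <- mut[genes, samples, drop = FALSE] == "MUT" |
    cn[genes, samples, drop = FALSE] == "loss"
  out <- matrix(ifelse(lost, "MUT", "WT"), length(genes), length(samples),
                dimnames = list(genes, samples))
  out
}
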