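# Ontology plumbing: a minimal OBO 1.2 reader/writer and gene-to-term
# annotation readers (two-column TSV or GAF 2.x). The term graph is a DAG of
# is_a / part_of links with per-relation contribution weights used by the
# semantic-similarity scorer.

#' Construct an ontology term graph
#'
#' @param terms Character vector of term identifiers.
#' @param edges Data frame with columns `child`, `parent`, `relation`
#'   (values among the names of `weights`). Endpoints absent from `terms`
#'   are added.
#' @param weights Named numeric contribution factors per relation type.
#' @return Object of class `"ontology_graph"`: list with `terms`, `edges`
#'   (with a `weight` column) and `parents` (per-term lookup).
#' @export
ontology_graph <- function(terms, edges,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  terms <- unique(as.character(terms))
  if (nrow(edges) > 0) {
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    bad <- setdiff(unique(edges$relation), names(weights))
    if (length(bad) > 0)
      stop_("unknown relation type(s): %s", paste(bad, collapse = ", "))
    edges$weight <- unname(weights[edges$relation])
    terms <- unique(c(terms, edges$child, edges$parent))
  } else {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), weight = numeric(0),
                        stringsAsFactors = FALSE)
  }
  g <- structure(list(terms = terms, edges = edges,
                      parents = split(edges[c("parent", "weight")],
                                      factor(edges$child, levels = terms))),
                 class = "ontology_graph")
  assert_acyclic(g)
  g
}

# Kahn's algorithm; cycles make ancestor weights ill-defined.
assert_acyclic <- function(g) {
  if (nrow(g$edges) == 0) return(invisible(TRUE))
  out_deg <- table(factor(g$edges$child, levels = g$terms))
  incoming <- split(g$edges$child, factor(g$edges$parent, levels = g$terms))
  queue <- g$terms[out_deg == 0]   # terms with no parents pending? (sinks)
  seen <- 0L
  deg <- as.integer(out_deg); names(deg) <- g$terms
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (c in incoming[[t]]) {
      deg[c] <- deg[c] - 1L
      if (deg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(g$terms))
    stop_("ontology graph contains a cycle")
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("Ontology graph: %d terms, %d edges (%s)\n",
              length(x$terms), nrow(x$edges),
              paste(unique(x$edges$relation), collapse = ", ")))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas for `id`, `is_a` and `relationship: part_of`
#' lines. Obsolete terms are dropped. Edge targets without their own stanza
#' are kept as bare terms.
#'
#' @param path Path to the OBO file.
#' @param weights Contribution factors per relation type.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  child <- character(0); parent <- character(0); relation <- character(0)
  cur <- NULL; in_term <- FALSE; obsolete <- FALSE
  cur_edges <- list()
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      for (e in cur_edges) {
        child <<- c(child, cur); parent <<- c(parent, e[2])
        relation <<- c(relation, e[1])
      }
    }
  }
  strip <- function(x) sub("\\s*!.*$", "", trimws(x))
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL; cur_edges <- list(); obsolete <- FALSE
      in_term <- identical(trimws(ln), "[Term]")
    } else if (in_term) {
      if (grepl("^id:", ln)) cur <- strip(sub("^id:", "", ln))
      else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
      else if (grepl("^is_a:", ln))
        cur_edges <- c(cur_edges, list(c("is_a", strip(sub("^is_a:", "", ln)))))
      else if (grepl("^relationship:\\s*part_of\\s", ln))
        cur_edges <- c(cur_edges,
                       list(c("part_of",
                              strip(sub("^relationship:\\s*part_of\\s", "", ln)))))
    }
  }
  flush()
  if (length(terms) == 0) stop_("no [Term] stanzas found in %s", path)
  ontology_graph(terms,
                 data.frame(child = child, parent = parent,
                            relation = relation, stringsAsFactors = FALSE),
                 weights = weights)
}

#' Write an ontology graph as a minimal OBO 1.2 file
#'
#' @param g An [ontology_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in g$terms) {
    writeLines(c("[Term]", paste("id:", t)), con)
    e <- g$edges[g$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (e$relation[i] == "is_a")
        writeLines(paste("is_a:", e$parent[i]), con)
      else
        writeLines(paste("relationship:", e$relation[i], e$parent[i]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' Two formats: `"tsv"` -- two columns (gene, term), optional third column
#' with the ontology aspect; `"gaf"` -- GAF 2.x, using columns 2 (gene
#' symbol), 5 (term) and 9 (aspect), skipping `!` comment lines.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return Data frame with columns `gene`, `term`, `aspect` (`NA` when
#'   absent), one row per annotation.
#' @export
read_annotation <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^!", lines) & nzchar(lines)]
    if (length(lines) == 0) stop_("no annotation rows in %s", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, 0L) < 9
    if (any(short)) stop_("GAF row with fewer than 9 columns in %s", path)
    ann <- data.frame(gene = vapply(parts, `[[`, "", 2),
                      term = vapply(parts, `[[`, "", 5),
                      aspect = vapply(parts, `[[`, "", 9),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (ncol(df) < 2) stop_("annotation TSV needs at least 2 columns")
    ann <- data.frame(gene = as.character(df[[1]]),
                      term = as.character(df[[2]]),
                      aspect = if (ncol(df) >= 3) as.character(df[[3]])
                               else NA_character_,
                      stringsAsFactors = FALSE)
  }
  unique(ann)
}

#' Drop annotations to terms missing from the ontology
#'
#' @param ann Annotation data frame from [read_annotation()].
#' @param g An [ontology_graph()].
#' @return The pruned annotation data frame (warns about dropped terms).
#' @export
prune_annotation <- function(ann, g) {
  unknown <- !(ann$term %in% g$terms)
  if (any(unknown)) {
    warn_("dropping %d annotation(s) to term(s) absent from the ontology: %s",
          sum(unknown),
          paste(utils::head(unique(ann$term[unknown]), 5), collapse = ", "))
    ann <- ann[!unknown, , drop = FALSE]
  }
  ann
}
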