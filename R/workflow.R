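# End-to-end workflow runner: wires the module stages in their canonical
# order (expression: bisep -> bigee -> fure; genomic: bisep -> beem -> fure;
# genetic: memu -> fure), validates the configuration up front, and writes
# deterministic tab-delimited outputs plus a provenance manifest.

workflow_config_keys <- c(
  "workflow", "expr", "mut", "cn", "obo", "anno", "annotation_format",
  "preset", "bi_min", "delta_min", "tail_exclusion",
  "min_mut_rate", "min_rate", "or_threshold", "p_threshold", "q_threshold",
  "max_low_low", "min_similarity", "out_dir", "seed")

#' Validate a workflow configuration
#'
#' Checks the key set (unknown keys are rejected), the workflow selector,
#' and that every input file the selected workflow needs exists -- before
#' any computation.
#'
#' @param config Named list; see [run_workflow()] for the keys.
#' @return The config with defaults filled in.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), workflow_config_keys)
  if (length(unknown) > 0)
    stop_("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$workflow) ||
      !config$workflow %in% c("expression", "genomic", "genetic"))
    stop_("config$workflow must be one of expression, genomic, genetic")
  need <- switch(config$workflow,
                 expression = "expr",
                 genomic = c("expr", "mut"),
                 genetic = "mut")
  for (k in need) {
    if (is.null(config[[k]]))
      stop_("workflow '%s' requires config$%s", config$workflow, k)
    if (!file.exists(config[[k]]))
      stop_("input file for '%s' not found: %s", k, config[[k]])
  }
  for (k in c("cn", "obo", "anno"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop_("input file for '%s' not found: %s", k, config[[k]])
  if (!is.null(config$obo) != !is.null(config$anno))
    stop_("functional redundancy needs both obo and anno")
  defaults <- list(preset = "cell_line", tail_exclusion = 0.1,
                   min_mut_rate = 0.05, min_rate = 0.05,
                   or_threshold = 2.5, p_threshold = NULL,
                   q_threshold = 0.1, max_low_low = 0.01,
                   annotation_format = "tsv",
                   out_dir = ".", seed = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  config
}

#' Run a synthetic-lethality mining workflow end to end
#'
#' Executes the selected workflow's stages in order and writes `pairs.tsv`
#' (the candidate pair table), `bimodal_fits.tsv` (for the expression-based
#' workflows) and `manifest.json` (package version, full parameter set,
#' seed, input checksums) into `out_dir`. Identical config and inputs give
#' identical outputs. If a stage fails, partial outputs are removed and the
#' error names the failing stage.
#'
#' @param config Named list: `workflow` (`"expression"`, `"genomic"` or
#'   `"genetic"`); input paths `expr`, `mut`, `cn` (optional copy-number
#'   calls merged into the mutation matrix), `obo` + `anno` (optional
#'   ontology and annotation for the redundancy score),
#'   `annotation_format`; threshold parameters `preset` or
#'   `bi_min`/`delta_min`, `tail_exclusion`, `min_mut_rate`, `min_rate`,
#'   `or_threshold`, `p_threshold`, `q_threshold`, `max_low_low`,
#'   `min_similarity`; `out_dir`; `seed`.
#' @return Invisibly, a list with the stage outputs (`bisep`, `pairs`) and
#'   the manifest.
#' @export
run_workflow <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_files <- file.path(out_dir,
                         c("pairs.tsv", "bimodal_fits.tsv", "manifest.json"))
  stage <- "setup"
  result <- tryCatch({
    inputs <- Filter(Negate(is.null),
                     config[c("expr", "mut", "cn", "obo", "anno")])
    checksums <- vapply(inputs, function(p) unname(tools::md5sum(p)), "")
    fit <- NULL
    mut <- NULL
    if (!is.null(config$mut)) {
      stage <- "read mutation data"
      mut <- read_mutation_matrix(config$mut)
      if (!is.null(config$cn))
        mut <- merge_copy_number(mut, read_copy_number(config$cn))
    }
    if (config$workflow %in% c("expression", "genomic")) {
      stage <- "bisep"
      expr <- read_expression(config$expr)
      fit <- if (is.null(config$bi_min))
        bisep(expr, preset = config$preset,
              tail_exclusion = config$tail_exclusion)
      else
        bisep(expr, bi_min = config$bi_min, delta_min = config$delta_min,
              tail_exclusion = config$tail_exclusion)
    }
    pairs <- switch(
      config$workflow,
      expression = {
        stage <- "bigee"
        bigee(fit, max_low_low = config$max_low_low)
      },
      genomic = {
        stage <- "beem"
        beem(fit, mut, min_mut_rate = config$min_mut_rate,
             p_threshold = if (is.null(config$p_threshold)) 0.25
                           else config$p_threshold)
      },
      genetic = {
        stage <- "memu"
        memu(mut, min_rate = config$min_rate,
             or_threshold = config$or_threshold,
             p_threshold = if (is.null(config$p_threshold)) 0.05
                           else config$p_threshold,
             q_threshold = config$q_threshold)
      })
    if (!is.null(config$obo) && nrow(pairs) > 0) {
      stage <- "fure"
      g <- read_obo(config$obo)
      ann <- read_annotation(config$anno, format = config$annotation_format)
      pairs <- fure(pairs, ann, g, min_similarity = config$min_similarity)
    }
    stage <- "write outputs"
    utils::write.table(pairs, out_files[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(fit))
      utils::write.table(fit$fits, out_files[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    manifest <- list(
      package = "synlethal",
      version = as.character(utils::packageVersion("synlethal")),
      workflow = config$workflow,
      parameters = config[setdiff(names(config),
                                  c("expr", "mut", "cn", "obo", "anno"))],
      inputs = as.list(checksums),
      n_pairs = nrow(pairs))
    jsonlite::write_json(manifest, out_files[3], auto_unbox = TRUE,
                         pretty = TRUE)
    list(bisep = fit, pairs = pairs, manifest = manifest)
  }, error = function(e) {
    unlink(out_files)
    stop_("workflow failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}
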