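fixture_dir <- function(seed = 120) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ds <- generate_sl_dataset(n_genes = 60, n_samples = 120, n_bimodal = 12,
                            n_pairs = 2, n_mut_genes = 15, seed = seed)
  ont <- generate_ontology_fixture(n_genes = 0, seed = seed)
  # annotate the planted genes so fure has something to score
  genes <- unique(c(ds$truth$pairs$gene_a, ds$truth$pairs$gene_b))
  leaves <- setdiff(ont$graph$terms, ont$graph$edges$parent)
  ont$annotation <- data.frame(
    gene = genes, term = leaves[(seq_along(genes) - 1) %% length(leaves) + 1],
    aspect = NA_character_)
  write_sl_dataset(ds, dir, ontology = ont)
  list(dir = dir, ds = ds)
}

test_that("configs with unknown keys or missing inputs fail before compute", {
  expect_error(validate_config(list(workflow = "expression",
                                    exprs = "typo.tsv")), "unknown")
  expect_error(validate_config(list(workflow = "teleport")), "workflow")
  expect_error(validate_config(list(workflow = "genomic",
                                    expr = "absent.tsv",
                                    mut = "absent.tsv")), "not found|requires")
})

plain <- function(d) {
  d <- as.data.frame(d)
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}

test_that("each workflow runs end to end and equals manual composition", {
  fx <- fixture_dir()
  out <- withr::local_tempdir()
  # expression workflow
  res <- run_workflow(list(workflow = "expression",
                           expr = file.path(fx$dir, "expression.tsv"),
                           obo = file.path(fx$dir, "go.obo"),
                           anno = file.path(fx$dir, "anno.tsv"),
                           out_dir = file.path(out, "expr")))
  manual <- bigee(bisep(read_expression(file.path(fx$dir, "expression.tsv")),
                        preset = "cell_line"))
  expect_equal(plain(res$pairs[names(manual)]), plain(manual))
  expect_true("similarity" %in% names(res$pairs))
  planted <- fx$ds$truth$pairs
  ee <- planted[planted$mechanism == "expression-expression", ]
  keys <- paste(pmin(res$pairs$gene_x, res$pairs$gene_y),
                pmax(res$pairs$gene_x, res$pairs$gene_y))
  expect_true(all(paste(pmin(ee$gene_a, ee$gene_b),
                        pmax(ee$gene_a, ee$gene_b)) %in% keys))
  # genomic workflow
  res2 <- run_workflow(list(workflow = "genomic",
                            expr = file.path(fx$dir, "expression.tsv"),
                            mut = file.path(fx$dir, "mutations.tsv"),
                            out_dir = file.path(out, "gen")))
  manual2 <- beem(bisep(read_expression(file.path(fx$dir, "expression.tsv")),
                        preset = "cell_line"),
                  read_mutation_matrix(file.path(fx$dir, "mutations.tsv")))
  expect_equal(plain(res2$pairs), plain(manual2))
  # genetic workflow
  res3 <- run_workflow(list(workflow = "genetic",
                            mut = file.path(fx$dir, "mutations.tsv"),
                            out_dir = file.path(out, "mut")))
  manual3 <- memu(read_mutation_matrix(file.path(fx$dir, "mutations.tsv")))
  expect_equal(plain(res3$pairs), plain(manual3))
  # manifest written with provenance
  man <- jsonlite::read_json(file.path(out, "expr", "manifest.json"))
  expect_equal(man$workflow, "expression")
  expect_true(all(c("expr", "obo", "anno") %in% names(man$inputs)))
})

test_that("reruns produce byte-identical outputs", {
  fx <- fixture_dir(seed = 121)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- list(workflow = "expression",
              expr = file.path(fx$dir, "expression.tsv"))
  run_workflow(c(cfg, out_dir = out1))
  run_workflow(c(cfg, out_dir = out2))
  expect_identical(readLines(file.path(out1, "pairs.tsv")),
                   readLines(file.path(out2, "pairs.tsv")))
})

test_that("stage failures remove partial outputs and name the stage", {
  fx <- fixture_dir(seed = 122)
  out <- withr::local_tempdir()
  bad_mut <- file.path(fx$dir, "bad_mut.tsv")
  writeLines(c("gene\ts1\ts2", "g1\tMUT\tMUT"), bad_mut)  # disjoint samples
  expect_error(run_workflow(list(workflow = "genomic",
                                 expr = file.path(fx$dir, "expression.tsv"),
                                 mut = bad_mut, out_dir = out)),
               "beem")
  expect_false(file.exists(file.path(out, "pairs.tsv")))
})

test_that("the command-line front end reports its version", {
  script <- system.file("scripts", "synlethal.R", package = "synlethal")
  expect_true(nzchar(script))
  out <- suppressWarnings(system2("Rscript", c(script, "version"),
                                  stdout = TRUE, stderr = TRUE))
  expect_true(any(grepl("synlethal", out)))
})

test_that("plot helpers run on a fitted screen", {
  expr <- tiny_expr()
  fit <- bisep(expr, preset = "cell_line")
  mut <- matrix("WT", 1, ncol(expr),
                dimnames = list("partner", colnames(expr)))
  mut[1, 30:40] <- "MUT"
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_no_error(plot(fit, gene = "bimA"))
  expect_no_error(plot_pair_expression(fit, "bimA", "bimB"))
  expect_no_error(plot_mutation_overlay(fit, mut, "bimA", "partner"))
})
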