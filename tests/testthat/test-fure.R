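test_that("term similarity reproduces hand-propagated values on the chain", {
  g <- chain_ontology()
  # S(A) = {A:1, root:0.8}; S(B) = {B:1, A:0.8, root:0.64}
  # shared = {A, root}: (1 + 0.8) + (0.8 + 0.64) over 1.8 + 2.44
  expect_equal(term_similarity("A", "B", g), 3.24 / 4.24, tolerance = 1e-9)
  expect_equal(term_similarity("A", "A", g), 1)
  expect_equal(term_similarity("B", "A", g), term_similarity("A", "B", g))
  expect_error(term_similarity("A", "missing", g), "missing")
})

test_that("disconnected terms score zero", {
  g <- ontology_graph(c("r1", "r2", "a", "b"),
                      data.frame(child = c("a", "b"),
                                 parent = c("r1", "r2"),
                                 relation = "is_a"))
  expect_equal(term_similarity("a", "b", g), 0)
})

test_that("cyclic term graphs are rejected", {
  expect_error(
    ontology_graph(c("a", "b"),
                   data.frame(child = c("a", "b"), parent = c("b", "a"),
                              relation = "is_a")),
    "cycle")
})

test_that("gene similarity combines terms by best-match average", {
  g <- chain_ontology()
  ann <- data.frame(gene = c("x", "y", "y"), term = c("A", "A", "B"),
                    aspect = NA_character_)
  sc <- gene_pair_similarity("x", "y", ann, g)
  expect_equal(sc$similarity, (1 + 1 + 3.24 / 4.24) / 3, tolerance = 1e-9)
  # symmetry
  sc2 <- gene_pair_similarity("y", "x", ann, g)
  expect_equal(sc2$similarity, sc$similarity)
  # identical annotation sets score exactly 1
  ann2 <- data.frame(gene = c("x", "y"), term = c("B", "B"),
                     aspect = NA_character_)
  expect_equal(gene_pair_similarity("x", "y", ann2, g)$similarity, 1)
  # unannotated gene: missing, not zero
  expect_true(is.na(gene_pair_similarity("x", "z", ann, g)$similarity))
})

test_that("adding a shared term never decreases the score", {
  fx <- generate_ontology_fixture(depth = 3, branching = 2, n_genes = 8,
                                  seed = 90)
  g <- fx$graph
  ann <- fx$annotation
  pair <- fx$truth[1, ]
  base <- gene_pair_similarity(pair$gene_a, pair$gene_b, ann, g)$similarity
  shared_term <- g$terms[2]
  ann_plus <- rbind(ann,
                    data.frame(gene = c(pair$gene_a, pair$gene_b),
                               term = shared_term, aspect = NA_character_))
  plus <- gene_pair_similarity(pair$gene_a, pair$gene_b, ann_plus,
                               g)$similarity
  expect_gte(plus + 1e-12, base)
})

test_that("same-branch pairs outscore disjoint-branch pairs", {
  fx <- generate_ontology_fixture(depth = 3, branching = 2, n_genes = 12,
                                  seed = 91)
  sims <- vapply(seq_len(nrow(fx$truth)), function(i)
    gene_pair_similarity(fx$truth$gene_a[i], fx$truth$gene_b[i],
                         fx$annotation, fx$graph)$similarity, 0)
  same <- sims[fx$truth$type == "same_branch"]
  disj <- sims[fx$truth$type == "disjoint_branch"]
  expect_gt(min(same), max(disj))
})

test_that("annotating a pair list preserves rows and ranking", {
  g <- chain_ontology()
  ann <- data.frame(gene = c("g1", "g2", "g3"), term = c("A", "B", "A"),
                    aspect = NA_character_)
  pairs <- data.frame(gene_a = c("g1", "g2", "g1"),
                      gene_b = c("g2", "g3", "unknown"),
                      p = c(0.01, 0.02, 0.03))
  out <- fure(pairs, ann, g)
  expect_equal(nrow(out), 3)
  expect_equal(out$p, pairs$p)              # ranking untouched
  expect_true(is.na(out$similarity[3]))     # unannotated gene kept as NA
  expect_equal(out$similarity[1], 3.24 / 4.24, tolerance = 1e-9)
  # similarity floor drops low-scoring pairs but keeps NA
  flo <- fure(pairs, ann, g, min_similarity = 0.9)
  expect_identical(flo$gene_b, "unknown")
})

test_that("OBO files and annotations round-trip through the parsers", {
  fx <- generate_ontology_fixture(depth = 3, branching = 2, n_genes = 6,
                                  seed = 92)
  obo <- withr::local_tempfile(fileext = ".obo")
  write_obo(fx$graph, obo)
  g2 <- read_obo(obo)
  expect_setequal(g2$terms, fx$graph$terms)
  expect_equal(nrow(g2$edges), nrow(fx$graph$edges))
  # similarity identical after the round trip
  t2 <- fx$graph$edges$child[1:2]
  expect_equal(term_similarity(t2[1], t2[2], g2),
               term_similarity(t2[1], t2[2], fx$graph))
  # GAF parsing picks columns 2, 5 and 9
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "BRCA1", "", "", "T0002", "", "", "", "P",
                     "", "", "", "", "", "", "", "", sep = "\t")), gaf)
  ann <- read_annotation(gaf, format = "gaf")
  expect_equal(ann$gene, "BRCA1")
  expect_equal(ann$term, "T0002")
  expect_equal(ann$aspect, "P")
})

test_that("part_of edges use their own contribution weight", {
  g <- ontology_graph(c("root", "A"),
                      data.frame(child = "A", parent = "root",
                                 relation = "part_of"))
  # S(A) = {A:1, root:0.6}; S(root) = {root:1}
  expect_equal(term_similarity("A", "root", g), (0.6 + 1) / (1.6 + 1))
})

test_that("unknown annotation terms are dropped with a warning", {
  g <- chain_ontology()
  ann <- data.frame(gene = "x", term = c("A", "GONE"),
                    aspect = NA_character_)
  expect_warning(pruned <- prune_annotation(ann, g), "GONE")
  expect_equal(pruned$term, "A")
})
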