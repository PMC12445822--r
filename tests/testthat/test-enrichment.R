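# Ontology parsing, annotation propagation, contingency construction and
# the one-sided Fisher engine.

write_obo <- function(stanzas) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}

test_that("OBO parsing loads terms and is_a edges", {
  path <- write_obo(c(
    "[Term]", "id: A", "name: a", "is_a: B ! b", "",
    "[Term]", "id: B", "name: b", "is_a: C ! c", "",
    "[Term]", "id: C", "name: c"))
  dag <- parse_obo(path)
  expect_setequal(term_ancestors(dag, "A"), c("B", "C"))

  path <- write_obo(c(
    "[Term]", "id: A", "is_a: B", "is_a: C", "",
    "[Term]", "id: B", "", "[Term]", "id: C"))
  expect_setequal(term_ancestors(parse_obo(path), "A"), c("B", "C"))

  expect_error(parse_obo(write_obo(c("[Term]", "id: A", "is_a: B"))),
               "undeclared")
  expect_error(parse_obo(write_obo(c(
    "[Term]", "id: A", "is_a: B", "",
    "[Term]", "id: B", "is_a: A"))), "cycle")
  expect_error(parse_obo(write_obo(c("[Term]", "id: A", "= garbage ="))),
               "line")
})

test_that("packaged ontology ancestor sets equal the closure oracle", {
  dag <- parse_obo(extdata("go_synthetic.obo"))
  expect_equal(nrow(dag$terms), 30L)
  for (id in dag$terms$id) {
    expect_identical(sort(term_ancestors(dag, id)),
                     closure_oracle(dag$parents, id),
                     info = id)
  }
})

test_that("BRITE htext maps D-level KOs to their C-level pathways", {
  path <- tempfile(fileext = ".keg")
  writeLines(c("A09100 Metabolism",
               "B  09101 Carbohydrate metabolism",
               "C    00010 Glycolysis [PATH:ko00010]",
               "D      K00844  HK; hexokinase",
               "D      K01810  GPI; isomerase"), path)
  ph <- parse_kegg_htext(path)
  expect_equal(nrow(ph$ko2pathway), 2L)
  expect_true(all(ph$ko2pathway$pathway_id == "ko00010"))

  ph <- parse_kegg_htext(extdata("ko00001_synthetic.keg"))
  # hand-built expectations from the fixture
  expect_setequal(
    ph$ko2pathway$pathway_id[ph$ko2pathway$ko == "K03283"],
    c("ko03018", "ko04141", "ko04213"))
  expect_setequal(
    ph$ko2pathway$pathway_id[ph$ko2pathway$ko == "K01623"],
    c("ko00010", "ko00020"))
  expect_equal(sum(ph$ko2pathway$pathway_id == "ko00020"), 9L)
  expect_true(all(ph$pathways$pathway_id %in%
                  c("ko00010", "ko00020", "ko00190", "ko03018",
                    "ko04141", "ko04213")))
  expect_warning(parse_kegg_htext(
    {p <- tempfile(); writeLines(c("A09 x", "D      K00001  orphan"), p); p}),
    "no enclosing")
})

test_that("annotation propagation follows is_a closure per gene", {
  dag <- parse_obo(write_obo(c(
    "[Term]", "id: A", "is_a: B", "", "[Term]", "id: B")))
  ann <- data.frame(gene = "g1", term = "A")
  out <- propagate_annotations(ann, dag)
  expect_setequal(out$term, c("A", "B"))

  expect_identical(propagate_annotations(ann, dag, propagate = FALSE)$term,
                   "A")

  dag <- parse_obo(extdata("go_synthetic.obo"))
  set.seed(5)
  ids <- dag$terms$id[!dag$terms$obsolete]
  ann <- data.frame(gene = rep(sprintf("g%d", 1:10), each = 2),
                    term = sample(ids, 20, replace = TRUE))
  out <- propagate_annotations(ann, dag)
  for (g in unique(ann$gene)) {
    direct <- unique(ann$term[ann$gene == g])
    want <- sort(unique(c(direct, unlist(lapply(direct, closure_oracle,
                                                parents = dag$parents)))))
    expect_identical(sort(out$term[out$gene == g]), want, info = g)
  }

  expect_warning(propagate_annotations(
    data.frame(gene = "g", term = c("GO:0000002", "NOPE")), dag),
    "unknown")
})

test_that("contingency tables partition study and background", {
  genes <- sprintf("g%03d", 1:100)
  ann <- data.frame(gene = genes[1:10], term = "T1")
  study <- c(genes[1:5], genes[11:15])
  tab <- build_contingency("T1", study, genes, ann)
  expect_identical(unclass(tab)[c("a", "b", "c", "d")],
                   c(a = 5L, b = 5L, c = 5L, d = 85L))

  tab <- build_contingency("T1", genes, genes, ann)  # study = background
  expect_equal(unname(tab["c"]), 0L)
  expect_equal(unname(tab["d"]), 0L)

  tab <- build_contingency("T9", study, genes, ann)  # empty term
  expect_equal(unname(tab["a"]), 0L)
  expect_equal(unname(tab["c"]), 0L)

  expect_error(build_contingency("T1", c(study, "zz"), genes, ann),
               "outside background")
})

test_that("one-sided Fisher p-values are exact", {
  expect_identical(fisher_exact_greater(0L, 10L, 5L, 85L), 1)

  # closed form: study of 3 drawn entirely from a term of 3 in N = 20
  p <- fisher_exact_greater(3L, 0L, 0L, 17L)
  expect_equal(p, 1 / choose(20, 3), tolerance = 1e-12)

  # (5,5,5,85) against direct tail enumeration
  enum <- sum(sapply(5:10, function(x) {
    choose(10, x) * choose(90, 10 - x) / choose(100, 10)
  }))
  expect_equal(fisher_exact_greater(5L, 5L, 5L, 85L), enum,
               tolerance = 1e-12)

  # agreement with stats::fisher.test on random tables
  set.seed(21)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(20:200, 1), runif(4)))
    p1 <- fisher_exact_greater(cells[1], cells[2], cells[3], cells[4])
    p2 <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(p1, p2, tolerance = 1e-9)
  }

  # monotone non-increasing in a with fixed margins
  K <- 15L; n <- 20L; N <- 120L
  p <- fisher_exact_greater(0:15, n - 0:15, K - 0:15,
                            N - n - K + 0:15)
  expect_true(all(diff(p) <= 1e-12))

  # log-space stability at large N
  p <- fisher_exact_greater(50L, 950L, 500L, 998500L)
  expect_true(is.finite(p) && p > 0 && p < 1)
})

test_that("fold enrichment is 1 when study and background proportions match", {
  genes <- sprintf("g%d", 1:100)
  ann <- data.frame(gene = genes[c(1:5, 51:55)], term = "T1")
  res <- run_enrichment(genes[1:50], ann, background_genes = genes)
  expect_equal(res$fold_enrichment[res$term == "T1"], 1)
})

test_that("enrichment recovers a planted term and respects the null", {
  genes <- sprintf("g%04d", 1:1000)
  study <- genes[1:100]
  gen <- generate_annotations(genes, study, n_terms = 20L,
                              planted_term_size = 30L, odds_ratio = 8,
                              seed = 42L)
  res <- run_enrichment(study, gen$annotations, background_genes = genes)
  row <- res[res$term == gen$ledger$planted_term, ]
  expect_true(row$significant)
  expect_gt(row$fold_enrichment, 1)

  # a=0 for all terms except one at fold 1: nothing significant
  ann <- data.frame(gene = c(genes[1], genes[101:110], genes[201:300]),
                    term = c("T1", rep("T2", 10), rep("T3", 100)))
  res <- run_enrichment(genes[1:100], ann, background_genes = genes)
  expect_false(any(res$significant))

  expect_error(run_enrichment(character(0), ann), "empty study")
})

test_that("BH correction and two-sided alternative are available", {
  genes <- sprintf("g%04d", 1:500)
  study <- genes[1:50]
  gen <- generate_annotations(genes, study, n_terms = 10L,
                              planted_term_size = 25L, odds_ratio = 6,
                              seed = 7L)
  res_n <- run_enrichment(study, gen$annotations,
                          background_genes = genes)
  res_bh <- run_enrichment(study, gen$annotations,
                           background_genes = genes, correction = "BH")
  m <- match(res_n$term, res_bh$term)
  expect_true(all(res_bh$p_adjusted[m] >= res_n$p_value - 1e-15))

  res_2s <- run_enrichment(study, gen$annotations,
                           background_genes = genes,
                           alternative = "two.sided")
  i <- which.max(res_2s$a)
  ft <- stats::fisher.test(matrix(c(res_2s$a[i], res_2s$b[i],
                                    res_2s$c[i], res_2s$d[i]),
                                  2, byrow = TRUE))$p.value
  expect_equal(res_2s$p_value[i], ft, tolerance = 1e-9)
})
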