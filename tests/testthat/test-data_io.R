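test_that("PPI reader dedupes, drops self-loops and keeps a load report", {
  f <- write_lines_tmp(c("A\tB", "B\tA", "C\tC", "A\tB"))
  net <- read_ppi_edgelist(f)
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1L)
  rep <- attr(net, "load_report")
  expect_equal(rep$input, rep$kept + rep$self_loop + rep$duplicate + rep$malformed)
  expect_equal(rep$self_loop, 1L)
  expect_equal(rep$duplicate, 2L)
})

test_that("every node of a loaded network has degree >= 1", {
  f <- write_lines_tmp(c("A\tB", "B\tC"))
  net <- read_ppi_edgelist(f)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_true(all(network_degree(net) >= 1L))
})

test_that("malformed edge lines are an error unless tolerant", {
  f <- write_lines_tmp(c("A"))
  expect_error(read_ppi_edgelist(f), "line 1")
  f2 <- write_lines_tmp(c("A", "B\tC"))
  net <- read_ppi_edgelist(f2, tolerant = TRUE)
  expect_equal(attr(net, "load_report")$malformed, 1L)
  expect_setequal(net$nodes, c("B", "C"))
})

test_that("symbols are trimmed and uppercased; empty networks are errors", {
  net <- gene_network(c(" tp53 ", "apc"), c("MDM2", "ctnnb1"))
  expect_setequal(net$nodes, c("TP53", "MDM2", "APC", "CTNNB1"))
  f <- write_lines_tmp(c("A\tA"))
  expect_error(read_ppi_edgelist(f), "empty network")
})

test_that("a written network round-trips to an identical edge set", {
  cfg <- synthetic_config(seed = 7, n_genes = 40)
  net <- generate_network(cfg)
  f <- tempfile(fileext = ".tsv")
  write_gene_network(net, f)
  back <- read_ppi_edgelist(f)
  expect_identical(back$edges, net$edges)
  expect_identical(back$nodes, net$nodes)
})

expr_fixture <- function(values_change = identity) {
  expr <- data.frame(
    gene = c("A", "B", "C"),
    P1_T = c(1, 2, 3), P1_N = c(4, 5, 6),
    P2_T = c(7, 8, 9), P2_N = c(0, 1, 2)
  )
  expr <- values_change(expr)
  man <- data.frame(
    sample_id = c("P1_T", "P1_N", "P2_T", "P2_N"),
    patient_id = c("P1", "P1", "P2", "P2"),
    role = c("tumor", "adjacent", "tumor", "adjacent")
  )
  fe <- tempfile(fileext = ".tsv")
  fm <- tempfile(fileext = ".tsv")
  utils::write.table(expr, fe, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(man, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = fe, manifest = fm)
}

test_that("expression reader validates pairing, signs and duplicates", {
  fx <- expr_fixture()
  et <- read_expression_table(fx$expr, fx$manifest)
  expect_s3_class(et, "expression_table")
  expect_equal(dim(et$values), c(3L, 4L))
  expect_setequal(unique(et$sample_patient), c("P1", "P2"))

  fx2 <- expr_fixture(function(e) { e$P1_T[2] <- -1; e })
  expect_error(read_expression_table(fx2$expr, fx2$manifest), "gene B.*P1_T")

  # a patient with two tumor samples
  fx3 <- expr_fixture()
  man <- utils::read.delim(fx3$manifest)
  man$role[2] <- "tumor"
  utils::write.table(man, fx3$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_expression_table(fx3$expr, fx3$manifest),
    "exactly one tumor"
  )
})

test_that("mutation reader collapses duplicates and enforces the schema", {
  f <- write_lines_tmp(c(
    "sample_id\tgene_symbol", "P1\tTP53", "P1\tTP53", "P1\tAPC"
  ))
  cat_ <- read_mutation_table(f)
  expect_equal(cat_$P1, c("APC", "TP53"))

  f2 <- write_lines_tmp("sample_id\tgene_symbol")
  expect_length(read_mutation_table(f2), 0L)

  f3 <- write_lines_tmp(c("P1\tTP53"))
  expect_error(read_mutation_table(f3), "columns")
})

test_that("GMT reader parses sets and rejects malformed collections", {
  f <- write_lines_tmp(c("S1\tdesc\tA\tB", "S2\tdesc\tC"))
  sets <- read_gmt(f)
  expect_equal(sets$S1, c("A", "B"))
  expect_error(read_gmt(write_lines_tmp(c("S1\td\tA", "S1\td\tB"))), "duplicate")
  expect_error(read_gmt(write_lines_tmp("S1\tdesc")), "malformed")
})

test_that("SIF pathway reader keeps direction and drops self-loops", {
  f <- write_lines_tmp(c("D1\tactivates\tX", "X\tactivates\tD2"), ".sif")
  pw <- read_pathway_sif(f)[[1]]
  expect_equal(pw$edges$from, c("D1", "X"))
  expect_equal(pw$edges$to, c("X", "D2"))

  f2 <- write_lines_tmp("X\tinhibits\tX", ".sif")
  expect_warning(pw2 <- read_pathway_sif(f2)[[1]], "self-loop")
  expect_equal(nrow(pw2$edges), 0L)

  f3 <- write_lines_tmp(character(0), ".sif")
  expect_warning(pw3 <- read_pathway_sif(f3)[[1]], "empty")
  expect_equal(nrow(pw3$edges), 0L)
})

test_that("clinical reader validates stages and subtypes", {
  f <- write_lines_tmp(c(
    "patient_id\tstage\tsubtype", "P1\t2\tCMS1", "P2\tNA\tNA"
  ))
  cl <- read_clinical_table(f)
  expect_equal(cl$stage, c(2L, NA))
  expect_error(
    read_clinical_table(write_lines_tmp(c(
      "patient_id\tstage\tsubtype", "P1\t7\tCMS1"
    ))),
    "stage"
  )
})
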