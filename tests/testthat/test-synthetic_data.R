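test_that("preferential-attachment networks have the predicted size", {
  cfg <- synthetic_config(seed = 1, n_genes = 100, m = 2)
  net <- generate_network(cfg)
  expect_length(net$nodes, 100L)
  expect_equal(nrow(net$edges), choose(3, 2) + 2 * 97) # 197
  expect_length(induced_components(net, net$nodes), 1L) # connected
  # determinism
  net2 <- generate_network(synthetic_config(seed = 1, n_genes = 100, m = 2))
  expect_identical(net$edges, net2$edges)
  expect_error(synthetic_config(n_genes = 5, m = 10), "n_genes")
  expect_error(synthetic_config(n_genes = 20, m = 25), "m must")
})

test_that("noise-free patients follow the planted driver order exactly", {
  cfg <- synthetic_config(seed = 4, p_swap = 0)
  cohort <- generate_cohort(cfg)
  rank0 <- match(cohort$truth$planted_order, cohort$truth$planted_order)
  for (s in cohort$truth$sequences) {
    expect_identical(s, cohort$truth$planted_order[seq_along(s)])
  }
})

test_that("stage bands follow the mutated-prefix quartile rule", {
  cfg <- synthetic_config(seed = 5)
  cohort <- generate_cohort(cfg)
  expect_equal(
    cohort$clinical$stage,
    as.integer(ceiling(4 * cohort$truth$prefix_len / cfg$n_drivers))
  )
  expect_true(all(cohort$clinical$stage %in% 1:4))
  # a prefix of 2 out of 8 drivers sits in the stage-1 band
  expect_equal(unique(cohort$clinical$stage[cohort$truth$prefix_len == 2]), 1L)
})

test_that("passengers live in mutated-driver neighborhoods (module overlap)", {
  cfg <- synthetic_config(seed = 6, n_patients = 6)
  cohort <- generate_cohort(cfg)
  for (p in names(cohort$profiles)) {
    pass <- cohort$truth$passengers[[p]]
    muts <- cohort$truth$sequences[[p]]
    nb <- unique(unlist(cohort$network$adj[muts]))
    expect_true(all(pass %in% nb))
  }
})

test_that("planted correlation structure is realized empirically", {
  rs <- vapply(1:8, function(i) {
    cfg <- synthetic_config(seed = 200 + i, n_patients = 30)
    cohort <- generate_cohort(cfg)
    m <- log_ratio_matrix(cohort$profiles, cohort$network$nodes)
    ac <- abs(stats::cor(t(m[cohort$truth$dnb_genes, ])))
    mean(ac[upper.tri(ac)])
  }, numeric(1))
  expect_gt(mean(rs), 0.65)
  expect_lt(mean(rs), 0.95)
})

test_that("planted group SD inflation separates reaching patients", {
  cfg <- synthetic_config(seed = 13)
  cohort <- generate_cohort(cfg)
  m <- log_ratio_matrix(cohort$profiles, cohort$network$nodes)
  reaches <- cohort$truth$prefix_len >= cfg$k_star
  dnb <- cohort$truth$dnb_genes
  sd_reach <- mean(apply(m[dnb, reaches], 1, sd))
  sd_not <- mean(apply(m[dnb, !reaches], 1, sd))
  expect_gt(sd_reach / sd_not, 1.5)
})

test_that("cohorts are byte-identical for identical configurations", {
  c1 <- generate_cohort(synthetic_config(seed = 8, n_genes = 80, n_patients = 5))
  c2 <- generate_cohort(synthetic_config(seed = 8, n_genes = 80, n_patients = 5))
  expect_identical(c1$network$edges, c2$network$edges)
  expect_identical(c1$truth, c2$truth)
  expect_identical(
    c1$profiles[[3]]$tumor_expr, c2$profiles[[3]]$tumor_expr
  )
})

test_that("infeasible correlation targets are rejected", {
  expect_error(synthetic_config(rho_in = 1.2), "rho_in")
  expect_error(synthetic_config(rho_in = 0.3, rho_out = 0.4), "rho_in > rho_out")
  expect_error(synthetic_config(dnb_size = 1), "dnb_size")
})

test_that("a written cohort reloads through the standard readers", {
  cfg <- synthetic_config(seed = 10, n_genes = 60, n_patients = 4)
  cohort <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(cohort, dir)
  net <- read_ppi_edgelist(file.path(dir, "ppi.tsv"))
  expect_identical(net$edges, cohort$network$edges)
  expr <- read_expression_table(
    file.path(dir, "expr.tsv"), file.path(dir, "manifest.tsv")
  )
  muts <- read_mutation_table(file.path(dir, "mutations.tsv"))
  profs <- cohort_profiles(expr, muts, read_clinical_table(file.path(dir, "clinical.tsv")))
  expect_setequal(names(profs), names(cohort$profiles))
  p <- names(profs)[1]
  expect_equal(
    unname(profs[[p]]$tumor_expr[cohort$network$nodes]),
    unname(cohort$profiles[[p]]$tumor_expr),
    tolerance = 1e-6
  )
  expect_identical(profs[[p]]$mutations, cohort$profiles[[p]]$mutations)
})
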