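test_that("log-ratio entries use pseudo-counted log2 fold changes", {
  profs <- lapply(1:3, function(i) {
    structure(
      list(patient_id = paste0("P", i),
        tumor_expr = c(g1 = 7, g2 = 5, g3 = 0),
        adjacent_expr = c(g1 = 3, g2 = 5, g3 = 0),
        mutations = character(0), stage = NA, subtype = NA
      ),
      class = "patient_profile"
    )
  })
  m <- log_ratio_matrix(profs, c("g1", "g2", "g3", "g4"))
  expect_equal(unname(m["g1", 1]), 1)
  expect_equal(unname(m["g2", 1]), 0)
  expect_equal(unname(m["g3", 1]), 0)
  expect_equal(unname(m["g4", 1]), 0) # missing gene
  expect_error(log_ratio_matrix(profs[1:2], "g1"), ">= 3 patients")
})

test_that("the criticality index reproduces the worked 3x4 example", {
  m <- ci_worked_matrix()
  res <- compute_ci(m, c("g1", "g2"), "g3")
  expect_equal(res$sd_i, (sd(1:4) + sd(c(2, 4, 6, 8))) / 2)
  expect_equal(res$pcc_i, 1)
  expect_equal(res$pcc_o, 0.44721, tolerance = 1e-4)
  expect_equal(res$ci, 8.6603, tolerance = 1e-3)
  # brute-force oracle agrees
  expect_equal(res$ci, ci_bruteforce(m, c("g1", "g2"), "g3"), tolerance = 1e-9)
})

test_that("degenerate groups and the correlation floor behave as specified", {
  m <- rbind(a = rep(1, 4), b = rep(2, 4), c = c(1, 2, 1, 2))
  res <- compute_ci(m, c("a", "b"), "c")
  expect_equal(res$ci, 0) # constant group: SD_i = 0
  # constant background engages the epsilon floor
  m2 <- rbind(a = c(1, 2, 3, 5), b = c(2, 4, 7, 9), c = rep(1, 4))
  res2 <- compute_ci(m2, c("a", "b"), "c")
  expect_true(res2$floor_engaged)
  expect_true(is.finite(res2$ci))
  expect_error(compute_ci(m, "a", "c"), ">= 2 genes")
  expect_error(compute_ci(m, c("a", "b", "c")), "background")
})

test_that("CI scales with the matrix and ignores patient order", {
  set.seed(1)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  g <- c("a", "b", "c")
  base <- compute_ci(m, g)
  scaled <- compute_ci(3 * m, g)
  expect_equal(scaled$ci, 3 * base$ci, tolerance = 1e-9)
  expect_equal(scaled$pcc_i, base$pcc_i, tolerance = 1e-9)
  perm <- compute_ci(m[, c(4, 2, 5, 1, 3)], g)
  expect_equal(perm$ci, base$ci, tolerance = 1e-9)
})

test_that("CI rises with SD_i and PCC_i and falls with PCC_o", {
  set.seed(2)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(letters[1:10], NULL))
  g <- c("a", "b")
  res <- compute_ci(m, g)
  # inflate group variance only
  m_sd <- m
  m_sd[g, ] <- 2 * m_sd[g, ]
  expect_gt(compute_ci(m_sd, g)$ci, res$ci)
  # perfectly correlated group maximizes PCC_i
  m_pc <- m
  m_pc["b", ] <- 2 * m_pc["a", ]
  expect_gt(compute_ci(m_pc, g)$pcc_i, res$pcc_i)
})

test_that("a planted tight high-variance cluster is the dominant group", {
  set.seed(7)
  np <- 20
  f <- rnorm(np)
  block <- t(vapply(1:4, function(i) 3 * (0.9 * f + sqrt(1 - 0.81) * rnorm(np)),
    numeric(np)
  ))
  rest <- matrix(rnorm(8 * np, sd = 0.7), 8, np)
  m <- rbind(block, rest)
  rownames(m) <- paste0("g", 1:12)
  mods <- list(d1 = make_module("d1", rownames(m)))
  gc <- structure(
    list(genes = rownames(m), seeds = "d1", size = 12L),
    class = "giant_cluster"
  )
  grp <- dominant_group_at_step(1, "d1", mods, gc, m)
  expect_setequal(intersect(grp$members, paste0("g", 1:4)), paste0("g", 1:4))
  expect_false(grp$fallback)
})

test_that("small filtered pools fall back to a flagged single group", {
  set.seed(8)
  m <- matrix(rnorm(15), 3, 5, dimnames = list(c("x", "y", "z"), NULL))
  mods <- list(d1 = make_module("d1", c("x", "y", "z")))
  gc <- structure(
    list(genes = c("x", "y", "z"), seeds = "d1", size = 3L),
    class = "giant_cluster"
  )
  # background must remain non-empty for PCC_o
  m <- rbind(m, w = rnorm(5))
  grp <- dominant_group_at_step(1, "d1", mods, gc, m)
  expect_true(grp$fallback)
  expect_setequal(grp$members, c("x", "y", "z"))
})

test_that("transition points take the earliest CI maximum", {
  fake_series <- function(ci) {
    structure(
      list(
        patient_id = "P", drivers = paste0("d", seq_along(ci)),
        groups = lapply(seq_along(ci), function(i) {
          list(step = i, members = c("a", "b"), ci = ci[i])
        })
      ),
      class = "ci_series"
    )
  }
  expect_equal(transition_point(fake_series(c(1, 2.5, 9.1, 3)))$step, 3L)
  expect_equal(transition_point(fake_series(c(2, 5, 5)))$step, 2L)
  expect_equal(transition_point(fake_series(4.2))$step, 1L)
  expect_warning(tp <- transition_point(fake_series(c(0, 0))), "no transition")
  expect_true(tp$no_signal)
})

test_that("a planted transition step is recovered along the driver sequence", {
  cfg <- synthetic_config(seed = 101)
  rep <- planted_dnb_replicate(cfg)
  expect_lte(abs(rep$detected_step - cfg$k_star), 1)
  expect_gt(rep$jaccard, 0.3)
})

test_that("clinical-order pairs classify as consistent/inconsistent/absent", {
  clinical <- data.frame(
    patient_id = c("E", "L", "M"),
    stage = c(2L, 4L, 4L),
    subtype = "CMS1"
  )
  results <- list(
    E = list(transition = "SPERT", order = c("SPERT", "AR")),
    L = list(transition = "EP300", order = c("SPERT", "AR", "EP300")),
    M = list(transition = "EP300", order = c("AR", "EP300"))
  )
  rep <- validate_clinical_order(results, clinical)
  expect_equal(nrow(rep$pairs), 2L)
  # E's SPERT precedes L's EP300: consistent; SPERT absent from M: not evaluable
  expect_equal(rep$pairs$status[rep$pairs$late == "L"], "consistent")
  expect_equal(rep$pairs$status[rep$pairs$late == "M"], "not_evaluable")
  expect_equal(rep$fraction, 0.5)

  # early transition gene after the late one: inconsistent
  results$L$order <- c("EP300", "SPERT")
  results$L$transition <- "EP300"
  rep2 <- validate_clinical_order(results, clinical)
  expect_equal(rep2$pairs$status[rep2$pairs$late == "L"], "inconsistent")
})
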