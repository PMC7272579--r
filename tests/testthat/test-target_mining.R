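cms_context <- function(dnb = "X", drivers = c("D1", "D2"),
                        order = c("D1", "D2")) {
  target_context("CMS1", dnb, drivers, order)
}

test_that("a DNB gene between ordered drivers is nominated", {
  pw <- make_pathway("pw1", c("D1", "X"), c("X", "D2"))
  out <- find_candidate_targets(list(pw), cms_context())
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene, "X")
  expect_equal(out$upstream, "D1")
  expect_equal(out$downstream, "D2")
})

test_that("paths contradicting the mutation order yield nothing", {
  pw <- make_pathway("pw1", c("D2", "X"), c("X", "D1"))
  out <- find_candidate_targets(list(pw), cms_context())
  expect_equal(nrow(out), 0L)
})

test_that("pathways with fewer than two drivers are skipped", {
  pw <- make_pathway("pw1", c("D1", "X"), c("X", "Y"))
  expect_message(
    out <- find_candidate_targets(list(pw), cms_context()),
    "no pathway"
  )
  expect_equal(nrow(out), 0L)
})

test_that("driver genes are never nominated and path length is bounded", {
  # D1 -> D3 -> D2 with D3 a driver: interior gene is a driver, not emitted
  pw <- make_pathway("pw1", c("D1", "D3"), c("D3", "D2"))
  ctx <- target_context("CMS1", c("X", "D3"), c("D1", "D2", "D3"),
    c("D1", "D3", "D2")
  )
  expect_equal(nrow(find_candidate_targets(list(pw), ctx)), 0L)
  # a long chain is excluded at small max_path_len, included at larger
  chain <- paste0("N", 1:5)
  pw2 <- make_pathway("pw2",
    c("D1", chain), c(chain, "D2")
  )
  ctx2 <- target_context("CMS1", chain, c("D1", "D2"), c("D1", "D2"))
  short <- find_candidate_targets(list(pw2), ctx2, max_path_len = 3)
  long <- find_candidate_targets(list(pw2), ctx2, max_path_len = 6)
  expect_equal(nrow(short), 0L)
  expect_equal(sort(long$gene), chain)
  # monotone in the path budget
  longer <- find_candidate_targets(list(pw2), ctx2, max_path_len = 8)
  expect_true(all(paste(long$pathway, long$gene) %in%
    paste(longer$pathway, longer$gene)))
})

random_pathway <- function(id, genes, n_edges) {
  from <- sample(genes, n_edges, replace = TRUE)
  to <- sample(genes, n_edges, replace = TRUE)
  keep <- from != to
  make_pathway(id, from[keep], to[keep])
}

test_that("generated candidates always satisfy the independent checker", {
  set.seed(99)
  n_checked <- 0L
  for (i in 1:25) {
    genes <- paste0("g", 1:12)
    drivers <- sample(genes, 4)
    dnb <- sample(setdiff(genes, drivers), 5)
    ctx <- target_context("CMS1", dnb, drivers, sample(drivers))
    pws <- lapply(1:3, function(j) {
      random_pathway(paste0("pw", j), genes, sample(6:14, 1))
    })
    out <- suppressMessages(find_candidate_targets(pws, ctx))
    if (nrow(out) > 0L) {
      ok <- verify_candidate_targets(out, pws, ctx)
      expect_true(all(ok))
      n_checked <- n_checked + nrow(out)
    }
  }
  expect_gt(n_checked, 10L) # the property was exercised, not vacuous
})

test_that("the checker rejects fabricated candidates", {
  pw <- make_pathway("pw1", c("D1", "X"), c("X", "D2"))
  ctx <- cms_context()
  bogus <- data.frame(
    pathway = "pw1", gene = "X", upstream = "D2", downstream = "D1",
    stringsAsFactors = FALSE
  )
  expect_false(verify_candidate_targets(bogus, list(pw), ctx))
  bogus2 <- data.frame(
    pathway = "pw1", gene = "D1", upstream = "D1", downstream = "D2",
    stringsAsFactors = FALSE
  )
  expect_false(verify_candidate_targets(bogus2, list(pw), ctx))
})

test_that("contexts assemble transition and preceding drivers per patient", {
  results <- list(
    P1 = list(
      transition = structure(
        list(patient_id = "P1", step = 3L, driver = "D3",
          dnb_genes = c("X", "Y"), ci = 5, no_signal = FALSE
        ),
        class = "transition_point"
      ),
      order = c("D1", "D2", "D3")
    ),
    P2 = list(
      transition = structure(
        list(patient_id = "P2", step = 1L, driver = "D1",
          dnb_genes = "Z", ci = 2, no_signal = FALSE
        ),
        class = "transition_point"
      ),
      order = c("D1", "D2")
    )
  )
  ctx <- build_target_context(results, c("P1", "P2"), "CMS1",
    c("D1", "D2", "D3")
  )
  expect_setequal(ctx$dnb_set, c("X", "Y", "Z"))
  # P1 contributes D3 and its predecessor D2; P2 (step 1) only D1
  expect_setequal(ctx$driver_set, c("D1", "D2", "D3"))
})
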