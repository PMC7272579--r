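test_that("merged cluster size counts the candidate's merged component", {
  net <- path_net(c("A", "B", "W"))
  expect_equal(merged_cluster_size(c("A", "B"), make_module("W", c("B", "W")), net), 3L)

  star <- gene_network(rep("B", 4), c("A", "X", "Y", "Z"))
  expect_equal(
    merged_cluster_size(c("A", "B"), make_module("X", c("B", "X", "Y", "Z")), star),
    5L
  )
  # candidate contained in current: no growth
  expect_equal(
    merged_cluster_size(c("A", "B", "W"), make_module("B", c("B")), net), 3L
  )
  expect_error(
    merged_cluster_size(c("A"), make_module("W", c("W")), net),
    "overlap"
  )
})

toy_patient <- function(net, seeds) {
  structure(
    list(patient_id = "T1", graph = net, seeds = seeds),
    class = "patient_network"
  )
}

test_that("one greedy sequence starts from every non-driver seed", {
  net <- path_net(c("A", "B", "C", "D"))
  mods <- list(
    A = make_module("A", c("A", "B")),
    C = make_module("C", c("B", "C")),
    D = make_module("D", c("C", "D"))
  )
  seqs <- enumerate_sequences(toy_patient(net, c("A", "C", "D")), mods,
    drivers = "D"
  )
  expect_length(seqs, 2L) # initials A and C
  expect_setequal(vapply(seqs, function(s) s$genes[1], character(1)), c("A", "C"))
  # chain of overlaps: greedy follows minimal growth, no fallbacks
  expect_false(any(unlist(lapply(seqs, `[[`, "fallback"))))
  expect_equal(seqs[[1]]$genes, c("A", "C", "D"))
})

test_that("pairwise-disjoint modules force flagged fallback appends", {
  net <- gene_network(c("A", "C", "E"), c("B", "D", "F"))
  mods <- list(
    A = make_module("A", c("A", "B")),
    C = make_module("C", c("C", "D")),
    E = make_module("E", c("E", "F"))
  )
  seqs <- enumerate_sequences(toy_patient(net, c("A", "C", "E")), mods,
    drivers = character(0)
  )
  expect_length(seqs, 3L)
  for (s in seqs) {
    expect_false(s$fallback[1])
    expect_true(all(s$fallback[-1]))
  }
})

test_that("patients with only driver seeds yield no sequences", {
  net <- gene_network("A", "B")
  mods <- list(A = make_module("A", c("A", "B")))
  expect_warning(
    out <- enumerate_sequences(toy_patient(net, "A"), mods, drivers = "A"),
    "no non-driver seeds"
  )
  expect_length(out, 0L)
})

test_that("every greedy step equals the exhaustive argmin oracle", {
  for (seed in 1:6) {
    cfg <- synthetic_config(
      seed = seed, n_genes = 60, n_patients = 3, n_drivers = 3,
      passengers_range = c(2L, 4L), prefix_range = c(2L, 3L)
    )
    cohort <- generate_cohort(cfg)
    for (prof in cohort$profiles) {
      pn <- build_patient_network(cohort$network, prof)
      if (length(pn$seeds) > 8L || length(pn$seeds) < 2L) next
      out <- propagate_patient(pn)
      member_sets <- lapply(out$modules, `[[`, "members")
      seqs <- suppressWarnings(
        enumerate_sequences(pn, out$modules, cohort$truth$drivers)
      )
      for (s in seqs) {
        covered <- member_sets[[s$genes[1]]]
        remaining <- setdiff(pn$seeds, s$genes[1])
        for (pos in seq_along(s$genes)[-1]) {
          overlapping <- remaining[vapply(
            remaining,
            function(x) length(intersect(member_sets[[x]], covered)) > 0,
            logical(1)
          )]
          if (length(overlapping) > 0L) {
            expect_false(s$fallback[pos])
            expect_identical(
              s$genes[pos],
              oracle_greedy_choice(pn$graph, covered, member_sets, overlapping)
            )
          } else {
            expect_true(s$fallback[pos])
          }
          covered <- unique(c(covered, member_sets[[s$genes[pos]]]))
          remaining <- setdiff(remaining, s$genes[pos])
        }
      }
    }
  }
})

test_that("precedence counts match the worked two-sequence example", {
  C <- pairwise_precedence(list(c("A", "B", "C"), c("B", "A", "C")))
  expect_equal(C["A", "B"], 1L)
  expect_equal(C["B", "A"], 1L)
  expect_equal(C["A", "C"], 2L)
  expect_equal(C["B", "C"], 2L)
  expect_equal(C["A", "B"] + C["B", "A"], 2L)
  expect_true(all(diag(C) == 0L))
})

test_that("precedence identity holds exhaustively on random sequences", {
  set.seed(42)
  genes <- LETTERS[1:6]
  seqs <- lapply(1:8, function(i) sample(genes, sample(2:6, 1)))
  C <- pairwise_precedence(seqs)
  for (i in genes) {
    for (j in genes) {
      if (i >= j) next
      both <- sum(vapply(seqs, function(s) all(c(i, j) %in% s), logical(1)))
      expect_equal(C[i, j] + C[j, i], both)
    }
  }
})

test_that("Copeland ordering resolves the worked example and ties", {
  C <- pairwise_precedence(list(c("A", "B", "C"), c("B", "A", "C")))
  ord <- derive_order(C, c("A", "B", "C"))
  expect_equal(ord$genes, c("A", "B", "C")) # A-B tie broken lexicographically
  # fully consistent sequences reproduce the common order
  C2 <- pairwise_precedence(list(c("C", "A", "B"), c("C", "A", "B")))
  expect_equal(derive_order(C2, c("A", "B", "C"))$genes, c("C", "A", "B"))
  expect_equal(derive_order(C2, "B")$genes, "B")
  expect_error(derive_order(C2, character(0)), "empty")
})

test_that("consensus over matrices is scale-invariant and tie-safe", {
  C <- pairwise_precedence(list(c("A", "B", "C")))
  same <- consensus_order(list(C, C), c("A", "B", "C"))
  expect_equal(same$genes, c("A", "B", "C"))
  rev1 <- pairwise_precedence(list(c("A", "B")))
  rev2 <- pairwise_precedence(list(c("B", "A")))
  tied <- consensus_order(list(rev1, rev2), c("A", "B"))
  expect_equal(tied$genes, c("A", "B"))
})

test_that("identical inputs give byte-identical sequences", {
  cfg <- synthetic_config(seed = 21, n_genes = 60, n_patients = 2)
  cohort <- generate_cohort(cfg)
  pn <- build_patient_network(cohort$network, cohort$profiles[[1]])
  out <- propagate_patient(pn)
  s1 <- suppressWarnings(enumerate_sequences(pn, out$modules, cohort$truth$drivers))
  s2 <- suppressWarnings(enumerate_sequences(pn, out$modules, cohort$truth$drivers))
  expect_identical(s1, s2)
})
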