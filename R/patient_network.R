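# Patient-specific networks: each patient's network keeps the global PPI
# edges whose two endpoint genes are each expressed (not zero in both the
# tumor and the tumor-adjacent sample); the patient's mutated genes present
# in the filtered network become propagation seeds.

#' Assemble per-patient profiles from cohort tables
#'
#' @param expr an `expression_table` (see [read_expression_table()]).
#' @param mutations a mutation catalog (named list patient -> symbols).
#' @param clinical optional clinical data.frame (see [read_clinical_table()]).
#' @return named list of `patient_profile` objects (patients having both
#'   expression and mutation data, the usable cohort): each a list with
#'   `patient_id`, `tumor_expr`, `adjacent_expr` (named numeric vectors over
#'   the measured genes), `mutations`, `stage`, `subtype`.
#' @export
cohort_profiles <- function(expr, mutations, clinical = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  patients <- intersect(unique(expr$sample_patient), names(mutations))
  profs <- lapply(patients, function(p) {
    smp <- names(expr$sample_patient)[expr$sample_patient == p]
    tum <- smp[expr$sample_role[smp] == "tumor"]
    adj <- smp[expr$sample_role[smp] == "adjacent"]
    stage <- NA_integer_
    subtype <- NA_character_
    if (!is.null(clinical) && p %in% clinical$patient_id) {
      row <- clinical[clinical$patient_id == p, ]
      stage <- row$stage
      subtype <- row$subtype
    }
    structure(
      list(
        patient_id = p,
        tumor_expr = expr$values[, tum],
        adjacent_expr = expr$values[, adj],
        mutations = sort(unique(norm_symbols(mutations[[p]]))),
        stage = stage,
        subtype = subtype
      ),
      class = "patient_profile"
    )
  })
  stats::setNames(profs, patients)
}

#' Build a patient-specific network
#'
#' An edge of the global network is retained iff both endpoint genes pass the
#' expression filter: a gene passes unless its expression is zero in both the
#' tumor and the adjacent sample. Genes absent from the expression table are
#' treated as zero in both tissues and fail the filter. Isolated nodes are
#' pruned after filtering. Seeds are the patient's mutated genes present in
#' the retained network.
#'
#' @param global the preprocessed global [gene_network].
#' @param profile a `patient_profile`.
#' @return a `patient_network`: list with `patient_id`, `graph` (a
#'   [gene_network]) and `seeds` (character). A patient whose filter removes
#'   every edge is a degenerate input and raises an error; a patient with no
#'   seeds is returned with a warning (unusable for propagation).
#' @export
build_patient_network <- function(global, profile) {
  stopifnot(inherits(global, "gene_network"), inherits(profile, "patient_profile"))
  tum <- profile$tumor_expr
  adj <- profile$adjacent_expr
  passes <- function(g) {
    t <- unname(tum[g])
    a <- unname(adj[g])
    t[is.na(t)] <- 0
    a[is.na(a)] <- 0
    !(t == 0 & a == 0)
  }
  ok <- passes(global$nodes)
  e1 <- ok[match(global$edges[, 1], global$nodes)]
  e2 <- ok[match(global$edges[, 2], global$nodes)]
  keep <- e1 & e2
  if (!any(keep)) {
    stop(sprintf(
      "degenerate patient %s: no edges survive the expression filter",
      profile$patient_id
    ), call. = FALSE)
  }
  graph <- gene_network(global$edges[keep, 1], global$edges[keep, 2])
  seeds <- intersect(profile$mutations, graph$nodes)
  if (length(seeds) == 0L) {
    warning(sprintf(
      "patient %s has no mutant seeds in the filtered network; excluded from propagation",
      profile$patient_id
    ), call. = FALSE)
  }
  structure(
    list(patient_id = profile$patient_id, graph = graph, seeds = seeds),
    class = "patient_network"
  )
}

#' @export
print.patient_network <- function(x, ...) {
  cat(sprintf(
    "patient_network %s: %d nodes, %d edges, %d seeds\n",
    x$patient_id, length(x$graph$nodes), nrow(x$graph$edges),
    length(x$seeds)
  ))
  invisible(x)
}
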