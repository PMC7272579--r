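# Greedy mutation-order inference. Somatic mutations are ordered per patient
# by repeatedly choosing, among the unmutated seeds whose propagation module
# overlaps the modules of the already-chosen seeds, the one that minimizes
# the size of the connected cluster it merges into. Per-patient sequences
# are summarized into a pairwise precedence matrix and aggregated into a
# consensus driver order by Copeland scoring.

#' Size of the merged connected cluster for a candidate mutation
#'
#' Given the union of the modules of the already-chosen seeds (`current`)
#' and a candidate seed's module, returns the size of the connected
#' component containing the candidate's seed in the subgraph induced by
#' `current` together with the candidate module's members.
#'
#' @param current character vector: union of previously chosen module genes.
#' @param candidate_module a `propagation_module`.
#' @param graph the patient's [gene_network].
#' @return integer component size.
#' @export
merged_cluster_size <- function(current, candidate_module, graph) {
  stopifnot(inherits(candidate_module, "propagation_module"))
  if (length(intersect(current, candidate_module$members)) == 0L) {
    stop("candidate module does not overlap the current cluster", call. = FALSE)
  }
  union_set <- unique(c(current, candidate_module$members))
  component_size_from(graph, union_set, candidate_module$seed)
}

#' Enumerate greedy mutation sequences for a patient
#'
#' One sequence is started from every non-driver seed (the initial
#' mutation). At each subsequent step the candidates are the unmutated
#' seeds whose module shares at least one gene with the union of the modules
#' of the seeds already chosen; the chosen candidate minimizes
#' [merged_cluster_size()], ties broken lexicographically. If no candidate
#' overlaps, the remaining seed with the smallest module (ties lexicographic)
#' is appended with its position flagged as a fallback, and the greedy rule
#' resumes.
#'
#' @param patient a `patient_network`.
#' @param modules named list of `propagation_module` objects, one per seed.
#' @param drivers character vector of driver gene symbols.
#' @return list of `mutation_sequence` objects (`patient_id`, `genes`,
#'   `fallback` logical flags per position). A patient with no non-driver
#'   seeds yields an empty list with a warning.
#' @export
enumerate_sequences <- function(patient, modules, drivers) {
  stopifnot(inherits(patient, "patient_network"))
  seeds <- patient$seeds
  if (!all(seeds %in% names(modules))) {
    stop("every seed must have a propagation module", call. = FALSE)
  }
  initials <- sort(setdiff(seeds, drivers))
  if (length(initials) == 0L) {
    warning(sprintf(
      "patient %s has no non-driver seeds; no sequences generated",
      patient$patient_id
    ), call. = FALSE)
    return(list())
  }
  member_sets <- lapply(modules, `[[`, "members")
  lapply(initials, function(init) {
    chosen <- init
    flags <- FALSE
    covered <- member_sets[[init]]
    remaining <- setdiff(seeds, init)
    while (length(remaining) > 0L) {
      overlaps <- vapply(
        remaining,
        function(s) length(intersect(member_sets[[s]], covered)) > 0L,
        logical(1)
      )
      if (any(overlaps)) {
        cand <- sort(remaining[overlaps])
        sizes <- vapply(
          cand,
          function(s) merged_cluster_size(covered, modules[[s]], patient$graph),
          integer(1)
        )
        pick <- cand[which.min(sizes)] # cand sorted: ties go lexicographic
        flags <- c(flags, FALSE)
      } else {
        cand <- sort(remaining)
        msize <- vapply(cand, function(s) length(member_sets[[s]]), integer(1))
        pick <- cand[which.min(msize)]
        flags <- c(flags, TRUE)
      }
      chosen <- c(chosen, pick)
      covered <- unique(c(covered, member_sets[[pick]]))
      remaining <- setdiff(remaining, pick)
    }
    structure(
      list(patient_id = patient$patient_id, genes = chosen, fallback = flags),
      class = "mutation_sequence"
    )
  })
}

#' Pairwise precedence matrix over mutation sequences
#'
#' `C[i, j]` counts the sequences in which gene i occurs earlier than gene
#' j; genes absent from a sequence contribute nothing for its pairs. For
#' every pair, `C[i, j] + C[j, i]` equals the number of sequences containing
#' both genes.
#'
#' @param sequences list of `mutation_sequence` objects (or bare character
#'   vectors of ordered genes).
#' @param genes optional gene universe; default is the union over sequences.
#' @return a `precedence_matrix`: integer matrix with dimnames.
#' @export
pairwise_precedence <- function(sequences, genes = NULL) {
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  seqs <- lapply(sequences, function(s) {
    if (inherits(s, "mutation_sequence")) s$genes else as.character(s)
  })
  if (is.null(genes)) genes <- sort(unique(unlist(seqs)))
  C <- matrix(0L, length(genes), length(genes), dimnames = list(genes, genes))
  for (g in seqs) {
    g <- g[g %in% genes]
    L <- length(g)
    if (L < 2L) next
    idx <- match(g, genes)
    for (a in seq_len(L - 1L)) {
      C[idx[a], idx[(a + 1L):L]] <- C[idx[a], idx[(a + 1L):L]] + 1L
    }
  }
  structure(C, class = c("precedence_matrix", "matrix"))
}

#' Derive a total order from a precedence matrix by Copeland scoring
#'
#' Gene i beats j iff `C[i, j] > C[j, i]`. Genes are ordered by descending
#' Copeland score (wins minus losses over the restricted pairs), ties by
#' descending net margin (sum of `C[i, j] - C[j, i]`), then lexicographic.
#'
#' @param matrix a `precedence_matrix`.
#' @param restrict_to genes to order (subset of the matrix genes), e.g. a
#'   patient's driver seeds.
#' @param scope label recorded on the result (patient id or CMS label).
#' @return a `consensus_order`: list with `scope`, `genes` (ordered) and
#'   `copeland` (named scores).
#' @export
derive_order <- function(matrix, restrict_to, scope = NA_character_) {
  genes <- intersect(rownames(matrix), restrict_to)
  if (length(genes) == 0L) stop("empty restriction", call. = FALSE)
  genes <- sort(genes)
  sub <- matrix[genes, genes, drop = FALSE]
  wins <- rowSums(sub > t(sub))
  losses <- rowSums(sub < t(sub))
  copeland <- wins - losses
  margin <- rowSums(sub - t(sub))
  ord <- order(-copeland, -margin, genes)
  structure(
    list(
      scope = scope,
      genes = genes[ord],
      copeland = stats::setNames(copeland, genes)[ord]
    ),
    class = "consensus_order"
  )
}

#' Consensus driver order across patients sharing a subtype
#'
#' Sums per-patient precedence matrices over the union of their genes, then
#' derives the order restricted to the driver genes present.
#'
#' @param matrices list of `precedence_matrix` objects.
#' @param drivers driver gene universe.
#' @param label scope label (e.g. "CMS2").
#' @return a `consensus_order` over the drivers observed in the matrices.
#' @export
consensus_order <- function(matrices, drivers, label = NA_character_) {
  if (length(matrices) == 0L) stop("no precedence matrices", call. = FALSE)
  genes <- sort(unique(unlist(lapply(matrices, rownames))))
  total <- matrix(0L, length(genes), length(genes),
    dimnames = list(genes, genes)
  )
  for (m in matrices) {
    g <- rownames(m)
    total[g, g] <- total[g, g] + m
  }
  total <- structure(total, class = c("precedence_matrix", "matrix"))
  derive_order(total, intersect(genes, drivers), scope = label)
}
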