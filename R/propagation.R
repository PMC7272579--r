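# Random-walk-with-restart propagation of mutation effects, score
# thresholding into per-seed propagation modules, and assembly of the mutant
# giant cluster (largest connected component of the module union).

#' Column-normalized transition matrix of a gene network
#'
#' M[i, j] = A[i, j] / degree(j); every column sums to one (no degree-0
#' nodes exist in a preprocessed network).
#'
#' @param graph a [gene_network].
#' @return a `transition_matrix`: list with `nodes` and `M` (sparse
#'   column-stochastic matrix with dimnames).
#' @export
column_normalize <- function(graph) {
  stopifnot(inherits(graph, "gene_network"))
  deg <- vapply(graph$iadj, length, integer(1))
  if (any(deg == 0L)) {
    stop("degree-0 node in network; preprocessing contract violated",
      call. = FALSE
    )
  }
  i <- match(graph$edges[, 1], graph$nodes)
  j <- match(graph$edges[, 2], graph$nodes)
  M <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i),
    x = c(1 / deg[j], 1 / deg[i]),
    dims = c(length(graph$nodes), length(graph$nodes)),
    dimnames = list(graph$nodes, graph$nodes)
  )
  structure(list(nodes = graph$nodes, M = M), class = "transition_matrix")
}

# Shared power iteration over one or more restart vectors (columns of P0).
#' @keywords internal
#' @noRd
rwr_iterate <- function(M, P0, r, tol, max_iter) {
  P <- P0
  for (it in seq_len(max_iter)) {
    P_next <- (1 - r) * (M %*% P) + r * P0
    delta <- max(abs(P_next - P))
    P <- P_next
    if (delta < tol) {
      return(list(P = as.matrix(P), iterations = it, residual = delta))
    }
  }
  stop(sprintf(
    "random walk did not converge in %d iterations (residual %.3g)",
    max_iter, delta
  ), call. = FALSE)
}

#' Random walk with restart from a single mutant seed
#'
#' Iterates P_{t+1} = (1 - r) M P_t + r P_0 from the indicator vector of the
#' seed until the max-norm difference between successive vectors falls below
#' `tol`. The stationary scores measure proximity of every node to the seed;
#' scores are zero outside the seed's connected component and the seed itself
#' always retains at least the restart mass (`p[seed] >= r`).
#'
#' @param graph a [gene_network] (typically a patient network).
#' @param seed seed gene symbol; must be a node of `graph`.
#' @param r restart probability in (0, 1); default 0.7.
#' @param tol convergence tolerance on the max-norm difference; default 1e-10.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a `propagation_result`: list with `seed`, `r`, `tol`, `scores`
#'   (named numeric summing to one) and `iterations`.
#' @export
rwr <- function(graph, seed, r = 0.7, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(graph, "gene_network"))
  if (!(seed %in% graph$nodes)) {
    stop("unknown seed gene: ", seed, call. = FALSE)
  }
  if (!(r > 0 && r < 1)) stop("restart probability r must be in (0, 1)", call. = FALSE)
  tm <- column_normalize(graph)
  P0 <- matrix(0, nrow = length(tm$nodes), ncol = 1L,
    dimnames = list(tm$nodes, seed))
  P0[seed, 1L] <- 1
  out <- rwr_iterate(tm$M, P0, r, tol, max_iter)
  structure(
    list(
      seed = seed, r = r, tol = tol,
      scores = stats::setNames(out$P[, 1L], tm$nodes),
      iterations = out$iterations
    ),
    class = "propagation_result"
  )
}

# All-seeds variant sharing one transition matrix and one iteration loop;
# returns a named list of propagation_result objects. Used by the pipeline
# where per-seed rwr() calls would rebuild M repeatedly.
#' @keywords internal
#' @noRd
rwr_all_seeds <- function(graph, seeds, r = 0.7, tol = 1e-10,
                          max_iter = 10000L) {
  stopifnot(all(seeds %in% graph$nodes))
  if (length(seeds) == 0L) return(list())
  tm <- column_normalize(graph)
  n <- length(tm$nodes)
  P0 <- Matrix::sparseMatrix(
    i = match(seeds, tm$nodes), j = seq_along(seeds), x = 1,
    dims = c(n, length(seeds)), dimnames = list(tm$nodes, seeds)
  )
  out <- rwr_iterate(tm$M, P0, r, tol, max_iter)
  res <- lapply(seq_along(seeds), function(k) {
    structure(
      list(
        seed = seeds[k], r = r, tol = tol,
        scores = stats::setNames(out$P[, k], tm$nodes),
        iterations = out$iterations
      ),
      class = "propagation_result"
    )
  })
  stats::setNames(res, seeds)
}

#' Threshold propagation scores into a mutation propagation module
#'
#' Module members are the nodes whose stationary score strictly exceeds the
#' threshold. With the default threshold (0.001) and any restart probability
#' above it, the seed is always a member.
#'
#' @param result a `propagation_result` from [rwr()].
#' @param threshold score threshold; strict `>` retention. Default 0.001.
#' @return a `propagation_module`: list with `seed`, `members` (character)
#'   and `scores` (named numeric over members). An empty module (threshold
#'   above the seed score) is allowed but flagged with a warning.
#' @export
build_module <- function(result, threshold = 0.001) {
  stopifnot(inherits(result, "propagation_result"))
  keep <- result$scores > threshold
  members <- names(result$scores)[keep]
  if (length(members) == 0L) {
    warning(sprintf(
      "empty module for seed %s at threshold %g", result$seed, threshold
    ), call. = FALSE)
  }
  structure(
    list(
      seed = result$seed,
      members = members,
      scores = result$scores[keep]
    ),
    class = "propagation_module"
  )
}

#' Assemble the mutant giant cluster from propagation modules
#'
#' Takes the union of all module gene sets, induces its subgraph in the
#' patient network, and returns the connected component with the most genes.
#' Ties are broken by more contributing seeds, then by the lexicographically
#' smallest gene set.
#'
#' @param modules list of `propagation_module` objects.
#' @param graph the [gene_network] the modules live in.
#' @return a `giant_cluster`: list with `genes`, `seeds` (seeds whose module
#'   intersects the cluster) and `size`.
#' @export
build_giant_cluster <- function(modules, graph) {
  stopifnot(inherits(graph, "gene_network"))
  member_sets <- lapply(modules, `[[`, "members")
  pool <- unique(unlist(member_sets))
  if (length(pool) == 0L) {
    stop("all modules empty: no giant cluster", call. = FALSE)
  }
  comps <- induced_components(graph, pool)
  # module genes absent from the graph (shouldn't happen by contract) ignored
  seeds_of <- function(comp) {
    vapply(modules, function(m) length(intersect(m$members, comp)) > 0L,
      logical(1)
    )
  }
  comps <- lapply(comps, sort)
  sizes <- vapply(comps, length, integer(1))
  nseeds <- vapply(comps, function(cp) sum(seeds_of(cp)), integer(1))
  keyfun <- vapply(comps, function(cp) paste(cp, collapse = "\r"), character(1))
  ord <- order(-sizes, -nseeds, keyfun)
  best <- comps[[ord[1]]]
  contributing <- vapply(modules, `[[`, character(1), "seed")[seeds_of(best)]
  structure(
    list(genes = best, seeds = sort(unique(contributing)), size = length(best)),
    class = "giant_cluster"
  )
}

#' Fraction of a patient's seeds contributing to the giant cluster
#'
#' @param gc a `giant_cluster`.
#' @param all_seeds character vector of all the patient's mutant seeds.
#' @return numeric in \[0, 1\].
#' @export
seed_coverage <- function(gc, all_seeds) {
  stopifnot(inherits(gc, "giant_cluster"))
  if (length(all_seeds) == 0L) {
    stop("seed coverage undefined for an empty seed set", call. = FALSE)
  }
  length(intersect(gc$seeds, all_seeds)) / length(unique(all_seeds))
}

#' Propagate all seeds of a patient network and build its giant cluster
#'
#' Convenience wrapper running [rwr()] for every seed, [build_module()] at
#' the given threshold, and [build_giant_cluster()].
#'
#' @param pnet a `patient_network`.
#' @param r,tol,threshold propagation parameters (see [rwr()],
#'   [build_module()]).
#' @return list with `modules` (named by seed), `gc` and `coverage`.
#' @export
propagate_patient <- function(pnet, r = 0.7, tol = 1e-10, threshold = 0.001) {
  stopifnot(inherits(pnet, "patient_network"))
  if (length(pnet$seeds) == 0L) {
    stop("patient ", pnet$patient_id, " has no seeds", call. = FALSE)
  }
  results <- rwr_all_seeds(pnet$graph, pnet$seeds, r = r, tol = tol)
  modules <- lapply(results, build_module, threshold = threshold)
  gc <- build_giant_cluster(modules, pnet$graph)
  list(
    modules = modules,
    gc = gc,
    coverage = seed_coverage(gc, pnet$seeds)
  )
}
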