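# Pathway-based candidate drug-target mining. A gene is nominated for a
# subtype when (1) a directed pathway contains at least two of the subtype's
# transition-window driver genes, (2) some driver pair is connected by a
# directed path whose direction agrees with the consensus mutation order,
# and (3) the gene lies strictly between the two drivers on such a path,
# belongs to the subtype's DNB set and is not itself a driver.

#' Target-mining context for one subtype
#'
#' @param subtype subtype label.
#' @param dnb_set union of transition-point dominant-group genes over the
#'   subtype's patients.
#' @param driver_set union of transition-point drivers and the drivers
#'   immediately preceding them in each patient's order.
#' @param order consensus order over `driver_set` (a `consensus_order` or a
#'   character vector; must cover `driver_set`).
#' @return a `target_context` list.
#' @export
target_context <- function(subtype, dnb_set, driver_set, order) {
  ord <- if (inherits(order, "consensus_order")) order$genes else as.character(order)
  if (!all(driver_set %in% ord)) {
    stop("consensus order must cover the driver set", call. = FALSE)
  }
  structure(
    list(
      subtype = subtype,
      dnb_set = unique(dnb_set),
      driver_set = unique(driver_set),
      order = ord
    ),
    class = "target_context"
  )
}

#' Build a target-mining context from per-patient transition results
#'
#' The driver set pools, over the subtype's patients, the transition-point
#' driver and the driver at the immediately preceding step of each patient's
#' own order (patients whose transition is at step 1 contribute only the
#' transition driver); the DNB set pools the transition dominant groups.
#'
#' @param results named list (by patient) with elements `transition` (a
#'   `transition_point`) and `order` (character driver order).
#' @param patients patient ids belonging to the subtype.
#' @param subtype subtype label.
#' @param consensus a `consensus_order` covering the drivers (typically the
#'   subtype consensus).
#' @return a `target_context`.
#' @export
build_target_context <- function(results, patients, subtype, consensus) {
  patients <- intersect(patients, names(results))
  if (length(patients) == 0L) stop("no patients for subtype", call. = FALSE)
  dnb <- character(0)
  drv <- character(0)
  for (p in patients) {
    tp <- results[[p]]$transition
    ord <- results[[p]]$order
    dnb <- c(dnb, tp$dnb_genes)
    drv <- c(drv, tp$driver)
    if (tp$step > 1L) drv <- c(drv, ord[tp$step - 1L])
  }
  cons <- if (inherits(consensus, "consensus_order")) consensus$genes else consensus
  target_context(subtype, unique(dnb), intersect(cons, unique(drv)), cons)
}

#' Find candidate drug-target genes in directed pathways
#'
#' @param pathways list of `pathway_graph` objects (see
#'   [read_pathway_sif()]).
#' @param context a `target_context`.
#' @param max_path_len maximum number of edges in an upstream-to-downstream
#'   simple path; default 6.
#' @return data.frame with columns `pathway`, `gene`, `upstream`,
#'   `downstream`, sorted by (pathway, gene); zero rows (with a message)
#'   when no pathway contains two drivers.
#' @export
find_candidate_targets <- function(pathways, context, max_path_len = 6L) {
  stopifnot(inherits(context, "target_context"))
  eligible <- setdiff(context$dnb_set, context$driver_set)
  rows <- list()
  any_cond1 <- FALSE
  for (pw in pathways) {
    if (nrow(pw$edges) == 0L) next
    nodes <- unique(c(pw$edges$from, pw$edges$to))
    drivers_in <- intersect(context$driver_set, nodes)
    if (length(drivers_in) < 2L) next
    any_cond1 <- TRUE
    g <- igraph::graph_from_data_frame(
      pw$edges[, c("from", "to")],
      directed = TRUE, vertices = nodes
    )
    pos <- match(drivers_in, context$order)
    for (a in drivers_in) {
      for (b in drivers_in) {
        if (a == b) next
        if (match(a, context$order) >= match(b, context$order)) next
        paths <- igraph::all_simple_paths(g, from = a, to = b,
          mode = "out", cutoff = max_path_len
        )
        for (p in paths) {
          interior <- setdiff(names(p), c(a, b))
          hits <- intersect(interior, eligible)
          for (h in hits) {
            rows[[length(rows) + 1L]] <- data.frame(
              pathway = pw$id, gene = h, upstream = a, downstream = b,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!any_cond1) {
    message("no pathway contains two or more driver-set genes")
  }
  if (length(rows) == 0L) {
    return(data.frame(
      pathway = character(0), gene = character(0),
      upstream = character(0), downstream = character(0)
    ))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$pathway, out$gene, out$upstream, out$downstream), ]
  rownames(out) <- NULL
  out
}

#' Independently re-verify candidate targets against the three conditions
#'
#' A checker separate from the generator: it re-tests, for every candidate
#' row, that the gene is in the DNB set but not the driver set, that both
#' drivers are in the driver set with the upstream one earlier in the
#' consensus order, that the pathway holds at least two driver-set genes,
#' and -- by its own depth-first path search -- that a simple directed path
#' of at most `max_path_len` edges runs upstream to downstream through the
#' gene.
#'
#' @param candidates data.frame as returned by [find_candidate_targets()].
#' @param pathways,context,max_path_len as for [find_candidate_targets()].
#' @return logical vector, one entry per candidate row.
#' @export
verify_candidate_targets <- function(candidates, pathways, context,
                                     max_path_len = 6L) {
  ids <- vapply(pathways, `[[`, character(1), "id")
  vapply(seq_len(nrow(candidates)), function(i) {
    row <- candidates[i, ]
    pw <- pathways[[match(row$pathway, ids)]]
    if (is.null(pw)) return(FALSE)
    if (!(row$gene %in% context$dnb_set) || row$gene %in% context$driver_set) {
      return(FALSE)
    }
    if (!all(c(row$upstream, row$downstream) %in% context$driver_set)) {
      return(FALSE)
    }
    if (match(row$upstream, context$order) >= match(row$downstream, context$order)) {
      return(FALSE)
    }
    nodes <- unique(c(pw$edges$from, pw$edges$to))
    if (length(intersect(context$driver_set, nodes)) < 2L) return(FALSE)
    succ <- split(pw$edges$to, pw$edges$from)
    # depth-first search for a simple path upstream -> downstream through gene
    found <- FALSE
    visit <- function(v, depth, through) {
      if (found) return(invisible())
      if (v == row$downstream) {
        if (through) found <<- TRUE
        return(invisible())
      }
      if (depth == max_path_len) return(invisible())
      for (w in succ[[v]] %||% character(0)) {
        if (w %in% path_stack) next
        path_stack <<- c(path_stack, w)
        visit(w, depth + 1L, through || w == row$gene)
        path_stack <<- path_stack[-length(path_stack)]
        if (found) break
      }
      invisible()
    }
    path_stack <- row$upstream
    visit(row$upstream, 0L, FALSE)
    found
  }, logical(1))
}
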