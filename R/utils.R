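# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
norm_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Connected components of the subgraph of `net` induced by `genes`.
# Returns a list of character vectors (gene sets), unordered.
# Hot path: plain integer BFS over the precomputed adjacency index;
# igraph::components is the independent oracle in the test suite.
#' @keywords internal
#' @noRd
induced_components <- function(net, genes) {
  idx <- match(genes, net$nodes)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(list())
  n <- length(net$nodes)
  member <- logical(n)
  member[idx] <- TRUE
  seen <- logical(n)
  comps <- list()
  for (s in idx) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, v)
      nb <- net$iadj[[v]]
      nb <- nb[member[nb] & !seen[nb]]
      if (length(nb) > 0L) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- net$nodes[comp]
  }
  comps
}

# Size of the connected component containing `start` in the subgraph of `net`
# induced by `genes` (start must be in genes). Avoids materializing all
# components in the greedy ordering loop.
#' @keywords internal
#' @noRd
component_size_from <- function(net, genes, start) {
  idx <- match(genes, net$nodes)
  idx <- idx[!is.na(idx)]
  s <- match(start, net$nodes)
  if (is.na(s) || !(s %in% idx)) {
    stop("start gene not in the induced gene set", call. = FALSE)
  }
  n <- length(net$nodes)
  member <- logical(n)
  member[idx] <- TRUE
  seen <- logical(n)
  queue <- s
  seen[s] <- TRUE
  size <- 0L
  while (length(queue) > 0L) {
    v <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    size <- size + 1L
    nb <- net$iadj[[v]]
    nb <- nb[member[nb] & !seen[nb]]
    if (length(nb) > 0L) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  size
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
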