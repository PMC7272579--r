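#' Gene interaction network
#'
#' An undirected interaction graph over gene symbols, the substrate for all
#' downstream analyses. Construction applies the standard preprocessing:
#' symbol normalization (trim, uppercase), removal of self-interactions,
#' collapse of duplicate unordered pairs, and removal of isolated nodes
#' (every retained node has degree >= 1 by construction, since nodes exist
#' only as edge endpoints).
#'
#' @param from,to character vectors of interacting gene symbols (parallel).
#'
#' @return An object of class `gene_network`: a list with elements
#'   `nodes` (character), `edges` (two-column character matrix, each row an
#'   unordered pair stored in sorted order), `adj` (named list of neighbor
#'   symbol vectors) and `iadj` (integer adjacency index, internal). The
#'   `load_report` attribute records how many input records were kept and
#'   dropped (`self_loop`, `duplicate`).
#'
#' @examples
#' net <- gene_network(c("TP53", "TP53", "APC"), c("MDM2", "TP53", "CTNNB1"))
#' net$nodes
#' attr(net, "load_report")
#' @export
gene_network <- function(from, to) {
  from <- norm_symbols(from)
  to <- norm_symbols(to)
  stopifnot(length(from) == length(to))
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("empty gene symbol in edge list", call. = FALSE)
  }
  n_in <- length(from)
  self <- from == to
  from <- from[!self]
  to <- to[!self]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]
  if (length(a) == 0L) {
    stop("empty network: no edges survive preprocessing", call. = FALSE)
  }
  nodes <- sort(unique(c(a, b)))
  edges <- cbind(a, b, deparse.level = 0)
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  iadj <- vector("list", length(nodes))
  half <- split(c(ib, ia), c(ia, ib))
  iadj[as.integer(names(half))] <- lapply(half, function(v) sort(unique(v)))
  for (i in seq_along(iadj)) if (is.null(iadj[[i]])) iadj[[i]] <- integer(0)
  adj <- lapply(iadj, function(v) nodes[v])
  names(adj) <- nodes
  structure(
    list(nodes = nodes, edges = edges, adj = adj, iadj = iadj),
    class = "gene_network",
    load_report = list(
      input = n_in,
      kept = length(a),
      self_loop = sum(self),
      duplicate = sum(dup)
    )
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "gene_network: %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Number of edges / degree lookup
#' @param net a `gene_network`.
#' @return `network_degree()`: named integer vector of node degrees.
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  vapply(net$adj, length, integer(1))
}

#' Convert a gene network to an igraph object
#'
#' @param net a `gene_network`.
#' @return an undirected `igraph` graph with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::graph_from_data_frame(
    data.frame(from = net$edges[, 1], to = net$edges[, 2]),
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Read a protein-protein interaction edge list
#'
#' Reads a two-or-more-column delimited file (TSV or SIF-like; only the first
#' two columns are used, except three-column files whose middle column is a
#' SIF relation label, where columns 1 and 3 are the endpoints) and applies
#' the network preprocessing: self-interaction removal, de-duplication of
#' unordered pairs, isolated-node removal.
#'
#' @param path path to the edge-list file.
#' @param sif logical; if `TRUE` treat the file as SIF (node relation node).
#' @param tolerant logical; if `TRUE`, malformed lines (fewer than two
#'   fields) are logged in the load report and skipped instead of raising an
#'   error.
#' @return a [gene_network]. The `load_report` attribute additionally counts
#'   `malformed` lines in tolerant mode.
#' @export
read_ppi_edgelist <- function(path, sif = FALSE, tolerant = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty network: no records in ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "[\t ]+")
  need <- if (sif) 3L else 2L
  bad <- which(vapply(fields, length, integer(1)) < need)
  if (length(bad) > 0L && !tolerant) {
    stop(sprintf(
      "malformed edge record at line %d of %s (fewer than %d fields)",
      bad[1], path, need
    ), call. = FALSE)
  }
  keep <- setdiff(seq_along(fields), bad)
  if (length(keep) == 0L) {
    stop("empty network: all records malformed in ", path, call. = FALSE)
  }
  from <- vapply(fields[keep], `[[`, character(1), 1L)
  to <- vapply(fields[keep], `[[`, character(1), if (sif) 3L else 2L)
  net <- gene_network(from, to)
  rep <- attr(net, "load_report")
  rep$input <- length(lines)
  rep$malformed <- length(bad)
  attr(net, "load_report") <- rep
  net
}

#' Write a gene network as a two-column TSV edge list
#'
#' @param net a [gene_network].
#' @param path output path.
#' @return `path`, invisibly. Re-reading with [read_ppi_edgelist()] yields an
#'   identical edge set.
#' @export
write_gene_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  utils::write.table(net$edges, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
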