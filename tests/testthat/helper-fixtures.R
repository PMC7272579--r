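# Shared fixtures, built in code.

triangle_net <- function() gene_network(c("A", "A", "B"), c("B", "C", "C"))

path_net <- function(nodes) {
  gene_network(nodes[-length(nodes)], nodes[-1])
}

# the 3-gene x 4-patient worked log-ratio matrix for the criticality index
ci_worked_matrix <- function() {
  m <- rbind(
    g1 = c(1, 2, 3, 4),
    g2 = c(2, 4, 6, 8),
    g3 = c(1, -1, 1, -1)
  )
  colnames(m) <- paste0("P", 1:4)
  m
}

# brute-force criticality index straight from the definition
ci_bruteforce <- function(mat, group, background, eps = 1e-8) {
  sd_i <- mean(vapply(group, function(g) stats::sd(mat[g, ]), numeric(1)))
  absr <- function(a, b) {
    if (stats::sd(mat[a, ]) == 0 || stats::sd(mat[b, ]) == 0) return(0)
    abs(stats::cor(mat[a, ], mat[b, ]))
  }
  pairs_i <- utils::combn(group, 2)
  pcc_i <- mean(vapply(
    seq_len(ncol(pairs_i)),
    function(j) absr(pairs_i[1, j], pairs_i[2, j]), numeric(1)
  ))
  pcc_o <- mean(outer(group, background, Vectorize(absr)))
  length(group) * sd_i * pcc_i / max(pcc_o, eps)
}

# propagation_module built directly (for cluster / ordering tests)
make_module <- function(seed, members) {
  structure(
    list(seed = seed, members = members,
      scores = stats::setNames(rep(1, length(members)), members)
    ),
    class = "propagation_module"
  )
}

# independent component oracle via igraph
igraph_components <- function(net, genes) {
  g <- igraph::induced_subgraph(as_igraph(net), genes)
  cmp <- igraph::components(g)
  split(names(cmp$membership), cmp$membership)
}

# independent greedy-step oracle: exhaustive argmin of merged component
# size over overlapping candidates, igraph for the component walk
oracle_greedy_choice <- function(net, covered, member_sets, candidates) {
  cand <- sort(candidates)
  sizes <- vapply(cand, function(s) {
    union_set <- unique(c(covered, member_sets[[s]]))
    comps <- igraph_components(net, intersect(union_set, net$nodes))
    hit <- comps[vapply(comps, function(cp) s %in% cp, logical(1))]
    length(hit[[1]])
  }, numeric(1))
  cand[which.min(sizes)]
}

make_pathway <- function(id, from, to, relation = "activates") {
  structure(
    list(id = id, edges = data.frame(
      from = from, relation = relation, to = to, stringsAsFactors = FALSE
    )),
    class = "pathway_graph"
  )
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
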