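# Gene-set enrichment of giant clusters (upper-tail hypergeometric test,
# Benjamini-Hochberg correction) and between-subtype comparison of
# enrichment profiles by exact Wilcoxon rank-sum tests.

#' Upper-tail hypergeometric p-value
#'
#' P(X >= overlap) for X hypergeometric with `universe` genes of which
#' `set_size` belong to the gene set, drawing `gc_size` genes (the giant
#' cluster).
#'
#' @param overlap observed overlap between cluster and set.
#' @param gc_size number of genes in the cluster (draws).
#' @param set_size number of genes in the set (successes in the universe).
#' @param universe universe size.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_pvalue <- function(overlap, gc_size, set_size, universe) {
  if (overlap > min(gc_size, set_size) || gc_size > universe ||
    set_size > universe || overlap < 0) {
    stop("hypergeometric bounds violated", call. = FALSE)
  }
  stats::phyper(overlap - 1, set_size, universe - set_size, gc_size,
    lower.tail = FALSE
  )
}

#' Enrich a giant cluster against a gene-set collection
#'
#' Sets are intersected with the universe (the preprocessed global network's
#' nodes) before testing; p-values are adjusted by Benjamini-Hochberg across
#' the collection.
#'
#' @param gc a `giant_cluster` (or a character vector of genes).
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector of universe genes; must contain the
#'   cluster genes.
#' @param patient optional patient label for the output.
#' @return data.frame with one row per set: `patient`, `set`, `overlap`,
#'   `gc_size`, `set_size`, `universe`, `p`, `p_adj`.
#' @export
enrich_gc <- function(gc, sets, universe, patient = NA_character_) {
  genes <- if (inherits(gc, "giant_cluster")) gc$genes else as.character(gc)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(genes %in% universe)) {
    stop("giant cluster genes must lie in the universe", call. = FALSE)
  }
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(genes, s))
    data.frame(
      patient = patient, set = nm, overlap = ov,
      gc_size = length(genes), set_size = length(s),
      universe = length(universe),
      p = hypergeometric_pvalue(ov, length(genes), length(s), length(universe)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Compare per-patient enrichment profiles between subtypes
#'
#' Each patient's enrichment profile is reduced to the median of
#' -log10(adjusted p) across the collection; every subtype pair with at
#' least two patients each is compared by an exact two-sided Wilcoxon
#' rank-sum test on these summaries.
#'
#' @param profiles named list (by patient id) of adjusted p-value vectors
#'   (one entry per gene set).
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @return data.frame with columns `subtype_a`, `subtype_b`, `n_a`, `n_b`,
#'   `p`; subtypes with fewer than two patients are skipped with a warning.
#' @export
compare_subtype_profiles <- function(profiles, clinical) {
  summ <- vapply(profiles, function(p) stats::median(-log10(p)), numeric(1))
  sub <- clinical$subtype[match(names(summ), clinical$patient_id)]
  keep <- !is.na(sub)
  summ <- summ[keep]
  sub <- sub[keep]
  types <- sort(unique(sub))
  counts <- table(sub)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warning(
      "subtype(s) with < 2 patients skipped: ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
    types <- setdiff(types, small)
  }
  if (length(types) < 2L) {
    return(data.frame(
      subtype_a = character(0), subtype_b = character(0),
      n_a = integer(0), n_b = integer(0), p = numeric(0)
    ))
  }
  combos <- utils::combn(types, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]
    b <- combos[2, i]
    xa <- summ[sub == a]
    xb <- summ[sub == b]
    p <- stats::wilcox.test(xa, xb, exact = TRUE)$p.value
    data.frame(
      subtype_a = a, subtype_b = b, n_a = length(xa), n_b = length(xb),
      p = p, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
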