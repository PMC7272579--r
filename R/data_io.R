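# Readers for the cohort input formats: expression + sample manifest,
# MAF-lite mutation tables, clinical tables, driver lists, GMT gene sets and
# SIF pathway graphs. All symbols are normalized (trimmed, uppercased) at the
# boundary.

#' Read a paired expression table with its sample manifest
#'
#' The expression file is a TSV with a `gene` column followed by one column
#' per sample (nonnegative abundances; the pipeline makes no assumption about
#' counts vs normalized values beyond nonnegativity). The manifest is a TSV
#' with columns `sample_id`, `patient_id`, `role` where role is `tumor` or
#' `adjacent`; every patient must contribute exactly one sample of each role.
#'
#' @param path path to the expression TSV.
#' @param manifest path to the sample-manifest TSV.
#' @return an `expression_table`: list with `genes`, `samples`, `values`
#'   (genes x samples numeric matrix), `sample_role` and `sample_patient`
#'   (named character vectors keyed by sample id).
#' @export
read_expression_table <- function(path, manifest) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab)) {
    stop("expression table must have a 'gene' column", call. = FALSE)
  }
  genes <- norm_symbols(tab$gene)
  if (anyDuplicated(genes)) {
    stop(
      "duplicate gene row in expression table: ",
      genes[duplicated(genes)][1],
      call. = FALSE
    )
  }
  values <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  if (!is.numeric(values)) {
    stop("non-numeric expression values", call. = FALSE)
  }
  rownames(values) <- genes
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "role")
  if (!all(need %in% names(man))) {
    stop(
      "manifest must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  missing_man <- setdiff(colnames(values), man$sample_id)
  if (length(missing_man) > 0L) {
    stop(
      "sample(s) missing from manifest: ",
      paste(missing_man, collapse = ", "),
      call. = FALSE
    )
  }
  man <- man[match(colnames(values), man$sample_id), ]
  if (!all(man$role %in% c("tumor", "adjacent"))) {
    stop("manifest role must be 'tumor' or 'adjacent'", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative expression value for gene %s in sample %s",
      genes[bad[1]], colnames(values)[bad[2]]
    ), call. = FALSE)
  }
  for (p in unique(man$patient_id)) {
    roles <- man$role[man$patient_id == p]
    if (sum(roles == "tumor") != 1L || sum(roles == "adjacent") != 1L) {
      stop(sprintf(
        "patient %s must have exactly one tumor and one adjacent sample", p
      ), call. = FALSE)
    }
  }
  structure(
    list(
      genes = genes,
      samples = colnames(values),
      values = values,
      sample_role = stats::setNames(man$role, man$sample_id),
      sample_patient = stats::setNames(man$patient_id, man$sample_id)
    ),
    class = "expression_table"
  )
}

#' Read a MAF-lite somatic mutation table
#'
#' TSV with header columns `sample_id` and `gene_symbol`; duplicate
#' (patient, gene) rows collapse into a set.
#'
#' @param path path to the mutation TSV.
#' @return a named list mapping patient id to a character vector of mutated
#'   gene symbols (a `MutationCatalog`).
#' @export
read_mutation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_symbol")
  if (!all(need %in% names(tab))) {
    stop(
      "mutation table must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(tab) == 0L) {
    return(structure(list(), names = character(0)))
  }
  genes <- norm_symbols(tab$gene_symbol)
  lapply(split(genes, tab$sample_id), function(g) sort(unique(g)))
}

#' Read a clinical table
#'
#' TSV with columns `patient_id`, `stage` (1-4 or NA) and `subtype`
#' (CMS1-CMS4 or NA).
#'
#' @param path path to the clinical TSV.
#' @return data.frame with columns `patient_id`, `stage` (integer, NA for
#'   unknown), `subtype` (character, NA for unknown).
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "stage", "subtype")
  if (!all(need %in% names(tab))) {
    stop(
      "clinical table must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  tab$stage <- suppressWarnings(as.integer(tab$stage))
  if (any(!is.na(tab$stage) & !(tab$stage %in% 1:4))) {
    stop("stage must be 1-4 or NA", call. = FALSE)
  }
  tab$subtype <- as.character(tab$subtype)
  tab$subtype[tab$subtype == ""] <- NA_character_
  if (any(!is.na(tab$subtype) & !(tab$subtype %in% paste0("CMS", 1:4)))) {
    stop("subtype must be CMS1-CMS4 or NA", call. = FALSE)
  }
  tab[, need]
}

#' Read a driver gene list (one symbol per line)
#'
#' @param path path to the list file.
#' @return character vector of unique, normalized driver symbols.
#' @export
read_driver_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- norm_symbols(x)
  sort(unique(x[nzchar(x)]))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: tab-separated lines `name<TAB>description<TAB>gene...`; the
#' description field is ignored.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (set name -> member symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short) > 0L) {
    stop(sprintf(
      "malformed GMT line %d (need name, description, >=1 gene)", short[1]
    ), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- lapply(fields, function(f) sort(unique(norm_symbols(f[-(1:2)]))))
  names(sets) <- nm
  sets
}

#' Read directed pathway graphs in SIF format
#'
#' One file per pathway (`source<TAB>relation<TAB>target`), pathway id =
#' file stem. Self-loop edges are dropped with a warning; edge order is
#' preserved.
#'
#' @param paths character vector of SIF file paths.
#' @return list of `pathway_graph` objects: lists with `id` and `edges`
#'   (data.frame with columns `from`, `relation`, `to`).
#' @export
read_pathway_sif <- function(paths) {
  lapply(paths, function(path) {
    id <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("empty pathway file: ", path, call. = FALSE)
      return(structure(
        list(id = id, edges = data.frame(
          from = character(0), relation = character(0), to = character(0)
        )),
        class = "pathway_graph"
      ))
    }
    fields <- strsplit(lines, "[\t ]+")
    bad <- which(vapply(fields, length, integer(1)) < 3L)
    if (length(bad) > 0L) {
      stop(sprintf(
        "malformed SIF line %d in %s", bad[1], path
      ), call. = FALSE)
    }
    from <- norm_symbols(vapply(fields, `[[`, character(1), 1L))
    rel <- vapply(fields, `[[`, character(1), 2L)
    to <- norm_symbols(vapply(fields, `[[`, character(1), 3L))
    self <- from == to
    if (any(self)) {
      warning(sprintf(
        "dropped %d self-loop edge(s) in pathway %s", sum(self), id
      ), call. = FALSE)
    }
    structure(
      list(id = id, edges = data.frame(
        from = from[!self], relation = rel[!self], to = to[!self],
        stringsAsFactors = FALSE
      )),
      class = "pathway_graph"
    )
  })
}
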