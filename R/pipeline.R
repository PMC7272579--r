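# End-to-end orchestration: networks -> propagation -> giant clusters ->
# mutation order -> consensus -> DNB/transition -> clinical validation ->
# enrichment -> drug targets, from one configuration, with per-stage
# outputs and a reproducible run manifest.

#' Run the full early-warning pipeline
#'
#' @param config either a path to a YAML file or a list, with elements:
#'   `inputs` (paths: `ppi`, `expr`, `manifest`, `mutations`, `clinical`,
#'   `drivers`; optional `gmt`, `pathways` (vector of SIF files)),
#'   `parameters` (optional: `r`, `tol`, `threshold`, `de_quantile`, `eps`,
#'   `max_path_len`) and `out_dir`.
#' @return the run manifest (also written to `out_dir/manifest.json`):
#'   parameters, input checksums and per-stage record counts. Reruns with
#'   the same config produce identical manifests.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inp <- config$inputs
  need <- c("ppi", "expr", "manifest", "mutations", "clinical", "drivers")
  missing <- need[!vapply(need, function(k) {
    !is.null(inp[[k]]) && file.exists(inp[[k]])
  }, logical(1))]
  if (length(missing) > 0L) {
    stop(
      "missing input file(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  par <- config$parameters %||% list()
  r <- par$r %||% 0.7
  tol <- par$tol %||% 1e-10
  threshold <- par$threshold %||% 0.001
  de_quantile <- par$de_quantile %||% 0.5
  eps <- par$eps %||% 1e-8
  max_path_len <- par$max_path_len %||% 6L
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  # stage 1: load + preprocess
  net <- read_ppi_edgelist(inp$ppi)
  expr <- read_expression_table(inp$expr, inp$manifest)
  muts <- read_mutation_table(inp$mutations)
  clinical <- read_clinical_table(inp$clinical)
  drivers <- read_driver_list(inp$drivers)
  profiles <- cohort_profiles(expr, muts, clinical)
  counts$load <- list(
    network_nodes = length(net$nodes), network_edges = nrow(net$edges),
    patients = length(profiles), drivers = length(drivers)
  )

  # stage 2: patient networks
  pnets <- lapply(profiles, function(p) build_patient_network(net, p))
  pnets <- Filter(function(pn) length(pn$seeds) > 0L, pnets)
  counts$networks <- list(patients_with_seeds = length(pnets))

  # stage 3: propagation modules + giant clusters
  prop <- lapply(pnets, propagate_patient,
    r = r, tol = tol, threshold = threshold
  )
  gc_tab <- data.frame(
    patient = names(prop),
    gc_size = vapply(prop, function(x) x$gc$size, integer(1)),
    n_seeds = vapply(pnets, function(x) length(x$seeds), integer(1)),
    seed_coverage = vapply(prop, `[[`, numeric(1), "coverage")
  )
  utils::write.table(gc_tab, file.path(out_dir, "giant_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    lapply(prop, function(x) {
      list(
        gc = x$gc$genes,
        modules = lapply(x$modules, `[[`, "members")
      )
    }),
    file.path(out_dir, "modules.json"),
    auto_unbox = TRUE, digits = NA
  )
  counts$propagation <- list(
    mean_gc_size = mean(gc_tab$gc_size),
    mean_seed_coverage = mean(gc_tab$seed_coverage)
  )

  # stage 4: greedy mutation sequences + per-patient driver orders
  orders <- list()
  matrices <- list()
  for (p in names(pnets)) {
    seqs <- suppressWarnings(
      enumerate_sequences(pnets[[p]], prop[[p]]$modules, drivers)
    )
    if (length(seqs) == 0L) next
    pm <- pairwise_precedence(seqs)
    driver_seeds <- intersect(rownames(pm), drivers)
    if (length(driver_seeds) == 0L) next
    matrices[[p]] <- pm
    orders[[p]] <- derive_order(pm, driver_seeds, scope = p)
  }
  counts$ordering <- list(patients_ordered = length(orders))
  jsonlite::write_json(
    lapply(orders, `[[`, "genes"),
    file.path(out_dir, "driver_orders.json"),
    auto_unbox = TRUE, digits = NA
  )

  # stage 5: per-subtype consensus orders
  consensus <- list()
  for (cms in sort(unique(stats::na.omit(clinical$subtype)))) {
    ids <- intersect(
      clinical$patient_id[!is.na(clinical$subtype) & clinical$subtype == cms],
      names(matrices)
    )
    if (length(ids) == 0L) next
    consensus[[cms]] <- consensus_order(matrices[ids], drivers, label = cms)
  }
  jsonlite::write_json(
    lapply(consensus, `[[`, "genes"),
    file.path(out_dir, "consensus_orders.json"),
    auto_unbox = TRUE, digits = NA
  )
  counts$consensus <- list(subtypes = length(consensus))

  # stage 6: DNB criticality series + transition points
  lr <- log_ratio_matrix(profiles, net$nodes)
  precomp <- ci_precompute(lr)
  results <- list()
  trans_rows <- list()
  for (p in names(orders)) {
    series <- tryCatch(
      ci_series(p, orders[[p]], prop[[p]]$modules, prop[[p]]$gc, lr,
        de_quantile = de_quantile, eps = eps, precomp = precomp
      ),
      error = function(e) NULL
    )
    if (is.null(series)) next
    tp <- suppressWarnings(transition_point(series))
    results[[p]] <- list(transition = tp, order = orders[[p]]$genes)
    trans_rows[[p]] <- data.frame(
      patient = p, step = tp$step, driver = tp$driver, ci = tp$ci,
      n_dnb_genes = length(tp$dnb_genes)
    )
  }
  trans_tab <- do.call(rbind, trans_rows)
  utils::write.table(trans_tab, file.path(out_dir, "transition_points.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    lapply(results, function(x) x$transition$dnb_genes),
    file.path(out_dir, "dnb_genes.json"),
    auto_unbox = TRUE, digits = NA
  )
  counts$dnb <- list(patients_with_transition = length(results))

  # stage 7: clinical-order validation
  validation <- suppressWarnings(validate_clinical_order(results, clinical))
  utils::write.table(validation$by_subtype,
    file.path(out_dir, "clinical_validation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  counts$validation <- list(
    pairs = nrow(validation$pairs),
    fraction_consistent = validation$fraction
  )

  # stage 8: giant-cluster enrichment (optional)
  if (!is.null(inp$gmt)) {
    sets <- read_gmt(inp$gmt)
    enr <- do.call(rbind, lapply(names(prop), function(p) {
      enrich_gc(prop[[p]]$gc, sets, net$nodes, patient = p)
    }))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    profiles_p <- lapply(split(enr, enr$patient), `[[`, "p_adj")
    subtype_cmp <- suppressWarnings(
      compare_subtype_profiles(profiles_p, clinical)
    )
    utils::write.table(subtype_cmp,
      file.path(out_dir, "subtype_comparison.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    counts$enrichment <- list(
      tests = nrow(enr), subtype_pairs = nrow(subtype_cmp)
    )
  }

  # stage 9: candidate drug targets (optional)
  if (!is.null(inp$pathways) && length(inp$pathways) > 0L) {
    pw <- suppressWarnings(read_pathway_sif(inp$pathways))
    target_rows <- list()
    for (cms in names(consensus)) {
      ids <- intersect(
        clinical$patient_id[!is.na(clinical$subtype) & clinical$subtype == cms],
        names(results)
      )
      if (length(ids) == 0L) next
      ctx <- build_target_context(results, ids, cms, consensus[[cms]])
      if (length(ctx$driver_set) == 0L) next
      tg <- suppressMessages(
        find_candidate_targets(pw, ctx, max_path_len = max_path_len)
      )
      if (nrow(tg) > 0L) {
        tg$subtype <- cms
        target_rows[[cms]] <- tg
      }
    }
    targets <- if (length(target_rows) > 0L) {
      do.call(rbind, target_rows)
    } else {
      data.frame(
        pathway = character(0), gene = character(0),
        upstream = character(0), downstream = character(0),
        subtype = character(0)
      )
    }
    utils::write.table(targets, file.path(out_dir, "candidate_targets.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    counts$targets <- list(candidates = nrow(targets))
  }

  manifest <- list(
    parameters = list(
      r = r, tol = tol, threshold = threshold, de_quantile = de_quantile,
      eps = eps, max_path_len = max_path_len
    ),
    inputs = lapply(
      inp[vapply(inp, function(x) is.character(x) && all(file.exists(x)), logical(1))],
      function(f) unname(tools::md5sum(f))
    ),
    stages = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
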