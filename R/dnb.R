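# Dynamic-network-biomarker (DNB) analysis. Expression fluctuation and
# correlation are measured across patients on per-patient tumor-vs-adjacent
# log-ratios; candidate dominant groups at each driver-mutation step are
# clustered out of the cumulative propagation-module pool inside the giant
# cluster, scored with the criticality index, and the CI peak over the
# driver sequence marks the patient's transition point.

#' Cohort log-ratio matrix
#'
#' Entry (g, p) = log2((tumor_gp + 1) / (adjacent_gp + 1)): the patient's
#' paired expression change for the gene, with a pseudo-count of 1. Genes
#' missing from a patient's profile contribute 0.
#'
#' @param cohort list of `patient_profile` objects (>= 3; standard deviation
#'   and correlation across patients are undefined below that).
#' @param genes character vector of genes to include (rows).
#' @return numeric matrix genes x patients with dimnames.
#' @export
log_ratio_matrix <- function(cohort, genes) {
  if (length(cohort) < 3L) {
    stop("log-ratio matrix needs >= 3 patients", call. = FALSE)
  }
  out <- vapply(cohort, function(p) {
    t <- p$tumor_expr[genes]
    a <- p$adjacent_expr[genes]
    t[is.na(t)] <- 0
    a[is.na(a)] <- 0
    log2((t + 1) / (a + 1))
  }, numeric(length(genes)))
  rownames(out) <- genes
  colnames(out) <- vapply(cohort, `[[`, character(1), "patient_id")
  out
}

#' Precompute per-gene standard deviations and absolute correlations
#'
#' Shared statistics for repeated criticality-index evaluation on the same
#' log-ratio matrix. Zero-variance genes get |r| = 0 against every partner.
#'
#' @param matrix a log-ratio matrix (genes x patients).
#' @return list with `sds` (named numeric) and `acor` (genes x genes
#'   absolute Pearson correlation matrix, zero-variance pairs set to 0).
#' @export
ci_precompute <- function(matrix) {
  sds <- apply(matrix, 1L, stats::sd)
  acor <- abs(suppressWarnings(stats::cor(t(matrix))))
  acor[!is.finite(acor)] <- 0
  list(sds = sds, acor = acor)
}

#' Criticality index of a candidate dominant group
#'
#' CI = size * SD_i * PCC_i / max(PCC_o, eps), where SD_i is the mean
#' standard deviation of group genes across patients, PCC_i the mean
#' absolute Pearson correlation over within-group gene pairs, and PCC_o the
#' mean absolute Pearson correlation over group-by-background pairs. A group
#' nearing a critical transition fluctuates strongly (high SD_i), couples
#' internally (high PCC_i) and decouples from the rest of the network (low
#' PCC_o), so all three push CI up. Pairs involving a zero-variance gene
#' contribute |r| = 0.
#'
#' @param matrix log-ratio matrix (genes x patients, >= 3 patients).
#' @param group character vector of group genes (>= 2).
#' @param background character vector of non-group genes (non-empty);
#'   default: all other matrix genes.
#' @param eps floor on PCC_o; default 1e-8.
#' @param precomp optional result of [ci_precompute()] on `matrix`.
#' @return list with `ci`, `sd_i`, `pcc_i`, `pcc_o`, `size` and
#'   `floor_engaged` (TRUE when PCC_o fell below `eps`).
#' @export
compute_ci <- function(matrix, group, background = NULL, eps = 1e-8,
                       precomp = NULL) {
  group <- unique(group)
  if (length(group) < 2L) {
    stop("dominant group must have >= 2 genes", call. = FALSE)
  }
  if (is.null(background)) background <- setdiff(rownames(matrix), group)
  background <- setdiff(unique(background), group)
  if (length(background) == 0L) {
    stop("empty background gene set", call. = FALSE)
  }
  if (ncol(matrix) < 3L) stop("need >= 3 patients", call. = FALSE)
  if (is.null(precomp)) {
    sub <- matrix[c(group, background), , drop = FALSE]
    precomp <- ci_precompute(sub)
  }
  sd_i <- mean(precomp$sds[group])
  gi <- precomp$acor[group, group, drop = FALSE]
  pcc_i <- mean(gi[upper.tri(gi)])
  pcc_o <- mean(precomp$acor[group, background, drop = FALSE])
  floor_engaged <- pcc_o < eps
  ci <- length(group) * sd_i * pcc_i / max(pcc_o, eps)
  list(
    ci = ci, sd_i = sd_i, pcc_i = pcc_i, pcc_o = pcc_o,
    size = length(group), floor_engaged = floor_engaged
  )
}

#' Dominant group at one driver-mutation step
#'
#' The candidate pool is the union of the propagation modules of the first
#' `step_k` drivers in the patient's sequence, intersected with the giant
#' cluster. A differential filter keeps pool genes whose mean absolute
#' log-ratio across patients reaches the `de_quantile` quantile of the pool.
#' The filtered pool is partitioned by k-medoids on the distance
#' 1 - |Pearson r|, with the number of clusters chosen in
#' \[2, min(8, n - 1)\] by maximum average silhouette width, and the cluster
#' with the highest criticality index is the step's dominant group. Pools
#' with fewer than 4 genes after filtering fall back to the whole pool as a
#' single (flagged) group.
#'
#' @param step_k step index (1-based) into the driver sequence.
#' @param sequence the patient's driver order (a `consensus_order` or a
#'   character vector).
#' @param modules named list of `propagation_module` objects keyed by seed.
#' @param gc the patient's `giant_cluster`.
#' @param matrix cohort log-ratio matrix.
#' @param de_quantile differential-filter quantile in \[0, 1\]; default 0.5.
#' @param eps PCC_o floor passed to [compute_ci()].
#' @param precomp optional [ci_precompute()] result for `matrix`.
#' @return a `dominant_group`: list with `step`, `members`, `ci`, `sd_i`,
#'   `pcc_i`, `pcc_o`, `size`, `k_clusters` (NA on fallback) and `fallback`.
#' @export
dominant_group_at_step <- function(step_k, sequence, modules, gc, matrix,
                                   de_quantile = 0.5, eps = 1e-8,
                                   precomp = NULL) {
  drivers <- if (inherits(sequence, "consensus_order")) sequence$genes else sequence
  stopifnot(step_k >= 1L, step_k <= length(drivers))
  use <- drivers[seq_len(step_k)]
  use <- use[use %in% names(modules)]
  pool <- unique(unlist(lapply(modules[use], `[[`, "members")))
  pool <- intersect(intersect(pool, gc$genes), rownames(matrix))
  if (length(pool) < 2L) {
    stop(sprintf("candidate pool at step %d has < 2 genes", step_k),
      call. = FALSE
    )
  }
  if (is.null(precomp)) precomp <- ci_precompute(matrix)
  de_score <- rowMeans(abs(matrix[pool, , drop = FALSE]))
  cut <- stats::quantile(de_score, de_quantile, names = FALSE)
  keep <- pool[de_score >= cut]
  as_group <- function(members, k_clusters, fallback) {
    res <- compute_ci(matrix, members, eps = eps, precomp = precomp)
    structure(
      c(list(step = step_k, members = sort(members)), res,
        list(k_clusters = k_clusters, fallback = fallback)
      ),
      class = "dominant_group"
    )
  }
  if (length(keep) < 4L) {
    return(as_group(pool, NA_integer_, TRUE))
  }
  d <- stats::as.dist(1 - precomp$acor[keep, keep])
  k_max <- min(8L, length(keep) - 1L)
  best_k <- NULL
  best_sil <- -Inf
  best_fit <- NULL
  for (k in 2:k_max) {
    fit <- cluster::pam(d, k, pamonce = 5)
    sil <- fit$silinfo$avg.width
    if (sil > best_sil + 1e-12) {
      best_sil <- sil
      best_k <- k
      best_fit <- fit
    }
  }
  groups <- split(keep, best_fit$clustering)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  cis <- vapply(
    groups,
    function(g) compute_ci(matrix, g, eps = eps, precomp = precomp)$ci,
    numeric(1)
  )
  as_group(groups[[which.max(cis)]], best_k, FALSE)
}

#' Criticality-index series along a patient's driver sequence
#'
#' @param patient_id patient label recorded on the series.
#' @param sequence the patient's driver order (see
#'   [dominant_group_at_step()]).
#' @param modules,gc,matrix,de_quantile,eps,precomp passed through to
#'   [dominant_group_at_step()].
#' @return a `ci_series`: list with `patient_id`, `drivers` and `groups`
#'   (one `dominant_group` per step).
#' @export
ci_series <- function(patient_id, sequence, modules, gc, matrix,
                      de_quantile = 0.5, eps = 1e-8, precomp = NULL) {
  drivers <- if (inherits(sequence, "consensus_order")) sequence$genes else sequence
  if (length(drivers) == 0L) stop("empty driver sequence", call. = FALSE)
  if (is.null(precomp)) precomp <- ci_precompute(matrix)
  groups <- lapply(seq_along(drivers), function(k) {
    tryCatch(
      dominant_group_at_step(k, drivers, modules, gc, matrix,
        de_quantile = de_quantile, eps = eps, precomp = precomp
      ),
      error = function(e) {
        stop(sprintf("step %d: %s", k, conditionMessage(e)), call. = FALSE)
      }
    )
  })
  structure(
    list(patient_id = patient_id, drivers = drivers, groups = groups),
    class = "ci_series"
  )
}

#' Transition point of a CI series
#'
#' The earliest step attaining the maximum CI; its dominant-group members
#' are the patient's DNB genes and its driver gene marks the transition.
#'
#' @param series a `ci_series`.
#' @return a `transition_point`: list with `patient_id`, `step`, `driver`,
#'   `dnb_genes`, `ci` and `no_signal` (TRUE when the whole series is zero).
#' @export
transition_point <- function(series) {
  stopifnot(inherits(series, "ci_series"))
  ci <- vapply(series$groups, `[[`, numeric(1), "ci")
  no_signal <- all(ci == 0)
  if (no_signal) {
    warning(sprintf(
      "patient %s: all-zero CI series, no transition signal",
      series$patient_id
    ), call. = FALSE)
  }
  step <- which.max(ci) # earliest max
  structure(
    list(
      patient_id = series$patient_id,
      step = step,
      driver = series$drivers[step],
      dnb_genes = series$groups[[step]]$members,
      ci = ci[step],
      no_signal = no_signal
    ),
    class = "transition_point"
  )
}

#' Validate transition order against clinical stage
#'
#' Within each subtype, for every ordered patient pair (e in an earlier
#' stage, l in a later stage), the pair is consistent iff every transition
#' driver of e that appears in l's driver order precedes every transition
#' driver of l in that order; pairs whose early-patient transition drivers
#' are all absent from the late patient's order are not evaluable. The
#' overall fraction counts consistent pairs over all compared pairs
#' (consistent + inconsistent + not evaluable), so missing genes weigh
#' against consistency.
#'
#' @param results named list (by patient id), each element a list with
#'   `transition` (a `transition_point`, or a character vector of transition
#'   driver genes) and `order` (the patient's driver order, character).
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @return list with `pairs` (one row per compared pair: subtype, early,
#'   late, status), `by_subtype` (counts) and `fraction` (overall
#'   consistency fraction; NA when no pairs are comparable).
#' @export
validate_clinical_order <- function(results, clinical) {
  getgenes <- function(x) {
    if (inherits(x$transition, "transition_point")) x$transition$driver
    else as.character(x$transition)
  }
  rows <- list()
  for (cms in sort(unique(stats::na.omit(clinical$subtype)))) {
    ids <- clinical$patient_id[
      !is.na(clinical$subtype) & clinical$subtype == cms &
        !is.na(clinical$stage)
    ]
    ids <- intersect(ids, names(results))
    if (length(ids) < 2L) next
    stage <- stats::setNames(
      clinical$stage[match(ids, clinical$patient_id)], ids
    )
    for (e in ids) {
      for (l in ids) {
        if (stage[e] >= stage[l]) next
        ord_l <- results[[l]]$order
        g_e <- intersect(getgenes(results[[e]]), ord_l)
        g_l <- intersect(getgenes(results[[l]]), ord_l)
        status <- if (length(g_e) == 0L || length(g_l) == 0L) {
          "not_evaluable"
        } else if (max(match(g_e, ord_l)) < min(match(g_l, ord_l))) {
          "consistent"
        } else {
          "inconsistent"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subtype = cms, early = e, late = l, status = status,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    warning("no evaluable patient pairs for clinical validation",
      call. = FALSE
    )
    return(list(
      pairs = data.frame(
        subtype = character(0), early = character(0),
        late = character(0), status = character(0)
      ),
      by_subtype = data.frame(),
      fraction = NA_real_
    ))
  }
  pairs <- do.call(rbind, rows)
  tab <- table(pairs$subtype, factor(
    pairs$status,
    levels = c("consistent", "inconsistent", "not_evaluable")
  ))
  by_subtype <- as.data.frame.matrix(tab)
  by_subtype$subtype <- rownames(by_subtype)
  rownames(by_subtype) <- NULL
  list(
    pairs = pairs,
    by_subtype = by_subtype[, c("subtype", "consistent", "inconsistent", "not_evaluable")],
    fraction = mean(pairs$status == "consistent")
  )
}
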