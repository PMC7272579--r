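# Replicated simulation studies over synthetic cohorts: RWR oracle
# agreement, planted-DNB transition recovery, consensus-order recovery and
# clinical-order validation. These back both the test suite and the
# results-reproduction script, so the study conditions live here, not in
# scripts.

#' Compare iterative RWR with the direct linear solve on random graphs
#'
#' For each replicate, draws a connected preferential-attachment graph
#' (10-200 nodes), a random seed node and a random restart probability, and
#' compares the power-iteration scores with the closed-form stationary
#' solution p = r (I - (1 - r) M)^-1 e_seed.
#'
#' @param n_graphs number of random (graph, seed, r) triples.
#' @param seed RNG seed.
#' @return data.frame with columns `n`, `r` and `max_abs_err` per replicate.
#' @export
rwr_oracle_study <- function(n_graphs = 50L, seed = 1L) {
  set.seed(seed)
  cases <- data.frame(
    n = sample(10:200, n_graphs, replace = TRUE),
    m = sample(1:3, n_graphs, replace = TRUE),
    r = stats::runif(n_graphs, 0.3, 0.9),
    gseed = sample.int(1e6, n_graphs)
  )
  cases$max_abs_err <- vapply(seq_len(n_graphs), function(i) {
    cfg <- synthetic_config(
      seed = cases$gseed[i], n_genes = cases$n[i], m = cases$m[i]
    )
    net <- generate_network(cfg)
    node <- sample(net$nodes, 1L)
    res <- rwr(net, node, r = cases$r[i])
    tm <- column_normalize(net)
    e <- stats::setNames(numeric(length(tm$nodes)), tm$nodes)
    e[node] <- 1
    direct <- cases$r[i] * solve(
      diag(length(e)) - (1 - cases$r[i]) * as.matrix(tm$M), e
    )
    max(abs(res$scores - direct))
  }, numeric(1))
  cases
}

# Shared per-cohort machinery: patient networks, propagation, giant
# clusters and the cohort log-ratio matrix.
#' @keywords internal
#' @noRd
cohort_propagation <- function(cohort, r = 0.7, tol = 1e-10,
                               threshold = 0.001) {
  pnets <- lapply(cohort$profiles, function(p) {
    build_patient_network(cohort$network, p)
  })
  prop <- lapply(pnets, propagate_patient, r = r, tol = tol,
    threshold = threshold
  )
  matrix <- log_ratio_matrix(cohort$profiles, cohort$network$nodes)
  list(
    pnets = pnets, prop = prop, matrix = matrix,
    precomp = ci_precompute(matrix)
  )
}

#' One planted-DNB recovery replicate
#'
#' Generates a cohort, propagates every patient's seeds, and runs the DNB
#' stage along each eligible patient's (planted, noisy) driver sequence.
#' Eligible patients are those whose mutated driver prefix reaches the
#' planted transition step k*. The replicate's detected step is the median,
#' over eligible patients, of the planted-order position of each patient's
#' transition driver; the detected DNB set holds the genes present in at
#' least half of those patients' transition dominant groups.
#'
#' @param config a `synthetic_config`.
#' @return list with `detected_step`, `jaccard` (detected vs planted DNB
#'   genes), `n_eligible` and `per_patient` (data.frame).
#' @export
planted_dnb_replicate <- function(config) {
  cohort <- generate_cohort(config)
  run <- cohort_propagation(cohort)
  truth <- cohort$truth
  eligible <- names(truth$prefix_len)[truth$prefix_len >= truth$k_star]
  stopifnot(length(eligible) > 0L)
  steps <- numeric(0)
  groups <- list()
  for (p in eligible) {
    seqs <- truth$sequences[[p]]
    series <- ci_series(p, seqs, run$prop[[p]]$modules, run$prop[[p]]$gc,
      run$matrix, precomp = run$precomp
    )
    tp <- transition_point(series)
    steps[p] <- match(tp$driver, truth$planted_order)
    groups[[p]] <- tp$dnb_genes
  }
  tab <- table(unlist(lapply(groups, unique)))
  detected <- names(tab)[tab >= length(eligible) / 2]
  jac <- length(intersect(detected, truth$dnb_genes)) /
    length(union(detected, truth$dnb_genes))
  list(
    detected_step = stats::median(steps),
    jaccard = jac,
    n_eligible = length(eligible),
    per_patient = data.frame(patient = eligible, step = unname(steps))
  )
}

#' Replicated planted-DNB recovery study
#'
#' @param n_reps number of replicates (each a fresh cohort seed).
#' @param base_seed first cohort seed; replicate i uses `base_seed + i - 1`.
#' @param ... overrides passed to [synthetic_config()].
#' @return list with `reps` (data.frame: seed, detected_step, jaccard,
#'   success), `success_rate` (fraction of replicates whose detected step is
#'   within 1 of the planted k*) and `mean_jaccard_success`.
#' @export
planted_dnb_study <- function(n_reps = 50L, base_seed = 1L, ...) {
  rows <- lapply(seq_len(n_reps), function(i) {
    cfg <- synthetic_config(seed = base_seed + i - 1L, ...)
    rep <- planted_dnb_replicate(cfg)
    data.frame(
      seed = cfg$seed,
      detected_step = rep$detected_step,
      jaccard = rep$jaccard,
      success = abs(rep$detected_step - cfg$k_star) <= 1
    )
  })
  reps <- do.call(rbind, rows)
  list(
    reps = reps,
    success_rate = mean(reps$success),
    mean_jaccard_success = mean(reps$jaccard[reps$success])
  )
}

#' Consensus-order recovery on one cohort
#'
#' Builds one precedence matrix per patient from the cohort's planted
#' (noise-scrambled) driver sequences, aggregates them into a consensus
#' order, and returns the Kendall tau between the consensus and the planted
#' order over the recovered genes.
#'
#' @param config a `synthetic_config`.
#' @return list with `tau`, `consensus` (a `consensus_order`) and
#'   `planted_order`.
#' @export
consensus_recovery <- function(config) {
  cohort <- generate_cohort(config)
  truth <- cohort$truth
  matrices <- lapply(truth$sequences, function(s) pairwise_precedence(list(s)))
  cons <- consensus_order(matrices, truth$drivers, label = "cohort")
  planted <- truth$planted_order[truth$planted_order %in% cons$genes]
  tau <- stats::cor(
    match(planted, planted), match(planted, cons$genes),
    method = "kendall"
  )
  list(tau = tau, consensus = cons, planted_order = truth$planted_order)
}

#' Replicated consensus-order recovery study
#'
#' @param n_reps replicates.
#' @param base_seed first seed.
#' @param p_swap pairwise order-noise level.
#' @param n_patients cohort size (default 12, full driver prefixes).
#' @param ... further overrides for [synthetic_config()].
#' @return data.frame with `seed` and `tau` per replicate.
#' @export
consensus_study <- function(n_reps = 20L, base_seed = 1L, p_swap = 0.1,
                            n_patients = 12L, ...) {
  rows <- lapply(seq_len(n_reps), function(i) {
    cfg <- synthetic_config(
      seed = base_seed + i - 1L, p_swap = p_swap,
      n_patients = n_patients, prefix_range = c(8L, 8L), ...
    )
    data.frame(seed = cfg$seed, tau = consensus_recovery(cfg)$tau)
  })
  do.call(rbind, rows)
}

#' Clinical-order validation on planted transitions
#'
#' Uses the cohort's planted per-patient driver sequences and takes each
#' patient's transition driver to be the last driver of their mutated
#' prefix. With noise-free planted orders the stage bands are consistent
#' with transition order by construction; optionally the stage labels are
#' shuffled to destroy that agreement.
#'
#' @param config a `synthetic_config` (use `p_swap = 0` for the consistent
#'   case).
#' @param shuffle_stages logical; permute stage labels across patients.
#' @return the [validate_clinical_order()] report.
#' @export
clinical_validation_replicate <- function(config, shuffle_stages = FALSE) {
  cohort <- generate_cohort(config)
  truth <- cohort$truth
  results <- lapply(names(cohort$profiles), function(p) {
    s <- truth$sequences[[p]]
    list(transition = s[length(s)], order = s)
  })
  names(results) <- names(cohort$profiles)
  clinical <- cohort$clinical
  if (shuffle_stages) {
    clinical$stage <- sample(clinical$stage)
  }
  validate_clinical_order(results, clinical)
}
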