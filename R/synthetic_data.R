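# Synthetic cohorts with planted ground truth: a preferential-attachment
# interaction network, per-patient somatic mutations following a planted
# driver order with tunable pairwise noise, and paired tumor/adjacent
# expression carrying a planted DNB group (correlated, high-variance genes
# attached to the driver at the planted transition step). Every pipeline
# stage is testable against the truth record without external downloads.

#' Synthetic cohort configuration
#'
#' Defaults are the package's reference study conditions: a 300-gene
#' preferential-attachment network (m = 2), 24 patients, 8 planted drivers,
#' a 6-gene planted DNB group with within-group correlation 0.8 against a
#' background correlation of 0.1 and a 3:1 SD inflation for patients whose
#' mutated driver prefix reaches the planted transition step k* = 5, and
#' pairwise order noise p_swap = 0.1.
#'
#' @param seed RNG seed (integer).
#' @param n_genes number of network genes (>= 10).
#' @param m preferential-attachment edges per new node.
#' @param n_patients cohort size.
#' @param n_drivers number of planted driver genes (placed on the
#'   highest-degree nodes).
#' @param p_swap order-noise level: probability that an adjacent driver pair
#'   of a patient's sequence is discordant with the planted order (0 =
#'   exact; >= 0.5 = a uniform random permutation, no order signal).
#' @param passengers_range integer range (min, max) of passenger mutations
#'   per patient, sampled from network neighborhoods of mutated drivers.
#' @param prefix_range integer range of the mutated driver prefix length.
#' @param dnb_size planted DNB group size (>= 2).
#' @param rho_in,rho_out target within-group / group-to-background absolute
#'   correlation of the planted group (rho_in > rho_out >= 0, rho_in < 1).
#' @param bg_block_size,bg_rho background genes are organized into
#'   co-expression blocks of this size with within-block correlation
#'   `bg_rho`, emulating the co-expressed modules of real expression data;
#'   cross-block correlation is negligible.
#' @param sd_ratio SD inflation factor of planted-group genes in patients
#'   whose prefix reaches `k_star`.
#' @param sd_low baseline log2 effect SD of background genes.
#' @param noise_sd technical log-noise SD of each expression measurement.
#' @param k_star planted transition step (position in the planted order);
#'   default 3, the start of the stage-2 band under the quartile stage rule,
#'   so that most of the cohort progresses past the planted tipping point.
#' @param n_subtypes number of CMS labels cycled over patients.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 300L, m = 2L,
                             n_patients = 24L, n_drivers = 8L,
                             p_swap = 0.1, passengers_range = c(3L, 6L),
                             prefix_range = c(1L, n_drivers),
                             dnb_size = 6L, rho_in = 0.8, rho_out = 0.1,
                             bg_block_size = 10L, bg_rho = 0.45,
                             sd_ratio = 3, sd_low = 0.4, noise_sd = 0.05,
                             k_star = 3L, n_subtypes = 2L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes), m = as.integer(m),
    n_patients = as.integer(n_patients), n_drivers = as.integer(n_drivers),
    p_swap = p_swap, passengers_range = as.integer(passengers_range),
    prefix_range = as.integer(prefix_range), dnb_size = as.integer(dnb_size),
    rho_in = rho_in, rho_out = rho_out,
    bg_block_size = as.integer(bg_block_size), bg_rho = bg_rho,
    sd_ratio = sd_ratio,
    sd_low = sd_low, noise_sd = noise_sd, k_star = as.integer(k_star),
    n_subtypes = as.integer(n_subtypes)
  )
  if (cfg$n_genes < 10L) stop("n_genes must be >= 10", call. = FALSE)
  if (cfg$m < 1L || cfg$m >= cfg$n_genes) {
    stop("attachment parameter m must satisfy 1 <= m < n_genes", call. = FALSE)
  }
  if (cfg$n_drivers > cfg$n_genes) stop("n_drivers > n_genes", call. = FALSE)
  if (cfg$dnb_size < 2L) stop("dnb_size must be >= 2", call. = FALSE)
  if (!(cfg$rho_in > cfg$rho_out && cfg$rho_out >= 0)) {
    stop("need rho_in > rho_out >= 0", call. = FALSE)
  }
  if (cfg$rho_in >= 1) stop("rho_in must be < 1", call. = FALSE)
  if (cfg$bg_rho < 0 || cfg$bg_rho >= 1) stop("bg_rho in [0, 1)", call. = FALSE)
  if (cfg$rho_out > sqrt(cfg$rho_in * cfg$bg_rho)) {
    stop("infeasible: rho_out exceeds sqrt(rho_in * bg_rho)", call. = FALSE)
  }
  if (cfg$k_star < 1L || cfg$k_star > cfg$n_drivers) {
    stop("k_star must be in 1..n_drivers", call. = FALSE)
  }
  if (cfg$p_swap < 0 || cfg$p_swap > 1) stop("p_swap in [0, 1]", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a preferential-attachment gene network
#'
#' Starts from a complete graph on m + 1 nodes; each subsequent node
#' attaches m edges to distinct existing nodes chosen with probability
#' proportional to degree. The result is connected with
#' `choose(m + 1, 2) + m * (n - m - 1)` edges, and identical for identical
#' seeds.
#'
#' @param config a `synthetic_config`.
#' @return a [gene_network] with nodes `G001`, `G002`, ...
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$m
  names_g <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
  core <- utils::combn(seq_len(m + 1L), 2L)
  from <- core[1, ]
  to <- core[2, ]
  deg <- integer(n)
  deg[seq_len(m + 1L)] <- m
  for (v in (m + 2L):n) {
    targets <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)])
    from <- c(from, rep(v, m))
    to <- c(to, targets)
    deg[targets] <- deg[targets] + 1L
    deg[v] <- m
  }
  gene_network(names_g[from], names_g[to])
}

# sample() treats a length-1 numeric first argument as 1:n; guard against it
#' @keywords internal
#' @noRd
sample_range <- function(a, b) {
  if (a >= b) return(as.integer(a))
  sample(seq.int(a, b), 1L)
}

# Rank-noise (Thurstonian) order scramble: each element's planted rank is
# perturbed by Gaussian noise scaled so that an adjacent pair is discordant
# with probability p_swap; distant pairs flip correspondingly less often.
# p_swap >= 0.5 degenerates to a uniform random permutation, so the order
# carries no signal at all.
#' @keywords internal
#' @noRd
scramble_order <- function(seq, p_swap) {
  L <- length(seq)
  if (L < 2L || p_swap <= 0) return(seq)
  if (p_swap >= 0.5) return(sample(seq))
  sigma <- 1 / (sqrt(2) * stats::qnorm(1 - p_swap))
  seq[order(seq_len(L) + stats::rnorm(L, 0, sigma))]
}

#' Generate per-patient mutations with a planted driver order
#'
#' Drivers occupy the highest-degree network nodes; the planted order is a
#' random permutation of them. Each patient mutates a prefix of the planted
#' order (length sampled from `prefix_range`), scrambled by pairwise noise
#' `p_swap`, plus passenger mutations sampled from network neighbors of the
#' mutated drivers (guaranteeing propagation-module overlap). The clinical
#' stage is the quartile band of the prefix length
#' (`ceiling(4 * prefix / n_drivers)`), so transition order and stage agree
#' by construction; subtypes cycle CMS1..CMSn.
#'
#' @param config a `synthetic_config`.
#' @param network the cohort [gene_network].
#' @return list with `catalog` (patient -> mutated genes), `clinical`
#'   (data.frame patient_id/stage/subtype) and `truth` (planted order,
#'   drivers, per-patient noisy driver sequences, prefix lengths,
#'   passengers).
#' @export
generate_mutations <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"), inherits(network, "gene_network"))
  set.seed(config$seed + 1L)
  deg <- network_degree(network)
  drivers <- names(sort(deg, decreasing = TRUE))[seq_len(config$n_drivers)]
  planted <- sample(drivers)
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  sequences <- list()
  catalog <- list()
  prefix_len <- integer(config$n_patients)
  passengers <- list()
  for (i in seq_len(config$n_patients)) {
    L <- sample_range(config$prefix_range[1], config$prefix_range[2])
    prefix_len[i] <- L
    seq_i <- scramble_order(planted[seq_len(L)], config$p_swap)
    pool <- setdiff(unique(unlist(network$adj[seq_i])), drivers)
    n_pass <- sample_range(config$passengers_range[1], config$passengers_range[2])
    pass <- if (length(pool) <= n_pass) pool else sample(pool, n_pass)
    sequences[[ids[i]]] <- seq_i
    passengers[[ids[i]]] <- sort(pass)
    catalog[[ids[i]]] <- sort(c(seq_i, pass))
  }
  clinical <- data.frame(
    patient_id = ids,
    stage = as.integer(ceiling(4 * prefix_len / config$n_drivers)),
    subtype = paste0("CMS", ((seq_len(config$n_patients) - 1L) %% config$n_subtypes) + 1L),
    stringsAsFactors = FALSE
  )
  list(
    catalog = catalog,
    clinical = clinical,
    truth = list(
      drivers = sort(drivers),
      planted_order = planted,
      sequences = sequences,
      prefix_len = stats::setNames(prefix_len, ids),
      passengers = passengers
    )
  )
}

#' Generate paired expression with a planted DNB group
#'
#' Adjacent samples are log-normal baseline noise around per-gene base
#' levels. Tumor samples add per-gene log2 effects: background genes carry a
#' weak global factor (pairwise correlation ~ rho_out, SD `sd_low`); the
#' planted DNB group -- `dnb_size` neighbors of the driver at the planted
#' step k*, hence inside that driver's propagation module -- shares a latent
#' factor giving within-group correlation ~ rho_in, group-to-background
#' correlation ~ rho_out, with SD inflated by `sd_ratio` in patients whose
#' mutated prefix reaches k*.
#'
#' @param config a `synthetic_config`.
#' @param network the cohort [gene_network].
#' @param mutinfo result of [generate_mutations()].
#' @return list with `tumor` and `adjacent` (genes x patients matrices) and
#'   `truth` (`dnb_genes`, `k_star`, `k_star_driver`).
#' @export
generate_expression <- function(config, network, mutinfo) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  genes <- network$nodes
  ids <- names(mutinfo$catalog)
  n <- length(genes)
  np <- length(ids)
  planted <- mutinfo$truth$planted_order
  k_driver <- planted[config$k_star]
  pool <- setdiff(network$adj[[k_driver]], mutinfo$truth$drivers)
  if (length(pool) < config$dnb_size) {
    pool <- unique(c(pool, setdiff(
      unlist(network$adj[network$adj[[k_driver]]]), mutinfo$truth$drivers
    )))
  }
  if (length(pool) < config$dnb_size) {
    stop("not enough genes near the transition driver to plant the DNB group",
      call. = FALSE
    )
  }
  dnb <- sort(sample(pool, config$dnb_size))
  reaches <- mutinfo$truth$prefix_len[ids] >= config$k_star
  base <- stats::rnorm(n, log(100), 0.5)
  f_grp <- stats::rnorm(np) # latent factor of the planted group
  delta <- matrix(0, n, np, dimnames = list(genes, ids))
  is_dnb <- genes %in% dnb
  # background co-expression blocks follow network locality (co-expression
  # tracks interaction neighborhoods): genes are chunked along a BFS order
  # of the network, and each block factor is weakly coupled to the group
  # factor so that cor(group gene, background gene) ~ rho_out
  bfs_order <- unlist(induced_components(network, network$nodes))
  bg_genes <- setdiff(bfs_order, dnb)
  bg_idx <- match(bg_genes, genes)
  n_blocks <- max(1L, ceiling(length(bg_idx) / config$bg_block_size))
  block_of <- rep(seq_len(n_blocks), each = config$bg_block_size,
    length.out = length(bg_idx)
  )
  w <- config$rho_out / sqrt(config$rho_in * config$bg_rho)
  h <- w * matrix(f_grp, n_blocks, np, byrow = TRUE) +
    sqrt(1 - w^2) * matrix(stats::rnorm(n_blocks * np), n_blocks, np)
  delta[bg_idx, ] <- config$sd_low * (
    sqrt(config$bg_rho) * h[block_of, , drop = FALSE] +
      sqrt(1 - config$bg_rho) * matrix(stats::rnorm(length(bg_idx) * np),
        length(bg_idx), np
      )
  )
  scale_p <- ifelse(reaches, config$sd_ratio, 1) * config$sd_low
  for (g in which(is_dnb)) {
    delta[g, ] <- scale_p * (
      sqrt(config$rho_in) * f_grp +
        sqrt(1 - config$rho_in) * stats::rnorm(np)
    )
  }
  eps_a <- matrix(stats::rnorm(n * np, 0, config$noise_sd), n, np)
  eps_t <- matrix(stats::rnorm(n * np, 0, config$noise_sd), n, np)
  adjacent <- exp(base + eps_a)
  tumor <- adjacent * 2^delta * exp(eps_t - eps_a)
  dimnames(adjacent) <- dimnames(tumor) <- list(genes, ids)
  list(
    tumor = tumor,
    adjacent = adjacent,
    truth = list(dnb_genes = dnb, k_star = config$k_star,
      k_star_driver = k_driver)
  )
}

#' Generate a full synthetic cohort
#'
#' Runs [generate_network()], [generate_mutations()] and
#' [generate_expression()] under one configuration and assembles
#' per-patient profiles. Byte-identical for identical configurations.
#'
#' @param config a `synthetic_config` (default: reference conditions).
#' @return a `synthetic_cohort`: list with `config`, `network`, `profiles`
#'   (named list of `patient_profile`), `clinical` and `truth` (planted
#'   order, per-patient sequences, DNB genes, k*).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  network <- generate_network(config)
  muts <- generate_mutations(config, network)
  expr <- generate_expression(config, network, muts)
  ids <- names(muts$catalog)
  profiles <- lapply(ids, function(p) {
    row <- muts$clinical[muts$clinical$patient_id == p, ]
    structure(
      list(
        patient_id = p,
        tumor_expr = expr$tumor[, p],
        adjacent_expr = expr$adjacent[, p],
        mutations = muts$catalog[[p]],
        stage = row$stage,
        subtype = row$subtype
      ),
      class = "patient_profile"
    )
  })
  structure(
    list(
      config = config,
      network = network,
      profiles = stats::setNames(profiles, ids),
      clinical = muts$clinical,
      truth = c(muts$truth, expr$truth)
    ),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to the standard input file formats
#'
#' Emits `ppi.tsv` (edge list), `expr.tsv` + `manifest.tsv`,
#' `mutations.tsv` (MAF-lite), `clinical.tsv`, `drivers.txt` and
#' `truth.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_network(cohort$network, file.path(dir, "ppi.tsv"))
  ids <- names(cohort$profiles)
  tum <- vapply(cohort$profiles, `[[`, numeric(length(cohort$network$nodes)),
    "tumor_expr"
  )
  adj <- vapply(cohort$profiles, `[[`, numeric(length(cohort$network$nodes)),
    "adjacent_expr"
  )
  colnames(tum) <- paste0(ids, "_T")
  colnames(adj) <- paste0(ids, "_N")
  expr <- data.frame(gene = cohort$network$nodes, tum, adj,
    check.names = FALSE
  )
  utils::write.table(expr, file.path(dir, "expr.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- data.frame(
    sample_id = c(colnames(tum), colnames(adj)),
    patient_id = rep(ids, 2L),
    role = rep(c("tumor", "adjacent"), each = length(ids))
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  maf <- do.call(rbind, lapply(ids, function(p) {
    data.frame(sample_id = p, gene_symbol = cohort$profiles[[p]]$mutations)
  }))
  utils::write.table(maf, file.path(dir, "mutations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(cohort$truth$drivers, file.path(dir, "drivers.txt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
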