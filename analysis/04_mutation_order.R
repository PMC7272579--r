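#!/usr/bin/env Rscript
# Infer mutation order: greedy minimal-growth sequences per patient, the
# pairwise precedence matrix, per-patient driver orders, and per-subtype
# consensus orders. The planted (ground-truth) sequences give the upper
# bound on what consensus aggregation recovers.

source("analysis/00_config.R")

cohort <- generate_cohort(ref_config())
truth <- cohort$truth

orders <- list()
matrices <- list()
for (prof in cohort$profiles) {
  pn <- build_patient_network(cohort$network, prof)
  out <- propagate_patient(pn)
  seqs <- suppressWarnings(enumerate_sequences(pn, out$modules, truth$drivers))
  if (length(seqs) == 0L) next
  pm <- pairwise_precedence(seqs)
  drv <- intersect(rownames(pm), truth$drivers)
  if (length(drv) == 0L) next
  matrices[[prof$patient_id]] <- pm
  orders[[prof$patient_id]] <- derive_order(pm, drv, scope = prof$patient_id)
}

order_tab <- data.frame(
  patient = names(orders),
  driver_order = vapply(orders, function(o) paste(o$genes, collapse = ">"),
    character(1)
  )
)
write_tsv(order_tab, "driver_orders.tsv")

tau_vs_planted <- function(genes) {
  planted <- truth$planted_order[truth$planted_order %in% genes]
  if (length(planted) < 3L) return(NA_real_)
  stats::cor(match(planted, planted), match(planted, genes), method = "kendall")
}

cons_rows <- list()
for (cms in sort(unique(cohort$clinical$subtype))) {
  ids <- intersect(
    cohort$clinical$patient_id[cohort$clinical$subtype == cms],
    names(matrices)
  )
  if (length(ids) == 0L) next
  greedy_cons <- consensus_order(matrices[ids], truth$drivers, label = cms)
  planted_cons <- consensus_order(
    lapply(truth$sequences[ids], function(s) pairwise_precedence(list(s))),
    truth$drivers, label = cms
  )
  cons_rows[[cms]] <- data.frame(
    subtype = cms,
    n_patients = length(ids),
    greedy_consensus = paste(greedy_cons$genes, collapse = ">"),
    tau_greedy = tau_vs_planted(greedy_cons$genes),
    planted_seq_consensus = paste(planted_cons$genes, collapse = ">"),
    tau_planted_seqs = tau_vs_planted(planted_cons$genes)
  )
}
cons <- do.call(rbind, cons_rows)
write_tsv(cons, "consensus_orders.tsv")
message("planted order: ", paste(truth$planted_order, collapse = ">"))
message(sprintf(
  "consensus from planted sequences recovers the order at tau = %.2f; the greedy module-growth order is structural (tau = %.2f) and is used as each patient's step axis downstream",
  mean(cons$tau_planted_seqs, na.rm = TRUE),
  mean(cons$tau_greedy, na.rm = TRUE)
))
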