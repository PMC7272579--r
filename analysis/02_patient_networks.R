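#!/usr/bin/env Rscript
# Build each patient's specific network: global PPI edges survive iff both
# endpoint genes are expressed in at least one of the patient's two tissue
# samples; the patient's mutated genes present in the filtered network
# become the propagation seeds.

source("analysis/00_config.R")

cohort <- generate_cohort(ref_config())
tab <- do.call(rbind, lapply(cohort$profiles, function(prof) {
  pn <- build_patient_network(cohort$network, prof)
  data.frame(
    patient = prof$patient_id,
    nodes = length(pn$graph$nodes),
    edges = nrow(pn$graph$edges),
    mutations = length(prof$mutations),
    seeds = length(pn$seeds),
    stage = prof$stage,
    subtype = prof$subtype
  )
}))
write_tsv(tab, "patient_networks.tsv")
message(sprintf(
  "patient networks: %d-%d nodes, %d-%d seeds per patient",
  min(tab$nodes), max(tab$nodes), min(tab$seeds), max(tab$seeds)
))
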