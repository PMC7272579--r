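# Shared settings for the analysis scripts: the reference synthetic cohort
# is regenerated deterministically from this configuration, so every script
# can be run on its own. Outputs go under results/.

library(tippingnet)

REF_SEED <- 1L
ref_config <- function() synthetic_config(seed = REF_SEED)
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

write_tsv <- function(x, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
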