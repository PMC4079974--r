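# Shared study configuration for the analysis workflow. Every numbered
# script rebuilds the panel deterministically from this seed, so the
# scripts can be run independently and in any order.

library(genarch)

study_config <- function(seed = 20260923L) {
  sim_config(n_lines = 100, seed = seed)
}

study_panel <- function(cfg = study_config()) {
  simulate_panel(cfg, phenotypes = TRUE)
}

contig_lengths <- function(cfg) {
  setNames(cfg$contigs$length, cfg$contigs$name)
}

inversion_regions <- function(cfg) {
  data.frame(contig = vapply(cfg$inversions, `[[`, character(1), "arm"),
             start = vapply(cfg$inversions, `[[`, numeric(1), "start"),
             end = vapply(cfg$inversions, `[[`, numeric(1), "end"),
             name = vapply(cfg$inversions, `[[`, character(1), "name"))
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
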