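# Shared simulated panels, built once per test run.
.panel_cache <- new.env(parent = emptyenv())

cached_panel <- function(key = "default") {
  if (is.null(.panel_cache[[key]])) {
    cfg <- switch(key,
      default = sim_config(n_lines = 60, seed = 101),
      nolinv = sim_config(n_lines = 40, seed = 202, inversions = list(),
                          snp_rate = 0.002, indel_rate = 5e-4,
                          contigs = data.frame(name = c("2L", "X"),
                                               length = c(2e5, 2e5),
                                               is_X = c(FALSE, TRUE))),
      stop("unknown panel key"))
    .panel_cache[[key]] <- simulate_panel(cfg, phenotypes = TRUE)
    .panel_cache[[paste0(key, "_cfg")]] <- cfg
  }
  .panel_cache[[key]]
}

cached_config <- function(key = "default") {
  cached_panel(key)
  .panel_cache[[paste0(key, "_cfg")]]
}

# A tiny single-exon gene on a short contig, for annotation tests.
tiny_gene_fixture <- function(cds_len = 60L, strand = "+", seed = 7L) {
  set.seed(seed)
  L <- 200L
  exons <- rbind(c(10L, 10L + cds_len + 20L))
  cds <- c(20L, 20L + cds_len)
  g <- gene_model("tg1", "c1", strand,
                  list(list(tx_id = "tg1_t1", exons = exons, cds = cds)))
  seq <- patch_gene_sequences(rand_dna(L), list(g))
  list(gene = g, seq = seq)
}
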