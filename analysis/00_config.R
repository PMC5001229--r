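# Shared settings for the analysis scripts. Every script regenerates the
# simulated study deterministically from this configuration, so the steps
# can be run independently or in order.

library(psikit)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

## The emulated study: two conditions in triplicate, 75-nt single-end
## reads, four AS event classes in roughly the proportions a genome-wide
## screen yields, a third of events truly affected with moderate-to-large
## shifts in exon inclusion.
study_config <- function(seed = 42L) {
  sim_config(n_genes = 150,
             event_type_mix = c(cassette = 0.42, alt5 = 0.14,
                                alt3 = 0.23, retained_intron = 0.21),
             read_length = 75L,
             depth_per_event = 1000,
             n_replicates = 3L,
             delta_psi_effects = c(0.1, 0.2, 0.3),
             frac_affected = 0.3,
             seed = seed)
}

study_pipeline_config <- function(seed = 42L, out_dir = RESULTS_DIR) {
  pipeline_config(sim = study_config(seed), out_dir = out_dir)
}

## Rebuild the simulated study (deterministic given the seed).
build_study <- function(seed = 42L) {
  cfg <- study_config(seed)
  tx <- make_transcriptome(cfg)
  list(cfg = cfg,
       tx = tx,
       truth = make_truth(tx, cfg),
       eff = effective_sizes_table(tx, cfg$read_length))
}
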