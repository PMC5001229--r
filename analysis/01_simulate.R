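#!/usr/bin/env Rscript
# Simulate the two-condition splicing study: transcript models, genome,
# ground-truth PSI per condition, and replicate read-class counts.
source("analysis/00_config.R")

study <- build_study()
counts <- simulate_counts(study$tx, study$truth, study$cfg, study$eff)
fixtures <- make_annotation_fixtures(study$tx)

write_genome_fasta(study$tx, file.path(RESULTS_DIR, "genome.fa"))
write_transcripts_gff3(study$tx, file.path(RESULTS_DIR, "transcripts.gff3"))
write_tsv(counts, file.path(RESULTS_DIR, "counts.tsv"))
write_tsv(study$truth, file.path(RESULTS_DIR, "truth.tsv"))
write_tsv(study$eff, file.path(RESULTS_DIR, "effective_sizes.tsv"))
write_tsv(fixtures$domains, file.path(RESULTS_DIR, "fixture_domains.tsv"))
write_tsv(fixtures$disorder, file.path(RESULTS_DIR, "fixture_disorder.tsv"))
write_tsv(fixtures$ptm, file.path(RESULTS_DIR, "fixture_ptm.tsv"))
write_meme(fixtures$pwms, file.path(RESULTS_DIR, "fixture_motifs.meme"))

types <- table(vapply(study$tx$events, `[[`, "", "event_type"))
message(sprintf("simulated %d events (%s); %d truly differential; %d untestable",
                length(study$tx$events),
                paste(names(types), types, sep = ":", collapse = ", "),
                sum(study$truth$is_differential),
                sum(!study$eff$testable)))
message(sprintf("wrote genome, transcript models, counts and annotation fixtures to %s/",
                RESULTS_DIR))
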