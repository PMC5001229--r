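#!/usr/bin/env Rscript
# Translate each frame-preserving coding AS region with 30-nt exonic
# flanks and intersect the peptides with protein-domain intervals.
source("analysis/00_config.R")

study <- build_study()
counts <- simulate_counts(study$tx, study$truth, study$cfg, study$eff)
calls <- call_events(counts, study$eff)
passing <- calls$calls$event_id[calls$calls$passes]
fixtures <- make_annotation_fixtures(study$tx)

peptides <- fixtures$peptides[fixtures$peptides$event_id %in% passing, ]
write_tsv(peptides[, c("event_id", "protein_id", "aa_start", "aa_end",
                       "peptide")],
          file.path(RESULTS_DIR, "flanked_peptides.tsv"))
overlaps <- overlap_domains(peptides, fixtures$domains)
write_tsv(overlaps, file.path(RESULTS_DIR, "domain_overlaps.tsv"))

message(sprintf("translated %d flanked AS peptides from passing calls",
                nrow(peptides)))
parts <- table(overlaps$which_part)
message(sprintf("%d domain overlaps (%s)", nrow(overlaps),
                if (nrow(overlaps)) paste(names(parts), parts, sep = ":",
                                          collapse = ", ") else "none"))
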