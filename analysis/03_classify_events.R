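#!/usr/bin/env Rscript
# Characterize the called events: localization within the transcript,
# frame preservation, premature stops / NMD candidacy, disorder category
# of the spliced peptide, and PTM sites gained or lost.
source("analysis/00_config.R")

study <- build_study()
counts <- simulate_counts(study$tx, study$truth, study$cfg, study$eff)
calls <- call_events(counts, study$eff)
passing <- calls$calls$event_id[calls$calls$passes]
fixtures <- make_annotation_fixtures(study$tx)

ann <- classify_events(study$tx$events, study$tx$genome, ids = passing)
write_tsv(ann, file.path(RESULTS_DIR, "annotations.tsv"))

loc <- table(ann$localization)
message(sprintf("of %d passing events: %s", nrow(ann),
                paste(names(loc), loc, sep = ":", collapse = ", ")))
cds <- ann[ann$localization == "CDS", ]
message(sprintf("coding events: %d frame-preserving, %d with a PTC and/or frame shift, %d NMD candidates",
                sum(cds$frame_preserving),
                sum(cds$premature_stop | !cds$frame_preserving),
                sum(cds$nmd_candidate)))

as_ivl <- fixtures$peptides[fixtures$peptides$event_id %in% passing,
                            c("event_id", "protein_id", "aa_start", "aa_end")]
dis <- disorder_categories(as_ivl, fixtures$disorder)
write_tsv(dis, file.path(RESULTS_DIR, "disorder_categories.tsv"))
dc <- table(dis$category)
message(sprintf("disorder over AS peptides: %s",
                paste(names(dc), dc, sep = ":", collapse = ", ")))

ptm <- intersect_ptm(as_ivl, fixtures$ptm)
write_tsv(ptm$hits, file.path(RESULTS_DIR, "ptm_hits.tsv"))
if (nrow(ptm$matrix))
  write_tsv(cbind(event_id = rownames(ptm$matrix), ptm$matrix),
            file.path(RESULTS_DIR, "ptm_matrix.tsv"))
message(sprintf("%d PTM sites fall inside AS regions (%d modification types)",
                nrow(ptm$hits), length(ptm$type_totals)))
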