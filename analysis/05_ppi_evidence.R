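#!/usr/bin/env Rscript
# Join structural (domain-domain) and experimental PPI evidence for the
# genes whose domains are disrupted by splicing, and intersect the AS
# gene list with a differential-expression gene list.
source("analysis/00_config.R")

fx <- ppi_demo_fixture()
merged <- merge_ppi(fx$experimental_a, fx$experimental_b)
message(sprintf("merged experimental network: %d edges (%d skipped rows)",
                nrow(merged), attr(merged, "n_skipped")))

interactions <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain,
                                   merged)
write_tsv(interactions, file.path(RESULTS_DIR, "interactions.tsv"))
write_interaction_dot(interactions, file.path(RESULTS_DIR, "interactions.dot"))
message(sprintf("%d interactions carry both experimental and structural evidence",
                nrow(unique(interactions[c("as_gene", "partner_gene")]))))

filtered <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain,
                               merged, expressed = fx$expressed)
dropped <- setdiff(interactions$partner_gene, filtered$partner_gene)
message(sprintf("expression filter removes: %s",
                if (length(dropped)) paste(dropped, collapse = ", ") else "nothing"))

## overlap between splicing-level and expression-level responses
as_genes <- unique(interactions$as_gene)
de_genes <- c("GeneR", "IrrelevantDE1", "IrrelevantDE2")
both <- intersect_de(as_genes, de_genes)
message(sprintf("genes both alternatively spliced and differentially expressed: %s",
                if (length(both)) paste(both, collapse = ", ") else "none"))
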