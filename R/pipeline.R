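#' Pipeline configuration
#'
#' Bundles the simulation settings, call thresholds and stage toggles of
#' one end-to-end run. Thresholds default to the calling rule (Bayes
#' factor > 5 with |delta PSI| > 0.05) and the motif cutoffs (raw p <
#' 1e-4, BH FDR < 0.1).
#'
#' @param sim a [sim_config()].
#' @param bf_min,dpsi_min differential-splicing call thresholds.
#' @param motif_p,motif_fdr motif scan cutoffs.
#' @param stages character vector of stages to run, in dependency order;
#'   a stage requires every stage before it in
#'   `c("simulate", "quantify", "classify", "domains", "ppi", "motifs")`.
#' @param out_dir output directory (`NULL` for no file output).
#' @param expression_filter apply the expressed-gene filter in the PPI
#'   join.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bf_min = 5, dpsi_min = 0.05,
                            motif_p = 1e-4, motif_fdr = 0.1,
                            stages = c("simulate", "quantify", "classify",
                                       "domains", "ppi", "motifs"),
                            out_dir = NULL,
                            expression_filter = FALSE) {
  if (!(bf_min > 0 && dpsi_min > 0 && motif_p > 0 && motif_fdr > 0))
    stop("thresholds must all be positive")
  all_stages <- c("simulate", "quantify", "classify", "domains", "ppi",
                  "motifs")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(sim = sim, bf_min = bf_min, dpsi_min = dpsi_min,
                 motif_p = motif_p, motif_fdr = motif_fdr,
                 stages = stages, out_dir = out_dir,
                 expression_filter = expression_filter),
            class = "pipeline_config")
}

.require_stage <- function(state, key, needed_stage, for_stage) {
  if (is.null(state[[key]]))
    stop("stage '", for_stage, "' requires output of stage '", needed_stage,
         "', which was not run")
}

#' Run the full differential-splicing pipeline
#'
#' Executes the configured stages in dependency order: simulate
#' (transcriptome, truth, counts, annotation fixtures), quantify (PSI
#' posteriors, Bayes factors, calls), classify (localization, frame, PTC,
#' NMD, disorder, PTM), domains (flanked peptides and domain overlap),
#' ppi (dual-evidence join on the fixture tables) and motifs (regulatory
#' regions and PWM occurrence). When `cfg$out_dir` is set, each stage
#' writes its tables (TSV/GFF3/FASTA/MEME/DOT) plus a JSON summary;
#' identical config and seed reproduce byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `tx`, `truth`,
#'   `eff`, `counts`, `calls`, `annotations`, `disorder`, `ptm`,
#'   `peptides`, `domain_overlaps`, `interactions`, `regions`, `motifs`,
#'   `fixtures`, `summary`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  st <- list()
  summary <- list(seed = cfg$sim$seed)

  if ("simulate" %in% cfg$stages) {
    st$tx <- make_transcriptome(cfg$sim)
    st$truth <- make_truth(st$tx, cfg$sim)
    st$eff <- effective_sizes_table(st$tx, cfg$sim$read_length)
    st$counts <- simulate_counts(st$tx, st$truth, cfg$sim, st$eff)
    st$fixtures <- make_annotation_fixtures(st$tx)
    tab <- table(vapply(st$tx$events, `[[`, "", "event_type"))
    summary$simulate <- list(
      n_events = length(st$tx$events),
      by_type = lapply(as.list(tab), as.integer),
      n_untestable = sum(!st$eff$testable))
  }

  if ("quantify" %in% cfg$stages) {
    .require_stage(st, "counts", "simulate", "quantify")
    st$calls <- call_events(st$counts, st$eff,
                            conditions = cfg$sim$conditions,
                            bf_min = cfg$bf_min, dpsi_min = cfg$dpsi_min)
    summary$quantify <- st$calls$summary
  }

  passing_ids <- if (!is.null(st$calls) && nrow(st$calls$calls))
    st$calls$calls$event_id[st$calls$calls$passes] else character(0)

  if ("classify" %in% cfg$stages) {
    .require_stage(st, "calls", "quantify", "classify")
    st$annotations <- classify_events(st$tx$events, st$tx$genome,
                                      ids = passing_ids)
    if (is.null(st$annotations))
      st$annotations <- data.frame(event_id = character(),
                                   localization = character(),
                                   frame_preserving = logical(),
                                   premature_stop = logical(),
                                   nmd_candidate = logical(),
                                   novel_cterm = logical(),
                                   exclusion_premature_stop = logical(),
                                   stringsAsFactors = FALSE)
    ann <- st$annotations
    cds <- ann[!is.na(ann$localization) & ann$localization == "CDS", ]
    as_ivl <- st$fixtures$peptides[
      st$fixtures$peptides$event_id %in% passing_ids,
      c("event_id", "protein_id", "aa_start", "aa_end")]
    st$disorder <- disorder_categories(as_ivl, st$fixtures$disorder)
    st$ptm <- intersect_ptm(as_ivl, st$fixtures$ptm)
    summary$classify <- list(
      n_annotated = nrow(ann),
      localization = lapply(as.list(table(ann$localization)), as.integer),
      n_frame_preserving = sum(cds$frame_preserving, na.rm = TRUE),
      n_ptc_or_frameshift = sum(cds$premature_stop | !cds$frame_preserving,
                                na.rm = TRUE),
      n_nmd_candidates = sum(cds$nmd_candidate, na.rm = TRUE),
      disorder = lapply(as.list(table(st$disorder$category)), as.integer),
      n_ptm_in_as_regions = nrow(st$ptm$hits))
  }

  if ("domains" %in% cfg$stages) {
    .require_stage(st, "annotations", "classify", "domains")
    st$peptides <- st$fixtures$peptides[
      st$fixtures$peptides$event_id %in% passing_ids, , drop = FALSE]
    st$domain_overlaps <- overlap_domains(st$peptides, st$fixtures$domains)
    summary$domains <- list(
      n_peptides = nrow(st$peptides),
      n_overlaps = nrow(st$domain_overlaps),
      by_part = lapply(as.list(table(st$domain_overlaps$which_part)),
                       as.integer))
  }

  if ("ppi" %in% cfg$stages) {
    .require_stage(st, "fixtures", "simulate", "ppi")
    fx <- st$fixtures$ppi
    merged <- merge_ppi(fx$experimental_a, fx$experimental_b)
    st$interactions <- dual_evidence_join(
      fx$disrupted, fx$ddi, fx$gene2domain, merged,
      expressed = if (cfg$expression_filter) fx$expressed else NULL)
    summary$ppi <- list(
      n_experimental_edges = nrow(merged),
      n_dual_evidence = nrow(unique(
        st$interactions[c("as_gene", "partner_gene")])))
  }

  if ("motifs" %in% cfg$stages) {
    .require_stage(st, "calls", "quantify", "motifs")
    st$regions <- regulatory_regions(st$tx, ids = passing_ids)
    st$motifs <- motif_enrichment(st$calls$calls, st$regions,
                                  st$fixtures$pwms,
                                  p_cut = cfg$motif_p,
                                  fdr_cut = cfg$motif_fdr)
    summary$motifs <- list(
      n_scanned_events = length(unique(st$regions$event_id)),
      n_hits = nrow(st$motifs$hits),
      n_motifs_up = length(st$motifs$motifs_up),
      n_motifs_down = length(st$motifs$motifs_down))
  }

  st$summary <- summary
  class(st) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(st, cfg)
  st
}

.write_pipeline_outputs <- function(st, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  if (!is.null(st$tx)) {
    write_genome_fasta(st$tx, p("genome.fa"))
    write_transcripts_gff3(st$tx, p("transcripts.gff3"))
    write_tsv(st$counts, p("counts.tsv"))
    write_tsv(st$truth, p("truth.tsv"))
    write_tsv(st$fixtures$domains, p("fixture_domains.tsv"))
    write_tsv(st$fixtures$disorder, p("fixture_disorder.tsv"))
    write_tsv(st$fixtures$ptm, p("fixture_ptm.tsv"))
    write_meme(st$fixtures$pwms, p("fixture_motifs.meme"))
  }
  if (!is.null(st$calls)) {
    write_tsv(st$calls$calls, p("calls.tsv"))
    write_tsv(st$calls$skipped, p("skipped_events.tsv"))
  }
  if (!is.null(st$annotations)) write_tsv(st$annotations, p("annotations.tsv"))
  if (!is.null(st$disorder)) write_tsv(st$disorder, p("disorder_categories.tsv"))
  if (!is.null(st$ptm) && nrow(st$ptm$hits)) {
    write_tsv(st$ptm$hits, p("ptm_hits.tsv"))
    mat <- cbind(event_id = rownames(st$ptm$matrix), st$ptm$matrix)
    write_tsv(mat, p("ptm_matrix.tsv"))
  }
  if (!is.null(st$domain_overlaps))
    write_tsv(st$domain_overlaps, p("domain_overlaps.tsv"))
  if (!is.null(st$interactions)) {
    write_tsv(st$interactions, p("interactions.tsv"))
    write_interaction_dot(st$interactions, p("interactions.dot"))
  }
  if (!is.null(st$motifs)) {
    write_tsv(st$motifs$hits, p("motif_hits.tsv"))
    write_tsv(st$motifs$occurrence, p("motif_occurrence.tsv"))
  }
  jsonlite::write_json(st$summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Intersect alternatively spliced and differentially expressed gene lists
#'
#' Exact set intersection by gene identifier, used to ask how much
#' overlap exists between splicing-level and expression-level responses
#' (differential expression itself is an upstream input, not computed
#' here).
#'
#' @param as_genes,de_genes character vectors of gene ids.
#' @return sorted character vector of genes present in both.
#' @export
intersect_de <- function(as_genes, de_genes) {
  stopifnot(!is.null(as_genes), !is.null(de_genes))
  sort(intersect(unique(as_genes), unique(de_genes)))
}
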