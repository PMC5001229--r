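## Closed-interval overlap length (1-based inclusive coordinates).
ivl_overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

#' Translate an alternatively spliced region with its exonic flanks
#'
#' Assembles, in spliced (mRNA) coordinates of the inclusion isoform, the
#' nucleotide window consisting of the alternative segment plus up to 30
#' nt of the upstream and downstream exons (truncated when a neighboring
#' exon is shorter, or at the CDS boundaries), snaps the window to the
#' annotated reading frame, and translates it. The protein-coordinate
#' interval of the AS-only portion is reported so that domain overlap can
#' distinguish segment hits from flank-only hits.
#'
#' @param ev a [splicing_event()], frame-preserving and CDS-localized.
#' @param genome named `DNAStringSet`.
#' @param flank flank width in nt (default 30).
#' @return one-row data.frame: `event_id`, `protein_id`, `window_start`,
#'   `window_end` (spliced nt coordinates), `window_seq`, `peptide`,
#'   `aa_start`, `aa_end` (AS-only protein interval), `win_aa_start`,
#'   `win_aa_end` (whole-window protein interval).
#' @export
build_flanked_peptide <- function(ev, genome, flank = 30L) {
  loc <- localize_event(ev)
  if (is.na(loc) || loc != "CDS")
    stop("build_flanked_peptide requires a CDS-localized event (",
         ev$event_id, ")")
  seg_len <- ev$seg[2] - ev$seg[1] + 1L
  if (seg_len %% 3L != 0L)
    stop("build_flanked_peptide requires a frame-preserving event (",
         ev$event_id, ")")
  chromseq <- genome[[ev$chrom]]
  inc_seq <- as.character(isoform_seq(ev$inc_exons, ev$strand, chromseq))
  seg <- seg_spliced_interval(ev)
  cs <- spliced_index(cds_first_base(ev), ev$inc_exons, ev$strand)
  ce <- spliced_index(cds_last_base(ev), ev$inc_exons, ev$strand)

  widths <- ev$inc_exons[, 2] - ev$inc_exons[, 1] + 1L
  bounds <- cumsum(widths)                       # spliced end of each exon
  starts <- c(1L, utils::head(bounds, -1L) + 1L) # spliced start of each exon

  a <- max(seg[1], cs); b <- min(seg[2], ce)     # clamp segment to CDS
  ## exon containing spliced position p is findInterval(p - 1, c(0, bounds))
  fl_up <- if (a <= 1L) 0L else {
    up_ex <- findInterval(a - 2L, c(0L, bounds))  # exon of the base before a
    max(0L, min(flank, a - starts[up_ex], a - cs))
  }
  dn_ex <- findInterval(b, c(0L, bounds))         # exon of the base after b
  fl_dn <- if (dn_ex > length(bounds)) 0L
           else max(0L, min(flank, bounds[dn_ex] - b, ce - b))

  win_start <- a - fl_up
  win_end <- b + fl_dn
  ## snap to the annotated reading frame
  win_start <- win_start + (3L - ((win_start - cs) %% 3L)) %% 3L
  win_end <- win_end - ((win_end - win_start + 1L) %% 3L)

  window_seq <- substr(inc_seq, win_start, win_end)
  peptide <- as.character(Biostrings::translate(
    Biostrings::DNAString(window_seq), no.init.codon = TRUE))
  peptide <- sub("\\*$", "", peptide)

  data.frame(event_id = ev$event_id, protein_id = ev$gene_id,
             window_start = win_start, window_end = win_end,
             window_seq = window_seq, peptide = peptide,
             aa_start = (a - cs) %/% 3L + 1L,
             aa_end = (b - cs) %/% 3L + 1L,
             win_aa_start = (win_start - cs) %/% 3L + 1L,
             win_aa_end = (win_end - 2L - cs) %/% 3L + 1L,
             stringsAsFactors = FALSE)
}

#' Flanked peptides for all eligible events
#'
#' @param events list of [splicing_event()]s or a `sim_transcriptome`.
#' @param genome named `DNAStringSet`.
#' @param annotations optional output of [classify_events()] used to
#'   select frame-preserving CDS events; computed when absent.
#' @param flank flank width in nt.
#' @return data.frame, one row per frame-preserving coding event.
#' @export
flanked_peptides <- function(events, genome = NULL, annotations = NULL,
                             flank = 30L) {
  if (inherits(events, "sim_transcriptome")) {
    if (is.null(genome)) genome <- events$genome
    events <- events$events
  }
  if (is.null(annotations)) annotations <- classify_events(events, genome)
  keep <- annotations$event_id[annotations$localization == "CDS" &
                               annotations$frame_preserving %in% TRUE]
  ids <- vapply(events, `[[`, "", "event_id")
  rows <- lapply(events[ids %in% keep], build_flanked_peptide,
                 genome = genome, flank = flank)
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(event_id = character(), protein_id = character(),
                      window_start = integer(), window_end = integer(),
                      window_seq = character(), peptide = character(),
                      aa_start = integer(), aa_end = integer(),
                      win_aa_start = integer(), win_aa_end = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Overlap flanked peptides with protein-domain intervals
#'
#' Intersects each event's window with the domain table of its host
#' protein in protein coordinates (1-based, closed). `which_part` records
#' whether the domain touches the AS segment itself (`AS_only`), only an
#' exonic flank (`flank_only`), or both — the distinction between domains
#' directly disrupted by splicing and domains adjacent to the splice
#' region.
#'
#' @param peptides data.frame from [flanked_peptides()].
#' @param domains data.frame with `protein_id`, `domain_accession`,
#'   `domain_name`, `start_aa`, `end_aa`.
#' @param min_overlap minimum reported overlap in aa (default 1).
#' @return data.frame: `event_id`, `protein_id`, `domain_accession`,
#'   `domain_name`, `overlap_aa`, `which_part`.
#' @export
overlap_domains <- function(peptides, domains, min_overlap = 1L) {
  if (nrow(domains)) {
    if (any(domains$end_aa < domains$start_aa) || any(domains$start_aa < 1L))
      stop("invalid domain interval(s): need 1 <= start_aa <= end_aa")
  }
  out <- list()
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides[i, ]
    cand <- domains[domains$protein_id == pep$protein_id, , drop = FALSE]
    if (!nrow(cand)) next
    o_as <- ivl_overlap(cand$start_aa, cand$end_aa, pep$aa_start, pep$aa_end)
    o_win <- ivl_overlap(cand$start_aa, cand$end_aa,
                         pep$win_aa_start, pep$win_aa_end)
    o_flank <- o_win - o_as
    keep <- o_win >= min_overlap
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      event_id = pep$event_id, protein_id = pep$protein_id,
      domain_accession = cand$domain_accession[keep],
      domain_name = cand$domain_name[keep],
      overlap_aa = o_win[keep],
      which_part = ifelse(o_as[keep] > 0L & o_flank[keep] > 0L, "both",
                   ifelse(o_as[keep] > 0L, "AS_only", "flank_only")),
      stringsAsFactors = FALSE)
  }
  if (length(out)) rbind_rows(out)
  else data.frame(event_id = character(), protein_id = character(),
                  domain_accession = character(), domain_name = character(),
                  overlap_aa = integer(), which_part = character(),
                  stringsAsFactors = FALSE)
}
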