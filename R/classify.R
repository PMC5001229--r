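#' Localize an event within its host transcript
#'
#' Maps the alternative segment into the spliced coordinates of the
#' inclusion isoform and compares it with the annotated CDS span. Any
#' overlap with the CDS classifies the event as `CDS` (protein-level
#' consequences dominate a partial UTR overlap); a segment entirely
#' 5' of the start codon is `UTR5`, entirely 3' of the stop codon `UTR3`.
#'
#' @param ev a [splicing_event()] with an annotated CDS.
#' @return `"CDS"`, `"UTR5"` or `"UTR3"`; `NA_character_` (with a warning)
#'   when the transcript lacks a CDS annotation.
#' @export
localize_event <- function(ev) {
  if (is.null(ev$cds)) {
    warning("event ", ev$event_id, " excluded: transcript lacks CDS annotation")
    return(NA_character_)
  }
  seg <- seg_spliced_interval(ev)
  cs <- spliced_index(cds_first_base(ev), ev$inc_exons, ev$strand)
  ce <- spliced_index(cds_last_base(ev), ev$inc_exons, ev$strand)
  if (is.na(cs) || is.na(ce))
    stop("CDS boundaries not on the inclusion isoform for ", ev$event_id)
  if (seg[1] <= ce && seg[2] >= cs) "CDS"
  else if (seg[2] < cs) "UTR5"
  else "UTR3"
}

## First in-frame stop codon at or after spliced position `from`
## (codon start position), scanning to the end of the isoform sequence.
## Returns NA when no stop is reached before the sequence runs out.
.first_stop <- function(seqchar, from) {
  n <- nchar(seqchar)
  starts <- seq(from, n - 2L, by = 3L)
  if (!length(starts)) return(NA_integer_)
  codons <- substring(seqchar, starts, starts + 2L)
  hit <- which(codons %in% .STOPS)[1]
  if (is.na(hit)) NA_integer_ else starts[hit]
}

## Premature-stop scan of one isoform: translate from the annotated start
## codon and compare the first in-frame stop with the annotated stop's
## position on that isoform.
.scan_isoform_stop <- function(ev, exons, chromseq) {
  seqchar <- as.character(isoform_seq(exons, ev$strand, chromseq))
  cs <- spliced_index(cds_first_base(ev), exons, ev$strand)
  stop_first_genomic <- if (ev$strand == "+") ev$cds[2] - 2L else ev$cds[1] + 2L
  annotated_stop <- spliced_index(stop_first_genomic, exons, ev$strand)
  first_stop <- .first_stop(seqchar, cs)
  widths <- exons[, 2] - exons[, 1] + 1L
  last_junction <- if (nrow(exons) > 1L) sum(widths[-nrow(exons)]) else NA_integer_
  list(first_stop = first_stop, annotated_stop = annotated_stop,
       premature = !is.na(first_stop) && !is.na(annotated_stop) &&
                   first_stop < annotated_stop,
       last_junction = last_junction)
}

#' Frame, premature-stop and NMD classification of a coding event
#'
#' For an event localized in the CDS: the alternative segment preserves
#' the reading frame iff its length is a multiple of 3. The inclusion
#' isoform (the one carrying the segment) is translated from the annotated
#' start codon; a stop codon strictly upstream of the annotated stop marks
#' a premature termination codon (PTC). A PTC ending more than 50 nt
#' upstream of the isoform's final exon-exon junction flags the transcript
#' as an NMD candidate (the standard 50-nt rule). A frame shift that does
#' not trigger NMD yields a novel C-terminus. The exclusion isoform is
#' scanned too and its PTC status reported alongside.
#'
#' @param ev a [splicing_event()] with localization `"CDS"`.
#' @param genome named `DNAStringSet` containing `ev$chrom`.
#' @return one-row data.frame: `event_id`, `localization`,
#'   `frame_preserving`, `premature_stop`, `nmd_candidate`, `novel_cterm`,
#'   `exclusion_premature_stop`.
#' @export
classify_frame <- function(ev, genome) {
  loc <- localize_event(ev)
  if (is.na(loc) || loc != "CDS")
    stop("classify_frame requires a CDS-localized event (", ev$event_id,
         " is ", loc, ")")
  chromseq <- genome[[ev$chrom]]
  if (length(chromseq) < max(ev$inc_exons))
    stop("sequence shorter than transcript annotation for ", ev$event_id)
  seg_len <- ev$seg[2] - ev$seg[1] + 1L
  frame_preserving <- seg_len %% 3L == 0L

  inc <- .scan_isoform_stop(ev, ev$inc_exons, chromseq)
  exc <- .scan_isoform_stop(ev, ev$exc_exons, chromseq)

  nmd <- FALSE
  if (inc$premature && !is.na(inc$last_junction)) {
    ptc_end <- inc$first_stop + 2L
    nmd <- (inc$last_junction - ptc_end) > 50L
  }
  data.frame(event_id = ev$event_id, localization = loc,
             frame_preserving = frame_preserving,
             premature_stop = inc$premature,
             nmd_candidate = nmd,
             novel_cterm = !frame_preserving && !nmd,
             exclusion_premature_stop = exc$premature,
             stringsAsFactors = FALSE)
}

#' Coding annotation of an event set
#'
#' Runs [localize_event()] on every event and [classify_frame()] on the
#' CDS-localized ones; UTR events carry `NA` coding flags. Events without
#' a CDS annotation are excluded with a logged reason.
#'
#' @param events list of [splicing_event()]s or a `sim_transcriptome`.
#' @param genome named `DNAStringSet`.
#' @param ids optional character vector restricting to a subset of events
#'   (e.g. the passing calls).
#' @return data.frame with one row per annotatable event.
#' @export
classify_events <- function(events, genome, ids = NULL) {
  if (inherits(events, "sim_transcriptome")) {
    if (is.null(genome)) genome <- events$genome
    events <- events$events
  }
  if (!is.null(ids)) events <- events[vapply(events, `[[`, "", "event_id") %in% ids]
  rows <- lapply(events, function(ev) {
    loc <- localize_event(ev)
    if (is.na(loc)) return(NULL)
    if (loc == "CDS") return(classify_frame(ev, genome))
    data.frame(event_id = ev$event_id, localization = loc,
               frame_preserving = NA, premature_stop = NA,
               nmd_candidate = NA, novel_cterm = NA,
               exclusion_premature_stop = NA, stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Disorder category of an alternatively spliced peptide region
#'
#' Consumes per-residue disorder calls (from an external predictor) over
#' the AS-region peptide and assigns the region to one of three
#' categories: `totally_disordered` (every residue called disordered,
#' fraction 1), `structured` (none, fraction 0), `partially_disordered`
#' otherwise. Peptides shorter than `min_len` residues are excluded with a
#' reason, mirroring the minimum peptide length required for reliable
#' disorder prediction.
#'
#' @param event_id event identifier.
#' @param calls 0/1 vector of per-residue disorder calls over the AS
#'   peptide.
#' @param min_len minimum peptide length (default 9 aa).
#' @return one-row data.frame: `event_id`, `n_residues`,
#'   `fraction_disordered`, `category`, `excluded_reason`.
#' @export
disorder_category <- function(event_id, calls, min_len = 9L) {
  n <- length(calls)
  if (n < min_len)
    return(data.frame(event_id = event_id, n_residues = n,
                      fraction_disordered = NA_real_,
                      category = NA_character_,
                      excluded_reason = sprintf("peptide < %d aa", min_len),
                      stringsAsFactors = FALSE))
  stopifnot(all(calls %in% c(0, 1)))
  frac <- mean(calls)
  cat <- if (frac == 1) "totally_disordered"
         else if (frac == 0) "structured"
         else "partially_disordered"
  data.frame(event_id = event_id, n_residues = n, fraction_disordered = frac,
             category = cat, excluded_reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Disorder categories for a table of per-residue calls
#'
#' @param as_intervals data.frame with `event_id`, `protein_id`,
#'   `aa_start`, `aa_end` (AS-region protein coordinates, closed).
#' @param disorder_calls data.frame with `protein_id`, `residue_index`,
#'   `call` (0/1).
#' @param min_len minimum peptide length.
#' @return data.frame, one row per event (see [disorder_category()]).
#' @export
disorder_categories <- function(as_intervals, disorder_calls, min_len = 9L) {
  rows <- lapply(seq_len(nrow(as_intervals)), function(i) {
    iv <- as_intervals[i, ]
    sub <- disorder_calls[disorder_calls$protein_id == iv$protein_id &
                          disorder_calls$residue_index >= iv$aa_start &
                          disorder_calls$residue_index <= iv$aa_end, ]
    disorder_category(iv$event_id, sub$call[order(sub$residue_index)], min_len)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(event_id = character(), n_residues = integer(),
                      fraction_disordered = numeric(), category = character(),
                      excluded_reason = character(), stringsAsFactors = FALSE)
  out
}

#' Intersect PTM sites with alternatively spliced protein regions
#'
#' A post-translational modification site lies in an AS region when its
#' residue position falls within the region's protein-coordinate interval
#' (closed on both ends). Sites beyond the host protein's length are
#' skipped with a warning. Output includes the per-event-by-type count
#' matrix used to summarize which modification classes splicing can add
#' or remove.
#'
#' @param as_intervals data.frame with `event_id`, `protein_id`,
#'   `aa_start`, `aa_end`.
#' @param ptm data.frame with `protein_id`, `position`, `type`, `source`
#'   (`known`/`predicted`).
#' @param protein_lengths optional named vector of protein lengths used to
#'   validate PTM positions.
#' @return list: `hits` (one row per PTM site inside an AS region),
#'   `matrix` (data.frame, events x PTM types, counts), `type_totals`
#'   (named integer vector).
#' @export
intersect_ptm <- function(as_intervals, ptm, protein_lengths = NULL) {
  if (!is.null(protein_lengths) && nrow(ptm)) {
    len <- protein_lengths[ptm$protein_id]
    bad <- !is.na(len) & ptm$position > len
    if (any(bad)) {
      warning(sum(bad), " PTM record(s) beyond protein length skipped")
      ptm <- ptm[!bad, ]
    }
  }
  hits <- list()
  for (i in seq_len(nrow(as_intervals))) {
    iv <- as_intervals[i, ]
    sub <- ptm[ptm$protein_id == iv$protein_id &
               ptm$position >= iv$aa_start & ptm$position <= iv$aa_end, ]
    if (nrow(sub))
      hits[[length(hits) + 1L]] <- cbind(
        data.frame(event_id = iv$event_id, stringsAsFactors = FALSE), sub)
  }
  hits <- if (length(hits)) rbind_rows(hits)
          else data.frame(event_id = character(), protein_id = character(),
                          position = integer(), type = character(),
                          source = character(), stringsAsFactors = FALSE)
  mat <- if (nrow(hits)) {
    tab <- table(hits$event_id, hits$type)
    as.data.frame.matrix(tab)
  } else data.frame()
  type_totals <- if (nrow(hits)) {
    tt <- table(hits$type)
    stats::setNames(as.integer(tt), names(tt))
  } else integer(0)
  list(hits = hits, matrix = mat, type_totals = type_totals)
}
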