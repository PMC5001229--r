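#' Construct a splicing event
#'
#' A splicing event is the unit of analysis: one alternative segment (a
#' cassette exon, a 5'/3' exon extension, or a retainable intron) embedded
#' in a host transcript, together with the exon chains of the two isoforms
#' it distinguishes. The inclusion isoform carries the alternative segment;
#' the exclusion isoform does not. All coordinates are 1-based inclusive
#' genomic positions on the event's chromosome.
#'
#' @param event_id character scalar, unique identifier.
#' @param gene_id host gene/protein identifier (used as protein id in the
#'   downstream domain/PTM stages).
#' @param chrom chromosome (sequence name in the genome `DNAStringSet`).
#' @param strand `"+"` or `"-"`.
#' @param event_type one of `"cassette"`, `"alt5"`, `"alt3"`,
#'   `"retained_intron"`.
#' @param seg length-2 integer vector `(start, end)` of the alternative
#'   segment.
#' @param inc_exons,exc_exons two-column matrices (`start`, `end`) of the
#'   inclusion/exclusion isoform exons, rows ordered 5' to 3' along the
#'   transcript (descending genomic position on the minus strand).
#' @param cds length-2 vector `(left, right)` of the genomic span of the
#'   annotated CDS (first to last coding base, introns included), or `NULL`
#'   for a non-coding host.
#'
#' @return an object of class `splicing_event`.
#' @export
splicing_event <- function(event_id, gene_id, chrom, strand, event_type,
                           seg, inc_exons, exc_exons, cds = NULL) {
  ev <- structure(
    list(event_id = event_id, gene_id = gene_id, chrom = chrom,
         strand = strand, event_type = event_type,
         seg = as.integer(seg),
         inc_exons = .as_exon_matrix(inc_exons),
         exc_exons = .as_exon_matrix(exc_exons),
         cds = if (is.null(cds)) NULL else as.integer(cds)),
    class = "splicing_event")
  validate_event(ev)
  ev
}

.as_exon_matrix <- function(x) {
  m <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  m
}

#' Validate a splicing event's structural invariants
#'
#' Checks that the alternative segment is non-empty, that exon intervals are
#' well formed and non-overlapping within each isoform and ordered along the
#' transcript, and that the exclusion isoform's exonic bases form a subset
#' of the inclusion isoform's.
#'
#' @param ev a `splicing_event`.
#' @return `ev`, invisibly; stops on violation.
#' @export
validate_event <- function(ev) {
  stopifnot(inherits(ev, "splicing_event"))
  if (!ev$event_type %in% c("cassette", "alt5", "alt3", "retained_intron"))
    stop("unknown event_type: ", ev$event_type)
  if (!ev$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (ev$seg[2] < ev$seg[1]) stop("alternative segment must be >= 1 nt")
  for (nm in c("inc_exons", "exc_exons")) {
    m <- ev[[nm]]
    if (any(m[, 2] < m[, 1])) stop(nm, ": malformed exon interval")
    if (nrow(m) > 1) {
      ord <- if (ev$strand == "+") diff(m[, 1]) > 0 else diff(m[, 1]) < 0
      if (!all(ord)) stop(nm, ": exons not in transcript order")
      gs <- sort(m[, 1]); ge <- sort(m[, 2])
      if (any(gs[-1] <= ge[-nrow(m)])) stop(nm, ": overlapping exons")
    }
  }
  inc <- .exonic_positions(ev$inc_exons)
  exc <- .exonic_positions(ev$exc_exons)
  if (!all(exc %in% inc))
    stop("exclusion isoform exonic sequence not contained in inclusion isoform")
  invisible(ev)
}

.exonic_positions <- function(m) {
  unlist(lapply(seq_len(nrow(m)), function(i) m[i, 1]:m[i, 2]), use.names = FALSE)
}

#' Genomic positions of an isoform in transcript order
#'
#' Returns the vector of genomic coordinates visited base by base when
#' reading the spliced isoform 5' to 3' (descending on the minus strand).
#' This vector is the bridge between spliced and genomic coordinates used
#' by the effective-size enumeration and the coding classifier.
#'
#' @param exons two-column exon matrix in transcript order.
#' @param strand `"+"` or `"-"`.
#' @return integer vector of genomic positions, length = spliced length.
#' @export
isoform_positions <- function(exons, strand) {
  unlist(lapply(seq_len(nrow(exons)), function(i) {
    if (strand == "+") exons[i, 1]:exons[i, 2] else exons[i, 2]:exons[i, 1]
  }), use.names = FALSE)
}

#' Spliced (sense-strand) sequence of an isoform
#'
#' @param exons two-column exon matrix in transcript order.
#' @param strand `"+"` or `"-"`.
#' @param chromseq a `DNAString` (the event's chromosome).
#' @return a `DNAString` of the mature isoform sequence, 5' to 3'.
#' @export
isoform_seq <- function(exons, strand, chromseq) {
  parts <- lapply(seq_len(nrow(exons)), function(i) {
    s <- Biostrings::subseq(chromseq, min(exons[i, ]), max(exons[i, ]))
    if (strand == "-") Biostrings::reverseComplement(s) else s
  })
  out <- parts[[1]]
  if (length(parts) > 1) for (i in 2:length(parts)) out <- Biostrings::xscat(out, parts[[i]])
  out
}

#' Strand-aware subsequence of a genomic interval
#'
#' Extracts the sense-strand sequence of `ivl = c(start, end)`.
#'
#' @param ivl length-2 genomic interval.
#' @param strand `"+"` or `"-"`.
#' @param chromseq a `DNAString`.
#' @return a `DNAString`.
#' @export
interval_seq <- function(ivl, strand, chromseq) {
  s <- Biostrings::subseq(chromseq, ivl[1], ivl[2])
  if (strand == "-") Biostrings::reverseComplement(s) else s
}

## Map genomic positions to spliced coordinates on an isoform (NA outside).
spliced_index <- function(positions, exons, strand) {
  match(positions, isoform_positions(exons, strand))
}

## First genomic base of the CDS in transcript orientation.
cds_first_base <- function(ev) {
  if (ev$strand == "+") ev$cds[1] else ev$cds[2]
}

## Last genomic base of the CDS (3' end of the stop codon).
cds_last_base <- function(ev) {
  if (ev$strand == "+") ev$cds[2] else ev$cds[1]
}

## Spliced interval of the alternative segment on the inclusion isoform.
seg_spliced_interval <- function(ev) {
  pos <- isoform_positions(ev$inc_exons, ev$strand)
  hit <- which(pos >= ev$seg[1] & pos <= ev$seg[2])
  c(min(hit), max(hit))
}

#' @export
print.splicing_event <- function(x, ...) {
  cat(sprintf("<splicing_event %s> %s %s:%d-%d (%s) gene %s\n",
              x$event_id, x$event_type, x$chrom, x$seg[1], x$seg[2],
              x$strand, x$gene_id))
  invisible(x)
}

## rbind a list of data.frame rows; NULL when empty (avoids the
## do.call(rbind, list(make.row.names = FALSE)) == FALSE trap).
rbind_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}
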