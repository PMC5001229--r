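# Hand-built toy events with fully controlled sequences and coordinates,
# and a coordinate-mirroring helper for strand-invariance checks.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## Assemble a single-event toy chromosome:
##   pad | exon1 | gapA | seg | gapB | exon2 | pad   (plus-strand layout)
## `cds_rel` is the CDS span in layout coordinates where exon1 starts at 1.
## For minus strand the chromosome is reverse-complemented and all
## coordinates flipped, exactly mirroring the plus-strand construction.
toy_event <- function(event_type = "cassette",
                      exon1_seq, seg_seq, exon2_seq,
                      gapA = NULL, gapB = NULL,
                      strand = "+", cds_rel = NULL, pad = 50L,
                      event_id = "toy", chrom = "chrT") {
  if (is.null(gapA)) gapA <- switch(event_type, cassette = 400L, alt5 = 0L,
                                    alt3 = 400L, retained_intron = 0L)
  if (is.null(gapB)) gapB <- switch(event_type, cassette = 400L, alt5 = 400L,
                                    alt3 = 0L, retained_intron = 0L)
  e1 <- nchar(exon1_seq); s <- nchar(seg_seq); e2 <- nchar(exon2_seq)
  chrom_seq <- paste0(rand_dna(pad), exon1_seq,
                      if (gapA > 0) rand_dna(gapA) else "", seg_seq,
                      if (gapB > 0) rand_dna(gapB) else "", exon2_seq,
                      rand_dna(pad))
  L <- nchar(chrom_seq)
  exon1 <- c(pad + 1L, pad + e1)
  seg <- c(exon1[2] + gapA + 1L, exon1[2] + gapA + s)
  exon2 <- c(seg[2] + gapB + 1L, seg[2] + gapB + e2)
  cds <- if (is.null(cds_rel)) NULL else pad + cds_rel
  inc <- switch(event_type,
    cassette = rbind(exon1, seg, exon2),
    alt5 = rbind(c(exon1[1], seg[2]), exon2),
    alt3 = rbind(exon1, c(seg[1], exon2[2])),
    retained_intron = rbind(c(exon1[1], exon2[2])))
  exc <- rbind(exon1, exon2)
  if (strand == "-") {
    chrom_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chrom_seq)))
    flip <- function(iv) c(L + 1L - iv[2], L + 1L - iv[1])
    seg <- flip(seg); inc <- t(apply(inc, 1L, flip))
    exc <- t(apply(exc, 1L, flip))
    if (!is.null(cds)) cds <- flip(cds)
  }
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- chrom
  ev <- psikit::splicing_event(event_id, paste0("gene_", event_id), chrom,
                               strand, event_type, seg, unname(inc),
                               unname(exc), cds)
  list(event = ev, genome = genome)
}

## Mirror an event and its chromosome onto the opposite strand (flip all
## coordinates, reverse-complement the sequence). Every structural and
## sequence property must be invariant under this transformation.
mirror_event <- function(ev, genome) {
  L <- length(genome[[ev$chrom]])
  flip <- function(iv) c(L + 1L - iv[2], L + 1L - iv[1])
  ev2 <- ev
  ev2$strand <- if (ev$strand == "+") "-" else "+"
  ev2$seg <- flip(ev$seg)
  ev2$inc_exons <- psikit:::.as_exon_matrix(t(apply(ev$inc_exons, 1L, flip)))
  ev2$exc_exons <- psikit:::.as_exon_matrix(t(apply(ev$exc_exons, 1L, flip)))
  if (!is.null(ev$cds)) ev2$cds <- flip(ev$cds)
  genome2 <- genome
  genome2[[ev$chrom]] <- Biostrings::reverseComplement(genome[[ev$chrom]])
  list(event = ev2, genome = genome2)
}

## In-frame, stop-free random coding segment (length a multiple of 3,
## codon-aligned insertions only).
sense_codons_dna <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_cod <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_cod, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, TRUE), collapse = "")
}
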