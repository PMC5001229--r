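#' Write the simulated genome as FASTA
#'
#' @param tx a `sim_transcriptome` (or a named `DNAStringSet`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(tx, path) {
  genome <- if (inherits(tx, "sim_transcriptome")) tx$genome else tx
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write transcript models as GFF3
#'
#' Emits gene, mRNA (inclusion and exclusion isoforms), exon and CDS
#' features for every event. Coordinates are 1-based inclusive, the GFF3
#' convention.
#'
#' @param tx a `sim_transcriptome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(tx, path) {
  grs <- list()
  for (ev in tx$events) {
    gid <- ev$gene_id
    span <- range(c(ev$inc_exons))
    add <- function(start, end, type, id, parent = NA_character_,
                    phase = NA_integer_) {
      GenomicRanges::GRanges(
        seqnames = ev$chrom,
        ranges = IRanges::IRanges(start, end),
        strand = ev$strand, type = type, ID = id,
        phase = phase,
        Parent = if (is.na(parent)) S4Vectors::List(character(0))
                 else S4Vectors::List(parent))
    }
    grs[[length(grs) + 1L]] <- add(span[1], span[2], "gene", gid)
    for (iso in c("inc", "exc")) {
      tid <- paste0(gid, ".", iso)
      exons <- ev[[paste0(iso, "_exons")]]
      grs[[length(grs) + 1L]] <- add(min(exons), max(exons), "mRNA", tid, gid)
      for (i in seq_len(nrow(exons)))
        grs[[length(grs) + 1L]] <- add(min(exons[i, ]), max(exons[i, ]),
                                       "exon", paste0(tid, ".e", i), tid)
      if (!is.null(ev$cds)) {
        cum <- 0L   # coding bases already emitted, for the GFF3 phase field
        for (i in seq_len(nrow(exons))) {
          cs <- max(min(exons[i, ]), ev$cds[1])
          ce <- min(max(exons[i, ]), ev$cds[2])
          if (cs <= ce) {
            grs[[length(grs) + 1L]] <- add(cs, ce, "CDS",
                                           paste0(tid, ".cds", i), tid,
                                           phase = (3L - cum %% 3L) %% 3L)
            cum <- cum + ce - cs + 1L
          }
        }
      }
    }
  }
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a PWM set in MEME motif text format
#'
#' Minimal MEME (version 4) motif format: background frequencies plus one
#' letter-probability matrix per motif.
#'
#' @param pwms list of [pwm()] objects.
#' @param path output file.
#' @param background length-4 background probabilities (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3],
                       background[4]), ""), con)
  for (m in pwms) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id, m$rbp), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      m$width), con)
    for (j in seq_len(m$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         m$mat[1, j], m$mat[2, j], m$mat[3, j], m$mat[4, j]),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a PWM set from MEME motif text format
#'
#' @param path input file.
#' @return list of [pwm()] objects; the file's background frequencies are
#'   attached as attribute `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_line <- grep("^Background letter frequencies", lines)
  if (length(bg_line) && bg_line[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_line[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  motif_lines <- grep("^MOTIF ", lines)
  pwms <- list()
  for (ml in motif_lines) {
    tok <- strsplit(trimws(lines[ml]), "\\s+")[[1]]
    motif_id <- tok[2]
    rbp <- if (length(tok) >= 3) tok[3] else motif_id
    hdr <- ml + 1L
    while (!grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1L
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mat <- t(mat)
    dimnames(mat) <- NULL
    mat <- sweep(mat, 2L, colSums(mat), "/")   # undo fixed-precision rounding
    pwms[[length(pwms) + 1L]] <- pwm(mat, motif_id, rbp)
  }
  attr(pwms, "background") <- bg
  pwms
}
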