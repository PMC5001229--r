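#' Simulation configuration
#'
#' Describes the synthetic study: a two-condition (control vs treated)
#' design with replicate event-level read-class counts over the four
#' alternative-splicing event classes (cassette exon, alternative 5' and
#' 3' splice site, retained intron). Defaults emulate the study design the
#' pipeline targets: triplicate 75-nt single-end sequencing, pooled per
#' condition before inference.
#'
#' @param n_genes number of genes (one event per gene).
#' @param event_type_mix named proportions over
#'   `c(cassette, alt5, alt3, retained_intron)`; must sum to 1.
#' @param read_length read length in nt (>= 20).
#' @param depth_per_event expected number of isoform-discriminating
#'   (inclusion- or exclusion-specific) reads per event per condition;
#'   shared reads are generated on top at the model's class odds.
#' @param n_replicates replicates per condition.
#' @param delta_psi_effects true |delta PSI| values injected into affected
#'   events (sign drawn at random per event).
#' @param frac_affected fraction of events with nonzero delta PSI.
#' @param seed integer seed; every generator draw derives from it.
#' @param localization_mix proportions of events placed in CDS, 5' UTR and
#'   3' UTR of their host transcript.
#' @param intron_length length of introns flanking cassette exons (nt);
#'   kept >= 400 by default so the intronic motif regions fit.
#' @param exon_length_range range of host (flanking) exon lengths.
#' @param seg_length_range range of alternative-segment lengths.
#' @param frac_inframe probability that a segment length is a multiple of
#'   3 (exercises both branches of the frame classifier).
#' @param frac_segment_stop_free probability that a CDS-localized
#'   segment is scrubbed of in-frame stop codons (emulating tolerated
#'   exons, which are depleted of stops); the rest keep whatever random
#'   sequence produced, exercising the premature-stop branch.
#' @param conditions labels of the two conditions (reference first).
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       event_type_mix = c(cassette = 0.42, alt5 = 0.14,
                                          alt3 = 0.23, retained_intron = 0.21),
                       read_length = 75L,
                       depth_per_event = 1000,
                       n_replicates = 3L,
                       delta_psi_effects = c(0.1, 0.2, 0.3),
                       frac_affected = 0.3,
                       seed = 1L,
                       localization_mix = c(CDS = 0.52, UTR5 = 0.24, UTR3 = 0.24),
                       intron_length = 1000L,
                       exon_length_range = c(120L, 300L),
                       seg_length_range = c(60L, 300L),
                       frac_inframe = 0.5,
                       frac_segment_stop_free = 0.6,
                       conditions = c("control", "treated")) {
  cfg <- list(n_genes = as.integer(n_genes),
              event_type_mix = event_type_mix,
              read_length = as.integer(read_length),
              depth_per_event = depth_per_event,
              n_replicates = as.integer(n_replicates),
              delta_psi_effects = delta_psi_effects,
              frac_affected = frac_affected,
              seed = as.integer(seed),
              localization_mix = localization_mix,
              intron_length = as.integer(intron_length),
              exon_length_range = as.integer(exon_length_range),
              seg_length_range = as.integer(seg_length_range),
              frac_inframe = frac_inframe,
              frac_segment_stop_free = frac_segment_stop_free,
              conditions = conditions)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  need <- c("cassette", "alt5", "alt3", "retained_intron")
  if (!all(need %in% names(cfg$event_type_mix)))
    stop("event_type_mix must name all of: ", paste(need, collapse = ", "))
  if (abs(sum(cfg$event_type_mix) - 1) > 1e-9)
    stop("event_type_mix proportions must sum to 1")
  if (any(cfg$event_type_mix < 0)) stop("event_type_mix proportions must be >= 0")
  if (abs(sum(cfg$localization_mix) - 1) > 1e-9)
    stop("localization_mix proportions must sum to 1")
  if (cfg$read_length < 20L) stop("read_length must be >= 20 nt")
  if (cfg$depth_per_event < 0) stop("depth_per_event must be >= 0")
  if (cfg$frac_affected < 0 || cfg$frac_affected > 1)
    stop("frac_affected must lie in [0, 1]")
  if (length(cfg$conditions) != 2L) stop("exactly two condition labels required")
  invisible(cfg)
}

## Evaluate `expr` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.STOPS <- c("TAA", "TAG", "TGA")

## Random open reading frame: ATG + (k-2) sense codons + one stop codon.
.rand_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, .STOPS)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(.STOPS, 1L))
}

.SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  setdiff(as.vector(outer(outer(bases, bases, paste0), bases, paste0)), .STOPS)
})

## Replace in-frame stop codons inside a segment inserted after `phase`
## coding bases of an incomplete codon (codon-aligned when phase == 0).
.strip_frame_stops <- function(seg, phase) {
  pos <- ((3L - phase) %% 3L) + 1L
  n <- nchar(seg)
  while (pos + 2L <= n) {
    if (substr(seg, pos, pos + 2L) %in% .STOPS)
      substr(seg, pos, pos + 2L) <- sample(.SENSE_CODONS, 1L)
    pos <- pos + 3L
  }
  seg
}

.draw_seg_length <- function(cfg) {
  s <- sample(cfg$seg_length_range[1]:cfg$seg_length_range[2], 1L)
  if (stats::runif(1) < cfg$frac_inframe) {
    s <- 3L * as.integer(round(s / 3))
    s <- max(s, 3L * ceiling(cfg$seg_length_range[1] / 3))
  } else if (s %% 3L == 0L) {
    s <- s + 1L
  }
  s
}

## Assemble one gene in plus-strand layout space; returns the chromosome
## sequence string and the event description (flipped later for minus
## strand genes).
.build_gene <- function(gene_id, event_type, localization, cfg) {
  pad <- 200L
  seg_len <- .draw_seg_length(cfg)
  if (event_type == "retained_intron") {
    gapA <- 0L; gapB <- 0L
  } else if (event_type == "alt5") {
    gapA <- 0L; gapB <- cfg$intron_length
  } else if (event_type == "alt3") {
    gapA <- cfg$intron_length; gapB <- 0L
  } else {
    gapA <- cfg$intron_length; gapB <- cfg$intron_length
  }

  exr <- cfg$exon_length_range
  if (localization == "CDS") {
    u5 <- sample(30:90, 1L)
    n_codons <- sample(40:130, 1L)
    c_len <- 3L * n_codons
    j <- sample(4:(c_len - 4L), 1L)          # CDS split at the junction
    orf <- .rand_orf(n_codons)
    u3 <- sample(50:150, 1L)
    exon1_seq <- paste0(.rand_dna(u5), substr(orf, 1L, j))
    exon2_seq <- paste0(substr(orf, j + 1L, c_len), .rand_dna(u3))
    e1 <- u5 + j
    e2 <- (c_len - j) + u3
    cds_rel <- c(u5 + 1L, e1 + gapA + seg_len + gapB + (c_len - j))
  } else if (localization == "UTR3") {
    u5 <- sample(30:90, 1L)
    n_codons <- sample(30:80, 1L)
    c_len <- 3L * n_codons
    orf <- .rand_orf(n_codons)
    u3a <- sample(20:60, 1L)
    exon1_seq <- paste0(.rand_dna(u5), orf, .rand_dna(u3a))
    e1 <- u5 + c_len + u3a
    e2 <- sample(exr[1]:exr[2], 1L)
    exon2_seq <- .rand_dna(e2)
    cds_rel <- c(u5 + 1L, u5 + c_len)
  } else { # UTR5
    e1 <- sample(exr[1]:exr[2], 1L)
    exon1_seq <- .rand_dna(e1)
    u5b <- sample(20:60, 1L)
    n_codons <- sample(30:80, 1L)
    c_len <- 3L * n_codons
    orf <- .rand_orf(n_codons)
    u3 <- sample(50:150, 1L)
    exon2_seq <- paste0(.rand_dna(u5b), orf, .rand_dna(u3))
    e2 <- u5b + c_len + u3
    off2 <- e1 + gapA + seg_len + gapB
    cds_rel <- c(off2 + u5b + 1L, off2 + u5b + c_len)
  }

  seg_seq <- .rand_dna(seg_len)
  if (localization == "CDS" && stats::runif(1) < cfg$frac_segment_stop_free)
    seg_seq <- .strip_frame_stops(seg_seq, phase = j %% 3L)
  chrom_seq <- paste0(.rand_dna(pad), exon1_seq,
                      if (gapA > 0) .rand_dna(gapA) else "",
                      seg_seq,
                      if (gapB > 0) .rand_dna(gapB) else "",
                      exon2_seq, .rand_dna(pad))
  L <- nchar(chrom_seq)

  exon1 <- c(pad + 1L, pad + e1)
  seg <- c(exon1[2] + gapA + 1L, exon1[2] + gapA + seg_len)
  exon2 <- c(seg[2] + gapB + 1L, seg[2] + gapB + e2)
  cds <- pad + cds_rel

  inc <- switch(event_type,
    cassette = rbind(exon1, seg, exon2),
    alt5 = rbind(c(exon1[1], seg[2]), exon2),
    alt3 = rbind(exon1, c(seg[1], exon2[2])),
    retained_intron = rbind(c(exon1[1], exon2[2])))
  exc <- rbind(exon1, exon2)

  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    chrom_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chrom_seq)))
    flip <- function(iv) c(L + 1L - iv[2], L + 1L - iv[1])
    seg <- flip(seg)
    cds <- flip(cds)
    inc <- t(apply(inc, 1L, flip))   # row order (= transcript order) kept
    exc <- t(apply(exc, 1L, flip))
  }

  ev <- splicing_event(
    event_id = paste0("ev_", gene_id), gene_id = gene_id,
    chrom = paste0("chr_", gene_id), strand = strand,
    event_type = event_type, seg = seg,
    inc_exons = unname(inc), exc_exons = unname(exc), cds = cds)
  ev$localization_truth <- localization
  list(seq = chrom_seq, event = ev)
}

#' Generate a synthetic transcriptome with one splicing event per gene
#'
#' Builds, deterministically from `cfg$seed`, a toy genome (one chromosome
#' per gene), multi-exon transcript models with annotated CDS, and a
#' catalog of well-formed splicing events of the four classes drawn from
#' `cfg$event_type_mix`. Strand is drawn at random per gene; introns
#' flanking cassette exons default to 1,000 nt so that the downstream
#' motif regions fit without truncation.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_transcriptome` with elements `genome`
#'   (named `DNAStringSet`), `events` (list of [splicing_event()]s, with a
#'   `localization_truth` field recording where the generator placed each
#'   segment), and `config`.
#' @export
make_transcriptome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    types <- sample(names(cfg$event_type_mix), cfg$n_genes, replace = TRUE,
                    prob = cfg$event_type_mix)
    locs <- sample(names(cfg$localization_mix), cfg$n_genes, replace = TRUE,
                   prob = cfg$localization_mix)
    ids <- sprintf("g%04d", seq_len(cfg$n_genes))
    built <- lapply(seq_len(cfg$n_genes), function(i)
      .build_gene(ids[i], types[i], locs[i], cfg))
  })
  genome <- Biostrings::DNAStringSet(vapply(built, `[[`, "", "seq"))
  events <- lapply(built, `[[`, "event")
  names(genome) <- vapply(events, `[[`, "", "chrom")
  names(events) <- vapply(events, `[[`, "", "event_id")
  structure(list(genome = genome, events = events, config = cfg),
            class = "sim_transcriptome")
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  tab <- table(vapply(x$events, `[[`, "", "event_type"))
  cat(sprintf("<sim_transcriptome> %d genes/events (%s)\n", length(x$events),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Ground-truth splicing parameters for simulated events
#'
#' Assigns each event a true PSI per condition. A fraction
#' `cfg$frac_affected` of events receives a true delta PSI drawn from
#' `cfg$delta_psi_effects` with random sign; control PSI is drawn
#' uniformly over the subinterval keeping both conditions inside
#' `[0.02, 0.98]`. Unaffected events share one PSI across conditions.
#'
#' @param events list of [splicing_event()]s (or a `sim_transcriptome`).
#' @param cfg a [sim_config()].
#' @return data.frame with columns `event_id`, `true_psi_control`,
#'   `true_psi_treated`, `is_differential`.
#' @export
make_truth <- function(events, cfg) {
  if (inherits(events, "sim_transcriptome")) events <- events$events
  n <- length(events)
  with_seed(cfg$seed + 500L, {
    affected <- rep(FALSE, n)
    n_aff <- round(cfg$frac_affected * n)
    if (n_aff > 0) affected[sample.int(n, n_aff)] <- TRUE
    psi_c <- psi_t <- numeric(n)
    for (i in seq_len(n)) {
      if (affected[i]) {
        d <- sample(cfg$delta_psi_effects, 1L) * sample(c(-1, 1), 1L)
        lo <- max(0.02, 0.02 - d); hi <- min(0.98, 0.98 - d)
        psi_c[i] <- stats::runif(1, lo, hi)
        psi_t[i] <- psi_c[i] + d
      } else {
        psi_c[i] <- psi_t[i] <- stats::runif(1, 0.05, 0.95)
      }
    }
  })
  data.frame(event_id = vapply(events, `[[`, "", "event_id"),
             true_psi_control = psi_c, true_psi_treated = psi_t,
             is_differential = affected, row.names = NULL,
             stringsAsFactors = FALSE)
}
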