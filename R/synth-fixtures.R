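#' Random PWM with a definite consensus
#'
#' Each column puts probability `conc` on a randomly chosen base and
#' spreads the rest uniformly; useful both as background motif material
#' and, at high `conc`, as a plantable motif whose consensus is recovered
#' by scanning.
#'
#' @param width motif width.
#' @param motif_id,rbp identifiers.
#' @param conc probability of the consensus base per column.
#' @return a [pwm()].
#' @export
random_pwm <- function(width, motif_id, rbp = motif_id, conc = 0.8) {
  cons <- sample(1:4, width, replace = TRUE)
  mat <- matrix((1 - conc) / 3, nrow = 4, ncol = width)
  mat[cbind(cons, seq_len(width))] <- conc
  pwm(mat, motif_id, rbp)
}

#' PWM concentrated on a given consensus sequence
#'
#' @param consensus character scalar over A/C/G/T/U.
#' @param motif_id,rbp identifiers.
#' @param conc probability of the consensus base per column.
#' @return a [pwm()].
#' @export
consensus_pwm <- function(consensus, motif_id, rbp = motif_id, conc = 0.97) {
  bases <- strsplit(chartr("Uu", "Tt", toupper(consensus)), "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  stopifnot(!anyNA(idx))
  mat <- matrix((1 - conc) / 3, nrow = 4, ncol = length(idx))
  mat[cbind(idx, seq_along(idx))] <- conc
  pwm(mat, motif_id, rbp)
}

#' Plant a motif consensus into a regulatory region of selected events
#'
#' Overwrites the genome so that `copies` tandem-adjacent copies of the
#' motif consensus appear (sense strand) inside the given regulatory
#' region of each selected cassette event. Used for plant-and-recover
#' validation of the motif stage.
#'
#' @param tx a `sim_transcriptome`.
#' @param event_ids cassette events to modify.
#' @param x a [pwm()] whose consensus is planted.
#' @param region region index 1-7.
#' @param copies number of copies per event.
#' @param at offset of the first copy within the region (default 10).
#' @return the modified `sim_transcriptome`.
#' @export
plant_motif <- function(tx, event_ids, x, region = 3L, copies = 2L, at = 10L) {
  cons <- pwm_consensus(x)
  insert <- strrep(cons, copies)
  for (id in event_ids) {
    ev <- tx$events[[id]]
    stopifnot(ev$event_type == "cassette")
    reg <- extract_regions(ev, tx$genome)
    iv <- c(reg$start[region], reg$end[region])
    stopifnot(iv[2] - iv[1] + 1L >= at + nchar(insert) - 1L)
    dna <- Biostrings::DNAString(insert)
    if (ev$strand == "+") {
      s <- iv[1] + at - 1L
    } else {
      s <- iv[2] - at - nchar(insert) + 2L
      dna <- Biostrings::reverseComplement(dna)
    }
    seqchar <- tx$genome[[ev$chrom]]
    tx$genome[[ev$chrom]] <- Biostrings::replaceAt(
      seqchar, IRanges::IRanges(s, s + nchar(insert) - 1L), dna)
  }
  tx
}

#' Annotation fixtures wired to a simulated event set
#'
#' Generates the annotation tables the downstream stages consume, shaped
#' to the simulated transcriptome so every stage has known-positive input:
#' protein-domain intervals overlapping a configurable number of AS
#' regions, per-residue disorder calls drawn from configurable category
#' proportions, a PTM site table with sites inside and outside AS
#' regions, and a random PWM set. The PPI/DDI tables come from
#' [ppi_demo_fixture()] and include a self-interacting domain pair.
#'
#' @param tx a `sim_transcriptome`.
#' @param n_domain_overlaps number of frame-preserving CDS events given an
#'   overlapping domain (capped at the number available).
#' @param disorder_mix proportions of `totally_disordered`,
#'   `partially_disordered`, `structured` regions.
#' @param n_ptm_sites expected number of PTM sites per eligible event.
#' @param n_pwms number of random PWMs.
#' @param pwm_width motif width for the random set.
#' @param seed integer seed (defaults to the simulation seed + 2000).
#' @return list of class `annotation_fixtures`: `domains`, `disorder`,
#'   `ptm`, `pwms`, `ppi` (list with `experimental_a`, `experimental_b`,
#'   `ddi`, `gene2domain`, `expressed`, `disrupted`), `peptides` (the
#'   flanked-peptide table the fixtures were wired to).
#' @export
make_annotation_fixtures <- function(tx, n_domain_overlaps = 5L,
                                     disorder_mix = c(totally_disordered = 0.523,
                                                      partially_disordered = 0.323,
                                                      structured = 0.154),
                                     n_ptm_sites = 1.5,
                                     n_pwms = 10L, pwm_width = 8L,
                                     seed = NULL) {
  stopifnot(inherits(tx, "sim_transcriptome"))
  if (is.null(seed)) seed <- tx$config$seed + 2000L
  ann <- classify_events(tx$events, tx$genome)
  peptides <- flanked_peptides(tx$events, tx$genome, annotations = ann)

  ptm_types <- c("proteolytic_cleavage", "phosphorylation", "amidation",
                 "hydroxylation", "carboxylation", "ADP-ribosylation",
                 "O-linked_glycosylation", "acetylation",
                 "GPI_anchor_amidation", "palmitoylation",
                 "pyrrolidone_carboxylic_acid", "methylation",
                 "ubiquitination")

  with_seed(seed, {
    ## --- protein domain intervals overlapping a subset of AS regions
    dom_rows <- list()
    if (nrow(peptides)) {
      k <- min(n_domain_overlaps, nrow(peptides))
      pick <- if (k > 0) sample(seq_len(nrow(peptides)), k) else integer(0)
      for (i in pick) {
        pep <- peptides[i, ]
        pad <- sample(0:5, 2L, replace = TRUE)
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = pep$protein_id,
          domain_accession = sprintf("PF%05d", length(dom_rows) + 1L),
          domain_name = sprintf("dom_%s", pep$protein_id),
          start_aa = max(1L, pep$aa_start - pad[1]),
          end_aa = pep$aa_end + pad[2], stringsAsFactors = FALSE)
      }
      ## distractor domains well outside the windows
      for (i in seq_len(min(5L, nrow(peptides)))) {
        pep <- peptides[i, ]
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = pep$protein_id,
          domain_accession = sprintf("PF9%04d", i),
          domain_name = sprintf("far_dom_%d", i),
          start_aa = pep$win_aa_end + 50L,
          end_aa = pep$win_aa_end + 80L, stringsAsFactors = FALSE)
      }
    }
    domains <- if (length(dom_rows)) rbind_rows(dom_rows)
    else data.frame(protein_id = character(), domain_accession = character(),
                    domain_name = character(), start_aa = integer(),
                    end_aa = integer(), stringsAsFactors = FALSE)

    ## --- per-residue disorder calls over each AS peptide
    dis_rows <- list()
    for (i in seq_len(nrow(peptides))) {
      pep <- peptides[i, ]
      n <- pep$aa_end - pep$aa_start + 1L
      if (n < 9L) next
      cat_i <- sample(names(disorder_mix), 1L, prob = disorder_mix)
      calls <- switch(cat_i,
        totally_disordered = rep(1L, n),
        structured = rep(0L, n),
        partially_disordered = {
          k <- sample(seq_len(n - 1L), 1L)
          sample(c(rep(1L, k), rep(0L, n - k)))
        })
      dis_rows[[length(dis_rows) + 1L]] <- data.frame(
        protein_id = pep$protein_id,
        residue_index = pep$aa_start:pep$aa_end,
        call = calls, stringsAsFactors = FALSE)
    }
    disorder <- if (length(dis_rows)) rbind_rows(dis_rows)
    else data.frame(protein_id = character(), residue_index = integer(),
                    call = integer(), stringsAsFactors = FALSE)

    ## --- PTM sites: some inside the AS interval, some outside
    ptm_rows <- list()
    for (i in seq_len(nrow(peptides))) {
      pep <- peptides[i, ]
      n_in <- stats::rpois(1L, n_ptm_sites)
      if (n_in > 0) {
        pos <- sample(pep$aa_start:pep$aa_end, n_in, replace = TRUE)
        ptm_rows[[length(ptm_rows) + 1L]] <- data.frame(
          protein_id = pep$protein_id, position = pos,
          type = sample(ptm_types, n_in, replace = TRUE),
          source = sample(c("known", "predicted"), n_in, replace = TRUE,
                          prob = c(0.2, 0.8)), stringsAsFactors = FALSE)
      }
      ptm_rows[[length(ptm_rows) + 1L]] <- data.frame(
        protein_id = pep$protein_id, position = pep$aa_end + 40L,
        type = sample(ptm_types, 1L), source = "predicted",
        stringsAsFactors = FALSE)
    }
    ptm <- if (length(ptm_rows)) rbind_rows(ptm_rows)
    else data.frame(protein_id = character(), position = integer(),
                    type = character(), source = character(),
                    stringsAsFactors = FALSE)

    pwms <- lapply(seq_len(n_pwms), function(i)
      random_pwm(pwm_width, sprintf("M%03d", i), sprintf("RBP%03d", i)))
  })

  structure(list(domains = domains, disorder = disorder, ptm = ptm,
                 pwms = pwms, ppi = ppi_demo_fixture(),
                 peptides = peptides),
            class = "annotation_fixtures")
}

#' Hand-wired dual-evidence PPI fixture
#'
#' A small interaction scenario mirroring the shape of a
#' three-AS-gene/eight-partner network with both evidence classes:
#' three genes whose spliced domains are `rabaptin_like` (self-interacting,
#' so the gene is its own candidate partner), `pkinase_like` and
#' `hormone_recep_like`; eight partner edges carry both experimental and
#' structural support. Distractors cover the failure modes: one
#' structural-only pair (no experimental edge), one experimental-only pair
#' (no DDI link), and one dual-evidence partner that is not expressed.
#'
#' @return list: `experimental_a`, `experimental_b` (edge lists),
#'   `ddi`, `gene2domain`, `expressed`, `disrupted` (AS gene/domain
#'   pairs), `expected_pairs` (the eight as_gene/partner pairs the join
#'   must recover; turning the expression filter on additionally drops
#'   the unexpressed partner).
#' @export
ppi_demo_fixture <- function() {
  disrupted <- data.frame(
    as_gene = c("GeneR", "GeneK", "GeneH"),
    as_domain = c("rabaptin_like", "pkinase_like", "hormone_recep_like"),
    stringsAsFactors = FALSE)
  ddi <- data.frame(
    domain_a = c("rabaptin_like", "rabaptin_like", "pkinase_like",
                 "hormone_recep_like", "hormone_recep_like",
                 "pkinase_like"),
    domain_b = c("rabaptin_like", "gga_ear", "camkk_dom",
                 "rxr_lbd", "nr_box", "orphan_dom"),
    stringsAsFactors = FALSE)
  gene2domain <- data.frame(
    gene = c("GeneR", "GeneK", "GeneH",
             "PartGga1", "PartGga2", "PartGga3",
             "PartCamkk", "PartRxra", "PartRxrb", "PartNr0b2",
             "StructOnly", "ExpOnly"),
    domain = c("rabaptin_like", "pkinase_like", "hormone_recep_like",
               "gga_ear", "gga_ear", "gga_ear",
               "camkk_dom", "rxr_lbd", "rxr_lbd", "nr_box",
               "orphan_dom", "unrelated_dom"),
    stringsAsFactors = FALSE)
  ## eight true dual-evidence edges (incl. the GeneR homodimer) split
  ## across two experimental datasets, plus an experimental-only edge
  experimental_a <- data.frame(
    gene_a = c("GeneR", "GeneR", "GeneR", "GeneK", "GeneH"),
    gene_b = c("GeneR", "PartGga1", "PartGga2", "PartCamkk", "PartRxra"),
    stringsAsFactors = FALSE)
  experimental_b <- data.frame(
    gene_a = c("GeneR", "GeneH", "GeneH", "GeneR", "GeneK"),
    gene_b = c("PartGga3", "PartRxrb", "PartNr0b2", "PartGga1", "ExpOnly"),
    stringsAsFactors = FALSE)
  expressed <- c("GeneR", "GeneK", "GeneH", "PartGga1", "PartGga2",
                 "PartGga3", "PartCamkk", "PartRxra", "PartRxrb",
                 "StructOnly", "ExpOnly")   # PartNr0b2 deliberately absent
  expected_pairs <- data.frame(
    as_gene = c("GeneR", "GeneR", "GeneR", "GeneR", "GeneK", "GeneH",
                "GeneH", "GeneH"),
    partner_gene = c("GeneR", "PartGga1", "PartGga2", "PartGga3",
                     "PartCamkk", "PartRxra", "PartRxrb", "PartNr0b2"),
    stringsAsFactors = FALSE)
  list(experimental_a = experimental_a, experimental_b = experimental_b,
       ddi = ddi, gene2domain = gene2domain, expressed = expressed,
       disrupted = disrupted, expected_pairs = expected_pairs)
}
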