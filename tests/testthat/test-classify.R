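# CDS layout used by the hand-placed fixtures below (plus-strand layout
# coordinates, exon1 starting at 1): 30 nt 5' UTR, then an ORF split at
# the exon1/exon2 junction, then a 3' UTR.
.coding_toy <- function(seg_seq, event_type = "cassette", strand = "+",
                        j = 60L, n_codons = 40L, u5 = 30L, u3 = 60L) {
  orf <- paste0("ATG", sense_codons_dna(n_codons - 2L), "TAA")
  c_len <- 3L * n_codons
  toy_event(event_type,
            exon1_seq = paste0(rand_dna(u5), substr(orf, 1, j)),
            seg_seq = seg_seq,
            exon2_seq = paste0(substr(orf, j + 1, c_len), rand_dna(u3)),
            strand = strand,
            cds_rel = c(u5 + 1L,
                        u5 + j + nchar(seg_seq) +
                          switch(event_type, retained_intron = 0L,
                                 cassette = 800L, alt5 = 400L, alt3 = 400L) +
                          (c_len - j)))
}

test_that("hand-placed segments localize to CDS, 5' UTR and 3' UTR as constructed", {
  set.seed(23)
  ## segment mid-ORF -> CDS
  toy <- .coding_toy(sense_codons_dna(30L))
  expect_equal(localize_event(toy$event), "CDS")
  ## ORF entirely inside exon1 -> downstream segment is 3' UTR
  orf <- paste0("ATG", sense_codons_dna(20L), "TAA")
  t3 <- toy_event("cassette", exon1_seq = paste0(rand_dna(30), orf, rand_dna(40)),
                  seg_seq = rand_dna(90), exon2_seq = rand_dna(150),
                  cds_rel = c(31L, 30L + nchar(orf)))
  expect_equal(localize_event(t3$event), "UTR3")
  ## ORF entirely inside exon2 -> upstream segment is 5' UTR
  t5 <- toy_event("cassette", exon1_seq = rand_dna(150),
                  seg_seq = rand_dna(90),
                  exon2_seq = paste0(rand_dna(40), orf, rand_dna(60)),
                  cds_rel = c(150L + 400L + 90L + 400L + 41L,
                              150L + 400L + 90L + 400L + 40L + nchar(orf)))
  expect_equal(localize_event(t5$event), "UTR5")
  ## segment straddling the start codon -> CDS by the any-overlap rule
  ts <- toy_event("retained_intron",
                  exon1_seq = paste0(rand_dna(30), "AT"),
                  seg_seq = paste0("G", sense_codons_dna(30L)),
                  exon2_seq = paste0(sense_codons_dna(20L), "TAA", rand_dna(50)),
                  cds_rel = c(31L, 32L + 91L + 63L))
  expect_equal(localize_event(ts$event), "CDS")
  ## no CDS annotation -> excluded with a warning
  tn <- toy_event("cassette", rand_dna(100), rand_dna(60), rand_dna(100))
  expect_warning(loc <- localize_event(tn$event), "lacks CDS")
  expect_true(is.na(loc))
})

test_that("frame preservation follows segment length mod 3 on both strands", {
  set.seed(29)
  for (strand in c("+", "-")) {
    toy <- .coding_toy(sense_codons_dna(24L), strand = strand)
    a <- classify_frame(toy$event, toy$genome)
    expect_true(a$frame_preserving)
    expect_false(a$premature_stop)
    toy70 <- .coding_toy(substr(sense_codons_dna(24L), 1, 70), strand = strand)
    a70 <- classify_frame(toy70$event, toy70$genome)
    expect_false(a70$frame_preserving)
  }
})

test_that("an in-frame stop far from the last junction is a PTC and NMD candidate", {
  set.seed(31)
  ## codon-aligned junction (j = 60) so the segment's first base starts a
  ## codon; TAA at segment offset 4-6 is in frame
  seg <- paste0("GCC", "TAA", sense_codons_dna(28L))
  toy <- .coding_toy(seg, j = 60L)
  a <- classify_frame(toy$event, toy$genome)
  expect_true(a$frame_preserving)
  expect_true(a$premature_stop)
  expect_true(a$nmd_candidate)     # whole downstream exon lies past the PTC
  ## frame preservation depends on segment length alone, not on the
  ## insertion phase: shifting the junction by 1 nt keeps it TRUE
  toy_off <- .coding_toy(seg, j = 61L)
  a_off <- classify_frame(toy_off$event, toy_off$genome)
  expect_true(a_off$frame_preserving)
  ## with the phase shifted, the planted TAA is no longer read in frame;
  ## the naive oracle must agree either way
  o_off <- naive_stop_classify(toy_off$event, toy_off$genome)
  expect_identical(a_off$premature_stop, o_off$premature)
})

test_that("classification agrees with a naive codon-walking oracle on random transcripts", {
  cfg <- sim_config(n_genes = 100, seed = 37,
                    localization_mix = c(CDS = 1, UTR5 = 0, UTR3 = 0))
  tx <- make_transcriptome(cfg)
  for (ev in tx$events) {
    a <- classify_frame(ev, tx$genome)
    o <- naive_stop_classify(ev, tx$genome)
    expect_identical(a$premature_stop, o$premature, info = ev$event_id)
    expect_identical(a$nmd_candidate, o$nmd, info = ev$event_id)
    expect_identical(a$frame_preserving,
                     (ev$seg[2] - ev$seg[1] + 1L) %% 3L == 0L,
                     info = ev$event_id)
  }
})

test_that("mirroring the genome onto the opposite strand preserves every classification", {
  cfg <- sim_config(n_genes = 25, seed = 41)
  tx <- make_transcriptome(cfg)
  for (ev in tx$events) {
    m <- mirror_event(ev, tx$genome)
    expect_identical(localize_event(ev), localize_event(m$event))
    if (localize_event(ev) == "CDS") {
      a <- classify_frame(ev, tx$genome)
      b <- classify_frame(m$event, m$genome)
      b$event_id <- a$event_id
      expect_identical(a, b)
    }
  }
})

test_that("localization and frame tallies partition the annotated events", {
  cfg <- sim_config(n_genes = 60, seed = 43)
  tx <- make_transcriptome(cfg)
  ann <- classify_events(tx$events, tx$genome)
  expect_equal(nrow(ann), length(tx$events))
  expect_equal(sum(ann$localization %in% c("CDS", "UTR5", "UTR3")), nrow(ann))
  cds <- ann[ann$localization == "CDS", ]
  expect_equal(sum(cds$frame_preserving) + sum(!cds$frame_preserving),
               nrow(cds))
  ## NMD implies a premature stop (with frame shift or not)
  expect_true(all(!cds$nmd_candidate | cds$premature_stop))
})

test_that("disorder categories follow the strict total/structured boundaries", {
  expect_equal(disorder_category("e1", rep(1, 12))$category,
               "totally_disordered")
  expect_equal(disorder_category("e2", rep(0, 12))$category, "structured")
  d <- disorder_category("e3", c(rep(1, 5), rep(0, 7)))
  expect_equal(d$category, "partially_disordered")
  expect_equal(d$fraction_disordered, 5 / 12, tolerance = 1e-12)
  short <- disorder_category("e4", rep(1, 8))
  expect_true(is.na(short$category))
  expect_match(short$excluded_reason, "< 9 aa")
})

test_that("PTM intersection respects closed interval boundaries and tallies types", {
  ivl <- data.frame(event_id = "ev1", protein_id = "p1",
                    aa_start = 10L, aa_end = 20L)
  empty <- intersect_ptm(ivl, data.frame(protein_id = character(),
                                         position = integer(),
                                         type = character(),
                                         source = character()))
  expect_equal(nrow(empty$hits), 0L)
  ptm <- data.frame(protein_id = "p1", position = c(9L, 10L, 20L, 21L),
                    type = "phosphorylation", source = "known")
  hits <- intersect_ptm(ivl, ptm)$hits
  expect_equal(sort(hits$position), c(10L, 20L))   # closed on both ends
  ## per-type tally on a cleavage-heavy fixture
  ivls <- data.frame(event_id = paste0("ev", 1:14),
                     protein_id = paste0("p", 1:14),
                     aa_start = 5L, aa_end = 30L)
  cleav <- data.frame(protein_id = paste0("p", 1:14), position = 12L,
                      type = "proteolytic_cleavage", source = "predicted")
  other <- data.frame(protein_id = "p1", position = 13L,
                      type = "acetylation", source = "known")
  res <- intersect_ptm(ivls, rbind(cleav, other))
  expect_equal(res$type_totals[["proteolytic_cleavage"]], 14L)
  expect_equal(res$type_totals[["acetylation"]], 1L)
  expect_equal(dim(res$matrix), c(14L, 2L))
})

test_that("PTM sites beyond the protein length are skipped with a warning", {
  ivl <- data.frame(event_id = "ev1", protein_id = "p1",
                    aa_start = 1L, aa_end = 50L)
  ptm <- data.frame(protein_id = "p1", position = c(10L, 99L),
                    type = "phosphorylation", source = "known")
  expect_warning(res <- intersect_ptm(ivl, ptm, protein_lengths = c(p1 = 60L)),
                 "beyond protein length")
  expect_equal(res$hits$position, 10L)
})
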