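test_that("long introns and exons give the canonical region lengths", {
  set.seed(87)
  toy <- toy_event("cassette", rand_dna(200), rand_dna(96), rand_dna(200),
                   gapA = 1000L, gapB = 1000L)
  r <- extract_regions(toy$event, toy$genome)
  expect_equal(r$length, c(150L, 300L, 300L, 96L, 300L, 300L, 150L))
  expect_equal(r$region, 1:7)
  ## exons shorter than 150 nt truncate R1/R7 to the whole exon
  short <- toy_event("cassette", rand_dna(80), rand_dna(90), rand_dna(70),
                     gapA = 1000L, gapB = 1000L)
  rs <- extract_regions(short$event, short$genome)
  expect_equal(rs$length[c(1, 7)], c(80L, 70L))
})

test_that("short introns split at the midpoint without overlap", {
  set.seed(89)
  toy <- toy_event("cassette", rand_dna(200), rand_dna(90), rand_dna(200),
                   gapA = 400L, gapB = 401L)
  r <- extract_regions(toy$event, toy$genome)
  expect_equal(r$length[2:3], c(200L, 200L))
  expect_equal(r$length[5:6], c(200L, 201L))   # odd length: 5' half smaller
  ## non-overlap and containment within the source intron
  expect_lt(r$end[2], r$start[3])
  up_intron <- c(toy$event$inc_exons[1, 2] + 1L, toy$event$inc_exons[2, 1] - 1L)
  expect_gte(r$start[2], up_intron[1])
  expect_lte(r$end[3], up_intron[2])
})

test_that("region partition holds on every generated cassette event", {
  cfg <- sim_config(n_genes = 20, seed = 91,
                    event_type_mix = c(cassette = 1, alt5 = 0, alt3 = 0,
                                       retained_intron = 0))
  tx <- make_transcriptome(cfg)
  regs <- regulatory_regions(tx)
  for (id in unique(regs$event_id)) {
    r <- regs[regs$event_id == id, ]
    expect_equal(r$length, r$end - r$start + 1L)
    expect_true(all(r$length >= 1L))
    ## R2/R3 disjoint, R5/R6 disjoint (genomic intervals)
    expect_true(min(r$end[2], r$end[3]) < max(r$start[2], r$start[3]))
    expect_true(min(r$end[5], r$end[6]) < max(r$start[5], r$start[6]))
  }
})

test_that("minus-strand regions are the reverse-complement mirror of plus-strand ones", {
  set.seed(93)
  e1 <- rand_dna(180); sg <- rand_dna(90); e2 <- rand_dna(160)
  tp <- toy_event("cassette", e1, sg, e2, gapA = 700L, gapB = 500L,
                  strand = "+")
  rp <- extract_regions(tp$event, tp$genome)
  mm <- mirror_event(tp$event, tp$genome)
  rm <- extract_regions(mm$event, mm$genome)
  expect_equal(rm$seq, rp$seq)       # sense-strand sequences identical
  expect_equal(rm$length, rp$length)
  L <- length(tp$genome[[1]])
  expect_equal(rm$start, L + 1L - rp$end)   # mirrored coordinates
})

test_that("non-cassette events violate the region contract", {
  set.seed(95)
  toy <- toy_event("retained_intron", rand_dna(100), rand_dna(90),
                   rand_dna(100))
  expect_error(extract_regions(toy$event, toy$genome), "cassette")
})

test_that("PWM validation rejects malformed matrices", {
  m <- matrix(0.25, 4, 6)
  expect_silent(pwm(m, "ok"))
  bad <- m; bad[1, 1] <- 0.5
  expect_error(pwm(bad, "bad"), "sum to 1")
  expect_error(pwm(matrix(0.2, 5, 4), "bad2"), "4 rows")
})

test_that("a PWM identical to the background scores zero everywhere", {
  u <- pwm(matrix(0.25, 4, 5), "uniform")
  hits <- scan_pwm(strrep("ACGT", 12), u)
  expect_true(all(hits$score == 0))
  expect_true(all(hits$p_value == 1))
})

test_that("the DP score distribution equals brute-force enumeration for w <= 6", {
  set.seed(97)
  for (w in 3:6) {
    m <- random_pwm(w, paste0("m", w), conc = runif(1, 0.5, 0.95))
    bg <- runif(4, 0.1, 1); bg <- bg / sum(bg)
    sc <- pwm_scorer(m, bg)
    expect_equal(sum(sc$dist), 1, tolerance = 1e-9)
    brute <- brute_pwm_tail(sc)
    dp <- sc$tail[brute$scores - sc$min_s + 1L]
    expect_lt(max(abs(dp - brute$tail)), 1e-12)
  }
})

test_that("scanning p-values match the brute-force tail at every offset", {
  set.seed(99)
  m <- random_pwm(4, "m4", conc = 0.8)
  bg <- c(0.3, 0.2, 0.3, 0.2)
  sc <- pwm_scorer(m, bg)
  brute <- brute_pwm_tail(sc)
  seqs <- strrep(rand_dna(60), 1)
  hits <- scan_pwm(seqs, sc)
  for (i in seq_len(nrow(hits))) {
    s_int <- as.integer(round(hits$score[i] / sc$bin))
    expect_equal(hits$p_value[i], brute$tail[match(s_int, brute$scores)])
  }
})

test_that("the consensus word achieves the maximal attainable score", {
  set.seed(101)
  m <- random_pwm(7, "m7", conc = 0.9)
  sc <- pwm_scorer(m)
  cons <- pwm_consensus(m)
  h <- scan_pwm(cons, sc)
  expect_equal(nrow(h), 1L)
  expect_equal(as.integer(round(h$score / sc$bin)),
               sum(apply(sc$r, 2, max)))
})

test_that("a planted consensus is the top hit at its planting offset", {
  set.seed(103)
  m <- consensus_pwm("TGACGTTA", "planted")
  seqs <- paste0(rand_dna(9), pwm_consensus(m), rand_dna(40))
  hits <- scan_pwm(seqs, m)
  expect_equal(hits$offset[which.max(hits$score)], 10L)
  expect_lt(hits$p_value[10], 1e-4)
})

test_that("sequences shorter than the motif give an empty hit list", {
  m <- random_pwm(8, "m8")
  expect_equal(nrow(scan_pwm("ACGT", m)), 0L)
})

test_that("BH q-values are monotone in p within each direction-motif stratum", {
  set.seed(107)
  calls <- data.frame(event_id = c("e1", "e2"), delta_psi = c(0.3, -0.3),
                      passes = TRUE)
  regions <- rbind(
    data.frame(event_id = "e1", region = 1:7, start = 1, end = 300,
               length = 300, seq = replicate(7, rand_dna(300))),
    data.frame(event_id = "e2", region = 1:7, start = 1, end = 300,
               length = 300, seq = replicate(7, rand_dna(300))))
  pwms <- lapply(1:4, function(i) random_pwm(6, paste0("m", i), conc = 0.9))
  enr <- motif_enrichment(calls, regions, pwms, p_cut = 0.05, fdr_cut = 1)
  h <- enr$hits
  for (key in unique(paste(h$direction, h$motif_id))) {
    sub <- h[paste(h$direction, h$motif_id) == key, ]
    sub <- sub[order(sub$p_value), ]
    expect_true(all(diff(sub$q_value) >= -1e-12))
    expect_true(all(sub$q_value > 0 & sub$q_value <= 1))
  }
})

test_that("a motif planted in Region 3 of up-regulated events is recovered there", {
  cfg <- sim_config(n_genes = 30, seed = 109, depth_per_event = 800,
                    event_type_mix = c(cassette = 1, alt5 = 0, alt3 = 0,
                                       retained_intron = 0),
                    frac_affected = 1, delta_psi_effects = c(0.4))
  tx <- make_transcriptome(cfg)
  truth <- make_truth(tx, cfg)
  m <- consensus_pwm("TGCATGACAT", "planted", "PLANT_RBP")
  up_ids <- truth$event_id[truth$true_psi_treated > truth$true_psi_control]
  tx <- plant_motif(tx, up_ids, m, region = 3L, copies = 2L)
  eff <- effective_sizes_table(tx, cfg$read_length)
  cts <- simulate_counts(tx, truth, cfg, eff)
  calls <- call_events(cts, eff)
  regs <- regulatory_regions(tx, ids = calls$calls$event_id[calls$calls$passes])
  enr <- motif_enrichment(calls$calls, regs,
                          list(m, random_pwm(8, "bgM", conc = 0.8)))
  occ <- enr$occurrence[enr$occurrence$motif_id == "planted", ]
  r3up <- occ$n_hits[occ$direction == "up" & occ$region == 3]
  expect_length(r3up, 1L)
  expect_true(all(occ$n_hits[!(occ$direction == "up" & occ$region == 3)]
                  < r3up / 4))
  expect_equal(sum(occ$n_hits[occ$direction == "down"]), 0L)
  expect_true("planted" %in% enr$exclusive_up)
})

test_that("hit counts on shuffled sequences match the exact background rate", {
  set.seed(113)
  ## expected count is exact: per motif, the attained alpha is the largest
  ## tail probability below the cutoff, known from the DP distribution
  seqs <- replicate(60, rand_dna(300))
  bg <- background_composition(seqs)
  pwms <- lapply(1:10, function(i) random_pwm(7, paste0("m", i), conc = 0.85))
  p_cut <- 1e-3
  expected <- 0; observed <- 0
  for (m in pwms) {
    sc <- pwm_scorer(m, bg)
    alpha <- max(c(0, sc$tail[sc$tail < p_cut]))
    expected <- expected + alpha * length(seqs) * (300 - m$width + 1)
    for (s in seqs)
      observed <- observed + sum(scan_pwm(s, sc)$p_value < p_cut)
  }
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 2)
})

test_that("MEME round trip preserves matrices, names and background", {
  set.seed(127)
  pwms <- lapply(1:3, function(i) random_pwm(5 + i, sprintf("M%d", i),
                                             sprintf("RBP%d", i)))
  path <- withr::local_tempfile(fileext = ".meme")
  bg <- c(0.3, 0.2, 0.2, 0.3)
  write_meme(pwms, path, background = bg)
  back <- read_meme(path)
  expect_length(back, 3L)
  expect_equal(attr(back, "background"), bg, tolerance = 1e-5)
  for (i in 1:3) {
    expect_equal(back[[i]]$motif_id, pwms[[i]]$motif_id)
    expect_equal(back[[i]]$rbp, pwms[[i]]$rbp)
    expect_equal(back[[i]]$mat, pwms[[i]]$mat, tolerance = 1e-5)
  }
})
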