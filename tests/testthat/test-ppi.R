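test_that("merging two lists sharing one edge gives |A| + |B| - 1 edges", {
  a <- data.frame(gene_a = c("g1", "g2", "g3"), gene_b = c("x1", "x2", "x3"))
  b <- data.frame(gene_a = c("g4", "g2"), gene_b = c("x4", "x2"))
  m <- merge_ppi(a, b)
  expect_equal(nrow(m), 4L)
  expect_equal(m$source_count[m$gene_a == "g2"], 2L)
})

test_that("reversed and case-varied edges canonicalize to a single edge", {
  a <- data.frame(gene_a = "Abc", gene_b = "Xyz")
  b <- data.frame(gene_a = "XYZ", gene_b = "abc")
  m <- merge_ppi(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$source_count, 2L)
})

test_that("self-loops survive the merge and malformed rows are counted", {
  a <- data.frame(gene_a = c("g1", "g1", ""), gene_b = c("g1", "g2", "g9"))
  m <- merge_ppi(a)
  expect_equal(nrow(m), 2L)
  expect_true(any(m$gene_a == "g1" & m$gene_b == "g1"))
  expect_equal(attr(m, "n_skipped"), 1L)
})

test_that("random edge lists merge to the brute-force set union", {
  set.seed(79)
  genes <- sprintf("G%02d", 1:15)
  mk <- function(n) data.frame(gene_a = sample(genes, n, TRUE),
                               gene_b = sample(genes, n, TRUE))
  for (i in 1:5) {
    a <- mk(30); b <- mk(30)
    m <- merge_ppi(a, b)
    key <- function(x, y) paste(pmin(tolower(x), tolower(y)),
                                pmax(tolower(x), tolower(y)))
    want <- unique(c(key(a$gene_a, a$gene_b), key(b$gene_a, b$gene_b)))
    expect_setequal(key(m$gene_a, m$gene_b), want)
  }
})

test_that("a self-interacting domain makes its carrier its own structural partner", {
  fx <- ppi_demo_fixture()
  p <- structural_partners("rabaptin_like", fx$ddi, fx$gene2domain)
  expect_true("GeneR" %in% p$partner_gene)   # homodimerization pattern
  expect_true(all(c("PartGga1", "PartGga2", "PartGga3") %in% p$partner_gene))
})

test_that("a domain absent from the DDI table yields an empty partner set", {
  fx <- ppi_demo_fixture()
  p <- structural_partners("unknown_dom", fx$ddi, fx$gene2domain)
  expect_equal(nrow(p), 0L)
  empty_ddi <- data.frame(domain_a = character(), domain_b = character())
  expect_equal(nrow(structural_partners("rabaptin_like", empty_ddi,
                                        fx$gene2domain)), 0L)
})

test_that("the dual-evidence fixture yields exactly eight interactions, matching brute force", {
  fx <- ppi_demo_fixture()
  merged <- merge_ppi(fx$experimental_a, fx$experimental_b)
  res <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain, merged)
  pairs <- unique(res[c("as_gene", "partner_gene")])
  expect_equal(nrow(pairs), 8L)
  expect_setequal(paste(pairs$as_gene, pairs$partner_gene),
                  paste(fx$expected_pairs$as_gene,
                        fx$expected_pairs$partner_gene))
  brute <- brute_dual_join(fx$disrupted, fx$ddi, fx$gene2domain, merged)
  expect_setequal(paste(pairs$as_gene, pairs$partner_gene),
                  paste(brute$as_gene, brute$partner_gene))
  ## distractors must not leak through
  expect_false("StructOnly" %in% res$partner_gene)
  expect_false("ExpOnly" %in% res$partner_gene)
  expect_true(all(res$has_experimental & res$has_structural))
})

test_that("the expression filter drops only the unexpressed partner", {
  fx <- ppi_demo_fixture()
  merged <- merge_ppi(fx$experimental_a, fx$experimental_b)
  res <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain, merged,
                            expressed = fx$expressed)
  pairs <- unique(res[c("as_gene", "partner_gene")])
  expect_equal(nrow(pairs), 7L)
  expect_false("PartNr0b2" %in% pairs$partner_gene)
})

test_that("no experimental edges means no output regardless of the DDI table", {
  fx <- ppi_demo_fixture()
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      source_count = integer())
  res <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain, empty)
  expect_equal(nrow(res), 0L)
})

test_that("adding evidence rows never removes an emitted interaction", {
  set.seed(83)
  fx <- ppi_demo_fixture()
  merged <- merge_ppi(fx$experimental_a, fx$experimental_b)
  base <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain, merged)
  key0 <- paste(base$as_gene, base$partner_gene)
  more_ddi <- rbind(fx$ddi, data.frame(domain_a = "pkinase_like",
                                       domain_b = "unrelated_dom"))
  more_ppi <- merge_ppi(fx$experimental_a, fx$experimental_b,
                        data.frame(gene_a = "GeneK", gene_b = "StructOnly"))
  grown <- dual_evidence_join(fx$disrupted, more_ddi, fx$gene2domain,
                              more_ppi)
  expect_true(all(key0 %in% paste(grown$as_gene, grown$partner_gene)))
  expect_gte(nrow(grown), nrow(base))
  ## every emitted pair independently passes both membership tests
  brute <- brute_dual_join(fx$disrupted, more_ddi, fx$gene2domain, more_ppi)
  expect_setequal(paste(unique(grown[c("as_gene", "partner_gene")])$as_gene,
                        unique(grown[c("as_gene", "partner_gene")])$partner_gene),
                  paste(brute$as_gene, brute$partner_gene))
})

test_that("the DOT export lists one edge per interaction", {
  fx <- ppi_demo_fixture()
  merged <- merge_ppi(fx$experimental_a, fx$experimental_b)
  res <- dual_evidence_join(fx$disrupted, fx$ddi, fx$gene2domain, merged)
  path <- withr::local_tempfile(fileext = ".dot")
  write_interaction_dot(res, path)
  lines <- readLines(path)
  expect_equal(sum(grepl(" -- ", lines)), nrow(res))
})
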