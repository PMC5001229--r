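## Canonical (unordered, case-insensitive) edge key.
.edge_key <- function(a, b) {
  la <- tolower(a); lb <- tolower(b)
  paste(pmin(la, lb), pmax(la, lb), sep = "\r")
}

#' Merge experimentally validated PPI edge lists
#'
#' Takes any number of edge lists (data.frames with `gene_a`, `gene_b`),
#' canonicalizes each edge as an unordered, case-insensitive gene pair,
#' deduplicates within each list, and unions across lists. `source_count`
#' records in how many input datasets each edge appears. Self-loops
#' (homodimers) are retained. Malformed rows (missing gene on either side)
#' are skipped and counted.
#'
#' @param ... edge-list data.frames.
#' @return data.frame with `gene_a`, `gene_b` (canonical order),
#'   `source_count`; attribute `n_skipped` counts malformed rows.
#' @export
merge_ppi <- function(...) {
  lists <- list(...)
  if (!length(lists)) stop("at least one edge list required")
  n_skipped <- 0L
  keys <- character(0); a_by_key <- character(0); b_by_key <- character(0)
  counts <- integer(0)
  for (el in lists) {
    bad <- is.na(el$gene_a) | is.na(el$gene_b) |
           el$gene_a == "" | el$gene_b == ""
    n_skipped <- n_skipped + sum(bad)
    el <- el[!bad, , drop = FALSE]
    k <- .edge_key(el$gene_a, el$gene_b)
    first <- !duplicated(k)
    k <- k[first]
    swap <- tolower(el$gene_a[first]) > tolower(el$gene_b[first])
    a <- ifelse(swap, el$gene_b[first], el$gene_a[first])
    b <- ifelse(swap, el$gene_a[first], el$gene_b[first])
    new <- !(k %in% keys)
    keys <- c(keys, k[new])
    a_by_key <- c(a_by_key, a[new])
    b_by_key <- c(b_by_key, b[new])
    counts <- c(counts, integer(sum(new)))
    counts[match(k, keys)] <- counts[match(k, keys)] + 1L
  }
  out <- data.frame(gene_a = a_by_key, gene_b = b_by_key,
                    source_count = counts, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Structural interaction partners of a disrupted domain
#'
#' Given the domain affected by splicing, looks up its binding-partner
#' domains in the domain-domain interaction (DDI) table (unordered pairs;
#' self-pairs allowed, so a self-interacting domain makes its own carriers
#' candidate partners) and returns every protein carrying any partner
#' domain according to the protein-to-domain map.
#'
#' @param as_domain domain accession of the spliced domain.
#' @param ddi data.frame with `domain_a`, `domain_b`.
#' @param gene2domain data.frame with `gene`, `domain`.
#' @return data.frame with `partner_gene`, `partner_domain`; empty when
#'   the domain is absent from the DDI table.
#' @export
structural_partners <- function(as_domain, ddi, gene2domain) {
  hit_a <- ddi$domain_a == as_domain
  hit_b <- ddi$domain_b == as_domain
  partner_domains <- unique(c(ddi$domain_b[hit_a], ddi$domain_a[hit_b]))
  sub <- gene2domain[gene2domain$domain %in% partner_domains, , drop = FALSE]
  unique(data.frame(partner_gene = sub$gene, partner_domain = sub$domain,
                    stringsAsFactors = FALSE))
}

#' Dual-evidence protein-protein interaction join
#'
#' The two-criteria join: an interaction between an AS gene (whose domain
#' is disrupted by splicing) and a partner is emitted only when (1) the
#' partner carries a domain that structurally interacts with the disrupted
#' domain (DDI evidence) and (2) the gene pair is present in the merged
#' experimentally validated PPI network. Partners absent from an optional
#' expressed-gene list are dropped.
#'
#' @param disrupted data.frame with `as_gene`, `as_domain` (one row per
#'   disrupted domain).
#' @param ddi data.frame with `domain_a`, `domain_b`.
#' @param gene2domain data.frame with `gene`, `domain`.
#' @param ppi_edges merged experimental network from [merge_ppi()].
#' @param expressed optional character vector; when supplied, partners not
#'   in it are filtered out.
#' @return data.frame: `as_gene`, `as_domain`, `partner_gene`,
#'   `partner_domain`, `has_experimental`, `has_structural` (both always
#'   TRUE for emitted rows).
#' @export
dual_evidence_join <- function(disrupted, ddi, gene2domain, ppi_edges,
                               expressed = NULL) {
  ppi_keys <- .edge_key(ppi_edges$gene_a, ppi_edges$gene_b)
  out <- list()
  for (i in seq_len(nrow(disrupted))) {
    g <- disrupted$as_gene[i]; d <- disrupted$as_domain[i]
    cand <- structural_partners(d, ddi, gene2domain)
    if (!nrow(cand)) next
    if (!is.null(expressed))
      cand <- cand[tolower(cand$partner_gene) %in% tolower(expressed), ,
                   drop = FALSE]
    if (!nrow(cand)) next
    keep <- .edge_key(rep(g, nrow(cand)), cand$partner_gene) %in% ppi_keys
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      as_gene = g, as_domain = d,
      partner_gene = cand$partner_gene[keep],
      partner_domain = cand$partner_domain[keep],
      has_experimental = TRUE, has_structural = TRUE,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) rbind_rows(out)
         else data.frame(as_gene = character(), as_domain = character(),
                         partner_gene = character(),
                         partner_domain = character(),
                         has_experimental = logical(),
                         has_structural = logical(), stringsAsFactors = FALSE)
  unique(res)
}

#' Export a dual-evidence interaction set as a DOT graph
#'
#' Writes the bipartite AS-gene/partner structure (genes as nodes, one
#' edge per emitted interaction, labelled by the mediating domain pair)
#' in Graphviz DOT text.
#'
#' @param interactions data.frame from [dual_evidence_join()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interaction_dot <- function(interactions, path) {
  lines <- c("graph dual_evidence_ppi {")
  as_genes <- unique(interactions$as_gene)
  for (g in as_genes)
    lines <- c(lines, sprintf("  \"%s\" [shape=box];", g))
  for (i in seq_len(nrow(interactions)))
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%s:%s\"];",
                              interactions$as_gene[i],
                              interactions$partner_gene[i],
                              interactions$as_domain[i],
                              interactions$partner_domain[i]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
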