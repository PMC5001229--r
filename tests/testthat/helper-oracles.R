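# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (adaptive quadrature, brute-force
# enumeration, naive loops) so agreement is informative.

## ---- quadrature oracles for the two-isoform model ----

.safe_exp <- function(x) {
  v <- exp(x)
  v[!is.finite(v)] <- 0
  v
}

oracle_log_marginal <- function(n, eff) {
  ll <- function(p) psikit:::loglik_psi(p, n$n_inc, n$n_exc, n$n_shared, eff)
  shift <- max(ll(seq(1e-4, 1 - 1e-4, length.out = 200)))
  log(stats::integrate(function(p) .safe_exp(ll(p) - shift), 0, 1,
                       rel.tol = 1e-12, subdivisions = 1000L)$value) + shift
}

oracle_post_mean <- function(n, eff) {
  lm <- oracle_log_marginal(n, eff)
  ll <- function(p) psikit:::loglik_psi(p, n$n_inc, n$n_exc, n$n_shared, eff)
  stats::integrate(function(p) p * .safe_exp(ll(p) - lm), 0, 1,
                   rel.tol = 1e-12, subdivisions = 1000L)$value
}

oracle_log_bf <- function(nc, nt, eff) {
  llc <- function(p) psikit:::loglik_psi(p, nc$n_inc, nc$n_exc, nc$n_shared, eff)
  llt <- function(p) psikit:::loglik_psi(p, nt$n_inc, nt$n_exc, nt$n_shared, eff)
  lm <- function(ll) {
    shift <- max(ll(seq(1e-4, 1 - 1e-4, length.out = 200)))
    log(stats::integrate(function(p) .safe_exp(ll(p) - shift), 0, 1,
                         rel.tol = 1e-12, subdivisions = 1000L)$value) + shift
  }
  lm(llc) + lm(llt) - lm(function(p) llc(p) + llt(p))
}

random_count_config <- function() {
  eff <- data.frame(eff_inc = sample(50:400, 1), eff_exc = sample(50:400, 1),
                    eff_shared = sample(1:400, 1))
  list(eff = eff,
       ctrl = list(n_inc = stats::rpois(1, 300), n_exc = stats::rpois(1, 300),
                   n_shared = stats::rpois(1, 150)),
       trt = list(n_inc = stats::rpois(1, 300), n_exc = stats::rpois(1, 300),
                  n_shared = stats::rpois(1, 150)))
}

## ---- brute-force effective sizes (naive footprint enumeration) ----

brute_effective_sizes <- function(ev, read_length, overhang = 1L) {
  fp <- function(exons) {
    g <- psikit::isoform_positions(exons, ev$strand)
    L <- length(g)
    if (L < read_length) return(character(0))
    vapply(seq_len(L - read_length + 1L), function(s)
      paste(g[s:(s + read_length - 1L)], collapse = ","), "")
  }
  block_ok <- function(key) {
    g <- as.integer(strsplit(key, ",")[[1]])
    runs <- rle(cumsum(c(0L, abs(diff(g)) != 1L)))$lengths
    length(runs) == 1L || min(runs) >= overhang
  }
  inc <- fp(ev$inc_exons); exc <- fp(ev$exc_exons)
  inc <- inc[vapply(inc, block_ok, TRUE)]
  exc <- exc[vapply(exc, block_ok, TRUE)]
  list(eff_inc = sum(!inc %in% exc),
       eff_exc = sum(!exc %in% inc),
       eff_shared = sum(exc %in% inc))
}

## ---- manual translation with a hardcoded genetic code ----

.CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

naive_translate <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  paste(.CODON_TABLE[substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))],
        collapse = "")
}

## Naive premature-stop / NMD classification by direct codon walking.
naive_stop_classify <- function(ev, genome) {
  inc <- as.character(psikit::isoform_seq(ev$inc_exons, ev$strand,
                                          genome[[ev$chrom]]))
  cs <- psikit:::spliced_index(psikit:::cds_first_base(ev), ev$inc_exons,
                               ev$strand)
  i <- cs; first <- NA_integer_
  while (i + 2L <= nchar(inc)) {
    if (.CODON_TABLE[substr(inc, i, i + 2L)] == "*") { first <- i; break }
    i <- i + 3L
  }
  ann_stop <- psikit:::spliced_index(
    if (ev$strand == "+") ev$cds[2] - 2L else ev$cds[1] + 2L,
    ev$inc_exons, ev$strand)
  prem <- !is.na(first) && first < ann_stop
  w <- ev$inc_exons[, 2] - ev$inc_exons[, 1] + 1L
  lj <- if (nrow(ev$inc_exons) > 1L) sum(w[-length(w)]) else NA_integer_
  nmd <- prem && !is.na(lj) && (lj - (first + 2L)) > 50L
  list(premature = prem, nmd = nmd)
}

## ---- brute-force dual-evidence join (triple loop) ----

brute_dual_join <- function(disrupted, ddi, gene2domain, merged_ppi,
                            expressed = NULL) {
  key <- function(a, b) paste(pmin(tolower(a), tolower(b)),
                              pmax(tolower(a), tolower(b)))
  ppi_keys <- key(merged_ppi$gene_a, merged_ppi$gene_b)
  out <- list()
  for (i in seq_len(nrow(disrupted))) {
    for (j in seq_len(nrow(ddi))) {
      d <- disrupted$as_domain[i]
      partner_dom <- if (ddi$domain_a[j] == d) ddi$domain_b[j]
                     else if (ddi$domain_b[j] == d) ddi$domain_a[j]
                     else next
      for (k in seq_len(nrow(gene2domain))) {
        if (gene2domain$domain[k] != partner_dom) next
        pg <- gene2domain$gene[k]
        if (!is.null(expressed) && !(tolower(pg) %in% tolower(expressed))) next
        if (!(key(disrupted$as_gene[i], pg) %in% ppi_keys)) next
        out[[length(out) + 1L]] <- c(disrupted$as_gene[i], pg)
      }
    }
  }
  if (!length(out)) return(data.frame(as_gene = character(),
                                      partner_gene = character()))
  m <- unique(do.call(rbind, out))
  data.frame(as_gene = m[, 1], partner_gene = m[, 2],
             stringsAsFactors = FALSE)
}

## ---- brute-force PWM score distribution ----

brute_pwm_tail <- function(scorer) {
  w <- scorer$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(words, 1L, function(wd) sum(scorer$r[cbind(wd, 1:w)]))
  probs <- apply(words, 1L, function(wd) prod(scorer$background[wd]))
  uniq <- sort(unique(scores))
  list(scores = uniq,
       tail = vapply(uniq, function(s) sum(probs[scores >= s]), 0))
}
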