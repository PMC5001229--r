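## Strand-aware interval slicing: first/last k nt of a genomic feature in
## transcript (5'->3') orientation.
.take5 <- function(ivl, k, strand) {
  if (strand == "+") c(ivl[1], ivl[1] + k - 1L) else c(ivl[2] - k + 1L, ivl[2])
}
.take3 <- function(ivl, k, strand) {
  if (strand == "+") c(ivl[2] - k + 1L, ivl[2]) else c(ivl[1], ivl[1] + k - 1L)
}

#' Seven regulatory regions of a cassette exon event
#'
#' Defines, in transcript orientation, the seven regions scanned for
#' RNA-binding-protein motifs around a cassette exon:
#' \itemize{
#'   \item R1 — 3'-most 150 nt of the upstream exon;
#'   \item R2 — first 300 nt of the upstream intron (donor-adjacent);
#'   \item R3 — last 300 nt of the upstream intron (acceptor-adjacent);
#'   \item R4 — the whole cassette exon;
#'   \item R5 — first 300 nt of the downstream intron;
#'   \item R6 — last 300 nt of the downstream intron;
#'   \item R7 — 5'-most 150 nt of the downstream exon.
#' }
#' Regions truncate to their source feature; introns shorter than 600 nt
#' are split at the midpoint so R2/R3 (and R5/R6) never overlap. Sequences
#' are sense-strand oriented; on the minus strand the construction is the
#' reverse-complement mirror of the plus-strand one.
#'
#' @param ev a cassette-exon [splicing_event()].
#' @param genome named `DNAStringSet`.
#' @param exon_flank,intron_flank region widths (defaults 150 and 300 nt).
#' @return data.frame: `event_id`, `region` (1-7), `start`, `end`
#'   (genomic), `length`, `seq`.
#' @export
extract_regions <- function(ev, genome, exon_flank = 150L, intron_flank = 300L) {
  if (ev$event_type != "cassette")
    stop("extract_regions requires a cassette event (", ev$event_id, " is ",
         ev$event_type, ")")
  stopifnot(nrow(ev$inc_exons) == 3L)
  up <- ev$inc_exons[1, ]; cas <- ev$inc_exons[2, ]; dn <- ev$inc_exons[3, ]
  gap <- function(x, y) {  # intron between consecutive transcript-order exons
    if (ev$strand == "+") c(x[2] + 1L, y[1] - 1L) else c(y[2] + 1L, x[1] - 1L)
  }
  int_up <- gap(up, cas); int_dn <- gap(cas, dn)
  len <- function(iv) iv[2] - iv[1] + 1L

  split_intron <- function(iv) {
    L <- len(iv)
    if (L >= 2L * intron_flank)
      list(first = .take5(iv, intron_flank, ev$strand),
           last = .take3(iv, intron_flank, ev$strand))
    else {
      k <- L %/% 2L
      list(first = .take5(iv, k, ev$strand), last = .take3(iv, L - k, ev$strand))
    }
  }
  su <- split_intron(int_up); sd <- split_intron(int_dn)
  regions <- list(
    .take3(up, min(exon_flank, len(up)), ev$strand),
    su$first, su$last,
    cas,
    sd$first, sd$last,
    .take5(dn, min(exon_flank, len(dn)), ev$strand))

  chromseq <- genome[[ev$chrom]]
  do.call(rbind, lapply(1:7, function(i) {
    iv <- regions[[i]]
    data.frame(event_id = ev$event_id, region = i,
               start = iv[1], end = iv[2], length = len(iv),
               seq = as.character(interval_seq(iv, ev$strand, chromseq)),
               stringsAsFactors = FALSE)
  }))
}

#' Regulatory regions for all cassette events
#'
#' @param events list of [splicing_event()]s or a `sim_transcriptome`.
#' @param genome named `DNAStringSet`.
#' @param ids optional subset of event ids (e.g. passing calls).
#' @inheritParams extract_regions
#' @return data.frame of stacked [extract_regions()] outputs.
#' @export
regulatory_regions <- function(events, genome = NULL, ids = NULL,
                               exon_flank = 150L, intron_flank = 300L) {
  if (inherits(events, "sim_transcriptome")) {
    if (is.null(genome)) genome <- events$genome
    events <- events$events
  }
  keep <- vapply(events, function(e) e$event_type == "cassette", TRUE)
  if (!is.null(ids))
    keep <- keep & vapply(events, `[[`, "", "event_id") %in% ids
  rows <- lapply(events[keep], extract_regions, genome = genome,
                 exon_flank = exon_flank, intron_flank = intron_flank)
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(event_id = character(), region = integer(),
                      start = integer(), end = integer(), length = integer(),
                      seq = character(), stringsAsFactors = FALSE)
  out
}

#' Position weight matrix
#'
#' @param mat 4-row numeric matrix (rows A, C, G, T) of per-position
#'   nucleotide probabilities; each column must sum to 1 (tolerance 1e-6).
#' @param motif_id motif identifier.
#' @param rbp RNA-binding-protein name (defaults to `motif_id`).
#' @return an object of class `pwm`.
#' @export
pwm <- function(mat, motif_id, rbp = motif_id) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop("PWM columns must each sum to 1")
  if (any(mat < 0)) stop("PWM entries must be >= 0")
  structure(list(mat = mat, motif_id = motif_id, rbp = rbp, width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s (%s), width %d, consensus %s>\n",
              x$motif_id, x$rbp, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#' @param x a [pwm()].
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

#' Exact log-odds score distribution of a PWM under an i.i.d. background
#'
#' Discretizes per-position log-odds scores (log2, `bin` bits per unit)
#' and convolves the per-position score distributions under the 0-order
#' background by dynamic programming, giving the exact null distribution
#' of the integer-binned match score. The scanner uses the same integer
#' scores, so per-hit p-values `P(score >= s)` are exact for the
#' discretized score.
#'
#' @param x a [pwm()].
#' @param background length-4 probability vector (A, C, G, T); uniform by
#'   default.
#' @param bin score bin width in bits (default 0.01).
#' @param pseudocount added to PWM entries (then renormalized) so all
#'   log-odds are finite (default 1e-3).
#' @return object of class `pwm_scorer`: integer score matrix `r`,
#'   distribution support `min_s`, probability vector `dist`, upper-tail
#'   vector `tail`, plus the inputs.
#' @export
pwm_scorer <- function(x, background = rep(0.25, 4), bin = 0.01,
                       pseudocount = 1e-3) {
  stopifnot(inherits(x, "pwm"), length(background) == 4L,
            abs(sum(background) - 1) < 1e-6, all(background > 0))
  p <- x$mat + pseudocount
  p <- sweep(p, 2L, colSums(p), "/")
  r <- round(log2(p / background) / bin)
  storage.mode(r) <- "integer"

  dist <- 1
  min_s <- 0L
  for (j in seq_len(ncol(r))) {
    rj <- r[, j]
    lo <- min(rj)
    width <- max(rj) - lo
    new <- numeric(length(dist) + width)
    for (b in 1:4) {
      sh <- rj[b] - lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    min_s <- min_s + lo
  }
  structure(list(r = r, min_s = min_s, dist = dist,
                 tail = rev(cumsum(rev(dist))),
                 bin = bin, background = background,
                 motif_id = x$motif_id, rbp = x$rbp, width = ncol(r)),
            class = "pwm_scorer")
}

#' Scan a sequence with a PWM, with exact p-values
#'
#' Scores every offset of the sense strand (RNA scanning: no
#' reverse-complement matches) with the integer-binned log-odds score and
#' assigns each the exact upper-tail p-value from the dynamic-programming
#' null distribution of [pwm_scorer()].
#'
#' @param seq character scalar over A/C/G/T (U is converted to T).
#' @param x a [pwm()] or a prebuilt [pwm_scorer()].
#' @param background background probabilities when `x` is a `pwm`.
#' @return data.frame: `offset` (1-based), `score` (bits), `p_value`.
#'   Empty when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(seq, x, background = rep(0.25, 4)) {
  sc <- if (inherits(x, "pwm_scorer")) x else pwm_scorer(x, background)
  s <- chartr("Uu", "Tt", toupper(seq))
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  n <- length(codes)
  w <- sc$width
  if (n < w)
    return(data.frame(offset = integer(), score = numeric(),
                      p_value = numeric()))
  n_off <- n - w + 1L
  total <- integer(n_off)
  for (j in seq_len(w))
    total <- total + sc$r[codes[j:(j + n_off - 1L)], j]
  idx <- total - sc$min_s + 1L
  pv <- numeric(n_off)
  inside <- idx >= 1L & idx <= length(sc$tail)
  pv[inside] <- sc$tail[idx[inside]]
  pv[idx < 1L] <- 1
  pv[idx > length(sc$tail)] <- 0   # unreachable for valid inputs
  data.frame(offset = seq_len(n_off), score = total * sc$bin, p_value = pv)
}

#' Background nucleotide composition of a region set
#'
#' 0-order composition estimated jointly from all scanned sequences, the
#' default background for motif scanning.
#'
#' @param seqs character vector of sequences.
#' @return length-4 probability vector (A, C, G, T).
#' @export
background_composition <- function(seqs) {
  s <- chartr("Uu", "Tt", toupper(paste(seqs, collapse = "")))
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) sum(strsplit(s, "")[[1]] == b), 0)
  counts / sum(counts)
}

#' Motif occurrence over regulatory regions, split by splicing direction
#'
#' Scans the seven regulatory regions of up-regulated (delta PSI > 0) and
#' down-regulated (delta PSI < 0) cassette events with a PWM set. Hits
#' are kept at `p_value < p_cut` and at BH `q < fdr_cut`, where q-values
#' are Benjamini-Hochberg adjusted over every scanned position within
#' each (direction, motif) stratum — the full multiple-testing burden,
#' as a FIMO-style q-value — so isolated chance matches are suppressed
#' while recurrent motifs survive. The output tallies retained
#' occurrences per region per direction and lists the motifs (and RBPs)
#' observed in each direction and exclusively in one.
#'
#' @param calls data.frame of differential calls (needs `event_id`,
#'   `delta_psi`, `passes`); only passing rows are used.
#' @param regions data.frame from [regulatory_regions()].
#' @param pwms list of [pwm()] objects.
#' @param p_cut raw p-value cutoff (default 1e-4).
#' @param fdr_cut BH FDR cutoff (default 0.1).
#' @param background optional length-4 composition; estimated from all
#'   region sequences when absent.
#' @return list of class `motif_enrichment`: `hits` (retained hits with
#'   `q_value`), `occurrence` (direction x region x motif counts),
#'   `motifs_up`, `motifs_down`, `exclusive_up`, `exclusive_down`,
#'   `rbps_up`, `rbps_down`, `background`.
#' @export
motif_enrichment <- function(calls, regions, pwms, p_cut = 1e-4,
                             fdr_cut = 0.1, background = NULL) {
  passing <- calls[calls$passes & calls$event_id %in% regions$event_id, ,
                   drop = FALSE]
  direction <- ifelse(passing$delta_psi > 0, "up", "down")
  names(direction) <- passing$event_id
  regions <- regions[regions$event_id %in% passing$event_id, , drop = FALSE]
  if (!nrow(regions)) {
    empty <- data.frame(motif_id = character(), rbp = character(),
                        event_id = character(), region = integer(),
                        direction = character(), offset = integer(),
                        score = numeric(), p_value = numeric(),
                        q_value = numeric(), stringsAsFactors = FALSE)
    return(structure(list(
      hits = empty,
      occurrence = data.frame(direction = character(), region = integer(),
                              motif_id = character(), n_hits = integer(),
                              n_events = integer(), stringsAsFactors = FALSE),
      motifs_up = character(0), motifs_down = character(0),
      exclusive_up = character(0), exclusive_down = character(0),
      rbps_up = character(0), rbps_down = character(0),
      background = if (is.null(background)) rep(0.25, 4) else background),
      class = "motif_enrichment"))
  }
  if (is.null(background)) background <- background_composition(regions$seq)

  hits <- list()
  all_p <- list()      # every scanned p-value per (direction, motif) stratum
  for (m in pwms) {
    sc <- pwm_scorer(m, background)
    for (i in seq_len(nrow(regions))) {
      h <- scan_pwm(regions$seq[i], sc)
      if (!nrow(h)) next
      dir_i <- direction[[regions$event_id[i]]]
      key <- paste(dir_i, m$motif_id, sep = "\r")
      base <- length(all_p[[key]])
      all_p[[key]] <- c(all_p[[key]], h$p_value)
      keep <- h$p_value < p_cut
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif_id = m$motif_id, rbp = m$rbp,
        event_id = regions$event_id[i], region = regions$region[i],
        direction = dir_i,
        offset = h$offset[keep], score = h$score[keep],
        p_value = h$p_value[keep],
        stratum_index = base + which(keep),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) rbind_rows(hits)
          else data.frame(motif_id = character(), rbp = character(),
                          event_id = character(), region = integer(),
                          direction = character(), offset = integer(),
                          score = numeric(), p_value = numeric(),
                          stratum_index = integer(), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$q_value <- NA_real_
    for (key in unique(paste(hits$direction, hits$motif_id, sep = "\r"))) {
      sel <- paste(hits$direction, hits$motif_id, sep = "\r") == key
      q_all <- stats::p.adjust(all_p[[key]], method = "BH")
      hits$q_value[sel] <- q_all[hits$stratum_index[sel]]
    }
    hits$stratum_index <- NULL
    hits <- hits[hits$q_value < fdr_cut, , drop = FALSE]
    rownames(hits) <- NULL
  } else hits$stratum_index <- NULL
  occurrence <- if (nrow(hits)) {
    agg <- stats::aggregate(list(n_hits = rep(1L, nrow(hits))),
                            by = hits[c("direction", "region", "motif_id")],
                            FUN = sum)
    ev <- stats::aggregate(list(n_events = hits$event_id),
                           by = hits[c("direction", "region", "motif_id")],
                           FUN = function(x) length(unique(x)))
    merge(agg, ev)
  } else data.frame(direction = character(), region = integer(),
                    motif_id = character(), n_hits = integer(),
                    n_events = integer(), stringsAsFactors = FALSE)
  motifs_up <- sort(unique(hits$motif_id[hits$direction == "up"]))
  motifs_down <- sort(unique(hits$motif_id[hits$direction == "down"]))
  structure(list(hits = hits, occurrence = occurrence,
                 motifs_up = motifs_up, motifs_down = motifs_down,
                 exclusive_up = setdiff(motifs_up, motifs_down),
                 exclusive_down = setdiff(motifs_down, motifs_up),
                 rbps_up = sort(unique(hits$rbp[hits$direction == "up"])),
                 rbps_down = sort(unique(hits$rbp[hits$direction == "down"])),
                 background = background),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("<motif_enrichment> %d retained hits; %d motifs up, %d down (%d/%d exclusive)\n",
              nrow(x$hits), length(x$motifs_up), length(x$motifs_down),
              length(x$exclusive_up), length(x$exclusive_down)))
  invisible(x)
}
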