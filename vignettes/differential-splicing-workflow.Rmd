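---
title: "Bayesian differential exon inclusion and downstream characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian differential exon inclusion and downstream characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psikit)
```

## The problem

Bulk RNA-seq of the same tissue under two conditions — here, the motivating
design is bone-marrow stromal cells before and after an inflammatory
(LPS) stimulus, sequenced in triplicate with 75-nt single-end reads —
changes not only how much of each gene is expressed but *which isoforms*
are made. `psikit` quantifies that second axis for four classes of local
alternative-splicing (AS) events: cassette exons, alternative 5′ and 3′
splice sites, and retained introns. Each event is reduced to a
two-isoform question: what fraction Ψ ("percent spliced in") of the
gene's transcripts carries the alternative segment, how does Ψ differ
between conditions, and what are the protein-level consequences of the
change?

The pipeline has six stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. **synthesis** — a model-consistent generator of transcript models,
   genome sequence, ground-truth Ψ and read-class counts;
2. **quantification** — Bayesian Ψ estimation per event and condition
   and a Bayes factor (BF) for differential splicing;
3. **classification** — localization (CDS/UTR), reading-frame
   preservation, premature termination codons (PTC), NMD candidacy,
   disorder category and PTM-site intersection;
4. **domains** — translation of each frame-preserving AS region with 30-nt
   exonic flanks and overlap with protein-domain intervals;
5. **ppi** — the dual-evidence protein-interaction join (experimental
   network ∩ structural domain–domain evidence);
6. **motifs** — PWM scanning of seven regulatory regions around each
   cassette exon with exact p-values and BH FDR control.

## The two-isoform read-class model

A read overlapping an event locus falls into one of three classes:
compatible only with the inclusion isoform, only with the exclusion
isoform, or with both. Class sizes depend on geometry: for read length
$R$, `effective_sizes()` enumerates every start position on each
isoform, maps it to its genomic footprint, and asks whether the same
footprint arises on the other isoform. The resulting *effective sizes*
$e_{inc}, e_{exc}, e_{sh}$ count the diagnostic and shared read
placements (a cassette-exon event, for instance, has $R-1$
exclusion-specific junction placements). A read spanning a junction with
fewer than `overhang` nucleotides on either side (default 1 nt;
configurable) is discarded from every class. Events with zero diagnostic
placements on either side are flagged untestable and skipped with a
logged reason.

Given inclusion fraction $\psi$, the class probabilities are

$$p_{inc} = \frac{\psi\, e_{inc}}{Z},\qquad
  p_{exc} = \frac{(1-\psi)\, e_{exc}}{Z},\qquad
  p_{sh} = \frac{e_{sh}}{Z},$$

with $Z = \psi(e_{inc}+e_{sh}) + (1-\psi)(e_{exc}+e_{sh})$. The
likelihood of pooled counts $(n_{inc}, n_{exc}, n_{sh})$ is the
corresponding multinomial kernel. With a uniform prior on $[0,1]$,
`psi_posterior()` evaluates the posterior on a fixed grid (1,001
equispaced points by default) and reports the posterior mean and a
central 95% credible interval. Grid inference rather than sampling was
a deliberate choice: it is deterministic, trivially testable against
adaptive quadrature, and entirely sufficient for a one-dimensional
posterior.

**Bayes factor.** The differential model $M_1$ gives each condition an
independent uniform Ψ; the null $M_0$ shares one uniform Ψ across both.
The BF is the marginal-likelihood ratio

$$\mathrm{BF} = \frac{m(D_c)\, m(D_t)}
  {\int_0^1 L_c(\psi) L_t(\psi)\, d\psi},$$

computed by grid integration in log space. BF = 5 means the data are
five times more likely under differential splicing. This
independent-vs-shared construction is this package's choice of a
standard Bayesian model comparison matching the stated interpretation of
the BF; it is documented here as a convention, not asserted as the only
possible one. An event is *called* when BF > 5 **and** |ΔΨ| > 0.05
(both strict), where ΔΨ is the difference of posterior means
(treated − control); posterior means rather than MAP estimates are used
because the mean is the quantity the credible interval is calibrated
around.

**Replicate handling.** Replicates are pooled per condition before
inference — the two-BAM design the pipeline emulates — with no
overdispersion term. A per-replicate mode is retained in the counts
schema for dispersion experiments, but calling always pools.

## Numerical choices

* Grid: 1,001 points on $[0,1]$; composite-Simpson quadrature weights
  for the marginal likelihood and posterior mean (error $O(h^4)$,
  comfortably below the $10^{-3}$ agreement we require against adaptive
  quadrature in the tests). Credible-interval quantiles interpolate a
  trapezoid CDF of the normalized density, which is locally smoother
  than cumulated Simpson masses.
* Boundary counts: $0\log 0$ terms are treated as 0, so zero counts in
  a class need no pseudocount; with no reads at all the posterior is
  exactly the prior and the result is flagged `low_information`.
* All-zero-count events report CI ≈ [0.025, 0.975] by construction.
* PWM scanning discretizes per-position log-odds (log2) scores into
  0.01-bit bins; the null score distribution is the exact convolution of
  the per-position distributions under the 0-order background, so p-values
  are exact for the binned score (verified against brute-force
  enumeration of all $4^w$ words in the tests). A pseudocount of
  $10^{-3}$ (renormalized) keeps log-odds finite.
* Background composition defaults to the 0-order composition of all
  scanned regions jointly; it is a parameter of `motif_enrichment()`.

## The synthetic-data generator

`make_transcriptome()` builds one gene per event: a padded chromosome
containing two host exons, the alternative segment, and introns. The
defaults encode the emulated study design and are not tuned per run:

* two conditions, three replicates, 75-nt reads;
* event-type mix (cassette 0.42, alt 5′ 0.14, alt 3′ 0.23, retained
  intron 0.21), matching the relative frequencies a genome-wide screen
  of this kind reports;
* introns flanking cassette exons 1,000 nt, so the 300-nt intronic
  motif regions fit without truncation; alternative segments 60–300 nt,
  a multiple of 3 with probability 0.5 so both branches of the frame
  classifier are exercised; host exons 120–300 nt so UTRs and split CDS
  pieces fit;
* segment placement in CDS / 5′ UTR / 3′ UTR with probabilities
  0.52 / 0.24 / 0.24, the coding-vs-UTR split such screens report;
* 60% of coding segments are scrubbed of in-frame stops (tolerated
  exons are strongly stop-depleted in real transcriptomes); the rest
  keep their random sequence and exercise the PTC branch;
* `depth_per_event` is the expected number of isoform-discriminating
  (inclusion- or exclusion-specific) reads per condition; shared reads
  are generated on top at the model's class odds. Defining depth in
  terms of discriminating reads makes statistical power comparable
  across event geometries, which differ widely in their shared-read
  fraction.

Counts are drawn multinomially from exactly the class probabilities the
inference likelihood uses, with Poisson read totals — so simulation and
model agree by construction, and parameter-recovery tests measure the
estimator, not a model mismatch. That is also the generator's main
limitation: it contains **no** mapping error, positional bias, library
or GC effects, overdispersion between replicates, or multi-isoform
genes. Passing the recovery and calibration tests therefore shows the
inference machinery is correct under its own assumptions; it does not
certify performance on real alignments, where read-class counts would
come from a BAM/GFF ingestion path and violate these assumptions to an
unknown degree.

Ground truth (`make_truth()`): a fraction `frac_affected` (default 0.3)
of events get a true ΔΨ drawn from `delta_psi_effects` (default
0.1/0.2/0.3, random sign), with the control Ψ drawn uniformly over the
subinterval that keeps both conditions inside [0.02, 0.98]; unaffected
events share one Ψ ~ U(0.05, 0.95). All generator randomness derives
from the single configuration seed, and reruns are byte-identical.

`make_annotation_fixtures()` produces the downstream annotation inputs
(domain intervals overlapping a configurable subset of AS regions,
per-residue disorder calls drawn from category proportions
0.523/0.323/0.154, PTM sites inside and outside AS regions, a random
PWM set) wired to the generated transcriptome, plus the hand-built
dual-evidence PPI scenario of `ppi_demo_fixture()`. These are synthetic
stand-ins shaped like the real resources (Pfam-style intervals,
iPfam-style DDI pairs, merged experimental networks); disorder and PTM
*predictors* are out of scope and only their outputs are consumed.

## Classification conventions

Several rules in the downstream stages are conventions this package had
to fix where the procedure it follows leaves them open:

* **Localization**: any overlap of the segment with the CDS classifies
  the event as CDS; protein-level consequences dominate a partial UTR
  overlap, and the rule keeps the CDS/UTR split binary.
* **Premature stop**: the isoform carrying the alternative segment (the
  inclusion isoform) is translated from the annotated start; a stop
  strictly upstream of the annotated stop is a PTC. The exclusion
  isoform is scanned too and reported in a separate column.
* **NMD**: a PTC ending more than 50 nt upstream of the final exon–exon
  junction flags the transcript, the standard 50-nt rule; a transcript
  whose inclusion isoform has no junction (a retained intron) can
  therefore never be flagged, which is the rule's verbatim consequence.
* **Disorder categories**: totally disordered ⇔ fraction 1, structured
  ⇔ fraction 0, partial otherwise — strict boundaries, since no
  quantitative definition of "partially disordered" is established.
* **Flanked peptides**: the AS segment plus ≤30 nt of each neighboring
  exon, truncated at exon and CDS boundaries, snapped to the annotated
  reading frame; the AS-only protein interval is carried along so domain
  overlap can distinguish `AS_only`, `flank_only` and `both`.
* **Region layout** (cassette events): R1/R7 are the 150-nt exon ends
  adjacent to the introns; R2/R5 are the donor-adjacent and R3/R6 the
  acceptor-adjacent 300 nt of the two introns; R4 is the whole exon.
  Introns shorter than 600 nt split at the midpoint (5′ half gets the
  floor), so R2/R3 and R5/R6 never overlap. On the minus strand the
  construction is the exact reverse-complement mirror.
* **Motif FDR**: hits are filtered at raw p < 1e-4, then BH-adjusted
  within each (direction × motif) stratum over *all* scanned positions
  (the full multiple-testing burden, FIMO-style) and kept at q < 0.1.
  Adjusting over all positions rather than only the filtered hits is
  what lets recurrent planted motifs survive while isolated chance
  matches are removed; the stratification itself is this package's
  choice.
* **PPI join**: gene-symbol keyed, case-insensitive, no ortholog
  mapping; an "expressed" partner is one present in a supplied
  expressed-gene list (no abundance cutoff is imposed here).

## Coordinates

All internal coordinates are 1-based inclusive — the native convention
of IRanges/GenomicRanges/Biostrings, which every sequence operation in
the package goes through — and GFF3 output uses the same convention.
Exon chains are stored in transcript order (descending genomic position
on the minus strand), and the single bridge between genomic and spliced
coordinates is `isoform_positions()`, which both the effective-size
enumeration and the coding classifier use; strand-mirror invariance of
every classification is asserted in the test suite.

## Validation problem sizes

The test-suite and acceptance-script checks run at sizes chosen to give
stable statistics while staying quick on a laptop: 100 random count
configurations against adaptive quadrature; 500 events at 1,000
discriminating reads for parameter recovery (mean |Ψ̂ − Ψ| and 95% CI
coverage); 1,000 null events for BF calibration; 200 events at
|ΔΨ| = 0.3 for power and sign accuracy; brute-force PWM enumeration up
to width 6; and a 40-event plant-and-recover run for the motif stage.

## Known limitations

* Two isoforms per event; genes with more isoforms must be decomposed
  into pairwise events upstream.
* Pooling discards between-replicate variability; a BF computed from
  pooled counts is anticonservative if replicates are overdispersed.
* Single-end reads only; no insert-size model for paired ends.
* The motif stage scans the sense strand only (RNA motifs) with a
  0-order background; higher-order backgrounds and motif discovery are
  out of scope.
* External database counts (interaction totals, domain inventories)
  depend on resource versions and are not reproduction targets; the
  dual-evidence join is validated on wired fixtures with known answers.
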