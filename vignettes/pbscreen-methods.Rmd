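---
title: "Methods: insertional-mutagenesis screen analysis with pbscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insertional-mutagenesis screen analysis with pbscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pbscreen)
```

# The screen and its quantification model

A piggyBac (PB) transposon mobilized in a cancer cell pool integrates at
TTAA tetranucleotides, duplicating the TTAA at both ends of the insertion.
After in vivo selection — primary tumours on one arm, lung metastases and
metastasis-derived lines on the other — the insertion repertoire of each
sample is read out by splinkerette PCR: genomic DNA is sonicated to roughly
250-bp fragments, adaptor-ligated, and amplified from the transposon end, so
that read 1 of every informative pair starts with the transposon-derived
sequence `TAGGGTTAA` followed by the genomic flank, and read 2 enters from
the sonication shear point.

Two consequences shape the whole analysis:

* **The insertion coordinate is a junction.** The first transposon-adjacent
  genomic base in read-1 orientation identifies the insertion, and the four
  bases immediately upstream on the read-1 strand must be the duplicated
  `TTAA`. Sites failing this motif check are artefacts (mispriming,
  mismapping) and are removed.
* **PCR duplicates are uninformative; shear points are not.** All reads
  from one ligated fragment share their shear point, so the number of
  *distinct shear ends* at an insertion — its **diversity** — counts
  independent genomic fragments and is robust to amplification depth. It is
  the screen's clonality proxy.

## Coordinate conventions

All coordinates are 0-based, half-open internally; 1-based coordinates
appear only in GTF/SAM/BED interchange. The junction coordinate `coord` is
defined so that the TTAA occupies `genome[coord-4, coord)` for a `+`
insertion and `genome[coord, coord+4)` (reverse-complemented) for a `-`
insertion; equivalently, `coord` is the boundary between the duplicated
TTAA and the sequenced flank in read-1 orientation. On the minus strand
this places `coord` one past the most-5' aligned base of read 1. The
convention is applied identically in the simulator, the aligner and the
site caller, which is what makes the motif filter exactly satisfiable on
simulated truth. Sites on opposite strands at the same coordinate are
distinct (the strand is part of the site key), and TTAA being palindromic
means one tetranucleotide can host both.

## Alignment contract

The original analysis required uniquely mapping read pairs within 1,000 bp.
The built-in aligner reproduces that contract semantically rather than
parameter-for-parameter: a pair is reported iff read 1 matches exactly one
locus at its best mismatch stratum (exact 20-nt 5' seed, at most one
substitution over the read, no gaps) and the mate has exactly one
consistent placement on the opposite strand within `max_insert = 1000` bp.
Reads whose seed carries a sequencing error go unmapped rather than
mismapped; with per-base error around 0.001 this costs about 2% of pairs
per read, which site-level recovery absorbs because nearly every site is
supported by several pairs. External alignments can be substituted via SAM
(`read_alignments()`), with the same junction conventions applied on
conversion.

## Site calling and diversity

Aligned pairs are grouped by `(chrom, strand, r1_start)`. Each group is one
integration site with `diversity` = number of distinct shear-end
coordinates and `raw_reads` = group size. Shear-end identity is exact — no
±1 bp fuzzy merging — because duplicate fragments are byte-identical
copies, whereas independent fragments differ by at least one base of
sonication randomness. Duplication therefore changes `raw_reads` but can
never change `diversity`, an exact invariant the tests exercise at
duplication factors up to 100.

## Gene association hierarchy

Sites are matched against transcript models on any strand and orientation.
A site overlapping no transcript is a **promoter** site if it falls in any
2,000-bp strand-aware window upstream of a transcript start, otherwise
**intergenic**. All other sites take the first matching region type in the
fixed order **5'UTR → CDS → 3'UTR → intron → ncRNA**, where ncRNA means
overlap with a transcript lacking an annotated CDS. Because "first overlap"
is otherwise underdetermined, ties between transcripts are resolved by a
deterministic scan order (chrom, transcript start, transcript id), making
classification invariant to input row order. Promoter windows are taken
per transcript, not per gene. Sites then group by their gene (promoter
sites included) or, if intergenic, by the ordered pair of flanking genes
with a `.` sentinel at chromosome ends — a partition of the site set.

## Enrichment statistic

For gene group $g$ and sample $s$, $D_{gs}$ is the summed diversity of the
sample's sites in $g$, $T_s = \sum_g D_{gs}$, and the screen's unit is the
percentage $P_{gs} = 100\, D_{gs} / T_s$, so each sample's column sums
to 100 and the measure is invariant to per-sample sequencing depth. The
phrase "total number of unique insertions for a given sample" is read as
total summed diversity, consistent with diversity being the count of unique
insertions per site; the alternative reading (count of distinct sites) is
available via `percentage_matrix(..., denominator = "sites")` rather than
silently chosen. Genes absent from a sample contribute $D = 0$.

Genes are ranked by $\Delta_g$ = mean metastatic minus mean tumour
percentage, with a two-tailed Mann–Whitney U test per gene. The U statistic
uses midranks; p-values are exact (full enumeration of all
$\binom{n_x+n_y}{n_x}$ labelings) when both groups have at most 10 samples
and there are no ties, otherwise a normal approximation with tie and
continuity corrections. Two-sided p is twice the smaller tail, capped at 1.
No multiple-testing correction is applied to the screen ranking — the
candidates are a handful of top genes — but a Benjamini–Hochberg column is
emitted for genome-wide use.

## Peak-to-gene association (basal + extension)

ChIP target sets are attached to genes by the basal-plus-extension rule:
each gene's TSS gets a strand-aware basal domain (5,000 bp upstream,
1,000 bp downstream), extended on each side up to the nearest neighbouring
basal domain and at most 10,000 bp beyond the basal edge; a peak associates
with every gene whose domain contains the peak midpoint. Three points the
rule leaves open are fixed and documented here: the cap is interpreted as
maximum extension *beyond the basal edge* (so an isolated gene reaches
15,000 bp upstream); peaks are anchored at their midpoint; and when two
basal domains leave a gap, both extensions may fill it, so a gap peak can
associate with both neighbours. Curated regulatory domains, a database
feature of the original association tool, are not reproducible from
annotations alone and are not supported. Gene-level TSS is the 5'-most
transcript start.

## Growth kinetics, qPCR, ChIP, IHC

* **Tumour volume** is $0.5 \times \ell \times s^2$ from the two calliper
  diameters (mm³); reversed inputs are swapped with a warning.
* **Time to threshold**: ordinary least squares of $\log V$ on $t$ over
  strictly positive volumes; $t^\* = (\log V^\* - a)/b$ at
  $V^\* = 250$ mm³. Natural log is used internally — the base cancels in
  $t^\*$ — and the threshold time is flagged when extrapolated beyond the
  observed days and reported as not-reached for non-positive slopes. Under
  the multiplicative log-normal noise this model assumes, the fit typically
  yields $R^2$ well above 0.7.
* **Relative expression**: $2^{-\Delta\Delta C_t}$ with technical-replicate
  Ct values averaged arithmetically and normalization to a housekeeping
  gene, then to the control condition.
* **ChIP percent input**: the named method's standard dilution-adjusted
  form, $100 \times 2^{(C_t^{input} - \log_2(1/f)) - C_t^{IP}}$ for input
  fraction $f$.
* **DAB quantification**: per ROI, rolling-ball background subtraction
  (50-px radius, implemented as grey-scale opening with a disc on the
  inverted light-background image), colour deconvolution with the standard
  H-DAB vectors (H = (0.650, 0.704, 0.286), DAB = (0.269, 0.568, 0.776),
  third channel the positive complement), extraction of channel 2 (DAB) on
  an 8-bit scale where darker = more stain, Gaussian blur with sigma 5,
  then a fixed threshold: 222 for CD31 areas, 170 for NFIB/ERO1A/VEGFA.
  Positive pixels are those at or below the threshold; the polarity is a
  flag because only the threshold values are fixed by the recipe, and the
  threshold is applied to the blurred channel. Metastatic burden is the
  union area of metastasis ROIs over the lung area, ×100.

# The synthetic-data generator

The generator emulates the screen's data-generating process at desk scale
so every stage is testable against planted truth.

* **Genome and genes**: i.i.d. random chromosomes (default 2 × 1 Mb) with
  50 non-overlapping genes, 2–5 exons each, 20% without CDS. Random
  sequence has a TTAA roughly every 256 bp, ample target density.
* **Insertions**: per sample, 100 background insertions uniform over
  interior TTAA sites; per-site diversity $1 + \text{Poisson}(2)$ — most
  insertions are low-clonality, a convention, since no per-site clonal
  abundance distribution is published. Genes with a planted fold $f$
  receive extra insertions in the named group with expectation
  $(f-1) \cdot p_G \cdot 100$, where $p_G$ is the gene span's share of TTAA
  sites (promoter through gene end), elevating expected in-gene diversity
  $f$-fold.
* **Libraries**: fragment lengths truncated-Normal(250, 60) — the sd is a
  realism choice, only the mean is documented by the protocol; distinct
  shear ends per site equal the site's diversity; each unique fragment is
  sequenced $1 + \text{Poisson}(5)$ times; substitution errors at $10^{-3}$
  per base; 1% of pairs replaced by non-transposon contaminants; constant
  `I` quality strings (the pipeline never uses qualities); 8-nt sample
  barcodes in read headers, with an inline-read-2 mode behind a flag.
* **Determinism**: every stage derives its RNG stream from the config seed;
  identical configs give byte-identical FASTA/GTF/FASTQ.

What the generator does **not** emulate — and what green tests therefore do
not certify about real libraries: adaptor-ligation chemistry and its
sequence biases, indels, chimeric PCR artefacts, non-mobilized donor
transposon reads (modelled only as a contaminant fraction), local hopping,
repeat-driven multi-mapping (random genomes are nearly repeat-free), and
real mouse gene structure. The enrichment power and type-I results below
are statements about the statistic under this generative model, not about
any particular biological dataset.

# Problem sizes and replication designs

Chosen once as the package's study conditions:

* End-to-end recovery: 2 groups × 4 samples on a 2-Mb genome,
  ~100 insertions/sample, duplication mean 5, error $10^{-3}$,
  contamination $10^{-2}$; requires ≥95% exact coordinate+strand recovery
  after TTAA filtering and no spurious diversity-≥2 site per $10^4$
  fragments. Runs in under two minutes on one core.
* Enrichment replication: 16 tumour vs 18 metastatic samples — the
  screen-scale cohort — with one gene at fold 5; 100 replicate cohorts
  share one genome (same study, replicate cohorts) and the planted gene
  must top the gene ranking in ≥95. The ranking retains intergenic
  flanking-pair groups, but candidates are genes; on a 2-Mb toy ~85% of
  the genome is intergenic, a desk-scale artefact a genome-wide screen
  does not share.
* Null calibration: the same design with no planted gene; across 2,000
  per-gene tests the fraction with p < 0.05 must sit within three
  Monte-Carlo standard errors of 0.05. The tie/continuity-corrected
  approximation is expected to sit slightly below 0.05 on sparse counts.
* Growth recovery: 100 series, $V_0 = 10$, rate 0.3/day, 8 points over 21
  days, log-normal sigma 0.2; median time-to-250 mm³ within 5% of
  $\ln(25)/0.3 \approx 10.73$ days and median $R^2 \ge 0.7$.
* IHC fixture: stained stripes (narrower than the rolling ball, so
  background subtraction preserves them; straight edges, so blur causes no
  curvature bias) covering exactly 20% of a 300×300 ROI, stain density set
  so the blurred edge profile crosses the panel threshold at the geometric
  boundary; measured positive fraction within ±0.02 of 0.20 and monotone
  over the full 0–255 threshold sweep.

# Numerical and degenerate-input choices

* Exact Mann–Whitney enumeration is capped at 10 per group
  (`exact_max_n`); `exact = TRUE` forces enumeration (refused on ties).
  All-identical pooled values give $U = n_x n_y / 2$, $p = 1$.
* Growth fits need at least two positive volumes at distinct times;
  all-zero series are an error, shrinking tumours report not-reached.
* Sites closer than 4 bp to a chromosome edge get `upstream4 = "NNNN"` and
  fail the motif filter; insertions are only planted ≥1,100 bp from edges
  so simulated fragments always fit.
* Samples with zero total insertions are dropped from the percentage
  matrix with a warning; ranking requires at least one sample per group.
* The rolling-ball radius and blur kernel are clipped with a warning on
  images smaller than the structuring element.

# Known limitations

The built-in aligner is for small simulated references; real libraries
should be aligned externally and ingested as SAM. Whether the original
site keying used strand or coordinate only is not documented; strand-keyed
is implemented and flagged. The percentage denominator ambiguity (summed
diversity vs distinct sites) is surfaced as an option rather than decided.
Common-insertion-site statistics, gene-length/TTAA-density background
corrections, nucleus segmentation and per-cell IHC scoring are out of
scope.
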