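# pbscreen

Analysis of in vivo **piggyBac transposon insertional-mutagenesis screens**
for metastasis genes, from splinkerette paired-end reads to a ranked list of
candidate genes, plus the quantitative procedures that surround such a
screen (tumour growth kinetics, qPCR/ChIP quantification, peak-to-gene
association, DAB immunohistochemistry area measurement). A synthetic-data
module generates genomes, transcript models, planted-insertion truth tables
and FASTQ libraries, so the whole pipeline is testable end to end without
any external data.

## Who this is for

Groups running (or re-analysing) transposon screens in which a mutagenized
cancer cell pool is selected in vivo — e.g. primary tumours versus lung
metastases — and insertion repertoires are read out by splinkerette PCR
from sonicated DNA. The pipeline identifies where the transposon landed,
how clonal each insertion is, which gene each insertion hits, and which
genes are preferentially hit in the metastatic compartment.

## The method in brief

piggyBac integrates at TTAA tetranucleotides, duplicating the TTAA. Read 1
of each informative pair begins with the transposon-derived prefix
`TAGGGTTAA`; after trimming it, uniquely mapping pairs (≤ 1,000 bp insert)
define an insertion at the junction coordinate of read 1, which must carry
the duplicated `TTAA` immediately upstream on the read-1 strand.

Each insertion site is quantified by its **diversity** — the number of
distinct sonication shear ends among its supporting pairs — which counts
independent genomic fragments and is exactly invariant to PCR duplication.
Sites are assigned to genes through a fixed hierarchy (promoter within
2 kb of a TSS, then 5'UTR → CDS → 3'UTR → intron → ncRNA, else intergenic
keyed by flanking gene pair). For gene *g* and sample *s* the screen's unit
is

> P[g,s] = 100 · (summed diversity of g in s) / (total summed diversity of s)

— the *percentage of unique insertions*, normalized per sample. Genes are
ranked by the difference in mean percentage between metastatic and tumour
samples, with a two-tailed Mann–Whitney U test per gene (exact by
enumeration for small groups, tie/continuity-corrected normal otherwise).

Accompanying procedures: GREAT-style basal+extension peak-to-gene
association (5 kb up / 1 kb down, 10 kb max extension); calliper tumour
volume `0.5 × large × small²` with log-linear fits of log V on t giving the
time to 250 mm³; `2^-ΔΔCt` relative expression; ChIP-qPCR percent input;
and H-DAB colour-deconvolution quantification of DAB-positive area at
fixed thresholds (222 for CD31, 170 for NFIB/ERO1A/VEGFA).

## Worked example

The `analysis/` scripts run the whole study on synthetic data. Script 01
simulates a 2-Mb genome, 50 genes, 4 tumour + 4 metastatic samples with
~100 insertions each (PCR duplication mean 5, 0.1% base error, 1%
contaminant pairs) and one gene, `g025`, carrying 5-fold elevated insertion
load in the metastatic group:

```sh
Rscript analysis/01_simulate_screen.R      # libraries -> scratch/screen/
Rscript analysis/02_call_insertion_sites.R # sites -> results/sites/*.bed
Rscript analysis/03_rank_metastatic_genes.R
```

which prints (script 02, then 03):

```
tumour_1: 1845 pairs -> 1769 aligned -> 100 TTAA sites (diversity 312)
...
mean prefix-discard fraction: 0.019 (contaminants + read-1 errors)

recovery: 811/811 planted sites (100.0%), 0 spurious (diversity>=2: 0)

top 5 candidate metastasis genes (by delta of % unique insertions):
   gene_id mean_pct_met mean_pct_tum delta  U      p
1     g025        2.944            0 2.944 16 0.0211
5     g015        1.200            0 1.200 14 0.0689
16    g010        0.636            0 0.636 12 0.1859
```

Every planted site is recovered at its exact coordinate and strand after
TTAA filtering, with no spurious multi-fragment site, and the planted gene
tops the ranking: 2.94% of the metastatic samples' unique insertions fall
in `g025` versus 0% in tumours (Mann–Whitney p = 0.021 at n = 4 + 4).
Scripts 04–07 demonstrate peak-to-gene association and top-list
intersection (recovering the single common target gene), growth kinetics
(control reaches 250 mm³ at 10.7 d vs 14.6 d under knockdown, median fit
R² = 0.99), 2^-ΔΔCt fold changes, percent-input ChIP, and IHC panels where
a planted 20% DAB-positive area measures 0.198.

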