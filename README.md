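# teloci

Locus-level analysis of transposable-element (TE) transcription from
short- and long-read RNA-seq.

Family-level TE quantification discards the question that matters for
mobilisation biology: *which individual copies are transcribed?* Only a
transcript spanning an intact element — the INT (gag/pol) domain of an
LTR retrotransposon, the transposase ORF of a DNA transposon, the whole
body of a LINE — can seed autonomous transposition. `teloci` is for
researchers in plant (and general) transposon biology who have an
annotated genome, a TE annotation with canonical element lengths, and
alignments, and want locus-resolved answers: which loci are expression
candidates, which are trackable and full-length, where they sit
relative to genes, how old the intact LTR copies are, whether TE and
host-gene expression move together, and whether any locus shows
full-length transcript evidence.

## What it computes

**Expression candidates** are annotated TE loci passing at least one of
three read-evidence filters (all thresholds strict, defaults in
`analysis_config()`):

| filter | evidence | pass condition |
|---|---|---|
| unique counts | unique-mapping reads, ambiguous overlaps dropped | count > 10 |
| coverage | all reported alignments (multi-mappers count at every placement) | count > 10 and mean depth > 5 |
| danglers | unique reads whose mates hit the canonical TE library, anchored ≤1 kb outside a locus boundary, oriented inward | danglers > 10 on a side and internal reads > 10 |

Candidates are **trackable** when they have unique-read support and
**full-length** when their span exceeds 90% of the family's canonical
length. Loci are then placed in a compartment hierarchy (genic vs
intergenic; exon > intron > N-flank > C-flank with 2 kb flanks) and
location bias is tested with a goodness-of-fit chi-square against the
annotation background.

**LTR insertion dating** uses the divergence of a locus's two LTRs:
with transition/transversion proportions *P*, *Q* from a global
pairwise alignment,

    K = -1/2 · ln[(1 − 2P − Q) · sqrt(1 − 2Q)]      (Kimura 2-parameter)
    T = K / (2r)                                     (r = 1.3e-8 /site/yr)

with per-family amplification peaks from a Gaussian-KDE mode.

**Differential expression** of trackable candidates and genes on a
time course (median-of-ratios normalisation, per-timepoint Welch test
with BH adjustment, or an externally supplied table), calls at
adjusted p < 0.05 and |log2FC| > 1 at ≥1 timepoint, joint Ward
clustering of fold-change patterns, and the concordant fraction of
co-localised DETE–DEG pairs.

**Long-read classification** per locus: de novo vs read-through
transcription start (strand-aware 5' positions), origin of
read-through starts (exonic/intronic/no_gene), breadth of coverage
over the superfamily-specific feature, alignment-end typing
(internal/external/clipped), and full-length transcript evidence
(read length ≥ feature length, ≥90% of the read aligned).

**Splicing/productivity**: Alt5/Alt3/IR/ES features of isoforms vs
their reference, TE overlaps, PRO/PTC/NGO/NST productivity (first ATG,
50-nt NMD rule), and localisation of premature stops relative to
TE-overlapping retained introns in transcript coordinates.

A first-class **synthetic-data module** generates genome, annotations,
alignments (authored directly, with planted multiplicities, danglers,
clips and splice gaps) and count matrices with a ground-truth manifest
that predicts every downstream result exactly.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic
cohort (two 200 kb chromosomes, 20 genes, 107 TE loci from five
families, 11 structurally intact). Run the scripts in order from the
repository root; each prints what it found and writes tables under
`results/` (the bulky simulated data goes to `scratch/synthetic_data/`).

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_call_candidates.R
...
Rscript analysis/07_splicing_productivity.R
```

Output of `02_call_candidates.R`:

```
43 of 107 annotated loci are expression candidates
  filters (unique / coverage / dangler): 33 / 13 / 3
  trackable: 33 (76.7%); full-length: 5 (11.6%)
  excluded: 0 below threshold, 64 without any evidence
  5 families contain candidates; largest: VLINE1 (12)
```

Exactly the 43 loci planted with sufficient evidence are recovered:
the 30 unique-read loci and the 3 dangler-supported loci (whose
planted internal reads have a single placement each, hence count as
unique) pass the unique filter, the 10 multi-mapping-only loci enter
through the coverage filter and are correctly un-trackable, and the 64
loci with no planted reads show no evidence at all. Downstream, `04_date_ltr_insertions.R` reports

```
  Copia-3: planted d = 0.020, mean K = 0.0203, mean T = 0.78 MYA
  Gypsy-12: planted d = 0.050, mean K = 0.0537, mean T = 2.06 MYA
mean divergence recovery error: 3.9%
```

— the K2P estimate sits slightly above the planted proportion, as it
should (multiple hits correction) — and `05_differential_expression.R`
recovers the planted 93% TE–gene pattern sharing as

```
13 DETE-DEG pairs, 12 concordant (92.31%)
```

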