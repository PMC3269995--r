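---
title: "radsnp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radsnp: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsnp)
```

## The problem

Restriction-site associated DNA (RAD) sequencing reduces a genome to the
short regions flanking the cut sites of one restriction enzyme. In a
three-parent design — here modelled on a globe artichoke x cultivated
cardoon x wild cardoon trio digested with PstI (CTGCAG) and sequenced as
2x54 nt paired ends — the shared loci across parents yield SNP markers that
can be validated as CAPS assays and placed on F1 linkage maps. `radsnp`
implements that entire analysis as tested, reusable code: a ground-truthed
simulator, a per-locus assembler, a multi-sample caller with
testcross/intercross classification, CpG-stratified k-mer spectra, CAPS
assay design, and segregation/linkage statistics.

## The simulator: what world it states

`sim_params()` fixes the stated world; the defaults are the experiment's
own conditions, not tuning knobs:

* **Reads** 2x54 nt; the single end (SE) starts exactly at a cut site, the
  mate is read inward from a shear point 300–800 nt away (truncated normal,
  mean 500 nt — the gel size-selection window), with per-sample yields in
  ratio 1.2 : 2.6 : 5.9.
* **Variation** pairwise divergence 5.6 variants / 1,000 nt between
  accessions; within-accession heterozygosity differs per accession
  (defaults 0.001 / 0.002 / 0.004 per nt, ordered like the published
  per-parent heterozygous-SNP counts; no per-accession rates are published,
  so these are fixed once as field-plausible values for a highly
  heterozygous outcrosser). 4.5% of variants are 1–2 nt indels (the
  published indel share of all variants).
* **Locus dropout** the fraction of cut sites destroyed homozygously per
  accession (`site_loss_fraction`, default 0.05) has no published estimate;
  it exists because taxon-specific RAD tags are a real phenomenon the
  classifier must tolerate. It is a free parameter, chosen once.
* **Background** i.i.d. sequence at GC 37.4% (the published assembly
  composition); spurious CTGCAG occurrences are resampled away so the locus
  inventory is exactly known. Mutations that would create a novel
  recognition site are redrawn for the same reason.
* **Qualities** constant Q40; `lowq_fraction` plants six Phred-10 bases in
  a chosen fraction of reads purely to exercise the quality filter. No
  empirical Illumina error model, no PCR duplicates, no adapters — the
  pipeline under test starts after demultiplexing.

What a green test on this world does **not** establish: robustness to real
base-quality structure, PCR bias, repeat families beyond the ones we plant,
or reference-free assembly of genomes whose cut-site spacing approaches the
insert length.

### Insert geometry and anchored contigs

With inserts of at least twice the read length (the stated invariant of the
shear window), the mate coverage island starts exactly one read length from
the cut and **no read spans the junction** between the SE block and the
island. A pure de Bruijn walk therefore cannot extend past the anchor. The
assembler recognises this geometry and assembles the island separately —
reverse-walking from its densest k-mer to the left tip, then forward — and
appends it to the anchor, which is correct whenever some mate was drawn
near the minimal insert (the island then abuts the anchor exactly). When no
such mate exists the contig silently omits a few bases after position 54;
the truth-evaluation code aligns the island block independently, so
coordinates stay honest. Under the full gel window (300–800 nt) the island
is disjoint from the SE block and anchored contigs are impossible by
construction; pipeline demonstrations therefore use a contiguous window
such as `insert_range = c(108, 400), insert_dist = "uniform"`, while the
generator default remains the published protocol window.

## Assembly rules

Reads with more than five bases at Phred <= 10 are discarded (pairs fail
together). SE reads sharing 100% identity form clusters; clusters outside
25–400x coverage are dropped (noise floor, repeat ceiling). The published
pipeline's proprietary assembler is replaced by a per-locus de Bruijn sweep
over k in {21, 25, 29, 33}; per k the best walk is kept by (length, mean
k-mer coverage) and distinct surviving sequences become NODE1, NODE2, ...
A clean two-way branch (both arms at >= 25% of the column) is treated as a
haplotype fork once per walk; **beyond the fork budget the walk follows the
majority arm rather than breaking**. Breaking at every clean branch — the
more conservative reading — truncates a third of heterozygous loci and
loses their distal markers; following the majority is what bubble-popping
assemblers do, and the minor haplotype's reads still align to the mosaic
contig within the three-mismatch limit, so its variants are recovered in
the pileup rather than in the graph. Truly ambiguous columns (three or more
supported continuations) still break the contig.

Two extra policies handle heterozygous cut flanks: exact-identity clusters
whose representatives differ by <= 3 nt are merged into one locus before
assembly (otherwise each SE haplotype founds a separate "reference" and
every SE-region heterozygote is invisible), and variant calling aligns
against NODE1 contigs only, so alternative haplotype contigs cannot siphon
off one haplotype's reads. Contig filters: length >= 100 nt, paired-end
coverage >= 4.0x, no NN run (a single N is never produced, so "N
homopolymer" is implemented as two or more consecutive N). The 25–400x
bounds are applied to reads pooled over samples by default
(`coverage_scope = "per_sample"` switches), and the assembly template
defaults to the sample with the most retained reads, as the published
pipeline chose its deepest sample.

## Calling rules

Alignment accepts a read iff it fits with <= 3 mismatches and <= 2 nt of
gaps (the documented acceptance thresholds of the original aligner; its
mapping-quality model is deliberately not reimplemented). The SE anchors
each pair; the mate is restricted to the SE's contig. CcRAD1 collects
columns with two observed alleles and pooled depth >= 6 (a flag switches to
per-sample depth; the comprehensive list predates per-sample requirements).
CcRAD2 keeps CcRAD1 sites with at least one read in every sample.

Zygosity per sample: heterozygous iff both top alleles have >= 2 reads,
depth >= 4 and the within-sample frequencies lie in [0.25, 0.75] (endpoints
inclusive); homozygous iff the minor-allele frequency is strictly below
0.10 **and depth >= 2** — a single read never yields a definite genotype
(`min_hom_depth = 1` restores the literal minor-frequency rule). The zone
between 0.10 and 0.25, never named in the published rules, is `ambiguous`;
so are columns with three alleles at >= 2 reads each. Testcross markers are
ordered-pair events (het in the informative parent, hom in the partner);
all-het sites are common intercross; everything else is uninformative.

**Recovery metric.** The simulator truth enables a concordance figure:
definite (het/hom) imputations at CcRAD2 SNV sites are compared with the
truth genotypes after mapping contig coordinates back to the genome
(anchor block directly, island block by gapped alignment). Abstentions are
reported as a separate definite-call rate, not silently counted either way
— under the stated thresholds a 20x heterozygous column already fails the
frequency window ~1.2% of the time by binomial noise alone, and
coverage-tapered locus edges abstain by design, so "accuracy over claims
plus an abstention floor" is the honest pair of numbers. Truth-indel sites
are excluded from the headline figure (left-anchoring is
strand-ambiguous); SNVs are over 95% of the comparable published set.

## K-mer spectra and CpG rate

Spectra are dense forward-strand counts over the 4^k words (k = 10 by
default; a flag enables canonical counting — the published counting tool's
setting is not stated, which is why the 0.53 value is only reproducible
with the original data in hand). Words are classed by overlap-counted CpG
content (0 / 1 / >= 2) and summarised as occurrence histograms; class
histograms sum cell-wise to the full histogram by construction. The CpG
rate is the Karlin–Mrazek ratio f(CpG) / (p(C) p(G)) with the dinucleotide
frequency computed per dinucleotide window (denominator L - 1 per
sequence). Negative controls re-split the same spectrum on random
dinucleotides other than CG.

## CAPS design

Recognition sites are matched IUPAC-degenerately on both strands; type IIS
enzymes (FokI GGATG(9), BccI CCATC(4)) carry their downstream top-strand
cut offsets from standard enzyme references, and the duplex cut coordinate
is used for fragments on either strand. Amplicons are placed geometrically
(primer landing confined to 50 nt windows at the contig ends, product
100–400 nt soft bounds — the published panel itself contains a 451 nt
product, so the bounds are configurable). An assay is accepted iff the
minimum pairwise difference among the distinct fragment lengths of the two
homozygote patterns is >= 20 nt; this is the strict reading forced by the
stated rejection example ({341} vs {180, 161} fails on 19), and one
published assay (fragments 176 vs 168) would not pass it. Scoring matches
an observed band set against hom-uncut / hom-cut / het (= union)
predictions within a ±5% gel tolerance; no or ambiguous match is left
unscored, which is how "missing cut" and "unclear" wet-lab outcomes are
represented. Primer thermodynamics are out of scope; reported primers are
the terminal 20-mers.

The packaged validation panel (`caps_validation_table()`) is transcribed
verbatim, including four rows whose printed fragment sums are internally
inconsistent; tests use only the consistent rows.

## Segregation and linkage

Chi-square goodness of fit with df = classes - 1; a marker is included for
mapping iff chi2 <= the alpha = 0.01 critical value (the lower bound of the
published inclusion window is the alpha = 1 critical value, which is zero,
so it never binds) and flagged distorted above the alpha = 0.1 critical
value. Two-point analysis on testcross-coded markers estimates r by
phase-minimised recombinant counting, clamps r to [1/(2n), 0.5] for the
LOD, and converts distances with the Kosambi function d = 25 ln((1+2r)/(1-2r)).
Grouping is single-linkage transitive closure over edges with LOD >= 6 and
r <= 0.40; within-group marker ordering (a proprietary regression mapper in
the original workflow) is intentionally not implemented.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open everywhere except VCF output (1-based per
the standard, indels re-anchored to the conventional left anchor base).
Alignment cost is 2 per mismatch and 3 per gap nt, so one 1 nt gap is
preferred to two mismatches; ties break by fewer mismatches, then leftmost
offset, then contig order. Assembly branch ties follow the
lexicographically smaller base. Empty inputs: digestion of an empty string,
an empty k-value sweep, a zero-length genome, zero controls and an empty
observed band set are errors; empty read sets flow through clustering and
pileups as empty results. All generator stages draw from seeds derived
deterministically from `sim_params()$seed`, so identical parameters give
byte-identical FASTA/FASTQ/truth output.

## Known limitations

* Under the published 300–800 nt insert window the package cannot produce
  SE-anchored contigs (geometry, not implementation — see above).
* Genotype concordance is defined over definite calls; an aggressive
  abstention policy would inflate it, which is why the definite-call rate
  is always reported and asserted alongside.
* The aligner is a seeded banded matcher bound by the documented mismatch
  and gap limits, not a bit-for-bit reimplementation of the original
  mapper; mapping qualities are not modelled.
* Minus-strand type IIS cut coordinates mirror the top-strand offset; the
  second (staggered) nick is ignored, as gel fragments follow the duplex
  cut.
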