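---
title: "Models and methods behind radiadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radiadiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

radiadiv analyses a multi-clade whole-genome resequencing panel together
with whole-genome bisulfite (CG methylation) data, the design used to study
adaptive radiations such as the columbines (*Aquilegia*): several species
per continental lineage, a handful of accessions per species, one reference
genome. This vignette explains the statistical machinery, the tunable
parameters and their defaults, what the synthetic data generator does and
does not emulate, and the design choices we made where more than one
reasonable option existed.

## Data model and quality control

Variants enter as a VCF with SnpEff-style `ANN` annotations. The
high-quality filter keeps genotypes with per-sample read depth above 3
(shallower calls become missing, not homozygous reference), drops records
with mapping quality at or below 20, and drops records whose missing
genotype fraction reaches 1 percent — with 36 samples this effectively
requires a complete genotype vector, which is the intended, conservative
reading. Multiallelic records are split into biallelic records; a genotype
carrying a different alternate allele is set missing in the split record
rather than silently recoded. Only biallelic SNPs enter diversity,
divergence, PCA and tree building; INDELs participate only in
clade-specific variant calling and CG-loss classification.

Cytosine reports (Bismark dialect) are restricted to CG context. The two
strands of a symmetric CpG are merged onto the plus-strand C by summing
counts (a flag keeps them separate). A site enters analysis for a sample
only with at least 3 reads; the methylation level is the beta value
$\beta = m/t$. Sites covered in at least 80 percent of samples form the
PCA mask — the filter we adopt for "passed quality control", since a
missingness rule is the conventional choice and mean-imputation below that
coverage would dominate the signal.

## Diversity and divergence scans

Windows are 100 kb, non-overlapping, anchored at coordinate 0, with the
short terminal window kept and flagged. Windowed nucleotide diversity uses
the unbiased per-site heterozygosity $\frac{n}{n-1} 2p(1-p)$ summed over
variant sites and divided by the full window length, so monomorphic
sequence counts in the denominator — the convention of the common windowed
implementations, which makes windows comparable. $F_{ST}$ is the
Weir–Cockerham (1984) two-population estimator in its weighted windowed
form $\hat\theta = \sum_s a_s / \sum_s (a_s + b_s + c_s)$; sites
monomorphic over both groups or missing an entire group are skipped, and a
window with no contributing site is undefined rather than zero. A fixed
difference gives exactly 1, and duplicating one population gives a
non-positive estimate — both are enforced in tests.

Low-diversity (LDGR) and high-divergence (HDGR) regions are the 5 percent
tails. Tail selection uses a closed threshold at the $k = \lceil qn \rceil$
order statistic, so ties at the threshold are all included and the
selected count can exceed the nominal 5 percent; this is deliberate — an
open threshold would make the tail depend on storage order.

PCA mean-imputes missing dosages per site, centers, and (for genotypes)
variance-standardizes before the singular value decomposition; beta values
are centered but not standardized, because a beta value already lives on a
fixed scale and standardization would up-weight near-constant sites. LD
pruning is greedy over 50-SNP windows advanced by 5 with an $r^2$ cap of
0.2 — conventional settings; only the pruned count, not the parameters, is
usually reported in studies of this kind.

Neighbor joining is the classic Saitou–Nei agglomeration with ties broken
by the smallest index pair and negative branch lengths clamped to zero.
The input distance is the allele-sharing distance
$1 - \text{shared}/(2 \cdot \text{compared})$ computed over loci at which
both samples are homozygous; heterozygous calls are excluded because the
published panels build trees from homozygous SNPs, and allele sharing on
homozygous calls is robust to the moderate depth of such panels. The
distance metric behind published trees of this kind is rarely stated; the
allele-sharing choice is ours and is flagged as such.

## dN/dS and selection classes

Per-sample coding sequences substitute homozygous-alternate SNPs into the
reference CDS; heterozygous variants and INDELs are ignored — the
biological consequence of a heterozygous call is ambiguous in these
panels, so only fixed states enter. Pairwise divergence uses Nei–Gojobori
(1986): synonymous site counts averaged over both sequences, difference
counts averaged over substitution pathways at multi-hit codons (pathways
through stop codons are excluded; if every pathway is blocked the
unrestricted average is used), Jukes–Cantor correction
$d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)$. Mutations *to* a stop codon count
as nonsynonymous sites. A ratio is undefined when $d_S = 0$; when a
proportion reaches the correction bound ($p \ge 3/4$) the distance
saturates to infinity, so a fully saturated synonymous axis with zero
nonsynonymous change still yields a ratio of 0. We use NG86 rather than a
maximum-likelihood counting method: the downstream classification only
uses the *ranking* of per-gene means, and NG86 preserves ranking while
being exactly checkable against an enumeration oracle.

A gene's score for a clade pair is the mean of defined ratios over all
cross-clade sample pairs (identical consensus sequences are collapsed and
weighted, which is exact and much faster). The 5 percent highest defined
means are "positive", the lowest 5 percent "purifying", with the same
closed-threshold tie rule as the window tails; genes with premature stops
in a consensus (e.g. carriers of a planted stop-gain) or no defined pair
are "undefined" and stay out of the quantiles.

## CMH-based differential methylation

DMRs are called on 100-bp non-overlapping windows. Within a window, each
CG site is one stratum of a Cochran–Mantel–Haenszel test: read counts are
pooled over the covered samples of each group at that site, giving a
2 (group) × 2 (methylated/unmethylated) table per site. The statistic is
$\chi^2 = (\sum_k a_k - E_k)^2 / \sum_k V_k$ with hypergeometric mean and
variance from the stratum margins, no continuity correction, 1 df.
Stratifying by site is our reading of "accounting for imbalanced read
depth": depth varies per site and per sample, and pooling within group per
site keeps each site's evidence weighted by its own depth rather than
letting deep sites swamp shallow ones in a single pooled table. Windows
with fewer than 3 informative strata are *untested* — excluded from the
Benjamini–Hochberg family, not counted as non-significant. BH runs over
all tested windows of one comparison genome-wide. A window is a DMR when
the adjusted p is below 0.05 *and* the pooled-beta divergence
$|\beta_A - \beta_B|$ exceeds 25 percent; genes with more than 20 percent
of their span covered by the union of DMR windows are DMGs (strict
inequality at the boundary).

The CMH test assumes counts are binomial within a stratum. With
biological replicates the pooled counts are over-dispersed, which makes
raw p values anticonservative; the divergence gate is what keeps the
false-positive rate near zero in that regime (the null-calibration test
verifies both statements: uniform p under pure binomial sampling, and an
essentially empty DMR set once the gate applies). A replicate-aware
beta-binomial model is deliberately out of scope: the CMH construction is
the method under study.

## MDI, CpG islands and metaprofiles

The chromosomal methylation discrepancy index compares one accession to a
reference accession: pool beta within 100-kb windows, average the absolute
differences over windows covered in both samples, and scale by 100. The
cited definition is not printed in the source literature we work from, so
this formula — mean absolute pooled-beta window difference in percentage
points — is our explicit stand-in; it is non-negative, symmetric, zero on
identity, and linear in a single-window difference (one window differing
by 0.5 among ten gives exactly 5.0).

CpG islands follow Gardiner-Garden–Frommer: 100-bp windows slid by 1 bp,
flagged when GC fraction exceeds 50 percent and observed/expected CpG
exceeds 0.6 (expected = $n_C n_G / L$), overlapping or abutting flagged
windows merged, and merged runs longer than 200 bp reported. N bases are
excluded from composition and windows that are mostly N are skipped. This
is the plain criterion scan (verified base-by-base against a brute-force
oracle), not a reimplementation of any particular tool's smoothing.

Metaprofiles pool read counts (not per-sample means) per bin: gene bodies
rescale to 100 bins with 5-kb flanks at 100 bp per bin, strand-aware so
the TSS is always on the left; islands rescale to 40 bins with 2-kb
shores. Shore width is a community convention; the read-pooled mean makes
the profile's weighted bin average equal the pooled regional mean, a
conservation property the tests assert.

## Genetic–epigenetic integration

A CG locus carries a *CG-loss variation* when a SNP sits on its C or G or
an INDEL's reference span overlaps either base. The effect of dosage on
methylation is measured by ordinary least squares of beta on alt-allele
count. Variability categories rank loci by the standard deviation of beta
across samples with the published rank cutoffs (10,000 / 50,000 /
150,000); with fewer loci the cutoffs scale proportionally.

The cis-driver scan tests, for each DMR, every variant within 500 bp of
the window. The per-sample phenotype is the read-pooled beta over the
window. Population structure is removed in the Eigenstrat manner: both
phenotype and dosage are residualized on the top principal components of
the genome-wide standardized dosage matrix, and
$\chi^2 = (n - K - 1)\, r^2$ on 1 df tests the residual correlation. A DMR
is "associated" at a threshold if any candidate passes — no per-DMR
multiplicity correction, matching the at-least-one-driver question the
scan answers. The threshold grid is {5e-5, 5e-6, 5e-7, 5e-8}, anchored at
the least stringent published value.

The number of axes $K$ defaults to 10, the EIGENSTRAT convention. Two
axes (one per extra lineage) are *not* enough for a ten-species panel:
the focal comparison is a within-lineage species pair, so label-keyed
methylation differences flanked by species-fixed variants would masquerade
as cis drivers unless the PCs span the species-level axes as well — a
ten-species panel has nine of them, which ten axes cover with the hybrid
accessions interpolating. The stratification-control test plants a
two-population null with structured phenotypes and verifies that the
corrected scan's genomic-control lambda sits in [0.9, 1.1] while the
uncorrected scan inflates past 1.3; with strongly diverged populations the
leading PC estimates the population axis accurately, which is what the
correction needs (weakly diverged pairs leave residual leakage — a known
property of the method, not of this implementation).

The DMG × selection association is a Pearson chi-square without continuity
correction on the 2×2 table of DMG status against membership in one
selection class, over the universe of genes with a defined class;
p values are reported unadjusted, as in the published tables, because the
overlapping gene sets across comparisons make the tests dependent.

## The synthetic data generator

The generator is first-class, tested code; its defaults *are* the study
conditions. The default panel is 36 accessions: an Asian lineage with the
focal sister pair (7 + 7 accessions) plus 4 putative hybrids and two more
species (2 + 2), a European lineage (3 + 3) and an American lineage
(2 + 2 + 2 + 2) — ten species, three lineages. The genome is 2 × 1 Mb of
iid sequence at 36 percent GC, with 30 planted CpG islands (250–1500 bp,
GC ≥ 60 percent, observed/expected CpG ≥ 0.8) and 300 protein-coding genes
(ATG start, 120–350 sense codons, 40 percent with one intron, no stop
codon so every consensus stays in frame by construction).

Variants drop on the lineage/species tree: each background variant is
assigned to a lineage branch, a species branch, or segregates within one
species at a uniform frequency; 10 percent are 1–3 bp INDELs. Rates
(1e-4/bp per lineage branch, 1e-4 per species branch, 2e-4 segregating)
give a panel of roughly 23,000 QC-pass variants — enough for dense PCA,
trees and window statistics at desk scale while keeping every end-to-end
run under a few minutes. Background variants avoid coding sequence and
CpG dinucleotides so that coding divergence and CG-loss status are fully
controlled by their own planting machinery. Hybrid genotypes are drawn
allele-wise from the two parent species' realized allele frequencies, so
fixed interspecific differences make hybrids heterozygous. A small
fraction of records is emitted as deliberate QC chaff (low MQ or uniform
low depth) that the reader must drop.

Coding substitutions realize the selection classes: "positive" genes get
about 15 nonsynonymous and 1 synonymous clade-fixed substitutions between
the two compared lineages, "purifying" genes the reverse, background genes
one or two of each; every species additionally receives Poisson(0.15)
private synonymous and nonsynonymous substitutions per gene so that *any*
species pair has defined dN/dS. Synonymous changes use third positions of
4-fold degenerate codons; nonsynonymous changes use second positions with
stop codons rejected.

Methylation: each CpG draws a latent beta from the plant-gene-body-like
mixture 0.6·Beta(8,2) + 0.4·Beta(2,8) (islands from Beta(2,8)); a
configured fraction of sites is redrawn per lineage (5 percent) and per
species (10 percent) in regional blocks of about 300 bp, the way heritable
epimutations spread over neighbouring CpGs — block structure is also what
makes DMRs span enough of a gene to produce DMGs. Planted DMR windows
(default 200, chosen among CpG-dense windows with at least 6 CpGs and no
coding overlap, so the planted effect has signal to carry it) shift the
two compared species by Δβ = 0.4 from a uniform(0.1, 0.5) base, with the
other species halfway between; for the 50 percent of planted DMRs paired
with a cis driver, the shift is keyed to the driver genotype
(β = base + Δβ·dosage/2) instead of the species label, with driver allele
frequencies 0.85/0.15 in the compared pair and 0.5 elsewhere. Any variant
ablating a CpG multiplies its carriers' beta by (1 − dosage/2), hom
carriers dropping to zero — the mechanical CG-loss effect. Per-sample
noise is Gaussian on beta (sd 0.03), and 1.5 percent of site-by-sample
cells are redrawn from the baseline mixture as sporadic epimutations —
the stochastic epiallele component documented in plants, and the reason
non-variant loci show intra-species variability that variant-carrying
loci (whose state follows genotype) lack. Read depth is
negative-binomial per strand (total mean 12, dispersion 5) and
methylated counts are binomial. Note that at this depth the per-sample
beta value carries binomial measurement noise of roughly 0.1 sd, which
caps the attainable per-locus R² of the CG-loss regression; dominance of
the genotype at carrying loci is therefore asserted as a majority
property at the top-variability scale, not as a near-1 ceiling.
Two derived configurations fix benchmark conditions: a two-species 6 vs 6
panel with only planted effects (DMR recovery), and its null variant with
zero effects and zero sample noise (type-I-error calibration, 2 × 1.75 Mb
so over 20,000 windows are testable).

What the generator does **not** emulate: linkage disequilibrium decay and
recombination (variants drop independently on branches), sequencing error
and bisulfite conversion failure, context-dependent mutation, CHG/CHH
methylation, copy-number variation, and realistic gene structure (UTRs,
alternative isoforms). Passing the recovery benchmarks therefore shows the
*estimators and filters* behave as specified under the assumed noise
model, not that the pipeline is robust to every artefact of real
libraries.

## Problem sizes and determinism

All bundled analyses run on one CPU: the full 36-sample pipeline in a few
minutes, the calibration benchmarks in about a minute each. These sizes
were chosen so that the whole battery — including the 20,000-window null —
exercises every code path at meaningful scale while staying comfortable to
re-run; scaling the genome or panel up is a matter of configuration, not
code. Every stochastic step draws from one seeded generator: the same
configuration reproduces byte-identical datasets and result tables.

## Known limitations

The CMH scan inherits anticonservativeness under replicate-level
overdispersion (mitigated, not removed, by the divergence gate). The MDI
formula is a declared stand-in for an unavailable published definition.
The Eigenstrat scan uses untransformed pooled beta phenotypes; a rank or
logit transform would be more robust to extreme betas but changes the
published quantity. NG86 underestimates divergence at high saturation
relative to ML counting; only rankings are consumed here. The NJ distance
metric and the methylome-PCA QC rule are explicit choices where the
source methods are silent.
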