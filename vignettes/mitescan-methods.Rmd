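---
title: "Methods and design of mitescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescan)
```

# Scope

`mitescan` implements the computational workflow used to discover and
characterize miniature, non-autonomous transposon-like insertions — the
kind exemplified by the 307-bp wheat element *Mariam*, which carries a
9-bp target-site duplication (TSD) but neither terminal inverted repeats
(TIRs) nor SINE hallmarks.  The workflow has five analytic stages
(homology retrieval, structural classification, genomic-context
annotation, insertional-polymorphism scoring with clustering, and
gene-impact analysis) plus a synthetic-genome generator that provides
ground truth for all of them.  This vignette records the models,
parameter choices and their rationale, what the simulations do and do
not emulate, and known limitations.

# Homology retrieval

Copies of a consensus element are retrieved by a seed-and-extend local
search: exact `word_size = 11` matches locate candidate regions on both
strands, each region is aligned by affine-gap local alignment (match +1,
mismatch −2, gap open 5, gap extend 2 — blastn-like scoring), and
alignments are kept when the Karlin–Altschul e-value
$E = K \, m \, n \, e^{-\lambda S}$ (ungapped estimates $\lambda =
0.625$, $K = 0.41$ for this scoring) is at most $10^{-3}$.  Overlapping
hits (> 50 % of the shorter span) are merged to the best-scoring record,
on the principle that one insertion locus yields one record.

Two retrieval conventions matter downstream:

* **Full-length calling.**  A hit is full length when the *unaligned*
  query length at each end is at most `end_mismatch_tol = 20` nt — an
  end-tolerance convention (permitted unaligned query length, not a
  mismatch count), which is what homology-based MITE retrieval tools
  mean by end mismatch tolerance.
* **Full-extent projection.**  A local alignment trims mismatching
  query ends, so the reported aligned span can stop a few bases short of
  the true element boundary whenever terminal bases have diverged.
  `search_copies` therefore also reports `full_start`/`full_end`, the
  aligned span projected to the full query extent.  TSD calling and
  flank extraction use the projected span; with substitution-only
  divergence the projection recovers the exact element boundary.

Flanks default to 1000 bp per side, truncated (never padded) at contig
ends with the truncation recorded.

On genomes up to ~50 kb the seeded search is tested for exact equality
against a brute-force sliding-window alignment scan over all positions
and both strands; recovery of planted copies is tested at up to 5 %
divergence.  One caveat is inherent to local alignment: co-optimal
alignments of a diverged copy can trim ends differently between a genome
and its reverse complement, so mirror symmetry of hit *endpoints* holds
only to a few base pairs, while scores are exactly mirror-invariant.

# Structural classification

**TSD.**  The detector returns the longest $k \in [k_{\min}, k_{\max}]$
such that the $k$-suffix of the upstream flank matches the $k$-prefix of
the downstream flank with at most `max_mismatch` mismatches, each copy
starting within `boundary_slack` bp of the element boundary; ties break
toward fewer mismatches, then smaller offsets.  The default "clear TSD"
rule — exact match, $k \in [8, 12]$, slack 2 bp — is deliberately
binary: it reproduces a clear/absent split without introducing a
similarity threshold the underlying assay never defines.  The detector
is tested for equality against a brute-force search over all
$(k, \text{offset})$ pairs.

**TIR.**  The 5′ terminal window (30 bp) is locally aligned against the
reverse complement of the 3′ window; a TIR is called at length ≥ 10 bp
and identity ≥ 80 % — typical MITE TIR dimensions, chosen because the
elements of interest are defined partly by *lacking* TIRs and the screen
must not miss real ones.

**SINE hallmarks.**  A poly-A tail is ≥ 8 adenines with at most one
interruption within the 3′-terminal 20 bp (a conventional SINE-tail
heuristic).  The internal Pol-III promoter screen uses the canonical
A-box consensus `TRGCNNARYNNG` (≤ 2 mismatches) and B-box `GTTCGANNC`
(≤ 1 mismatch) in the element's 5′ half with 25–75 bp spacing.

**Classification** is a pure rule table: TIR present → TIR-superfamily
candidate; no TIR but SINE features → SINE candidate; no TIR, no SINE
features, 9-bp TSD → Mutator-derived MITE candidate (9-bp TSDs are the
Mutator signature); otherwise unclassified miniature element.

**Conservation** uses global alignment with the same scoring; identity
is matches over alignment columns, so gaps count as mismatches.  Both
mean and minimum pairwise identity are reported, because "conservation
over X %" can refer to either.  Sequence-logo matrices report
per-position frequencies and information content $IC = 2 - H$ bits; the
small-sample correction $3/(2 n \ln 2)$ is available but off by default
so that IC is exactly comparable across panels of different sizes.

# Genomic context

Insertions are classified against gene models (GFF3, converted on read
to the package-wide 0-based half-open convention) and TE annotations
(BED) with precedence exon (CDS) > UTR > intron > gene-proximal >
TE-adjacent > intergenic, using a single 500-bp adjacency window for
genes and TEs alike.  The precedence order is a design decision — the
underlying survey reports category counts without tie rules — and the
same window is applied to TEs because no separate value is defined.

# Insertional polymorphism and clustering

In-silico PCR reports every forward-primer match paired with every
downstream reverse-complemented reverse-primer match within
`max_product_size = 5000` bp, in both template orientations; matching is
exact by default, with an option of ≤ 2 mismatches excluding the three
3′-terminal bases.  Full/empty calls compare product lengths to expected
sizes within a ±10 bp tolerance, and populations are summarized with the
standard codes 0 (empty in all accessions), 1 (full in some), 2 (full in
all).  Expected full/empty sizes are configurable per locus rather than
derived from a fixed element length, since per-locus indels and gel
rounding make the printed size difference locus-specific.

Accessions are clustered on Bray-Curtis dissimilarity
$d(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})$ — on 0/1
data this equals one minus the Sørensen similarity, an identity the
tests assert — with group-average (UPGMA) linkage, the linkage used by
the clustering-software family this analysis descends from.  Binary data
enter unstandardized (presence/absence is already commensurate).  A pair
of all-zero profiles has undefined dissimilarity; it is set to 1 with a
warning.

**SIMPROF.**  Each dendrogram node is tested for internal structure: the
actual resemblance profile is the sorted vector of pairwise
dissimilarities; null profiles are generated by independently permuting
each locus column across the node's accessions; the mean profile is the
rank-wise mean of 1000 null profiles; the statistic is
$\pi = \sum_{\text{ranks}} |\text{actual} - \text{mean}|$; and
significance comes from 999 further null profiles via
$p = (1 + \#\{\pi_{\text{null}} \ge \pi_{\text{obs}}\}) / (1 + 999)$.
The traversal is top-down and children of a non-significant node are not
tested, so the significant nodes delimit the supported groups.
Permutation counts (1000/999) and $\alpha = 0.05$ are package defaults;
only the significance level is inherited from the original analysis.
Two implementation choices are worth recording: rows are put into a
canonical order (sorted by profile content) before any permutation is
drawn, which makes p-values invariant to accession input order at a
fixed seed; and the permutation core evaluates binary Bray-Curtis by the
closed form $1 - 2 s_{ij}/(r_i + r_j)$, which the tests pin to
`vegan::vegdist` on 0/1 data.  Calibration is simulation-tested: the
root-node type-I error over 500 null datasets (i.i.d. Bernoulli(0.5)
columns, 20 accessions × 11 loci) must lie in [0.02, 0.08], and power
against two disjoint planted groups (10 + 10 accessions, 11 loci) must
be ≥ 95 %.

# Gene impact

Mature mRNAs are exon concatenations (minus-strand genes
reverse-complemented).  An exonic insertion is retained in the mature
transcript and contributes element + one extra TSD copy, so the
transcript grows by exactly $307 + 9 = 316$ nt in the default geometry —
the convention consistent with a 626 bp → 942 bp product pair from
primers flanking the insertion.  (For genomic site-specific PCR the
same arithmetic applies; printed gel sizes may round.)  Insertions whose
duplicated target site would span a splice junction are refused as an
unsupported case.

ORF reports translate from the CDS start with the standard nuclear code,
locate the first in-frame stop, and compare protein lengths between the
insertion allele and the reference allele (the same transcript with the
inserted segment excised).  A premature stop inside the element is
reported 1-based within the element's nucleotides, as the position of
the stop codon's final base.

Relative expression uses the comparative method
$RQ = 2^{-[(CT_t - CT_c)_{\text{sample}} - (CT_t - CT_c)_{\text{calibrator}}]}$,
so the calibrator's RQ is exactly 1, one extra target cycle halves RQ,
and adding any constant to every CT changes nothing — all asserted as
closed-form tests.  Group comparisons use one-way ANOVA with Tukey HSD
(`stats::aov`/`TukeyHSD`); groups with a single observation are excluded
with a warning.  Standard-curve efficiency is
$((10^{-1/y}) - 1) \times 100\,\%$.

# The synthetic-genome generator

The generator emulates the study conditions the analysis assumes:

* **Background**: i.i.d. uniform ACGT.  Uniform composition avoids
  accidental homology with planted elements; it is the one deliberate
  departure from real genomes (see limitations).
* **Element**: a fixed synthetic 307-bp consensus
  (`mite_consensus()`), generated once under structural constraints —
  an in-frame TAA at nucleotides 39–41 of the element in the host-gene
  frame, no TIR, no poly-A tail, no Pol-III boxes, no internal copy of
  the target-site motif — so that classification and ORF arithmetic are
  exercised exactly.  It is synthetic, not a natural sequence.
* **Copies**: 12 per genome by default (a tetraploid-wheat-like copy
  number), each planted with a TSD by duplicating the 9 bases at the
  integration site, mutated at 3 % per-site substitution probability
  (keeping mean pairwise identity above 90 %), on a random strand,
  well separated and away from the host gene.  Mutations are
  substitutions only; TSD decay is modelled separately as ≥ 3
  substitutions inside one TSD copy, which guarantees the strict
  clear-TSD rule fails — half the copies decay by default, mirroring a
  survey in which roughly half the insertions showed clear TSDs.
* **Host gene**: 7 exons (130/120/110/100/160/250/300 nt of mRNA,
  85-bp introns, 60-nt 5′ UTR, 843-nt CDS ending in exon 7), with the
  9-bp target-site motif at CDS positions 701–709 and the index copy
  planted there, inside exon 6.  This geometry was solved so that one
  construction yields all the reference numbers at once: a 280-aa
  reference product, a premature stop at element nucleotide 41
  truncating it to 249 aa, and exon-5/exon-7 primers giving a
  626/942-bp product pair.  The simulated reference genome is the
  insertion-bearing allele with GFF3 coordinates on the post-insertion
  sequence; `ancestral_gene()` excises the insertion to recover the
  empty-site allele.
* **Accession panels**: five populations × nine accessions by default.
  Presence of each locus in each accession is an independent Bernoulli
  draw from a locus × population probability matrix; empty sites carry
  exactly one copy of the target site, full sites the duplicated site
  plus element.  Accessions are simulated homozygous — wild emmer is
  predominantly self-pollinating, and the underlying assay scores
  presence/absence, not genotype.  When no profile is supplied, loci
  are drawn from a mixture of archetypes (15 % fixed, 45 %
  population-specific, 40 % broadly polymorphic) whose frequencies
  roughly match the published 11-locus code matrix.
* **CT tables**: group effects shift the target gene's CT only (one
  cycle ≈ twofold), with i.i.d. normal noise (SD 0.2 by default) on both
  target and control.

Everything is seeded: identical configuration and seed give
byte-identical genomes, panels and files.

What the simulations do **not** emulate — and hence what passing tests
do not show about real data: repetitive and GC-structured genomic
background, nested or fragmented element copies, indel divergence
between copies (an optional knob, off by default), polyploid subgenome
homeology, heterozygous accessions, linkage between loci, and
amplification failure in PCR.  Tests passing on this generator certify
the algorithms and their arithmetic, not performance on wheat-scale
assemblies.

# Problem sizes and numerical choices

The shipped tests run at desk scale, chosen to keep the full suite in
the minutes range while still exercising every path: unit simulations
use 2 chromosomes × 40 kb with 6 copies; the survey-scale test uses 4 ×
120 kb with 33 copies; brute-force alignment equivalence uses ≤ 45 kb
genomes; SIMPROF calibration uses 500 null datasets of 20 × 11 with
1000 + 999 permutations each.  Degenerate inputs are handled
explicitly: homopolymer queries are rejected; empty genomes return empty
hit tables; flanks shorter than $k_{\min}$ return a reasoned not-found;
all-zero dissimilarity pairs are defined as 1 with a warning; SIMPROF
nodes of fewer than 3 accessions auto-pass as non-significant;
single-observation ANOVA groups are dropped with a warning.

# Known limitations

Per-species copy counts from the original wheat genome drafts depend on
those assemblies and the exact scoring of the original retrieval tool;
they are recovery-tested on synthetic data only.  Published expression
levels and their ANOVA cannot be recomputed because the underlying raw
CT values are unpublished; the package reproduces the method and is
power-tested on simulated CT tables.  Protein-domain consequences of the
truncation are out of scope (the package compares ORF lengths, not
domain annotations).  The retrieval engine is written for desk-scale
genomes; whole-genome wheat scans would need a compiled aligner behind
the same interfaces.
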