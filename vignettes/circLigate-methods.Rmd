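---
title: "Methods: ligation-probe quantification of linear and circular splice junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligation-probe quantification of linear and circular splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circLigate)
```

## The assay model

A ligation-probe panel places two oligonucleotide probes at every exon
boundary of the targeted genes: an *acceptor* probe at the 5′ edge and a
*donor* probe at the 3′ edge (terminal exons carry only the inward-facing
probe). When a splice event joins two exons in a transcript, the donor
probe of the upstream exon and the acceptor probe of the downstream exon
hybridise adjacently on the cDNA and are joined by ligase. The ligation
product — `UMI ++ donor probe ++ acceptor probe`, with the sample barcode
introduced at amplification — is sequenced, and each *distinct* UMI per
junction counts one original molecule, because PCR duplicates inherit the
molecule's UMI.

The probe order encodes topology. With exons ranked by their ordinal
position:

* acceptor ordinal > donor ordinal → **linear** splice
  (canonical if the pair is adjacent in the reference transcript,
  otherwise alternative — including skipping);
* acceptor ordinal ≤ donor ordinal → **backsplice** (a circRNA
  junction; equality is a single-exon circle).

Alternative exon boundaries (labels with a `p`/`q` suffix, e.g. `5q`)
are modelled as distinct exon entries with ordinals adjacent to their
parent exon, so the classification stays purely ordinal and
backsplices from them keep the suffix in their name
(`BRCA1_circRNA_5q-3`). SNP-allele probe pairs and intronic control
probes short-circuit the rule into `snp_allele` and `intronic_control`
classes; pairs with wrong probe sides or spanning two genes are
`artifact` (fusion detection is out of scope).

Two further probe classes carry auxiliary signals. Each assayed SNP has
two allele-specific probes plus one shared partner probe (10 SNPs × 3 =
30 probes in the packaged panel — the only architecture consistent with
the panel's printed probe count and with detecting both alleles by
ligation). Allelic imbalance at a heterozygous SNP is an indirect
readout of allele loss or nonsense-mediated decay. Intronic probes only
produce ligations on genomic DNA, so their UMI share estimates DNA
contamination.

## Ratio definitions

For one sample and gene, with $u_j$ the distinct-UMI count of junction
$j$, $C$ the set of backsplice junctions, $L$ the set of linear-ordered
junctions (canonical *and* alternative), and $n$ the number of canonical
junction pairs in the panel:

* relative proportion of circRNA $c$: $u_c / \sum_{j \in C} u_j$;
* per-circRNA ratio: $100 \cdot u_c \big/ \left(\sum_{j \in L} u_j / n\right)$
  — one circular junction against the *average* linear junction;
* gene-wide ratio: $100 \cdot \sum_{j \in C} u_j / \sum_{j \in L} u_j$,
  reported per 100 linear junctions.

The linear sum deliberately includes alternative linear junctions while
the divisor counts only canonical pairs, following the formula's wording;
within a sample the per-circRNA ratio is therefore an exact constant
multiple of the relative proportion (asserted to 1e-9 in the tests).
SNP-allele and intronic UMIs are excluded from both pools — they measure
alleles and contamination, not junction abundance.

## UMI statistics

A 7-base UMI has $N = 4^7 = 16384$ states. $m$ molecules drawing UMIs
uniformly occupy $K$ distinct states with
$\mathbb{E}[K] = N(1-(1-1/N)^m)$ and exact occupancy variance
$\mathrm{Var}[K] = N(1-1/N)^m + N^2(1-1/N)(1-2/N)^m - N^2(1-1/N)^{2m}$.
Raw distinct-UMI counts are the reported currency everywhere; an exact
inverse $\hat m = \log(1-K/N)/\log(1-1/N)$ is available behind a
`correctSaturation` flag for settings where per-junction input approaches
the UMI space (at $m = 4500$ molecules per junction, roughly 13% of
molecules collide, which inflates a circular-to-linear ratio whose
numerator is far from saturation — the cohort-recovery analyses therefore
enable the correction).

An optional directional single-mismatch merge (`collapseUMIs(...,
directional = TRUE)`, parent ≥ 2·child − 1) absorbs sequencing-error
UMIs; it is off by default since raw counts are the assay's convention.

## The simulator: what it emulates and what it does not

`simulateReads()` turns a declarative sample description into reads plus
ground truth. Each canonical-transcript molecule emits one product per
canonical junction; alternative and circular molecules emit one product
at their junction; every product gets an independent uniform UMI, is
replicated `readsPerMolecule` times (default 3) with the same UMI, and
receives independent per-base substitutions at `errorRate`. Design
choices:

* **Circle interiors.** A circRNA containing several exons also splices
  internally, producing linear-looking junctions. By default
  (`circ_internal_linear = FALSE`) these are *not* emitted, matching the
  convention of the ratio definitions, which attribute every
  linear-ordered junction to mRNA; the flag exists so the resulting bias
  can be studied.
* **Capture.** One ligation product per junction per molecule, with an
  optional independent thinning `efficiency` ∈ (0, 1]; thinning
  preserves ratios in expectation, so the default 1.0 is a scale choice,
  not a bias choice.
* **Degradation.** FFPE fragmentation is subsumed by the molecule
  counts (the template needed per junction is only ~60 bases); it is not
  modelled separately.
* **Not modelled**: indels, quality-score variation (constant Q40),
  chimeric ligation artifacts, probe-specific capture biases. Passing
  recovery tests therefore demonstrates correctness of the counting and
  ratio machinery under the assay's idealised noise model, not
  robustness to probe chemistry effects in real libraries.

`simulateCounts()` is the molecule-level counterpart for cohort-scale
studies: it draws distinct-UMI counts directly from the occupancy
distribution — exactly (multinomial occupancy) for $m \le 3000$, and via
a normal approximation with the exact occupancy mean and variance above
that (at $m > 3000$ the occupancy distribution is asymptotically normal
and the approximation error is far below sampling noise).

## Read processing

Reads are positionally rigid, so probe identification is fixed-offset
Hamming comparison, not alignment: the UMI is the first 7 bases, the left
probe is matched at offset 8 over all panel probes of each length (exact
dictionary hit first, Hamming fallback otherwise), and the right probe
immediately after the left probe's end. A unique best match within
`maxMismatch` (default 2) is required; exact ties are `ambiguous`.
Barcodes tolerate 1 mismatch by default, backed by a validated pairwise
barcode distance ≥ 3 (= 2·tolerance + 1) that makes assignment
unambiguous. Panel validation also rejects duplicate or prefix-nested
probe sequences, which would defeat fixed-offset matching. The source
material does not state its mismatch tolerances; these defaults are this
package's declared choices and are configurable.

## QC, presence calls, anomalies, imbalance

* **1500-UMI rule.** The interpretability threshold is 1500 distinct
  UMIs per sample "for both" target genes — ambiguous between a combined
  and a per-gene reading. The default is the combined total (no per-gene
  figures exist to calibrate the stricter reading); `mode = "per-gene"`
  is provided.
* **Presence.** A junction is "detected" in a sample at
  `umi_count ≥ 1` after QC (configurable); detection frequencies are
  rounded half away from zero to 2 decimals, which reproduces every
  frequency cell of the packaged reference tables from its (count, n)
  pair.
* **Anomalies.** Non-canonical junctions are reported when their UMI
  count reaches 1% (default) of the gene's mean canonical-junction UMI
  count — the depth at which known alternative transcripts remain
  detectable — classified as `skipping` (ordinal gap > 1), `novel`, or
  `unexpected_backsplice`, and annotated known/novel against the
  reference repertoire. A backsplice explained by a germline tandem
  duplication (a *pseudo-circRNA*: linear splicing across the
  duplicated segment joins the last exon's donor to the duplicated first
  exon's acceptor) is indistinguishable at the read level, so
  `annotatePseudoCirc()` flags it only from supplied duplication
  annotations and never alters counts.
* **Imbalance.** Exact two-sided binomial test against 0.5 with ≥ 20
  informative UMIs; flagged when p < 0.01 *and* the allele fraction
  leaves [0.3, 0.7]. The effect floor is this package's choice — the
  phenomenon of interest (allele loss, NMD) produces frank deviations,
  and a pure p-threshold would flag trivial imbalances at depth.

## Profiles

`renderProfile()` writes hand-assembled SVG: exon boxes in ordinal order
(alternative exons unnumbered), linear arcs above the baseline in green,
backsplices below in red, intronic signals as blue marks, apex heights
proportional to `sqrt(umi)` by default (linear and log options; the
square root keeps 100-fold UMI ranges readable, and the height scaling of
the original profile plots is not documented). Identical inputs yield
byte-identical files — no timestamps, fixed ordering and number
formatting — and junctions below the display threshold (0.1% of the mean
canonical count) are returned in a `suppressed` table rather than dropped
silently.

## Cohort comparison

`compareGroups()` performs a two-sided two-sample t-test on per-100
gene-wide ratios. The default is the Welch variant: group sizes (38 vs
90 in the motivating design) and variances differ, and the pooled test's
equal-variance assumption is not defensible there; `variant = "pooled"`
reproduces the classical Student test for comparability. No
multiple-testing correction is applied across panels by default,
matching common practice for a two-gene confirmatory comparison.

## The cohort scenario generator

`buildCohortScenario()` emits the study conditions used by the recovery
analyses: 38 normal vs 90 tumor samples; 100,000 linear junction
molecules per sample and gene spread evenly over the canonical
junctions; per-sample true gene-wide ratios drawn as
Normal(1.89, 0.5) / Normal(1.14, 0.5) per 100 for BRCA1
(normal/tumor) and Normal(0.51, ·) / Normal(0.23, ·) for BRCA2 with the
SD scaled proportionally (0.5 · 0.51/1.89 ≈ 0.135, constant coefficient
of variation — no separate SD is documented for the second gene),
truncated at 0.02 to stay positive; circular molecules allocated
multinomially over the 21-junction top repertoire with the normal-tissue
relative proportions as weights. Each sample's *realized* truth ratio is
recomputed from the integer molecule counts, and recovery is judged
against that realization, not against the drawn mean.

## Numerical and degenerate-input choices

* Zero circular UMIs: relative proportions return an empty map with a
  note (not NaN); the gene-wide ratio is 0.
* Zero linear UMIs: ratio functions raise "no mRNA signal" rather than
  dividing by zero; anomaly detection likewise refuses to normalize
  against a zero canonical mean.
* Degenerate groups (n < 2, or zero variance in both) raise errors, not
  NaN statistics.
* Rounding of printed percentages uses half-away-from-zero, the
  convention that reproduces the reference tables (base `round()` is
  half-to-even).
* Exact ties in probe matching are surfaced as `ambiguous`, never
  broken arbitrarily.

## Problem sizes in the shipped analyses

The test-suite and acceptance analyses use a toy 6-exon panel with ~10⁴
error-free reads for exact oracle equivalence; 20 seeds × {10², 10³,
10⁴} molecules for the occupancy law; and 100 replicate 128-sample
cohorts at the molecule level (with saturation-corrected ratios) for
group-mean recovery within ±0.1 and test power at α = 10⁻³. These sizes
give Monte-Carlo error comfortably below the tested tolerances.

## Known limitations

* Probe and barcode sequences in the packaged panel are synthetic
  placeholders satisfying the design invariants; real panel sequences
  are not public.
* The reference repertoire tables ship only the published rows (top-20
  plus novel junctions per gene); the full landscape beyond them is not
  fabricated.
* Cross-gene ligations are tallied as artifacts, not interpreted;
  intron exonization is only indirectly visible as canonical-junction
  depression.
* The pipeline assumes the rigid read layout; structurally variant
  reads (adapters, indels) are unassigned rather than rescued.
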