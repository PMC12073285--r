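---
title: "Methods: SSR marker development and evaluation from resequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR marker development and evaluation from resequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
```

# Overview

`ssrkit` implements a whole-genome-resequencing (WGR) route to
microsatellite (SSR) marker development for a diploid plant panel, and the
downstream population-genetic evaluation of the resulting codominant
markers. The pipeline has six analytical stages:

1. **Repeat mining** — MISA-compatible detection of perfect tandem repeats
   (motif length 1–6) in nucleotide sequence.
2. **Variant pipeline** — extraction of long insertion/deletion alleles
   from a population VCF, quality control, collapsing of repeat-bearing
   variants to genomic loci, and candidate selection on genotype
   frequencies.
3. **Primer design** — enumeration and filtering of flanking PCR primer
   pairs under a fixed design window.
4. **Diversity statistics** — per-locus allele counts and heterozygosity
   statistics, PIC, and marker screening.
5. **Population structure** — Nei's genetic distance, UPGMA clustering,
   hierarchical AMOVA, pairwise Fst, and Evanno ΔK post-processing.
6. **Fingerprinting** — binary band-presence matrices and a panel
   discrimination rate.

A deterministic synthetic-data module generates every input the pipeline
consumes, together with truth tables, so each stage is testable without
external data.

# Repeat mining

A tract is reported when a motif of length $m \in \{1,\dots,6\}$ repeats
perfectly at least $r_m$ times, with defaults
$r = (10, 6, 5, 5, 5, 5)$ — the standard MISA thresholds for mono- through
hexanucleotide motifs. Detection works on the periodicity profile of the
sequence: position $j$ is $m$-periodic when base $j$ equals base $j+m$ and
neither is `N`; maximal runs of periodic positions are the repeat regions,
each reported once, anchored at its left edge, with
`repeat_count = floor(length/m)`.

Three conventions matter and are fixed here:

* **Shortest motif wins.** A region that is both a dinucleotide and a
  (degenerate) tetranucleotide repeat is reported as the dinucleotide:
  motifs that are themselves tandem repetitions of a shorter unit are never
  reported. `(AT)6` is a hit; `(ATAT)3` is not a separate one.
* **Strand pairing without rotation collapse.** A motif is labelled with
  its reverse complement, observed motif first (`TAT/ATA`). Rotations stay
  distinct — `AT/AT` and `TA/TA` are different classes — matching how
  genome-survey motif inventories are conventionally reported. An optional
  collapse mode merges a label pair under its lexicographically smaller
  member for programmatic grouping.
* **Compound flagging.** Tracts whose distance to an adjacent tract is at
  most 100 bp are flagged compound; compound and mononucleotide loci are
  excluded from marker design, because their products are hard to score on
  capillary electrophoresis.

The unit tests compare the scanner, case by case, against an exhaustive
brute-force oracle that tries every (start, motif) pair literally; the two
agree exactly on hundreds of random repeat-rich kilobase sequences.

# Variant pipeline

SSR alleles manifest in a population VCF as long InDels whose inserted or
deleted sequence is a repeat tract. The pipeline keeps sites where at least
one ALT differs from REF by **more than 10 nt**, runs the repeat miner on
the long allele of each such site, and collapses candidates to one locus
per `(chromosome, position)` with the locus id `chrom_pos`.

Quality control applies, in order:

* per-call masking — genotype calls with GQ ≤ 40 or DP outside [5, 100]
  are set missing (QUAL and GQ thresholds are strict, the depth window
  inclusive);
* site filtering — a site passes when QUAL > 40 **and** the
  allele-frequency/missingness rule holds.

The frequency rule has two modes. The default (`maf_mode = "lt"`) keeps a
site when its minor allele frequency is below 0.05 *or* its missing rate is
at most 5% — a disjunction that prioritises low-frequency variants and
keeps any well-genotyped site. The conventional alternative
(`maf_mode = "ge"`) keeps common variants only: MAF ≥ 0.05 *and*
missingness ≤ 5%. Both are exposed because the literal disjunctive form is
unusual in variant QC; the default follows the literal rule, and the choice
is recorded in output provenance.

Whether QC precedes or follows mining is configurable in the CLI
(`--order`); the default mines first and intersects with QC-passing sites,
which is equivalent for site-level rules and keeps the truth-table
bookkeeping simple.

Candidate selection keeps loci with a *secondary common genotype*: the
second-most-frequent diploid genotype must reach frequency
`min_secondary = 0.05`. The threshold is deliberately permissive — observed
secondary-genotype frequencies in real panels start around 0.08, so 0.05
excludes only near-monomorphic loci without discarding borderline markers.

# Primer design

Templates are the repeat tract ± 150 bp, truncated at sequence ends. The
design window is: primer length 18–27 bp (optimum 20), Tm 57–61 °C
(optimum 60, pair difference ≤ 5 °C), GC 20–80%, product 100–300 bp
containing the whole tract. All feasible windows are enumerated; pairs are
ranked by a fixed penalty

$$\mathrm{penalty} = |L_f - 20| + |L_r - 20| + |T_f - 60| + |T_r - 60|
  + 0.1\,(|GC_f - 50| + |GC_r - 50|) + |T_f - T_r|$$

and the best three per locus are returned (ranked-list semantics; the
alternative of forcing distinct product-size windows was rejected as it
often leaves loci with fewer than three feasible pairs). Weights are
documented constants: 1 per bp of length deviation, 1 per °C, 0.1 per GC
percentage point.

A post-design filter, stricter than the design window, then discards pairs
with (i) products below the 100 bp floor, (ii) a homopolymer run of ≥ 4
bases in either primer (optionally also ≥ 3 tandem dinucleotide copies), or
(iii) "extreme" GC outside 40–60%. The extreme-GC band is configurable; the
default is intentionally tighter than the 20–80% design bound so that the
filter is non-vacuous.

**Melting temperature.** Tm uses the SantaLucia (1998) unified
nearest-neighbor parameters with terminal initiation corrections, the
entropy salt correction $\Delta S \mathrel{+}= 0.368\,(N-1)\ln[\mathrm{Na}^+_{eq}]$
at the von Ahsen monovalent equivalent
$[\mathrm{Na}^+_{eq}] = [\mathrm{Na}^+] + 120\sqrt{[\mathrm{Mg}^{2+}]}$
(mM), and the $R\ln(C_T/4)$ concentration term. Defaults emulate a PCR
buffer: 50 mM monovalent, 1.5 mM free Mg²⁺, 250 nM primer. Published
primers designed for a 57–61 °C window score 58.9–63.3 °C on this scale.
The Wallace rule $2(A{+}T) + 4(G{+}C)$ is available as a quick fallback.
The implementation is cross-checked in the tests against an independent
published nearest-neighbor calculator at identical conditions (agreement
well within 1 °C). Dimer and hairpin thermodynamics are out of scope.

# Diversity statistics

For allele frequencies $p_i$ at a locus with $N$ genotyped accessions:

* $N_a$ — observed alleles; $N_e = 1/\sum p_i^2$ — effective alleles;
* $I = -\sum p_i \ln p_i$ — Shannon's information index;
* $H_o$ — fraction of heterozygous accessions;
  $H_e = 1 - \sum p_i^2$ — Nei's expected heterozygosity (biased form, the
  GenAlEx default; an unbiased $2N/(2N-1)$ variant sits behind a flag);
* $F = (H_e - H_o)/H_e$ — fixation index, defined 0 for monomorphic loci;
* $PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ — Botstein's form, as
  computed by Cervus, banded low/moderate/high at 0.25 and 0.50.

Missing calls are excluded locus-wise (pairwise deletion), so per-locus $N$
varies. Allele labels are exact integer fragment sizes; no ±1 bp size
binning is applied by default. Marker screening keeps loci with
$N_a \ge 3$ and $PIC > 0.30$ (strict).

Identities used as test oracles: $N_e = k$ exactly for $k$ equally frequent
alleles; $PIC \le H_e$ whenever $N_a \ge 2$; at $p = (\tfrac12, \tfrac12)$,
$H_e = 0.5$, $I = \ln 2$, $PIC = 0.375$.

# Population structure

**Nei's (1972) standard distance** between frequency sets:
$D = -\ln\!\big(J_{xy} / \sqrt{J_x J_y}\big)$ with the identities summed
over loci. Identical sets give 0; disjoint fixed alleles give infinite
distance, reported as a flagged sentinel (a finite cap is available for
tree building). Accession-level distances treat each accession as a
frequency set with entries 0, ½, 1.

**UPGMA** is average-linkage agglomeration with node height equal to half
the merge distance, giving an ultrametric tree written as Newick. The
implementation delegates to `stats::hclust(method = "average")` and
`ape::as.phylo`, which produce exactly those branch lengths; ties follow
`hclust`'s ordering. The hand-computable three-taxon case
($d_{AB} = 2$, $d_{AC} = d_{BC} = 6$ → `((A:1,B:1):2,C:3);`) and an
independent cross-check against `phangorn::upgma` are in the tests.

**AMOVA** is the three-level hierarchical partition for codominant diploid
data — among populations, among individuals within populations, within
individuals — computed as a nested ANOVA on per-gene-copy allele indicator
vectors (equivalent to the squared-distance formulation). Degrees of
freedom are $k-1$, $N-k$, $N$; components come from expected mean squares
with the unequal-size coefficient $n_c = (N - \sum n_p^2/N)/(k-1)$;
negative components are truncated to zero by default, GenAlEx-style, with
raw values retained. With missing data, sums of squares accumulate per
locus over the individuals genotyped there while the df keep the full
design; at the low missingness simulated here the effect is negligible.
Note the standard level names: the middle level (df $N-k$) is *among
individuals within populations* and the bottom level (df $N$) is *within
individuals* — published tables sometimes swap these two row labels.

**Pairwise Fst** is $\sigma^2_{among}/\sigma^2_{total}$ from a two-level
AMOVA on the gene copies of each population pair, clipped to $[0,1]$ —
the AMOVA-based estimator (recorded in output metadata), not
Weir–Cockerham θ; published values computed with GenAlEx-style software
follow this route, but an exact numeric match to any particular program is
not guaranteed.

**Evanno ΔK** post-processes replicate log-likelihoods of an external
admixture-model run (the MCMC itself is out of scope):
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$
with the sample standard deviation; interior K with zero sd are flagged
undefined and excluded from the argmax.

# Fingerprinting

The binary matrix has one column per (locus, allele); an accession's cell
is 1 when it carries that allele. A fully missing locus contributes an
explicit missing marker to the profile key, so it cannot collide with an
all-zero observed pattern. The discrimination rate counts every member of a
shared-profile group as ambiguous: with $n$ accessions and duplicated
groups of sizes $g_1, g_2, \dots$,
$\mathrm{rate} = 100\,(n - \sum g_i)/n$. A 149-accession panel with three
duplicated pairs gives $100 \times 143/149 = 95.97\%$. Under the default
`strict` missing policy a missing locus distinguishes profiles; the
`ignore` policy wildcard-matches missing loci and links matches
transitively.

# Synthetic data

The generators define the study conditions under which all properties are
tested:

* **Reference** — scaffolds of random background sequence scrubbed of
  spontaneous repeats, with planted perfect tracts at recorded coordinates,
  breaker bases at tract boundaries (so planted tracts are exactly
  maximal), and ≥ 400 bp spacing (so none are compound).
* **Population VCF** — one InDel site per planted tract; ALT alleles are
  repeat-count expansions whose length differences exceed the 10 nt rule
  (or deliberately fall below it); 60 accessions by default, matching the
  resequencing panel size the pipeline targets; genotypes drawn under
  within-subpopulation Hardy–Weinberg; QUAL/GQ/DP drawn with known
  violation fractions so QC outcomes are predictable from the truth table.
* **Genotype matrix** — 149 accessions × 20 loci by default (the size of
  the evaluated marker panel), 3–12 alleles per locus, allele labels
  encoded as fragment sizes `base + motif_len × (repeat count − 1)`.
  Subpopulation allele frequencies follow the **Balding–Nichols** model:
  ancestral frequencies $p$ are Dirichlet(1), subpopulation frequencies are
  Dirichlet$\big(p\,(1-\theta)/\theta\big)$, so the divergence parameter
  $\theta$ is approximately the expected Fst and parameter recovery is
  directly testable. The default $\theta = 0.07$ sits mid-way through the
  0.05–0.09 pairwise-Fst range typical of weakly differentiated cultivated
  tree collections. Default missing-call rate is 1%, consistent with
  per-locus sample sizes of 145–149 out of 149 in real panels.
* **Log-likelihood tables** — a planted knee at the true cluster number
  (steep rise before, near-plateau after, small replicate noise) for ΔK
  recovery tests.

All generators take an integer seed and are bit-for-bit reproducible (R's
default Mersenne-Twister stream; one `set.seed` per generator call).

What the generators do *not* emulate: imperfect/interrupted repeats,
stepwise mutation dynamics, allele dropout and stutter in fragment calling,
linkage between loci, and inbreeding within subpopulations. Passing tests
therefore demonstrate correctness of the computations under idealised
codominant sampling, not robustness to those artefacts in real data.

# Numerical choices and degenerate inputs

* Quality thresholds are strict (> 40) for QUAL/GQ and inclusive ([5, 100])
  for DP, following the usual reading of "greater than" vs "between".
* $F$ is 0 when $H_e = 0$; PIC classification errors outside $[0,1]$.
* Nei identity is clamped to $\le 1$ before the log; a zero identity
  returns the configured cap with a `capped` attribute.
* AMOVA components are truncated at zero *after* estimation; percentages
  use truncated components and sum to 100 by construction.
* Primer enumeration is fully deterministic; ties in the ranking penalty
  break on template coordinates.
* UPGMA refuses NA or infinite distances rather than guessing.
* The locus key is the VCF record position, not the repeat's offset within
  the allele, matching the `scaffold_pos` identifier convention.

# Problem sizes

The test suite and the acceptance script run at deliberately small scales
chosen to make every stochastic check stable: 100 × 1 kb sequences for the
oracle equivalence, 2–3 scaffolds × 8 kb with 4–5 planted tracts per
scaffold for pipeline truth tables, 60-sample VCFs, 2000 accessions for the
Hardy–Weinberg recovery, 400 accessions × 50 loci for the Fst recovery,
500 accessions for the panmixia AMOVA bound, and 100 replicate tables for
ΔK. These sizes keep the full run to a couple of minutes on one CPU while
leaving comfortable statistical margins on every threshold.

# Known limitations

* Perfect repeats only; compound loci are flagged and excluded, not
  modelled.
* Fst is the AMOVA estimator; no Weir–Cockerham θ, no bootstrap CIs.
* No null-allele estimation, exact HWE tests, or linkage disequilibrium.
* Primer thermodynamics ignore secondary structure and dimers; no in-silico
  PCR against a genome.
* The admixture model itself (Bayesian MCMC) is not implemented — only the
  ΔK post-processing of externally produced log-likelihoods.
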