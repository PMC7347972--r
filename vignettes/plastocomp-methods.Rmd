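---
title: "Comparative plastome analysis with plastocomp: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`plastocomp` implements the comparative analyses that small plastid-genome
studies run on a handful of closely related species: detection of the
quadripartite LSC/IRb/SSC/IRa architecture and of the gene context at its
four junctions, auditing of the frequently pseudogenized *ndh* gene family,
codon usage and RSCU, dispersed-repeat and microsatellite discovery,
hypervariable-marker ranking from a whole-plastome alignment, and
site-level positive-selection scanning under M0/M8a/M8 codon models.  A
synthetic plastome evolver generates annotated genomes with a complete
truth log, so every stage of the pipeline can be validated without any
external sequence data.

# Structural analysis

## Inverted-repeat detection

Plastomes carry two near-identical inverted repeats.  `detect_inverted_repeat()`
uses exact 25-mer matches between the (doubled, for circular records)
sequence and its reverse complement to seed candidate anti-diagonals, then
extends the densest diagonals outward while the running mismatch fraction
stays below `max_mismatch_frac` (default 0.01).  Because a global
percentage budget would allow the extension to creep a few dozen bases of
near-random sequence past the true junction, both ends are finally trimmed
back until they terminate in a 10 bp exact-match run; a spurious overshoot
would need ten consecutive chance complement matches (probability
$4^{-10}$ per position) to survive.  With `max_mismatch_frac = 0` the
planted boundaries of synthetic genomes are recovered exactly.  The two
single-copy intervals are labeled LSC/SSC by length, and IRb is the repeat
copy that follows the LSC in genome order.

The default `min_len` of 10 kb reflects the size of real plastome IRs
(25-27 kb in the genomes this package models); reduced-scale synthetic
genomes should pass a smaller threshold.

## Junctions and the ndhF typology

`junction_report()` reports, for each of J_LB, J_SB, J_SA and J_LA, the
feature spanning the junction point (or the nearest feature within 1 kb)
and a signed overlap: base pairs of the feature inside the adjacent IR,
negative values giving the distance to the junction for non-overlapping
features.  The IRb/SSC junction types follow the *ndhF* configuration:
type 1 (*ndhF* wholly in the SSC), type 2 (*ndhF* spanning the junction),
type 3 (*ndhF* lost, the IR expanded toward *ycf1*).  A feature whose
interval merely *touches* the junction (such as the *ycf1* pseudogene
fragment ending exactly at J_SB) does not count as spanning.

## ndh audit and length relationships

`ndh_audit()` calls a gene *intact* when it is annotated as a CDS, starts
with ATG (or the GTG/ACG initiators seen in plastid genes), contains no
internal stop, and reaches 90% of a supplied reference length; *truncated*
when a feature is present but fails these checks; *lost* otherwise.
`length_regression()` is ordinary least squares with the F statistic on
(1, n-2) degrees of freedom reported alongside r-squared, because the two
printed together in comparative tables are often mutually inconsistent and
the identity $F = r^2 (n-2) / (1-r^2)$ makes the arithmetic checkable.
`ndh_ssc_correlation()` operationalizes "residual ndh content" as the
summed length of annotated ndh features intersected with the SSC — a
choice, since published analyses rarely state the exact quantity.

# Codon usage

RSCU is the observed codon count divided by its expectation under uniform
synonymous usage, $\mathrm{RSCU}(c) = n_c \, k_{aa} / \sum_{c'} n_{c'}$,
computed under the standard genetic code over all intact CDSs of a genome
(pseudogenes excluded).  Stop codons are counted but carry no RSCU; codons
containing N are skipped; internal stop codons are counted and flagged
(they arise in truncated genes).  GTG/ACG initiators are reported by
`start_codon_audit()` but are never treated as different amino acids.

# Repeats and SSRs

## Dispersed repeats

`find_long_repeats()` reports maximal repeat pairs of three classes —
forward (substring vs substring), reverse (vs the reversed substring) and
palindromic (vs the reverse-complemented substring) — with length at least
30 bp and Hamming distance at most 3, the configuration plastome surveys
run in REPuter.  All three classes reduce to plain diagonal matching
between the sequence and a transformed copy, and any admissible window of
length $\ge L$ with $\le k$ mismatches must contain an exact run of
$\lfloor L/(k+1) \rfloor$ bases (pigeonhole), so exact 7-mer seed matches
enumerate every neighborhood that can hold a hit; local mismatch walks
then recover the maximal windows.  The reported set is *exactly* the
brute-force enumeration — the test suite asserts set equality against an
independent all-diagonal oracle on dozens of random sequences.

Reported-pair conventions: a window is admissible when it carries at most
`max_mismatch` mismatches and both endpoints match; windows contained in
longer admissible windows are suppressed; on anti-diagonals,
mirror-duplicates are collapsed and a window symmetric about its center (a
perfect self-palindrome) is reported once as its two half-intervals, so
the two intervals of a hit are never identical.

## Microsatellites

`scan_ssrs()` reports maximal perfect tandem runs with the survey
thresholds 10/5/3/3/3/3 for unit lengths 1-6.  Runs whose motif is a power
of a shorter motif are suppressed (a poly-A tract is one mononucleotide
locus, never also (AA)n), and motifs are canonicalized to the
lexicographically minimal rotation over both strands, which makes locus
counts invariant to reverse complementation.  Compound or interrupted
runs are not merged; each simple run meeting its threshold counts once.
Cross-species locus grouping (`polymorphic_ssrs()`) matches canonical
motifs and requires one 20 bp flank to match within 2 mismatches; a group
is polymorphic when present in at least `k = 4` species with at least two
distinct repeat counts — both presence and length variation are required,
and `k` is exposed as a parameter.

Primer validation (`check_primer_constraints()`) applies the usual
plastome-marker rules (product 100-500 bp, primer 18-27 bp, GC 40-60%,
Tm difference at most 1 °C) with the simple salt-free approximation
$T_m = 64.9 + 41 (GC_{count} - 16.4)/\ell$; any fixed formula satisfies a
*difference* constraint reproducibly.

# Hypervariable-marker screen

From a multi-genome alignment and the reference genome's per-base
CDS/intron/IGS map, `segment_alignment()` keeps contiguous single-class
segments with ungapped reference length at least 150 bp.  Segments in
which any sequence is more than half gaps are dropped — the analogue of
requiring the locus to be present and flanked by the same regions in all
genomes; wholly deleted genes otherwise yield degenerate SV = 100%
segments.  Per segment:

* **mutations (Eta)** — the minimum mutation count, the sum over gap-free
  columns of (distinct A/C/G/T states − 1); ambiguous bases are excluded
  from the state set and gap-containing columns are handled solely by
  indel events;
* **indel events** — simple indel coding: one event per distinct gap span
  (start, end) observed in any sequence; spans sharing both endpoints
  count once, nested or overlapping spans with different endpoints count
  separately;
* **conserved sites** — gap-free monomorphic columns;
* **PIS** — gap-free columns with at least two states each carried by at
  least two sequences;
* **SV** — $100 (\eta + i) / (c + \eta + i)$, undefined (reported missing)
  when the denominator is zero.

Rates are pooled per class as events per 100 bp of reference length, kept
at full precision internally and rounded half-away-from-zero to two
decimals at presentation.  Ranking is by SV with ties broken by PIS, then
segment length, then name, so the top-k list is deterministic.

# Selection scan

## Model

The codon model is GY94-style: only single-nucleotide codon changes have
nonzero rate, transitions are scaled by $\kappa$, nonsynonymous changes by
$\omega$, and target-codon frequencies are F3x4 estimates from the data
(with a 0.5 pseudocount per position and a $10^{-8}$ floor so unobserved
codons remain reachable).  The matrix is normalized so one unit of branch
length is one expected substitution per codon site averaged over the site
classes.  Site classes: M0 has a single free $\omega$; M8 draws $\omega$
from 10 equal-probability discretized Beta(p, q) categories (category-mean
representatives computed from the incomplete beta function) with
probability $p_0$, else from an extra class at $\omega_s \ge 1$; M8a fixes
$\omega_s = 1$ and is the null for positive selection.  Likelihoods come
from Felsenstein pruning over a fixed tree with per-site scaling,
implemented in compiled code and verified against exhaustive
ancestral-state summation to $10^{-8}$.

## Fitting and tests

Branch lengths are fully optimized under M0 (together with $\kappa$ and
$\omega$, all log-transformed, bounded quasi-Newton).  M8a and M8 then
keep the M0 branch-length *proportions* and re-optimize a single
tree-scale factor jointly with $\kappa$, $p_0$, $p$, $q$ (and $\omega_s$
for M8) — the standard two-stage shortcut, which keeps replicated
calibration studies tractable without changing the hypotheses being
compared.  M8 is started both from the M8a solution (with $\omega_s$ just
above 1) and from a positive-selection start, and is anchored at the M8a
optimum so the nesting inequality $\ln L_{M8} \ge \ln L_{M8a}$ holds at
the reported optima.  The LRT statistic $2\Delta \ln L$ is clamped at zero
and referred to $\chi^2_1$ — deliberately conservative for this boundary
case (the test suite verifies empirical size $\le 0.08$ at $\alpha =
0.05$ over 100 null replicates).  Site calls use naive empirical Bayes at
the MLEs: a site is positively selected when the LRT is significant at
0.05, the posterior probability of the $\omega_s$ class is at least 0.95,
and the posterior mean $\omega$ exceeds 1.  NG86 pathway counting with
Jukes-Cantor correction (`ng86_dnds()`) is included purely as an
independent counting-method cross-check of the likelihood machinery.

Per-gene trees come from neighbor joining on K2P distances (`nj_tree()`),
with a p-distance fallback under saturation and negative branch lengths
clamped to zero; branch lengths are re-estimated under the codon model.
Gene divergence is the arithmetic mean branch length of the M0 fit.

# The synthetic plastome evolver

## What it emulates

`build_ancestor()` constructs a circular genome LSC | IRb | SSC | IRa with
IRa the exact reverse complement of IRb, a plastid-like gene map (the
11-gene *ndh* family with seven members in the SSC, *rpl22* at the
LSC/IRb junction, the *trnH-rps19* cluster and rRNA operon in the IR, two
intron-bearing genes, GTG/ACG initiators on *rps19*/*rpl2*), *ycf1*
spanning the SSC/IRa junction with its truncated mirror copy at IRb/SSC,
and planted SSR loci.  Default region lengths (33 kb / 10.3 kb / 5.6 kb)
keep the LSC : IR : SSC proportions of sequenced Bulbophyllum plastomes
at about one-third scale, so a full eight-genome simulation plus analysis
runs on a desk machine in minutes; region background GC follows the
observed ordering (IR richest, SSC poorest).  IR boundaries are made
sharp — the flanking bases break complementarity — so the planted
partition is the maximal inverted-repeat pair and detection can be tested
at ±1 bp.

`evolve()` runs the genome down a tree: substitutions are sampled as
Poisson event counts per region class and branch (rate multipliers default
to 1 : 1.38 : 2.02 for CDS : intron : IGS, the ratio of published pooled
per-100-bp mutation rates) with HKY jump probabilities at each event;
indels have geometric lengths and are restricted to non-coding single-copy
sequence (published tables show indels concentrated there, and this keeps
synthetic genomes annotatable); events sampled in IRb are mirrored into
IRa so the repeats stay identical, as in real plastomes; configured *ndh*
events delete (shrinking the SSC) or truncate (internal stop) their gene;
planted SSR loci undergo one-unit slippage per branch.  Genes under
selection evolve instead under the M8 codon mixture via
`simulate_codon_gene()` on the same tree (branch lengths scaled by 3,
since the genome process is normalized per nucleotide site and the codon
process per codon site) and are spliced in, with their per-branch
substitutions logged.  A realism note: at the default congeneric
divergence (tree length ≈ 0.055 substitutions/site) a 500-codon gene
with 10% of sites at $\omega_s = 3$ usually does *not* yield a
significant M8-vs-M8a test — most selected sites accumulate zero or one
change, and the likelihood at the generating parameters can sit below
the M8a optimum.  This mirrors the practical situation in shallow
plastome studies, where detectable site-level selection is confined to
the longest, fastest genes.  Planted repeat and SSR loci are
shielded from further point mutation so their truth coordinates stay
exact; slippage is the only process that moves them.

## Truth log and alignment bookkeeping

Every base of the ancestor carries a stable numeric column key; insertions
interpolate new keys (with a tiny jitter to keep keys from independent
lineages distinct).  The true alignment is materialized by placing every
leaf's (and the ancestor's) bases at their keys, which guarantees the
degapping invariant: removing gaps from any row reproduces that genome's
sequence byte-for-byte.  The truth log also carries per-branch event
lists, per-leaf SSR states, planted-repeat coordinates, and per-site true
$\omega$ classes for selection genes.

## What the simulator does not model

No rearrangement or recombination, no IR expansion/contraction as a
stochastic process (junction movement enters only through configured gene
events), no rate heterogeneity within a class, no sequencing or assembly
error, and no base-composition evolution.  Passing tests on simulator
output therefore demonstrate correctness of the statistics and detectors
under a clean generative model, not robustness to misassembly or
annotation error in real data.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at the following sizes, chosen to exercise every code path on one CPU in
minutes: an eight-leaf clade over a ~59 kb quadripartite ancestor for the
structural, SSR, and variability stages; 3-4-taxon, 30-40-codon toys for
exhaustive-likelihood comparisons; 4-taxon, 80-codon genes for the
100-replicate LRT size study; 8-taxon, 200-codon genes for the
20-replicate M8 recovery study (the percentile interval of the replicate
estimates of $\omega_s$ and $p_0$ brackets the generating values — at
these sizes the $(p_0, \omega_s)$ profile is ridged, so individual MLEs
scatter widely and only the ensemble is informative).  Optimizer settings
(L-BFGS-B, `factr = 1e9`, at most 100 iterations, parameters
log/logit-transformed with wide box bounds) trade a few hundredths of a
log-likelihood unit for a large constant-factor speedup; the LRT
conclusions are insensitive at this tolerance.  Degenerate inputs are
handled explicitly: empty intervals, zero-variance regressions and
correlations, saturated K2P distances, zero-length branches, and
denominator-zero SV all either error informatively or return missing
values rather than NaN.
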