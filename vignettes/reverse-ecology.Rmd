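---
title: "Reverse-ecology trait inference: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-ecology trait inference: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reveco)
```

Uncultivated archaea and bacteria leave no growth curves to measure, but
their genomes carry compositional fingerprints of the environments they
grew in. `reveco` implements a desk-scale version of that reverse-ecology
programme for metagenome-assembled genomes (MAGs): temperature preference
from amino-acid composition, intracellular pH regime from proteome
isoelectric points, lineage-aware marker-based genome quality control,
proteome relatedness by average amino-acid identity (AAI), and the
projection of the composition traits backwards in time over a phylogeny.
This vignette explains each model, the tunable parameters and their
defaults, the synthetic-data generator the test-suite rests on, and the
numerical choices made where the design was genuinely open.

## Temperature from composition: the IVYWREL estimator

Across prokaryotes the summed frequency $F$ of seven residues — Ile, Val,
Tyr, Trp, Arg, Glu, Leu (IVYWREL) — correlates linearly with optimal
growth temperature (OGT). `ogt_from_ivywrel()` applies the affine map

$$\widehat{\mathrm{OGT}} = 937\,F - 335 \quad [^\circ\mathrm{C}],$$

the published proteome-wide fit of that correlation. Both coefficients
are arguments, because recalibrations of the estimator on other genome
sets shift them slightly; the defaults are what you get when you cite
the original regression. The estimator is a single linear functional of
composition: it is exactly affine (tested as a property), and its whole
uncertainty budget is the scatter of the underlying regression (±~10 °C
on real proteomes), not the solver.

Two companion fractions are reported with it because they carry the same
thermal signal: the Arg+Glu fraction (`f_re`, salt-bridge stabilisation)
and the proline fraction (`f_p`, backbone rigidity).

All composition arithmetic first strips the ambiguous residue codes
B, J, O, U, X, Z and `*` from both numerator and denominator, so
frequencies always sum to 1 over the counted residues. That rule is the
simplest one that keeps denominators predictable across annotation
pipelines with different ambiguity habits.

## Intracellular pH regime: pI profiles, the trough, and pI bias

The isoelectric point of a protein is the pH at which its
Henderson–Hasselbalch net charge

$$Q(\mathrm{pH}) = \sum_{g\,\mathrm{basic}} \frac{n_g}{1+10^{\mathrm{pH}-pK_{a,g}}}
\;-\; \sum_{g\,\mathrm{acidic}} \frac{n_g}{1+10^{pK_{a,g}-\mathrm{pH}}}$$

crosses zero, counting one N- and one C-terminus per chain and the
ionizable side chains D, E, C, Y (acidic) and K, R, H (basic). $Q$ is a
sum of strictly decreasing terms, so the root is unique and bisection on
$[0, 14]$ is guaranteed to converge. `protein_pi()` iterates until the
net charge is within `tol` (default $10^{-4}$ charge units) *and* the
bracket is narrower than $10^{-6}$ pH units; the bracket condition
matters because on long flat stretches of $Q$ — large proteins buffered
far from any pKa — the charge criterion alone can stop visibly short of
the root.

Two pKa tables ship with the package and the choice is explicit
everywhere (`get_pka("ipc")`, the default, versus `get_pka("emboss")`).
Computed pI values differ by roughly 0.2–0.5 pH units between tables,
which is larger than the solver error by three orders of magnitude: the
table, not the root-finder, is the decision that matters. The IPC-style
constants are the default because they were optimised against large
curated protein pI sets.

Whole proteomes have characteristically *bimodal* pI distributions —
proteins are unstable near their pI, so few sit close to the
intracellular pH. The package exploits that structure: `pi_trough()`
fits a Gaussian kernel density (Silverman's bandwidth) on a fixed grid
of step 0.01 over $[0, 14]$ and takes the density minimum between the
two highest local maxima, restricted to a search window of pH 4–10.
Local maxima below 5 % of the peak density are ignored — they are grid
artefacts in flat tails, not modes. When the density is unimodal, or
fewer than 10 pIs are available, the detector falls back to a fixed
breakpoint of 7.0 and flags it, so downstream statistics are always
defined.

The partition at the trough yields the **pI bias**,

$$\mathrm{bias} = \frac{n_\mathrm{basic} - n_\mathrm{acidic}}{n_\mathrm{basic} + n_\mathrm{acidic}} \in [-1, 1],$$

with ties at the breakpoint counted acidic so the partition is
deterministic. Positive bias means basic proteins predominate — the
signature of a circumneutral intracellular milieu and hence of
acid-*tolerant* rather than acidophilic physiology; strongly negative
bias is the acid-shifted proteome of organisms that run their cytoplasm
acidic. The proportion-difference form is the simplest statistic with
the required sign semantics and the antisymmetry property (reflecting
all pIs about the breakpoint flips the sign), which the tests assert.
The per-genome `average_pi` is the arithmetic mean over all proteins
with a defined pI, not a per-category mean.

## Genome features

`genome_features()` reports size, GC (ambiguous bases excluded from the
GC denominator only), CDS count, coding density and the
overlapping-gene ratio. Two definitions are worth making explicit
because the field often leaves them implicit:

* **coding density** is the union length of all CDS intervals, strands
  merged first, divided by genome size — a per-base property, invariant
  to how genes are split into adjacent records;
* **overlapping-gene ratio** is the fraction of genes sharing at least
  one base with at least one other gene on the same contig,
  strand-agnostic.

Coordinates are 1-based inclusive (GFF convention) at every interface.
`size_cds_regression()` is ordinary least squares of CDS count on
genome size — the streamlining diagnostic: in reduced genomes, size
differences are explained almost entirely by gene count. The regression
direction (count on size) follows the axis convention of the
genome-feature comparison this reproduces.

## Lineage-aware marker QC

Universal single-copy marker sets overestimate incompleteness in
lineages that have genuinely *lost* markers. The QC stage therefore
derives, per genus, the set of markers absent from **every** member
genome (`derive_exclusion()`), removes them from the expected set
(`adjusted_set()`), and scores

$$\mathrm{completeness} = 100\cdot\frac{\#\{\mathrm{markers\ with\ count} \ge 1\}}{|\mathrm{set}|},
\qquad
\mathrm{contamination} = 100\cdot\frac{\sum \max(\mathrm{count}-1, 0)}{|\mathrm{set}|}.$$

A marker missing from only some members stays in the expected set —
that absence is evidence of incompleteness, not lineage history.
Contamination uses the per-marker excess-copy form; it does not
reproduce CheckM's collocated-marker-set weighting, which belongs to
the gene-calling machinery upstream of this package. Completeness is
monotone under exclusion of absent markers (a tested property), and a
genome whose only missing markers are genus-universal absences scores
exactly 100 % after adjustment.

The curated per-genus exclusion lists for the
Jingweiarchaeales/Parvarchaeales genera ship in
`parvarchaeales_exclusions.txt` (blocks: 9 shared ids, and 9/21/29/24/17
ids for Jingweiarchaeum, Haiyanarchaeum, Rehaiarchaeum,
Acidifodinimicrobium and Parvarchaeum respectively). The companion
149-id marker file is **synthetic**: it contains the 34 distinct
published exclusion accessions plus labelled filler ids, enough to
exercise the set arithmetic; for real QC, substitute a curated archaeal
roster. `quality_tier()` applies MIMAG-style thresholds (high:
$\ge 90\,\%$ complete, $< 5\,\%$ contamination, both rRNAs, $> 18$
tRNAs; medium: $> 50\,\%$ complete, $< 5\,\%$ contamination); rRNA and
tRNA presence are inputs, never detected here.

## AAI from reciprocal best hits

Orthologs are defined operationally as reciprocal best hits (rBBH):
protein pairs that are each other's highest-scoring match across two
proteomes, under Smith–Waterman local alignment with BLOSUM62 and
affine gaps (open 11, extend 1). AAI is 100 × the mean alignment
identity over rBBH pairs, with identity counted as matches over all
alignment columns, gaps included.

BLAST's E-value screen is replaced by a raw-score threshold (default
50) plus a coverage filter (the alignment must span at least half of
the shorter sequence). Karlin–Altschul statistics would add a database
dependence without changing which pairs are reciprocal best at desk
scale; the thresholds are configurable in `aai_filters()` and are
declared substitutes, not reconstructions of any particular BLAST
configuration. For tractability, candidate subjects are ranked with
score-only alignments and full alignments are computed only down the
rank order until the coverage filter passes; ties are broken by
lexicographically smallest subject id so results are reproducible to
the byte. Self-AAI is 100, the matrix is exactly symmetric (each pair
computed once), and AAI decreases monotonically with the generator's
substitution rate — all tested.

## Ancestral states under Brownian motion

Continuous traits (OGT, average pI, pI bias) are modelled as Brownian
motion on a rooted tree: along a branch of length $t$ the trait change
is $N(0, \sigma^2 t)$. Felsenstein's pruning recursion turns the tips
into $n-1$ independent contrasts; the rate is estimated as
$\hat\sigma^2 = \mathrm{mean}(u_i^2)$ over standardized contrasts $u_i$
(the REML form, invariant to the rooting), and the ML state at an
internal node equals the ML root estimate of the tree re-rooted at that
node.

`anc_ml()` computes all node estimates in one $O(n)$ double pass — a
downward pruning pass, then an upward pass propagating the complement
of each subtree — rather than physically re-rooting $n-1$ times. The
variance of the estimate at a node is $\hat\sigma^2$ divided by the
combined precision of the downward and upward messages, and 95 %
intervals are $\pm 1.96$ standard errors. The equivalence to explicit
re-rooting, to brute-force maximisation of the joint BM likelihood on
small trees (tolerance $10^{-6}$), and to an independent reference
implementation of the same re-rooting scheme are all asserted in the
tests, as are affine equivariance and the shrinking root error on
growing trees at fixed height.

Polytomies are resolved to binary with zero-length branches, and any
non-positive branch length is floored at $10^{-8}$ × tree height —
contrasts need strictly positive expected variances, and the floor is
small enough to leave estimates unchanged at printing precision. Only
BM is implemented: no trend, no Ornstein–Uhlenbeck pull, no
rate-smoothing — matching the scope of the analysis this package
supports, where the tree and tip traits are strictly inputs.

## The synthetic-data generator

Every input class has a generator that records the latent truth it
embeds, so each stage can be scored against ground truth without
downloads:

* `gen_proteome()` — i.i.d. residues with controllable weights; the
  degenerate, uniform and law-of-large-numbers cases anchor the
  composition arithmetic.
* `gen_bimodal_proteome()` — a two-component mixture (D/E-enriched vs
  K/R-enriched, default tenfold over uniform) with the true class per
  protein, emulating the bimodal pI structure of real proteomes.
* `gen_diverged_pair()` — per-residue substitution at a set rate,
  always to a different residue, reporting the realized identical
  fraction exactly; the AAI calibration target.
* `gen_marker_table()` — exact completeness/contamination targets by
  construction (`round(c·|set|)` present, `round(x·|set|)` duplicated).
* `gen_tree()` + `simulate_bm()` — balanced or random-split topologies
  with U(0.1, 1) branch lengths and exact Gaussian BM increments (no
  Euler discretisation), recording every internal node's true state.
* `gen_annotations()` — interval layouts hitting a requested
  overlapping-gene fraction exactly, via clusters of two (plus one
  triple for odd targets).

All generators are pure functions of their parameters including the
seed (`withr::with_seed`; no global RNG state leaks), and determinism
is tested at the byte level through the pipeline's TSV outputs.

What the generator does *not* emulate matters for interpretation: real
proteomes are not i.i.d. residue strings (no domain structure, no
length–composition correlation), real marker absence is phylogenetically
correlated rather than uniformly random, real orthology is confounded by
paralogy and gene loss, and real traits did not evolve by exact BM.
Passing tests therefore demonstrate that the *estimators implement
their definitions* and are calibrated under their own generating models
— not that those models capture every property of field data.

## Problem sizes and numerical choices

The validation workloads are sized for a laptop-class single core:
1 000 random proteins against a $10^{-4}$-step grid-scan oracle for the
pI solver; 100 random trees of 3–6 tips against brute-force likelihood
maximisation; 500 replicates on a 64-tip tree for root CI coverage
(nominal 0.95) and contrast variance (nominal 1); 100 proteins × 100
residues (10 kaa) per divergence level for AAI calibration at
substitution rates 0.05/0.10/0.20. Degenerate inputs are handled
explicitly rather than by accident: empty proteomes error (or warn, for
the documented `n = 0` case), proteins without ionizable groups get
`NA` pI and are counted, unimodal pI densities fall back to a flagged
breakpoint at 7.0, and zero reciprocal best hits yield an `NA` AAI with
a warning rather than a silent 0.

## Group comparisons

`group_compare()` applies the unpaired two-sample Wilcoxon rank-sum
test to every pair of groups with Benjamini–Hochberg correction and
derives compact letter displays (maximal cliques of the
not-significantly-different graph) at a default $\alpha$ of 0.005.
Genera are independent samples, so the rank-sum variant is the coherent
choice even where a signed-rank test is named in casual usage; the
default $\alpha$ is deliberately conservative and both it and the
adjustment method are arguments.

## Known limitations

* The OGT map is a fixed affine estimator; it inherits the scatter and
  taxon bias of the regression it implements and is not a trained
  predictor.
* pI values are sequence-only: no structural pKa shifts, no
  post-translational modifications.
* Contamination scoring ignores marker collocation.
* The shipped 149-id marker file is a synthetic scaffold around the 34
  published exclusion accessions, not a curated marker roster.
* rBBH orthology degrades with paralogy; the score/coverage filter is a
  declared substitute for E-value screening.
* Ancestral reconstruction assumes the tree and its branch lengths; no
  uncertainty in the phylogeny propagates into the node CIs.
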