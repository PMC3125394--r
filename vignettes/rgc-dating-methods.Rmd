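---
title: "Dating deep divergences with rare genomic changes: models and methods"
author: "rgcclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating deep divergences with rare genomic changes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcclock)
```

## The character and the model behind it

A rare genomic change at a conserved amino acid (RGC_CA) is an alignment
column with a very specific shape. Given a set of ingroup taxa (here,
eukaryotes) and a polarising outgroup (prokaryotes):

* every outgroup taxon carries the same residue, X;
* the ingroup carries exactly two residues, X and one other residue Y;
* the Y-bearing taxa form a nonempty strict subset of the ingroup.

Because the outgroup is unanimous, X is taken as the ancestral state and
the Y-bearing set as the carriers of a single derived replacement that
occurred on the branch subtending them. Replacements are further
classified by the minimal number of nucleotide substitutions the genetic
code requires to turn a codon of X into a codon of Y (1, 2 or 3); the
stricter RGC_CAM variant keeps only classes 2–3, trading character count
for an even lower chance of parallel origin.

Polarisation here is purely by the outgroup: the derived subset may be a
majority of the ingroup (a replacement on a deep branch such as the
opisthokont stem produces exactly that pattern). An option
(`max_derived_fraction`) restores a strict-minority rule for users who
want the more conservative reading.

Two assumptions drive everything downstream:

1. **Rarity.** At positions conserved across outgroup and most of the
   ingroup, accepted replacements are rare, so two independent origins of
   the same residue at the same position are unlikely — most characters
   are homoplasy-free.
2. **Approximate strict clock.** The number of such replacements
   accumulating on a branch is proportional to the branch's duration.

Neither assumption is taken on faith; the mapping stage measures the
homoplasy level, and the diagnostics stage measures clocklikeness.

## Reliable positions

Alignment columns near indels are untrustworthy. A column is *reliable*
when no analysed taxon has a gap within `flank` (default 5) columns on
either side of it, and the whole window fits inside the alignment, so a
13-column gap-free alignment has reliable columns 6–8 (1-based) only.
Columns containing ambiguity codes (X, B, Z, ...) in any analysed taxon
are additionally unusable for detection, since an ambiguous state cannot
be polarised. This is deliberately the strictest reading of a
window rule: truncated windows at the alignment ends disqualify a
position, and the rule is applied over *all* analysed taxa, outgroup
included.

## From characters to branch lengths

Each detected character is defined by its derived taxon set. On a rooted
species tree, the character is *compatible* if that set is exactly the
tip set of one branch's clade, and it then adds one unit to that branch's
length; otherwise it is *incompatible* — evidence of homoplasy (a
parallel change or reversal). The bookkeeping identity

    compatible + incompatible = total characters

holds on every run and is asserted by the tests. The homoplasy fraction
`incompatible / total` is the empirical check of the rarity assumption;
under the default simulation conditions it sits near 15%. Because
polarity is fixed by the outgroup, a derived set equal to the complement
of a clade is still incompatible: there is no reversal rescue.

Columns with more than two ingroup states never become characters; they
are tallied separately (`count_state_distribution()`), and the two-state
fraction (~84% under the default conditions) measures how often candidate
positions behave as genuine two-state rare changes.

## Strict-clock parsimony dating

On an ultrametric time tree, the expected number of characters on the
path from an internal node down to any descendant tip is (rate × node
age), independent of the tip chosen. Hence for a calibration node with
fossil date Tc and a target node, the estimator

    Te = Tc × K(target → tip) / K(calibration → tip)

recovers the target's age, for any choice of the two descending tip
paths. Each (calibration, calibration tip, target tip) combination gives
one estimate; the package enumerates all of them and reports
mean/median/sd/min/max per target. The estimator satisfies, and the
tests assert:

* **self-calibration identity** — estimating a calibration's own node
  returns Tc exactly, for every path;
* **scale equivariance** — rescaling all Tc rescales all Te;
* **exactness** — if counts equal rate × duration exactly, every
  estimate equals the true age, with zero spread.

The parsimony estimator uses calibration *points*; an interval endpoint
can be substituted (the `Tc` argument of `estimate_age()`) to produce an
estimate band. Zero-count calibration paths make the ratio undefined;
such combinations are skipped and reported, never imputed.

Cross-validation guards against a bad fossil anchor: each calibration in
turn is withheld and its node re-dated from the others; the discrepancy
ΔTc = |Tc − Te^c| flags anchors inconsistent with the clock implied by
the rest. Clock diagnostics correlate node-to-tip path counts with the
midpoints of the calibration intervals; a Pearson r near 1 supports the
clock assumption. A comparator (`clock_diagnostics_pdist()`) runs the
same correlation with a plain proportion-of-differences distance, which
is typically less linear than the RGC_CA counts — the motivation for
using rare changes in the first place.

## The synthetic-data generator

Real inputs for this analysis are genome-scale ortholog alignments,
which are neither small nor redistributable. The generator therefore
produces datasets with the statistical structure the analysis assumes,
plus complete ground truth, and is the substrate for every quantitative
test.

The generative model, per gene:

* a random ancestral residue per column; invariant columns are identical
  across all taxa, outgroup included;
* a fixed set of *eligible* sites (65% of columns by default, placed in
  the reliable interior) may change; the total number of changes per gene
  is Poisson with mean λ × eligible sites × total tree duration, and each
  change lands on a branch with probability proportional to the branch's
  duration — equivalent to independent per-branch, per-site Poisson
  counts;
* each change gets its own site (sampling without replacement), and the
  derived residue is drawn at a genetic-code distance sampled from
  `class_probs` (default 0.70/0.25/0.05 favouring single-nucleotide
  replacements);
* with probability `h` (default 0.15) the same derived residue is also
  planted on a second branch whose clade is disjoint from the first and
  does not complete the whole ingroup — the resulting character is
  incompatible by construction, making homoplasy ground truth
  unambiguous;
* with probability `m` (default 0.16) a *different* derived residue is
  planted on another disjoint branch, producing a ≥3-state column that
  detection must reject; the expected two-state fraction is 1 − m;
* codon rows are generated alongside: the ancestral codon is a random
  codon of the ancestral residue, and each derived residue receives a
  codon of minimal Hamming distance from it.

Giving every change its own site is what makes two invariants exactly
attainable: with `h = m = 0`, detection recovers the planted character
set perfectly and mapping reports zero incompatible characters. A
with-replacement process would produce a small, uncontrolled background
of site collisions on top of the controlled h and m.

Optional layers test the filters rather than the estimator: `gap_prob`
injects indels to exercise the reliable-window rule; `outgroup_noise`
scatters outgroup residues to exercise the unanimity rule; and
`saturated_fraction` converts a fraction of sites into fast-evolving
two-residue sites where every taxon draws independently. Saturated sites
are how the outgroup-size experiment becomes emergent: with 10 unanimous
outgroup taxa almost none of them slip through the filter, while with 5
they do at ~30× the rate and contribute tree-incompatible characters, so
the measured homoplasy fraction rises as the outgroup shrinks (in our
runs, from ~15% at 10 outgroup taxa to ~22% at 5).

### Default study conditions

The default configuration encodes the conditions of the analysis the
package reimplements: a 20-taxon dataset (10 eukaryotes — human, chicken,
fly, mosquito, nematode, two yeasts, two angiosperms, moss — and 10
prokaryote outgroup taxa) on the coelomate topology, with node ages
LECA 1130, opisthokonts 949, bilaterians 619, monocot–dicot 339,
moss–angiosperm 450, human–chicken 370 and fly–mosquito 260 Mya, and the
three fossil calibrations 260 (250–260), 450 (430–450) and 370 (310–370)
Mya. The two internal nodes no published date constrains — the
fission–budding yeast split and the vertebrate–arthropod (coelomate)
split — are set to 500 and 550 Mya, round mid-range values consistent
with the neighbouring dated nodes; they affect only how characters
distribute among nearby branches, not the target ages themselves.

The rate λ = 9.5 × 10⁻⁶ per eligible site per My is fixed so that the
expected number of detected characters, λ × 26,000 eligible sites ×
6,297 My of total branch duration × (1 − m), is ≈ 1300 at the default
problem size of 100 genes × 400 sites. That size keeps a full
simulate–detect–map–date cycle around five seconds, so the test suite
can afford replicated end-to-end experiments; the same rate at a larger
gene count only narrows the sampling error, as the quadrupled-rate
recovery test verifies.

### What passing tests do and do not show

The generator emulates the *statistical* structure of the real data:
rarity, outgroup polarisation, clocklike accumulation, controlled
homoplasy and multi-state contamination. It does not emulate
misalignment, gene-specific rate variation (all genes share one λ),
site-rate heterogeneity beyond the binary eligible/invariant split,
lineage effects (the clock is exactly strict in expectation), annotation
errors, or orthology mistakes — several of which are the dominant error
sources on real genomes. Parameter-recovery results on synthetic data
therefore validate the estimator and its implementation, not the
biological accuracy of any particular published date.

## Numerical and design choices

* **Path-rate comparison.** `compare_paths(k1, k2)` uses the
  1-degree-of-freedom chi-square goodness-of-fit of the two counts
  against equal expectations, without continuity correction (equivalently
  a two-sided normal z on the difference); for the genome-wide path
  lengths 123 vs 118 this gives p = 0.75. The exact binomial test is
  available as an option and agrees closely at these counts.
* **Codon distances.** The class of a replacement defaults to the
  code-wide minimum over all sense-codon pairs (stop codons excluded);
  when a codon layer is present, `codon_strict = TRUE` uses the observed
  Hamming distance between the aligned codons instead. The code-wide
  minimum is the default because the character is defined at the
  amino-acid level.
* **Coordinates.** Column indices are 1-based everywhere, matching R and
  the common alignment viewers.
* **Ties and degenerate input.** Empty character sets map to a summary
  with total 0 and an undefined (NA) homoplasy fraction; a derived set
  equal to the whole ingroup is never a character; identical residues are
  not a substitution (class 0 is an error, not a class).
* **Cross-validation pooling** uses the mean of the withheld node's
  estimates. The corrupted-calibration experiment in the acceptance
  tests corrupts the *vertebrate* anchor, whose long terminal branch
  makes it the natural analogue of a problematic fossil calibration.
* **Clock-diagnostic replicates** use calibrations at every dated
  internal node of the study tree (nine nodes, 37 pairs), the analogue of
  a many-calibration analysis; with only the three fossil anchors the
  midpoints 255/440/340 are not an affine function of the node ages
  260/450/370, which caps the achievable correlation and makes a
  three-anchor r an unstable statistic.

## Known limitations

* Only binary compatible/incompatible mapping is provided; there is no
  probabilistic treatment of multi-hit characters.
* The tree is user input; no inference or rooting is attempted, and the
  estimator is only as good as the local topology around the calibration
  and target nodes.
* The strict-clock estimator inherits the usual ratio-estimator bias
  (upward by roughly 1/K for a calibration path of K characters), visible
  as a percent-level overestimate at the default scale.
* Estimate pools from different calibrations overlap in the branches they
  count, so the reported sd understates the true uncertainty of the
  pooled mean.

## A worked run

```{r example, eval = FALSE}
cfg <- default_study_config(seed = 42)
sim <- simulate_dataset(cfg)
chars <- detect_characters(sim$alignments, sim$roles)
counts <- branch_lengths(chars, study_time_tree())
counts
est <- all_estimates(counts, study_calibrations(), study_targets())
summarize_estimates(est)
cross_validate(counts, study_calibrations())
```

At seed 42 this detects 1295 characters, maps 1113 of them (homoplasy
14.1%), and the pooled means land within a few percent of the generating
ages (LECA 1106, opisthokonts 915, bilaterians 594, monocot–dicot 323
versus the true 1130/949/619/339).
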