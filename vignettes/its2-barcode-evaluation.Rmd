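---
title: "Evaluating ITS2 as a DNA barcode: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ITS2 as a DNA barcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2eval)
```

## The problem

The internal transcribed spacer 2 (ITS2) of the nuclear ribosomal cistron is
a short, variable locus flanked by strongly conserved gene segments (the
5.8S tail upstream, the 28S head downstream). Those properties make it a
candidate DNA barcode: the conserved flanks support universal primers and
reliable delimitation, while the variable core carries enough signal to
separate closely related species. Evaluating a barcode locus involves four
steps, and this package implements each of them as a testable module:

1. **Delimitation (annotation).** Locate the conserved anchors on each raw
   amplicon and trim the sequence to the core between them.
2. **Curation.** Remove records that cannot support the analysis: too-short
   fragments, ambiguity-riddled sequences, unnamed species, genera in which
   no congeneric comparison is possible, and suspected fungal contaminants;
   then build a per-species consensus reference.
3. **Divergence.** Quantify the separation between intra-specific variation
   and inter-specific divergence with Kimura two-parameter (K2P) distances —
   the "barcoding gap" that distance-based identification relies on.
4. **Identification.** Score species assignment with the top-hit rule: a
   query is assigned to the species of its highest-scoring database hit, a
   tie across species leaves it ambiguous.

Because the published evaluations of this kind run on tens of thousands of
GenBank sequences that cannot be bundled or re-downloaded reproducibly, the
package ships a seeded simulator that generates taxonomically structured
datasets with known ground truth. Every claim the test suite makes is a
claim about behaviour on data whose true structure is known exactly.

## The synthetic data generator

`simulation_params()` describes a nested taxonomy (groups, families, genera,
species, sequences per species) and a substitution regime. Sequences evolve
under a continuous-time K2P process with transition/transversion rate ratio
`kappa` (default 2), simulated per site from the closed-form transition
probabilities of the chain, with rates scaled so that a branch of length
*t* carries *t* expected substitutions per site. The simulated truth is
therefore directly commensurable with the K2P distances the divergence
module estimates.

**Genealogy.** Within each genus the tree is an ultrametric star-within-star:
one ancestral core per genus, species ancestors at depth `inter_branch`
below it, and every sequence at depth `intra_branch` below its species
ancestor. Two conspecific sequences are therefore separated by `2 *
intra_branch` expected substitutions per site and two congeneric
heterospecific sequences by exactly `2 * inter_branch`. We chose this
parameterisation (rather than adding the sequence-level branches on top of
full-length species branches) because it gives the two headline expectations
a clean closed form — the estimator checks in the test suite compare pooled
congeneric K2P against `2 * inter_branch` directly. A nested coalescent
would be more realistic but would make the truth a distribution rather than
a number; with real genealogies unknown anyway, the star tree is the
simplest structure that realises "inter exceeds intra".

**Defaults.** Cores are drawn at `gc_target = 0.55` GC (inside the 48–65%
band typical for this locus) and 400 nt long (the locus runs roughly
100–700 nt; 400 nt sits in the upper-middle of the reported averages and
keeps distance estimates reasonably tight). Each record carries one
canonical 30-nt 5.8S-tail and 28S-head copy with 2% per-site noise — anchors
are conserved but not invariant in real data. Branch depths default to
`intra_branch = 0.01`, `inter_branch = 0.2`, matching the regime in which
inter-specific divergence clearly exceeds intra-specific variation. The
substitution process is stationary at uniform base frequencies, so GC
content drifts slightly toward 0.5 with depth; at the default depths the
drift is about 1.5 percentage points, well inside the ±3% tolerance the
tests assert.

**Degenerate records.** `inject_degenerates()` reproduces the record classes
the curation filters target, each tagged with its intended reject reason:
truncation below 100 nt, three or more N bases, species labels carrying the
literal "sp."/"aff." tokens, and replacement by a fungal decoy drawn from a
separate high-divergence pool that shares a conserved fungal anchor motif
(so both screening routes can find it). The generator does **not** simulate
indels, secondary structure, or ITS paralogy/intra-genomic copy variation —
multi-copy behaviour is documented in the literature but comes with no
quantitative model we could implement honestly. Consequences: passing tests
demonstrate correctness of the machinery under substitution-only evolution
with a clean single-copy locus; they do not certify performance on
paralogous or heavily gapped real data.

## Annotation: profile models and E-values

`build_profile()` turns a gapped alignment of a conserved segment into a
position-specific scoring model. Columns with gap fraction above 0.5 are
dropped; emissions are pseudocount-smoothed counts,
`(count + pc * background) / (residues + pc)`, scored as log-odds against
the background. `scan_profile()` aligns the whole model against a local
window of the target (glocal Viterbi with affine gap penalties, default
−4/−1 bits) — the anchors are short and expected in full, so a partial-model
mode would only blur the boundary. Ties in the optimum resolve to the
leftmost lowest-start window, for reproducibility. The ITS2 interval is the
region strictly between the 5.8S hit end and the 28S hit start, in 0-based
half-open coordinates; a missing anchor or inverted order is a status, not
an error, and a one-sided anchor never yields a guessed boundary.

**E-value calibration.** Significance is calibrated per target: the model is
scanned against `n_shuffle` (default 200) seeded shuffles of the target,
and a Gumbel distribution is fitted to the null best scores by the method
of moments (`lambda = pi / (sd * sqrt(6))`, `mu = mean − gamma / lambda`).
The reported E-value is scaled to the calibration ensemble,
`E = n_shuffle * exp(−lambda * (S − mu))`, i.e. the expected number of
targets in the shuffle ensemble reaching the observed score. This is a
deliberately conservative scaling: the best score of an unrelated random
sequence is itself a draw from the null, so an unscaled per-target Gumbel
would put its E-value near 1 about two-thirds of the time, making the
conventional acceptance threshold E ≤ 1.0 meaningless for rejecting junk.
Under the ensemble scaling an unrelated sequence scores E ≤ 1 with
probability about `1 − exp(−1/n_shuffle)` ≈ 0.005, while a genuine anchor
(tens of bits above the null) still scores E values that are practically
zero. The calibration seed is an explicit argument; fixed seed means
bit-identical E-values.

## Curation

`apply_filters()` applies the rules in a fixed order — length, N count,
species-name tokens, genus occupancy — and reports the first failing rule
as the rejection reason, so provenance is reproducible no matter how the
rules overlap. Both thresholds read inclusively on the keep side: exactly
100 nt and exactly 2 Ns survive. The genus-occupancy rule is evaluated on
the set surviving the first three rules, which makes the result independent
of record order; the unnamed-species tokens are "spp." and "aff." plus the
singular "sp." as an obvious extension, matched case-insensitively. The
length filter applies to the trimmed core (trimming precedes curation in
the pipeline), since a flank-inflated length says nothing about the usable
barcode.

Fungal screening reports its two routes separately — a profile-model hit at
E ≤ `fungal_max_evalue` and a best local-alignment similarity of at least
`fungal_min_identity` against the fungal reference set — because suspected
counts, not silent deletions, are the observable of interest; dropping is
an explicit configuration choice. Similarity is defined as the fraction of
query positions matched in the best local alignment: a short spurious local
hit on an unrelated sequence scores low by this measure, while a true decoy
aligns nearly end to end, and a value of 1.0 demands an exact full-length
match.

Per-species consensus barcodes are built by center-star alignment around
the longest conspecific record followed by column majority vote; ties
become the IUPAC code of the tied set (information-preserving and standard
in consensus building) and majority-gap columns are dropped. An
assembly-based consensus would demand chromatograms the data do not have;
for same-species ITS2 clusters the center-star merge is deterministic and
dependency-free.

## Divergence statistics

All distances are K2P on optimal pairwise global alignments
(Needleman–Wunsch, affine gaps, defaults match +1 / mismatch −1 /
gap open −5 / extend −1 — conventional DNA scoring, configurable). We
compute distances per pair rather than from a per-group multiple alignment:
pairwise optimal alignment is deterministic, and the distance definition is
itself pairwise. Columns where either residue is a gap or an N are excluded
from the transition proportion `P` and transversion proportion `Q`;
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`. Saturated pairs (a non-positive
log argument) are flagged invalid and excluded from every mean with a
logged count — clamping them to a ceiling would fabricate a number.

The six summary statistics split three-by-three:

| statistic | sample | averaging |
|---|---|---|
| all intra-specific distance | conspecific pairs | pooled |
| theta | per-species mean conspecific distance | unweighted over species |
| coalescent depth | per-species maximum conspecific distance | unweighted over species |
| all inter-specific distance | congeneric heterospecific pairs | pooled |
| theta prime | per-genus mean heterospecific distance | unweighted over genera |
| minimum inter-specific distance | per-species minimum to a congeneric heterospecific | unweighted over species |

The pooled/"per-taxon unweighted" distinction is stated explicitly because
the three-plus-three parameter scheme implies it without giving formulas.
Standard deviations divide by *n* (population style) and are taken over
each statistic's own sample — the pooled pair set for the "all" variants,
the per-taxon values for the others — so the output table carries both
flavours side by side rather than guessing which one a published table
used. `coalescent_depth >= theta` holds on every dataset (a maximum
dominates a mean before averaging), and the two pooled/unweighted intra
variants coincide exactly when every species contributes the same number
of pairs; both facts are asserted in the tests.

## Identification

`similarity_search()` scores the query against every non-excluded database
record by affine Smith–Waterman with the same scoring configuration as the
distance module, so similarity rankings and distance rankings cannot
disagree about what "closest" means. Ordering is deterministic (score
descending, id ascending) and ties share rank 1. The tie tier is exact
score equality, not a score window — the trichotomy outcome demands a crisp
criterion. An optional shared-k-mer pre-screen can skip alignment of
subjects sharing no k-mer with the query; skipped subjects score zero,
which cannot displace a top tier that contains any k-mer-sharing subject.

`blast1_identify()` evaluates with leave-one-out by default: when a
database queries itself, every query would otherwise trivially self-match
and the success rates would be vacuous, so the query's own record (not its
species) is excluded. The flag can be disabled to reproduce the literal
self-inclusive protocol. Outcomes are correct / ambiguous / incorrect at
both species and genus rank; a species-level tie confined to one genus
still assigns the genus. "Incorrect" is tracked as a third outcome even
where published tables print only two columns;
`fold_incorrect_into_ambiguous` reproduces the two-column presentation.
Queries whose species is absent from the searched database are flagged
(`species_in_db = FALSE`) and necessarily come out incorrect or ambiguous —
open-set novel-species detection is out of scope.

## Numerical and testing choices

Problem sizes in the test suite and acceptance script were chosen to hold
the sampling error of each asserted quantity well below its tolerance: the
regime dataset uses 50 genera × 2 species × 3 sequences with 400-nt cores
(450 congeneric pairs per replicate, five replicates), estimator-recovery
checks use 200 two-sequence replicates at 300 nt, and the top-hit oracle
comparison runs 20 random fixtures of at most 50 sequences against an
independent exhaustive local-alignment implementation. The alignment and
Viterbi kernels are compiled (Rcpp); pure-R dynamic programming would make
these sizes impractical.

Degenerate inputs behave as contracts, not surprises: empty record sets
write valid headed files; an all-gap alignment, a ragged alignment or an
empty sequence is an error naming the problem; a record with no taxonomy
row is a hard error naming the id; an empty post-curation database is an
explicit error rather than a silent empty directory.

## Known limitations

* Substitution-only evolution: no indels, so alignment difficulty is
  understated relative to real ITS2, where length variation is substantial.
* Single-copy assumption: ITS paralogy and intra-genomic variation are not
  modelled; on real data they can blur both the barcoding gap and top-hit
  assignment.
* The Gumbel null is fitted per target with a finite shuffle ensemble;
  E-values below about `1/n_shuffle` are extrapolations of the fitted tail.
* Secondary-structure information, which can aid alignment and
  identification for this locus, is not used anywhere in the package.
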