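---
title: "Ensemble-based sRNA target-site prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-based sRNA target-site prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnatarget)
```

## The problem

Bacterial small RNAs (sRNAs, typically 50–150 nt) regulate mRNAs through
short, imperfect base-pairing interactions, usually in the 5' UTR around the
Shine-Dalgarno sequence. Predicting where an sRNA binds is hard for exactly
the reasons that make the biology interesting: the paired region is short, it
tolerates bulges and mismatches, different parts of the same sRNA can pair
different targets, and secondary structure on either molecule can block an
otherwise perfect match. This package implements a thermodynamic pipeline
that addresses those obstacles directly, together with the companion analysis
problem: deciding from paired RNA-seq/Ribo-seq experiments *which* genes an
sRNA regulates and *how* (mRNA stability versus translation).

## The energy model

All stages share one nearest-neighbor free-energy model at 37 °C
(`energy_params()`): stacking increments for the six pair types (AU, UA, GC,
CG, GU, UG), length-indexed hairpin/bulge/interior-loop penalties with
logarithmic extrapolation beyond the tabulated lengths
(coefficient 1.75·RT·ln(n/n₀)), affine multiloop terms (closing 3.4, branch
0.4, unpaired 0.0 kcal/mol) and a 0.5 kcal/mol terminal penalty for AU/GU
helix ends. The shipped values are a Turner-2004-style set; the stack table
is symmetrized on construction so a helix scores identically read from either
strand. Absolute energies therefore depend on this parameterization, and the
package treats the parameter set as a swappable backend (plain-text format,
`read_energy_params()`/`write_energy_params()`): the backend contract is
three quantities — structure energy, duplex energy, pair probabilities — and
every downstream result is a function of those.

One deliberate simplification keeps the whole system self-consistent: the
terminal AU/GU penalty is charged for every AU/GU-type pair adjacent to any
loop *except* a stack — hairpin closing pairs, both pairs of a bulge or
interior loop, multiloop closing and branch pairs, and exterior or duplex
helix ends. Full Turner rules exempt single-nucleotide bulges and fold
terminal effects into mismatch tables; pricing them uniformly lets the
structure evaluator, the partition function and the duplex dynamic program
use literally the same loop terms, which is what makes the
enumeration-oracle tests in `tests/testthat/` possible. Dangling ends,
coaxial stacking, pseudoknots and temperature scanning are out of scope.
Lonely (isolated) pairs are permitted and priced without special-casing,
because the local-alteration step below can create them.

## Structure ensembles

An RNA molecule exists in vivo in an equilibrium population of structures,
not a single fold, so all structural quantities here are ensemble averages.
`partition_function()` runs a McCaskill-style O(n³) inside recursion over
pseudoknot-free structures (hairpin loops ≥ 3 nt, bulge/interior loops capped
at `max_loop_span = 30` nt total); `sample_structures()` draws n independent
stochastic tracebacks, so empirical structure frequencies converge to
exp(−E/RT)/Z. The default sample size is 1000 structures, which is sufficient
to reproduce the major structural characteristics of an ensemble; the
acceptance tests verify convergence of sampled frequencies, pair
probabilities and single-strandedness profiles against exhaustive enumeration
on short sequences. Sampling requires an explicit integer seed — there is no
hidden global seed — and the traceback branches on cumulative sums in a fixed
order with an integer-state RNG (splitmix64), so a given seed yields the same
ensemble on any platform.

Exact pair probabilities (`pair_probabilities()`) come from the outside
recursion; its multiloop term is O(n⁴) here, so exact mode is capped at
300 nt and intended for sRNA-scale molecules. Longer RNAs use the empirical
profile of the 1000-structure sample, which is also what the prediction
pipeline itself uses. Boltzmann weights are propagated in linear (not log)
space; for the ≤ 500 nt 5' UTR regions this pipeline folds, partition values
stay far below double-precision overflow.

`centroid_structure()` applies the majority rule (pairs with probability
> 0.5 cannot cross, so the centroid is always a valid structure).
`cluster_ensemble()` groups structures by base-pair symmetric-difference
distance with average-linkage agglomeration, choosing the cluster count by
the largest mean silhouette over 2..5. No published description of the
original clustering procedure was available to copy, so this scheme is a
documented, configurable choice; only the centroid's largest hairpin loop
feeds the downstream pipeline, and both the overall-ensemble centroid
(default, cheaper) and the largest-cluster centroid are exposed via
`centroid_source` in `predict_sites()`.

## Seeding on accessibility

Single-stranded regions — hairpin loops above all — nucleate RNA:RNA
interactions. The pipeline therefore seeds the duplex search on the sRNA
side only: the largest hairpin loop of the selected centroid wins; if no
centroid loop reaches `min_len` (default 4 nt), maximal single-stranded runs
of the empirical profile at probability ≥ 0.5 are the fallback
(`select_seed_region()`). The 0.5 threshold is the natural "more often open
than not" reading of high-probability single-strandedness and is
configurable. Because hybridization can elongate beyond the nucleation site,
the seed is extended by flanks before the search; the defaults (9 nt
upstream, 17 nt downstream) reproduce the canonical geometry in which a
15-nt loop at positions 37–51 of a ~90-nt sRNA widens to a 28–68 search
window. mRNA-side accessibility is deliberately *not* screened: it enters
the score through the disruption energy instead.

## Hybridization

`hybridize()` is a dynamic program over duplex states only — stacks, bulges
and interior loops with per-side spans ≤ `max_loop` (default 15 nt), no
intramolecular pairs, no branching — between the sRNA window and the mRNA.
It reports the minimum-free-energy hybrid plus up to `n_suboptimal`
alternatives whose mRNA intervals overlap any better hybrid by < 50%
(several candidate sites per 5' UTR are the norm, so a non-redundant list is
required), each pairing at least `min_overlap_with_seed` nucleotides inside
the unextended seed. Only hybrids with ΔG_hybrid < 0 are reported; an empty
list is a result, not an error. Equal-energy ties break deterministically:
smaller mRNA start, then smaller sRNA start, then fewer pairs. The DP is
verified against brute-force enumeration of every monotone antiparallel
pairing on small fixtures. The duplex initiation term of the energy table
defaults to 0 because the cost of initiating an intermolecular interaction
enters the total energy exactly once, as ΔG_initiation below. A
`min_contiguous_block` filter for the "≈7 bp continuous block" heuristic
discussed in the sRNA literature is intentionally *not* part of the scoring;
the energetic criterion stands on its own.

## Total energy and the verdict

For each candidate hybrid, the structural cost of opening both molecules is
the ensemble-averaged *disruption energy*. Local alteration
(`locally_alter()`) removes exactly the intramolecular pairs with at least
one endpoint among the duplex-paired nucleotides — a nucleotide cannot pair
intramolecularly and intermolecularly at once, but duplex-internal bulged
nucleotides are not required to be free — and assumes no longer-range
refolding. Then

ΔG_disruption = ΔG_before − ΔG_after,

with ΔG_before the mean energy of the n sampled structures and ΔG_after the
mean energy of the n locally altered structures, each re-evaluated from
scratch. Note the sign: removing stabilizing pairs makes this quantity
*negative*. The total energy restores it as a penalty through subtraction:

ΔG_total = ΔG_initiation + ΔG_hybrid − (ΔG_T-disruption + ΔG_S-disruption),

with ΔG_initiation = 4.1 kcal/mol, and a site is predicted functional when
ΔG_total < 0 (strictly: zero is not favorable). Do not negate the disruption
terms yourself — the formula already does. The sRNA-side disruption uses the
full-sRNA ensemble with the sRNA-side duplex footprint (the alternative —
restricting to the extended window — is not what an equilibrium ensemble of
the whole molecule means, and the whole sRNA is folded anyway).

`predict_sites()` chains all stages under one master seed, deriving
per-molecule sampling seeds as (seed·69069 + k) mod (2³¹ − 1), k = 1, 2 — a
small multiplicative hash that stays exact in double precision — so one flag
reproduces the entire report byte for byte.

## Ribo-seq target calling

The experimental side consumes a gene-level table of log2 fold changes and
p-values from paired RNA-seq (total RNA) and Ribo-seq (ribosome footprints)
in sRNA-minus versus sRNA-plus conditions, in the orientation where positive
log2 values mark repression by the sRNA. Upstream differential-expression
machinery (alignment, assembly, testing) is out of scope; the module starts
from its output table. The rules, each a separate verb:

* `filter_low_coverage()`: a gene needs ≥ 200 reads (inclusive) in *both*
  assays.
* `call_targets()`: a gene passes when |log2fc| ≥ 1 in *either* assay —
  inclusive, so a printed 1.00 qualifies. Statistical significance is
  deliberately not part of the pass rule: the shipped reference table
  contains accepted targets whose p-values are non-significant in both
  assays, and only the pure fold-change rule reproduces its 64/16/80 tally.
* `classify_mode()`: translational when the Ribo-seq change exceeds the
  RNA-seq change by ≥ 0.5 log2 units *and* the RNA-seq change is itself
  non-significant (α = 0.05); stability when the changes are concordant
  (delta < 0.5) and the RNA-seq change is significant; mixed otherwise. The
  0.5/0.05 defaults are artifact choices that reproduce the three benchmark
  exemplars shipped with the package (fepB and yegD translational, dhaK
  stability) and are reported in output metadata.
* `fold_linear()`: 2^|log2fc| rounded half-up to one decimal, the form fold
  changes are quoted in prose.

## What the synthetic generators emulate — and what they do not

`make_sequence_scenario()` builds the interaction geometry the pipeline is
designed around: a 90-nt sRNA with a designed 8-bp GC stem whose purine
(A/G) hairpin loop spans positions 37–51, and an mRNA 5' UTR + early ORF
carrying the loop's reverse complement at positions 41–55, upstream of an
AUG. Purine loops make the planted site pyrimidine-only, and adenine mRNA
flanks make everything outside the site unpairable with the search window,
so ground truth is unambiguous. The `"hairpin_occluded"` variant adds the
site's complement 16 nt downstream (farther than a duplex loop can bridge),
locking the site into a stable hairpin: the same hybrid then pays a
disruption cost, and ΔG_total rises by the stem stability net of the hairpin
loop penalty. Because that occluder is the site's exact complement, the rise
is large but need not flip the verdict — a physically occluded site whose
occluding stem is weaker than the hybrid remains (marginally) favorable.

`make_table_scenario()` draws negative-binomial counts (default dispersion
0.05, baseline mean 500 reads, two replicates per condition and assay —
realistic for a two-replicate bacterial experiment) with planted 4-fold
effects: translational targets shift Ribo-seq only, stability targets shift
both assays. Its p-values come from a moment-based Wald test inside the
generator; they exist to exercise the classifier, not to replicate a
production differential pipeline, and truth columns are emitted so tests
never re-derive ground truth.

Passing tests on these scenarios demonstrate that the machinery recovers
planted signals under the stated noise; they do not demonstrate accuracy on
natural sequences, whose accessible regions are less clean, whose sites
include wobbles and mismatches, and whose energetics depend on the parameter
backend. Reference-sequence results for real sRNA:mRNA pairs are therefore
backend-sensitive and are not asserted by the test suite; the synthetic
stand-ins are labelled as such everywhere they appear.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive at the interfaces (0-based half-open in
  BED output); start-codon-relative display coordinates have no position 0
  (…, −2, −1, +1, …) with +1 = A of AUG.
* T is auto-converted to U on input, with a message.
* An empty pairing has energy 0 (structures) or `duplex_init` (duplexes);
  "no favorable hybrid" is an empty table and a successful exit.
* The arithmetic identity linking ΔG_total to its four terms holds to
  1e−9 on every emitted record, enforced by tests.
* Exact pair probabilities ≤ 300 nt; partition function ≤ 2000 nt; longer
  inputs raise capacity errors rather than silently windowing.
* `evaluate_mutant_pairing()` calls an interaction compensatory when both
  matched combinations hybridize below a −5 kcal/mol cutoff and both
  mismatched combinations do not; the cutoff is a configurable
  duplex-stability bar appropriate for 10–25 nt sites.
* Test problem sizes: enumeration oracles run at ≤ 18 nt (structures) and
  ≤ 12 paired nt (duplexes); recovery experiments use 100 scenario seeds at
  the default n = 1000 sample size.

## Known limitations

The energy backend is a style-faithful but not value-exact Turner table, so
absolute ΔG values should be compared across sites scored by this package,
not against other tools' outputs. The multiloop model is affine with no
coaxial stacking; duplexes have no branch loops. Interaction prediction
seeds on the single best accessible region (other regions can be examined by
passing an explicit window to `hybridize()`); joint folding-and-binding partition
functions, Hfq-site (A-R-N) scanning and conservation features are outside
the model. The mode classifier inherits whatever biases the upstream
differential pipeline puts into its fold changes and p-values.
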