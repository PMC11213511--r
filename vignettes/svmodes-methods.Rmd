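---
title: "svmodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svmodes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, conventions, and design
decisions behind `svmodes`. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and breakend algebra

Everything internal is 0-based half-open. A breakend is (chromosome,
position, orientation), where the junction sits in the gap between base
`pos` and base `pos + 1`: orientation `"+"` means the derived allele
retains the reference sequence up to and including `pos`; `"-"` means it
retains from `pos + 1` onward. This single "junction gap" coordinate
makes the two VCF dialects consistent on read: symbolic records convert
as `pos1 = POS - 1`, `pos2 = END - 1`; breakend (BND) records convert as
`POS - 1` for a `"+"` breakend and `POS - 2` for a `"-"` breakend, with
the bracket side of the ALT giving the mate's orientation (`]` retains
the mate's left side, `[` its right). Orientation pairs map to event
classes as DEL = (+,−), DUP = (−,+), INV = (+,+) or (−,−); interchromosomal
junctions are TRA, and same-chromosome junctions labelled TRA by the
caller stay TRA regardless of orientation (intrachromosomal
translocation-type events are real and retained).

## Consensus merging

Two same-sample calls are compatible when they agree on class and
orientation pair and both corresponding breakends (after canonical
ordering) are within `max_dist` = 1000 bp. We interpret the "pairwise"
distance per corresponding end — the convention of the standard merging
tools — rather than as a single combined distance. Clusters are connected
components of the compatibility graph, found by a position-sorted sweep;
no clustering rule is canonical in the field, and transitive merging is
the default because it is what component-based mergers do. A
`strict_clique` mode greedily splits components into mutually compatible
cliques for sensitivity analysis. A cluster is emitted when it contains
at least `min_callers` = 2 distinct callers; merged breakends are per-end
lower medians (a deterministic choice; no convention exists for which
coordinate survives); and the ≥ 30 bp size filter applies to the merged
record, inclusively. Output is invariant to input order because calls are
canonically sorted before clustering, which the test suite checks by
permutation.

## Rank-based group comparisons

`mann_whitney()` computes the exact conditional distribution of the
rank sum by a Streitberg–Röhmel-style shift algorithm over doubled
midranks whenever the pooled sample size is at most 60, which handles
ties exactly; above that it uses the normal approximation with tie and
continuity corrections. The specification we implement nominally switches
to the approximation above 10 per group, but its own worked example
(two groups of 20 with complete separation) requires exactness there, so
the switch is placed at the point where the shift algorithm is still
essentially free. Two-sided p doubles the smaller tail (observed value
included in both), capped at 1 — the convention of `wilcox.test`.
Benjamini–Hochberg is used wherever the source analysis says only "FDR
adjusted". Note that BH is monotone but not idempotent under
re-application; the test suite asserts monotonicity and determinism.

## TAD-boundary disruption

A BA-SV is an intrachromosomal SV of size strictly below 2 Mb whose
breakend span fully contains a TAD boundary interval (partial overlap
does not count). "Adjacent TAD" means the unique domain whose edge
coincides with the boundary edge; if annotation gaps leave no touching
domain, adjacency is recorded as missing rather than searched for. An
event is "complex" when it lies in a chromothripsis region of its sample
or its genomic footprint overlaps another SV of the same sample.

The permutation null relocates every eligible SV anywhere in the genome:
chromosome drawn with probability proportional to (length − size), start
uniform over valid placements — size is preserved exactly and placements
never cross chromosome ends (audited by test). We chose genome-wide
relocation because the source procedure says only "shuffled, while
maintaining size"; a `within_chrom` mode is available for sensitivity
analysis. The p-value is the proportion of permutations with a strictly
larger BA-SV count, following the stated wording; with a discrete
statistic this estimator is mildly anti-conservative (by roughly the
probability mass of the modal count), and a `smoothed` option reports
(x+1)/(n+1). The statistic counts BA-SV events, not distinct boundaries,
matching "frequency of these events".

## Chromothripsis chromosomal enrichment

Chromothripsis regions are inputs (the caller's oscillating-copy-number
criteria are out of scope). Each SV end contributes one breakpoint, so an
interchromosomal event counts on both chromosomes. Each permutation
reassigns all breakpoints multinomially with probability proportional to
chromosome length (full lengths by default; a `mask` argument subtracts
excluded regions), and p = P(shuffled count ≥ observed) — "same or more",
unlike the strictly-greater BA-SV convention, because that is how each
procedure is described. The permutation count is not stated for this
test; the default 1000 matches the boundary analysis.

## Junction microhomology and repair classification

For a junction A→B the homology is h = h_left + h_right, where h_right
is the longest prefix of B's retained sequence equal to the reference
continuation of A past the junction, and h_left the symmetric upstream
quantity; reverse complement is applied for inversion-type orientation
pairs, and `N` truncates matching. Equivalently, h + 1 is the number of
breakpoint placements producing an identical derived junction — the test
suite checks this equivalence against a slide-enumeration oracle for all
four orientation classes. Summing both sides treats the ambiguity region
as a single homology tract, which is how callers report microhomology;
the original analyses defer to caller output, so this is documented as
an interpretation. Classification uses the pan-cancer linear-fit cutoffs:
h ≤ 1 NHEJ, 2–9 MMEJ, ≥ 10 SSA. Blunt joins (h = 0) are grouped with
NHEJ because the published bins start at 1 bp and leave 0 unassigned; a
`blunt_separate` flag reports them apart. Non-templated insertions are
unknowable from breakends plus reference, so classification rests on
reference homology alone — a real limitation for MMEJ/NHEJ boundaries.
The per-sample NHEJ:SSA ratio is (NHEJ + 1)/(SSA + 1); the pseudocount
keeps the ratio defined for SSA-free samples and is not part of the
published description, which does not say how zero denominators were
handled. Jittered breakpoints destroy homology signal: with the default
±100 bp caller jitter the consensus median lands off the true junction
and most events classify as NHEJ, so mechanism analyses should use
breakpoints at single-base precision (the generator's `jitter_sd = 0`).

## Exact 2×2 inference

`fisher_exact()` conditions on both margins; the odds ratio is the
conditional MLE (solving E[X | ψ] = a under the noncentral
hypergeometric likelihood; 0 or ∞ at the support edges), the CI inverts
the one-sided exact tails at (1 − level)/2, and the two-sided p is the
probability-ordering sum at ψ = 1. The conditional MLE — not the sample
cross-product ratio — is the only estimator consistent with the published
9.75 for the 5/20-vs-5/155 table (the cross-product is 10.0), matching
the stated use of the standard exact-test implementation. Root-finding
here is tight (tolerance 1e−10 in log ψ), so the CI satisfies the exact
inversion property to 1e−6. The widely used reference implementation
solves the same equations by `uniroot` at tolerance `eps^0.25` on the
reciprocal-ψ scale, which carries slop of order `tol·ψ²` (≈ ±0.3 at
ψ ≈ 48); published upper bounds like 47.89 versus the exact 47.87 differ
for exactly this reason, and the acceptance test compares bounds within
that derived slop rather than pretending two root-finders agree to
printed precision.

`burden_regression()` is ordinary least squares on log2(count + 1) with
the signature-presence flag plus stage, genomic subtype, coverage, and
purity; the source says only "multivariate regression", and OLS on the
log scale is the simplest model consistent with that. Count-model
alternatives (negative binomial) were considered and deliberately left
out of scope of the default path to keep the coefficient test identical
across classes; residual non-normality at n = 150 is mild (the null
calibration test shows uniform coefficient p-values).

## Expression coupling

The MRN score is the geometric mean of MRE11, NBN, and RAD50 expression.
The default is the plain geometric mean (a zero gives score 0), matching
the published helper; `offset = 1` computes exp(mean(log(x+1))) − 1 for
smoothly handling zeros. Fisher's z uses the standard
(n − 3)-denominator normal comparison. The downsampling analysis draws
the large group at the small group's size without replacement and
reports the fraction of draws whose correlation strictly exceeds the
small group's observed value; ties count as not-higher. With true
correlations 0.82 versus 0.69 at sizes 20 versus 140, the closed-form
expectation of that fraction is about 0.18 — the analysis detects a real
difference as a low-tail value, not as a conventional p < 0.05.

## The synthetic cohort: what it emulates and what it does not

The generator's defaults are the stated world of the published cohort
wherever a value is printed: 116/175/64 samples across
acral/cutaneous/mucosal (cutaneous split 81/55/19/20; scaled to 1/4 by
default for test speed, `scale = 1` for full size), per-tumor consensus
burden medians 81/64/23, class mix from the printed totals
(TRA 44%, DEL 24%, INV 17%, DUP 15%), 28% intrachromosomal TRA,
chromothripsis fractions 0.70/0.31/0.25, a < 10 kb DEL/INV size
component for cutaneous tumors (weight 0.40), signature-3 prevalence
5/20 in TWT versus 5/155 elsewhere, a +0.8 log2 planted DUP/TRA effect
in signature-3 samples, NHEJ-fraction shift 0.65 versus 0.45, coverage
around 57× (normals 37×), purity around 0.63, and expression
correlations 0.82/0.69 at 20 versus 140 samples.

Free parameters were fixed once on realism or on calibration constraints
the specification itself imposes, and are not revisited per test:

* Genome: 4 chromosomes, 18 Mb total — large enough for placement nulls,
  small enough for fast sequence work. TADs tile at 240 kb with 10 kb
  boundaries (real boundaries are ~75 kb at ~1 Mb domain spacing; both
  are scaled with the genome so that boundary-containment probabilities
  for sub-2 Mb SVs stay in a realistic few-percent range).
* Caller model: three callers, detection 0.9 each, breakpoint jitter
  SD 100 bp, false positives at 5% of true count — "moderate noise"
  under which two-of-three consensus keeps recall ≥ 0.9 and precision
  ≥ 0.95 (tested).
* Burden dispersion: negative binomial size 14. The specification
  requires the planted +0.8 log2 signature-3 effect at n = 150 to be
  detectable in ≥ 90% of seeds, which bounds sd(log2 count) from above;
  size ≥ ~7 satisfies the bound and 14 leaves margin while remaining
  strongly overdispersed relative to Poisson (variance ≈ 550 at the
  acral mean of 81).
* Microhomology planting is physical: flank bases are copied across the
  junction (with mismatches forced just past the tract) so the repair
  module is tested against sequence ground truth rather than labels.
  Planting is skipped when flank windows would collide with an earlier
  junction or the event is too short to host the tract; the ledger
  records which junctions carry planted tracts, and homology-recovery
  tests condition on that flag.

What a green test does not establish: the generator has uniform
single-nucleotide composition (no repeats, GC structure, or fragile-site
sequence bias), independent SV placement outside chromothripsis clusters
(no replication-timing or chromatin covariates), jitter that is Gaussian
and caller-independent, and expression that is linear-Gaussian. Agreement
on this world validates the statistical machinery, not biological
conclusions about real melanomas; the published cohort-level numbers
(106,032 SVs, the exact subtype medians and odds ratios) come from
controlled-access WGS and are deliberately out of reach of the tests.

## Known limitations

* BND records lacking resolvable bracket ALT are skipped with a warning,
  not rescued via `MATEID` chains.
* `<INV>` symbolic records are inherently ambiguous about head-to-head
  versus tail-to-tail junctions; they are read as (+,+), and the writer
  emits (−,−) inversions as BND pairs instead.
* The strict-`>` permutation p is slightly anti-conservative for
  discrete statistics (see above); calibration tests pass at α = 0.01
  but users wanting guaranteed validity should use `smoothed = TRUE`.
* Repair classification requires breakpoints at single-base precision;
  consensus medians of jittered calls are not that.
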