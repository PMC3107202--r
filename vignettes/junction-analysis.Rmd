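---
title: "Annotating translocation breakpoint junctions: model, conventions, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating translocation breakpoint junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctura)
```

## The experimental system

Paired designer nucleases (e.g. zinc-finger nucleases) cut two loci on
different chromosomes; rare joining of the ends across chromosomes produces
reciprocal derivative chromosomes. Junction-spanning amplicons recovered by
nested PCR are Sanger-sequenced, and the anatomy of each scar — deletion
from each end, junctional microhomology, inserted sequence — is compared
across repair-genotype panels. Two quantitative readouts anchor the
analysis: the per-cell translocation frequency, estimated from the number
of PCR-positive wells on a plate of known cell occupancy, and the
distribution of microhomology lengths relative to what random joining would
produce by chance.

`junctura` implements both readouts plus a generative simulator so that
every stage can be validated end to end.

## Reference model and coordinates

All coordinates are 0-based, half-open, on the top strand; lengths are in
nucleotides. A `ReferenceLocus` stores a cut locus with its two nick
offsets; `nickBottom - nickTop` is the 5′ overhang (default 4 nt for a
FokI-type nuclease; configurable because the true overhang geometry at a
given target is usually not stated). Fill-in of a 5′ overhang converts each
end to a blunt end and duplicates the overhang bases on both sides of the
break. The derivative reference is the concatenation of the filled-in left
(5′) fragment of one locus and the filled-in right (3′) fragment of the
other, and its blunt joint is the **zero-deletion state**: every reported
deletion is measured from these post-fill-in ends. `N` is a legal reference
base but never matches anything.

## Annotation conventions

A junction read is orientation-normalized by exact seed matching (default
seed 15 nt; both the left-reference start seed and the right-reference end
seed must be found in one orientation, otherwise the junction is
unalignable). The maximal exact prefix match into the left reference
(endpoint `eL`) and maximal exact suffix match into the right reference
(start `sR`) are then computed; matching is exact and stops at the first
mismatch or `N` — junction reads here are Sanger-grade consensus sequences,
so mismatch tolerance would only blur the deletion/microhomology
bookkeeping (quality trimming, if needed, belongs upstream).

* **Overlap** of the two matches by `m` read bases means `m` nt of
  junctional microhomology. The breakpoint position inside a microhomology
  is intrinsically ambiguous; we canonicalize it at the right edge of the
  microhomology, so `del_left = leftEnd - eL` (with `eL` the maximal
  left-match endpoint) and `del_right = (sR + m) - rightStart`. Under this
  convention `del_total` is invariant under the ambiguity, `mh_len` is
  reported separately, and reconstruction
  `left[0:eL] + insertion + right[sR + m:]` is byte-exact (it is asserted
  on every annotation; failure is an internal error, never a silent
  result). For a perfect join whose right flank happens to extend the left
  match past the blunt end, `del_left` can be negative while `del_total`
  stays 0 — the sign is an artifact of canonicalization, not sequence
  loss. Whether a published dataset measured deletions to the inner or
  outer edge of the microhomology is typically unstated; this convention
  is a documented package decision, chosen for determinism and a
  well-defined `del_total`.
* **A gap** between the matches is the insertion (`mh_len = 0`;
  microhomology is scored only at direct joints). Junctions whose insert
  is flanked by homology are classed as insertions — they count toward the
  "with insertions" percentage and are excluded from the microhomology
  distribution.
* **Terminal-base rule.** Some nucleases cleave variably by one base, so a
  junction can retain an extra copy of the reference end base that is
  neither a deletion nor a true insertion. If the right locus declares
  `variableTerminalBases = v > 0` and the putative insertion is exactly
  `<= v` copies of the right fragment's first retained base, it is recorded
  as `terminal_copies` with `terminal_rule_applied = TRUE` and excluded
  from both the insertion and deletion tallies. The rule is per-locus
  configuration rather than a hard-coded base, generalizing the
  terminal-G convention used for variable cleavage.
* **Ties.** Among equally long decompositions the one maximizing total
  matched length, then the left match, is chosen — annotation is
  deterministic.

Insertions of at least 7 nt (i.e. > 6 bp) are searched against both strands
of both parental loci for an exact full-length match; ties are broken by
left locus before right, forward before inverted, then smallest start.
`flanking_mh` reports the longer of the two exact overlaps between an
insert edge and the junction-adjacent parental sequence (prefix of the
insert vs the bases ending at the left match end; suffix vs the bases
starting at the right match start) — the annealing signature of a
templated insert.

## Per-genotype summaries

`summarizeGenotype()` computes, over **all** junctions of a genotype, the
percentage without microhomology and the percentage with insertions
(insertion junctions are included in the denominator of the
"without microhomology" figure — their joints carry no scored
microhomology, and published totals are consistent with this choice);
over **simple-deletion** junctions only, the microhomology length
distribution and the median combined deletion; over insertion junctions,
the median insertion length; and the percentage of junctions with long
insertions (strictly greater than 50 nt by default).

## The chance-microhomology null

If two ends join at a random position, the number of junctional bases that
happen to match is governed by the per-position match probability
`m = Σ_b p_b²` of the base composition (uniform by default, `m = 1/4`).
One matching run flanks each side of the joint, so the annotator's
two-sided maximal-overlap score is the sum of two independent geometric
runs:

$$P(k) = (k+1)\,(1-m)^2\,m^k, \qquad P(0) = (1-m)^2 = 0.5625
\text{ for uniform composition.}$$

The one-sided geometric variant `P(k) = (1-m) m^k` is also provided; the
two-sided form is the default because it is *exactly* the distribution the
annotation convention induces on random joins — self-consistency between
the null and the annotator is the testable requirement, and the historical
calculation this class of null descends from is not printed in the sources
available to us. `simulateChanceMH()` draws an independent random reference
pair per junction, joins directly, and scores with the annotation engine;
its counts are a multinomial sample from the analytic pmf (verified by
chi-square in the test suite at $n = 10^5$).

An important subtlety: junctions generated from **one fixed reference
pair** do not follow the analytic pmf, because the microhomology at each
candidate joint is a deterministic function of the two fixed sequences —
the histogram converges to a reference-specific mixture, not to the
ensemble law. The null therefore describes ensembles of independent
references, and the consistency checks pool junctions across many
independently generated reference pairs (2,000 pairs × 5 junctions for the
full generator-to-annotator chain), keeping the residual within-pair
correlation negligible.

## Statistical operations

* **Mann-Whitney (two-tailed).** Microhomology distributions are heavily
  tied, so the exact path enumerates group assignments of the observed
  (tied) ranks whenever `choose(nx + ny, nx)` ≤ 5 × 10⁴ and takes
  `p = 2 min(one-sided)` capped at 1; larger samples use the tie-corrected
  normal approximation with continuity correction. The exact path is
  validated against an independent full-enumeration oracle for every
  sample-size pair with `nx + ny <= 10`, and against `wilcox.test` on
  tie-free data.
* **Fisher's exact 2×2** and the **pooled-variance t test** wrap the
  standard R implementations (`fisher.test`, `t.test(var.equal = TRUE)`;
  Welch available by flag). Pooled variance is the default because that is
  what an unqualified "unpaired t test" denotes; replicate structure is
  whatever the user supplies.
* **Plate frequency.** With `k` of `w` wells positive at `c` cells per
  well, the naive estimate is `k/(w c)`; because several independent
  events can occur among the cells of one well, the Poisson
  (limiting-dilution) correction `-log(1 - k/w)/c >= naive` is also
  returned. A saturated plate (all wells positive) is an error advising
  dilution. The naive estimate is the default report since at ~200 cells
  per well and frequencies of a few × 10⁻⁴ the correction is ~2%.
* **Fold changes** are rounded half-up at the stated number of decimals,
  matching how such factors are printed.
* **Surveyor arithmetic.** `% indel = 100 (1 - sqrt(1 - f_cleaved))` and
  its exact inverse; colony hybridization gives
  `100 * non-hybridizing / total`.

## The junction generator

`simulateJunctions()` embodies a resection-annealing model of alt-NHEJ:

| parameter | default | meaning |
|---|---|---|
| `resectionP` | 0.08 | geometric resection per end; mean `(1-p)/p` ≈ 11.5 nt, placing the median combined deletion in the tens of nt |
| `mhBiasWeight` | 4 | a joint is microhomology-driven with probability `w/(1+w)` (0.8 by default); `0` is unbiased ("Lig1-like"), large values microhomology-dominated ("Lig3-like") |
| `insertionProb` | 0.2 | fraction of junctions carrying an insertion (observed cohorts run ~15–27%) |
| `templatedInsertionProb` | 0.5 | templated (copied near a cut, possibly inverted) vs untemplated |
| `insertLenP` | 0.25 | untemplated insert length `1 + Geom(p)` |
| `longInsertRate` | 0.028 | per-junction probability of a long (> 50 nt) templated insert; raising it to ~0.135 emulates a long-insert-prone genotype |
| `templateWindow` | 100 | nt around each cut that templated inserts copy from |

A microhomology-driven joint scans all offsets within the two resected
windows and picks the single longest exposed microhomology (ties resolved
toward the unresected ends), using precomputed longest-common-extension
tables so the scan is table lookups. Insertion junctions join at the
resected ends. Long templated inserts are `51 + Geom(0.028)` nt, giving a
median of ~75 nt within the long class — the only length statistic
reported for such cohorts; with long inserts at ~54% of all insertions
(the proportion implied by published cohort percentages), the
whole-cohort median insertion length sits at the low edge of the long
class rather than at the long-class median, a known shape limitation of
the geometric tail. Resection draws that would exhaust a reference are
resampled (at most 10 times, then an error).

Truth records are emitted pre-canonicalized with the annotation
conventions, so round-trip tests are exact string/integer comparisons.
The generator emulates junction *sequence* anatomy only: no chromatin
context, cell-cycle structure, canonical-NHEJ competition kinetics,
quality noise, or chimeric reads. Passing round-trip and null-consistency
tests therefore demonstrates internal coherence of annotation, null model
and simulator — not that real junction cohorts follow these parameter
values.

`simulatePlate()` scores each well positive with probability
`1 - exp(-f c)` (Poisson occupancy at frequency `f`, `c` cells per well).

## Validation problem sizes and numerical choices

The acceptance-grade checks run at: 10⁵ chance-null draws (chi-square at
α = 0.01, `P(0)` within 3 binomial SE of 0.5625); 2,000 reference pairs ×
5 junctions for the generator-chain null consistency; 1,000 randomized
junctions against an exhaustive decomposition oracle (references ≤ 200
nt); 1,000 simulated junctions across 10 seeds for exact truth recovery;
100 repetitions of 200-vs-200-junction cohorts (`mhBiasWeight` 0 vs 99)
for Mann-Whitney discrimination at p < 0.01 in ≥ 95 of 100; and 2,000
plate pairs at 3.7 × 10⁻⁴ vs 1.6 × 10⁻⁴ for estimator consistency (mean
Poisson-corrected estimate within 5% of truth). For the plate fold
change we report the ratio of the mean estimates across plates rather
than the mean of per-pair ratios: at the lower frequency a plate has a
~4% chance of zero positive wells, so per-pair ratios are undefined or
heavy-tailed and their mean is upward-biased (Jensen), while the ratio of
means is the natural moment estimator.

All randomness flows from explicit integer seeds (`withr::with_seed`
internally, so the caller's RNG state is untouched). The chance pmf is
normalized with an open tail bin; goodness-of-fit pooling merges tail bins
until every expected count is ≥ 5. TSV outputs use tab separation, a
header row and '.' decimals, and rerunning the pipeline on identical
inputs is byte-identical.

## Known limitations

* Exact matching cannot annotate reads with sequencing errors near the
  joint; such reads surface as inflated deletions or failed seeds rather
  than being silently mis-scored.
* Multi-breakpoint (three-way) rearrangements and chimeric reads are out
  of scope.
* The chance null assumes i.i.d. base composition; locus-specific nulls
  conditioned on the actual flanking sequences would be a natural
  extension.
* The generator's resection and insert-length laws are conventions chosen
  for scale realism, not fitted distributions; summary statistics of real
  cohorts constrain them only loosely.
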