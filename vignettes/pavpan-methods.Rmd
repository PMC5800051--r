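---
title: "Methods: PAV discovery, breakpoint signatures and read-depth genotyping"
author: "pavpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAV discovery, breakpoint signatures and read-depth genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavpan)
```

`pavpan` analyses presence/absence variants (PAVs): sequences of at least
1 kb present in one genotype's genome and entirely absent from another's.
This vignette is the package's account of its methods — the models and
rules, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical and design decisions taken where
more than one choice was defensible.

## 1. The discovery filter cascade

Candidate deletions (from external SV callers, consumed here as interval
tables) pass five conjunctive rules, in this order:

1. **Self-consistency.** A variant also detected when the genotype's own
   reads are mapped back to its assembly reflects an assembly artefact,
   not a genotype difference; it is discarded. The caller flag is honoured
   when present; otherwise candidates are tested for overlap against a
   self-mapping call set. The overlap rule is not dictated by the
   procedure itself, so the default is the conservative *any overlap*,
   with a 50% reciprocal-overlap mode available.
2. **Minimum size** — 1 kb. Reported PAV size classes start at 1 kb, so
   the boundary is taken *inclusive* (`length >= 1000`); the threshold is
   a parameter.
3. **Specificity.** Keep a candidate only if the opposite genotype's read
   depth is below 5X (strict `<`) over at least 70% (inclusive `>=`) of
   its bases. This is what separates true PAVs from copy-number variants
   and misclassified duplications, whose sequence attracts reads from the
   other copies.
4. **Assembly support.** Keep only candidates whose own genotype's
   properly-paired reads (correct orientation and insert size) cover
   strictly more than 90% of the interval; a region a mapper cannot
   traverse with concordant pairs is suspect. Proper pairs rather than
   long-insert mate pairs are used because many PAVs are too short for
   mate-pair coverage.
5. **Oversize flag.** Putative deletions above 200 kb (strict `>`) are,
   on inspection, duplications misread as deletions; they are flagged
   `oversize_suspect` and excluded from the PAV output — flagged rather
   than silently dropped, to keep the audit trail complete.

Anchoring then assigns categories: the deletion-junction context (100 bp
of flank on each side, a parameter) is matched exactly against the
acceptor genome; one placement gives `anchored_unique` with a breakpoint,
several give `anchored_ambiguous`, none gives `unanchored`. Exact-flank
matching is a deliberately simple stand-in for alignment-based anchoring,
sufficient for synthetic genomes where flanks are unique by construction;
real-data anchoring with a local aligner is out of scope.

Scaffolds nearly invisible to the opposite genotype's reads never reach
SV calling (nothing aligns to define a breakpoint). A scaffold with fewer
than 20% of bases covered (depth >= 1) that also meets the specificity
criterion over its full length becomes an `incomplete` PAV, with no
breakpoint. Note that with "covered" defined as depth >= 1, the <20%
covered condition already implies at least 80% of bases at depth 0 — so
the specificity clause only binds when the covered-fraction bound is
relaxed; both conjuncts are nevertheless implemented and tested
independently.

Because the filters are conjunctive, the retained set is order-invariant;
the per-stage report (which telescopes exactly over the candidate stages)
attributes each rejection to the *first* failing stage in the order
above. The minimum caller support (3 reads at Q20) is an ingestion
precondition applied inside the callers; `check_caller_support()` can
re-assert it but it is not a pipeline stage.

## 2. Breakpoint microhomology

For a deletion of `[s, e)` on the genome that carries the segment, the
microhomology (MH) is the maximal exact match between the deleted
sequence's ends and the remaining flanks: on the right, the largest `k`
with `seq[s, s+k) == seq[e, e+k)`; on the left, the mirror image. MMEJ
double-strand-break repair leaves exactly such traces.

Two numerical decisions:

- **Placement canonicalization.** When the breakpoint sits inside an MH
  tract, a window of placements yields the same acceptor sequence, and
  naive side-wise maxima depend on the placement chosen. Breakpoints are
  therefore shifted to the *leftmost* equivalent placement before
  extraction, which makes the reported length invariant to the caller's
  placement (a property the test suite checks by shifting planted
  breakpoints through their tracts). At the leftmost placement the left
  side can only contribute when the deletion is flush against a contig
  edge; ties between sides are reported as `right`.
- **MH-present threshold** — 3 bp, the smallest size treated as a genuine
  signature rather than a chance match (1–2 bp matches occur at random in
  more than half of breakpoints); configurable.

**Excess at a focal size.** The bulk of MH sizes decays roughly
exponentially — short chance matches are common, long ones rare. An
insertion mechanism with a fixed-length signature (LTR retrotransposons
duplicate 5 bp at their target site) shows up as extra mass at one size.
`excess_at_mode()` fits a geometric decay (support from the 3-bp
threshold upward, unbounded) by maximum likelihood to all bins *except*
the focal one, renormalized for the missing bin; the excess is the
observed share at the focal size minus the fitted null's share there,
with a seeded bootstrap (default B = 1000) for its uncertainty. A
histogram concentrated on a single size is rejected as degenerate. One
known bias, documented rather than corrected: when a true spike of mass
`s` sits on a geometric base, the estimator converges to
`s · (1 − g)` with `g` the null share at the mode (about 15% here), a
downward relative bias of order `g` — well inside the ±0.03 recovery
tolerance the tests use at n = 2000.

## 3. Pan-genome construction

Anchored and unanchored genotype-specific sequences are concatenated into
two pseudomolecule-like sequences (`pav_anchored`, `pav_unanchored`)
appended to the reference, consecutive sequences separated by exactly
100 N (a parameter). Spacers are internal only — none before the first or
after the last sequence, which the published convention leaves unstated;
an empty input set simply omits its pseudomolecule. Input order is
preserved (anchored sequences are supplied in reference-position order by
the discovery pipeline; unanchored in input order). The coordinate map is
exact and bidirectional: `map_to_pan()` and `map_from_pan()` are mutually
inverse on every non-spacer position, spacer positions return a sentinel,
and slicing the mapped intervals out of a pseudomolecule reproduces the
input sequences byte for byte. FASTA is written 60 columns wide via
Biostrings.

## 4. The read-depth genotyping model

With `x_i` the donor's sqrt-transformed read count over region `i` and
`Y_i` the target line's, the model is a two-component mixture of linear
regressions (presence cluster 1: depth tracks the donor's, slope near 1;
absence cluster 0: depth near zero regardless of `x`), Gaussian errors
with cluster-specific variance, mixing proportion `pi`. The square-root
transform stabilises the variance of count data; it must be applied
exactly once, and the `pav_depth` container records this and refuses a
second application.

**EM.** The E-step computes posterior memberships from the Gaussian
densities in log space (so an extreme outlier underflows to a 0/1
posterior, never NaN); the M-step solves two weighted least-squares
problems, weighted variances (floored at 1e-12 so noise-free fixtures
remain computable) and the mixing proportion. Convergence is declared
when the log-likelihood changes by less than `tol = 1e-8` (at most 500
iterations); the trace is stored, and monotonicity is asserted in the
tests on every fixture.

**Initialization and starts.** The first start splits regions at the
median of `y / x` (the natural axis separating the two lines); the
remaining `n_starts - 1` (default 4) use random soft memberships, seeded.
The best final log-likelihood wins. Labels are then canonicalized —
cluster 1 is the component with the larger slope — so calls are invariant
to how starts were labelled.

**Degeneracy.** A component whose effective weight falls below 2
observations aborts that start; if every start aborts, or the two fitted
components are separated by less than one residual sd on average, the fit
is refused as degenerate: the data contain a single cluster and a
two-cluster answer would be noise. `genotype_panel()` catches this and
falls back to a single weighted regression, adopted also whenever its BIC
beats the mixture's; under a single component every region is assigned to
the one cluster (present when the fitted slope is >= 0.5, the midpoint of
the two nominal slopes). This is exactly what the donor and
opposite-reference control lines require: the donor carries every region
and the opposite reference none, so their columns hold one cluster by
construction.

**BFDR control.** Each region's MAP call has posterior misclassification
probability `q_i = 1 - max(tau_i0, tau_i1)`. Sorting by `q` and taking
the largest prefix whose running mean stays at or below the nominal level
(default 0.01) controls the posterior expected share of wrong calls among
those made — the standard posterior-expected-FDR prefix rule; the
remainder stays unclassified, and the achieved running mean is reported
as the realized-BFDR estimate. Counts of zero are legitimate
(`sqrt(0) = 0`, no pseudo-count); lines whose counts are all zero are
skipped and reported. Per-line sequencing-depth normalisation (median
scaling) is available but off by default, since the procedure is defined
on raw counts and the ambiguity is unresolved.

**A note on recovery tolerances.** At n = 5000 with `x ~ Uniform(10, 40)`
the slope, residual-sd and mixing estimates have sampling sds of about
0.002, 0.011 and 0.007 — far inside the ±0.05 / ±0.03 recovery
tolerances the tests assert per fixture. The intercepts are different:
extrapolating to `x = 0` from data in [10, 40] inflates their sampling sd
to ~0.049, the same size as the tolerance, so a single-fixture
intercept-vs-truth assertion would fail on a fair draw about a third of
the time whatever the implementation. The suite therefore asserts
intercept recovery against truth on the mean of the 20-replicate ensemble
(sampling sd ~0.011), and additionally requires the single-fixture EM
estimates to agree with the supervised oracle — weighted least squares on
the true labels — to 2e-3, which is the sharp statement of what EM can
recover at this cluster separation.

## 5. The synthetic-data generator

The generator produces every input the pipeline consumes, with complete
ground truth, under one master seed. Each stage draws from a sub-stream
derived from the seed and a stable stage label, so adding a stage never
shifts another's draws, and identical configurations give byte-identical
outputs.

What it emulates, and the defaults chosen as the study conditions:

- **Genome pair** (default 200 kb donor): 8 uniquely anchorable planted
  PAVs of 1–3 kb, 2 with duplicated junction context (ambiguous
  anchoring), 2 sub-kilobase deletions and 2 duplication decoys, plus 3
  incomplete scaffolds of 2–8 kb. Deletion breakpoints carry planted MH:
  the first `k` deleted bases are copied after the deletion end and the
  flanking bases forced to mismatch, so the maximal MH is exactly `k` and
  the planted placement is leftmost-canonical.
- **MH lengths**: a spike of mass 0.10 at 5 bp on a truncated geometric
  base over 3–37 bp. The geometric decay `p = 1/3` follows from the
  reported mean MH size of 5 nt on support starting at 3
  (`(1-p)/p = 2`), and makes 5 bp a genuine secondary mode once the spike
  is added; 60% of breakpoints carry no MH at all (`p_no_mh = 0.6`,
  matching the reported 40% with MH). Truncation at 37 bp mirrors the
  largest observed stretch.
- **Coverage**: Poisson per-base depth at 40X (the depth of the data the
  procedure was designed for) over shared sequence; truly deleted
  segments get Poisson(`leak_frac` × 40) opposite depth. The depth
  distribution of residually-covered absent regions is not documented
  anywhere, so the leak model is an explicit assumption exposed as a
  parameter, default 0 (exactly zero coverage).
- **Count matrices**: responses are drawn on the sqrt scale exactly as
  the model states — `Y = a_Z + b_Z x + N(0, sigma_Z)` with
  `x ~ Uniform(10, 40)` and defaults `(0, 0, 0.8; 0, 1, 0.8)` — so the
  genotyper's assumptions hold exactly in fixtures; emitted raw counts
  are `round(pmax(Y, 0)^2)`, and a Poisson mode on the raw scale is
  provided as a deliberately misspecified robustness setting.
- **Panel**: four groups of five lines (named for the maize heterotic
  groups they imitate) with per-group PAV frequencies drawn from Beta
  distributions, optional group-private PAVs, and two control columns —
  the donor (all present) and the opposite reference (all absent).
- **LD haplotypes**: a first-order chain along sorted positions in which
  each line's allele matches the previous locus with probability
  `0.5 + 0.5 exp(-d / L)`, giving correlation `exp(-d / L)` at distance
  `d` — a smooth decay adequate for testing the binning machinery, not a
  coalescent.

What it does **not** emulate: read-level artefacts (no FASTQ, no
sequencing error, no mapper behaviour, no GC or mappability bias),
genuine copy-number gradation (decoys are all-or-nothing), linked
selection or realistic site-frequency spectra, and reference N-gaps.
Passing tests therefore demonstrate that the *rules and estimators* are
implemented correctly and calibrated under their own assumptions — not
that those assumptions hold on any particular real data set.

## 6. Population summaries

- **Shared fraction**: per line, the percentage of donor PAVs called
  present, unclassified calls excluded from the denominator; the donor
  control is 100% and the opposite reference 0% by construction.
- **Missing-call policy**: pairwise-complete for LD (each pair uses the
  lines typed at both loci); complete-case for sharing classes, mirroring
  the convention of classifying only fully typed variants. Group
  frequencies report presence among typed lines, with the underlying
  counts attached so totals can be audited.
- **PCA**: lines × complete-case loci, column-centered, unscaled by
  default (0/1 frequencies carry the signal; unit-variance scaling is an
  option). Component signs are fixed by making each component's
  largest-magnitude loading positive, so coordinates are deterministic;
  the full score matrix satisfies the Gram identity with the centered
  data to numerical precision.
- **LD**: on a fully homozygous panel, genotype codes are
  haplotype-equivalent and LD is the squared Pearson correlation of
  allele codes; monomorphic loci return NA with a reason rather than 0.
  For distance, a PAV is represented either as a 0/1 locus at its
  breakpoint or by its nearest internal SNP; decay curves are averaged in
  500-bp bins up to 20 kb by default, and bins with no pairs are omitted,
  never zero-filled.
- **Density tracks**: sliding windows (default 10 Mb, step 1 Mb),
  truncated at the contig end, with optional scaling relative to the
  highest window.

## 7. Problem sizes and reproducibility

The test and acceptance workloads were sized to run comfortably on a
single core: genome fixtures of 200 kb; 1000-breakpoint brute-force
comparisons; n = 5000 regions per mixture fit, 20 replicate fits for the
calibration and recovery ensembles; 2000 breakpoints for spike recovery;
bootstrap B of 200–1000. The full suite runs in well under a minute, the
acceptance script in seconds; every random draw in both descends from an
explicit seed, so both are exactly reproducible.

## 8. Known limitations

- Anchoring is exact-match only; diverged or repetitive flanks that a
  local aligner would place are reported unanchored or ambiguous.
- The genotyper models presence/absence only; intermediate copy number is
  outside the model (such regions surface as poorly classified).
- Per-line fits share no information across lines; a hierarchical joint
  model could borrow strength for low-coverage lines but would depart
  from the per-line procedure implemented here.
- The BFDR guarantee is conditional on the fitted mixture being the true
  generative model; under misspecification (e.g. the Poisson generator
  mode) the realized FDR can exceed the nominal level.
- `excess_at_mode()` assumes a single-parameter geometric null; a
  heavier-tailed null would shrink the estimated excess.
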