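---
title: "Methods and modelling notes for stripemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling notes for stripemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripemeth)
```

# The problem

Striped apple peel alternates red sectors (anthocyanin-rich, *MYB10*
expressed) and green sectors (anthocyanin-poor).  When the primary DNA
sequence of the *MYB10* promoter and coding region is identical between the
two tissues, the natural suspect is epigenetic: cytosine methylation of the
promoter, higher in green stripes, lower in red.  stripemeth implements the
two measurement chains used to test that hypothesis at candidate-gene scale
— McrBC methylation-sensitive qPCR and amplicon bisulfite Sanger-clone
sequencing — together with efficiency-corrected relative transcript
quantification and promoter sequence-feature scanning, plus a simulator for
all of the above.

# Coordinate conventions

Promoter positions are ATG-relative with no zero: +1 is the A of the
translation-start ATG, −1 the base immediately 5' of it, so the fragment
−51..+105 has 156 positions.  Internally sequences are stored as plain R
strings with 1-based indices (the natural R convention); `atg_to_index()` /
`index_to_atg()` form the bijection, and every user-facing function speaks
ATG-relative inclusive endpoints.  Fragment endpoints are treated as
inclusive amplicon boundaries; whether the original assay's printed
endpoints were primer 5' ends or amplicon edges is not decidable from the
available material, and nothing downstream depends on the distinction.

# The McrBC/qPCR estimator

McrBC requires two methylated purine-C half-sites 40–3000 bp apart and cuts
between them.  For template that survives digestion at fraction $f$, the
McrBC-side reaction crosses threshold $\log_E(1/f)$ cycles later than the
mock, so

$$\%M = 100\,\bigl(1 - E^{-(Ct_{McrBC} - Ct_{mock})}\bigr).$$

The source assay's printed formula did not survive reproduction (it was an
un-rendered figure), so this package adopts the standard estimator above; it
is consistent with the assay's description of percent methylation as the
proportion of copies cut, and with the observed occurrence of *negative*
raw estimates when noise puts the McrBC Ct below the mock Ct.  Negative raw
values are clamped to zero and flagged `negative_clamped` rather than
discarded — the flag preserves the information that the true value is near
zero.

Quality control mirrors the failure mode of heavily methylated fragments:
when nearly every template copy is cut, the McrBC-side reaction runs out of
template, Ct values drift high and become irreproducible, and the estimate
is meaningless.  `aggregate_replicates()` therefore withholds the estimate
(flag `low_template`) when the McrBC-side mean Ct exceeds 35 cycles or the
replicate SD exceeds 1.5 cycles.  Both cutoffs are package choices — the
source material states only that one fragment could not be estimated — and
both are arguments, not constants.

Replicate structure is PCR replicates (typically 3) nested in independent
enzyme digestions (typically 2–3).  The point estimate is the mean of
digestion-level means; the SE is across digestions when more than one is
present, otherwise across PCR replicates.  Group comparisons default to
Welch's t-test (stripe samples have no reason to share a variance); the
pooled test is available by flag.  `required_sample_size()` wraps the
standard two-sample t power computation.

Efficiency defaults to 2.0 unless a calibration series is supplied
(`calibrate_efficiency()`, $E = 10^{-1/\text{slope}}$); per-fragment
efficiencies can be passed as a named vector, since the original assays
calibrated per amplicon (observed range 1.839–1.945).

# Bisulfite clone analysis

Alignment of clones to the *unconverted* reference uses Needleman–Wunsch
with an asymmetric substitution matrix in which clone-T over reference-C
(expected conversion) and clone-C over reference-C (methylation) both score
as full matches; this prevents a clone's conversion state from biasing its
own alignment.  Gap open 5, extend 1, match 2, mismatch −2; all
configurable.  Clones are rejected — not silently dropped — when their
length deviates more than 20% from the reference or their identity on non-C
reference positions falls below 80% (a reverse-complement clone fails this
floor; the caller can retry after reverse-complementing).

Calls are per reference cytosine: clone C → methylated, T → unmethylated,
anything else (gap, N, A, G) → ambiguous.  Ambiguous calls are excluded from
denominators; they are never counted as unmethylated.  No clone is filtered
for "failed conversion": in plants non-CG methylation is genuine, so a
C-rich clone cannot be presumed unconverted; a per-clone percent table is
reported instead so outliers are visible.

Context classification follows the plant convention (CG / CHG / CHH, H ∈
{A,C,T}) read from the unconverted reference.  A CG call needs only one
downstream base; CHG/CHH need two; sequence ends and Ns give `unknown`.
Only the forward (bisulfite top) strand is analyzed — the amplicons are
strand-specific after conversion.

`compare_stripes()` reports both the region-wide difference (difference of
pooled percentages; the default) and the mean of per-position differences,
because summary statements of the form "green exceeds red by X points" are
ambiguous between the two; ties count in the denominator of the
fraction-higher statistic and never in its numerator.

# The simulator: what it emulates, and what it does not

The generator's defaults are the study system's stated operating points:
per-context methylation CG 1.6%, CHG 16.9%, CHH 20.2%; a hypermethylated
block in the upstream promoter; a green-minus-red offset of 9.3 points in
the −1007..−684 amplicon and 5.2 in −534..−184; 12–48 clones per sample;
PCR triplicates over two independent digestions; Ct noise SD 0.15 cycles;
amplification efficiencies near 1.9.  Where the source states no value we
chose once: bisulfite conversion efficiency 0.995 and per-base sequencing
error 0.001 (typical kit and Sanger figures), GC fraction 0.38 for a plant
promoter, mock-template Ct 25.

Simplifications to keep in mind when reading a green test:

* Methylation states are drawn independently per cytosine and per molecule;
  real methylation is spatially correlated within molecules (mosaicism is
  modelled only through the regional block and the stripe offset).
* McrBC digestion is deterministic given the states — every eligible pair
  cuts (the assay digested overnight "to completion") — and the cut is
  placed at the pair midpoint; partial digestion kinetics are not modelled.
* Digestion is fragment-scoped: half-sites outside the amplicon that could
  pair with inside half-sites are not simulated.
* PCR amplification bias beyond primer degeneracy checking, cloning
  chimeras, and reverse-strand methylation are out of scope.

A green parameter-recovery test therefore establishes that the estimators
are correct for independently sampled mosaics at realistic operating
points, not that any biological conclusion is reproduced.

# Recovery experiments and their tolerances

The acceptance experiments (`recovery_experiment_contexts()`,
`recovery_experiment_stripes()`, `recovery_experiment_mcrbc()`) simulate at
the truths above and accept within 3 binomial/replicate standard errors.
Two deliberate choices:

* They run with conversion efficiency 1 and sequencing error 0.  The
  tolerance is the binomial sampling SE, which presumes an unbiased
  Bernoulli draw; incomplete conversion adds a small known positive bias
  (≈ +0.5 points at the CG level of 1.6%) that is a property of the assay,
  not of the estimator under test.  The artefact paths are exercised in the
  unit suite instead.
* The McrBC pool for the 95%-digestible experiment is constructed directly
  at its digestible fraction (`digestible_fraction = 0.95`) rather than
  solved for through per-site probabilities, because the quantity the assay
  reports *is* the digestible fraction.

At 24 clones per stripe the stripe-difference estimator has an SE of about
1.2 points, so single-seed estimates of a 5.2-point offset scatter
noticeably (roughly 2–8 points across seeds); that scatter is the honest
operating characteristic of the published design, and the tolerance stays
at 3 SEs rather than being widened or the design quietly enlarged.

# Numerical and degenerate-input choices

* `percent_methylation` is exact at ΔCt = 0 (0%) and monotone in ΔCt and in
  E; a missing McrBC Ct with a present mock Ct is the no-amplification
  sentinel (percent 100, `low_template`); both Cts missing →
  `not_evaluated`.
* Zero-variance groups short-circuit the t-test: equal constants p = 1,
  distinct constants p = 0.
* Pairwise identity (global mode) counts matching columns over all
  alignment columns, gaps included; match 1, mismatch −1, gap open −2,
  extend −1.
* E-box scanning defaults to both strands (CACATG is non-palindromic);
  palindromic motifs double-report by strand, by design.
* Half-site separation is measured between half-site start coordinates;
  the 40–3000 window is inclusive at both edges.
* All generators restore the caller's RNG state; fixed seed ⇒ identical
  output, different seed ⇒ different draws.

# Known limitations

The E-box count check against the real promoter accession requires that
sequence, which cannot be fetched in an offline build and is not fabricated;
the corresponding test fails with an instruction for supplying the file
locally.  Reverse-strand and hemimethylation calls, multi-reference-gene
normalization, genome-scale liftover and read-mapping bisulfite pipelines
are explicit non-goals.
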