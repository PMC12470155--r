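---
title: "Methods: dinucleotide property landscapes around genomic annotations"
author: "dinuscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dinucleotide property landscapes around genomic annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinuscape)
```

## The model chain

`dinuscape` operationalises a three-link causal chain: sequence repeats shape
local dinucleotide content; dinucleotide content determines structural DNA
properties (each property is, to good approximation, additive over
dinucleotide steps); and structural properties are associated with histone
occupancy, transcription-factor binding and large-scale chromatin
organisation. The package does not model the third link — it quantifies the
first two around user-supplied functional annotations, and provides null
models that separate genuine dinucleotide-level signal from what nucleotide
composition alone would produce.

## Binned maps

All analyses run on fixed-resolution binned tracks (default 1000 bp).
Dinucleotides are counted overlapping on the forward strand; the step spanning
positions $(i, i+1)$ is assigned to the bin containing $i$. With this
"left-bin" rule every genomic step is counted exactly once and a fully valid
interior bin satisfies $\sum_{XY} n_{XY} = \text{resolution}$, which makes the
sum-mode property track exactly additive across resolutions (asserted in the
test suite). Complement classes are *not* merged at counting time — property
models are defined per ordered dinucleotide — but reporting functions can
group a class with its reverse complement (AA/TT etc.).

`N` (and any other ambiguity character, which raises an error naming the
position) breaks runs and steps. Each bin carries the fraction of
non-ambiguous bases; bins below 0.5 are flagged invalid and propagate `NA`,
mirroring the 50 % rule used for masking in the profile stage, never a silent
zero. `mask_gaps()` applies the same rule to arbitrary tracks before
correlation, which is how centromere-scale gaps are kept out of the
statistics.

## Property models

A property model is 16 finite step values $m_{XY}$. Two normalisations are
supported:

* `sum`: $\sum_{XY} m_{XY}\, n_{XY}$ per bin — an extensive quantity, exactly
  additive, used wherever exact decompositions matter;
* `mean` (default): the sum divided by $\sum_{XY} n_{XY}$ — intensive, which
  keeps bins with different valid lengths comparable when partial masking is
  in play.

The bundled model table is a *synthetic fixture* with literature-typical
magnitudes (degrees for Roll/Twist/Tilt, ångströms for Slide/Shift/Rise,
nanometres for persistence length). Within the fixture, the Roll variants
carry their field-typical qualitative structure — CC/GG steps clearly above
the model average, GC at the bottom — because the package's end-to-end
demonstrations drive Roll through CC/GG flank enrichment. Every numerical
test in the suite is invariant-based (linearity, constancy, complement
symmetry, intensivity); none pins fixture magnitudes. For real analyses users
should load the property database of their choice via `load_model_table()`.

## Null references

**Zero-order.** $E[n_{XY}] = n_X n_Y / L_{seq}$ per bin, computed from the
bin's own nucleotide counts and valid length. This is the expectation under a
zero-order Markov (i.i.d.) model of the bin's composition. Two subtleties are
documented because they matter at test precision: the linear count of a
length-$L$ bin has $L-1$ steps, so the formula is exact for the circular
count and within $O(1/L)$ for the linear one; and under *permutation*
(shuffling without replacement) the homopolymer expectation is
$n_X(n_X-1)/L$, not $n_X^2/L$. The package's oracle therefore resamples
i.i.d. from the empirical composition — the model the formula describes —
and the permutation identities are unit-tested separately.

**First-order (tandem repeats).** The expected number of start positions of a
two-unit repeat $(XY)_2$ (total length 4; longer runs contribute one start
per phase-aligned offset) under a first-order chain is
$E = n_{XY}^2 n_{YX} / (n_X n_Y)$; for homopolymer classes ($X = Y$) the
formula degenerates to $n_{XX}^3 / n_X^2$, which simulation confirms without
special-casing. By continuity the expectation is 0 whenever $n_{XY} = 0$. The
"start-count" reading was fixed by a Monte-Carlo oracle before the package
was built: to leading order $(L-1)^3/L^2 = L - 3 + O(1/L)$, exactly the
number of start positions, and simulations at the model-expected contents are
unbiased. Evaluating the formula with *empirical counts of the same
realisation* (its per-bin use) adds a second-order ratio bias of roughly
$-1$ to $-1.5\%$ at $L = 1000$; a dedicated test asserts the plug-in tracks
simulation at the 2.5 % relative level. Higher-order references
(composition-preserving shuffles beyond dinucleotides) are out of scope.

**Uniform.** `global_reference()` supplies the valid-fraction-weighted
genomic mean and SD of any track.

## Tandem-repeat detection

A tandem repeat is a head-to-tail repetition of a 1–6 bp unit with total
length $\ge \max(4, 2 \times \text{unit})$ — at least two full units.
Detection is exact (no mismatches or indels; approximate repeats are Tandem
Repeats Finder territory and out of scope). Rules, in order:

* maximal runs per unit length, found by run-length encoding of the
  $s_i = s_{i+u}$ match vector;
* smallest-period rule: a run whose minimal period is smaller than $u$ is not
  reported again at $u$ (an (A)$_n$ run is never also an (AA)$_n$ run);
* class label = lexicographically smallest rotation of the unit (ACAC and
  CACA are both (AC)$_n$); merging with reverse-complement classes is a
  reporting option, never part of detection;
* overlaps are resolved greedily — longest run first, then leftmost, then
  shortest unit — and later candidates are trimmed to uncovered bases and
  kept only if the trimmed piece still qualifies, so no base is claimed
  twice.

The same contract is implemented twice: once efficiently in the package and
once as a brute-force (start, unit) scanner in the test suite, and the two
are compared exhaustively over all sequences up to length 12 on a two-letter
alphabet plus random 60-mers.

## Environment profiles

For each anchor the track is read outward in both directions from the
anchor's reference point at the map resolution, out to a half-width $D$
(default 1 Mb, comfortably beyond the 800 kb baseline threshold below). The
reference point is the interval midpoint: TAD borders and binding sites are
near-point features, and one convention for long features (genes) beats a
mixed one; `start`/`end` modes exist for users who prefer edges. Profiles are
not strand-flipped by default (regulatory annotations are typically
strandless).

Masking: the interiors of the anchors themselves and of any annotation set
passed via `mask` are removed — a bin loses the overlapped fraction of its
weight; bins with more than the discard threshold (default 50 %) masked are
dropped entirely. This is what removes the clustering bias (e.g. promoters
sitting next to genes); a property test plants clustered anchors on a uniform
background and asserts the masked profile is flat. Remaining bins are
weighted by unmasked fraction times valid fraction. Per distance, the pooled
weighted mean and a reliability-weighted variance
($\sum w (x - \bar x)^2 / (\sum w - \sum w^2/\sum w)$) are reported together
with the effective weight and the contributing-anchor count; distances
running off a chromosome end simply contribute nothing.

One practical geometry note: if anchors are wider than the bin size, their
midpoint bins are fully masked and the profile has no distance-0 estimate.
The synthetic designs therefore use point-like anchors (30 bp at 100 bp
resolution — the same ratio as a CTCF motif at 1 kb), matching the intended
use.

## Peak calling

The baseline pools all profile bins beyond a minimum distance (default
800 kb) into a weighted mean, SD, and standard error $SD/\sqrt{n_\text{bins}}$,
on the assumption that anchors no longer influence the environment out there
(at least 10 far bins are required). The central statistic is

$$z(d) = \frac{\text{mean}(d) - \text{baseline}}{\sqrt{SE(d)^2 + SE_b^2}},
\qquad SE(d) = \sqrt{\text{variance}(d)/\text{weight}(d)}.$$

A peak exists iff $|z(0)|$ exceeds the threshold (default 2; the choice is
exposed because no universal level exists, and raw sigmas are reported rather
than multiplicity-corrected ones). The significant span grows outward from 0
and stops, independently on each side, at the first non-significant bin; a
`gap_tolerance` option allows $g$ consecutive non-significant bins (default
0, the strict reading). Height is the maximum $|\text{mean}(d) -
\text{baseline}|$ over the span; width is the span's distance bounds; the
height uncertainty is the profile SE at the apex bin.

Because the height is a maximum over a noisy span, it carries an upward
selection bias of roughly one per-distance SD for a triangular peak of
50-bin half-width — about 17 % at an 8 SD apex, 11 % at 10 SD, under 9 % from
12 SD. The validation ladder for height recovery therefore spans 10–28 SD,
the regime where the estimator is accurate to better than 15 %; rank
monotonicity (Spearman $\rho > 0.95$) holds throughout.

`relative_significance()` compares two signed peak heights in units of their
combined uncertainty, $\sigma_{rel} = (h_e - h_r)/\sqrt{u_e^2 + u_r^2}$, with
an undetected reference contributing height 0 and its center-bin SE. With the
zero-order reference this cancels peaks driven purely by nucleotide or G+C
composition: on synthetic genomes whose anchor flanks carry only a G+C
gradient (dinucleotides at their zero-order proportions), empirical Roll
peaks are reliably *called* but $|\sigma_{rel}| < 2$ in well over 90 % of
seeds, while genuinely dinucleotide-specific enrichment (CC/GG at fixed G+C)
survives the comparison.

## Map correlation

`bootstrap_correlation()` samples, per repetition, $k$ jointly valid bin
positions genome-wide *with replacement* (bootstrap semantics; the sampling
scheme in the field is usually described without replacement details, and at
genome scale the distinction is negligible) and computes a Pearson
coefficient; defaults are 50 repetitions of 50 positions. The null applies
the identical procedure to independently position-shuffled copies of both
maps, preserving marginals while destroying alignment. The significance is
the difference of the two means over the quadrature sum of the two
repetition SDs; under the null this statistic is close to standard normal
(with $k = R$ the two variance scales match), and calibration is asserted
over hundreds of seeded runs. Known limitation, deliberately not papered
over: positions are sampled independently, so strong spatial autocorrelation
inflates the effective information per repetition; a block bootstrap would be
the remedy and is out of scope.

## Influence decomposition

Property tracks are linear in dinucleotide content, so a peak can be
decomposed exactly. All profiles involved — the property, the 16 per-class
tracks, and the repeat-partitioned tracks — are aggregated by one engine with
identical weights, which makes profiling commute with linear combination. The
contribution of class $XY$ is
$m_{XY}\,(f_{XY}(\text{apex}) - f_{XY}(\text{baseline}))$, where $f$ is the
per-bin count (sum mode) or the per-bin count *fraction* (mean mode). Using
per-bin fractions — the average of ratios rather than the ratio of averages —
makes the mean-mode decomposition exactly additive too, so the
"normalisation residual" the design anticipated is zero to machine precision;
it is still reported for transparency.

Repeat partitioning assigns a step to a repeat class iff both its bases lie
inside one interval of that class, with a fixed, documented precedence
(transposon families before tandem-repeat classes; first wins) and exact
count conservation (partitions plus "outside" reproduce the total, asserted
bitwise). Two normalisations are emitted side by side, column-labelled:
`rel_abs_pct`, the share of the summed absolute dinucleotide contributions
(sums to 100 over the 16 classes; repeat classes use the same denominator so
both categories live on one scale), and `pct_of_peak`, the signed
contribution relative to the signed height (which can exceed 100 in both
directions — the property value is often a tightly balanced average of
opposing influences, and hiding that behind a signed normalisation would be
misleading).

## Synthetic data: what it does and does not emulate

The generator produces i.i.d. or first-order Markov backgrounds; repeat
insertions that *overwrite* the sequence (coordinates never shift, which
keeps truth bookkeeping trivial and matches the fact that a real genome is a
fixed string); and anchors whose flanks are resampled from a local
first-order chain whose stationary dinucleotide distribution equals the
background scaled by the requested enrichment factors, discretised in
distance steps. The truth record stores the exact stationary distribution
per distance bin — the quantity the profile stage must recover — and
recovery is asserted at 3–4 standard errors. Enrichment can be specified per
dinucleotide, or per nucleotide (`nuc_enrichment`), the latter expanding to
$g_{XY} = g_X g_Y$, i.e. a pure composition gradient with dinucleotides at
zero-order proportions — exactly the confound the reference models must
cancel. Every operation draws its RNG stream from the master seed plus an
operation key (`derive_seed()`), so stages regenerate independently and
reruns are byte-identical.

Not emulated, by design: transposon phylogenies and subfamily structure
(the bundled AluLike/L1Like consensi are deterministic synthetic sequences
with family-typical composition — G+C/AG-rich vs A+T-rich — not biological
consensi), CpG-island methylation landscapes, mutation processes, and
assembly artefacts beyond `N` runs. Passing tests therefore demonstrate that
the *machinery* recovers known compositional structure; they do not
demonstrate anything about a particular real genome.

## Problem sizes and numerical choices

The test and validation designs use two 150–300 kb chromosomes at 100 bp
resolution with 20–40 anchors, 3 kb flank supports, 6 kb profile half-widths
and 4 kb baseline thresholds — a 1:10 scale model of the 1 kb / 1 Mb / 800 kb
defaults, chosen so the full suite runs in minutes while keeping every
per-distance estimate comfortably away from small-sample pathology (20+
anchors per distance, 40+ baseline bins). Oracle replication depths (10 000
shuffles; 3 x 1000 Markov simulations; 200 correlation runs; 50-seed
cancellation experiments) are the points where the corresponding standard
errors are several times smaller than the tolerances being asserted.
Degenerate inputs are contracts, not accidents: empty bins propagate `NA`
under mean mode rather than dividing by zero; an all-invalid track refuses a
global reference; a profile whose center bin has no weight refuses a peak
call; zero-variance bootstrap samples are redrawn a bounded number of times
and then error out.

## Known limitations

* Exact-match tandem repeats only; no mismatch/indel tolerance.
* Raw significance levels; no multiplicity correction across models and
  annotation sets (raw sigmas are the honest output when the downstream use
  is ranking).
* Independent-position bootstrap; no block bootstrap for autocorrelated maps.
* The peak-height estimator's selection bias (quantified above) is inherent
  to "maximum over the significant span"; heights below ~10 per-distance SDs
  are systematically overestimated by more than 10 %.
* Influence decomposition is a linear attribution, not a causal claim.
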