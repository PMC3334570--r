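---
title: "Indel linkage disequilibrium and imputation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indel linkage disequilibrium and imputation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelLD)
```

indelLD characterizes how well short insertion–deletion variants (indels,
< 50 bp, bi-allelic) are captured by nearby SNPs in phased diploid panels,
and how accurately their genotypes can be imputed from those SNPs.  This
vignette is the package's own account of the underlying models, the
choices embedded in their defaults, and what the bundled simulator can and
cannot tell you about real data.

## Data model

A `hap_panel` holds an ordered site table and a strictly binary phased
haplotype matrix (rows `2i−1`, `2i` belong to sample `i`).  Three rules
are enforced at construction and never relaxed downstream:

* **Bi-allelic sites only.**  Multi-allelic records are dropped (tallied)
  at VCF read time; a site is a SNP iff both alleles have length 1, a
  deletion iff the reference allele is longer, an insertion otherwise,
  with `indel_length = |len(ref) − len(alt)| < 50`.
* **No missing or unphased genotypes.**  `./.` or `0/1` aborts the read.
  The panels this package models are complete phased call sets; silently
  imputing or dropping entries would shift every downstream statistic
  without leaving a trace.
* **One site per position.**  When an indel and a SNP share a position —
  in a merged file or when merging an indel panel with a SNP panel — the
  indel is retained and the SNP discarded (counted).  Two same-class
  records at one position are an error, not a silent choice.

Coordinates are 1-based VCF positions; distances are `|pos_a − pos_b|` bp
and windows are closed intervals.  Sex chromosomes are accepted
syntactically but treated like autosomes; ploidy nuances are out of scope.
Minor allele frequencies are always re-computed from the panel's own
haplotypes, never taken from input annotations, so sample subsetting is
automatically reflected.  The MAF convention throughout: below 1 %
excluded (in the data this package emulates these were all singletons),
1–5 % "low frequency", above 5 % "common".  A MAF of exactly 5 % is binned
common; the boundary is configurable in `maf_bin_scheme()`.

## Linkage disequilibrium

`pairwise_r2()` computes r² from the 2×2 phased haplotype table:
`D = p11 − p·q`, `r² = D²/(p(1−p)q(1−q))`.  Because the input is phased
there is no EM or composite-LD ambiguity, and no genotype-correlation mode
is offered.  `ld_scan()` pairs each focal variant with every polymorphic
SNP within ±100 kb (default); partners are SNPs both for indel focals
(indel–SNP LD) and SNP focals (the SNP–SNP control), so the two are
directly comparable.

Summaries follow the field's conventions:

* `average_r2_curve()` — mean r² over all pairs in 100-bp distance bins;
* `mean_max_r2_curve()` — for each focal variant and 1-kb bin, the best
  partner r² in that bin, averaged over focal variants with at least one
  partner there.  An alternative reading (assign each focal's single
  overall maximum to its best partner's bin) exists; this package
  implements per-bin maxima and documents, not implements, the
  alternative.
* `tagging_summary()` — percentage of focal variants with a partner above
  r² 0.5 / 0.8 / 1.0.  "Greater than" is strict; "equal to 1" uses a
  1e-9 tolerance because r² = 1 arises from identical columns whose
  floating-point frequencies can differ in the last ulp.
* `haplotype_span()` — the positional extent (max − min position) of the
  set {focal} ∪ {partners with r² > 0.8}.  "Haplotype length" has no
  single standard definition; this span of the high-LD neighbourhood is
  an interpretation, chosen because it is computable from the pair table
  alone and monotone in the quantity of interest (how far useful LD
  extends).

Empty distance bins are emitted with `n = 0` and `NA` values and excluded
from plots and statistics rather than zero-filled, which would bias curve
averages downward.

## The haplotype-copying imputer

`copying_posteriors()` implements a Li–Stephens-style HMM.  States are the
`H` reference haplotypes; across a gap of `d` bp the chain stays put with
probability `exp(−λd) + (1 − exp(−λd))/H` and moves to each specific other
state with probability `(1 − exp(−λd))/H`; emissions match the target
allele with probability `1 − ε`.  Posterior state weights are computed by
forward–backward (scaled, in compiled code) and read at the context SNP
nearest the query position — left on ties — rather than interpolated
between flanking SNPs; in the dense-SNP regime the nearest SNP is
essentially at the query position and interpolation would buy complexity,
not accuracy.

Parameters, units and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `switch_rate` (λ) | per-bp switch intensity | 4e-5 | expected copy segment ≈ 25 kb, the observed scale of extended haplotypes around common variants |
| `emission_error` (ε) | allele mismatch probability | 0.005 | treats observed panel genotypes as correct with likelihood 0.995 |
| `window` | context radius | 100 000 bp | matches the LD scan window |

`impute_indel_genotype()` evaluates one (sample, indel) pair
**leave-one-individual-out**: the sample's two haplotypes are removed from
the reference, the focal indel is masked in the target, each target
haplotype's alt probability is the posterior-weighted mean of the
remaining haplotypes' indel alleles, and the two haplotypes combine under
phased independence into a posterior over ref/ref, ref/alt, alt/alt.
Whether the evaluation should be in-sample or leave-out is a genuine
design fork; leave-one-out is chosen because in-sample evaluation lets the
HMM copy the sample's own haplotypes and trivially reproduce the truth
(the package exposes `include_focal = TRUE` precisely to demonstrate that
degenerate 100 % as a machinery check).  Hard calls are the posterior
argmax, ties broken toward the genotype class more frequent in the panel
(then the lower class index); tie counts are logged.

`loo_concordance()` pools genotypes into 3×3 true-by-imputed tables.
Concordance is genotype-weighted (every evaluated genotype counts once)
rather than indel-weighted; the alternative — average per-indel
concordances — would up-weight indels with few evaluable genotypes.
Focal/sample combinations where leave-out leaves the indel monomorphic in
the reference are skipped and tallied: there is nothing left to copy, and
scoring a forced call would conflate panel composition with imputer skill.

`r2_binned_concordance()` groups each focal's context SNPs by their r²
with the focal into 20 bins of width 0.05 (left-open, right-closed, the
first closed at 0) and reruns the leave-one-out evaluation per bin using
only that bin's SNPs — the HMM is rerun on the restricted SNP set rather
than reusing full-context state posteriors, because the question is what
those SNPs alone can do.  `freq_matched_concordance()` restricts context
to SNPs in the focal's own MAF bin.

## The founder-mosaic simulator

`simulate_panel()` generates phased panels in three seeded stages:

1. **Founders** — `n_sites` positions drawn uniformly without replacement;
   per-site frequency from a truncated `f^−a` density on
   `[f_min, 0.5]` (`a = sfs_exponent`, default 1, a 1/f-like spectrum);
   founder alleles i.i.d. Bernoulli(f), resampling sites monomorphic
   across founders (so retained frequencies are conditioned on
   polymorphism — visible as a slight upward shift of the realized mean).
2. **Mosaic sampling** — each of the `2·n_samples` haplotypes copies a
   uniform founder, switching to a uniform founder between consecutive
   sites with probability `1 − exp(−switch_rate_sim·d)`; each entry then
   flips with probability `mutation_rate`.  Sites monomorphic in the
   sample are dropped and tallied — `n_sites` is a target, not a
   guarantee.
3. **Indel overlay** — a random `indel_fraction` of sites is relabelled
   indel: deletion with odds `deletion_odds` (default 1.25, the deletion
   excess reported for large short-read call sets), length
   `1 + Geometric(p)` capped at 49 bp with `p = 1 − 0.1^(1/6)` so that
   P(length ≤ 6) = 0.9 exactly, allele strings synthesized in anchor-base
   VCF convention, and LOF labels assigned with probability `lof_rate`
   (default 0.44, the observed LOF share among exonic indels) only inside
   exon intervals, matching the notion of LOF as coding/splice
   disruption.

Default conditions: 60 diploid samples (a single-population panel of the
size this analysis was designed around), 1 Mb regions, 1 000 target sites,
20 founders, `switch_rate_sim = 4e-5` (≈ 25 kb founder segments — chosen
to match the measured median extended-haplotype scale for common
variants, and deliberately equal to the imputer's default λ scale),
`mutation_rate = 1e-3`, `indel_fraction = 0.08` (the indel:SNP ratio of
large joint call sets), `f_min = 0.025`.  Stage seeds derive from the
configuration seed as `seed`, `seed+1`, `seed+2` (`seed+3` for site-list
subsampling), so each stage is independently reproducible and every output
is a pure function of the configuration.

A founder-mosaic model was chosen over a coalescent simulator because it
is small, seedable, dependency-free and gives directly tunable LD decay.
**Demographic realism is explicitly not a goal.**  What the simulator
does emulate: distance-decaying LD, a 1/f-like MAF spectrum with a
tunable low-frequency share, the deletion excess, the indel size
distribution, and LOF enrichment in exons.  What it does not emulate, and
what passing tests on it therefore cannot certify about real data:

* **Allele-age structure.**  Every simulated variant — indel or SNP — is a
  function of local founder identity plus sparse noise.  Real
  low-frequency variants are *recent* mutations on one branch of a local
  genealogy; SNPs in weak LD with them genuinely cannot identify carrier
  haplotypes.  In the mosaic model, a sufficiently dense set of even
  weakly-correlated SNPs can pinpoint the local founder and hence the
  indel allele.  The practical consequence: in the r²-binned experiment
  the lowest bin (r² 0–0.05), which contains most window SNPs, imputes
  heterozygotes *better* than the sparsely-populated neighbouring bins,
  so the concordance-versus-r² curve rises steeply from the second bin
  onward but is not monotone at its first step.  On real panels the same
  experiment is expected to show the monotone rise, because aggregate
  founder identification is not available there.
* **The r² continuum.**  With i.i.d. founder columns, high r² between two
  sites requires a chance coincidence of founder patterns, so high-LD
  indel–SNP pairs are much rarer than in real data (where shared
  genealogy makes them common).  Tagging percentages from the simulator
  are therefore far below published values and should be read only
  comparatively (between strata), never as absolute calibration.
* Multiple populations, gene conversion, and locally elevated mutation
  rates at repeat loci are absent.

## Statistical tests

`two_proportion_test()` is the pooled two-sided z-test without continuity
correction; published uses of this test rarely state sidedness or
correction, so results may differ from other software in the last digit.
`mann_whitney_test()` computes U by midrank sums and a two-sided p from
the normal approximation with tie-corrected variance and continuity
correction — appropriate at the sample sizes this package targets; exact
enumeration appears only as a brute-force oracle in the test suite.
Degenerate inputs (pooled proportion 0 or 1; all values tied) return
`p = 1` with an explicit flag rather than `NaN`.  Stratum comparison
reports apply **no multiple-testing correction**, mirroring the common
reporting convention for this analysis; the output carries a note saying
so, so readers are not misled.

## Numerical and scale choices

* Forward–backward uses per-site normalization (no log-space needed at
  these scales); the transition's rank-one structure gives O(H) updates.
* r² = 1 detection uses a 1e-9 tolerance; posterior ties use 1e-12.
* Problem sizes in the test suite and acceptance script — 650-site 1-Mb
  panels (~50 focal indels) at 60 samples, 20 replicate seeds for
  stochastic properties, five replicates in the acceptance script — were
  chosen so each stochastic check pools thousands of genotypes while the
  whole suite stays comfortable on a laptop-class single core.
* Focal sampling (`focal_sample_n`) is optional and seeded; the default
  analyzes all focal indels, since at these panel sizes sampling is a
  cost knob, not a statistical necessity.

## Known limitations

Beyond the simulator caveats above: the imputer is a transparent
stand-in, not a reimplementation of production engines (no genotype
likelihoods, no unphased targets, no phasing, no reference-panel
selection across populations); region annotation is a plain first-match
BED interval lookup, not gene-model annotation; and LOF status is an
input label, never predicted.  Absolute concordance and tagging values on
synthetic panels reflect the mosaic model's LD regime and transfer to
real data only as qualitative patterns: class-stratified concordance
ordering, frequency-matched tagging structure, and the steep gain in
heterozygote imputation once moderately informative SNPs are available.
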