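---
title: "Deconvoluting Barrett's Esophagus subclones and testing their phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting Barrett's Esophagus subclones and testing their phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beclone)
```

## The inference problem

A Barrett's segment is sampled by 4–6 epithelial biopsies per patient,
each sequenced to roughly 60x, taken at known heights (cm) above the
gastroesophageal junction and at 2–3 endoscopies years apart. A biopsy
is a bulk of ~10^6 cells and often mixes clonal lineages; lineages can
differ in local copy number and in ploidy. The quantity of interest is
the within-patient phylogeny of those lineages — which biopsies carry
related clones, how many independent clonal origins a segment has, and
how far lineages carrying candidate-gene mutations have spread.

The signal is the somatic SNV. Over 99% of SNVs are annotated as
non-functional, so averages over hundreds of SNVs trace the history of
the clone carrying them rather than selection on individual sites. A
group of SNVs born on one ancestral lineage is detected in the same
subset of samples and sits at a common variant allele frequency (VAF)
per sample, determined by the carrying lineage's cell fraction (CF)
and the local copy state: a heterozygous SNV on 1 of 2 copies in a
lineage at CF *f* has expected VAF *f*/2.

## Model and procedure

**Partitioning.** SNVs are grouped by the exact subset of samples in
which they are detected (≥ 3 alt reads by default). Detection, not
VAF, defines the partition; allelic dropout of low-CF lineages moves
SNVs between partitions and is handled later. Three filters mirror the
reliability floor used throughout: SNVs whose absent samples include
one with minor copy number 0 at the position are excluded (their
ancestral absence is unreadable after haplotype loss); biopsies in
which no partition (private SNVs included) reaches 100 SNVs are
dropped; and only partitions/peaks of ≥ 100 SNVs count as
phylogenetic evidence.

**Peak detection and weighting.** Within each partition and
copy-number group, each sample's VAF histogram is smoothed with a
Gaussian kernel (bandwidth: Silverman's rule × 0.5, floored at 0.01
VAF) and local maxima closer than 0.03 VAF merge into the higher one.
The candidate peaks seed one-dimensional Gaussian mixtures; nested
models over the 1..K most prominent peaks are compared by BIC, and the
selected model's mixing proportions give the SNV count under each
peak. Component standard deviations are floored at 0.01 and *capped*
at 1.3× the binomial read-sampling level for the group's mean depth:
at known depth, spread beyond counting noise is structural (multiple
lineages or haplotype levels), and the cap is what lets the model
tell one over-dispersed component from two genuine peaks ~0.15 VAF
apart. This resolution limit is physical: two lineages whose CFs
differ by less than ~0.3 produce VAF peaks closer than ~2.5 noise
standard deviations at 60x and cannot reliably be told apart — the
same limit that applies to hand deconvolution of such data.

**Interpreting multiple peaks.** Two or more retained peaks in a group
admit three explanations, tried in order: (1) *unbalanced copy
number* — accepted only when the CN call is unbalanced and the peak
ratio matches the haplotype copy ratio (relative tolerance 0.25); (2)
*genome doubling on the branch* — accepted only when every partition
sample has externally corroborated doubling and the peaks differ by a
factor of two (a doubling pattern without corroboration is never
treated as doubling); (3) *split lineages* — the partition holds two
(or more) lineages relating the same samples at different time
depths. For the split case the SNVs are separated in the joint VAF
space across samples by a diagonal-Gaussian EM (Ward-initialized,
binomially capped, component count by BIC), because distinct lineage
vectors can collapse onto the same marginal peak in every single
sample. Groups with more than three peaks in any sample are
unresolvable and flag the patient.

**Assembly.** Each retained (partition, lineage) pair is a *claim*:
a sample set with per-sample CFs (VAF × total copies / mutant copies,
capped at 1) and an SNV support count. Claims are processed
two-samples-first, larger support first, ties lexicographic. A claim
becomes an internal node; existing root clades whose sample set is a
subset of the claim's and whose CFs fit within the claim's per-sample
CF budget (tolerance 0.10) become its children, chosen greedily by
support; per-sample CF left over (≥ 0.15, the detectable minimum)
becomes a new lineage tip. Sample groups never joined by a ≥ 100-SNV
claim remain disjoint trees — scored as independent origins. After
assembly, each biopsy's tip CFs must sum to ≤ 1.05; a violation is
resolved by reclassifying the smallest conflicting claim as allelic
dropout of a compatible superset claim (at most 5 attempts), after
which the patient is declared unresolvable and excluded from
statistics. Tip CFs are then re-estimated as the support-weighted mean
over the branches on the tip's root path in which it is its sample's
only lineage — a tip keeps the CF it had when it diverged; private
SNVs are never deconvoluted.

**Branch lengths and candidate loci.** Each usable SNV is assigned to
the branch whose descendant biopsies are exactly its detected set;
among several such branches the one with the nearest expected VAF
wins; unmatched SNVs are discordant and dropped. Functional
(MODERATE/HIGH severity) mutations in the candidate loci are placed
the same way but preferring branches that permit heterozygosity;
zygosity per sample compares the observed VAF with CF/total-copies
(het) and CF (hom), ties to het; mixed patterns assume an ancestral
heterozygote with wild-type losses as secondary events on tipward
branches.

## Statistical tests

All significance testing resamples on the inferred forests themselves,
since a credible forward model of BE segment growth is not available.
The permutation engine draws 10,000 resamples by default, counts
resamples more extreme than the observed statistic, resolves
observed/resampled ties with fair coin flips, doubles the smaller tail
for two-tailed tests, and reports exact zeroes as "< 1/n". Tips from
the same biopsy always carry the same label and move together under
permutation.

* *Clustering* (one-tailed): summed minimum parsimony changes over
  patients, for Upper/Lower (unordered; lowest biopsy and those nearer
  to it than to the highest are "L", equidistant biopsies join the
  smaller group or "U" on a tie, all-equal patients are excluded),
  time point (unordered), and cm-from-GEJ (ordered, cost = |Δcm|,
  i.e. Wagner parsimony; the null permutes the multiset of cm values).
  Both counts are computed by a generalized Sankoff dynamic program so
  multifurcations are exact, and no changes are scored between
  disjoint trees. For linear costs, optimal internal states can be
  chosen from the tip values, so the DP over the tip-value lattice is
  exact (the suite checks this against denser grids).
* *Subclonality* (two-tailed): a sample is subclonal when the forest
  shows ≥ 2 lineages for it. Four tests permute subclonality status
  across samples: patient-level clustering, CO/NCO, Upper/Lower, and
  TP1/TP2 (TP3 omitted).
* *Expansion* (two-tailed): total descendant leaves and total
  descendant CF of mutation-carrying lineages per locus, vs re-placing
  the same per-patient mutation counts on branches with probability
  proportional to branch SNV length. Heterozygous/homozygous variants
  re-place secondary events among branches tipward of the initial
  placement.
* *Dispersion* (two-tailed): number of patients carrying the locus's
  mutations, vs cohort-wide weighted re-placement.
* *Ordering*: for a locus pair (or locus vs genome doubling), each
  patient's event pairs are classified same-branch / A-first /
  B-first / skew, averaged within the patient, summed over patients,
  and compared with resampled expectations by a chi-square
  heterogeneity statistic with 6 degrees of freedom (configurable; the
  convention is kept although four categories would suggest fewer).
* Benjamini–Hochberg q-values are computed within families mirroring
  the analysis tables (the nine clustering tests; the four
  subclonality tests; expansion cells; dispersion per locus; ordering
  pairs), via `stats::p.adjust`.

Permutations are within-patient for the clustering statistic (it is a
per-patient tree property); the subclonality statistics permute across
the cohort, following the description of the source analyses.

## The synthetic cohort

The generator emulates the cohort structure the pipeline targets:
half cancer-outcome (CO) patients with 4 biopsies at 2 time points,
noncancer-outcome (NCO) patients with 4 or 6 (25% have a third time
point); 60x Poisson depth with binomial alt counts and a 3-alt-read
detection threshold; origin counts drawn from the observed 43:29:5:1
split over 1–4 origins, each origin holding a spatially contiguous
block of biopsies; random bifurcating lineage trees per origin with
150–600 SNVs per branch; ~44% of biopsies carrying two lineages.
Topology couples to biopsy position through a trait that mixes
standardized GEJ distance with Gaussian noise (`spatial_autocorrelation`
∈ [0,1]; 0 makes topology independent of position — the calibration
null) and never couples to time point. Genome doubling (default 3%
per eligible branch) halves the VAF of post-doubling SNVs in doubled
samples, yielding the factor-of-two two-peak signature; unbalanced CN
(2+1) and one-haplotype losses (2+0/1+0) are drawn per near-diploid
sample and chromosome. Candidate loci carry functional mutations at
~0.35 per patient per locus, homozygous with probability 0.4; an
expansion-bias exponent (default positive for *TP53* and *CDKN2A*,
zero elsewhere) up-weights branches with many descendant leaves when a
homozygous mutation is placed, so both null and enriched regimes are
available.

Two generator choices are resolution-driven rather than copied from
any data: the two lineages of a subclonal biopsy are drawn with CFs
separated by ≥ 0.3 (mixtures closer than that are below the VAF peak
resolution at 60x and not deconvolutable by any method at this depth),
and the two lineages of one biopsy are never each other's closest
relatives (such substructure is indistinguishable from private
variation; tip lineages that split further after divergence are not
deconvoluted).

What passing recovery tests on this generator shows is that the
pipeline correctly inverts its own observation model — detection,
binomial noise, dropout, copy-state arithmetic — on identifiable
structure. It does not show robustness to mutational signatures,
subclonal copy-number variation within a biopsy, sample contamination,
or caller-specific artifacts, none of which are modeled.

## Numerical choices and degenerate inputs

Kernel bandwidth, merge tolerance, the 100-SNV floors, CF tolerance
(0.10), ratio tolerance (0.25), and the detection threshold are config
keys (`be_config()`) with the defaults above. Mixture EMs run at most
100 iterations to a relative tolerance of 1e-7 with a (0.01)^2
variance floor; a degenerate fit falls back to hard assignment by
nearest peak with a warning. Assembly is fully deterministic — ties
break by support then lexicographically — so a cohort deconvolutes
identically on every run. Constant VAF vectors yield a single peak at
that value; groups smaller than 100 SNVs are never deconvoluted;
patients whose biopsies all sit at one GEJ distance are excluded from
the Upper/Lower analysis; a patient with no usable SNVs yields an
empty forest that downstream tests skip.

The problem sizes used by the validation suite — 100 simulated
patients for topology/CF recovery, 200 replicate 6-patient cohorts at
1,000 resamples for test calibration, 1,000 random trees (≤ 12 tips)
for the exhaustive parsimony check — were chosen to give stable
empirical rates while keeping a full run of the suite comfortable on a
single core. Calibration runs the statistics on the generator's true
forests: it isolates the test machinery's type-I error from
deconvolution error, which the recovery criterion measures separately.

## Known limitations

Private-mutation substructure is not deconvoluted; tip CFs are those
at divergence. Loss of a candidate locus purely by deletion is
invisible to an SNV-based analysis, so homozygous-loss counts for
deletion-prone loci (notably *CDKN2A*) are underestimates. Lineage
mixtures with CF separation below ~0.3 at 60x merge silently. The
ordering test inherits the 6-df chi-square convention; its calibration
depends on that choice. Genome doubling enters ordering and expansion
tests as a mutation-like event, which implicitly assumes SNV counts
proxy the opportunity for doubling on a lineage — results involving GD
should be read with that caveat.
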