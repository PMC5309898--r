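---
title: "Models and methods behind hybridtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridtrace)
```

`hybridtrace` implements the statistical chain used to argue that a
species radiation began as a hybrid swarm: detect admixture (D
statistics), quantify it (F4 ratio), orient it (five-population test),
localize it (fd scans and ancestry painting), and trace the sorting of
the admixture-derived variation among daughter species (F<sub>ST</sub>
outlier enrichment by ancestry category). This vignette records the
models, the parameter choices, and the places where a design decision had
to be made.

## Quartet statistics

All frequency-based statistics work on per-group derived allele
frequencies. Polarization uses the outgroup **major** allele as
ancestral; sites where the outgroup is missing or exactly 50/50 are
flagged unpolarizable and dropped from polarized analyses. (With a
polymorphic outgroup there is no unambiguous rule; the major-allele
convention is the least surprising and the tie case is rare and
unsalvageable.)

Patterson's D weights each site by its fit to the ABBA or BABA pattern
(a site with derived frequencies 0, 0.5, 1, 0 is half an ABBA site). Two
conventions had to be pinned down:

- **Sign.** `d_statistic()` puts Σ(BABA − ABBA) in the numerator so that
  D > 0 means excess sharing between P1 and P3. Durand-style
  presentations use the mirror image; the choice here matches the
  orientation in which the radiation is P1 and its Congolese sister P2,
  so that admixture with P3 appears as positive D. The fd scan follows
  the opposite, recipient-as-P2 convention of its original description -
  the roles are explicit arguments precisely because silent misordering
  is the classic mistake with these tests.
- **Label invariance.** Internally both allele-label orientations are
  summed (ABBA gains the term p₁(1−p₂)(1−p₃)p₄), which makes D exactly
  invariant to which allele a VCF happens to call the alternate. Under an
  outgroup fixed for the ancestral allele the extra term vanishes and the
  weights equal their textbook form.

Significance uses a delete-one **block jackknife** over contiguous runs
of 500 sites within scaffolds (configurable; the count-based default
avoids any dependence on scaffold length heterogeneity), with blocks
weighted by size (the delete-m_j scheme of Busing et al. 1999, which
reduces to the classic jackknife for equal blocks) and |z| ≥ 3 as the
significance threshold. The F4 ratio jackknifes the ratio of sums, not
the ratio of means, so unequal terminal blocks are handled correctly;
a denominator below 1e−12 in absolute value is reported as an undefined
ratio rather than a number.

Missing data are handled complete-case per statistic: a site enters a
quartet or quintet computation only if every required group has a
frequency there.

Because the precision of the F4 ratio depends strongly on which
unadmixed relative plays A, `f4_ratio_sweep()` fits every candidate and
returns them ranked by jackknife SE instead of hard-coding one choice.

## Five-population directionality

The five-population test works on haploidized single individuals:
heterozygous sites take one allele uniformly at random (seeded;
re-drawn per panel run rather than cached, so repeated panels are
honest replicates). Sites are classified into the eight patterns over
(P1, P2, P3a, P3b, O) with the outgroup allele defining the ancestral
state; sites where the outgroup carries the alternate allele are treated
as polarization failures and excluded rather than re-polarized. The four
contrasts are

D1 = (BABAA−ABBAA)/(BABAA+ABBAA), D2 = (BAABA−ABABA)/(BAABA+ABABA),
D12 = (BABBA−ABBBA)/(BABBA+ABBBA), D3 = (BBBAA−BBABA)/(BBBAA+BBABA).

The D12 and D3 contrasts are stated explicitly in the five-population
test's description; D1/D2 are completed per the partitioned-D convention
of Eaton & Ree. The mapping lives in one function (`partitioned_d()`) so
that a different orientation is a one-line change.

Bootstrap z scores resample sites with replacement, implemented as a
multinomial redraw of the per-site pattern-class counts - exactly the
same distribution as resampling site indices, at a fraction of the cost.
The direction rule: significant positive D12 with non-significant D3 is
gene flow from the P3 clade into P1; significant D3 with non-significant
D12 is flow out of P1 into P3a (positive) or P3b (negative); both
significant is ambiguous. One caveat found while validating the design:
donor-side introgression does leak a small positive expectation into D3
through terminal-branch variance, so the test's discrimination relies on
the deep (parental) divergence dominating the within-lineage splits.
With internal-branch drift 0.3 and terminal drift 0.05 - the regime
matching a ~2-6 My parental split against young species - recovery is
essentially perfect at a donor fraction of 0.2; with comparable internal
and terminal drift the ambiguous rate rises.

## Windows, fd and tracts

Coordinates are 1-based inclusive on VCF input, 0-based half-open for
all internal window arithmetic, and BED convention on tract output.
Windows are non-overlapping, 10 kb for fd and 3 kb for ancestry
painting; terminal windows keep their true (shorter) span, with the
scaffold extent taken as the last observed site position since a VCF
carries no contig lengths. Integer-phrased pattern thresholds are
applied to the weighted (real-valued) totals: fd windows need a weighted
ABBA+BABA total ≥ 5, painting windows a weighted ABBA+BBAA total > 1.
"Scaffolds with < 100 kb of data" is read as scaffolds whose span of
windows with data is below 100 kb (configurable).

fd divides the observed ABBA−BABA excess by its value when the donor
frequency (the larger of p₂, p₃, chosen per site) replaces the
recipient's. Windows with negative D are set to fd = 0 - only positive
fd is a correctly standardized admixture fraction - and retained values
are clamped to [0, 1]. fd works fine on single diploid individuals
(frequencies 0, 0.5, 1), which is how the per-individual correlation
analysis uses it.

Ancestry painting colours a window Upper Nile when ABBA/(ABBA+BBAA) ≥
0.7, Congolese when ≤ 0.3. Tract merging joins consecutive same-colour
windows, bridging a *single* interior no-data window (two or more break
the run, as do unassigned windows). The analytic expectation for the
minor-ancestry tract length is 1/((1−m)·r·t): 500 bp at m = 0.2,
r = 2.5×10⁻⁸, t = 100,000 generations, 1 kb at t = 50,000. Since 500 bp
≪ 3 kb, most painted blocks span one window and the block-size
distribution measures window resolution more than tract length; the
package states this rather than pretending otherwise.

## Allele sorting

Per-SNP global F<sub>ST</sub> is Weir & Cockerham's (1984)
multi-population θ, vectorized over sites; negative estimates are
retained. The outlier flag needs a null. Rather than reconstruct a
specific hierarchical-coalescent tool whose configuration is not
recoverable, `flag_outliers()` simulates a transparent finite-island
null matched on expected-heterozygosity bins: ancestral frequencies
resampled within each bin, Balding-Nichols deme frequencies with F set
to the data's own multilocus θ, binomial genotype sampling at the
observed sizes, and a one-tailed empirical P per SNP (P < 0.05 flags an
outlier). An empirical top-quantile mode exists for pipelines that want
no simulation. The null is calibrated by construction and verified by a
test that neutral island-model data yield ≈5% flags.

Ancestry categories follow presence/absence of the two radiation
alleles in the parental lineages: (1) only one allele seen in both
parents together, (2) both within the Congolese taxa, (3) Congolese
monomorphic but Upper Nile polymorphic, (4) parents fixed for
alternative alleles. The categories are implemented as **disjoint**
(category 3 excludes divergently fixed sites) because the enrichment
comparison needs non-overlapping bins; a nested reading (4 ⊂ 3) exists
in the literature but would double-count. "Fixed" means literally all
observed alleles identical among the ≥ 3 called individuals required per
parental group - with samples this small a frequency tolerance would
manufacture fixation. LV-monomorphism is evaluated on the samples that
survive the coverage filter.

The category-5 control set weights parental frequencies 0.84/0.16
(congolese/nile), folds to a weighted minor allele frequency, and keeps
sites in the 14-18% window that are not divergently fixed - sites with
the same expected starting frequency in the swarm as category-4 sites
but no possible parental incompatibility. Enrichment is a two-sided
Fisher exact test of each category against this control set, and
`weight_robustness()` repeats everything across Upper Nile weights
0.10-0.30.

## The simulator

`sim_hybrid_swarm()` is a frequency-and-tract simulator, not a
coalescent: ancestral frequencies are uniform on (0.05, 0.95), each
parental lineage drifts by a Balding-Nichols beta (F = 0.2 by default,
standing in for the deep Congo/Nile divergence), and frequencies within
`loss_threshold` = 0.01 of the boundary are set to exact loss/fixation -
a finite parental deme carries no alleles rarer than ~1/(2N), and
without this the parental lineages could never be genuinely fixed
anywhere and ancestry categories 1 and 3-4 (beyond the forced subset)
could not occur. A `frac_bdm` = 0.02 subset of sites is forced to
divergent fixation; with `bdm_drift` > 0 those sites additionally get
exaggerated per-species sorting (each species' minor-parent frequency
drawn with drift 0.8), emulating strong differential sorting at
incompatibility-like loci while keeping the across-species mean at the
ancestry proportion.

Ancestry along each haplotype is a stationary two-state Markov process:
Upper Nile tracts exponential with mean 1/((1−α)·r·t), Congolese with
mean 1/(α·r·t), so the stationary Upper Nile fraction is exactly α
(default 0.2, r = 2.5×10⁻⁸, t = 100,000).

Daughter species come in two flavours, chosen by `species_model`:

- `"tracts"` (default): each species has `n_founders` = 4 founder
  haplotype mosaics; sampled haplotypes copy a founder's tracts and draw
  alleles from per-species drifted parental frequencies conditional on
  local ancestry. The founder bottleneck is what makes conspecific
  individuals share an admixture history, so their fd profiles correlate
  while different species' profiles do not - the structure the
  window-scan analyses are about.
- `"drift"`: each species' allele frequency at every site is a single
  Balding-Nichols draw (F = `f_species` = 0.05) around the swarm mean
  α·pN + (1−α)·pC, with no ancestry linkage. This is the correct neutral
  null for the sorting analysis on unlinked RAD-like SNPs: under the
  tract model, divergently fixed sites carry ancestry-mosaic variance
  that frequency-matched control sites dilute, so the two categories are
  never drift-matched and a "neutral" run would still show spurious
  category-4 enrichment. Under the drift model, fixation probability
  depends on initial frequency alone - exactly the assumption the
  frequency-matched control set is designed to test.

The simulator also emits an unadmixed Congolese-side sister, an
Eastern-like sister of the Upper Nile lineage (drift 0.1 from it), pairs
of control species unrelated to the admixture, and an outgroup fixed for
the ancestral allele at every site (so the reference allele is ancestral
and polarization is exact in tests). The whole panel is a deterministic
function of one seed; `draw_parental_freqs()` and
`simulate_ancestry_tracts()` use the ambient RNG so the wrapper can
stream everything from that seed.

What the simulator does **not** emulate: linkage disequilibrium beyond
the ancestry-tract scale, mutation (all variation is ancestral standing
variation), selection other than the BDM sorting flag, sequencing error,
depth variation, or reference bias. Passing tests therefore demonstrate
that the statistics recover the truth of this generative model at
realistic parameter values - not that any particular empirical dataset
is free of those complications.

## Quartet/quintet calibration simulators

`sim_quartet()`/`sim_quintet()` generate drift-structured frequency or
haploid data on ((P1,P2),P3(,P3b)),O topologies with optional one-way
gene-flow mixtures, for calibration: type-I error of D under no gene
flow, and direction recovery of the five-population test (internal
drift 0.3, terminal drift 0.05, donor fraction 0.2, as discussed above).

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately bounded
sizes chosen to keep statistical properties measurable: 50,000 SNPs and
10 diploids per group (20 seeds) for F4-ratio recovery, 100 replicates
of 2,000 SNPs for D-statistic type-I error, 50 replicates of 20,000
haploid sites per gene-flow direction for the five-population test,
8,000 SNPs across six species for the sorting analyses, and ≥ 10,000
simulated tracts for the tract-length check. Fisher P values are
verified against an exhaustive enumeration oracle over all 2×2 tables
with total ≤ 16 plus 500 random tables with margins up to 30.

Degenerate inputs have defined behaviour rather than crashes: an empty
VCF body gives zero sites; a filter that removes everything warns and
returns an empty table; a zero ABBA+BABA total is an undefined-statistic
error; a zero bootstrap s.d. with nonzero D reports an infinite z with a
warning; a 2×2 table with a zero margin reports p = 1 with a warning.

## Interfaces

The package is function-first: tibbles in, tibbles out, `tidy()` and
`glance()` on fitted objects, `plot_fd_scan()`, `plot_ancestry_painting()`,
`plot_tract_lengths()` and `autoplot()` on the enrichment table.
`run_pipeline()` drives simulate → filter → D/F4 → five-population →
fd → blocks → sorting from a single list or YAML config with all the
analysis defaults baked in (|z| ≥ 3, 500-site blocks, 100 bootstraps,
10-kb/3-kb windows, 0.7/0.3 colour thresholds, 0.84/0.16 weights,
14-18% control window, P < 0.05 outliers), logs every parameter actually
used, hashes the config, and writes TSV/BED/JSON outputs. Genotype
depth filtering is exposed as a `min_depth` argument on `read_vcf()`
rather than fixed globally, since different upstream pipelines apply
different thresholds (and often have already applied them).
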