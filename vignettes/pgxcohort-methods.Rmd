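---
title: "Methods: from tag-SNP calls and Ct values to actionable pharmacogenetic phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tag-SNP calls and Ct values to actionable pharmacogenetic phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcohort)
```

## The problem

Targeted pharmacogenetic panels genotype a handful of tag rsIDs per gene and,
for CYP2D6, add a qPCR copy-number assay, because whole-gene deletions (*5)
and multiplications (xN) change enzyme dose in ways SNPs cannot show. Between
that raw data and a prescribing decision sit several inferential steps that
are usually done in vendor software and spreadsheets: copy-number
quantification and QC, star-allele diplotype resolution from unphased doses,
phenotype translation, cohort statistics and guideline lookup. `pgxcohort`
implements each step as a tested, seedable function with explicit file
formats, and ships a truth-known simulator so the whole chain can be verified
end to end.

## Copy number by the comparative ΔΔCt method

Per replicate $i$, the paired difference $\Delta Ct_i = Ct^{target}_i -
Ct^{ref}_i$ cancels well-to-well input differences; we aggregate replicates as
the mean of these paired differences (not as means of raw Cts per assay).
Against a calibrator of known diploid copy number,

$$\Delta\Delta Ct = \overline{\Delta Ct}_{sample} -
\overline{\Delta Ct}_{calibrator}, \qquad
\widehat{CN} = 2 \cdot 2^{-\Delta\Delta Ct}.$$

A target assay that never amplifies is assigned $\widehat{CN} = 0$. The
integer call is the nearest integer; classification is deletion ($\le 1$),
normal (2), duplication ($\ge 3$).

**Quality banding.** Commercial callers attach a z-score and a confidence
value to each call with proprietary formulas; we define reproducible
surrogates that keep the same threshold semantics. By the delta method the
dispersion of $\widehat{CN}$ is $\sigma_{CN} = \widehat{CN}\,\ln 2\,
\sigma_{\Delta\Delta Ct}$, and

$$z = \frac{\widehat{CN} - \mathrm{round}(\widehat{CN})}{\sigma_{CN}},
\qquad
\mathrm{confidence} = 2\Phi\!\left(\frac{0.5 - |\widehat{CN} -
\mathrm{round}(\widehat{CN})|}{\sigma_{CN}}\right) - 1,$$

clipped to $[0,1]$. Bands: $|z| < 1.75$ high confidence, $1.75 \le |z| \le
2.5$ caution, $|z| > 2.5$ reject; a calibrator confidence below 0.5 is logged
as potential model drift. Rejected calls never contribute to diplotypes or
frequencies.

Two design choices matter here. First, $\sigma_{\Delta\Delta Ct}$ is estimated
at the **plate level**: within-sample $\Delta Ct$ variances are pooled across
all multi-replicate samples and the sample and calibrator contributions add
($\sigma_{\Delta\Delta Ct} = \sqrt{2}\,s_{pooled}$). Pooling gives the
denominator many degrees of freedom — a per-sample standard deviation from
two or three replicates would make $z$ heavy-tailed and flag many perfectly
good calls. Second, the yardstick is the **replicate-level** scatter, not the
standard error of the replicate mean. That makes the band deliberately
conservative: a call is only rejected when its deviation from an integer copy
number exceeds what individual replicates routinely show.

Numerical corner cases: an estimate exactly half-way between integers rounds
*away from 2* and is banded caution (half-integer estimates are inherently
ambiguous, and the bias flags a putative variant for review rather than
normalising it); zero dispersion with a non-integer estimate is caution
(single-replicate runs cannot support a confidence claim); estimates above 6
are reported as 6 with caution (the assay's dynamic range — Ct outliers
should not produce absurd copy numbers).

## Star-allele resolution from unphased doses

Each biallelic call contributes a variant dose (0/1/2) at its rsID. Doses are
decomposed into star alleles by a containment hierarchy, resolved greedily
from the largest tag set down: each *41 consumes one rs28371725 dose **and**
one rs16947 dose (the *41 haplotype carries the *2 backbone variant); each *4
consumes one rs3892097 and one rs1065852 dose; residual rs16947 doses are *2,
residual rs1065852 doses are *10; remaining haplotype slots are *1. This
codifies the manual, PharmVar-guided curation such panels otherwise rely on.
Unphased data cannot distinguish cis from trans tag combinations, so
bookkeeping conflicts are *flagged* (`inconsistent`), and any no-call on a
panel rsID flags the sample `ambiguous` — never silently dropped. `*2A` is
accepted as an alias of `*2` (same tag, same normal function).

The integer copy number then disambiguates structure: two copies keep the two
resolved haplotypes; one copy means a hemizygote, which presents as
homozygous in SNP calls, so the second allele becomes *5 (two distinct
resolved haplotypes at CN 1 are flagged inconsistent); zero copies is `*5/*5`
(and explains away the no-calls); three or more copies annotate one allele
with the extra copies, written `xK` (K copies on one chromosome-equivalent,
total CN = K + partner copies — so `*10x3/*1` has four gene copies and
activity score 1.75).

**Duplication policy.** A single-probe (exon 9) CNV assay counts gene copies
but cannot localise which allele is multiplied. The default policy assigns
the extra copies to the highest-activity resolved allele, with ties going to
the higher-numbered label; a per-sample override column can name the
duplicated allele when orthogonal evidence exists. Every duplication call is
flagged `ambiguous`, because the assignment is an assumption: round-trip
tests verify that truth configurations matching the policy are recovered
exactly and that all others are flagged, never silently miscalled.

Rendered labels order alleles by activity descending, then label ascending,
then copies descending, so equal diplotypes compare equal as strings, and
`parse_diplotype()` is the exact inverse (the published "X ≥ 3" notation
parses to the minimum consistent K = 3 with an `ambiguous` flag; the
phenotype category is unchanged for any K ≥ 3).

## Phenotype translation

CYP2D6 uses the CPIC activity score: AS = Σ over alleles of activity value ×
copy count, with shipped values 1 (*1, *2), 0.5 (*41), 0.25 (*10) and 0
(*3, *4, *5, *6). Bins are inclusive as published: PM at exactly 0, IM
0.25–1.0, NM 1.25–2.25, UM above 2.25. With the shipped values every
achievable score is a multiple of 0.25 and the gaps (0, 0.25) and (1.0, 1.25)
are unreachable (a property test enumerates all diplotypes with copies ≤ 3);
custom allele tables that do produce gap values map to `indeterminate` rather
than to the nearest bin — unsupported extensions should fail loudly.

CYP2C19 has no activity-score system; the phenotype follows from the pair of
function classes: {none, none} PM; {none, normal} and {none, increased} IM;
{normal, normal} NM; {normal, increased} RM; {increased, increased} UM. The
six rules are total over the shipped allele table. RM and UM are always
reported separately; aggregation (e.g. pooling them as "actionable") is the
report layer's job.

## Cohort statistics

Allele frequencies use gene counting, `(2·hom + het) / (2·n)`, with missing
genotypes excluded listwise per variant (the conservative general rule when
per-variant denominators are not published). Hardy–Weinberg is tested two
ways: the 1-df chi-square without continuity correction (a `correct` flag
enables Yates), and the two-sided exact test that sums the conditional
probabilities of all heterozygote counts no more probable than the observed
one — the standard tail definition, not mid-p. The conditional distribution
is evaluated by the numerically stable two-directional recurrence from its
mode, so the test runs in O(rare-allele copies) and handles cohort-scale
counts; the unit tests verify it against a full log-factorial enumeration for
every genotype table with up to 25 individuals.

Two practical notes. The exact test is conservative: at n = 509 and allele
frequency 0.37 its measured type-I error at nominal α = 0.05 is ≈ 0.046
(2,000 seeded replicates). And agreement with the chi-square p-value is
asymptotic but *discrete*: a single heterozygote configuration carries
probability of order $1/\sqrt{n}$ (≈ 0.014 at n = 5,000), which bounds the
pointwise difference between the two p-values; the tests therefore assert
mean agreement within 0.01 at n = 5,000 rather than a pointwise 0.01.

The heterozygote-deficit diagnostic is $F = 1 - H_{obs}/H_{exp}$; under
two-deme substructure its expectation is the Wahlund quantity
$\mathrm{Var}(p)/(\bar p \bar q)$ (two equal demes at allele frequencies
0.1/0.9 give F = 0.64, which the simulator reproduces). Bonferroni thresholds
are α divided by the per-gene number of variants tested, and the sample-size
helper implements the infinite-population single-proportion formula with
ceiling rounding.

## Actionability

The recommendation engine is an exact-match lookup in a *data* table
(gene, phenotype, drug → action, strength) covering eight antidepressants;
guidelines evolve, so users can ship an updated TSV without touching code.
A drug absent from the table returns an explicit `unknown_drug` result. An
individual is actionable iff any gene's category is IM, PM, RM or UM.

The combined cross-gene prevalence is reported two ways side by side: the
direct count of individuals with at least one actionable phenotype, and the
independence formula $1 - \prod_g p_{NM,g}$ (CYP2D6 and CYP2C19 sit on
different chromosomes). The independence input uses NM proportions rounded
to three decimals, making the rounding convention of published estimates
explicit — with the published phenotype counts the two routes differ by
about 0.03 percentage points. Indeterminate phenotypes are excluded from all
proportions and reported separately, so neither the NM nor the actionable
group is inflated.

## The synthetic cohort generator

The generator is the package's substitute for undeposited cohort data, and it
defines the conditions under which the pipeline is tested. Individuals are
assigned to demes by weight; within a deme, the two haplotypes are drawn
i.i.d. from the deme's star-allele frequency vector (random union of gametes,
i.e. HWE within demes); pooling divergent demes produces the Wahlund
heterozygote deficit. Haplotype frequencies — not per-rsID minor allele
frequencies — are the generative unit, because the star allele is the thing
that segregates; per-rsID frequencies arise downstream as observables.

Default frequencies are the published cohort values: CYP2D6 *3 0.057, *4
0.104, *5 0.042, *6 0.019, *10 0.216, *41 0.173; CYP2C19 *1 0.443, *2 0.373,
*3 0.023, *17 0.161. The published CYP2D6 *2 figure (40.9%, with *2A at
46.8%) is a per-rsID variant frequency that cannot coexist with the other
haplotype frequencies in a vector summing to 1, so the default sets *2 =
0.300 — inside the 21–38% range reported across Indian cohorts — and assigns
the residual 0.089 to *1. Duplications are a haplotype attribute (4.1%
haplotype frequency, 2 or 3 copies with equal probability, matching reports
of both three- and four-copy genomes); the deletion is the *5 haplotype with
0 copies. Deletion and duplication are mutually exclusive within an
individual: a duplication opposite a deleted allele is copy-number neutral
and categorically undetectable by a single-probe assay, so such compound
genomes are excluded from the generative model, analogous to the exclusion of
hybrid alleles.

Assay noise: symmetric single-allele flip errors (default 0.5%) and no-calls
(default 1%) on genotype calls; Gaussian Ct noise (default sd 0.1 cycles) on
every Ct value, three replicates per sample, calibrator at 26/25 cycles
(target/reference). A homozygous deletion emits the no-amplification sentinel
on the target assay and `NOCALL` at every SNP; a hemizygote presents as
homozygous for its surviving haplotype. All randomness derives from one
integer seed through a documented stream-splitting scheme (`split_seed`), so
fixtures are bit-reproducible and adding a stream never perturbs another.

**What the generator does not emulate — and what passing tests therefore do
not show.** It draws the two genes independently (they are on chromosomes 22
and 10) and knows nothing of linkage, hybrid/tandem alleles (*36+*10, *13,
*14), phenoconversion by co-medication, or raw fluorescence cluster geometry.
It also cannot reproduce the published diplotype-class table from the
published allele frequencies: those two sets of published numbers are not
HWE-consistent with each other (the cohort itself deviates from HWE, and the
*2/*2A figures are per-rsID). The recovery and calibration tests therefore
validate the *inference machinery* under known truth; the desk-scale
reproduction of the published headline statistics works directly from the
published count tables, not from simulation.

## Problem sizes and test design

The shipped tests run at deliberately modest sizes chosen for tight
statistical bands at interactive runtimes: frequency calibration over 200
seeds at n = 120; Wahlund checks at n = 10,000 haplotype draws; exact-test
calibration over 2,000 cohorts of n = 509; exact-vs-enumeration equality for
all genotype tables up to n = 25; noise-free round trips at n = 400; noisy
copy-number recovery at n = 1,000 (≥ 99% of CN 1–3 samples called correctly
with high confidence at Ct noise 0.1 and 3 replicates). `scripts/acceptance.R`
re-runs the same computations from scratch under a caller-supplied seed.

## Known limitations

The allele panel is the AMP Tier 1 set, not the full PharmVar catalogue;
diplotypes involving untyped alleles will resolve to their nearest panel
interpretation (typically *1). Duplication localisation is an explicit,
flagged assumption. CYP2C19 copy number is not assayed (copy counts fixed
at 1 per allele). The independence formula for combined prevalence ignores
any cross-gene correlation induced by population substructure; the
count-based estimate is reported alongside it for exactly that reason.
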