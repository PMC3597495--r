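---
title: "Prioritizing rare copy-number variants in a short-stature case-control cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare copy-number variants in a short-stature case-control cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

## The problem

Idiopathic short stature (height below −2 SD scores with no recognized cause)
is common, and in most patients no causal variant is found. Under a
"frequent disease – rare variant" model, a fraction of severe growth
retardation should be explained by individually rare copy-number variants
(CNVs) of large effect: deletions or duplications spanning dosage-sensitive
growth genes. Finding them in an array-CGH/SNP-array screen requires a
pipeline rather than a single test: array calling produces dozens of calls
per genome, nearly all of which are inherited polymorphisms shared with the
general population.

`rarecnv` implements that pipeline as a set of composable, individually
tested steps:

1. **Polymorphism filtering** of case calls against a control cohort
   (`run_cascade()`),
2. **size-burden statistics** comparing case and control CNV size
   distributions (`threshold_scan()`, `quintile_analysis()`),
3. **trio segregation** and **de novo enrichment**
   (`classify_inheritance()`, `de_novo_enrichment()`),
4. **pseudomarker permutation association** (`associate_markers()`),
5. **GWAS-locus overlap** with a derived Bonferroni bound
   (`summarize_overlap()`, `overlap_enrichment()`),
6. **dosage-concordant expression** with a binomial enrichment test
   (`analyze_expression()`, `concordance_binomial()`),
7. **MLPA confirmation** (`mlpa_classify()`) and **lines-of-evidence
   reporting** (`evidence_profile()`, `candidate_rule()`,
   `summarize_cohort()`).

A synthetic-cohort generator (`generate_cohort()` and friends) produces all
input tracks with ground-truth labels, so every stage can be validated for
calibration (no signal in, no signal out) and recovery (spiked signal in,
signal recovered).

## Filtering model

All coordinates inside the package are 0-based half-open; 1-based inclusive
array exports are converted at the I/O boundary (`read_segments(dialect =
"array")`).

The cascade applies, in order: a calling prefilter (minimum 10 kb, 5
markers, excluded chromosomes dropped — Y-chromosome calling is unreliable
on these arrays), a 50 kb candidate floor, polymorphism exclusion,
gene-coverage exclusion, and an exonic filter. Choices that the wording of
the underlying rules leaves open are fixed as follows:

- **Overlap is query-relative.** A control call matches a patient call when
  it covers strictly more than `overlap_fraction` (default 0.95) of the
  *patient* call. The intent of the rule is to remove patient calls that are
  common in controls, so the patient call is the natural denominator. A
  reciprocal mode (`filter_config(reciprocal = TRUE)`) additionally requires
  the converse.
- **Matching is same-type.** A deletion is only explained by control
  deletions, a duplication by duplications; gains and losses are treated as
  separate signals throughout the package.
- **Exclusion triggers at carrier count > 15** (strictly more), while the
  gene-coverage rule uses ≥ 15 ("at least"); both are configurable.
- **Gene-free calls never trigger the gene-coverage rule.** A call
  overlapping zero genes would satisfy the "all included genes covered"
  condition vacuously; we disallow the vacuous case so that every excluded
  call has exactly one first-failing stage (gene-free calls are the exonic
  filter's job).
- **The 50 kb floor is inclusive** (`size >= 50`). The candidate set this
  pipeline is modeled on contains calls quoted at sizes that round to the
  floor, and an inclusive boundary keeps a size printed as exactly 50.0 kb
  scoreable; the boundary is configurable.

## Burden statistics

`fisher_exact_2x2()` implements the two-sided Fisher exact test as the sum
of hypergeometric probabilities no larger than the observed table's (the
classical definition); the odds ratio is the sample cross-product ratio with
an `Inf` sentinel for empty off-diagonals. The implementation is checked in
the test suite against full enumeration over all tables with margins up to
12 and against `stats::fisher.test()`.

`threshold_scan()` counts CNV *calls* above/below each threshold — the
per-bin quantity the quintile display is built on is "fraction of CNVs",
and call-level counting reproduces that framing. A per-sample mode
(`unit = "sample"`) counts carriers instead. How the original analysis chose
its size cut-off is not specified anywhere; we select the minimal-p
threshold over a log-spaced grid (default 200 points, 50–1000 kb), break
ties toward the smaller threshold, flag significance against a Bonferroni
bound over the grid, and export the whole curve so other selection rules can
be applied. Because the grid is highly correlated and Fisher p-values are
discrete (no midpoint correction), the null distribution of the *minimum* p
is conservative; the calibration test therefore checks the family-wise flag
rather than uniformity of the minimum.

Quintile borders are type-7 (linear-interpolation) percentiles of the pooled
case+control size vector; the method is configurable since borders computed
from someone else's raw data cannot otherwise be reproduced exactly.

## Segregation and de novo enrichment

A parental match is a same-type parental call covering at least
`match_fraction` (default 0.5) of the child call. The default is looser than
the 0.95 polymorphism cut on purpose: parental confirmation is often a
single MLPA probe, and breakpoint estimates jitter between platforms, so
requiring a 95% reciprocal match would misclassify genuinely transmitted
CNVs as de novo. Calls matched only in unaffected parents are categorized
`inherited_unaffected` and excluded by the candidate rule, implementing the
co-segregation requirement at single-trio resolution (extended pedigrees are
not modeled).

De novo enrichment compares the observed de novo count against the
population expectation of 6×10⁻³ de novo CNVs per haploid genome per
generation, i.e. λ = 2 × n_patients × rate. Three methods are exposed
(`poisson` tail — the default, `binomial` tail, and a one-sided
`fisher_vs_expected` 2×2); the construction behind the original "Fisher"
phrasing for this comparison is not reconstructible from its description, so
no single method is privileged as "the" published one (the Poisson tail at
λ = 2.4 for ≥ 7 events is ≈ 0.0116).

MLPA probe ratios classify with strict thresholds: ratio < 0.75 deletion,
ratio > 1.25 duplication; the boundary values themselves are *normal*
because the underlying wording ("under", "over") is strict.

## Association

Pseudomarkers are the deduplicated endpoints of all pooled segments; carrier
status at a marker uses half-open containment (a segment carries its start
position, not its end). The per-marker statistic is the Pearson χ² on the
carrier × group table without continuity correction; significance comes from
case/control label permutations with the +1 correction,
p = (1 + #{χ²_perm ≥ χ²_obs}) / (1 + n_perm), so a permutation p of 0 is
impossible. One permutation set is shared across markers within a run by
default (the per-marker independent mode is available), gains and losses are
separate families, and Bonferroni correction is applied across the union of
informative markers. An exhaustive mode enumerates all label assignments for
small cohorts and is tested against independent enumeration.

## GWAS overlap

The Bonferroni bound for the SNP-overlap analysis is α divided by the number
of SNPs falling inside the union of candidate CNVs (joint counting across
CNVs — this reproduces printed bounds of the form 0.05/36,316 = 1.377×10⁻⁶),
with the genome-wide CNV bound 0.05/2,000 = 2.5×10⁻⁵ derived from the
estimated number of copy-number polymorphisms ≥ 50 kb per genome. The
enrichment null — how many candidate CNVs would contain a significant SNP by
chance — is not specified in the analysis this package is modeled on; we use
Monte-Carlo placement of size-matched intervals uniform on the genome with
the +1-corrected empirical p. LD structure is deliberately not modeled.

## Expression

Per-gene differential expression between carriers and non-carriers uses the
equal-variance one-way ANOVA (for two groups, F = t²). Genes carried by a
single sample — the typical case when each candidate CNV has one proband —
fall back to the Crawford–Howell single-case t (the carrier compared against
the reference group with the 1 + 1/n variance inflation). Fold changes are
computed on anti-logged group means with the signed-reciprocal convention
(+1.25 and −1.33 are the default magnitude gates for up/down calls), and a
gene is *concordant* when it is significant at the raw per-gene α = 0.05 and
its direction matches the CNV (gain up, loss down). No per-gene multiple
testing correction is applied: the global claim is carried by the binomial
test of the concordant count with per-gene null probability 0.025 (α = 0.05
halved because direction must also match), computed by log-space summation
and cross-checked against `pbinom()`. The null probability is a parameter,
since the appropriate null depends on how the gene universe was chosen.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes, with
every signal labelled in a returned ground-truth object:

- **Call counts** per sample are Poisson with mean 32 (the emulated study's
  per-patient average).
- **Sizes** are log-normal in kb, truncated at the 10 kb calling floor.
  meanlog = log(120) and sdlog = 0.8 were chosen once so that pooled
  quintile borders land at the same order as the reference analysis
  (≈ 62/98/147/237 kb in a typical run vs 68/99/150/298 printed); the true
  size law of array calls is unknown and heavier-tailed than log-normal in
  the extreme tail, which we accept as a modelling simplification.
- **Polymorphic pool**: a configurable number of fixed loci, centred on
  genes (common CNVs are mostly gene-affecting, so the polymorphism stage —
  not the exonic filter — must remove them), carried identically by cases,
  controls and parents at the configured rate. With the default 5% carrier
  rate and 820 controls, each pool locus has ≈ 41 control carriers, safely
  above the >15 exclusion cut.
- **Pathogenic spikes** in 10% of cases (35% de novo), centred on an
  annotated gene so they survive the exonic filter, preferentially
  (`spike_evidence_fraction = 0.8`) on genes with an evidence flag — the
  premise of a gene-based prioritization is that causal CNVs contain
  growth-relevant genes. De novo spikes appear in neither parent; inherited
  spikes are copied into exactly one parent who is flagged affected, and
  spike carriers' height SDS is shifted by −0.6 (carriers are shorter).
- **Background transmission**: each case background call is mirrored into
  one unaffected parent with probability 0.9995, leaving ≈ 32 × 5×10⁻⁴
  ≈ 0.016 truly de novo background calls per child — the order implied by a
  6×10⁻³ per-haploid-genome de novo rate. Without this, every background
  call would look de novo and the segregation stage would be meaningless.
- **Case burden dials**: `case_excess_rate` injects extra Poisson calls per
  case with sizes > 100 kb (an excess of large CNVs in cases — this is the
  construct under which the threshold scan recovers a cut near 100 kb), and
  `case_size_shift` multiplies case sizes above a boundary instead. The two
  are not equivalent: under the multiplicative shift the case/control
  discrimination stays nearly flat from the shifted boundary far into the
  tail, so the minimal-p threshold lands above the shift factor times the
  boundary rather than at the boundary itself.
- **Expression** adds +log2(1.5) (gain) or −1 (loss) to carrier samples of
  dosage-responsive genes over a per-gene Gaussian baseline with
  measurement noise (default SD 0.3 log2 units); **SNP tracks** are uniform
  p-values with at least one sub-threshold SNP guaranteed inside each
  requested signal locus; **MLPA** ratios are 0.5/1.0/1.5 plus Gaussian
  noise.

What the generator does *not* emulate: raw array intensities and their
wave/batch artifacts, LD among SNPs, recombination maps, sex chromosomes,
multi-copy states (only states 1 and 3), and breakpoint uncertainty between
platforms. Passing recovery tests on this cohort therefore demonstrates the
correctness and calibration of the statistical machinery, not robustness to
array-level noise.

## Problem sizes used by the test suite

The validation suite exercises the properties at sizes chosen to make each
check sharp while remaining comfortable on a single CPU: filter
recovery/removal over 20 replicates of 30 cases vs 150 controls (pool
carrier rate 0.3, i.e. ≈ 45 > 15 carriers per pool locus); Fisher exactness
over all 2×2 tables with margins ≤ 12; permutation exactness on 8-sample
cohorts; threshold-scan calibration over 100 null replicates (25 vs 25
samples) and recovery over 50 replicates (50 vs 100 samples, excess rate 8);
expression recovery with 40 spiked genes at 10 carriers vs 10 references and
noise SD 0.3. The `analysis/` drivers run the full emulated scale (200
cases + parents, 820 controls).

## Known limitations

- The evidence flags (known growth gene, mouse knock-out phenotype,
  functional candidacy, Decipher overlap, tissue expression,
  haploinsufficiency percentile) are consumed from the gene annotation
  file; the package does not query OMIM/MGI/Decipher/GEPIS and ships no
  curated content from them.
- The candidate rule gates on segregation plus the four evidence lines;
  microdeletion-syndrome overlap is reported but not used as a gate.
- Permutation association does not adjust for covariates or population
  structure.
- Single-case expression tests have limited power at realistic noise: a
  +log2(1.5) gain in one carrier at noise SD 0.3 is usually *not*
  significant, and a −1 loss usually is; replicated carriers are needed for
  reliable gain detection.
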