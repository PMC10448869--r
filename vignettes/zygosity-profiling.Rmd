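---
title: "Zygosity profiling of somatic mutations: model, thresholds, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zygosity profiling of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetprofiler)
```

## The model

A somatic mutation observed in bulk tumor sequencing is a mixture
measurement. If the sequenced sample has purity $p$ (fraction of tumor
cells), the site carries $C_t$ copies in the tumor cells of which $m$ are
mutant, and the contaminating normal cells contribute two wild-type
copies, then the expected variant allele fraction is

$$\mathrm{E[VAF]} = \frac{m\,p}{C_t\,p + 2(1-p)}.$$

Two zygosity states dominate for a tumor-suppressor-like gene:

* **heterozygous**: one mutant copy on a diploid background
  ($m = 1$, $C_t = 2$), expected VAF $p/2$ — strictly below 0.5 for any
  impure sample;
* **hemizygous via LOH**: loss of the wild-type copy leaves a single
  mutant copy ($m = C_t = 1$), expected VAF $p/(2-p)$ — above 0.5 when
  $p > 2/3$.

The cohort report exploits this separation with a fixed rule: among a
gene's oncogenic-annotated mutations, those with $\mathrm{VAF} < 0.5$
(strict inequality) are counted as heterozygous, deletion-class records
are excluded from that count (read support at a deleted site does not
reflect zygosity), and the **proportion heterozygous** is the
sub-threshold count over the *total* oncogenic count. A gene whose
proportion strictly exceeds 0.5 is classified
*heterozygous-preferential*. The report row also carries the number of
distinct mutant samples whose gene-level GISTIC code is $\ge 0$
(diploid or gain), the maximum VAF, and the percent of cohort samples
mutated (computed only when the cohort size is supplied).

```{r}
expected_vaf(1, 2, 0.6)   # heterozygous at 60% purity
expected_vaf(1, 1, 0.6)   # hemizygous at 60% purity
expected_vaf(1, 1, 2/3)   # the crossing: exactly 0.5
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `vaf_threshold` | 0.5 | VAF below which an oncogenic, non-deletion record counts as heterozygous (strict `<`) |
| `het_cutoff` | 0.5 | proportion above which a gene is heterozygous-preferential (strict `>`) |
| `cn_floor` | 0 | minimum GISTIC code counted as diploid-or-gain |
| `deletion_mode` | `"variant_class"` | what "exclude deletions" excludes (below) |

Two readings of "exclude deletions" are defensible, and the filter is a
flag rather than a hard-coded rule. The default excludes deletion-class
*variant records*. The alternative, `deletion_mode = "copy_number"`,
instead drops records from samples whose gene is deep-deleted
(GISTIC $-2$) and lets deletion-class records count. The default is used
everywhere in the package's own validation; the alternative exists so the
other reading is one argument away, never a silent switch.

Undefined quantities stay undefined: a gene with zero oncogenic mutations
reports an `NA` proportion and `NA` classification, never 0, so no
classification is fabricated for unmutated genes.

## What the simulator emulates

`simulate_cohort()` generates cohorts with exactly the structure the
profiling procedure assumes, plus a ground-truth table:

* per-sample purity, uniform over `purity_range`; the default
  $[0.6, 0.9]$ is a typical purity band for TCGA-like solid-tumor
  cohorts;
* per-(sample, gene) GISTIC codes from `cn_state_probs` (default mostly
  diploid with modest loss/gain mass);
* per-mutation zygosity: heterozygous with probability
  `true_het_fraction` (then the copy-number code is forced to
  diploid-or-gain), otherwise hemizygous LOH (code forced to shallow
  loss) — the minimal two-state model that the VAF statistic is designed
  to separate;
* read support: total depth Poisson(`depth_mean`, default 200) floored
  at 1, alt reads binomial at the expected VAF — the simplest
  overdispersion-free sequencing model;
* consequence classes, including deletion-class records at
  `deletion_rate` (default 5%) so the exclusion filter has work to do,
  and truncating mutations whose positions can be biased toward the
  C-terminal half with `cterminal_weight`;
* every mutation has exactly one truth record (purity, copies, zygosity
  label, expected VAF), and runs are bit-identical given a seed.

The simulator deliberately omits subclonality, multi-region sampling,
sequencing error, and germline contamination. Tests passing on these
cohorts therefore show that the procedure is correct *under its own
model assumptions*; they do not show robustness to subclonal mutations
(which depress VAF like impurity does) or to copy-number states beyond
the two modeled.

## Estimating the heterozygous fraction from simulated data

The fixed 0.5 threshold is the report's definition, and the package
reproduces it as such. As an *estimator* of the underlying heterozygous
fraction, however, it has a purity-dependent blind spot that follows
directly from the mixture model: the hemizygous expectation $p/(2-p)$
falls below 0.5 once $p < 2/3$, so at purities in the low 0.6s most LOH
mutations are counted as heterozygous, and at $p = 1$ the heterozygous
expectation sits exactly on the threshold, where a strict inequality
counts half of the reads draws. `recover_metrics()` therefore scores
recovery with a purity-aware decision boundary by default: the midpoint
of the two class expectations,

$$t(p) = \tfrac{1}{2}\left(\frac{p}{2} + \frac{p}{2-p}\right),$$

applied per sample (`purity_aware_threshold()`). The fixed rule remains
available as `method = "fixed"`, and the package's validation asserts
both behaviors: midpoint-threshold recovery achieves mean absolute error
well under 0.05 across heterozygous fractions $\{0, 0.25, 0.5, 0.75,
1\}$ at purities 0.6–0.8 and depth 200, while the fixed rule's accuracy
on hemizygous mutations collapses as purity falls through the analytic
crossing at $p = 2/3$.

```{r}
purity_aware_threshold(c(0.6, 2/3, 0.8, 1))
```

## The C-terminal clustering test

Truncating mutations in SOX9-class genes concentrate in the C-terminal
half of the protein, where the transactivation-associated domains sit.
The package quantifies this with a construction of its own: the
C-terminal half is every residue strictly beyond $\lceil L/2 \rceil$ (for
odd $L$ the middle residue is N-terminal, making the null unambiguous),
and the C-terminal count among positioned mutations is tested one-sided
against a uniform-over-length binomial null with success probability
$\lfloor L/2 \rfloor / L$ via `stats::binom.test()`. Exactness makes the
test conservative, so its type-I error is at or below nominal level; the
package's calibration check bounds it empirically over 1000 null
instances. No multiple-testing correction is applied for a single gene;
`cterminal_clustering_scan()` adds a Benjamini–Hochberg column for
multi-gene use. Splice-site variants count as truncating by
loss-of-function convention, configurable via `splice_is_truncating`.

Domain coordinates are a required input (`read_domain_table()`), because
published schematics rarely pin residue-exact boundaries. The shipped
SOX9-like model (`sox9_like_model()`,
`inst/extdata/sox9_like_domains_synthetic.tsv`) is a synthetic stand-in
with the right shape — 509 residues, DIM and HMG domains N-terminal,
three domains (K2, PQA, TA) in the C-terminal half — not a curated
reference annotation.

## Numerical and degenerate-input choices

* All thresholds are strict (`< vaf_threshold`, `> het_cutoff`); a
  record at exactly 0.5 VAF is not heterozygous and a gene at exactly
  proportion 0.5 is not heterozygous-preferential.
* Zero-depth records cannot yield a VAF: parsers drop them with a
  tallied reason, and the counting functions skip any that arrive by
  other routes, with a warning.
* Parsing never repairs a row; every input row is either kept or dropped
  with a reason, and `n_read = n_kept + n_dropped` is asserted as an
  invariant.
* Duplicate (sample, gene) copy-number rows keep the first occurrence
  with a warning; mutant samples with no copy-number record are excluded
  from the diploid-or-gain column rather than imputed.
* Profiles are sorted by percent-of-samples-mutated descending with gene
  symbol as tie-break; when no cohort size is given, by oncogenic total.
* Simulated depth is floored at 1 read so every record has a defined
  VAF.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to make the
stochastic checks decisive while keeping a default run fast: parameter
recovery uses 100 mutations per gene over 20 seeds per heterozygous
fraction; clustering calibration uses 1000 null gene instances of 50
mutations (type-I) and 100 instances of 200 mutations (power at
C-terminal weight 3); the grouped profile implementation is checked
against an independent brute-force per-record loop on 50 random cohorts
of up to 200 records; and the fixed-threshold breakdown is probed on
fixed-purity grids straddling $p = 2/3$ at depths 200–2000.

## Known limitations

* VAFs are used raw (`alt / (alt + ref)`); the cohort report applies no
  purity correction, matching how such tables are built in practice.
  Purity enters only through the simulator and the recovery estimator.
* Oncogenicity is consumed as an input flag; the package does not
  re-derive it from variant annotations.
* The two-state zygosity model ignores higher copy states with multiple
  mutant copies (e.g. amplified mutant alleles), subclonality, and tumor
  ploidy estimation; inferring purity or ploidy from the data is out of
  scope.
* The statistic is descriptive: the report attaches no significance
  measure to the heterozygous proportion itself.
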