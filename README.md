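# hetprofiler

Gene-level zygosity profiling and protein-domain mutation clustering for
tumor cohorts.

## The problem

Some cancer genes are not simply "mutated or not": *how* they are mutated
carries the signal. In colorectal cancer, the WNT-pathway transcription
factor *SOX9* is recurrently hit by truncating mutations that almost always
leave the wild-type copy intact — a heterozygous null allele — and the same
pattern recurs for *TCF7L2* and other WNT regulators. Detecting that
pattern from cohort sequencing data requires looking at the **variant
allele fraction (VAF)** of each somatic mutation together with the gene's
copy-number state, not just at mutation frequency.

`hetprofiler` implements that procedure as a tested, reusable pipeline:

1. **Zygosity profile.** For each gene, over its oncogenic-annotated
   mutations, count the mutations with

   VAF = alt / (alt + ref) < 0.5

   (excluding deletion-class records, whose read support does not reflect
   zygosity). In a tumor of purity *p*, a heterozygous mutation on a
   diploid background has expected VAF *p*/2 < 0.5, whereas a mutation
   made hemizygous by loss of heterozygosity (LOH) has expected VAF
   *p*/(2 − *p*) > 0.5 for *p* > 2/3, so the sub-50% share separates the
   two classes. The per-gene statistic is

   proportion heterozygous = #{VAF < 0.5, oncogenic, non-deletion} / #{oncogenic},

   and a gene is classified *heterozygous-preferential* when this
   proportion exceeds 0.5. The report also carries the number of mutant
   samples with diploid-or-gain copy number (GISTIC code ≥ 0), the
   maximum VAF, and the percent of cohort samples mutated.

2. **Domain clustering.** Mutations are mapped onto protein-domain models
   (1-based inclusive intervals), split by truncating status
   (nonsense / frameshift / splice-site), and C-terminal clustering is
   quantified by a one-sided exact binomial test of the C-terminal-half
   count against the uniform-over-length null, success probability
   ⌊L/2⌋/L for a protein of length L.

3. **Synthetic cohorts.** A simulator generates cohorts with known
   per-sample purity, per-gene copy number, per-mutation zygosity, and
   Poisson-depth/binomial read support around the expected VAF, so every
   stage of the pipeline is validated against ground truth without any
   external download.

Inputs are TCGA-style MAF mutation tables (or a simple TSV dialect),
gene-level GISTIC-coded copy-number tables, and protein-domain TSVs.

## Worked example

The package ships the published gene-level tallies for the TCGA PanCancer
Atlas colorectal adenocarcinoma cohort
(`inst/extdata/tcga_crc_gene_counts.tsv`) and can expand them into a
record-level cohort that realizes the same statistics:

```r
library(hetprofiler)

counts <- crc_gene_counts()
cohort <- cohort_from_gene_counts(counts)
profiles <- profile_cohort(cohort$mutations, cohort$copy_numbers,
                           cohort_size = cohort$cohort_size)
profiles[profiles$gene %in% c("TP53", "KRAS", "SOX9"),
         c("gene", "total_oncogenic", "het_lt50_count",
           "proportion_heterozygous", "classification")]
#> # A tibble: 3 × 5
#>   gene  total_oncogenic het_lt50_count proportion_heterozygous classification
#> 1 TP53              328             48                   0.146 not_heterozygous_preferential
#> 2 KRAS              219            144                   0.658 heterozygous_preferential
#> 3 SOX9               54             41                   0.759 heterozygous_preferential
```

*SOX9* shows the heterozygous-preferential pattern: 41 of its 54 oncogenic
mutations (0.75926) sit below 50% VAF, so most mutant tumors retain a
wild-type copy. *TP53*, dominated by LOH, sits at 0.14634. Of the 31
profiled genes, 25 are heterozygous-preferential:

```r
glance(profiles)
#> # A tibble: 1 × 5
#>   n_genes n_het_preferential median_proportion vaf_threshold het_cutoff
#> 1      31                 25               0.8           0.5        0.5
```

Validation against simulated ground truth, including the C-terminal
clustering of truncating mutations:

```r
co <- simulate_cohort(simulation_params(
  n_samples = 150, purity_range = c(0.6, 0.8), depth_mean = 200,
  genes = gene_params("SOX9", true_het_fraction = 0.75, mutation_rate = 1),
  cterminal_weight = 3, seed = 42))

recover_metrics(co$mutations, co$truth)
#> # A tibble: 1 × 6
#>   gene  n_truth true_het_fraction n_used estimated_het_fraction abs_error
#> 1 SOX9      150              0.74    142                  0.746   0.00648

cterminal_clustering_test(co$mutations, sox9_like_model(),
                          truncating_only = TRUE)
#> # A tibble: 1 × 7
#>   gene  n_positioned n_cterminal observed_fraction null_prob  p_value
#> 1 SOX9            86          71             0.826     0.499 3.17e-10
```

`autoplot()` methods draw the profile dot plot, per-domain count bars, and
recovery scatter; `tidy()`/`glance()` give broom-style summaries. A thin
command-line wrapper with `profile`, `simulate`, and `recover` subcommands
lives at `inst/cli/hetprofiler.R`.

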