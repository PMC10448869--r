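test_that("allele fraction is alt over total depth and rejects zero depth", {
  expect_equal(allele_fraction(5, 5), 0.5)
  expect_equal(allele_fraction(0, 30), 0)
  expect_equal(allele_fraction(89, 11), 0.89)
  expect_error(allele_fraction(0, 0), "alt_count \\+ ref_count")

  muts <- make_mutations("G", c("S1", "S2"), alt = c(3L, 0L), ref = c(7L, 0L))
  expect_warning(out <- add_allele_fraction(muts), "zero or missing")
  expect_equal(out$allele_fraction, c(0.3, NA))
})

test_that("count operations implement the report's filters exactly", {
  muts <- dplyr::bind_rows(
    make_mutations("SOX9", "S1", 30, 70),                       # het, diploid
    make_mutations("SOX9", "S1", 20, 80),                       # same sample
    make_mutations("SOX9", "S2", 50, 50),                       # AF exactly 0.5
    make_mutations("SOX9", "S3", 30, 70, classification = "deletion"),
    make_mutations("SOX9", "S4", 40, 60, oncogenic = FALSE),
    make_mutations("SOX9", "S5", 80, 20),                       # supra, loss
    make_mutations("TP53", "S1", 10, 90)
  )
  cn <- make_cn(c("S1", "S2", "S3", "S5"), "SOX9", c(0L, 1L, -2L, -1L))

  # oncogenic total includes deletions, excludes the non-oncogenic decoy
  expect_equal(count_total_oncogenic(muts, "SOX9"), 5)
  # distinct samples, cn >= 0: S1 and S2 only (S3 at -2, S5 at -1, S4 has
  # no oncogenic record); sample semantics collapse S1's two mutations
  expect_equal(
    count_diploid_or_gain_samples(muts, cn, "SOX9", quiet = TRUE), 2)
  # strict < 0.5, deletions excluded: S1 twice only
  expect_equal(count_het_lt50(muts, "SOX9"), 2)
  # copy-number reading of the deletion exclusion: drop deep-deletion
  # samples (S3) instead of deletion-class records
  expect_equal(count_het_lt50(muts, "SOX9", deletion_mode = "copy_number",
                              copy_numbers = cn), 2 + 1 - 1)
})

test_that("mutant samples without a copy-number record are excluded with a warning", {
  muts <- make_mutations("SOX9", c("S1", "S2"), alt = 30, ref = 70)
  cn <- make_cn("S1", "SOX9", 0L)
  expect_warning(
    n <- count_diploid_or_gain_samples(muts, cn, "SOX9"),
    "without a copy-number record")
  expect_equal(n, 1)
})

test_that("profile_gene assembles a report row and flags undefined proportions", {
  muts <- make_mutations("SOX9", sprintf("S%d", 1:4),
                         alt = c(30L, 30L, 30L, 89L),
                         ref = c(70L, 70L, 70L, 11L))
  cn <- make_cn(sprintf("S%d", 1:4), "SOX9", c(0L, 0L, 1L, -1L))
  row <- profile_gene(muts, cn, "SOX9", cohort_size = 40)

  expect_equal(row$total_oncogenic, 4L)
  expect_equal(row$mutant_samples_diploid_or_gain, 3L)
  expect_equal(row$het_lt50_count, 3L)
  expect_equal(row$proportion_heterozygous, 0.75)
  expect_equal(row$max_allele_fraction, 0.89)
  expect_equal(row$pct_samples_mutated, 10)
  expect_equal(row$classification, "heterozygous_preferential")

  # no oncogenic mutations: proportion undefined, never coerced to 0
  none <- profile_gene(muts[0, ], cn, "SOX9", cohort_size = 40, quiet = TRUE)
  expect_true(is.na(none$proportion_heterozygous))
  expect_true(is.na(none$classification))
  expect_equal(none$total_oncogenic, 0L)
})

test_that("classification uses a strict cutoff", {
  muts <- make_mutations("G", c("S1", "S2"), alt = c(30L, 70L),
                         ref = c(70L, 30L))
  cn <- make_cn(c("S1", "S2"), "G", 0L)
  row <- profile_gene(muts, cn, "G")  # proportion exactly 0.5
  expect_equal(row$proportion_heterozygous, 0.5)
  expect_equal(row$classification, "not_heterozygous_preferential")
})

test_that("profile_cohort emits one sorted row per mutated gene", {
  cohort <- random_cohort(120)
  prof <- profile_cohort(cohort$mutations, cohort$copy_numbers,
                         cohort_size = cohort$cohort_size)
  mutated <- sort(unique(cohort$mutations$gene[cohort$mutations$oncogenic]))
  expect_setequal(prof$gene, mutated)
  ord <- order(-prof$pct_samples_mutated, prof$gene)
  expect_equal(ord, seq_len(nrow(prof)))
})

test_that("profiles are invariant to input record order", {
  set.seed(512)
  cohort <- random_cohort(150)
  prof <- profile_cohort(cohort$mutations, cohort$copy_numbers,
                         cohort_size = cohort$cohort_size)
  shuffled <- profile_cohort(
    cohort$mutations[sample(nrow(cohort$mutations)), ],
    cohort$copy_numbers[sample(nrow(cohort$copy_numbers)), ],
    cohort_size = cohort$cohort_size)
  expect_equal(as.data.frame(prof), as.data.frame(shuffled))
})

test_that("grouped profiles match the brute-force per-record oracle", {
  set.seed(513)
  for (rep in 1:10) {
    cohort <- random_cohort(sample(30:200, 1))
    prof <- profile_cohort(cohort$mutations, cohort$copy_numbers,
                           cohort_size = cohort$cohort_size)
    for (g in prof$gene) {
      oracle <- oracle_profile_gene(cohort$mutations, cohort$copy_numbers,
                                    g, cohort$cohort_size)
      row <- prof[prof$gene == g, ]
      expect_equal(row$total_oncogenic, oracle$total_oncogenic)
      expect_equal(row$mutant_samples_diploid_or_gain,
                   oracle$mutant_samples_diploid_or_gain)
      expect_equal(row$het_lt50_count, oracle$het_lt50_count)
      expect_equal(row$proportion_heterozygous,
                   oracle$proportion_heterozygous)
      expect_equal(row$max_allele_fraction, oracle$max_allele_fraction)
      expect_equal(row$pct_samples_mutated, oracle$pct_samples_mutated)
      expect_equal(row$classification, oracle$classification)
    }
  }
})

test_that("extreme simulated het fractions are recovered by the fixed threshold", {
  all_het <- simulate_cohort(simulation_params(
    n_samples = 150, purity_range = c(0.8, 0.8), depth_mean = 200,
    genes = gene_params("G", true_het_fraction = 1, mutation_rate = 1),
    deletion_rate = 0, seed = 21))
  prof <- profile_cohort(all_het$mutations, all_het$copy_numbers,
                         cohort_size = all_het$cohort_size)
  expect_gte(prof$proportion_heterozygous, 0.95)

  all_hom <- simulate_cohort(simulation_params(
    n_samples = 150, purity_range = c(0.8, 0.8), depth_mean = 200,
    genes = gene_params("G", true_het_fraction = 0, mutation_rate = 1),
    deletion_rate = 0, seed = 22))
  prof <- profile_cohort(all_hom$mutations, all_hom$copy_numbers,
                         cohort_size = all_hom$cohort_size)
  expect_lte(prof$proportion_heterozygous, 0.10)
})

test_that("tidy and glance summarize zygosity profiles", {
  cohort <- cohort_from_gene_counts(crc_gene_counts())
  prof <- profile_cohort(cohort$mutations, cohort$copy_numbers,
                         cohort_size = cohort$cohort_size)
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "zygosity_profile"))
  gl <- glance(prof)
  expect_equal(gl$n_genes, nrow(prof))
  expect_equal(gl$n_het_preferential,
               sum(prof$classification == "heterozygous_preferential"))
  expect_equal(gl$het_cutoff, 0.5)
})

test_that("autoplot methods return ggplot objects", {
  cohort <- cohort_from_gene_counts(crc_gene_counts())
  prof <- profile_cohort(cohort$mutations, cohort$copy_numbers,
                         cohort_size = cohort$cohort_size)
  expect_s3_class(autoplot(prof), "ggplot")

  co <- simulate_cohort(simulation_params(
    n_samples = 50, genes = gene_params("SOX9", mutation_rate = 1),
    seed = 5))
  counts <- count_by_domain(co$mutations, sox9_like_model())
  expect_s3_class(autoplot(counts), "ggplot")
  expect_s3_class(autoplot(recover_metrics(co$mutations, co$truth)),
                  "ggplot")
})
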