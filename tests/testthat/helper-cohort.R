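# Builders for small in-memory cohorts and an independent brute-force
# oracle for the per-gene profile (plain loops, no grouped/vectorized code).

make_mutations <- function(gene, sample, alt, ref,
                           classification = "missense",
                           oncogenic = TRUE, protein_pos = NA_integer_) {
  tibble::tibble(
    gene = gene, sample = sample, classification = classification,
    protein_pos = as.integer(protein_pos),
    alt_count = as.integer(alt), ref_count = as.integer(ref),
    oncogenic = oncogenic
  )
}

make_cn <- function(sample, gene, cn_code) {
  tibble::tibble(sample = sample, gene = gene, cn_code = as.integer(cn_code))
}

random_cohort <- function(n_records, n_genes = 4, n_samples = 25) {
  genes <- paste0("G", seq_len(n_genes))
  samples <- paste0("S", seq_len(n_samples))
  depth <- sample(20:200, n_records, replace = TRUE)
  alt <- vapply(depth, function(d) sample.int(d + 1, 1) - 1L, integer(1))
  muts <- tibble::tibble(
    gene = sample(genes, n_records, replace = TRUE),
    sample = sample(samples, n_records, replace = TRUE),
    classification = sample(c("missense", "nonsense", "frameshift",
                              "deletion", "other"),
                            n_records, replace = TRUE),
    protein_pos = NA_integer_,
    alt_count = as.integer(alt),
    ref_count = as.integer(depth - alt),
    oncogenic = sample(c(TRUE, TRUE, TRUE, FALSE), n_records, replace = TRUE)
  )
  cn_pairs <- expand.grid(sample = samples, gene = genes,
                          stringsAsFactors = FALSE)
  keep <- runif(nrow(cn_pairs)) < 0.9  # some pairs lack a CN record
  cn <- tibble::tibble(
    sample = cn_pairs$sample[keep], gene = cn_pairs$gene[keep],
    cn_code = sample(-2:2, sum(keep), replace = TRUE)
  )
  list(mutations = muts, copy_numbers = cn, cohort_size = n_samples)
}

# Brute-force per-record reference implementation of one profile row.
oracle_profile_gene <- function(mutations, copy_numbers, gene, cohort_size,
                                vaf_threshold = 0.5, het_cutoff = 0.5,
                                cn_floor = 0) {
  total <- 0L; het <- 0L
  max_af <- NA_real_
  mutant_samples <- character()
  for (i in seq_len(nrow(mutations))) {
    r <- mutations[i, ]
    if (r$gene != gene || !isTRUE(r$oncogenic)) next
    total <- total + 1L
    if (!r$sample %in% mutant_samples) {
      mutant_samples <- c(mutant_samples, r$sample)
    }
    depth <- r$alt_count + r$ref_count
    if (depth > 0) {
      af <- r$alt_count / depth
      if (is.na(max_af) || af > max_af) max_af <- af
      if (r$classification != "deletion" && af < vaf_threshold) {
        het <- het + 1L
      }
    }
  }
  dg <- 0L
  for (s in mutant_samples) {
    cn <- NA_integer_
    for (j in seq_len(nrow(copy_numbers))) {
      if (copy_numbers$sample[j] == s && copy_numbers$gene[j] == gene) {
        cn <- copy_numbers$cn_code[j]
        break
      }
    }
    if (!is.na(cn) && cn >= cn_floor) dg <- dg + 1L
  }
  prop <- if (total > 0) het / total else NA_real_
  list(
    total_oncogenic = total,
    mutant_samples_diploid_or_gain = dg,
    het_lt50_count = het,
    proportion_heterozygous = prop,
    max_allele_fraction = max_af,
    pct_samples_mutated = 100 * length(mutant_samples) / cohort_size,
    classification = if (is.na(prop)) NA_character_
      else if (prop > het_cutoff) "heterozygous_preferential"
      else "not_heterozygous_preferential"
  )
}

extdata <- function(name) {
  system.file("extdata", name, package = "hetprofiler", mustWork = TRUE)
}
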