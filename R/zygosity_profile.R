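#' Variant allele fraction
#'
#' The fraction of reads supporting the variant allele,
#' `alt / (alt + ref)`. In a tumor sample of purity p, a heterozygous
#' mutation on a diploid background has expected VAF p/2 (< 0.5 for any
#' impure sample), while a mutation rendered hemizygous by loss of
#' heterozygosity has expected VAF p/(2 - p); the sub-50% VAF count is
#' therefore the working definition of a heterozygous mutation.
#'
#' @param alt_count,ref_count Non-negative read counts (vectorized).
#' @return Numeric vector of allele fractions in \[0, 1\].
#' @export
#' @examples
#' allele_fraction(89, 11)  # 0.89
allele_fraction <- function(alt_count, ref_count) {
  total <- alt_count + ref_count
  if (any(is.na(total)) || any(total <= 0)) {
    abort("Allele fraction requires alt_count + ref_count > 0 for every record.")
  }
  alt_count / total
}

#' Add an `allele_fraction` column to a mutation tibble
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @return The tibble with an `allele_fraction` column appended. Records
#'   with zero total depth get `NA` with a warning (they cannot contribute
#'   to VAF-based statistics).
#' @export
add_allele_fraction <- function(mutations) {
  total <- mutations$alt_count + mutations$ref_count
  bad <- is.na(total) | total <= 0
  if (any(bad)) {
    warn(sprintf("%d record(s) with zero or missing read depth: allele fraction set to NA.",
                 sum(bad)))
  }
  mutations$allele_fraction <-
    ifelse(bad, NA_real_, mutations$alt_count / total)
  mutations
}

#' Count oncogenic-annotated mutations for a gene
#'
#' All oncogenic-annotated records count, deletion-class records included;
#' the deletion exclusion applies only to the sub-threshold heterozygous
#' count ([count_het_lt50()]).
#'
#' @param mutations Mutation tibble.
#' @param gene Gene symbol, or `NULL` to count across all genes.
#' @return Integer count.
#' @export
count_total_oncogenic <- function(mutations, gene = NULL) {
  df <- filter_gene(mutations, gene)
  sum(df$oncogenic, na.rm = TRUE)
}

#' Count mutant samples with diploid-or-gain copy number
#'
#' Distinct samples that carry at least one oncogenic mutation in the gene
#' and whose gene-level copy-number code is at or above `cn_floor`
#' (default 0: diploid, gain, or amplification). Mutant samples with no
#' copy-number record for the gene are excluded, with a warning.
#'
#' @param mutations Mutation tibble.
#' @param copy_numbers Copy-number tibble (see [read_copy_number_table()]).
#' @param gene Gene symbol.
#' @param cn_floor Minimum GISTIC code counted as intact (default 0).
#' @param quiet Suppress the missing-copy-number warning.
#' @return Integer count of distinct samples.
#' @export
count_diploid_or_gain_samples <- function(mutations, copy_numbers, gene,
                                          cn_floor = 0, quiet = FALSE) {
  mutant_samples <- filter_gene(mutations, gene) %>%
    filter(.data$oncogenic) %>%
    pull("sample") %>%
    unique()
  cn <- filter_gene(copy_numbers, gene)
  cn_for <- cn$cn_code[match(mutant_samples, cn$sample)]
  missing <- is.na(cn_for)
  if (any(missing) && !quiet) {
    warn(sprintf("%s: %d mutant sample(s) without a copy-number record excluded from the diploid-or-gain count.",
                 gene, sum(missing)))
  }
  sum(cn_for >= cn_floor, na.rm = TRUE)
}

#' Count sub-threshold allele-fraction mutations (the heterozygous count)
#'
#' Oncogenic-annotated mutations of the gene whose allele fraction is
#' strictly below `vaf_threshold`, excluding deletions. With
#' `deletion_mode = "variant_class"` (default) deletion-class variant
#' records are excluded, because read support at a deleted site does not
#' reflect zygosity. With `deletion_mode = "copy_number"` records from
#' samples whose gene copy-number code is -2 (deep deletion) are excluded
#' instead, and deletion-class records count like any other.
#'
#' @inheritParams count_diploid_or_gain_samples
#' @param vaf_threshold Allele-fraction threshold (default 0.5, strict `<`).
#' @param deletion_mode `"variant_class"` or `"copy_number"`.
#' @param copy_numbers Required when `deletion_mode = "copy_number"`.
#' @return Integer count.
#' @export
count_het_lt50 <- function(mutations, gene, vaf_threshold = 0.5,
                           deletion_mode = c("variant_class", "copy_number"),
                           copy_numbers = NULL, quiet = FALSE) {
  deletion_mode <- arg_match(deletion_mode)
  df <- filter_gene(mutations, gene) %>% filter(.data$oncogenic)
  df <- exclude_deletions(df, deletion_mode, copy_numbers, gene)
  total <- df$alt_count + df$ref_count
  zero <- is.na(total) | total <= 0
  if (any(zero) && !quiet) {
    warn(sprintf("%s: %d record(s) with zero read depth skipped in the heterozygous count.",
                 gene, sum(zero)))
  }
  df <- df[!zero, , drop = FALSE]
  sum(df$alt_count / (df$alt_count + df$ref_count) < vaf_threshold)
}

#' Zygosity profile for one gene
#'
#' Assembles one row of the zygosity report: total oncogenic mutations,
#' mutant samples with diploid-or-gain copy number, sub-threshold
#' allele-fraction count, proportion heterozygous (sub-threshold count over
#' total oncogenic), maximum allele fraction, percent of cohort samples
#' mutated, and the heterozygous-preferential classification (proportion
#' strictly greater than `het_cutoff`). A gene with zero oncogenic
#' mutations yields an `NA` proportion and classification -- undefined is
#' reported as missing, never coerced to 0.
#'
#' @inheritParams count_het_lt50
#' @param cohort_size Number of samples in the data set; the denominator of
#'   `pct_samples_mutated`. `NULL` leaves that column `NA`.
#' @param het_cutoff Classification cutoff on the heterozygous proportion
#'   (default 0.5, strict `>`).
#' @param cn_floor Minimum GISTIC code counted as intact (default 0).
#' @return A one-row tibble (see [profile_cohort()] for the columns).
#' @export
profile_gene <- function(mutations, copy_numbers, gene, cohort_size = NULL,
                         vaf_threshold = 0.5, het_cutoff = 0.5, cn_floor = 0,
                         deletion_mode = c("variant_class", "copy_number"),
                         quiet = FALSE) {
  deletion_mode <- arg_match(deletion_mode)
  total <- count_total_oncogenic(mutations, gene)
  dg <- count_diploid_or_gain_samples(mutations, copy_numbers, gene,
                                      cn_floor = cn_floor, quiet = quiet)
  het <- count_het_lt50(mutations, gene, vaf_threshold = vaf_threshold,
                        deletion_mode = deletion_mode,
                        copy_numbers = copy_numbers, quiet = quiet)
  onc <- filter_gene(mutations, gene) %>% filter(.data$oncogenic)
  depth <- onc$alt_count + onc$ref_count
  af <- onc$alt_count[depth > 0] / depth[depth > 0]
  prop <- if (total > 0) het / total else NA_real_
  tibble(
    gene = gene,
    total_oncogenic = as.integer(total),
    mutant_samples_diploid_or_gain = as.integer(dg),
    het_lt50_count = as.integer(het),
    proportion_heterozygous = prop,
    max_allele_fraction = if (length(af)) max(af) else NA_real_,
    pct_samples_mutated = if (is.null(cohort_size)) NA_real_ else
      100 * n_distinct(onc$sample) / cohort_size,
    classification = classify_het(prop, het_cutoff)
  )
}

#' Zygosity profiles for a whole cohort
#'
#' Runs the per-gene zygosity procedure over every gene with at least one
#' oncogenic-annotated mutation (or over an explicit gene list) and returns
#' one report row per gene, sorted by percent of samples mutated
#' (descending, ties broken by gene symbol).
#'
#' @inheritParams profile_gene
#' @param genes `"all"` (default) or a character vector of gene symbols.
#' @return A tibble of class `zygosity_profile` with columns `gene`,
#'   `total_oncogenic`, `mutant_samples_diploid_or_gain`, `het_lt50_count`,
#'   `proportion_heterozygous`, `max_allele_fraction`,
#'   `pct_samples_mutated`, `classification`
#'   (`"heterozygous_preferential"`, `"not_heterozygous_preferential"`, or
#'   `NA` when undefined).
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_params(
#'   n_samples = 40, genes = gene_params("SOX9", true_het_fraction = 0.9),
#'   seed = 1
#' ))
#' profile_cohort(cohort$mutations, cohort$copy_numbers,
#'                cohort_size = cohort$cohort_size)
profile_cohort <- function(mutations, copy_numbers, cohort_size = NULL,
                           genes = "all", vaf_threshold = 0.5,
                           het_cutoff = 0.5, cn_floor = 0,
                           deletion_mode = c("variant_class", "copy_number"),
                           quiet = TRUE) {
  deletion_mode <- arg_match(deletion_mode)
  if (identical(genes, "all")) {
    genes <- mutations %>%
      filter(.data$oncogenic) %>%
      pull("gene") %>%
      unique() %>%
      sort()
  }
  out <- purrr::map(genes, function(g) {
    profile_gene(mutations, copy_numbers, g, cohort_size = cohort_size,
                 vaf_threshold = vaf_threshold, het_cutoff = het_cutoff,
                 cn_floor = cn_floor, deletion_mode = deletion_mode,
                 quiet = quiet)
  }) %>%
    bind_rows()
  if (nrow(out)) {
    if (all(is.na(out$pct_samples_mutated))) {
      out <- arrange(out, dplyr::desc(.data$total_oncogenic), .data$gene)
    } else {
      out <- arrange(out, dplyr::desc(.data$pct_samples_mutated), .data$gene)
    }
  }
  new_zygosity_profile(out, vaf_threshold = vaf_threshold,
                       het_cutoff = het_cutoff, cn_floor = cn_floor,
                       deletion_mode = deletion_mode)
}

classify_het <- function(prop, het_cutoff) {
  dplyr::if_else(
    is.na(prop), NA_character_,
    dplyr::if_else(prop > het_cutoff,
                   "heterozygous_preferential",
                   "not_heterozygous_preferential")
  )
}

new_zygosity_profile <- function(df, ...) {
  structure(
    df,
    params = list(...),
    class = c("zygosity_profile", class(tibble())))
}

#' @export
print.zygosity_profile <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("# Zygosity profile: %d gene(s), VAF threshold %s, het cutoff %s\n",
              nrow(x), format(p$vaf_threshold), format(p$het_cutoff)))
  NextMethod()
}

filter_gene <- function(df, gene) {
  if (is.null(gene)) df else df[df$gene == gene, , drop = FALSE]
}

exclude_deletions <- function(df, deletion_mode, copy_numbers, gene) {
  if (deletion_mode == "variant_class") {
    df[df$classification != "deletion", , drop = FALSE]
  } else {
    if (is.null(copy_numbers)) {
      abort("deletion_mode = \"copy_number\" requires `copy_numbers`.")
    }
    cn <- filter_gene(copy_numbers, gene)
    cn_for <- cn$cn_code[match(df$sample, cn$sample)]
    df[is.na(cn_for) | cn_for > -2, , drop = FALSE]
  }
}
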