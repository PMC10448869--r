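#' Published gene-level zygosity tallies for TCGA colorectal adenocarcinoma
#'
#' Per-gene counts for recurrently mutated genes in the TCGA PanCancer
#' Atlas colorectal adenocarcinoma cohort: total oncogenic-annotated
#' mutations, mutant samples with diploid-or-gain copy number, mutations
#' with allele fraction below 50% (oncogenic, deletions excluded), the
#' published heterozygous proportion and its heterozygous-preferential
#' flag, the maximum allele fraction, and the percent of samples mutated.
#' Shipped as `inst/extdata/tcga_crc_gene_counts.tsv`.
#'
#' These are summary counts, not per-mutation records;
#' [cohort_from_gene_counts()] expands them into a record-level cohort
#' that realizes the same statistics.
#'
#' @return A tibble with columns `gene`, `total_oncogenic`,
#'   `diploid_or_gain_samples`, `het_lt50`, `proportion_published`,
#'   `max_allele_fraction`, `pct_samples_mutated`, `het_preferential`.
#' @export
crc_gene_counts <- function() {
  path <- system.file("extdata", "tcga_crc_gene_counts.tsv",
                      package = "hetprofiler", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    total_oncogenic = readr::col_integer(),
    diploid_or_gain_samples = readr::col_integer(),
    het_lt50 = readr::col_integer(),
    proportion_published = readr::col_double(),
    max_allele_fraction = readr::col_double(),
    pct_samples_mutated = readr::col_double(),
    het_preferential = readr::col_logical()
  ))
}

#' Expand gene-level count tallies into a record-level cohort
#'
#' Constructs a deterministic per-mutation cohort that realizes given
#' gene-level tallies: for each gene, `het_lt50` oncogenic non-deletion
#' records with allele fraction below 0.5 and `total_oncogenic - het_lt50`
#' records at or above 0.5, with the maximum allele fraction equal to
#' `max_allele_fraction`; `diploid_or_gain_samples` of the mutant samples
#' are diploid, the rest carry a shallow loss. One mutation per sample;
#' read depth 100 so two-decimal allele fractions are exact.
#'
#' Running [profile_cohort()] on the result reproduces each gene's
#' published heterozygous proportion and classification, which is how the
#' published statistics are checked end to end through the pipeline.
#'
#' @param counts A tibble as returned by [crc_gene_counts()] (columns
#'   `gene`, `total_oncogenic`, `diploid_or_gain_samples`, `het_lt50`,
#'   `max_allele_fraction`).
#' @return A list with elements `mutations`, `copy_numbers`,
#'   `cohort_size`.
#' @export
#' @examples
#' cohort <- cohort_from_gene_counts(crc_gene_counts())
#' profiles <- profile_cohort(cohort$mutations, cohort$copy_numbers,
#'                            cohort_size = cohort$cohort_size)
#' profiles[profiles$gene == "SOX9", ]
cohort_from_gene_counts <- function(counts) {
  check_columns(counts,
                c("gene", "total_oncogenic", "diploid_or_gain_samples",
                  "het_lt50", "max_allele_fraction"),
                "counts")
  rows <- purrr::map(seq_len(nrow(counts)), function(i) {
    g <- counts[i, ]
    b <- g$total_oncogenic
    d <- g$het_lt50
    stopifnot(d <= b, g$diploid_or_gain_samples <= b)
    # Sub-threshold records sit at 0.30 unless every record is
    # sub-threshold, in which case they sit at the gene's maximum AF
    # (< 0.5 by construction); supra-threshold records all sit at the
    # maximum AF (>= 0.5 whenever any exist).
    af <- c(
      rep(if (b > d) 0.30 else g$max_allele_fraction, d),
      rep(g$max_allele_fraction, b - d)
    )
    alt <- as.integer(round(af * 100))
    samples <- sprintf("%s_S%03d", g$gene, seq_len(b))
    list(
      mutations = tibble(
        gene = g$gene, sample = samples, classification = "missense",
        protein_pos = NA_integer_, alt_count = alt,
        ref_count = 100L - alt, oncogenic = TRUE
      ),
      copy_numbers = tibble(
        gene = g$gene, sample = samples,
        cn_code = dplyr::if_else(seq_len(b) <= g$diploid_or_gain_samples,
                                 0L, -1L)
      )
    )
  })
  mutations <- bind_rows(purrr::map(rows, "mutations"))
  copy_numbers <- bind_rows(purrr::map(rows, "copy_numbers"))
  list(
    mutations = mutations,
    copy_numbers = copy_numbers[c("sample", "gene", "cn_code")],
    cohort_size = dplyr::n_distinct(mutations$sample)
  )
}
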