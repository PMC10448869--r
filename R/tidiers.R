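#' Tidy a zygosity profile
#'
#' @param x A `zygosity_profile` from [profile_cohort()].
#' @param ... Unused.
#' @return A plain tibble with one row per gene.
#' @export
tidy.zygosity_profile <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a zygosity profile
#'
#' @param x A `zygosity_profile` from [profile_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: number of genes profiled, number classified
#'   heterozygous-preferential, the median heterozygous proportion, and
#'   the thresholds used.
#' @export
glance.zygosity_profile <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_genes = nrow(x),
    n_het_preferential = sum(x$classification == "heterozygous_preferential",
                             na.rm = TRUE),
    median_proportion = stats::median(x$proportion_heterozygous, na.rm = TRUE),
    vaf_threshold = p$vaf_threshold,
    het_cutoff = p$het_cutoff
  )
}

#' Tidy per-gene recovery metrics
#'
#' @param x A `recovery_metrics` from [recover_metrics()].
#' @param ... Unused.
#' @return A plain tibble with one row per gene.
#' @export
tidy.recovery_metrics <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of recovery metrics
#'
#' @param x A `recovery_metrics` from [recover_metrics()].
#' @param ... Unused.
#' @return A one-row tibble with the estimator used, the number of genes,
#'   and the aggregate mean absolute error.
#' @export
glance.recovery_metrics <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_genes = nrow(x),
    mae = attr(x, "mae")
  )
}

#' Tidy a domain count table
#'
#' @param x A `domain_counts` from [count_by_domain()].
#' @param ... Unused.
#' @return A plain tibble with one row per domain bucket.
#' @export
tidy.domain_counts <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a domain count table
#'
#' @param x A `domain_counts` from [count_by_domain()].
#' @param ... Unused.
#' @return A one-row tibble: records supplied, mapped, unmapped, the
#'   C-terminal-half count, and the C-terminal fraction of mapped records.
#' @export
glance.domain_counts <- function(x, ...) {
  n_mapped <- attr(x, "n_mapped")
  n_cterm <- attr(x, "n_cterminal")
  tibble(
    n_supplied = attr(x, "n_supplied"),
    n_mapped = n_mapped,
    n_unmapped = attr(x, "n_unmapped"),
    n_cterminal = n_cterm,
    cterminal_fraction = if (n_mapped > 0) n_cterm / n_mapped else NA_real_
  )
}
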