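#' Purity-aware VAF threshold separating heterozygous from hemizygous calls
#'
#' At purity p, a diploid heterozygous mutation has expected VAF p/2 and a
#' hemizygous (LOH) mutation p/(2 - p). The midpoint of the two is the
#' equal-margin decision boundary between the classes. The fixed 0.5
#' threshold used in the cohort report coincides with this boundary only at
#' p = 1; below p = 2/3 the hemizygous expectation itself drops under 0.5,
#' which is where the fixed-threshold classifier breaks down.
#'
#' @param p Tumor purity in (0, 1\] (vectorized).
#' @return The midpoint threshold `(p/2 + p/(2 - p)) / 2`.
#' @export
#' @examples
#' purity_aware_threshold(1)    # 0.75
#' purity_aware_threshold(2/3)  # 0.41667; compare fixed threshold 0.5
purity_aware_threshold <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  (expected_vaf(1, 2, p) + expected_vaf(1, 1, p)) / 2
}

#' Per-record zygosity calls from allele fractions
#'
#' Calls each usable record (oncogenic-annotated, non-deletion, non-zero
#' depth) heterozygous when its allele fraction falls below the decision
#' threshold, hemizygous (LOH) otherwise. `method = "fixed"` uses the
#' report's fixed sub-50% rule; `method = "purity_aware"` uses the
#' per-sample midpoint threshold of [purity_aware_threshold()] and
#' requires sample purities.
#'
#' @param mutations Mutation tibble.
#' @param purity A data frame with columns `sample` and `purity` (for
#'   example the truth table of [simulate_cohort()]); required for
#'   `method = "purity_aware"`.
#' @param method `"purity_aware"` or `"fixed"`.
#' @param vaf_threshold Threshold for `method = "fixed"` (default 0.5).
#' @return The usable records with columns `allele_fraction`, `threshold`,
#'   and `zygosity_call` appended.
#' @export
classify_zygosity <- function(mutations, purity = NULL,
                              method = c("purity_aware", "fixed"),
                              vaf_threshold = 0.5) {
  method <- arg_match(method)
  df <- mutations %>%
    filter(.data$oncogenic,
           .data$classification != "deletion",
           .data$alt_count + .data$ref_count > 0) %>%
    mutate(allele_fraction = .data$alt_count /
             (.data$alt_count + .data$ref_count))
  if (method == "fixed") {
    df$threshold <- vaf_threshold
  } else {
    if (is.null(purity)) {
      abort("method = \"purity_aware\" requires per-sample `purity`.")
    }
    pur <- distinct(as_tibble(purity)[c("sample", "purity")])
    df <- left_join(df, pur, by = "sample")
    if (any(is.na(df$purity))) {
      abort("Some samples have no purity value; cannot apply the purity-aware threshold.")
    }
    df$threshold <- purity_aware_threshold(df$purity)
  }
  df$zygosity_call <- dplyr::if_else(df$allele_fraction < df$threshold,
                                     "heterozygous", "homozygous_loh")
  df
}

#' Per-gene heterozygous-fraction estimates
#'
#' Share of usable records called heterozygous by [classify_zygosity()],
#' per gene.
#'
#' @inheritParams classify_zygosity
#' @return A tibble with columns `gene`, `n_used`,
#'   `estimated_het_fraction`.
#' @export
estimate_het_fraction <- function(mutations, purity = NULL,
                                  method = c("purity_aware", "fixed"),
                                  vaf_threshold = 0.5) {
  classify_zygosity(mutations, purity = purity, method = method,
                    vaf_threshold = vaf_threshold) %>%
    group_by(.data$gene) %>%
    summarise(
      n_used = n(),
      estimated_het_fraction = mean(.data$zygosity_call == "heterozygous"),
      .groups = "drop"
    )
}

#' Recovery metrics: estimated versus ground-truth heterozygous fractions
#'
#' Joins per-gene heterozygous-fraction estimates against a simulation
#' truth table and reports the absolute error per gene plus the aggregate
#' mean absolute error. The default estimator is purity-aware, taking
#' per-sample purity from the truth table itself.
#'
#' @param mutations Mutation tibble from a simulated cohort.
#' @param truth Truth tibble from [simulate_cohort()] (or
#'   [read_truth_table()]).
#' @inheritParams classify_zygosity
#' @return A tibble of class `recovery_metrics` with columns `gene`,
#'   `n_truth`, `true_het_fraction`, `n_used`, `estimated_het_fraction`,
#'   `abs_error`; the aggregate MAE is available via [glance()] or
#'   `attr(x, "mae")`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_params(
#'   n_samples = 100, genes = gene_params("SOX9", true_het_fraction = 0.75,
#'                                        mutation_rate = 1),
#'   seed = 11
#' ))
#' recover_metrics(cohort$mutations, cohort$truth)
recover_metrics <- function(mutations, truth,
                            method = c("purity_aware", "fixed"),
                            vaf_threshold = 0.5) {
  method <- arg_match(method)
  true_frac <- truth %>%
    group_by(.data$gene) %>%
    summarise(n_truth = n(),
              true_het_fraction = mean(.data$zygosity == "heterozygous"),
              .groups = "drop")
  est <- estimate_het_fraction(
    mutations,
    purity = if (method == "purity_aware") truth else NULL,
    method = method, vaf_threshold = vaf_threshold
  )
  out <- true_frac %>%
    left_join(est, by = "gene") %>%
    mutate(abs_error = abs(.data$estimated_het_fraction -
                             .data$true_het_fraction))
  structure(out,
            mae = mean(out$abs_error, na.rm = TRUE),
            method = method,
            class = c("recovery_metrics", class(tibble())))
}
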