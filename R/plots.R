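#' Plot a zygosity profile
#'
#' Per-gene heterozygous proportions as a dot plot with the
#' heterozygous-preferential cutoff drawn as a dashed line; point size
#' tracks the number of oncogenic mutations behind each proportion.
#'
#' @param object A `zygosity_profile` from [profile_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zygosity_profile <- function(object, ...) {
  p <- attr(object, "params")
  df <- as_tibble(object) %>%
    filter(!is.na(.data$proportion_heterozygous)) %>%
    mutate(gene = stats::reorder(.data$gene, .data$proportion_heterozygous))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$proportion_heterozygous, y = .data$gene,
    colour = .data$classification, size = .data$total_oncogenic
  )) +
    ggplot2::geom_vline(xintercept = p$het_cutoff, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("Proportion of oncogenic mutations with VAF < %s",
                  format(p$vaf_threshold)),
      y = NULL, colour = NULL, size = "Oncogenic\nmutations"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a domain count table
#'
#' Stacked bars of mutation counts per domain bucket, split by truncating
#' status.
#'
#' @param object A `domain_counts` from [count_by_domain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.domain_counts <- function(object, ...) {
  model <- attr(object, "model")
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(c("n_truncating", "n_other"),
                        names_to = "class", values_to = "count") %>%
    mutate(
      class = dplyr::recode(.data$class, n_truncating = "truncating",
                            n_other = "non-truncating"),
      domain = factor(.data$domain, levels = unique(object$domain))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("%s domain", model$gene), y = "Mutations",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot recovery metrics
#'
#' Estimated versus true per-gene heterozygous fractions with the identity
#' line.
#'
#' @param object A `recovery_metrics` from [recover_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_metrics <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$true_het_fraction, y = .data$estimated_het_fraction
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "True heterozygous fraction",
                  y = "Estimated heterozygous fraction") +
    ggplot2::theme_minimal()
}
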