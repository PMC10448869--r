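#' Is a consequence class truncating?
#'
#' Nonsense, frameshift, and (by loss-of-function convention) splice-site
#' alterations produce a shortened or aberrant protein and are classed as
#' truncating.
#'
#' @param classification Character vector of internal consequence classes.
#' @param splice_is_truncating Count splice-site variants as truncating
#'   (default `TRUE`).
#' @return Logical vector.
#' @export
is_truncating <- function(classification, splice_is_truncating = TRUE) {
  trunc_classes <- c("nonsense", "frameshift",
                     if (splice_is_truncating) "splice_site")
  classification %in% trunc_classes
}

#' Is a residue in the C-terminal half?
#'
#' The C-terminal half is every position strictly greater than
#' `ceiling(protein_length / 2)`; for odd lengths the middle residue is
#' N-terminal, so the C-terminal half always holds
#' `floor(protein_length / 2)` residues.
#'
#' @param position 1-based residue position(s).
#' @param protein_length Protein length in residues.
#' @return Logical vector.
#' @export
is_cterminal <- function(position, protein_length) {
  position > ceiling(protein_length / 2)
}

#' Map a protein position onto a domain model
#'
#' @param position 1-based residue position(s) within the protein.
#' @param model A [domain_model()].
#' @return Character vector: the name of the unique domain whose
#'   \[start, end\] interval contains the position, or `"inter-domain"`.
#' @export
#' @examples
#' map_to_domain(c(106, 200), sox9_like_model())
map_to_domain <- function(position, model) {
  if (any(is.na(position)) || any(position < 1) ||
      any(position > model$protein_length)) {
    abort(sprintf("Positions must lie in [1, %d].", model$protein_length))
  }
  d <- model$domains
  if (nrow(d) == 0) return(rep("inter-domain", length(position)))
  idx <- findInterval(position, d$start)
  hit <- idx >= 1 & position <= d$end[pmax(idx, 1)]
  dplyr::if_else(hit, d$name[pmax(idx, 1)], "inter-domain")
}

#' Count mutations per protein domain
#'
#' Tallies positioned mutations into their domain (or the inter-domain
#' bucket), split by truncating status, and conserves totals: mapped
#' buckets plus unmapped (records without a protein position) equal the
#' number of records supplied.
#'
#' @param mutations Mutation tibble for one gene.
#' @param model A [domain_model()].
#' @param splice_is_truncating Passed to [is_truncating()].
#' @return A tibble of class `domain_counts` with one row per domain plus
#'   `"inter-domain"` (columns `domain`, `n_truncating`, `n_other`,
#'   `n_total`), carrying attributes `n_supplied`, `n_mapped`,
#'   `n_unmapped`, `n_cterminal`, and the model.
#' @export
count_by_domain <- function(mutations, model, splice_is_truncating = TRUE) {
  n_supplied <- nrow(mutations)
  positioned <- mutations[!is.na(mutations$protein_pos), , drop = FALSE]
  n_unmapped <- n_supplied - nrow(positioned)

  levels <- c(model$domains$name, "inter-domain")
  if (nrow(positioned)) {
    counts <- positioned %>%
      mutate(
        domain = factor(map_to_domain(.data$protein_pos, model),
                        levels = levels),
        truncating = is_truncating(.data$classification,
                                   splice_is_truncating)
      ) %>%
      group_by(.data$domain, .drop = FALSE) %>%
      summarise(n_truncating = sum(.data$truncating),
                n_other = sum(!.data$truncating), .groups = "drop") %>%
      mutate(domain = as.character(.data$domain),
             n_total = .data$n_truncating + .data$n_other)
    n_cterminal <- sum(is_cterminal(positioned$protein_pos,
                                    model$protein_length))
  } else {
    counts <- tibble(domain = levels, n_truncating = 0L, n_other = 0L,
                     n_total = 0L)
    n_cterminal <- 0L
  }

  structure(
    counts,
    n_supplied = n_supplied,
    n_mapped = nrow(positioned),
    n_unmapped = n_unmapped,
    n_cterminal = as.integer(n_cterminal),
    model = model,
    class = c("domain_counts", class(tibble()))
  )
}

#' Exact binomial test for C-terminal clustering
#'
#' Tests whether positioned mutations fall in the C-terminal half of the
#' protein more often than a uniform-over-length null would predict. The
#' null success probability is the share of residues in the C-terminal
#' half (`floor(L/2) / L`, exactly 1/2 for even lengths); the p-value is a
#' one-sided (greater) exact binomial test via [stats::binom.test()].
#'
#' @param mutations Mutation tibble for one gene; only records with a
#'   protein position are used, and at least one is required.
#' @param model A [domain_model()].
#' @param truncating_only Restrict to truncating mutations (default
#'   `FALSE`).
#' @param null Null model; only `"uniform_length"` is implemented.
#' @return A one-row tibble: `gene`, `n_positioned`, `n_cterminal`,
#'   `observed_fraction`, `null_prob`, `p_value`, `method`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_params(
#'   n_samples = 100, genes = gene_params("SOX9", mutation_rate = 1),
#'   cterminal_weight = 5, seed = 3
#' ))
#' cterminal_clustering_test(cohort$mutations, sox9_like_model())
cterminal_clustering_test <- function(mutations, model,
                                      truncating_only = FALSE,
                                      null = "uniform_length") {
  null <- arg_match(null, "uniform_length")
  df <- mutations[!is.na(mutations$protein_pos), , drop = FALSE]
  if (truncating_only) {
    df <- df[is_truncating(df$classification), , drop = FALSE]
  }
  if (nrow(df) == 0) {
    abort("C-terminal clustering test requires >= 1 mutation with a protein position.")
  }
  len <- model$protein_length
  n_cterm <- sum(is_cterminal(df$protein_pos, len))
  null_prob <- floor(len / 2) / len
  ht <- binom.test(n_cterm, nrow(df), p = null_prob, alternative = "greater")
  tibble(
    gene = model$gene,
    n_positioned = nrow(df),
    n_cterminal = as.integer(n_cterm),
    observed_fraction = n_cterm / nrow(df),
    null_prob = null_prob,
    p_value = unname(ht$p.value),
    method = "one-sided exact binomial vs uniform-over-length null"
  )
}

#' C-terminal clustering scan over several genes
#'
#' Runs [cterminal_clustering_test()] per gene and applies a
#' Benjamini-Hochberg correction across genes.
#'
#' @param mutations Mutation tibble (multiple genes).
#' @param models Named list of [domain_model()] objects, e.g. from
#'   [read_domain_table()].
#' @param adjust Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @inheritParams cterminal_clustering_test
#' @return A tibble with one row per tested gene plus a `p_adjusted`
#'   column; genes with no positioned mutations are skipped.
#' @export
cterminal_clustering_scan <- function(mutations, models, adjust = "BH",
                                      truncating_only = FALSE) {
  out <- purrr::map(models, function(model) {
    df <- mutations[mutations$gene == model$gene, , drop = FALSE]
    if (!any(!is.na(df$protein_pos))) return(NULL)
    cterminal_clustering_test(df, model, truncating_only = truncating_only)
  }) %>%
    purrr::compact() %>%
    bind_rows()
  if (nrow(out)) out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out
}

#' Lollipop-ready per-position mutation counts
#'
#' Aggregates positioned mutations of one gene to (position, count,
#' truncating) rows suitable for external lollipop plotting.
#'
#' @inheritParams count_by_domain
#' @return A tibble with columns `position`, `truncating`, `count`.
#' @export
lollipop_data <- function(mutations, model, splice_is_truncating = TRUE) {
  mutations %>%
    filter(!is.na(.data$protein_pos)) %>%
    mutate(truncating = is_truncating(.data$classification,
                                      splice_is_truncating)) %>%
    group_by(position = .data$protein_pos, .data$truncating) %>%
    summarise(count = n(), .groups = "drop") %>%
    arrange(.data$position)
}
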