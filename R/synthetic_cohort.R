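#' Expected variant allele fraction under the tumor mixture model
#'
#' For a site carrying `m` mutant copies out of `c_t` total tumor copies in
#' a sample of purity `p` (contaminating normal cells contribute 2
#' wild-type copies), the expected VAF is
#' `m * p / (c_t * p + 2 * (1 - p))`. A diploid heterozygote gives p/2; a
#' hemizygous mutation after loss of heterozygosity (m = c_t = 1) gives
#' p/(2 - p), which crosses 0.5 exactly at p = 2/3. The function is
#' strictly increasing in both `m` and `p`.
#'
#' @param m Mutant copies, integer with `1 <= m <= c_t` (vectorized).
#' @param c_t Total tumor copies at the site, positive integer.
#' @param p Tumor purity in (0, 1\].
#' @return Expected allele fraction in \[0, 1\].
#' @export
#' @examples
#' expected_vaf(1, 2, 1)    # 0.5, pure diploid heterozygote
#' expected_vaf(1, 2, 0.6)  # 0.3
#' expected_vaf(1, 1, 2/3)  # 0.5, the LOH breakdown purity
expected_vaf <- function(m, c_t, p) {
  n <- max(length(m), length(c_t), length(p))
  m <- rep_len(m, n); c_t <- rep_len(c_t, n); p <- rep_len(p, n)
  if (any(is.na(m)) || any(m < 1) || any(m > c_t)) {
    abort("`m` must satisfy 1 <= m <= c_t.")
  }
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  m * p / (c_t * p + 2 * (1 - p))
}

#' Sample read support around an expected allele fraction
#'
#' Total depth is Poisson(`depth_mean`) floored at 1; alt reads are
#' binomial in the depth at the expected VAF. Uses the current RNG state.
#'
#' @param vaf Expected allele fraction(s) in \[0, 1\].
#' @param depth_mean Expected total read depth (> 0).
#' @return A tibble with columns `alt_count`, `ref_count`, one row per
#'   element of `vaf`.
#' @export
sample_read_support <- function(vaf, depth_mean) {
  if (any(is.na(vaf)) || any(vaf < 0) || any(vaf > 1)) {
    abort("`vaf` must lie in [0, 1].")
  }
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    abort("`depth_mean` must be > 0.")
  }
  n <- length(vaf)
  depth <- pmax(rpois(n, depth_mean), 1L)
  alt <- rbinom(n, depth, vaf)
  tibble(alt_count = as.integer(alt), ref_count = as.integer(depth - alt))
}

#' Draw a protein position, optionally biased toward the C-terminal half
#'
#' Non-truncating positions are uniform over the protein. Truncating
#' positions give every residue in the C-terminal half (position strictly
#' greater than `ceiling(length / 2)`; for odd lengths the middle residue
#' is N-terminal) relative weight `cterminal_weight` versus 1 for
#' N-terminal residues, uniform within each half. `cterminal_weight = 1`
#' recovers the uniform null; large weights reproduce the C-terminal
#' clustering of truncating mutations seen for SOX9-class genes.
#'
#' @param model A [domain_model()] (only `protein_length` is used).
#' @param truncating Logical; apply the C-terminal bias?
#' @param cterminal_weight Relative weight (>= 1) of C-terminal residues.
#' @param n Number of positions to draw.
#' @return Integer vector of 1-based residue positions.
#' @export
draw_protein_position <- function(model, truncating, cterminal_weight = 1,
                                  n = 1) {
  len <- model$protein_length
  if (len < 2) abort("Protein length must be >= 2.")
  if (cterminal_weight < 1) abort("`cterminal_weight` must be >= 1.")
  if (!truncating || cterminal_weight == 1) {
    return(sample.int(len, n, replace = TRUE))
  }
  boundary <- ceiling(len / 2)
  w <- rep(1, len)
  w[(boundary + 1):len] <- cterminal_weight
  sample.int(len, n, replace = TRUE, prob = w)
}

#' Per-gene simulation parameters
#'
#' @param gene Gene symbol.
#' @param true_het_fraction Probability that an emitted mutation is
#'   heterozygous (1 mutant copy on a diploid background) rather than
#'   hemizygous via loss of heterozygosity.
#' @param mutation_rate Per-sample probability that the gene is mutated.
#' @param truncating_fraction Share of non-deletion mutations that are
#'   truncating (nonsense/frameshift/splice-site).
#' @param model A [domain_model()] used to draw protein positions; defaults
#'   to the synthetic SOX9-like model.
#' @return A one-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()].
#' @export
gene_params <- function(gene, true_het_fraction = 0.7, mutation_rate = 0.1,
                        truncating_fraction = 0.6, model = sox9_like_model()) {
  stopifnot(true_het_fraction >= 0, true_het_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            truncating_fraction >= 0, truncating_fraction <= 1)
  tibble(
    gene = gene,
    true_het_fraction = true_het_fraction,
    mutation_rate = mutation_rate,
    truncating_fraction = truncating_fraction,
    model = list(model)
  )
}

#' Cohort simulation parameters
#'
#' Defaults emulate a TCGA-like colorectal cohort: per-sample purity
#' uniform on \[0.6, 0.9\], mean sequencing depth 200, mostly diploid
#' copy-number states, and a small share of deletion-class records so the
#' deletion-exclusion filter has something to act on.
#'
#' @param n_samples Number of tumor samples.
#' @param purity_range Length-2 interval in (0, 1\] for per-sample purity.
#' @param depth_mean Expected total reads per mutated site.
#' @param genes A tibble from [gene_params()] (rows may be bound together).
#' @param deletion_rate Probability an emitted mutation is a
#'   deletion-class record.
#' @param cn_state_probs Probability vector over GISTIC codes -2..2; must
#'   sum to 1.
#' @param cterminal_weight C-terminal position weight for truncating
#'   mutations (see [draw_protein_position()]).
#' @param decoy_oncogenic_fraction Share of emitted records flagged as not
#'   oncogenic-annotated (decoys for the oncogenic filter).
#' @param seed Integer seed; simulation is fully reproducible from it.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_samples = 200,
                              purity_range = c(0.6, 0.9),
                              depth_mean = 200,
                              genes = gene_params("SOX9"),
                              deletion_rate = 0.05,
                              cn_state_probs = c(0.02, 0.08, 0.70, 0.15, 0.05),
                              cterminal_weight = 1,
                              decoy_oncogenic_fraction = 0,
                              seed = NULL) {
  stopifnot(n_samples >= 1,
            length(purity_range) == 2,
            purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            depth_mean > 0,
            deletion_rate >= 0, deletion_rate <= 1,
            decoy_oncogenic_fraction >= 0, decoy_oncogenic_fraction <= 1,
            cterminal_weight >= 1,
            length(cn_state_probs) == 5, all(cn_state_probs >= 0))
  if (abs(sum(cn_state_probs) - 1) > 1e-12) {
    abort("`cn_state_probs` must sum to 1.")
  }
  structure(
    list(n_samples = as.integer(n_samples), purity_range = purity_range,
         depth_mean = depth_mean, genes = genes,
         deletion_rate = deletion_rate, cn_state_probs = cn_state_probs,
         cterminal_weight = cterminal_weight,
         decoy_oncogenic_fraction = decoy_oncogenic_fraction,
         seed = seed),
    class = "simulation_params"
  )
}

#' Simulate a tumor cohort with known zygosity ground truth
#'
#' Generates a cohort with the statistical structure the zygosity-profiling
#' procedure assumes. Per sample, purity is uniform over `purity_range`;
#' per (sample, gene), a GISTIC copy-number code is drawn from
#' `cn_state_probs` and a mutation is emitted with the gene's
#' `mutation_rate`. An emitted mutation is heterozygous with probability
#' `true_het_fraction` (1 mutant of 2 tumor copies; the copy-number code is
#' forced to diploid-or-gain) or hemizygous via LOH otherwise (1 mutant of
#' 1 copy; code forced to shallow loss). Read support is
#' Poisson-depth/binomial around the expected VAF of
#' [expected_vaf()]. Every mutation record has exactly one truth record,
#' paired by (sample, gene).
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `synthetic_cohort` with elements `mutations`,
#'   `copy_numbers`, `truth` (columns `sample`, `gene`, `purity`,
#'   `tumor_total_copies`, `mutant_copies`, `zygosity`, `expected_vaf`),
#'   `cohort_size`, and `params`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_params(
#'   n_samples = 50,
#'   genes = gene_params("SOX9", true_het_fraction = 0.75, mutation_rate = 1),
#'   seed = 42
#' ))
#' head(cohort$truth)
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  samples <- sprintf("S%04d", seq_len(params$n_samples))
  purity <- runif(params$n_samples, params$purity_range[1],
                  params$purity_range[2])
  names(purity) <- samples

  mutations <- list()
  copy_numbers <- list()
  truth <- list()

  for (gi in seq_len(nrow(params$genes))) {
    g <- params$genes[gi, ]
    model <- g$model[[1]]
    cn <- sample(GISTIC_CODES, params$n_samples, replace = TRUE,
                 prob = params$cn_state_probs)
    mutated <- runif(params$n_samples) < g$mutation_rate
    n_mut <- sum(mutated)

    if (n_mut > 0) {
      idx <- which(mutated)
      het <- runif(n_mut) < g$true_het_fraction
      m <- rep(1L, n_mut)
      c_t <- dplyr::if_else(het, 2L, 1L)
      cn[idx] <- dplyr::if_else(het, pmax(cn[idx], 0L), -1L)
      p <- purity[idx]
      evaf <- expected_vaf(m, c_t, p)
      reads <- sample_read_support(evaf, params$depth_mean)

      is_del <- runif(n_mut) < params$deletion_rate
      is_trunc <- !is_del &
        runif(n_mut) < g$truncating_fraction
      classification <- character(n_mut)
      classification[is_del] <- "deletion"
      n_tr <- sum(is_trunc)
      classification[is_trunc] <- sample(
        c("nonsense", "frameshift", "splice_site"), n_tr,
        replace = TRUE, prob = c(0.45, 0.45, 0.10))
      n_other <- sum(!is_del & !is_trunc)
      classification[!is_del & !is_trunc] <- sample(
        c("missense", "in_frame_indel"), n_other,
        replace = TRUE, prob = c(0.9, 0.1))

      pos <- integer(n_mut)
      if (n_tr > 0) {
        pos[is_trunc] <- draw_protein_position(
          model, truncating = TRUE,
          cterminal_weight = params$cterminal_weight, n = n_tr)
      }
      if (any(!is_trunc)) {
        pos[!is_trunc] <- draw_protein_position(
          model, truncating = FALSE, n = sum(!is_trunc))
      }

      oncogenic <- if (params$decoy_oncogenic_fraction > 0) {
        runif(n_mut) >= params$decoy_oncogenic_fraction
      } else rep(TRUE, n_mut)

      mutations[[gi]] <- tibble(
        gene = g$gene, sample = samples[idx],
        classification = classification, protein_pos = pos,
        alt_count = reads$alt_count, ref_count = reads$ref_count,
        oncogenic = oncogenic
      )
      truth[[gi]] <- tibble(
        sample = samples[idx], gene = g$gene, purity = unname(p),
        tumor_total_copies = c_t, mutant_copies = m,
        zygosity = dplyr::if_else(het, "heterozygous", "homozygous_loh"),
        expected_vaf = evaf
      )
    }
    copy_numbers[[gi]] <- tibble(sample = samples, gene = g$gene,
                                 cn_code = as.integer(cn))
  }

  mut_tbl <- bind_rows(mutations)
  if (ncol(mut_tbl) == 0) mut_tbl <- empty_mutation_tbl()
  truth_tbl <- bind_rows(truth)
  if (ncol(truth_tbl) == 0) truth_tbl <- empty_truth_tbl()

  structure(
    list(
      mutations = mut_tbl,
      copy_numbers = bind_rows(copy_numbers),
      truth = truth_tbl,
      cohort_size = params$n_samples,
      params = params
    ),
    class = "synthetic_cohort"
  )
}

empty_mutation_tbl <- function() {
  tibble(gene = character(), sample = character(),
         classification = character(), protein_pos = integer(),
         alt_count = integer(), ref_count = integer(), oncogenic = logical())
}

empty_truth_tbl <- function() {
  tibble(sample = character(), gene = character(), purity = double(),
         tumor_total_copies = integer(), mutant_copies = integer(),
         zygosity = character(), expected_vaf = double())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d gene(s), %d mutation(s)\n",
              x$cohort_size, nrow(x$params$genes), nrow(x$mutations)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the mutation table (MAF or simple TSV dialect), the copy-number
#' TSV, the ground-truth TSV, and the simulation parameters as YAML.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param dialect Mutation-table dialect, `"simple_tsv"` or `"maf"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("simple_tsv", "maf")) {
  dialect <- arg_match(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    mutations = file.path(dir, if (dialect == "maf") "mutations.maf.tsv"
                          else "mutations.tsv"),
    copy_numbers = file.path(dir, "copy_numbers.tsv"),
    truth = file.path(dir, "truth.tsv"),
    params = file.path(dir, "params.yaml")
  )
  write_mutation_table(cohort$mutations, files[["mutations"]], dialect)
  write_copy_number_table(cohort$copy_numbers, files[["copy_numbers"]])
  readr::write_tsv(cohort$truth, files[["truth"]])
  p <- cohort$params
  yaml::write_yaml(
    list(n_samples = p$n_samples, purity_range = p$purity_range,
         depth_mean = p$depth_mean, deletion_rate = p$deletion_rate,
         cn_state_probs = p$cn_state_probs,
         cterminal_weight = p$cterminal_weight,
         decoy_oncogenic_fraction = p$decoy_oncogenic_fraction,
         seed = p$seed,
         genes = purrr::map(seq_len(nrow(p$genes)), function(i) {
           list(gene = p$genes$gene[i],
                true_het_fraction = p$genes$true_het_fraction[i],
                mutation_rate = p$genes$mutation_rate[i],
                truncating_fraction = p$genes$truncating_fraction[i],
                protein_length = p$genes$model[[i]]$protein_length)
         })),
    files[["params"]]
  )
  invisible(files)
}

#' Read a ground-truth table written by [write_cohort()]
#'
#' @param path Path to the truth TSV.
#' @return A tibble with the truth columns of [simulate_cohort()].
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    gene = readr::col_character(),
    purity = readr::col_double(),
    tumor_total_copies = readr::col_integer(),
    mutant_copies = readr::col_integer(),
    zygosity = readr::col_character(),
    expected_vaf = readr::col_double()
  ))
}
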