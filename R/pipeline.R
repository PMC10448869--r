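#' Run the zygosity-profiling pipeline on files
#'
#' Reads a mutation table and a copy-number table, computes the per-gene
#' zygosity profile, and writes the report (TSV and JSON), the validation
#' summary, an optional C-terminal clustering scan (when domain models are
#' supplied), and a run manifest with the configuration echo and input
#' checksums. Reruns on identical inputs and configuration are
#' byte-identical.
#'
#' @param mutations_path Path to the mutation table.
#' @param copy_number_path Path to the copy-number table.
#' @param out_dir Output directory (created if needed).
#' @param dialect Mutation-table dialect (see [read_mutation_table()]).
#' @param cohort_size Number of samples in the data set, or `NULL`.
#' @param domains_path Optional domain-model TSV
#'   (see [read_domain_table()]).
#' @inheritParams profile_cohort
#' @return Invisibly, a list with the `profiles` tibble and the paths of
#'   the files written.
#' @export
run_profile <- function(mutations_path, copy_number_path, out_dir,
                        dialect = c("maf", "simple_tsv"),
                        cohort_size = NULL, domains_path = NULL,
                        vaf_threshold = 0.5, het_cutoff = 0.5, cn_floor = 0,
                        deletion_mode = c("variant_class", "copy_number")) {
  dialect <- arg_match(dialect)
  deletion_mode <- arg_match(deletion_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mutations <- read_mutation_table(mutations_path, dialect = dialect)
  if (nrow(mutations) == 0) {
    abort("no mutations: the mutation table contains no usable records.")
  }
  copy_numbers <- read_copy_number_table(copy_number_path)

  profiles <- profile_cohort(
    mutations, copy_numbers, cohort_size = cohort_size,
    vaf_threshold = vaf_threshold, het_cutoff = het_cutoff,
    cn_floor = cn_floor, deletion_mode = deletion_mode
  )

  files <- c(profile_tsv = file.path(out_dir, "profile.tsv"),
             profile_json = file.path(out_dir, "profile.json"),
             validation = file.path(out_dir, "validation.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write_profile_report(profiles, files[["profile_tsv"]], "tsv")
  write_profile_report(profiles, files[["profile_json"]], "json")
  jsonlite::write_json(
    list(mutations = unclass(validation_report(mutations)),
         copy_numbers = unclass(validation_report(copy_numbers))),
    files[["validation"]], auto_unbox = TRUE, pretty = TRUE
  )

  if (!is.null(domains_path)) {
    models <- read_domain_table(domains_path)
    scan <- cterminal_clustering_scan(mutations, models)
    files[["clustering"]] <- file.path(out_dir, "clustering.tsv")
    readr::write_tsv(scan, files[["clustering"]])
  }

  inputs <- c(mutations = mutations_path, copy_numbers = copy_number_path)
  if (!is.null(domains_path)) inputs[["domains"]] <- domains_path
  write_manifest(
    files[["manifest"]],
    command = "profile",
    config = list(dialect = dialect, cohort_size = cohort_size,
                  vaf_threshold = vaf_threshold, het_cutoff = het_cutoff,
                  cn_floor = cn_floor, deletion_mode = deletion_mode),
    inputs = inputs,
    outputs = files[setdiff(names(files), "manifest")]
  )
  invisible(list(profiles = profiles, files = files))
}

#' Simulate a cohort and write it to disk
#'
#' Wraps [simulate_cohort()] and [write_cohort()] and adds a run manifest.
#' Reruns with the same parameters (including the seed) are bit-identical.
#'
#' @param params A [simulation_params()] object; its `seed` drives all
#'   randomness.
#' @param out_dir Output directory.
#' @param dialect Mutation-table dialect to emit.
#' @return Invisibly, a list with the `cohort` and the file paths written.
#' @export
run_simulate <- function(params, out_dir,
                         dialect = c("simple_tsv", "maf")) {
  dialect <- arg_match(dialect)
  cohort <- simulate_cohort(params)
  files <- write_cohort(cohort, out_dir, dialect = dialect)
  manifest <- file.path(out_dir, "manifest.json")
  write_manifest(
    manifest,
    command = "simulate",
    config = list(n_samples = params$n_samples,
                  purity_range = params$purity_range,
                  depth_mean = params$depth_mean,
                  deletion_rate = params$deletion_rate,
                  cterminal_weight = params$cterminal_weight,
                  seed = params$seed, dialect = dialect),
    inputs = character(),
    outputs = files
  )
  invisible(list(cohort = cohort, files = c(files, manifest = manifest)))
}

#' Score zygosity recovery against a simulation truth table
#'
#' Reads a simulated mutation table and its ground-truth table, estimates
#' per-gene heterozygous fractions, and writes the per-gene recovery
#' metrics plus an aggregate summary (mean absolute error).
#'
#' @param mutations_path Path to the simulated mutation table.
#' @param truth_path Path to the truth TSV written by [write_cohort()].
#' @param out_dir Output directory.
#' @param dialect Mutation-table dialect.
#' @inheritParams recover_metrics
#' @return Invisibly, a list with the `metrics` tibble and file paths.
#' @export
run_recover <- function(mutations_path, truth_path, out_dir,
                        dialect = c("simple_tsv", "maf"),
                        method = c("purity_aware", "fixed"),
                        vaf_threshold = 0.5) {
  dialect <- arg_match(dialect)
  method <- arg_match(method)
  if (!file.exists(truth_path)) {
    abort(sprintf("missing truth table: %s", truth_path))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mutations <- read_mutation_table(mutations_path, dialect = dialect)
  truth <- read_truth_table(truth_path)
  metrics <- recover_metrics(mutations, truth, method = method,
                             vaf_threshold = vaf_threshold)

  files <- c(recovery_tsv = file.path(out_dir, "recovery.tsv"),
             summary = file.path(out_dir, "recovery_summary.json"),
             manifest = file.path(out_dir, "recovery_manifest.json"))
  readr::write_tsv(as_tibble(metrics), files[["recovery_tsv"]])
  jsonlite::write_json(
    list(method = method, n_genes = nrow(metrics),
         mae = attr(metrics, "mae")),
    files[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_manifest(
    files[["manifest"]],
    command = "recover",
    config = list(dialect = dialect, method = method,
                  vaf_threshold = vaf_threshold),
    inputs = c(mutations = mutations_path, truth = truth_path),
    outputs = files[c("recovery_tsv", "summary")]
  )
  invisible(list(metrics = metrics, files = files))
}

# Manifest: configuration echo, tool version, and MD5 checksums of inputs
# and outputs -- enough to re-run and verify a report. No timestamps, so
# identical runs produce identical manifests.
write_manifest <- function(path, command, config, inputs, outputs) {
  checksum <- function(paths) {
    if (!length(paths)) return(NULL)
    md5 <- tools::md5sum(unname(unlist(paths)))
    as.list(setNames(unname(md5), names(paths)))
  }
  jsonlite::write_json(
    list(
      tool = "hetprofiler",
      version = as.character(packageVersion("hetprofiler")),
      command = command,
      config = config,
      input_md5 = checksum(inputs),
      output_md5 = checksum(outputs)
    ),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(path)
}
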