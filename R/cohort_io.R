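#' Read a somatic mutation table
#'
#' Reads per-mutation calls from a tab-separated file in one of two dialects
#' and returns a tidy mutation tibble. Rows that violate record invariants
#' (missing identifiers, missing or zero read support, protein positions
#' below 1) are dropped and tallied in the attached validation report --
#' never silently repaired.
#'
#' Dialects:
#' \describe{
#'   \item{`maf`}{TCGA-style Mutation Annotation Format. Required columns:
#'     `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`,
#'     `t_alt_count`, `t_ref_count`. Optional: `Protein_position` (leading
#'     integer is used, so `"123/509"` parses as 123) and `oncogenic`
#'     (logical-ish; if absent all records are taken as oncogenic-annotated,
#'     with a warning in the report). `Variant_Classification` strings are
#'     mapped onto the internal consequence classes
#'     (`Nonsense_Mutation` to `nonsense`, `Frame_Shift_Ins`/`Frame_Shift_Del`
#'     to `frameshift`, `Missense_Mutation` to `missense`, `Splice_Site` to
#'     `splice_site`, `In_Frame_Ins`/`In_Frame_Del` to `in_frame_indel`,
#'     `Deletion` to `deletion`, anything else to `other`).}
#'   \item{`simple_tsv`}{columns `gene`, `sample`, `classification`,
#'     `protein_pos`, `alt_count`, `ref_count`, `oncogenic`, with
#'     `classification` already in the internal vocabulary.}
#' }
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"maf"` or `"simple_tsv"`.
#'
#' @return A tibble with columns `gene`, `sample`, `classification`,
#'   `protein_pos`, `alt_count`, `ref_count`, `oncogenic`, carrying the
#'   validation report as an attribute (see [validation_report()]).
#' @seealso [read_copy_number_table()], [write_mutation_table()]
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_maf_60.maf.tsv",
#'                     package = "hetprofiler")
#' muts <- read_mutation_table(path, dialect = "maf")
#' validation_report(muts)
read_mutation_table <- function(path, dialect = c("maf", "simple_tsv")) {
  dialect <- arg_match(dialect)
  raw <- read_tsv_checked(path)
  warnings <- character()

  if (dialect == "maf") {
    required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification", "t_alt_count", "t_ref_count")
    check_columns(raw, required, path)
    df <- tibble(
      gene = as.character(raw$Hugo_Symbol),
      sample = as.character(raw$Tumor_Sample_Barcode),
      classification = map_maf_classification(raw$Variant_Classification),
      protein_pos = parse_protein_position(raw[["Protein_position"]], nrow(raw)),
      alt_count = parse_count(raw$t_alt_count),
      ref_count = parse_count(raw$t_ref_count)
    )
    if ("oncogenic" %in% names(raw)) {
      df$oncogenic <- parse_flag(raw$oncogenic)
    } else {
      df$oncogenic <- TRUE
      warnings <- c(warnings,
                    "no 'oncogenic' column; all records treated as oncogenic-annotated")
    }
  } else {
    required <- c("gene", "sample", "classification", "alt_count", "ref_count")
    check_columns(raw, required, path)
    df <- tibble(
      gene = as.character(raw$gene),
      sample = as.character(raw$sample),
      classification = normalize_classification(raw$classification),
      protein_pos = parse_protein_position(raw[["protein_pos"]], nrow(raw)),
      alt_count = parse_count(raw$alt_count),
      ref_count = parse_count(raw$ref_count),
      oncogenic = if ("oncogenic" %in% names(raw)) parse_flag(raw$oncogenic) else TRUE
    )
    if (!"oncogenic" %in% names(raw)) {
      warnings <- c(warnings,
                    "no 'oncogenic' column; all records treated as oncogenic-annotated")
    }
  }

  drop_reason <- case_when(
    is.na(df$gene) | df$gene == "" |
      is.na(df$sample) | df$sample == "" ~ "missing_identifiers",
    is.na(df$alt_count) | is.na(df$ref_count) ~ "missing_read_support",
    df$alt_count < 0 | df$ref_count < 0 ~ "negative_read_support",
    df$alt_count + df$ref_count == 0 ~ "zero_depth",
    !is.na(df$protein_pos) & df$protein_pos < 1 ~ "bad_protein_position",
    TRUE ~ NA_character_
  )

  kept <- df[is.na(drop_reason), , drop = FALSE]
  report <- new_validation_report(
    n_read = nrow(df),
    drop_reasons = table_drop_reasons(drop_reason),
    warnings = warnings
  )
  attr(kept, "validation") <- report
  kept
}

#' Read a gene-level copy-number table
#'
#' Reads GISTIC-style integer copy-number calls, one row per
#' (sample, gene): -2 deep deletion, -1 shallow loss, 0 diploid, 1 gain,
#' 2 amplification. Codes outside -2..2 are dropped and tallied; duplicate
#' (sample, gene) pairs keep the first row, with a warning.
#'
#' @param path Path to a tab-separated file with columns `sample`, `gene`,
#'   `cn_code`.
#' @return A tibble with columns `sample`, `gene`, `cn_code`, carrying a
#'   validation report attribute (see [validation_report()]).
#' @export
read_copy_number_table <- function(path) {
  raw <- read_tsv_checked(path)
  check_columns(raw, c("sample", "gene", "cn_code"), path)
  warnings <- character()

  df <- tibble(
    sample = as.character(raw$sample),
    gene = as.character(raw$gene),
    cn_code = parse_count(raw$cn_code)
  )
  drop_reason <- dplyr::if_else(
    is.na(df$cn_code) | !df$cn_code %in% GISTIC_CODES,
    "bad_cn_code", NA_character_
  )
  kept <- df[is.na(drop_reason), , drop = FALSE]
  drop_reasons <- table_drop_reasons(drop_reason)

  dup <- duplicated(kept[c("sample", "gene")])
  if (any(dup)) {
    msg <- sprintf("%d duplicate (sample, gene) copy-number rows; kept first occurrence",
                   sum(dup))
    warn(msg)
    warnings <- c(warnings, msg)
    kept <- kept[!dup, , drop = FALSE]
    drop_reasons <- c(drop_reasons, duplicate_pair = sum(dup))
  }

  report <- new_validation_report(
    n_read = nrow(df),
    drop_reasons = drop_reasons,
    warnings = warnings
  )
  attr(kept, "validation") <- report
  kept
}

#' Write a zygosity profile report
#'
#' Serializes gene zygosity profiles as TSV or JSON. Column order follows
#' the report layout: gene, total oncogenic mutations, mutant samples with
#' diploid-or-gain copy number, sub-threshold allele-fraction count,
#' proportion heterozygous, maximum allele fraction, percent of samples
#' mutated, and the heterozygous-preferential classification. Proportions
#' are written with 5 decimal places.
#'
#' @param profiles A zygosity profile tibble from [profile_cohort()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_profile_report <- function(profiles, path, format = c("tsv", "json")) {
  format <- arg_match(format)
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("`profiles` must be a non-empty data frame of gene zygosity profiles.")
  }
  cols <- c("gene", "total_oncogenic", "mutant_samples_diploid_or_gain",
            "het_lt50_count", "proportion_heterozygous", "max_allele_fraction",
            "pct_samples_mutated", "classification")
  check_columns(profiles, cols, "profiles")
  out <- profiles[cols]
  if (format == "tsv") {
    out$proportion_heterozygous <- format_5dp(out$proportion_heterozygous)
    readr::write_tsv(out, path, na = "NA")
  } else {
    out$proportion_heterozygous <- round(out$proportion_heterozygous, 5)
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a profile report written by [write_profile_report()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble of gene zygosity profiles.
#' @export
read_profile_report <- function(path, format = c("tsv", "json")) {
  format <- arg_match(format)
  if (format == "tsv") {
    out <- readr::read_tsv(
      path,
      col_types = readr::cols(
        gene = readr::col_character(),
        total_oncogenic = readr::col_integer(),
        mutant_samples_diploid_or_gain = readr::col_integer(),
        het_lt50_count = readr::col_integer(),
        proportion_heterozygous = readr::col_double(),
        max_allele_fraction = readr::col_double(),
        pct_samples_mutated = readr::col_double(),
        classification = readr::col_character()
      )
    )
  } else {
    out <- as_tibble(jsonlite::fromJSON(path))
    out$total_oncogenic <- as.integer(out$total_oncogenic)
    out$mutant_samples_diploid_or_gain <- as.integer(out$mutant_samples_diploid_or_gain)
    out$het_lt50_count <- as.integer(out$het_lt50_count)
  }
  as_tibble(out)
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]: writes a tidy mutation tibble in
#' either dialect. The internal `deletion` consequence class is written as
#' `Variant_Classification` `"Deletion"` in the MAF dialect (a dialect
#' extension; standard TCGA MAFs have no such class).
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param path Output path.
#' @param dialect `"maf"` or `"simple_tsv"`.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path, dialect = c("maf", "simple_tsv")) {
  dialect <- arg_match(dialect)
  if (dialect == "maf") {
    out <- tibble(
      Hugo_Symbol = mutations$gene,
      Tumor_Sample_Barcode = mutations$sample,
      Variant_Classification = maf_class_string(mutations$classification),
      Protein_position = mutations$protein_pos,
      t_alt_count = mutations$alt_count,
      t_ref_count = mutations$ref_count,
      oncogenic = mutations$oncogenic
    )
  } else {
    out <- mutations[c("gene", "sample", "classification", "protein_pos",
                       "alt_count", "ref_count", "oncogenic")]
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Write a gene-level copy-number table
#'
#' @param copy_numbers Tibble with columns `sample`, `gene`, `cn_code`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_copy_number_table <- function(copy_numbers, path) {
  readr::write_tsv(copy_numbers[c("sample", "gene", "cn_code")], path)
  invisible(path)
}

#' Retrieve the validation report attached to a parsed table
#'
#' Parsing functions conserve records: every input row is either kept or
#' dropped with a tallied reason (`n_records_read = n_kept + n_dropped`).
#'
#' @param x A tibble returned by [read_mutation_table()] or
#'   [read_copy_number_table()].
#' @return A `validation_report`: list with `n_records_read`,
#'   `n_records_kept`, `n_records_dropped`, `drop_reasons` (named integer
#'   vector), and `warnings`.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation", exact = TRUE)
  if (is.null(rep)) abort("`x` carries no validation report.")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d read, %d kept, %d dropped\n",
              x$n_records_read, x$n_records_kept, x$n_records_dropped))
  if (length(x$drop_reasons)) {
    for (r in names(x$drop_reasons)) {
      cat(sprintf("  dropped [%s]: %d\n", r, x$drop_reasons[[r]]))
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

read_tsv_checked <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("Cannot read file: %s", paste(path, collapse = ", ")))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

map_maf_classification <- function(x) {
  case_when(
    x == "Nonsense_Mutation" ~ "nonsense",
    x %in% c("Frame_Shift_Ins", "Frame_Shift_Del") ~ "frameshift",
    x == "Missense_Mutation" ~ "missense",
    x == "Splice_Site" ~ "splice_site",
    x %in% c("In_Frame_Ins", "In_Frame_Del") ~ "in_frame_indel",
    x == "Deletion" ~ "deletion",
    TRUE ~ "other"
  )
}

maf_class_string <- function(x) {
  case_when(
    x == "nonsense" ~ "Nonsense_Mutation",
    x == "frameshift" ~ "Frame_Shift_Del",
    x == "missense" ~ "Missense_Mutation",
    x == "splice_site" ~ "Splice_Site",
    x == "in_frame_indel" ~ "In_Frame_Del",
    x == "deletion" ~ "Deletion",
    TRUE ~ "Unknown"
  )
}

normalize_classification <- function(x) {
  x <- tolower(as.character(x))
  dplyr::if_else(x %in% VARIANT_CLASSES, x, "other")
}

parse_count <- function(x) {
  suppressWarnings(as.integer(as.character(x)))
}

parse_protein_position <- function(x, n) {
  if (is.null(x)) return(rep(NA_integer_, n))
  suppressWarnings(as.integer(sub("/.*$", "", as.character(x))))
}

parse_flag <- function(x) {
  x <- tolower(as.character(x))
  case_when(
    x %in% c("true", "t", "yes", "y", "1") ~ TRUE,
    x %in% c("false", "f", "no", "n", "0") ~ FALSE,
    TRUE ~ NA
  )
}

format_5dp <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.5f", x))
}

table_drop_reasons <- function(drop_reason) {
  dropped <- drop_reason[!is.na(drop_reason)]
  if (!length(dropped)) return(integer())
  tab <- table(dropped)
  setNames(as.integer(tab), names(tab))
}

new_validation_report <- function(n_read, drop_reasons, warnings,
                                  n_kept = n_read - sum(drop_reasons)) {
  structure(
    list(
      n_records_read = as.integer(n_read),
      n_records_kept = as.integer(n_kept),
      n_records_dropped = as.integer(n_read - n_kept),
      drop_reasons = drop_reasons,
      warnings = warnings
    ),
    class = "validation_report"
  )
}
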