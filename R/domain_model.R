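#' Construct a protein-domain model
#'
#' A domain model is the ordered set of annotated domains of one protein,
#' given as 1-based inclusive residue intervals, plus the total protein
#' length. Intervals must be non-overlapping and lie within the protein.
#'
#' @param gene Gene symbol.
#' @param protein_length Total protein length in residues (>= 2).
#' @param domains Data frame with columns `name`, `start`, `end`
#'   (1-based inclusive); may be empty.
#' @return An object of class `domain_model`.
#' @export
#' @examples
#' dm <- domain_model("SOX9L", 509, data.frame(
#'   name = c("HMG", "TA"), start = c(105, 402), end = c(180, 496)
#' ))
#' dm
domain_model <- function(gene, protein_length, domains) {
  protein_length <- as.integer(protein_length)
  if (is.na(protein_length) || protein_length < 2) {
    abort("`protein_length` must be an integer >= 2.")
  }
  domains <- as_tibble(domains)
  if (nrow(domains) > 0) {
    check_columns(domains, c("name", "start", "end"), "domains")
    domains <- domains %>%
      mutate(name = as.character(.data$name),
             start = as.integer(.data$start),
             end = as.integer(.data$end)) %>%
      arrange(.data$start)
    bad <- domains$start < 1 | domains$end > protein_length |
      domains$start > domains$end
    if (any(bad)) {
      abort(sprintf("Domain interval(s) out of bounds for %s (length %d): %s",
                    gene, protein_length,
                    paste(domains$name[bad], collapse = ", ")))
    }
    if (nrow(domains) > 1 &&
        any(domains$start[-1] <= domains$end[-nrow(domains)])) {
      abort(sprintf("Domains of %s overlap.", gene))
    }
  } else {
    domains <- tibble(name = character(), start = integer(), end = integer())
  }
  structure(
    list(gene = as.character(gene), protein_length = protein_length,
         domains = domains),
    class = "domain_model"
  )
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model> %s, %d aa, %d domain(s)\n",
              x$gene, x$protein_length, nrow(x$domains)))
  if (nrow(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      cat(sprintf("  %s: %d-%d\n", x$domains$name[i],
                  x$domains$start[i], x$domains$end[i]))
    }
  }
  invisible(x)
}

#' Read protein-domain models from a TSV file
#'
#' Expects columns `gene`, `protein_length`, `domain_name`, `start`, `end`
#' (1-based inclusive), one row per domain. Returns one model per gene.
#'
#' @param path Path to the TSV file.
#' @return A named list of [domain_model()] objects, one per gene.
#' @export
read_domain_table <- function(path) {
  raw <- read_tsv_checked(path)
  check_columns(raw, c("gene", "protein_length", "domain_name", "start", "end"),
                path)
  raw %>%
    mutate(protein_length = as.integer(.data$protein_length),
           start = as.integer(.data$start),
           end = as.integer(.data$end)) %>%
    split(.$gene) %>%
    purrr::map(function(g) {
      domain_model(
        gene = g$gene[1],
        protein_length = g$protein_length[1],
        domains = tibble(name = g$domain_name, start = g$start, end = g$end)
      )
    })
}

#' A synthetic SOX9-like domain model
#'
#' A 509-residue model in the shape of the SOX9 transcription factor, with
#' an N-terminal dimerization (DIM) and DNA-binding high-mobility-group
#' (HMG) domain and three C-terminal-half domains (K2, PQA, TA). The
#' coordinates are synthetic stand-ins for testing and simulation, not a
#' curated reference annotation (see
#' `inst/extdata/sox9_like_domains_synthetic.tsv`).
#'
#' @return A [domain_model()].
#' @export
sox9_like_model <- function() {
  domain_model(
    gene = "SOX9",
    protein_length = 509L,
    domains = tibble(
      name = c("DIM", "HMG", "K2", "PQA", "TA"),
      start = c(66L, 106L, 299L, 339L, 402L),
      end = c(102L, 182L, 336L, 379L, 496L)
    )
  )
}
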