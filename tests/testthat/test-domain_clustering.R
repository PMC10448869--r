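toy_model <- function(len = 100) {
  domain_model("TOY", len, tibble::tibble(
    name = c("D1", "D2", "D3"),
    start = c(10L, 40L, 71L),
    end = c(20L, 55L, 90L)
  ))
}

test_that("truncating classes are nonsense, frameshift, and splice-site", {
  expect_true(all(is_truncating(c("nonsense", "frameshift", "splice_site"))))
  expect_false(any(is_truncating(c("missense", "in_frame_indel",
                                   "deletion", "other"))))
  expect_false(is_truncating("splice_site", splice_is_truncating = FALSE))
})

test_that("domain lookup is boundary-inclusive and matches an exhaustive oracle", {
  m <- toy_model()
  expect_equal(map_to_domain(10, m), "D1")   # start inclusive
  expect_equal(map_to_domain(20, m), "D1")   # end inclusive
  expect_equal(map_to_domain(21, m), "inter-domain")
  expect_equal(map_to_domain(91, m), "inter-domain")  # past last domain
  expect_error(map_to_domain(0, m), "Positions")
  expect_error(map_to_domain(101, m), "Positions")

  # exhaustive per-residue oracle over models up to length 1000
  for (len in c(100L, 509L, 1000L)) {
    scale <- len / 100
    m <- domain_model("TOY", len, tibble::tibble(
      name = c("D1", "D2", "D3"),
      start = as.integer(ceiling(c(10, 40, 71) * scale)),
      end = as.integer(floor(c(20, 55, 90) * scale))
    ))
    oracle <- vapply(seq_len(len), function(pos) {
      for (i in seq_len(nrow(m$domains))) {
        if (pos >= m$domains$start[i] && pos <= m$domains$end[i]) {
          return(m$domains$name[i])
        }
      }
      "inter-domain"
    }, character(1))
    expect_equal(map_to_domain(seq_len(len), m), oracle)
  }
})

test_that("domain models validate their intervals", {
  expect_error(domain_model("G", 100, tibble::tibble(
    name = "D", start = 50, end = 120)), "out of bounds")
  expect_error(domain_model("G", 100, tibble::tibble(
    name = c("A", "B"), start = c(10, 15), end = c(20, 30))), "overlap")
  expect_error(domain_model("G", 1, tibble::tibble(
    name = character(), start = integer(), end = integer())),
    "protein_length")
})

test_that("the packaged synthetic SOX9-like model round-trips through TSV", {
  models <- read_domain_table(extdata("sox9_like_domains_synthetic.tsv"))
  expect_named(models, "SOX9")
  m <- models$SOX9
  expect_equal(m$protein_length, 509L)
  expect_equal(m$domains$name, c("DIM", "HMG", "K2", "PQA", "TA"))
  expect_identical(m$domains, sox9_like_model()$domains)
  # three of the five domains sit wholly in the c-terminal half
  in_cterm <- is_cterminal(m$domains$start, m$protein_length)
  expect_equal(sum(in_cterm), 3)
})

test_that("domain counts conserve every supplied mutation", {
  m <- toy_model()
  muts <- dplyr::bind_rows(
    make_mutations("TOY", "S1", 5, 5, classification = "nonsense",
                   protein_pos = 15),
    make_mutations("TOY", "S2", 5, 5, classification = "missense",
                   protein_pos = 45),
    make_mutations("TOY", "S3", 5, 5, classification = "missense",
                   protein_pos = 30),
    make_mutations("TOY", "S4", 5, 5, classification = "frameshift",
                   protein_pos = NA)  # unmapped
  )
  counts <- count_by_domain(muts, m)
  expect_equal(sum(counts$n_total) + attr(counts, "n_unmapped"), nrow(muts))
  expect_equal(counts$n_truncating[counts$domain == "D1"], 1L)
  expect_equal(counts$n_other[counts$domain == "D2"], 1L)
  expect_equal(counts$n_total[counts$domain == "inter-domain"], 1L)
  expect_equal(attr(counts, "n_unmapped"), 1L)

  gl <- glance(counts)
  expect_equal(gl$n_supplied, 4L)
  expect_equal(gl$n_mapped, 3L)

  empty <- count_by_domain(muts[0, ], m)
  expect_true(all(empty$n_total == 0))
  expect_equal(attr(empty, "n_supplied"), 0L)

  # 5 mutations all inside one domain land in that bucket
  five <- make_mutations("TOY", sprintf("S%d", 1:5), 5, 5,
                         protein_pos = c(41, 45, 50, 52, 55))
  counts5 <- count_by_domain(five, m)
  expect_equal(counts5$n_total[counts5$domain == "D2"], 5L)
})

test_that("conservation holds for random simulated inputs", {
  set.seed(601)
  for (i in 1:10) {
    co <- simulate_cohort(simulation_params(
      n_samples = 60, genes = gene_params("SOX9", mutation_rate = 0.8),
      cterminal_weight = sample(1:4, 1), seed = 600 + i))
    counts <- count_by_domain(co$mutations, sox9_like_model())
    expect_equal(sum(counts$n_total) + attr(counts, "n_unmapped"),
                 nrow(co$mutations))
    expect_equal(sum(counts$n_truncating),
                 sum(is_truncating(co$mutations$classification) &
                       !is.na(co$mutations$protein_pos)))
  }
})

test_that("the clustering test has closed-form behavior in edge cases", {
  even <- domain_model("EVEN", 100, tibble::tibble(
    name = "D", start = 60L, end = 90L))
  all_cterm <- make_mutations("EVEN", sprintf("S%d", 1:10), 5, 5,
                              protein_pos = 51:60)
  res <- cterminal_clustering_test(all_cterm, even)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$null_prob, 0.5)
  expect_equal(res$p_value, 0.5^10)

  # at the null expectation the one-sided p-value is large
  at_null <- make_mutations("EVEN", sprintf("S%d", 1:200), 5, 5,
                            protein_pos = rep(c(25, 75), 100))
  res0 <- cterminal_clustering_test(at_null, even)
  expect_gte(res0$p_value, 0.4)

  no_pos <- make_mutations("EVEN", "S1", 5, 5, protein_pos = NA)
  expect_error(cterminal_clustering_test(no_pos, even), "protein position")
})

test_that("odd-length proteins use the floor(L/2)/L null", {
  m <- sox9_like_model()
  muts <- make_mutations("SOX9", sprintf("S%d", 1:3), 5, 5,
                         protein_pos = c(255, 256, 300))
  res <- cterminal_clustering_test(muts, m)
  expect_equal(res$null_prob, 254 / 509)
  # residue 255 is the middle of 509 and counts as n-terminal
  expect_equal(res$n_cterminal, 2L)
})

test_that("the multi-gene scan applies a BH correction", {
  set.seed(602)
  models <- list(
    A = domain_model("A", 200, tibble::tibble(name = "D", start = 150L,
                                              end = 190L)),
    B = domain_model("B", 200, tibble::tibble(name = "D", start = 10L,
                                              end = 50L))
  )
  muts <- dplyr::bind_rows(
    make_mutations("A", sprintf("S%d", 1:30), 5, 5,
                   protein_pos = sample(150:200, 30, replace = TRUE)),
    make_mutations("B", sprintf("S%d", 1:30), 5, 5,
                   protein_pos = sample(1:200, 30, replace = TRUE))
  )
  scan <- cterminal_clustering_scan(muts, models)
  expect_equal(nrow(scan), 2)
  expect_equal(scan$p_adjusted,
               p.adjust(scan$p_value, method = "BH"))
})

test_that("lollipop data aggregates positioned mutations", {
  muts <- make_mutations("TOY", sprintf("S%d", 1:4), 5, 5,
                         classification = c("nonsense", "nonsense",
                                            "missense", "missense"),
                         protein_pos = c(15, 15, 15, NA))
  ld <- lollipop_data(muts, toy_model())
  expect_equal(sum(ld$count), 3)
  expect_equal(ld$count[ld$truncating], 2)
})
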