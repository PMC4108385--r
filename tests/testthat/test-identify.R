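test_that("mutual best hits form pairs; non-mutual do not", {
  hits <- dplyr::bind_rows(
    hit_row("a", "b", bit = 300),
    hit_row("b", "a", bit = 300),
    hit_row("a", "c", bit = 100),
    hit_row("c", "a", bit = 400) # c prefers a, but a prefers b
  )
  rbh <- reciprocal_best_hits(hits)
  expect_equal(nrow(rbh), 1L)
  expect_equal(c(rbh$gene_a, rbh$gene_b), c("a", "b"))
})

test_that("RBH keeps only the top HSP per ordered pair and breaks ties deterministically", {
  hits <- dplyr::bind_rows(
    hit_row("a", "b", bit = 200, pident = 0.8),
    hit_row("a", "b", bit = 500, pident = 0.7), # top HSP
    hit_row("b", "a", bit = 500, pident = 0.7),
    # same bit score as a->b's top: identity then subject id break the tie
    hit_row("a", "c", bit = 500, pident = 0.6),
    hit_row("c", "a", bit = 500, pident = 0.6)
  )
  rbh <- reciprocal_best_hits(hits)
  expect_equal(nrow(rbh), 1L)
  expect_equal(rbh$gene_b, "b") # higher identity wins over c
  expect_equal(rbh$identity, 0.7)
})

test_that("RBH equals exhaustive enumeration on a crafted six-protein fixture", {
  withr::local_seed(41)
  prots <- letters[1:6]
  hits <- purrr::map_dfr(prots, function(q) {
    purrr::map_dfr(setdiff(prots, q), function(s) {
      hit_row(q, s, bit = sample(100:999, 1), pident = runif(1, 0.3, 1))
    })
  })
  # brute-force oracle: per query, scan all hits for the best partner
  best_of <- function(q) {
    h <- hits[hits$query_id == q, ]
    h <- h[order(-h$bit_score, -h$percent_identity, h$subject_id), ]
    h$subject_id[1]
  }
  expected <- sort(unique(vapply(prots, function(q) {
    p <- best_of(q)
    if (best_of(p) == q) paste(min(q, p), max(q, p), sep = "|") else NA_character_
  }, character(1))))
  expected <- expected[!is.na(expected)]
  rbh <- reciprocal_best_hits(hits)
  expect_equal(paste(rbh$gene_a, rbh$gene_b, sep = "|"), expected)
  # symmetry: no gene has two distinct partners
  genes <- c(rbh$gene_a, rbh$gene_b)
  expect_equal(anyDuplicated(genes), 0L)
})

test_that("the identity threshold follows the length-dependent curve", {
  expect_equal(identity_threshold(200), 0.30)
  expect_equal(identity_threshold(151), 0.30)
  # independent evaluation of the short-alignment expression at L = 100
  L <- 100
  expected <- 0.01 * 6 + 4.8 * L^(-0.32 * (1 + exp(-L / 1000)))
  expect_equal(identity_threshold(100), expected)
  expect_gt(expected, 0.31) # so identity 0.31 at L = 100 is rejected
})

test_that("coverage and identity criteria keep and reject the right pairs", {
  proteins <- dplyr::bind_rows(
    protein_row("a", 200), protein_row("b", 210),
    protein_row("c", 100), protein_row("d", 100)
  )
  cand <- tibble::tibble(
    gene_a = c("a", "a", "c"),
    gene_b = c("b", "b", "d"),
    identity = c(0.95, 0.95, 0.31),
    aligned_length = c(200, 165, 100),
    bit_score = c(400, 330, 90)
  )
  kept <- apply_duplicate_criteria(cand[1, ], proteins)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$coverage, 200 / 210)

  # coverage 165/210 = 0.786 < 0.8: rejected
  expect_equal(nrow(apply_duplicate_criteria(cand[2, ], proteins)), 0L)
  # identity 0.31 < threshold(100) ~ 0.355: rejected
  expect_equal(nrow(apply_duplicate_criteria(cand[3, ], proteins)), 0L)
  # missing protein is an error naming the gene
  expect_error(
    apply_duplicate_criteria(cand, proteins[-4, ]),
    "d"
  )
})

test_that("criteria are monotone: stricter thresholds never add pairs", {
  withr::local_seed(42)
  proteins <- purrr::map_dfr(sprintf("p%02d", 1:20), protein_row, len = 120)
  cand <- purrr::map_dfr(1:10, function(i) {
    tibble::tibble(
      gene_a = sprintf("p%02d", 2 * i - 1), gene_b = sprintf("p%02d", 2 * i),
      identity = runif(1, 0.2, 1), aligned_length = sample(60:120, 1),
      bit_score = 100
    )
  })
  loose <- apply_duplicate_criteria(cand, proteins, min_coverage = 0.5, constant = 0.2)
  tight <- apply_duplicate_criteria(cand, proteins, min_coverage = 0.9, constant = 0.5)
  expect_true(all(
    paste(tight$gene_a, tight$gene_b) %in% paste(loose$gene_a, loose$gene_b)
  ))
})

test_that("pseudogene pairs are removed", {
  models <- dplyr::bind_rows(
    gene_model_row("a"), gene_model_row("b"),
    gene_model_row("c", biotype = "processed_pseudogene"), gene_model_row("d")
  )
  pairs <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"))
  kept <- filter_pseudogenes(pairs, models)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$gene_a, "a")
  # no pseudogenes: identity mapping
  expect_equal(filter_pseudogenes(pairs[1, ], models), pairs[1, ])
  expect_error(
    filter_pseudogenes(tibble::tibble(gene_a = "zz", gene_b = "a"), models),
    "zz"
  )
})

test_that("locality and lineage classification follow the both-genes rule", {
  models <- dplyr::bind_rows(
    gene_model_row("a", chromosome = "chr5", lineage_specific = TRUE),
    gene_model_row("b", chromosome = "chr5", lineage_specific = TRUE),
    gene_model_row("c", chromosome = "chr2", lineage_specific = TRUE),
    gene_model_row("d", chromosome = "chr3", lineage_specific = FALSE)
  )
  pairs <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"))
  cls <- classify_pairs(pairs, models)
  expect_equal(cls$locality, c("intra", "inter"))
  expect_equal(cls$lineage, c("species_specific", "shared"))
})

test_that("chromosome summaries match hand-enumerated counts on a small fixture", {
  models <- dplyr::bind_rows(
    gene_model_row("a1", "chr1", lineage_specific = TRUE),
    gene_model_row("a2", "chr1", lineage_specific = TRUE),
    gene_model_row("a3", "chr1"),
    gene_model_row("b1", "chr2"),
    gene_model_row("b2", "chr2"),
    gene_model_row("c1", "chr3"),
    gene_model_row("c2", "chr3")
  )
  pairs <- classify_pairs(
    tibble::tibble(
      gene_a = c("a1", "a3", "b2"),
      gene_b = c("a2", "b1", "c1")
    ),
    models
  )
  s <- summarize_by_chromosome(pairs, models)
  chr1 <- s[s$chromosome == "chr1", ]
  # a1-a2 intra; a3 inter (to b1)
  expect_equal(chr1$n_dup_intra, 2L)
  expect_equal(chr1$n_dup_inter, 1L)
  expect_equal(chr1$duplicate_content, 100 * 3 / 3)
  expect_equal(chr1$n_ss_intra, 2L)
  chr3 <- s[s$chromosome == "chr3", ]
  expect_equal(chr3$n_dup_inter, 1L)
  expect_equal(chr3$n_dup_intra, 0L)
  all_row <- s[s$chromosome == "All", ]
  expect_equal(all_row$n_genes, 7L)
  expect_equal(all_row$n_dup, 2L + 1L + 2L + 1L)
  # single chromosome with zero pairs
  lonely <- summarize_by_chromosome(pairs[0, ] , gene_model_row("z", "chrZ"))
  expect_equal(lonely$duplicate_content, c(0, 0))
})

test_that("published bovine counts reproduce the printed content percentages", {
  s <- chromosome_summary_from_counts(bovine_chromosome_counts())
  pct <- function(chr) {
    round(s$duplicate_content[s$chromosome == chr], 1)
  }
  expect_equal(pct("15"), 34.2)
  expect_equal(pct("29"), 29.1)
  expect_equal(pct("X"), 31.5)
  expect_equal(pct("All"), 25.5)
  expect_equal(round(s$ss_content[s$chromosome == "All"], 1), 5.8)
  expect_equal(round(s$ss_content[s$chromosome == "15"], 1), 16.3)
  # genome totals
  all_row <- s[s$chromosome == "All", ]
  expect_equal(all_row$n_genes, 24559L)
  expect_equal(all_row$n_dup, 6262L)
  expect_equal(all_row$n_ss, 1424L)
})
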