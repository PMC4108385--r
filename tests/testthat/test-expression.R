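test_that("the log transform maps the documented anchor values", {
  mat <- expression_fixture(list(g1 = c(0, 1, 7)))
  out <- log_transform(mat)
  expect_equal(as.numeric(out[1, -1]), c(0, 1, 3)) # log2(1), log2(2), log2(8)
  expect_error(log_transform(mat, offset = 0), "offset")
})

test_that("transformed r is strictly increasing and antisymmetric", {
  r <- seq(-0.99, 0.99, by = 0.01)
  tr <- transform_r(r)
  expect_true(all(diff(tr) > 0))
  expect_equal(transform_r(-r), -tr)
  # clamped at the boundary rather than diverging
  eps <- 1e-6
  expect_equal(transform_r(1), log((2 - eps) / eps))
})

test_that("identical profiles give r = 1 and the clamped transform", {
  mat <- expression_fixture(list(
    g1 = c(5, 10, 0.5, 30, 3, 8, 12),
    g2 = c(5, 10, 0.5, 30, 3, 8, 12)
  ))
  cmp <- compare_pair_expression("g1", "g2", mat)
  expect_equal(cmp$r, 1)
  eps <- 1e-6
  expect_equal(cmp$transformed_r, log((2 - eps) / eps))
  expect_true(cmp$eligible)
  expect_equal(cmp$n_divergent_tissues, 0L)
})

test_that("fully anticorrelated on/off profiles diverge in every tissue", {
  mat <- expression_fixture(list(
    g1 = c(10, 20, 30, 40, 50, 60, 70),
    g2 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  ))
  cmp <- compare_pair_expression("g1", "g2", mat)
  expect_equal(cmp$n_divergent_tissues, 7L)
  expect_false(cmp$eligible) # g2 never on
})

test_that("the ambiguous FPKM zone never counts as divergence", {
  mat <- expression_fixture(list(
    g1 = c(10, 1.5, 0.5),
    g2 = c(1.2, 0.5, 10)
  ))
  cmp <- compare_pair_expression("g1", "g2", mat)
  st <- cmp$states[[1]]
  expect_equal(st$state_a, c("on", "ambiguous", "off"))
  expect_equal(st$state_b, c("ambiguous", "off", "on"))
  expect_equal(cmp$n_divergent_tissues, 1L) # only tissue 3 (off vs on)
})

test_that("r matches a hand computation and handles zero variance", {
  fa <- c(2, 4, 8, 1, 3, 9, 5)
  fb <- c(3, 5, 6, 2, 4, 7, 6)
  mat <- expression_fixture(list(g1 = fa, g2 = fb))
  cmp <- compare_pair_expression("g1", "g2", mat)
  la <- log2(fa + 1)
  lb <- log2(fb + 1)
  hand_r <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(cmp$r, hand_r, tolerance = 1e-12)

  flat <- expression_fixture(list(g1 = rep(5, 7), g2 = fb))
  cmp_flat <- compare_pair_expression("g1", "g2", flat)
  expect_true(is.na(cmp_flat$r))
  expect_true(is.na(cmp_flat$transformed_r))

  expect_error(compare_pair_expression("g1", "nope", mat), "nope")
})

test_that("state calls and r are invariant under a common tissue permutation", {
  withr::local_seed(61)
  fa <- runif(7, 0, 30)
  fb <- runif(7, 0, 30)
  perm <- sample(7)
  c1 <- compare_pair_expression("a", "b", expression_fixture(list(a = fa, b = fb)))
  c2 <- compare_pair_expression(
    "a", "b", expression_fixture(list(a = fa[perm], b = fb[perm]))
  )
  expect_equal(c1$r, c2$r)
  expect_equal(c1$n_divergent_tissues, c2$n_divergent_tissues)
})

test_that("divergence summaries count fixture fractions exactly", {
  profiles <- list()
  # 4 of 10 pairs divergent in tissue 1; none elsewhere
  for (i in 1:10) {
    a <- c(if (i <= 4) 10 else 5, 5, 5)
    b <- c(if (i <= 4) 0.2 else 5, 5, 5)
    profiles[[sprintf("g%02da", i)]] <- a
    profiles[[sprintf("g%02db", i)]] <- b
  }
  mat <- expression_fixture(profiles)
  pairs <- tibble::tibble(
    gene_a = sprintf("g%02da", 1:10), gene_b = sprintf("g%02db", 1:10)
  )
  cmp <- expression_comparison_table(pairs, mat)
  s <- divergence_summary(cmp)
  expect_equal(
    s$per_tissue$frac_divergent[s$per_tissue$tissue == "t1"], 0.4
  )
  expect_equal(s$overall$frac_ge1, 0.4)
  expect_equal(s$overall$frac_ge2, 0)

  # all-identical profiles: all fractions zero
  same <- expression_fixture(list(x1 = c(5, 5, 5), x2 = c(5, 5, 5)))
  s0 <- divergence_summary(expression_comparison_table(
    tibble::tibble(gene_a = "x1", gene_b = "x2"), same
  ))
  expect_true(all(s0$per_tissue$frac_divergent == 0))

  # lineage stratification
  cls <- dplyr::mutate(pairs,
    lineage = rep(c("species_specific", "shared"), each = 5)
  )
  s2 <- divergence_summary(cmp, cls)
  ss_row <- s2$overall[s2$overall$stratum == "species_specific", ]
  expect_equal(ss_row$n_pairs, 5L)
  expect_equal(ss_row$frac_ge1, 4 / 5)
})

test_that("divergent fractions increase with the silencing rate", {
  withr::local_seed(62)
  frac_at <- function(smax) {
    mean(replicate(300, {
      e <- simulate_expression_pair(1, 1,
        n_tissues = 7, silencing_max = smax,
        silencing_midpoint = 0.5
      )
      any(e$fpkm_a > 2 & e$fpkm_b < 1 | e$fpkm_a < 1 & e$fpkm_b > 2)
    }))
  }
  expect_gt(frac_at(0.4), frac_at(0.05))
})

test_that("bin_size 1 reduces the binned regression to unbinned OLS", {
  withr::local_seed(63)
  n <- 60
  ds <- runif(n, 0.05, 1.5)
  tr <- 2 - 1.5 * ds + rnorm(n, 0, 0.4)
  comparisons <- tibble::tibble(
    pair_id = sprintf("p%03d", 1:n),
    transformed_r = tr, eligible = TRUE
  )
  divergences <- tibble::tibble(pair_id = comparisons$pair_id, dS = ds)
  res <- expression_vs_divergence_regression(
    comparisons, divergences,
    covariate = "dS", bin_size = 1L
  )
  direct <- lm(tr ~ ds)
  expect_equal(res$slope, unname(coef(direct)[2]), tolerance = 1e-12)
  expect_equal(res$intercept, unname(coef(direct)[1]), tolerance = 1e-12)

  # binned version has the documented shape
  res5 <- expression_vs_divergence_regression(
    comparisons, divergences,
    covariate = "dS", bin_size = 5L
  )
  expect_equal(res5$n_bins, 12L)
  expect_lt(res5$slope, 0)
  expect_error(
    expression_vs_divergence_regression(
      comparisons[1:10, ], divergences,
      covariate = "dS", bin_size = 5L
    ),
    "3 full bins"
  )
})

test_that("the dN covariate is split into strata at dn_split", {
  withr::local_seed(64)
  n <- 80
  dn <- c(runif(n / 2, 0, 0.3), runif(n / 2, 0.3001, 1))
  comparisons <- tibble::tibble(
    pair_id = sprintf("p%03d", 1:n),
    transformed_r = 1 - dn + rnorm(n, 0, 0.3),
    eligible = TRUE
  )
  divergences <- tibble::tibble(pair_id = comparisons$pair_id, dN = dn)
  res <- expression_vs_divergence_regression(
    comparisons, divergences,
    covariate = "dN", dn_split = 0.3, bin_size = 5L
  )
  expect_setequal(res$stratum, c("below_split", "above_split"))
  expect_equal(res$n_pairs[res$stratum == "below_split"], 40L)
})

test_that("high-divergence flagging returns exactly the pairs below the ceiling", {
  profiles <- list(
    a1 = c(10, 1, 20, 1, 10, 1, 20), b1 = c(1, 10, 1, 20, 1, 10, 1), # negative r
    a2 = c(10, 12, 14, 16, 18, 20, 22), b2 = c(11, 13, 15, 17, 19, 21, 23), # r ~ 1
    a3 = c(30, 1, 30, 1, 30, 1, 30), b3 = c(1, 30, 1, 30, 1, 30, 1) # negative r
  )
  mat <- expression_fixture(profiles)
  pairs <- tibble::tibble(
    gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"),
    lineage = c("species_specific", "species_specific", "shared")
  )
  cmp <- expression_comparison_table(pairs, mat)
  expect_equal(flag_high_divergence_pairs(cmp, pairs, r_max = -1)$pair_id, character(0))
  expect_equal(
    sort(flag_high_divergence_pairs(cmp, pairs, r_max = 1.01)$pair_id),
    c("a1|b1", "a2|b2") # a3|b3 is not species-specific
  )
  expect_equal(flag_high_divergence_pairs(cmp, pairs, r_max = 0)$pair_id, "a1|b1")
})

test_that("the 1-tissue and 3-tissue eligibility variants agree in slope sign", {
  bundle <- small_bundle()
  pairs <- bundle$truth[, c("gene_a", "gene_b")]
  divergences <- tibble::tibble(
    pair_id = bundle$truth$pair_id, dS = bundle$truth$t
  )
  slopes <- vapply(c(1L, 3L), function(k) {
    cmp <- expression_comparison_table(
      pairs, bundle$expression,
      min_tissues_expressed = k
    )
    expression_vs_divergence_regression(
      cmp, divergences,
      covariate = "dS", bin_size = 5L
    )$slope[1]
  }, numeric(1))
  expect_true(all(slopes < 0))
})
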