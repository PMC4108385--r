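make_comparisons <- function(tr, eligible = TRUE) {
  tibble::tibble(
    pair_id = sprintf("p%04d", seq_along(tr)),
    transformed_r = tr, r = tanh(tr / 2), eligible = eligible
  )
}

make_structures <- function(classes) {
  tibble::tibble(
    pair_id = sprintf("p%04d", seq_along(classes)), class = classes
  )
}

test_that("SD vs NSD comparison detects a real group difference", {
  withr::local_seed(71)
  n <- 400
  sd_flag <- runif(n) < 0.5
  tr <- 1.5 - 0.8 * sd_flag + rnorm(n)
  res <- compare_sd_nsd(
    make_comparisons(tr),
    make_structures(ifelse(sd_flag, "class1", "identical"))
  )
  g <- res$groups
  expect_lt(
    g$mean_transformed_r[g$group == "SD"],
    g$mean_transformed_r[g$group == "NSD"]
  )
  expect_lt(res$tests$p_value[1], 0.05)
})

test_that("single-pair groups still yield an exact test result", {
  res <- compare_sd_nsd(
    make_comparisons(c(1.2, -0.4)),
    make_structures(c("identical", "class2"))
  )
  expect_false(is.na(res$tests$statistic[1]))
  expect_equal(res$tests$p_value[1], 1) # exact p for n = 1 vs 1
})

test_that("empty contrasts are skipped with a warning", {
  expect_warning(
    res <- compare_sd_nsd(
      make_comparisons(c(1, 2, 3)),
      make_structures(c("class1", "class1", "class2"))
    ),
    "empty group"
  )
  expect_true(is.na(res$tests$p_value[1]))
})

test_that("rank-sum p agrees with a brute-force permutation oracle on 4 vs 4", {
  x <- c(1.3, 2.1, 0.4, 3.3)
  y <- c(0.1, 0.2, 0.9, 0.5)
  res <- compare_sd_nsd(
    make_comparisons(c(x, y)),
    make_structures(rep(c("class1", "identical"), each = 4))
  )
  # enumerate all assignments of the 8 values into the SD group
  vals <- c(x, y)
  w_obs <- sum(rank(vals)[1:4]) - 4 * 5 / 2 # Mann-Whitney U of the SD group
  combs <- utils::combn(8, 4)
  w_all <- apply(combs, 2, function(idx) sum(rank(vals)[idx]) - 4 * 5 / 2)
  p_exact <- mean(abs(w_all - 8) >= abs(w_obs - 8)) # center U at n1 n2 / 2
  expect_equal(res$tests$statistic[1], w_obs)
  expect_equal(res$tests$p_value[1], p_exact)
})

test_that("ANCOVA recovers an injected class effect and rejects a null one", {
  withr::local_seed(72)
  n <- 1000
  ds <- runif(n, 0.05, 1.5)
  sd_flag <- runif(n) < plogis(2 * (ds - 0.5))
  classes <- ifelse(sd_flag, "class1", "identical")
  divergences <- tibble::tibble(pair_id = sprintf("p%04d", 1:n), dS = ds)

  # null: no class effect beyond the shared dS trend
  tr0 <- 2 - 1.5 * ds + rnorm(n, 0, 0.8)
  fit0 <- ancova_structure_expression(
    make_comparisons(tr0), make_structures(classes), divergences
  )
  expect_lt(abs(fit0$structure_effect), 3 * fit0$structure_se)

  # injected -0.5 additive class effect
  tr1 <- tr0 - 0.5 * sd_flag
  fit1 <- ancova_structure_expression(
    make_comparisons(tr1), make_structures(classes), divergences
  )
  expect_lt(abs(fit1$structure_effect - (-0.5)), 3 * fit1$structure_se)
  expect_lt(fit1$structure_p, 0.05)
  expect_equal(fit1$n_sd + fit1$n_nsd, n)

  # tidy/glance surface the same numbers
  td <- tidy(fit1)
  expect_equal(td$estimate[td$term == "sdTRUE"], fit1$structure_effect)
  expect_equal(glance(fit1)$n, n)
})

test_that("per-class regression lines equal the closed-form OLS solution", {
  ds <- c(0.1, 0.3, 0.5, 0.9, 0.2, 0.4, 0.8, 1.2)
  tr <- c(2.0, 1.5, 1.2, 0.6, 1.1, 0.9, 0.4, 0.1)
  classes <- rep(c("identical", "class2"), each = 4)
  fit <- ancova_structure_expression(
    make_comparisons(tr), make_structures(classes),
    tibble::tibble(pair_id = sprintf("p%04d", 1:8), dS = ds)
  )
  for (k in 1:2) {
    idx <- if (k == 1) 1:4 else 5:8
    x <- ds[idx]
    y <- tr[idx]
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    row <- fit$per_class[fit$per_class$class == c("NSD", "SD")[k], ]
    expect_equal(row$slope, slope, tolerance = 1e-12)
    expect_equal(row$intercept, intercept, tolerance = 1e-12)
  }
})

test_that("a one-class design is a rank-deficiency error", {
  expect_error(
    ancova_structure_expression(
      make_comparisons(rnorm(10)),
      make_structures(rep("class1", 10)),
      tibble::tibble(pair_id = sprintf("p%04d", 1:10), dS = runif(10))
    ),
    "one structural class"
  )
})

test_that("identity distributions: identical groups give KS statistic 0", {
  pairs <- tibble::tibble(
    gene_a = sprintf("a%d", 1:8), gene_b = sprintf("b%d", 1:8),
    identity = rep(c(0.4, 0.6, 0.8, 0.9), 2),
    locality = rep(c("intra", "inter"), each = 4),
    lineage = rep(c("species_specific", "shared"), 4)
  )
  res <- identity_distribution_tests(pairs)
  loc_ks <- res$tests[res$tests$contrast == "intra vs inter" &
    res$tests$test == "ks", ]
  expect_equal(loc_ks$statistic, 0)
  expect_equal(sum(res$histogram$n[res$histogram$group == "all"]), 8)
  expect_error(
    identity_distribution_tests(pairs[pairs$lineage == "shared", ]),
    "at least 2"
  )
})

test_that("a right-shifted species-specific identity distribution is detected", {
  withr::local_seed(73)
  n <- 500
  ss <- runif(n) < 0.3
  pairs <- tibble::tibble(
    gene_a = sprintf("a%d", 1:n), gene_b = sprintf("b%d", 1:n),
    identity = ifelse(ss, runif(n, 0.7, 1), runif(n, 0.3, 0.9)),
    locality = sample(c("intra", "inter"), n, replace = TRUE),
    lineage = ifelse(ss, "species_specific", "shared")
  )
  res <- identity_distribution_tests(pairs)
  lin <- res$tests[res$tests$contrast == "species_specific vs shared", ]
  expect_true(all(lin$p_value < 0.05))
})

test_that("chromosome heterogeneity is quiet under the null and flags enrichment", {
  uniform <- tibble::tibble(
    chromosome = sprintf("c%d", 1:10),
    n_genes = rep(1000L, 10),
    n_dup_intra = rep(100L, 10), n_dup_inter = rep(150L, 10),
    n_ss_intra = rep(20L, 10), n_ss_inter = rep(30L, 10)
  )
  s <- chromosome_summary_from_counts(uniform)
  res <- chromosome_distribution_test(s)
  expect_gt(res$heterogeneity$p_value, 0.05)
  expect_equal(res$enriched_2fold, character(0))

  # published bovine counts: heterogeneity is significant; the only
  # chromosome above twice the genome-average content is 15, and only for
  # the species-specific subset
  sb <- chromosome_summary_from_counts(bovine_chromosome_counts())
  resb <- chromosome_distribution_test(sb)
  expect_lt(resb$heterogeneity$p_value, 0.05)
  expect_equal(resb$enriched_2fold, character(0))
  expect_equal(resb$ss_enriched_2fold, "15")
  # chromosomes with intrachromosomal excess include 15, 29 and X
  signif_intra <- resb$binomial$chromosome[
    resb$binomial$p_value < 0.05 &
      resb$binomial$n_intra / resb$binomial$n_total >
        resb$binomial$p_genome_intra
  ]
  expect_true(all(c("15", "29", "X") %in% signif_intra))
})

test_that("a single chromosome skips the heterogeneity test with a message", {
  one <- tibble::tibble(
    chromosome = "c1", n_genes = 100L,
    n_dup_intra = 10L, n_dup_inter = 5L, n_ss_intra = 2L, n_ss_inter = 1L
  )
  expect_message(
    res <- chromosome_distribution_test(chromosome_summary_from_counts(one)),
    "skipped"
  )
  expect_null(res$heterogeneity)
  expect_equal(nrow(res$binomial), 1L)
})

test_that("results are invariant to pair order and within-pair relabeling", {
  withr::local_seed(74)
  n <- 60
  tr <- rnorm(n)
  classes <- sample(c("identical", "class1", "class2"), n, replace = TRUE)
  ds <- runif(n)
  cmp <- make_comparisons(tr)
  st <- make_structures(classes)
  dv <- tibble::tibble(pair_id = cmp$pair_id, dS = ds)
  perm <- sample(n)
  f1 <- ancova_structure_expression(cmp, st, dv)
  f2 <- ancova_structure_expression(cmp[perm, ], st[sample(n), ], dv[sample(n), ])
  expect_equal(f1$structure_effect, f2$structure_effect, tolerance = 1e-12)
  r1 <- compare_sd_nsd(cmp, st)
  r2 <- compare_sd_nsd(cmp[perm, ], st)
  expect_equal(r1$tests$p_value, r2$tests$p_value)
})
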