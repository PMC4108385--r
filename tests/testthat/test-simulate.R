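test_that("zero divergence time yields identical copies and zero divergence", {
  withr::local_seed(31)
  p <- simulate_cds_pair(60, 0, 0.3)
  expect_identical(p$cds_a, p$cds_b)
  expect_identical(p$cds_a, p$ancestor)
  expect_equal(p$true_dS, 0)
  expect_equal(p$true_dN, 0)

  s <- simulate_structure_pair(5, 0, 3)
  expect_identical(s$lengths_a, s$lengths_b)
  expect_equal(s$true_class, "identical")
})

test_that("omega = 0 forbids nonsynonymous substitutions", {
  withr::local_seed(32)
  p <- simulate_cds_pair(100, 0.4, 0)
  expect_equal(p$n_nonsyn_events, 0)
  expect_identical(translate_cds(p$cds_a), translate_cds(p$ancestor))
  expect_identical(translate_cds(p$cds_b), translate_cds(p$ancestor))
  expect_gt(p$n_syn_events, 0)
})

test_that("the event log replays exactly under an independent oracle", {
  withr::local_seed(33)
  p <- simulate_cds_pair(300, 0.2, 0.3)
  ra <- oracle_replay_cds(p$ancestor, p$events, "a")
  rb <- oracle_replay_cds(p$ancestor, p$events, "b")
  expect_identical(ra$cds, p$cds_a)
  expect_identical(rb$cds, p$cds_b)
  expect_equal(ra$n_syn + rb$n_syn, p$n_syn_events)
  expect_equal(ra$n_nonsyn + rb$n_nonsyn, p$n_nonsyn_events)
})

test_that("very large t warns about falling below the detection threshold", {
  withr::local_seed(34)
  expect_warning(simulate_cds_pair(60, 6, 0.8), "20%")
})

test_that("structure-event counts follow the Poisson closed form", {
  withr::local_seed(35)
  # rate * t = 2: fraction of pairs with at least one event ~ 1 - exp(-2)
  hits <- replicate(1000, {
    s <- simulate_structure_pair(4, 1, 2)
    nrow(s$events) >= 1
  })
  p_expected <- 1 - exp(-2)
  se <- sqrt(p_expected * (1 - p_expected) / 1000)
  expect_lt(abs(mean(hits) - p_expected), 3 * se)
})

test_that("a single boundary shift is Class 2 by construction", {
  withr::local_seed(36)
  found <- FALSE
  for (i in 1:200) {
    s <- simulate_structure_pair(4, 0.2, 3)
    if (nrow(s$events) == 1 && s$events$type == "shift") {
      found <- TRUE
      expect_equal(length(s$lengths_a), length(s$lengths_b))
      expect_equal(sum(s$lengths_a != s$lengths_b), 1L)
      expect_equal(s$true_class, "class2")
      break
    }
  }
  expect_true(found)
})

test_that("net exon gain/loss is Class 1; exon lengths stay frame-multiples", {
  withr::local_seed(37)
  for (i in 1:50) {
    s <- simulate_structure_pair(4, 1, 3)
    if (s$net_exon_change != 0) expect_equal(s$true_class, "class1")
    expect_true(all(s$lengths_a %% 3 == 0))
    expect_true(all(s$lengths_b %% 3 == 0))
  }
})

test_that("expression correlation at t = 0 is limited only by the noise floor", {
  withr::local_seed(38)
  e <- simulate_expression_pair(
    0, 1,
    n_tissues = 10000, noise_sd = 0.25, silencing_max = 0
  )
  r <- cor(log2(e$fpkm_a + 1), log2(e$fpkm_b + 1))
  # attenuation of the latent rho = 1 by independent noise
  sd_sig <- 2
  rho_att <- sd_sig^2 / (sd_sig^2 + 0.25^2)
  se_z <- 1 / sqrt(10000 - 3)
  expect_lt(abs(atanh(r) - atanh(rho_att)), 3 * se_z + 0.05)
  expect_gt(r, 0.95)
})

test_that("expression correlation decays towards zero as lambda t grows", {
  withr::local_seed(39)
  e <- simulate_expression_pair(50, 1, n_tissues = 5000, silencing_max = 0)
  expect_equal(e$rho, exp(-50))
  r <- cor(log2(e$fpkm_a + 1), log2(e$fpkm_b + 1))
  expect_lt(abs(r), 3 / sqrt(5000 - 3))
})

test_that("population-level monotonicity: dS up, correlation down, divergence up with t", {
  withr::local_seed(40)
  ts <- c(0.1, 0.5, 1.2)
  stats <- vapply(ts, function(t) {
    ds <- mean(replicate(30, simulate_cds_pair(60, t, 0.3)$true_dS))
    rr <- mean(replicate(30, {
      e <- simulate_expression_pair(t, 1, n_tissues = 7, silencing_max = 0)
      cor(log2(e$fpkm_a + 1), log2(e$fpkm_b + 1))
    }))
    div <- mean(replicate(
      30, simulate_structure_pair(4, t, 3)$true_class != "identical"
    ))
    c(ds, rr, div)
  }, numeric(3))
  expect_true(all(diff(stats[1, ]) > 0))
  expect_true(all(diff(stats[2, ]) < 0))
  expect_true(all(diff(stats[3, ]) > 0))
})

test_that("bundles are deterministic under a fixed seed, byte for byte", {
  cfg <- simulation_config(seed = 99L, n_pairs = 5L, n_decoys = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture(cfg, d1)
  p2 <- make_fixture(cfg, d2)
  for (f in names(p1)) {
    expect_identical(
      readLines(p1[[f]]), readLines(p2[[f]]),
      info = f
    )
  }
})

test_that("intra_fraction = 1 places every truth pair on one chromosome", {
  b <- simulate_study(simulation_config(
    seed = 5L, n_pairs = 10L, intra_fraction = 1, n_decoys = 0L
  ))
  expect_true(all(b$truth$locality == "intra"))
  chrom <- setNames(b$gene_models$chromosome, b$gene_models$gene_id)
  expect_true(all(chrom[b$truth$gene_a] == chrom[b$truth$gene_b]))
})

test_that("the pipeline recovers recent duplicates from a simulated bundle", {
  bundle <- small_bundle()
  pairs <- identify_duplicates(
    bundle$hits, bundle$proteins, bundle$gene_models
  )
  found <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  recent <- bundle$truth$pair_id[bundle$truth$t <= 0.3]
  expect_gte(mean(recent %in% found), 0.95)
  # locality recorded in truth agrees with classification
  m <- match(found, bundle$truth$pair_id)
  expect_equal(pairs$locality[!is.na(m)], bundle$truth$locality[m[!is.na(m)]])
})
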