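# Self-contained simulation experiments used to validate the estimators and
# the statistical layer: dS parameter recovery, and Type-I-error calibration
# of the group-comparison, binned-regression and ANCOVA tests under their
# null.

#' dS parameter-recovery experiment
#'
#' Simulates duplicate CDS pairs across a grid of divergence times, runs the
#' full estimation path (protein alignment, codon projection, NG86 counting),
#' and regresses the estimated dS on the realized per-site synonymous
#' divergence of each pair. An unbiased estimator gives a slope near 1.
#'
#' @param n_pairs Number of simulated pairs.
#' @param t_min,t_max Range of divergence times, spanned evenly.
#' @param omega dN/dS acceptance ratio of the simulation.
#' @param length_codons CDS length in codons.
#' @return A list: `data` (tibble with `t`, `true_dS`, `est_dS`), `slope`,
#'   `intercept` (OLS of estimated on true dS), `n`.
#' @export
ds_parameter_recovery <- function(n_pairs = 200L, t_min = 0.05, t_max = 0.5,
                                  omega = 0.3, length_codons = 200L) {
  ts <- seq(t_min, t_max, length.out = n_pairs)
  rows <- purrr::map_dfr(ts, function(t) {
    sim <- simulate_cds_pair(length_codons, t, omega)
    prot_a <- translate_cds(sim$cds_a)
    prot_b <- translate_cds(sim$cds_b)
    aln <- align_proteins_global(prot_a, prot_b)
    est <- estimate_dn_ds(project_to_codons(aln, sim$cds_a, sim$cds_b))
    tibble(t = t, true_dS = sim$true_dS, est_dS = est$dS)
  })
  keep <- rows[!is.na(rows$est_dS), ]
  fit <- lm(est_dS ~ true_dS, data = keep)
  list(
    data = rows,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n = nrow(keep)
  )
}

#' Type-I-error calibration of the statistical layer
#'
#' Simulates replicates under the null of no structure-expression coupling
#' (no expression decay, no class effect on expression: `lambda = 0`,
#' transformed-r shift 0) while keeping structure events tied to divergence
#' time, and records the rejection rate at level `alpha` of (i) the SD vs NSD
#' rank-sum comparison, (ii) the binned regression slope of transformed r on
#' divergence, and (iii) the ANCOVA structure coefficient. Divergence times
#' themselves serve as the dS covariate: the calibration targets the
#' statistical layer, and estimation noise is orthogonal to this null.
#' Rejection rates of a well-calibrated test fall within the central 99%
#' binomial range around `alpha`.
#'
#' @param n_replicates Null replicates (default 200).
#' @param n_pairs Pairs per replicate (default 200).
#' @param alpha Nominal level (default 0.05).
#' @param bin_size Bin size of the regression under test.
#' @return A list: `rates` (named rejection rates), `bounds` (99% binomial
#'   acceptance interval for the rate), `n_replicates`.
#' @export
calibrate_null_rejection <- function(n_replicates = 200L, n_pairs = 200L,
                                     alpha = 0.05, bin_size = 5L) {
  reject <- matrix(NA, n_replicates, 3,
    dimnames = list(NULL, c("wilcoxon", "slope", "ancova"))
  )
  tissues <- sprintf("t%d", 1:7)
  for (rep in seq_len(n_replicates)) {
    t <- runif(n_pairs, 0.05, 1.5)
    classes <- character(n_pairs)
    fpkm <- matrix(0, 2 * n_pairs, 7)
    for (i in seq_len(n_pairs)) {
      st <- simulate_structure_pair(4L, t[i], 3)
      classes[i] <- st$true_class
      # silencing must be off too: its probability grows with t, which would
      # couple expression to divergence time and break the null
      e <- simulate_expression_pair(t[i], 0, 7L,
        silencing_max = 0, fisher_shift = 0
      )
      fpkm[2 * i - 1, ] <- e$fpkm_a
      fpkm[2 * i, ] <- e$fpkm_b
    }
    ids_a <- sprintf("g%04da", seq_len(n_pairs))
    ids_b <- sprintf("g%04db", seq_len(n_pairs))
    mat <- dplyr::bind_cols(
      tibble(gene_id = as.vector(rbind(ids_a, ids_b))),
      as_tibble(setNames(as.data.frame(fpkm), tissues))
    )
    pairs <- tibble(gene_a = ids_a, gene_b = ids_b)
    cmp <- expression_comparison_table(pairs, mat)
    structures <- tibble(pair_id = cmp$pair_id, class = classes)
    divergences <- tibble(pair_id = cmp$pair_id, dS = t)

    gc_res <- suppressWarnings(compare_sd_nsd(cmp, structures))
    reject[rep, "wilcoxon"] <- isTRUE(gc_res$tests$p_value[1] < alpha)
    reg <- tryCatch(
      expression_vs_divergence_regression(cmp, divergences,
        covariate = "dS", bin_size = bin_size
      ),
      error = function(e) NULL
    )
    reject[rep, "slope"] <- isTRUE(!is.null(reg) && reg$p_value[1] < alpha)
    anc <- tryCatch(
      ancova_structure_expression(cmp, structures, divergences),
      error = function(e) NULL
    )
    reject[rep, "ancova"] <- isTRUE(!is.null(anc) && anc$structure_p < alpha)
  }
  bounds <- stats::qbinom(c(0.005, 0.995), n_replicates, alpha) / n_replicates
  list(
    rates = colMeans(reject),
    bounds = bounds,
    n_replicates = n_replicates
  )
}
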