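# Expression divergence between duplicate genes: per-tissue on/off divergence
# calls on raw FPKM, Pearson correlation of log-transformed expression across
# tissues, and the variance-stabilizing transform ln((1+r)/(1-r)) used as the
# expression-similarity scale in the regression analyses.
#
# On/off calls: a gene is off in a tissue below 1 FPKM and on above 2 FPKM;
# the gap 1 <= FPKM <= 2 is ambiguous and never counts as divergence. A tissue
# is divergent for a pair iff one gene is on and the other off there.

FPKM_OFF <- 1
FPKM_ON <- 2
R_CLAMP_EPS <- 1e-6

#' Log-transform an FPKM matrix
#'
#' Elementwise `log2(FPKM + offset)`; with the default offset of 1 an FPKM of
#' zero maps to zero.
#'
#' @param mat Expression tibble from [read_expression_matrix()].
#' @param offset Positive offset added before the log.
#' @return The tibble with all tissue columns transformed.
#' @export
log_transform <- function(mat, offset = 1.0) {
  stopifnot(offset > 0)
  vals <- as.matrix(mat[, -1])
  if (any(vals < 0)) abort("negative expression values")
  dplyr::mutate(mat, dplyr::across(-"gene_id", ~ log2(.x + offset)))
}

#' Transform a correlation to the expression-similarity scale
#'
#' `ln((1 + r)/(1 - r))`, with `r` clamped to `[-1 + eps, 1 - eps]` so the
#' transform stays finite at `|r| = 1`. Strictly increasing and antisymmetric.
#'
#' @param r Pearson correlation(s).
#' @param eps Clamping margin (default `1e-6`).
#' @return Transformed value(s).
#' @export
transform_r <- function(r, eps = R_CLAMP_EPS) {
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  log((1 + r) / (1 - r))
}

expression_state <- function(fpkm) {
  ifelse(fpkm < FPKM_OFF, "off", ifelse(fpkm > FPKM_ON, "on", "ambiguous"))
}

#' Compare the expression profiles of one duplicate pair
#'
#' On/off states are called on raw FPKM; the Pearson correlation is computed
#' across tissues on `log2(FPKM + offset)` values (set `log_scale = FALSE` for
#' raw-scale correlation). `r` is undefined when either gene has zero variance
#' across tissues. A pair is `eligible` for the correlation analyses iff both
#' genes are on (FPKM > 2) in at least `min_tissues_expressed` tissue(s) each.
#'
#' @param gene_a,gene_b Gene ids; both must be present in `mat`.
#' @param mat Expression tibble from [read_expression_matrix()].
#' @param offset Log offset.
#' @param log_scale Correlate log-transformed (default) or raw values.
#' @param min_tissues_expressed Minimum on-tissues per gene for eligibility.
#' @return One-row tibble: `pair_id`, `gene_a`, `gene_b`, `states` (list of
#'   per-tissue state pairs), `n_divergent_tissues`, `divergent_tissues`
#'   (list), `r`, `transformed_r`, `eligible`.
#' @export
compare_pair_expression <- function(gene_a, gene_b, mat, offset = 1.0,
                                    log_scale = TRUE,
                                    min_tissues_expressed = 1L) {
  missing <- setdiff(c(gene_a, gene_b), mat$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) missing from expression matrix: %s",
      paste(missing, collapse = ", ")
    ))
  }
  tissues <- names(mat)[-1]
  fa <- as.numeric(mat[match(gene_a, mat$gene_id), -1])
  fb <- as.numeric(mat[match(gene_b, mat$gene_id), -1])
  compare_expression_core(
    gene_a, gene_b, fa, fb, tissues, offset, log_scale, min_tissues_expressed
  )
}

compare_expression_core <- function(gene_a, gene_b, fa, fb, tissues, offset,
                                    log_scale, min_tissues_expressed) {
  sa <- expression_state(fa)
  sb <- expression_state(fb)
  divergent <- (sa == "on" & sb == "off") | (sa == "off" & sb == "on")
  va <- if (log_scale) log2(fa + offset) else fa
  vb <- if (log_scale) log2(fb + offset) else fb
  r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else cor(va, vb)
  tibble::new_tibble(
    list(
      pair_id = paste(gene_a, gene_b, sep = "|"),
      gene_a = gene_a, gene_b = gene_b,
      states = list(tibble::new_tibble(
        list(tissue = tissues, state_a = sa, state_b = sb),
        nrow = length(tissues)
      )),
      n_divergent_tissues = sum(divergent),
      divergent_tissues = list(tissues[divergent]),
      r = r,
      transformed_r = if (is.na(r)) NA_real_ else transform_r(r),
      eligible = sum(sa == "on") >= min_tissues_expressed &&
        sum(sb == "on") >= min_tissues_expressed
    ),
    nrow = 1L
  )
}

#' Expression comparison for a table of pairs
#'
#' @param pairs Pair tibble with `gene_a`, `gene_b`.
#' @param mat Expression tibble.
#' @inheritParams compare_pair_expression
#' @return One row per pair, as [compare_pair_expression()].
#' @export
expression_comparison_table <- function(pairs, mat, offset = 1.0,
                                        log_scale = TRUE,
                                        min_tissues_expressed = 1L) {
  missing <- setdiff(
    unique(c(pairs$gene_a, pairs$gene_b)), mat$gene_id
  )
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) missing from expression matrix: %s",
      paste(missing, collapse = ", ")
    ))
  }
  tissues <- names(mat)[-1]
  vals <- as.matrix(mat[, -1])
  rownames(vals) <- mat$gene_id
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    compare_expression_core(
      pairs$gene_a[i], pairs$gene_b[i],
      vals[pairs$gene_a[i], ], vals[pairs$gene_b[i], ],
      tissues, offset, log_scale, min_tissues_expressed
    )
  })
}

#' Summarize on/off expression divergence across pairs
#'
#' Per-tissue divergent fractions and the fractions of pairs divergent in at
#' least one and at least two tissues, over all compared pairs and, when a
#' classified pair table is supplied, stratified by lineage class.
#'
#' @param comparisons Output of [expression_comparison_table()].
#' @param pairs Optional classified pairs (from [classify_pairs()]) providing
#'   the `lineage` column for stratification.
#' @return A `dd_expression_summary` list: `per_tissue` (tibble with
#'   `stratum`, `tissue`, `n_pairs`, `frac_divergent`) and `overall` (tibble
#'   with `stratum`, `n_pairs`, `frac_ge1`, `frac_ge2`).
#' @export
divergence_summary <- function(comparisons, pairs = NULL) {
  strata <- list(all = comparisons)
  if (!is.null(pairs) && "lineage" %in% names(pairs)) {
    ss_ids <- paste(pairs$gene_a, pairs$gene_b, sep = "|")[
      pairs$lineage == "species_specific"
    ]
    strata$species_specific <- comparisons[comparisons$pair_id %in% ss_ids, ]
  }
  per_tissue <- purrr::imap_dfr(strata, function(cmp, label) {
    if (nrow(cmp) == 0L) {
      return(tibble(
        stratum = character(), tissue = character(),
        n_pairs = integer(), frac_divergent = numeric()
      ))
    }
    tidyr::unnest(cmp[, c("pair_id", "states")], "states") |>
      dplyr::group_by(.data$tissue) |>
      dplyr::summarise(
        n_pairs = dplyr::n(),
        frac_divergent = mean(
          (.data$state_a == "on" & .data$state_b == "off") |
            (.data$state_a == "off" & .data$state_b == "on")
        ),
        .groups = "drop"
      ) |>
      dplyr::mutate(stratum = label, .before = 1)
  })
  overall <- purrr::imap_dfr(strata, function(cmp, label) {
    tibble(
      stratum = label,
      n_pairs = nrow(cmp),
      frac_ge1 = mean(cmp$n_divergent_tissues >= 1L),
      frac_ge2 = mean(cmp$n_divergent_tissues >= 2L)
    )
  })
  structure(
    list(per_tissue = per_tissue, overall = overall),
    class = "dd_expression_summary"
  )
}

#' @export
print.dd_expression_summary <- function(x, ...) {
  cat("On/off expression divergence\n")
  print(x$overall)
  invisible(x)
}

#' Binned regression of expression similarity on sequence divergence
#'
#' Eligible pairs with a defined correlation and an unsaturated covariate are
#' ranked by the covariate (dS or dN), grouped into consecutive bins of
#' `bin_size` (trailing partial bin dropped), and the bin means of the
#' covariate and of transformed r are related by ordinary least squares. With
#' `bin_size = 1` this reduces exactly to the unbinned regression. For the dN
#' covariate the regression is run separately below and above `dn_split`.
#'
#' @param comparisons Output of [expression_comparison_table()].
#' @param divergences Output of [divergence_table()].
#' @param covariate `"dS"` or `"dN"`.
#' @param dn_split Split point for the dN strata (default 0.3).
#' @param bin_size Pairs per bin (default 5).
#' @return A `dd_binned_regression`: tibble with one row per stratum
#'   (`stratum`, `n_pairs`, `n_bins`, `slope`, `intercept`, `r`, `p_value`)
#'   and the per-stratum bin tables in attribute `bins`.
#' @export
expression_vs_divergence_regression <- function(comparisons, divergences,
                                                covariate = c("dS", "dN"),
                                                dn_split = 0.3,
                                                bin_size = 5L) {
  covariate <- match.arg(covariate)
  df <- dplyr::inner_join(
    comparisons[, c("pair_id", "transformed_r", "eligible")],
    divergences[, c("pair_id", covariate)],
    by = "pair_id"
  ) |>
    dplyr::rename(x = dplyr::all_of(covariate)) |>
    dplyr::filter(.data$eligible, !is.na(.data$transformed_r), !is.na(.data$x))

  strata <- if (covariate == "dS") {
    list(all = df)
  } else {
    list(
      below_split = df[df$x <= dn_split, ],
      above_split = df[df$x > dn_split, ]
    )
  }

  bins_list <- list()
  res <- purrr::imap_dfr(strata, function(d, label) {
    n_bins <- nrow(d) %/% bin_size
    if (n_bins < 3L) {
      abort(sprintf(
        "stratum '%s': need at least 3 full bins of %d pairs (have %d pairs)",
        label, bin_size, nrow(d)
      ))
    }
    bins <- d |>
      dplyr::arrange(.data$x) |>
      dplyr::slice_head(n = n_bins * bin_size) |>
      dplyr::mutate(bin = rep(seq_len(n_bins), each = bin_size)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(
        mean_x = mean(.data$x),
        mean_transformed_r = mean(.data$transformed_r),
        .groups = "drop"
      )
    bins_list[[label]] <<- bins
    fit <- lm(mean_transformed_r ~ mean_x, data = bins)
    sm <- summary(fit)
    tibble(
      stratum = label,
      covariate = covariate,
      n_pairs = n_bins * bin_size,
      n_bins = n_bins,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r = unname(sign(coef(fit)[2]) * sqrt(sm$r.squared)),
      p_value = sm$coefficients[2, 4]
    )
  })
  structure(res,
    class = c("dd_binned_regression", class(res)),
    bins = bins_list, bin_size = bin_size
  )
}

#' Flag species-specific pairs with very high expression divergence
#'
#' Returns the eligible species-specific pairs whose Pearson correlation is
#' defined and below `r_max`, joined with their structural classification when
#' available.
#'
#' @param comparisons Output of [expression_comparison_table()].
#' @param pairs Classified pairs with a `lineage` column.
#' @param r_max Correlation ceiling.
#' @param structures Optional output of [compare_structures()].
#' @return Tibble of flagged pairs (`pair_id`, `r`, `transformed_r`, and
#'   `class` when structures are given).
#' @export
flag_high_divergence_pairs <- function(comparisons, pairs, r_max,
                                       structures = NULL) {
  ss_ids <- paste(pairs$gene_a, pairs$gene_b, sep = "|")[
    pairs$lineage == "species_specific"
  ]
  out <- comparisons |>
    dplyr::filter(
      .data$pair_id %in% ss_ids, .data$eligible,
      !is.na(.data$r), .data$r < r_max
    ) |>
    dplyr::select("pair_id", "gene_a", "gene_b", "r", "transformed_r")
  if (!is.null(structures)) {
    out <- dplyr::left_join(
      out, structures[, c("pair_id", "class")],
      by = "pair_id"
    )
  }
  out
}
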