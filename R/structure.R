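# Exon-intron structural divergence: Class 1 (different exon counts), Class 2
# (equal counts, at least one pair of positionally homologous exons with
# different lengths), and the binned relationship between the proportion of
# structurally divergent pairs and synonymous divergence.

#' Compare the exon-intron structure of two gene models
#'
#' Exon lengths are `end - start + 1`. When the exon counts are equal, exons
#' are paired positionally in transcription order (5' to 3', i.e. reversed
#' genomic order on the minus strand); any length inequality makes the pair
#' Class 2. Different exon counts make it Class 1.
#'
#' @param model_a,model_b One-row gene-model tibbles (as rows of
#'   [read_gene_models()] output).
#' @param pair_id Optional label.
#' @return One-row tibble: `pair_id`, `n_exons_a`, `n_exons_b`, `class`
#'   (`identical`, `class1`, `class2`), `differing_exons` (list-column of
#'   1-based transcription-order indices; empty unless Class 2).
#' @export
compare_structure <- function(model_a, model_b, pair_id = NA_character_) {
  len_tx <- function(m) {
    ex <- m$coding_exons[[1]]
    stopifnot(nrow(ex) >= 1L)
    lens <- ex$end - ex$start + 1L
    if (m$strand == "-") rev(lens) else lens
  }
  la <- len_tx(model_a)
  lb <- len_tx(model_b)
  if (length(la) != length(lb)) {
    cls <- "class1"
    diff_idx <- integer(0)
  } else {
    diff_idx <- which(la != lb)
    cls <- if (length(diff_idx) == 0L) "identical" else "class2"
  }
  tibble(
    pair_id = pair_id,
    n_exons_a = length(la), n_exons_b = length(lb),
    class = cls,
    differing_exons = list(diff_idx)
  )
}

#' Structural comparison for a table of pairs
#'
#' @param pairs Pair tibble with `gene_a`, `gene_b`.
#' @param gene_models Gene-model tibble containing every pair member.
#' @return One row per pair: [compare_structure()] columns plus `gene_a`,
#'   `gene_b`.
#' @export
compare_structures <- function(pairs, gene_models) {
  idx <- setNames(seq_len(nrow(gene_models)), gene_models$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(idx))
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) missing from gene models: %s", paste(missing, collapse = ", ")
    ))
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    cmp <- compare_structure(
      gene_models[idx[ga], ], gene_models[idx[gb], ],
      pair_id = paste(ga, gb, sep = "|")
    )
    dplyr::mutate(cmp, gene_a = ga, gene_b = gb, .after = "pair_id")
  })
}

#' Binned trend of structural divergence against synonymous divergence
#'
#' Pairs with a defined (unsaturated) dS are ranked by dS and grouped into
#' consecutive bins of `bin_size` (a trailing partial bin is dropped). Per bin
#' the mean dS and the proportion of pairs with class other than `identical`
#' are computed, and the Pearson correlation of the two across bins is tested
#' two-sided. If the proportions have zero variance across bins the
#' correlation is undefined and reported as `NA`.
#'
#' @param comparisons Output of [compare_structures()].
#' @param divergences Output of [divergence_table()].
#' @param bin_size Pairs per bin (default 200).
#' @return A `dd_binned_trend` list: `bins` (tibble with `bin`, `mean_dS`,
#'   `proportion_divergent`, `n`), `estimate` (Pearson r), `p_value`,
#'   `n_bins`, `n_pairs`.
#' @export
structure_vs_ds_trend <- function(comparisons, divergences, bin_size = 200L) {
  df <- dplyr::inner_join(
    comparisons[, c("pair_id", "class")],
    divergences[, c("pair_id", "dS")],
    by = "pair_id"
  ) |>
    dplyr::filter(!is.na(.data$dS))
  n_bins <- nrow(df) %/% bin_size
  if (n_bins < 2L) {
    abort(sprintf(
      "need at least 2 full bins of %d pairs; only %d usable pairs",
      bin_size, nrow(df)
    ))
  }
  bins <- df |>
    dplyr::arrange(.data$dS) |>
    dplyr::slice_head(n = n_bins * bin_size) |>
    dplyr::mutate(bin = rep(seq_len(n_bins), each = bin_size)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_dS = mean(.data$dS),
      proportion_divergent = mean(.data$class != "identical"),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (stats::sd(bins$proportion_divergent) == 0 || stats::sd(bins$mean_dS) == 0) {
    inform("proportion divergent is constant across bins; correlation undefined")
    est <- NA_real_
    p <- NA_real_
  } else {
    ct <- cor.test(bins$mean_dS, bins$proportion_divergent, method = "pearson")
    est <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(
      bins = bins, estimate = est, p_value = p,
      n_bins = n_bins, n_pairs = n_bins * bin_size,
      response = "proportion_divergent"
    ),
    class = "dd_binned_trend"
  )
}

#' @export
print.dd_binned_trend <- function(x, ...) {
  cat(sprintf(
    "Binned trend (%d bins of %d pairs): Pearson r = %.3f, p = %.3g\n",
    x$n_bins, x$bins$n[1], x$estimate, x$p_value
  ))
  invisible(x)
}

#' Structural class proportions from raw counts
#'
#' Arithmetic helper mirroring how published class counts are summarized:
#' percentages of pairs with different exon counts (Class 1), equal counts but
#' differing exon lengths (Class 2), and any structural difference.
#'
#' @param n_class1,n_class2 Pair counts per class.
#' @param n_total Total pairs compared.
#' @return One-row tibble with `pct_class1`, `pct_class2`, `pct_divergent`.
#' @export
structure_class_proportions <- function(n_class1, n_class2, n_total) {
  stopifnot(n_total > 0, n_class1 + n_class2 <= n_total)
  tibble(
    n_class1 = n_class1, n_class2 = n_class2, n_total = n_total,
    pct_class1 = 100 * n_class1 / n_total,
    pct_class2 = 100 * n_class2 / n_total,
    pct_divergent = 100 * (n_class1 + n_class2) / n_total
  )
}
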