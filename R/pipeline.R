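# Config-driven orchestration: identify -> divergence -> structure ->
# expression -> stats, every stage's table written to disk as TSV/JSON so the
# pipeline is restartable and its intermediates inspectable, plus a
# reproducibility manifest (config hash, versions, seed).

#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold. Thresholds are validated
#' against their documented domains; the config round-trips through YAML.
#'
#' @param proteins,cds,gene_models,hits,expression Input paths (`hits` is an
#'   alignment table in the outfmt 6 dialect).
#' @param lineage Optional lineage-table path (required when the gene-model
#'   source carries no lineage flags, e.g. GFF3).
#' @param gene_model_format `"tsv"` or `"gff3"`.
#' @param out_dir Output directory.
#' @param min_coverage Minimum fraction of the longer protein aligned (0.8).
#' @param identity_constant,identity_long_cutoff,identity_n Identity-threshold
#'   parameters, see [identity_threshold()].
#' @param fpkm_on,fpkm_off On/off FPKM cutoffs (2 and 1).
#' @param log_offset Offset of the log2 transform (1.0).
#' @param structure_bin_size,expression_bin_size Bin sizes of the two binned
#'   analyses (200 and 5).
#' @param dn_split dN split point of the stratified regression (0.3).
#' @param r_max Correlation ceiling of the high-divergence flag (0).
#' @param min_tissues_expressed On-tissue minimum per gene for correlation
#'   eligibility (1).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `dd_pipeline_config` list.
#' @export
pipeline_config <- function(proteins, cds, gene_models, hits, expression,
                            lineage = NULL,
                            gene_model_format = c("tsv", "gff3"),
                            out_dir = "dupdiverge_out",
                            min_coverage = 0.8,
                            identity_constant = 0.30,
                            identity_long_cutoff = 150,
                            identity_n = 6,
                            fpkm_on = 2, fpkm_off = 1,
                            log_offset = 1.0,
                            structure_bin_size = 200L,
                            expression_bin_size = 5L,
                            dn_split = 0.3,
                            r_max = 0,
                            min_tissues_expressed = 1L,
                            seed = 1L) {
  cfg <- list(
    proteins = proteins, cds = cds, gene_models = gene_models,
    hits = hits, expression = expression, lineage = lineage,
    gene_model_format = match.arg(gene_model_format),
    out_dir = out_dir,
    min_coverage = min_coverage,
    identity_constant = identity_constant,
    identity_long_cutoff = identity_long_cutoff,
    identity_n = identity_n,
    fpkm_on = fpkm_on, fpkm_off = fpkm_off,
    log_offset = log_offset,
    structure_bin_size = as.integer(structure_bin_size),
    expression_bin_size = as.integer(expression_bin_size),
    dn_split = dn_split,
    r_max = r_max,
    min_tissues_expressed = as.integer(min_tissues_expressed),
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "dd_pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  check <- function(ok, what) {
    if (!ok) abort(sprintf("invalid pipeline config: %s", what))
  }
  check(cfg$min_coverage >= 0 && cfg$min_coverage <= 1, "min_coverage must be in [0, 1]")
  check(cfg$identity_constant >= 0 && cfg$identity_constant <= 1,
    "identity_constant must be in [0, 1]"
  )
  check(cfg$identity_long_cutoff > 0, "identity_long_cutoff must be positive")
  check(cfg$log_offset > 0, "log_offset must be positive")
  check(cfg$fpkm_off >= 0 && cfg$fpkm_on >= cfg$fpkm_off,
    "FPKM cutoffs must satisfy 0 <= off <= on"
  )
  check(cfg$structure_bin_size >= 1L, "structure_bin_size must be >= 1")
  check(cfg$expression_bin_size >= 1L, "expression_bin_size must be >= 1")
  check(cfg$min_tissues_expressed >= 1L, "min_tissues_expressed must be >= 1")
  invisible(cfg)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with the [pipeline_config()] fields.
#' @return A `dd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline config to YAML
#'
#' @param config A `dd_pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages run in order identify, divergence, structure, expression, stats;
#' every stage's table is written under `config$out_dir`, along with a
#' `stats.json` report and a `manifest.json` (config hash, package and R
#' versions, seed). Missing inputs abort before any stage runs; per-pair
#' estimation failures are isolated in the divergence table's `error` column.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dd_pipeline_config"))
  inputs <- c(
    config$proteins, config$cds, config$gene_models,
    config$hits, config$expression, config$lineage
  )
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L) {
    abort(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  proteins <- read_fasta(config$proteins, kind = "protein")
  cds <- read_fasta(config$cds, kind = "cds")
  models <- read_gene_models(config$gene_models, format = config$gene_model_format)
  if (!is.null(config$lineage)) {
    lin <- read_lineage_table(config$lineage)
    models$lineage_specific <- lin$lineage_specific[
      match(models$gene_id, lin$gene_id)
    ]
  }
  if (anyNA(models$lineage_specific)) {
    abort("gene models lack lineage flags; supply a lineage table")
  }
  hits <- read_alignment_table(config$hits)
  expr <- read_expression_matrix(config$expression)

  # identify
  pairs <- identify_duplicates(
    hits, proteins, models,
    min_coverage = config$min_coverage,
    constant = config$identity_constant,
    long_cutoff = config$identity_long_cutoff,
    n_param = config$identity_n
  )
  readr::write_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))
  summaries <- summarize_by_chromosome(pairs, models)
  readr::write_tsv(summaries, file.path(config$out_dir, "chromosome_summary.tsv"))

  # divergence
  divergences <- divergence_table(pairs, proteins, cds)
  readr::write_tsv(
    divergences[, c(
      "pair_id", "dS", "dN", "S_sites", "N_sites", "S_diffs", "N_diffs",
      "saturated", "error"
    )],
    file.path(config$out_dir, "divergence.tsv")
  )

  # structure
  structures <- compare_structures(pairs, models)
  readr::write_tsv(
    dplyr::mutate(structures,
      differing_exons = vapply(
        .data$differing_exons, paste, character(1), collapse = ";"
      )
    ),
    file.path(config$out_dir, "structure.tsv")
  )
  structure_trend <- tryCatch(
    structure_vs_ds_trend(structures, divergences, config$structure_bin_size),
    error = function(e) conditionMessage(e)
  )

  # expression
  comparisons <- expression_comparison_table(
    pairs, expr,
    offset = config$log_offset,
    min_tissues_expressed = config$min_tissues_expressed
  )
  readr::write_tsv(
    dplyr::select(comparisons, -"states", -"divergent_tissues"),
    file.path(config$out_dir, "expression.tsv")
  )
  expr_summary <- divergence_summary(comparisons, pairs)
  expr_regression <- tryCatch(
    expression_vs_divergence_regression(
      comparisons, divergences,
      covariate = "dS", bin_size = config$expression_bin_size
    ),
    error = function(e) conditionMessage(e)
  )
  flagged <- flag_high_divergence_pairs(
    comparisons, pairs, config$r_max,
    structures = structures
  )
  readr::write_tsv(flagged, file.path(config$out_dir, "high_divergence_pairs.tsv"))

  # stats
  group_comparison <- compare_sd_nsd(
    comparisons, structures, pairs,
    lineage_stratified = TRUE
  )
  ancova <- tryCatch(
    ancova_structure_expression(comparisons, structures, divergences),
    error = function(e) conditionMessage(e)
  )
  identity_tests <- tryCatch(
    identity_distribution_tests(pairs),
    error = function(e) conditionMessage(e)
  )
  chromosome_tests <- chromosome_distribution_test(summaries)

  report <- list(
    n_pairs = nrow(pairs),
    n_species_specific = sum(pairs$lineage == "species_specific"),
    n_intra = sum(pairs$locality == "intra"),
    n_inter = sum(pairs$locality == "inter"),
    structure_classes = as.list(table(structures$class)),
    structure_trend = if (is.character(structure_trend)) {
      structure_trend
    } else {
      list(r = structure_trend$estimate, p = structure_trend$p_value)
    },
    expression_summary = list(
      overall = expr_summary$overall,
      per_tissue = expr_summary$per_tissue
    ),
    expression_regression = if (is.character(expr_regression)) {
      expr_regression
    } else {
      as.data.frame(expr_regression)
    },
    n_high_divergence = nrow(flagged),
    group_comparison = list(
      groups = group_comparison$groups, tests = group_comparison$tests
    ),
    ancova = if (is.character(ancova)) {
      ancova
    } else {
      list(
        structure_effect = ancova$structure_effect,
        structure_se = ancova$structure_se,
        structure_p = ancova$structure_p,
        ds_effect = ancova$ds_effect,
        r_squared = ancova$r_squared
      )
    },
    identity_tests = if (is.character(identity_tests)) {
      identity_tests
    } else {
      identity_tests$tests
    },
    chromosome_tests = list(
      heterogeneity = chromosome_tests$heterogeneity,
      enriched_2fold = chromosome_tests$enriched_2fold,
      ss_enriched_2fold = chromosome_tests$ss_enriched_2fold
    )
  )
  jsonlite::write_json(
    report, file.path(config$out_dir, "stats.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )

  manifest <- list(
    package = "dupdiverge",
    package_version = as.character(utils::packageVersion("dupdiverge")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = unclass(config)
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    pairs = pairs, summaries = summaries, divergences = divergences,
    structures = structures, structure_trend = structure_trend,
    comparisons = comparisons, expression_summary = expr_summary,
    expression_regression = expr_regression, flagged = flagged,
    group_comparison = group_comparison, ancova = ancova,
    identity_tests = identity_tests, chromosome_tests = chromosome_tests
  ))
}
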