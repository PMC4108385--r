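# Synthetic-data generator: duplicated CDS pairs evolved under a minimal codon
# model with an omega acceptance factor, exon-intron structure evolution whose
# event count grows with divergence time, and seven-tissue FPKM profiles whose
# between-duplicate correlation decays with divergence time. The generator
# defines the regimes the downstream analyses are tested against; all shapes
# are exposed through `simulation_config()`.
#
# All functions draw from R's global RNG (Mersenne-Twister by default);
# `simulate_study()` fixes the stream with `withr::with_seed()` so a bundle is
# reproducible from its config alone.

#' Simulation configuration
#'
#' @param seed Integer RNG seed used by [simulate_study()].
#' @param n_pairs Number of duplicate gene pairs.
#' @param n_chromosomes Number of chromosomes genes are placed on.
#' @param intra_fraction Probability a pair is intrachromosomal.
#' @param branch_length_range Range of the pair divergence time `t`, in
#'   expected proposed substitutions per nucleotide site separating the two
#'   copies (both branches combined); realized synonymous divergence tracks
#'   `t` closely.
#' @param omega_range Range of the dN/dS acceptance ratio.
#' @param structure_event_rate Expected structure events per unit `t`.
#' @param expression_decay Rate `lambda` linking `t` to the expected
#'   between-copy correlation of latent log-expression, `rho = exp(-lambda t)`.
#' @param tissue_count Number of tissues in the expression matrix.
#' @param species_specific_t_max Pairs with `t` below this are labelled
#'   lineage-specific (recent duplicates not yet observed outside the focal
#'   species).
#' @param cds_length_codons Ancestral CDS length in codons.
#' @param exon_count_range Range of ancestral coding-exon counts.
#' @param noise_sd SD of independent per-gene, per-tissue measurement noise on
#'   the log2 scale (the noise floor that keeps sample correlations below 1).
#' @param expression_mean_log2,expression_sd_log2 Mean and SD of the latent
#'   log2 expression signal.
#' @param silencing_max,silencing_midpoint,silencing_scale Parameters of the
#'   logistic per-tissue silencing probability
#'   `silencing_max * plogis((t - midpoint)/scale)`; a silencing event forces
#'   one copy's FPKM below 1 in one tissue (on/off expression divergence).
#' @param structure_expression_shift Additive shift, on the transformed-r
#'   scale `ln((1+r)/(1-r))`, applied to the latent expression correlation of
#'   structurally divergent pairs; the class effect the covariance analysis is
#'   expected to recover.
#' @param n_decoys Number of unrelated singleton genes added to the bundle
#'   (default: 10% of `n_pairs`).
#' @param pseudogene_fraction Fraction of decoy genes annotated as pseudogenes.
#' @return A validated `dd_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_pairs = 200L,
                              n_chromosomes = 30L,
                              intra_fraction = 0.31,
                              branch_length_range = c(0.05, 1.5),
                              omega_range = c(0.05, 0.8),
                              structure_event_rate = 3,
                              expression_decay = 1,
                              tissue_count = 7L,
                              species_specific_t_max = 0.35,
                              cds_length_codons = 200L,
                              exon_count_range = c(2L, 12L),
                              noise_sd = 0.25,
                              expression_mean_log2 = 3,
                              expression_sd_log2 = 2,
                              silencing_max = 0.3,
                              silencing_midpoint = 0.5,
                              silencing_scale = 0.25,
                              structure_expression_shift = -0.5,
                              n_decoys = NULL,
                              pseudogene_fraction = 0) {
  cfg <- list(
    seed = as.integer(seed), n_pairs = as.integer(n_pairs),
    n_chromosomes = as.integer(n_chromosomes),
    intra_fraction = intra_fraction,
    branch_length_range = branch_length_range,
    omega_range = omega_range,
    structure_event_rate = structure_event_rate,
    expression_decay = expression_decay,
    tissue_count = as.integer(tissue_count),
    species_specific_t_max = species_specific_t_max,
    cds_length_codons = as.integer(cds_length_codons),
    exon_count_range = as.integer(exon_count_range),
    noise_sd = noise_sd,
    expression_mean_log2 = expression_mean_log2,
    expression_sd_log2 = expression_sd_log2,
    silencing_max = silencing_max,
    silencing_midpoint = silencing_midpoint,
    silencing_scale = silencing_scale,
    structure_expression_shift = structure_expression_shift,
    n_decoys = as.integer(n_decoys %||% ceiling(0.1 * n_pairs)),
    pseudogene_fraction = pseudogene_fraction
  )
  stopifnot(
    cfg$n_pairs >= 1L, cfg$n_chromosomes >= 1L,
    cfg$intra_fraction >= 0, cfg$intra_fraction <= 1,
    length(cfg$branch_length_range) == 2L,
    cfg$branch_length_range[1] <= cfg$branch_length_range[2],
    all(cfg$branch_length_range >= 0),
    all(cfg$omega_range >= 0),
    cfg$structure_event_rate >= 0, cfg$expression_decay >= 0,
    cfg$tissue_count >= 2L, cfg$cds_length_codons >= 50L,
    cfg$noise_sd >= 0, cfg$silencing_max >= 0, cfg$silencing_max <= 1,
    cfg$pseudogene_fraction >= 0, cfg$pseudogene_fraction <= 1
  )
  structure(cfg, class = "dd_sim_config")
}

DEFAULT_TISSUES <- c(
  "adipose", "muscle", "hypothalamus", "duodenum", "liver", "lung", "kidney"
)

# nucleotide triple -> codon index in names(GENETIC_CODE) order (T,C,A,G nested)
nt_triple_to_codon <- function(n1, n2, n3) {
  16L * (n1 - 1L) + 4L * (n2 - 1L) + n3
}

random_sense_cds <- function(n_codons) {
  ct <- codon_tables()
  idx <- sample(ct$sense, n_codons, replace = TRUE)
  paste(ct$codons[idx], collapse = "")
}

#' Simulate one duplicated CDS pair under the omega-acceptance codon model
#'
#' An ancestral CDS of uniform sense codons is duplicated and each copy
#' accumulates proposed single-nucleotide changes (uniform over sites and
#' target nucleotides). A proposal is accepted with probability 1 if
#' synonymous and `omega` if nonsynonymous; proposals creating a stop codon
#' are always rejected. The realized per-site divergences are returned for
#' parameter-recovery tests: accepted synonymous (nonsynonymous) events
#' divided by the NG86 synonymous (nonsynonymous) site count of the ancestor.
#'
#' @param ancestral_length_codons CDS length in codons (>= 50).
#' @param t Expected proposed changes per nucleotide site separating the two
#'   copies; each copy draws `Poisson(3 L t / 2)` proposals.
#' @param omega Acceptance probability of nonsynonymous proposals.
#' @return A list: `cds_a`, `cds_b`, `true_dS`, `true_dN`, `n_syn_events`,
#'   `n_nonsyn_events`, `ancestor`, and an `events` tibble logging every
#'   proposal (copy, site, position, from/to nucleotide, type, accepted).
#' @export
simulate_cds_pair <- function(ancestral_length_codons, t, omega) {
  stopifnot(ancestral_length_codons >= 50L, t >= 0, omega >= 0)
  if (omega > 0 && exp(-2.16 * t * omega) < 0.2) {
    warn(sprintf(
      "t = %.3g is large: expected protein identity below 20%%; pairs may fall below the detection threshold",
      t
    ))
  }
  ct <- codon_tables()
  L <- ancestral_length_codons
  anc_idx <- sample(ct$sense, L, replace = TRUE)
  # vapply gives a 3 x L matrix (one column per codon); column-major
  # flattening yields the nucleotide sequence in codon order
  anc_nt <- as.integer(vapply(
    anc_idx, function(i) match(ct$nuc[i, ], NUCS), integer(3)
  ))

  aa_code <- match(ct$aa, unique(ct$aa))

  evolve <- function(copy_label) {
    n_prop <- rpois(1L, 3 * L * t / 2)
    res <- .evolve_cds_cpp(anc_nt, n_prop, omega, ct$is_stop, aa_code)
    list(
      nt = res$nt,
      events = tibble(
        copy = copy_label, site = res$site,
        from = NUCS[res$from], to = NUCS[res$to],
        type = c("stop", "synonymous", "nonsynonymous")[res$type + 1L],
        accepted = res$accepted
      )
    )
  }

  a <- evolve("a")
  b <- evolve("b")
  events <- dplyr::bind_rows(a$events, b$events)
  n_syn <- sum(events$accepted & events$type == "synonymous")
  n_nonsyn <- sum(events$accepted & events$type == "nonsynonymous")
  S_anc <- sum(ct$syn_sites[anc_idx])
  N_anc <- 3 * L - S_anc
  list(
    cds_a = paste(NUCS[a$nt], collapse = ""),
    cds_b = paste(NUCS[b$nt], collapse = ""),
    true_dS = n_syn / S_anc,
    true_dN = n_nonsyn / N_anc,
    n_syn_events = n_syn,
    n_nonsyn_events = n_nonsyn,
    ancestor = paste(NUCS[anc_nt], collapse = ""),
    events = events
  )
}

#' Simulate exon-intron structure evolution of a duplicate pair
#'
#' An ancestral coding-exon length layout is duplicated; `Poisson(rate * t)`
#' structure events are applied, each to one randomly chosen copy: exon gain,
#' exon loss (only if more than one exon remains), or a frame-preserving
#' boundary shift of a multiple of 3 nucleotides. Gene models are materialized
#' with random intron lengths at the requested genomic locations.
#'
#' @param base_exons Ancestral number of coding exons (>= 1).
#' @param t Divergence time of the pair.
#' @param rate Expected structure events per unit `t`.
#' @param gene_ids,chromosomes,strands,starts Length-2 vectors describing the
#'   two materialized gene models.
#' @return A list: `model_a`, `model_b` (one-row gene-model tibbles), `events`
#'   tibble, `lengths_a`, `lengths_b` (exon lengths in transcription order),
#'   `true_class` (`identical`, `class1`, `class2`), `net_exon_change`.
#' @export
simulate_structure_pair <- function(base_exons, t, rate,
                                    gene_ids = c("gene_a", "gene_b"),
                                    chromosomes = c("chr1", "chr1"),
                                    strands = c("+", "+"),
                                    starts = c(10000L, 2000000L)) {
  stopifnot(base_exons >= 1L, t >= 0, rate >= 0)
  exon_pool <- 3L * (20:150)
  anc <- sample(exon_pool, base_exons, replace = TRUE)
  lens <- list(a = anc, b = anc)

  n_events <- rpois(1L, rate * t)
  ev_copy <- character(n_events)
  ev_type <- character(n_events)
  ev_exon <- integer(n_events)
  ev_delta <- integer(n_events)
  for (e in seq_len(n_events)) {
    copy <- sample(c("a", "b"), 1L)
    cur <- lens[[copy]]
    types <- if (length(cur) > 1L) c("gain", "loss", "shift") else c("gain", "shift")
    type <- sample(types, 1L)
    if (type == "gain") {
      new_len <- sample(exon_pool, 1L)
      at <- sample.int(length(cur) + 1L, 1L)
      cur <- append(cur, new_len, after = at - 1L)
      delta <- new_len
    } else if (type == "loss") {
      at <- sample.int(length(cur), 1L)
      delta <- -cur[at]
      cur <- cur[-at]
    } else {
      at <- sample.int(length(cur), 1L)
      delta <- 3L * sample(1:10, 1L) * sample(c(-1L, 1L), 1L)
      if (cur[at] + delta < 3L) delta <- abs(delta)
      cur[at] <- cur[at] + delta
    }
    lens[[copy]] <- cur
    ev_copy[e] <- copy
    ev_type[e] <- type
    ev_exon[e] <- at
    ev_delta[e] <- delta
  }
  events <- tibble(copy = ev_copy, type = ev_type, exon = ev_exon, delta = ev_delta)

  materialize <- function(lengths, gene_id, chromosome, strand, start) {
    genomic <- if (strand == "-") rev(lengths) else lengths
    introns <- if (length(genomic) > 1L) {
      sample(200:2000, length(genomic) - 1L, replace = TRUE)
    } else {
      integer(0)
    }
    starts_v <- start + cumsum(c(0L, genomic[-length(genomic)] + introns))
    exons <- tibble::new_tibble(
      list(
        start = as.integer(starts_v),
        end = as.integer(starts_v + genomic - 1L)
      ),
      nrow = length(genomic)
    )
    tibble::new_tibble(
      list(
        gene_id = gene_id, chromosome = chromosome, strand = strand,
        biotype = "protein_coding", lineage_specific = NA,
        n_exons = length(genomic),
        coding_exons = list(exons)
      ),
      nrow = 1L
    )
  }

  la <- lens$a
  lb <- lens$b
  true_class <- if (length(la) != length(lb)) {
    "class1"
  } else if (all(la == lb)) {
    "identical"
  } else {
    "class2"
  }
  list(
    model_a = materialize(la, gene_ids[1], chromosomes[1], strands[1], starts[1]),
    model_b = materialize(lb, gene_ids[2], chromosomes[2], strands[2], starts[2]),
    events = events,
    lengths_a = la, lengths_b = lb,
    true_class = true_class,
    net_exon_change = length(la) - length(lb)
  )
}

#' Simulate the tissue-expression profiles of a duplicate pair
#'
#' Per tissue, the latent log2 signals of the two copies are bivariate normal
#' with correlation `rho = exp(-lambda t)` (optionally shifted on the
#' transformed-r scale for structurally divergent pairs); independent
#' measurement noise is added to each copy and the result exponentiated to the
#' FPKM scale. Silencing events then force one randomly chosen copy's FPKM
#' below 1 in a tissue, with the logistic-in-`t` probability described in
#' [simulation_config()].
#'
#' @param t Divergence time.
#' @param lambda Correlation decay rate.
#' @param n_tissues Number of tissues (>= 2).
#' @param noise_sd,mean_log2,sd_log2 Noise floor and latent signal moments.
#' @param silencing_max,silencing_midpoint,silencing_scale Silencing model.
#' @param fisher_shift Additive shift on the `ln((1+r)/(1-r))` scale applied
#'   to the latent correlation.
#' @return A list: `fpkm_a`, `fpkm_b`, `rho` (latent correlation after any
#'   shift, before noise), `n_silenced`.
#' @export
simulate_expression_pair <- function(t, lambda, n_tissues = 7L,
                                     noise_sd = 0.25,
                                     mean_log2 = 3, sd_log2 = 2,
                                     silencing_max = 0.3,
                                     silencing_midpoint = 0.5,
                                     silencing_scale = 0.25,
                                     fisher_shift = 0) {
  stopifnot(n_tissues >= 2L, t >= 0, lambda >= 0)
  rho <- exp(-lambda * t)
  if (fisher_shift != 0) {
    rho <- tanh(atanh(min(rho, 1 - 1e-12)) + fisher_shift / 2)
  }
  z1 <- rnorm(n_tissues)
  z2 <- rnorm(n_tissues)
  x_a <- mean_log2 + sd_log2 * z1 + rnorm(n_tissues, 0, noise_sd)
  x_b <- mean_log2 + sd_log2 * (rho * z1 + sqrt(1 - rho^2) * z2) +
    rnorm(n_tissues, 0, noise_sd)
  fpkm_a <- 2^x_a
  fpkm_b <- 2^x_b
  p_sil <- silencing_max * plogis((t - silencing_midpoint) / silencing_scale)
  n_sil <- 0L
  for (i in seq_len(n_tissues)) {
    if (runif(1L) < p_sil) {
      n_sil <- n_sil + 1L
      if (runif(1L) < 0.5) {
        fpkm_a[i] <- runif(1L, 0, 0.9)
      } else {
        fpkm_b[i] <- runif(1L, 0, 0.9)
      }
    }
  }
  list(fpkm_a = fpkm_a, fpkm_b = fpkm_b, rho = rho, n_silenced = n_sil)
}

#' Simulate a complete study bundle
#'
#' Generates `n_pairs` duplicate gene families (CDS pairs, proteins, gene
#' models, lineage flags, tissue expression) plus unrelated decoy genes,
#' computes an all-vs-all protein alignment-hit table with the in-repo aligner
#' behind a shared-k-mer seeding prescreen (emulating a seeded database
#' search), and records a truth table for parameter-recovery tests. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `dd_bundle` list: `proteins`, `cds` (sequence tibbles),
#'   `gene_models`, `lineage`, `hits`, `expression`, `truth`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "dd_sim_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  tissues <- if (cfg$tissue_count == 7L) {
    DEFAULT_TISSUES
  } else {
    sprintf("tissue%02d", seq_len(cfg$tissue_count))
  }
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))

  rows_cds <- list()
  rows_models <- list()
  rows_expr <- list()
  rows_truth <- list()

  for (i in seq_len(cfg$n_pairs)) {
    t <- runif(1L, cfg$branch_length_range[1], cfg$branch_length_range[2])
    omega <- runif(1L, cfg$omega_range[1], cfg$omega_range[2])
    ga <- sprintf("g%04da", i)
    gb <- sprintf("g%04db", i)

    seqs <- suppressWarnings(
      simulate_cds_pair(cfg$cds_length_codons, t, omega)
    )

    intra <- runif(1L) < cfg$intra_fraction
    chr_a <- sample(chroms, 1L)
    chr_b <- if (intra) chr_a else sample(setdiff(chroms, chr_a), 1L)
    start_a <- sample.int(10000000L, 1L)
    start_b <- if (intra) start_a + 3000000L + sample.int(1000000L, 1L) else sample.int(10000000L, 1L)
    base_exons <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1L)
    struct <- simulate_structure_pair(
      base_exons, t, cfg$structure_event_rate,
      gene_ids = c(ga, gb),
      chromosomes = c(chr_a, chr_b),
      strands = sample(c("+", "-"), 2L, replace = TRUE),
      starts = c(start_a, start_b)
    )

    shift <- if (struct$true_class != "identical") cfg$structure_expression_shift else 0
    expr <- simulate_expression_pair(
      t, cfg$expression_decay, cfg$tissue_count,
      noise_sd = cfg$noise_sd,
      mean_log2 = cfg$expression_mean_log2, sd_log2 = cfg$expression_sd_log2,
      silencing_max = cfg$silencing_max,
      silencing_midpoint = cfg$silencing_midpoint,
      silencing_scale = cfg$silencing_scale,
      fisher_shift = shift
    )

    ls_flag <- t < cfg$species_specific_t_max
    ma <- struct$model_a
    mb <- struct$model_b
    ma$lineage_specific <- ls_flag
    mb$lineage_specific <- ls_flag
    rows_models[[length(rows_models) + 1L]] <- dplyr::bind_rows(ma, mb)
    rows_cds[[length(rows_cds) + 1L]] <- tibble(
      id = c(ga, gb), kind = "cds", residues = c(seqs$cds_a, seqs$cds_b)
    )
    rows_expr[[length(rows_expr) + 1L]] <- dplyr::bind_rows(
      tibble(gene_id = ga, tissue = tissues, fpkm = expr$fpkm_a),
      tibble(gene_id = gb, tissue = tissues, fpkm = expr$fpkm_b)
    )
    rows_truth[[length(rows_truth) + 1L]] <- tibble(
      pair_id = paste(ga, gb, sep = "|"),
      gene_a = ga, gene_b = gb,
      t = t, omega = omega,
      true_dS = seqs$true_dS, true_dN = seqs$true_dN,
      n_structure_events = nrow(struct$events),
      net_exon_change = struct$net_exon_change,
      true_class = struct$true_class,
      rho = expr$rho,
      n_silenced = expr$n_silenced,
      lineage_specific = ls_flag,
      locality = if (intra) "intra" else "inter"
    )
  }

  # unrelated decoy genes (singletons, some optionally pseudogenes)
  for (d in seq_len(cfg$n_decoys)) {
    gid <- sprintf("d%04d", d)
    cds <- random_sense_cds(cfg$cds_length_codons)
    chr <- sample(chroms, 1L)
    n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1L)
    st <- simulate_structure_pair(
      n_ex, 0, 0,
      gene_ids = c(gid, "unused"), chromosomes = c(chr, chr),
      strands = c(sample(c("+", "-"), 1L), "+"),
      starts = c(sample.int(10000000L, 1L), 1L)
    )
    m <- st$model_a
    m$lineage_specific <- FALSE
    if (runif(1L) < cfg$pseudogene_fraction) m$biotype <- "processed_pseudogene"
    rows_models[[length(rows_models) + 1L]] <- m
    rows_cds[[length(rows_cds) + 1L]] <- tibble(id = gid, kind = "cds", residues = cds)
    rows_expr[[length(rows_expr) + 1L]] <- tibble(
      gene_id = gid, tissue = tissues,
      fpkm = 2^rnorm(cfg$tissue_count, cfg$expression_mean_log2, cfg$expression_sd_log2)
    )
  }

  cds_tbl <- dplyr::bind_rows(rows_cds)
  proteins <- tibble(
    id = cds_tbl$id, kind = "protein", residues = translate_cds(cds_tbl$residues)
  )
  gene_models <- finalize_gene_models(dplyr::bind_rows(rows_models))
  expression <- dplyr::bind_rows(rows_expr) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "fpkm")
  truth <- dplyr::bind_rows(rows_truth)
  lineage <- tibble(
    gene_id = gene_models$gene_id,
    lineage_specific = gene_models$lineage_specific
  )
  hits <- all_vs_all_hits(proteins)

  structure(
    list(
      proteins = proteins, cds = cds_tbl, gene_models = gene_models,
      lineage = lineage, hits = hits, expression = expression,
      truth = truth, config = cfg
    ),
    class = "dd_bundle"
  )
}

#' All-vs-all protein hits with the in-repo aligner
#'
#' Emulates a seeded database search: only protein pairs sharing at least
#' `min_shared_kmers` k-mers are aligned (unrelated random sequences almost
#' never pass the seed filter, just as they would not produce a reportable
#' database hit). Each aligned pair is emitted in both query/subject
#' directions; the alignment score fills the score column of the tabular
#' dialect.
#'
#' @param proteins Protein tibble from [read_fasta()].
#' @param k Seed k-mer length.
#' @param min_shared_kmers Minimum number of shared k-mers to trigger an
#'   alignment.
#' @return An alignment-hit tibble in the [read_alignment_table()] layout.
#' @export
all_vs_all_hits <- function(proteins, k = 5L, min_shared_kmers = 2L) {
  n <- nrow(proteins)
  kmer_df <- purrr::map_dfr(seq_len(n), function(i) {
    s <- proteins$residues[i]
    if (nchar(s) < k) {
      return(tibble(idx = integer(), kmer = character()))
    }
    km <- unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    tibble(idx = i, kmer = km)
  })
  cand <- dplyr::inner_join(kmer_df, kmer_df, by = "kmer",
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$idx.x < .data$idx.y) |>
    dplyr::count(.data$idx.x, .data$idx.y) |>
    dplyr::filter(.data$n >= min_shared_kmers)

  if (nrow(cand) == 0L) {
    return(tibble(
      query_id = character(), subject_id = character(),
      percent_identity = numeric(), aligned_length = numeric(),
      mismatches = numeric(), gap_openings = numeric(),
      query_start = numeric(), query_end = numeric(),
      subject_start = numeric(), subject_end = numeric(),
      evalue = numeric(), bit_score = numeric()
    ))
  }

  nc <- nrow(cand)
  identity <- numeric(nc)
  length_ <- numeric(nc)
  mism <- numeric(nc)
  gap_open <- numeric(nc)
  score <- numeric(nc)
  for (r in seq_len(nc)) {
    i <- cand$idx.x[r]
    j <- cand$idx.y[r]
    aln <- align_proteins_global(proteins$residues[i], proteins$residues[j])
    gaps <- is.na(aln$a_pos) | is.na(aln$b_pos)
    identity[r] <- aln$identity
    length_[r] <- aln$n_columns
    mism[r] <- aln$n_columns - aln$n_identical - sum(gaps)
    gap_open[r] <- sum(diff(c(FALSE, gaps)) == 1L)
    score[r] <- aln$score
  }
  len_x <- nchar(proteins$residues[cand$idx.x])
  len_y <- nchar(proteins$residues[cand$idx.y])
  rows <- tibble(
    query_id = c(proteins$id[cand$idx.x], proteins$id[cand$idx.y]),
    subject_id = c(proteins$id[cand$idx.y], proteins$id[cand$idx.x]),
    percent_identity = rep(identity, 2),
    aligned_length = rep(length_, 2),
    mismatches = rep(mism, 2),
    gap_openings = rep(gap_open, 2),
    query_start = 1,
    query_end = c(len_x, len_y),
    subject_start = 1,
    subject_end = c(len_y, len_x),
    evalue = 0,
    bit_score = rep(score, 2)
  )
  rows[, OUTFMT6_COLS] |>
    dplyr::arrange(.data$query_id, .data$subject_id)
}

#' Write a simulated bundle to disk as a pipeline fixture
#'
#' Emits exactly the dialects the readers consume: protein and CDS FASTA,
#' gene-model TSV, alignment table, lineage table, expression TSV, plus the
#' truth table and the config as YAML.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly; the bundle as attribute
#'   `bundle`.
#' @export
make_fixture <- function(config, dir) {
  bundle <- simulate_study(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    proteins = file.path(dir, "proteins.faa"),
    cds = file.path(dir, "cds.fna"),
    gene_models = file.path(dir, "gene_models.tsv"),
    hits = file.path(dir, "hits.tsv"),
    lineage = file.path(dir, "lineage.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_fasta(bundle$proteins, paths$proteins)
  write_fasta(bundle$cds, paths$cds)
  write_gene_models_tsv(bundle$gene_models, paths$gene_models)
  write_alignment_table(bundle$hits, paths$hits)
  write_lineage_table(bundle$lineage, paths$lineage)
  write_expression_matrix(bundle$expression, paths$expression)
  readr::write_tsv(bundle$truth, paths$truth)
  yaml::write_yaml(unclass(bundle$config), paths$config)
  invisible(structure(paths, bundle = bundle))
}
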