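# Readers and writers for every external format the pipeline touches. This is
# the single place where coordinate and dialect conventions are fixed:
#   - genomic coordinates are 1-based inclusive everywhere (the GFF3
#     convention); BED-style half-open inputs are not supported;
#   - alignment tables use the 12-column BLAST tabular ("outfmt 6") dialect,
#     with percent identity on the 0-100 scale in the file and rescaled to
#     [0, 1] in memory;
#   - the gene-model TSV dialect is
#     gene_id, chromosome, strand, biotype, lineage_specific, exons
#     with exons encoded "start-end;start-end;..." in genomic order.

#' Read a FASTA file into a sequence tibble
#'
#' Record ids are the first whitespace-delimited token of each header. CDS
#' records are validated: after trimming one terminal stop codon the length
#' must be divisible by three and free of internal stops. Protein records must
#' not contain internal stops.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"` or `"cds"`.
#' @return A tibble with columns `id`, `kind`, `residues`.
#' @export
read_fasta <- function(path, kind = c("protein", "cds")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(sprintf("FASTA file '%s' contains no records", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  res <- tibble(id = ids, kind = kind, residues = unname(toupper(as.character(set))))
  validate_sequences(res)
  res
}

validate_sequences <- function(seqs) {
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$id[i]
    s <- seqs$residues[i]
    if (seqs$kind[i] == "cds") {
      s <- gsub("U", "T", s)
      core <- trim_terminal_stop(s)
      if (nchar(core) %% 3L != 0L) {
        abort(sprintf(
          "CDS '%s': length %d not divisible by 3 after terminal-stop trimming",
          id, nchar(core)
        ))
      }
      ct <- codon_tables()
      idx <- tryCatch(codon_to_index(split_codons(core)),
        error = function(e) abort(sprintf("CDS '%s': %s", id, conditionMessage(e)))
      )
      if (any(ct$is_stop[idx])) {
        abort(sprintf("CDS '%s': internal stop codon", id))
      }
    } else {
      if (grepl("\\*", sub("\\*$", "", s))) {
        abort(sprintf("protein '%s': internal stop", id))
      }
    }
  }
  invisible(seqs)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `residues` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3 or the in-repo TSV dialect
#'
#' Coding exons are assembled per gene from CDS features (GFF3) or parsed from
#' the `exons` column (TSV), sorted by genomic start, and validated to be
#' non-overlapping with `start <= end`. When a GFF3 gene has several
#' transcripts, the transcript with the longest summed CDS is kept (longest
#' isoform convention). Genes without any CDS feature are skipped with a
#' warning. GFF3 carries no lineage information, so `lineage_specific` is set
#' to `NA` there and can be filled from a lineage table.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"gff3"`.
#' @return A tibble with one row per gene: `gene_id`, `chromosome`, `strand`,
#'   `biotype`, `lineage_specific`, `n_exons`, and a `coding_exons` list-column
#'   of `start`/`end` tibbles (1-based inclusive).
#' @export
read_gene_models <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") read_gene_models_tsv(path) else read_gene_models_gff3(path)
}

read_gene_models_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("gene_id", "chromosome", "strand", "biotype", "lineage_specific", "exons")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("gene-model TSV lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  exons <- lapply(seq_len(nrow(raw)), function(i) {
    parts <- strsplit(raw$exons[i], ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) {
      abort(sprintf(
        "gene '%s': malformed exon coordinate '%s'",
        raw$gene_id[i], parts[bad][1]
      ))
    }
    tibble(
      start = as.integer(vapply(m, `[[`, character(1), 2L)),
      end = as.integer(vapply(m, `[[`, character(1), 3L))
    )
  })
  models <- tibble(
    gene_id = raw$gene_id,
    chromosome = raw$chromosome,
    strand = raw$strand,
    biotype = raw$biotype,
    lineage_specific = as.logical(raw$lineage_specific),
    coding_exons = exons
  )
  finalize_gene_models(models)
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p)[1]
  }, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  biotype_col <- intersect(c("biotype", "gene_biotype"), names(df))[1]

  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, , drop = FALSE]
    tx_cds <- lapply(tx$ID, function(tid) {
      cdss[!is.na(cdss$Parent) & cdss$Parent == tid, , drop = FALSE]
    })
    lens <- vapply(tx_cds, function(d) {
      if (nrow(d) == 0L) 0L else sum(d$end - d$start + 1L)
    }, integer(1))
    if (length(lens) == 0L || max(lens) == 0L) {
      warn(sprintf("gene '%s' has no CDS features; skipped", gid))
      next
    }
    best <- tx_cds[[which.max(lens)]]
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = gid,
      chromosome = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      biotype = if (!is.na(biotype_col)) as.character(genes[[biotype_col]][i]) else "protein_coding",
      lineage_specific = NA,
      coding_exons = list(tibble(start = as.integer(best$start), end = as.integer(best$end)))
    )
  }
  if (length(rows) == 0L) {
    abort(sprintf("no usable gene models in '%s'", path))
  }
  finalize_gene_models(dplyr::bind_rows(rows))
}

finalize_gene_models <- function(models) {
  models$coding_exons <- lapply(seq_len(nrow(models)), function(i) {
    ex <- models$coding_exons[[i]]
    gid <- models$gene_id[i]
    if (nrow(ex) < 1L) abort(sprintf("gene '%s': no coding exons", gid))
    if (any(is.na(ex$start)) || any(is.na(ex$end))) {
      abort(sprintf("gene '%s': malformed exon coordinates", gid))
    }
    if (any(ex$end < ex$start)) {
      abort(sprintf("gene '%s': exon end < start", gid))
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      abort(sprintf("gene '%s': overlapping coding exons", gid))
    }
    ex
  })
  if (!all(models$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  dup <- unique(models$gene_id[duplicated(models$gene_id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate gene id(s): %s", paste(dup, collapse = ", ")))
  }
  models$n_exons <- vapply(models$coding_exons, nrow, integer(1))
  dplyr::relocate(as_tibble(models), "gene_id", "chromosome", "strand",
    "biotype", "lineage_specific", "n_exons", "coding_exons"
  )
}

#' Write gene models in the TSV dialect
#'
#' @param models Gene-model tibble (as from [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_tsv <- function(models, path) {
  out <- tibble(
    gene_id = models$gene_id,
    chromosome = models$chromosome,
    strand = models$strand,
    biotype = models$biotype,
    lineage_specific = models$lineage_specific,
    exons = vapply(models$coding_exons, function(ex) {
      paste(sprintf("%d-%d", ex$start, ex$end), collapse = ";")
    }, character(1))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

OUTFMT6_COLS <- c(
  "query_id", "subject_id", "percent_identity", "aligned_length", "mismatches",
  "gap_openings", "query_start", "query_end", "subject_start", "subject_end",
  "evalue", "bit_score"
)

#' Read an all-vs-all protein alignment table (BLAST outfmt 6 dialect)
#'
#' Percent identity is rescaled from the file's 0-100 scale to `[0, 1]`;
#' self-hits (query equal to subject) are dropped.
#'
#' @param path Path to a 12-column tab-separated file without header.
#' @return A tibble of alignment hits.
#' @export
read_alignment_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path,
    col_names = OUTFMT6_COLS,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0L) {
    abort(sprintf("alignment table '%s' is empty", path))
  }
  num_cols <- setdiff(OUTFMT6_COLS, c("query_id", "subject_id"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      abort(sprintf(
        "non-numeric value in column '%s' at line %d",
        col, which(is.na(v))[1]
      ))
    }
    raw[[col]] <- v
  }
  raw$percent_identity <- raw$percent_identity / 100
  hits <- raw[raw$query_id != raw$subject_id, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warn(sprintf("alignment table '%s' contains only self-hits", path))
  }
  as_tibble(hits)
}

#' Write an alignment-hit tibble in the outfmt 6 dialect
#'
#' The inverse of [read_alignment_table()]: identity is written back on the
#' 0-100 scale, without header.
#'
#' @param hits Alignment-hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(hits, path) {
  out <- hits[, OUTFMT6_COLS]
  out$percent_identity <- round(out$percent_identity * 100, 2)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a genes-by-tissues FPKM matrix
#'
#' @param path TSV with header `gene_id` then one column per tissue.
#' @return A wide tibble, one row per gene; all FPKM values non-negative.
#' @export
read_expression_matrix <- function(path) {
  stopifnot(file.exists(path))
  mat <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  if (!identical(names(mat)[1], "gene_id")) {
    abort("expression matrix must have 'gene_id' as its first column")
  }
  tissues <- names(mat)[-1]
  if (length(tissues) == 0L) abort("expression matrix has no tissue columns")
  if (anyDuplicated(tissues)) abort("duplicate tissue names")
  if (anyDuplicated(mat$gene_id)) abort("duplicate gene ids in expression matrix")
  vals <- as.matrix(mat[, -1])
  if (anyNA(vals)) abort("missing cells in expression matrix")
  if (any(vals < 0)) abort("negative FPKM values in expression matrix")
  mat
}

#' Write a genes-by-tissues FPKM matrix
#'
#' @param mat Expression tibble (as from [read_expression_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Read a gene lineage table
#'
#' Maps each gene to a flag stating whether it lacks any recorded homolog
#' outside the focal species (`TRUE` = lineage-specific).
#'
#' @param path TSV with header columns `gene_id`, `lineage_specific`.
#' @return A tibble with those two columns.
#' @export
read_lineage_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), lineage_specific = readr::col_logical()
  ))
  if (anyDuplicated(tbl$gene_id)) abort("duplicate gene ids in lineage table")
  tbl
}

#' Write a gene lineage table
#'
#' @param tbl Tibble with columns `gene_id`, `lineage_specific`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(tbl, path) {
  readr::write_tsv(tbl[, c("gene_id", "lineage_specific")], path)
  invisible(path)
}
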