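# Codon-level machinery shared by the NG86 estimator and the sequence
# simulator: codon indexing, translation, per-codon synonymous site counts and
# pathway-averaged difference counts between codon pairs.
#
# Conventions (standard genetic code throughout):
#   - codons are indexed 1..64 in the order of names(Biostrings::GENETIC_CODE);
#   - stop codons carry NA site counts and never appear in codon alignments;
#   - synonymous site count of a codon position is the fraction of its three
#     single-nucleotide changes that are synonymous, with changes that create a
#     stop codon removed from the denominator;
#   - differences between two codons are averaged over all minimal mutational
#     pathways, pathways passing through a stop codon excluded (if every
#     pathway is blocked, all pathways are used as a fallback).

NUCS <- c("T", "C", "A", "G")

codon_tables <- function() {
  if (!is.null(the$codon_tables)) {
    return(the$codon_tables)
  }
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  is_stop <- aa == "*"
  # codon string -> index
  codon_index <- setNames(seq_along(codons), codons)
  # nucleotide composition, 64 x 3
  nuc <- do.call(rbind, strsplit(codons, ""))

  syn_sites <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (is_stop[i]) next
    s <- 0
    for (pos in 1:3) {
      alt_nucs <- setdiff(NUCS, nuc[i, pos])
      neighbours <- vapply(alt_nucs, function(n) {
        x <- nuc[i, ]
        x[pos] <- n
        paste(x, collapse = "")
      }, character(1))
      keep <- !is_stop[codon_index[neighbours]]
      if (!any(keep)) next
      s <- s + sum(aa[codon_index[neighbours[keep]]] == aa[i]) / sum(keep)
    }
    syn_sites[i] <- s
  }

  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(
      c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
    )
  )

  syn_diff <- matrix(NA_real_, 64L, 64L)
  nonsyn_diff <- matrix(NA_real_, 64L, 64L)
  for (i in seq_len(64L)) {
    if (is_stop[i]) next
    syn_diff[i, i] <- 0
    nonsyn_diff[i, i] <- 0
    for (j in seq_len(64L)) {
      if (j <= i || is_stop[j]) next
      pos_diff <- which(nuc[i, ] != nuc[j, ])
      k <- length(pos_diff)
      path_syn <- numeric(0)
      path_nonsyn <- numeric(0)
      path_valid <- logical(0)
      for (ord in perms[[as.character(k)]]) {
        cur <- nuc[i, ]
        ns <- 0
        nn <- 0
        valid <- TRUE
        for (p in pos_diff[ord]) {
          nxt <- cur
          nxt[p] <- nuc[j, p]
          from_aa <- gc_map[[paste(cur, collapse = "")]]
          to_aa <- gc_map[[paste(nxt, collapse = "")]]
          if (to_aa == "*") valid <- FALSE
          if (identical(from_aa, to_aa)) ns <- ns + 1 else nn <- nn + 1
          cur <- nxt
        }
        path_syn <- c(path_syn, ns)
        path_nonsyn <- c(path_nonsyn, nn)
        path_valid <- c(path_valid, valid)
      }
      use <- if (any(path_valid)) path_valid else rep(TRUE, length(path_valid))
      syn_diff[i, j] <- syn_diff[j, i] <- mean(path_syn[use])
      nonsyn_diff[i, j] <- nonsyn_diff[j, i] <- mean(path_nonsyn[use])
    }
  }

  the$codon_tables <- list(
    codons = codons, aa = aa, is_stop = is_stop, codon_index = codon_index,
    nuc = nuc, syn_sites = syn_sites,
    syn_diff = syn_diff, nonsyn_diff = nonsyn_diff,
    sense = which(!is_stop)
  )
  the$codon_tables
}

# split a CDS string into codon strings
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    abort(sprintf("CDS length %d is not divisible by 3", n))
  }
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

codon_to_index <- function(codons) {
  ct <- codon_tables()
  idx <- ct$codon_index[codons]
  if (anyNA(idx)) {
    abort(sprintf(
      "non-nucleotide codon(s): %s",
      paste(unique(codons[is.na(idx)]), collapse = ", ")
    ))
  }
  unname(idx)
}

#' Translate coding sequences with the standard genetic code
#'
#' Terminal stop codons are trimmed before translation; an internal stop is an
#' error.
#'
#' @param cds Character vector of coding sequences (nucleotides, `TCAG`).
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  ct <- codon_tables()
  vapply(cds, function(x) {
    idx <- codon_to_index(split_codons(trim_terminal_stop(x)))
    if (any(ct$is_stop[idx])) {
      abort("internal stop codon in CDS")
    }
    paste(ct$aa[idx], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# remove a single terminal stop codon, if present
trim_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && n %% 3L == 0L) {
    last <- substr(cds, n - 2L, n)
    if (last %in% c("TAA", "TAG", "TGA")) {
      return(substr(cds, 1L, n - 3L))
    }
  }
  cds
}
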