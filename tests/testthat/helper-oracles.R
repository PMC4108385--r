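# Independent oracles used to cross-check the implementation. Each is written
# as plainly as possible (recursion, enumeration, direct translation via
# Biostrings::GENETIC_CODE) and stays independent of the code paths it checks.

# --- global affine alignment score by memoized recursion -------------------
# Same scoring convention as the implementation (a gap of length L costs
# open + L * extend), computed top-down over (i, j, last-operation) states.
oracle_nw_score <- function(a, b, sm, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    val <- if (i == 0 && j == 0) {
      if (last == "S") 0 else -Inf
    } else if (last == "S") {
      -Inf
    } else if (last == "M") {
      if (i == 0 || j == 0) {
        -Inf
      } else {
        sm[av[i], bv[j]] + max(rec(i - 1, j - 1, "S"), rec(i - 1, j - 1, "M"),
          rec(i - 1, j - 1, "X"), rec(i - 1, j - 1, "Y")
        )
      }
    } else if (last == "X") { # gap in b, consumes a[i]
      if (i == 0) {
        -Inf
      } else {
        max(
          rec(i - 1, j, "S") - open - ext, rec(i - 1, j, "M") - open - ext,
          rec(i - 1, j, "X") - ext, rec(i - 1, j, "Y") - open - ext
        )
      }
    } else { # Y: gap in a, consumes b[j]
      if (j == 0) {
        -Inf
      } else {
        max(
          rec(i, j - 1, "S") - open - ext, rec(i, j - 1, "M") - open - ext,
          rec(i, j - 1, "X") - open - ext, rec(i, j - 1, "Y") - ext
        )
      }
    }
    memo[[key]] <- val
    val
  }
  max(rec(n, m, "M"), rec(n, m, "X"), rec(n, m, "Y"))
}

# --- NG86 counts by brute-force enumeration --------------------------------
GC_MAP <- Biostrings::GENETIC_CODE
ORACLE_NUCS <- c("T", "C", "A", "G")

oracle_translate1 <- function(codon) unname(GC_MAP[codon])

oracle_syn_sites_codon <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (alt in setdiff(ORACLE_NUCS, nts[pos])) {
      mut <- nts
      mut[pos] <- alt
      mut_codon <- paste(mut, collapse = "")
      if (oracle_translate1(mut_codon) == "*") next
      valid <- valid + 1
      if (oracle_translate1(mut_codon) == oracle_translate1(codon)) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# enumerate every ordering of the differing positions recursively
oracle_codon_paths <- function(from, to) {
  f <- strsplit(from, "")[[1]]
  tt <- strsplit(to, "")[[1]]
  diff <- which(f != tt)
  if (length(diff) == 0) {
    return(list(list(syn = 0, nonsyn = 0, valid = TRUE)))
  }
  paths <- list()
  walk <- function(cur, remaining, syn, nonsyn, valid) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(syn = syn, nonsyn = nonsyn, valid = valid)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- tt[p]
      from_aa <- oracle_translate1(paste(cur, collapse = ""))
      to_aa <- oracle_translate1(paste(nxt, collapse = ""))
      walk(
        nxt, setdiff(remaining, p),
        syn + as.integer(from_aa == to_aa && to_aa != "*"),
        nonsyn + as.integer(from_aa != to_aa && to_aa != "*"),
        valid && to_aa != "*"
      )
    }
  }
  walk(f, diff, 0, 0, TRUE)
  paths
}

oracle_codon_diffs <- function(from, to) {
  paths <- oracle_codon_paths(from, to)
  valid <- Filter(function(p) p$valid, paths)
  use <- if (length(valid) > 0) valid else paths
  c(
    syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn"))
  )
}

# full NG86 counts for two aligned gapless codon vectors
oracle_ng86 <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  S_a <- sum(vapply(codons_a, oracle_syn_sites_codon, numeric(1)))
  S_b <- sum(vapply(codons_b, oracle_syn_sites_codon, numeric(1)))
  S_sites <- (S_a + S_b) / 2
  N_sites <- 3 * length(codons_a) - S_sites
  d <- vapply(
    seq_along(codons_a),
    function(i) oracle_codon_diffs(codons_a[i], codons_b[i]),
    numeric(2)
  )
  list(
    S_sites = S_sites, N_sites = N_sites,
    S_diffs = sum(d["syn", ]), N_diffs = sum(d["nonsyn", ])
  )
}

SENSE_CODONS <- names(GC_MAP)[GC_MAP != "*"]

random_codon_vector <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

# mutate a sense codon vector: random single-nucleotide changes avoiding stops
mutate_codons <- function(codons, n_changes) {
  for (k in seq_len(n_changes)) {
    repeat {
      i <- sample(length(codons), 1)
      nts <- strsplit(codons[i], "")[[1]]
      pos <- sample(3, 1)
      nts[pos] <- sample(setdiff(ORACLE_NUCS, nts[pos]), 1)
      cand <- paste(nts, collapse = "")
      if (oracle_translate1(cand) != "*") {
        codons[i] <- cand
        break
      }
    }
  }
  codons
}

# --- event-log replay for the CDS simulator --------------------------------
# Applies the accepted events of a simulate_cds_pair() log to the ancestor
# and independently reclassifies each accepted event by direct translation.
oracle_replay_cds <- function(ancestor, events, copy) {
  nts <- strsplit(ancestor, "")[[1]]
  ev <- events[events$copy == copy, , drop = FALSE]
  n_syn <- 0
  n_nonsyn <- 0
  for (i in seq_len(nrow(ev))) {
    site <- ev$site[i]
    stopifnot(nts[site] == ev$from[i] || ev$accepted[i] == FALSE)
    codon_i <- (site - 1) %/% 3 + 1
    old_codon <- paste(nts[(3 * codon_i - 2):(3 * codon_i)], collapse = "")
    cand <- nts
    cand[site] <- ev$to[i]
    new_codon <- paste(cand[(3 * codon_i - 2):(3 * codon_i)], collapse = "")
    type <- if (oracle_translate1(new_codon) == "*") {
      "stop"
    } else if (oracle_translate1(new_codon) == oracle_translate1(old_codon)) {
      "synonymous"
    } else {
      "nonsynonymous"
    }
    stopifnot(type == ev$type[i])
    if (ev$accepted[i]) {
      nts <- cand
      if (type == "synonymous") n_syn <- n_syn + 1
      if (type == "nonsynonymous") n_nonsyn <- n_nonsyn + 1
    }
  }
  list(cds = paste(nts, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn)
}
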