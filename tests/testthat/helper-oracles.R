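# Independent oracles used across the suite. These re-derive expected
# values by brute force or a second route and must stay independent of the
# implementation paths they check.

# Optimal global affine-gap alignment score by explicit 3-state dynamic
# programming (match/Ix/Iy). A gap of length L scores gap_open +
# L * gap_extend, matching align_global()'s convention.
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -6, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # last column aligned A[i] with B[j]
  X <- matrix(NEG, n + 1, m + 1)   # last column a gap in B (A[i] vs -)
  Y <- matrix(NEG, n + 1, m + 1)   # last column a gap in A (- vs B[j])
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- gap_open + i * gap_extend
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- gap_open + j * gap_extend
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Per-chain expansion of integer areas: treat each area unit as one chain
# and compute the moments directly.
oracle_moments <- function(dp, counts) {
  chains <- rep(dp, counts)
  xn <- mean(chains)
  xw <- sum(chains^2) / sum(chains)
  list(x_n = xn, x_w = xw, pdi = xw / xn)
}

# Naive overlapping-regex scan for an IUPAC pattern on plain-ACGT
# sequences; both orientations, duplicates collapsed.
iupac_to_regex <- function(pattern) {
  map <- vapply(svkit:::IUPAC_SETS, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, "")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

oracle_sites <- function(seq_string, pattern) {
  scan1 <- function(pat) {
    hits <- gregexpr(paste0("(?=", iupac_to_regex(pat), ")"), seq_string,
                     perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  rc <- svkit::revcomp(pattern)
  sort(unique(c(scan1(pattern), if (rc != pattern) scan1(rc))))
}

# Protein-level diff by translating both full CDSs and comparing
# position-wise (only valid when lengths match, i.e. no indels).
oracle_protein_diff <- function(ref, alt) {
  pr <- strsplit(translate_cds(ref)$residues, "")[[1]]
  pa <- strsplit(translate_cds(alt)$residues, "")[[1]]
  stopifnot(length(pr) == length(pa))
  which(pr != pa)
}

# Letter-display soundness: two groups share >= 1 letter iff their
# pairwise p-value is >= alpha.
cld_is_sound <- function(lg) {
  labs <- names(lg$letters)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i >= j) next
      share <- length(intersect(strsplit(lg$letters[[labs[i]]], "")[[1]],
                                strsplit(lg$letters[[labs[j]]], "")[[1]])) > 0
      nonsig <- lg$p_matrix[labs[i], labs[j]] >= lg$alpha
      if (share != nonsig) return(FALSE)
    }
  }
  TRUE
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random chain distribution with integer areas (for the expansion oracle).
random_int_dist <- function() {
  k <- sample(2:20, 1)
  dp <- sort(sample(1:80, k))
  chain_dist("r", "1", dp, sample(1:50, k, replace = TRUE))
}
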