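test_that("align_global handles identity, SNPs and gaps as expected", {
  a <- seq_record("r", "ACGTACGT")
  ident <- align_global(a, seq_record("x", "ACGTACGT"))
  expect_equal(ident$gapped_ref, ident$gapped_alt)
  expect_equal(ident$score, 8)

  aln <- align_global(a, seq_record("x", "ACGAACGT"))
  rr <- strsplit(aln$gapped_ref, "")[[1]]
  aa <- strsplit(aln$gapped_alt, "")[[1]]
  mism <- which(rr != aa)
  expect_equal(aln$ref_coord_map[mism], 4L)

  ref <- seq_record("r", "ACGATTTCGATG")
  alt <- seq_record("x", "ACGACGATG")   # internal TTT removed
  aln2 <- align_global(ref, alt)
  gaps <- gregexpr("-+", aln2$gapped_alt)[[1]]
  expect_length(as.integer(gaps), 1L)               # one gap run
  expect_equal(attr(gaps, "match.length"), 3L)      # of three columns

  empty <- structure(list(id = "e", residues = "", alphabet = "DNA"),
                     class = "seq_record")
  expect_error(align_global(a, empty), "empty")
})

test_that("alignment score matches the brute-force affine DP oracle", {
  set.seed(5)
  for (i in 1:60) {
    a <- random_dna(8)
    b <- random_dna(sample(6:10, 1))
    got <- align_global(seq_record("a", a), seq_record("b", b))$score
    expect_equal(got, oracle_align_score(a, b), info = paste(a, b))
  }
})

test_that("alignment invariants: gap-stripping recovers inputs", {
  set.seed(9)
  for (i in 1:20) {
    sim <- simulate_allele_pair(allele_sim_spec(length = 150, n_snps = 2,
                                                n_silent = 1,
                                                indel_lengths = 3L,
                                                seed = i))
    aln <- align_global(sim$ref, sim$alt)
    expect_equal(svkit:::ungap(aln$gapped_ref), sim$ref$residues)
    expect_equal(svkit:::ungap(aln$gapped_alt), sim$alt$residues)
    cmap <- aln$ref_coord_map
    expect_true(!is.unsorted(cmap[!is.na(cmap)], strictly = TRUE))
  }
})

test_that("call_variants recovers planted truth and round-trips", {
  expect_equal(nrow(call_variants(align_global(
    seq_record("a", "ACGTACGT"), seq_record("b", "ACGTACGT")))), 0)
  set.seed(13)
  for (i in 1:50) {
    n_snps <- sample(0:6, 1)
    sim <- simulate_allele_pair(allele_sim_spec(
      length = 300, n_snps = n_snps, n_silent = min(n_snps, sample(0:2, 1)),
      indel_lengths = if (i %% 2) 3L else integer(0)))
    v <- call_variants(align_global(sim$ref, sim$alt))
    expect_equal(v[c("ref_pos", "ref_allele", "alt_allele", "kind")],
                 sim$truth[c("ref_pos", "ref_allele", "alt_allele", "kind")])
    expect_equal(apply_variants(sim$ref, v)$residues, sim$alt$residues)
  }
})

test_that("translate_cds follows the standard code and ambiguity rule", {
  expect_equal(translate_cds(seq_record("x", "ATGGCC"))$residues, "MA")
  expect_equal(translate_cds(seq_record("x", "ACA"))$residues, "T")
  expect_equal(translate_cds(seq_record("x", "CCA"))$residues, "P")
  expect_equal(translate_cds(seq_record("x", "ATGNNN"))$residues, "MX")
  # ambiguity resolving to a unique residue is translated, not X
  expect_equal(translate_cds(seq_record("x", "GCN"))$residues, "A")
  expect_equal(translate_cds(seq_record("x", "ATGTAA"))$residues, "M*")
  expect_error(translate_cds(seq_record("x", "ATGG")), "divisible")
})

test_that("classify_effects distinguishes silent/missense/indels", {
  # codon 2 ACC -> CCC: Thr -> Pro missense at aa 2
  ref <- seq_record("r", "ATGACCGCTTAA")
  v <- data.frame(ref_pos = 4L, ref_allele = "A", alt_allele = "C",
                  kind = "SNP", effect = "unknown", aa_ref = NA_character_,
                  aa_pos = NA_integer_, aa_alt = NA_character_,
                  domain = NA_character_)
  out <- classify_effects(v, ref)
  expect_equal(out$effect, "missense")
  expect_equal(out[c("aa_ref", "aa_pos", "aa_alt")],
               data.frame(aa_ref = "T", aa_pos = 2L, aa_alt = "P"))

  # third-position GCT -> GCC is silent
  v2 <- v
  v2$ref_pos <- 9L; v2$ref_allele <- "T"; v2$alt_allele <- "C"
  expect_equal(classify_effects(v2, ref)$effect, "silent")

  # frameshift and noncoding
  v3 <- data.frame(ref_pos = 4L, ref_allele = "AC", alt_allele = "",
                   kind = "deletion", effect = "unknown",
                   aa_ref = NA_character_, aa_pos = NA_integer_,
                   aa_alt = NA_character_, domain = NA_character_)
  expect_equal(classify_effects(v3, ref)$effect, "frameshift")
  v4 <- v
  v4$ref_pos <- 2L; v4$ref_allele <- "T"; v4$alt_allele <- "A"
  expect_equal(classify_effects(v4, ref, cds_offset = 3L)$effect,
               "noncoding")
})

test_that("a 3-nt deletion at codon 654 classifies at aa 654", {
  set.seed(654)
  body <- svkit:::random_cds(2100)   # 700 codons
  ref <- seq_record("r", body)
  p <- 3L * 653L + 1L   # first base of codon 654
  del <- substr(body, p, p + 2L)
  v <- data.frame(ref_pos = p, ref_allele = del, alt_allele = "",
                  kind = "deletion", effect = "unknown",
                  aa_ref = NA_character_, aa_pos = NA_integer_,
                  aa_alt = NA_character_, domain = NA_character_)
  out <- classify_effects(v, ref)
  expect_equal(out$effect, "in_frame_deletion")
  expect_equal(out$aa_pos, 654L)
  expect_equal(out$aa_ref,
               substr(translate_cds(ref)$residues, 654, 654))
})

test_that("effect classification agrees with the translate-and-diff oracle", {
  set.seed(31)
  for (i in 1:30) {
    sim <- simulate_allele_pair(allele_sim_spec(length = 300,
                                                n_snps = sample(1:6, 1),
                                                n_silent = sample(0:1, 1)))
    v <- classify_effects(call_variants(align_global(sim$ref, sim$alt)),
                          sim$ref)
    changed_aa <- oracle_protein_diff(sim$ref, sim$alt)
    expect_setequal(v$aa_pos[v$effect == "missense"], changed_aa)
    # silent SNPs must not appear in the protein diff
    silent_codons <- (v$ref_pos[v$effect == "silent"] - 1) %/% 3 + 1
    expect_length(intersect(silent_codons, changed_aa), 0)
  }
})

test_that("assign_domains labels aa positions by the SSIII map", {
  map <- ssiii_domain_map()
  mk <- function(aa) data.frame(ref_pos = aa * 3L, ref_allele = "A",
                                alt_allele = "C", kind = "SNP",
                                effect = "missense", aa_ref = "T",
                                aa_pos = as.integer(aa), aa_alt = "P",
                                domain = NA_character_)
  expect_equal(assign_domains(mk(654), map)$domain, "N-terminal")
  expect_equal(assign_domains(mk(768), map)$domain, "N-terminal")
  expect_equal(assign_domains(mk(769), map)$domain, "homology")
  expect_equal(assign_domains(mk(1227), map)$domain, "catalytic")
  expect_equal(assign_domains(mk(2000), map)$domain, "outside")
  expect_error(domain_map(c("a", "b"), c(1, 5), c(10, 20)), "overlap")
})

test_that("summarize_alleles partitions the variant list", {
  expect_equal(summarize_alleles(svkit:::empty_variant_table()),
               list(n_snps = 0L, n_silent = 0L, n_missense = 0L,
                    n_indels = 0L))
  sim <- simulate_allele_pair(allele_sim_spec(length = 600, n_snps = 12,
                                              n_silent = 5, seed = 2))
  s <- summarize_alleles(sim$truth)
  expect_equal(s, list(n_snps = 12, n_silent = 5, n_missense = 7,
                       n_indels = 0))
  expect_equal(s$n_silent + s$n_missense, s$n_snps)
})
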