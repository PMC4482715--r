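# Variant calling from a global alignment, conceptual translation, coding
# effect classification and protein-domain assignment.
#
# Coordinate conventions (all 1-based, forward strand of the reference):
#   SNP        ref_pos = the substituted base.
#   deletion   ref_pos = first deleted reference base; alt_allele = "".
#   insertion  ref_pos = reference base AFTER which the bases are inserted
#              (0 for an insertion before the first base); ref_allele = "".
# Indels are left-normalized (shifted to the lowest equivalent reference
# position), the convention used in variant normalization generally, so the
# output does not depend on the aligner's gap-placement tie-breaking.

#' Call variants from a global alignment
#'
#' One SNP per mismatch column; maximal runs of gap columns are merged into
#' single indel events and left-normalized. Positions are 1-based on the
#' reference and the result is sorted by `ref_pos`.
#'
#' @param aln an `alignment_result` from [align_global()].
#' @return variant data.frame (columns `ref_pos, ref_allele, alt_allele,
#'   kind, effect, aa_ref, aa_pos, aa_alt, domain`); effect columns are
#'   `"unknown"`/NA until [classify_effects()] is applied.
#' @export
call_variants <- function(aln) {
  stopifnot(inherits(aln, "alignment_result"))
  rchars <- strsplit(aln$gapped_ref, "", fixed = TRUE)[[1]]
  achars <- strsplit(aln$gapped_alt, "", fixed = TRUE)[[1]]
  ref_seq <- ungap(aln$gapped_ref)
  rpos <- cumsum(rchars != "-")
  n <- length(rchars)
  state <- ifelse(rchars == "-", "ins", ifelse(achars == "-", "del",
                  ifelse(rchars == achars, "match", "snp")))
  out <- list()
  i <- 1L
  while (i <= n) {
    s <- state[[i]]
    if (s == "match") { i <- i + 1L; next }
    if (s == "snp") {
      out[[length(out) + 1L]] <- list(ref_pos = rpos[[i]],
                                      ref_allele = rchars[[i]],
                                      alt_allele = achars[[i]], kind = "SNP")
      i <- i + 1L
    } else {
      j <- i
      while (j < n && state[[j + 1L]] == s) j <- j + 1L
      if (s == "del") {
        ev <- normalize_deletion(ref_seq, rpos[[i]],
                                 paste(rchars[i:j], collapse = ""))
      } else {
        ev <- normalize_insertion(ref_seq, rpos[[i]],
                                  paste(achars[i:j], collapse = ""))
      }
      out[[length(out) + 1L]] <- ev
      i <- j + 1L
    }
  }
  if (!length(out)) return(empty_variant_table())
  v <- data.frame(ref_pos = vapply(out, `[[`, 0, "ref_pos"),
                  ref_allele = vapply(out, `[[`, "", "ref_allele"),
                  alt_allele = vapply(out, `[[`, "", "alt_allele"),
                  kind = vapply(out, `[[`, "", "kind"),
                  effect = "unknown", aa_ref = NA_character_,
                  aa_pos = NA_integer_, aa_alt = NA_character_,
                  domain = NA_character_, stringsAsFactors = FALSE)
  v <- v[order(v$ref_pos), , drop = FALSE]
  rownames(v) <- NULL
  validate_variant_table(v)
}

# Shift a deletion of ref[p .. p+k-1] to its leftmost equivalent placement.
normalize_deletion <- function(ref_seq, p, deleted) {
  k <- nchar(deleted)
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  while (p > 1 && rc[p - 1L] == rc[p + k - 1L]) p <- p - 1L
  list(ref_pos = p, ref_allele = paste(rc[p:(p + k - 1L)], collapse = ""),
       alt_allele = "", kind = "deletion")
}

# Shift an insertion (after ref position p) leftward through repeat context.
normalize_insertion <- function(ref_seq, first_missing_ref_pos, inserted) {
  # gap columns in the reference carry rpos = position of previous ref base
  p <- first_missing_ref_pos
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  s <- strsplit(inserted, "", fixed = TRUE)[[1]]
  k <- length(s)
  while (p >= 1 && s[k] == rc[p]) {
    s <- c(rc[p], s[-k])
    p <- p - 1L
  }
  list(ref_pos = as.integer(p), ref_allele = "",
       alt_allele = paste(s, collapse = ""), kind = "insertion")
}

#' Apply a variant set to a reference sequence
#'
#' Reconstructs the alternate sequence; `apply_variants(ref,
#' call_variants(align_global(ref, alt)))` recovers `alt` exactly.
#'
#' @param ref [seq_record()] reference.
#' @param variants variant data.frame in reference coordinates.
#' @return [seq_record()] with the edits applied.
#' @export
apply_variants <- function(ref, variants) {
  validate_variant_table(variants)
  chars <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  # apply right-to-left so earlier coordinates stay valid
  ord <- order(variants$ref_pos, decreasing = TRUE)
  for (i in ord) {
    p <- variants$ref_pos[i]
    kind <- variants$kind[i]
    if (kind == "SNP") {
      if (chars[p] != variants$ref_allele[i]) {
        stop("apply_variants: ref allele mismatch at ", p)
      }
      chars[p] <- variants$alt_allele[i]
    } else if (kind == "deletion") {
      k <- nchar(variants$ref_allele[i])
      if (paste(chars[p:(p + k - 1L)], collapse = "") != variants$ref_allele[i]) {
        stop("apply_variants: ref allele mismatch at ", p)
      }
      chars <- chars[-(p:(p + k - 1L))]
    } else {
      ins <- strsplit(variants$alt_allele[i], "", fixed = TRUE)[[1]]
      chars <- append(chars, ins, after = p)
    }
  }
  seq_record(paste0(ref$id, "_edited"), paste(chars, collapse = ""), "DNA")
}

#' Translate a coding sequence
#'
#' Standard genetic code. Stop codons are rendered `*`; a codon containing
#' ambiguity codes translates to the unique amino acid shared by all of its
#' concrete resolutions, else `X`.
#'
#' @param cds [seq_record()] (DNA), length divisible by 3, read in frame
#'   from base 1.
#' @param code named character vector codon -> amino acid; default the
#'   standard table.
#' @return [seq_record()] protein of length `nt/3` (any terminal `*`
#'   included in the string but by convention excluded from amino-acid
#'   numbering).
#' @examples
#' translate_cds(seq_record("x", "ATGGCC"))$residues  # "MA"
#' @export
translate_cds <- function(cds, code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(cds, "seq_record"), cds$alphabet == "DNA")
  n <- nchar(cds$residues)
  if (n %% 3 != 0) stop("translate_cds: length ", n, " not divisible by 3")
  codons <- substring(cds$residues, seq(1, n, 3), seq(3, n, 3))
  aas <- vapply(codons, translate_codon, "", code = code, USE.NAMES = FALSE)
  seq_record(paste0(cds$id, "_aa"), paste(aas, collapse = ""), "PROTEIN",
             description = cds$description)
}

translate_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  aa <- code[codon]
  if (!is.na(aa)) return(unname(aa))
  sets <- IUPAC_SETS[strsplit(codon, "", fixed = TRUE)[[1]]]
  if (any(vapply(sets, is.null, TRUE))) {
    stop("translate_codon: illegal codon '", codon, "'")
  }
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  aas <- unique(code[apply(combos, 1, paste, collapse = "")])
  if (length(aas) == 1L && !is.na(aas)) unname(aas) else "X"
}

#' Classify the coding effect of called variants
#'
#' SNPs are silent iff the translated codon is unchanged, otherwise missense
#' with the (reference aa, 1-based aa position, alternate aa) recorded.
#' Indels with length divisible by 3 are in-frame (residues removed/inserted
#' recorded), otherwise frameshift. Variants outside the CDS are noncoding.
#'
#' @param variants variant data.frame from [call_variants()].
#' @param ref full reference [seq_record()].
#' @param cds_offset 0-based offset of the CDS start within `ref` (0 when
#'   the record is the CDS itself). Amino-acid positions are numbered from
#'   the CDS start.
#' @param cds_length CDS length in nt (divisible by 3); default: the longest
#'   multiple of 3 from the offset to the sequence end.
#' @return the variant data.frame with `effect`, `aa_ref`, `aa_pos`,
#'   `aa_alt` filled in.
#' @export
classify_effects <- function(variants, ref, cds_offset = 0L,
                             cds_length = NULL) {
  validate_variant_table(variants)
  stopifnot(inherits(ref, "seq_record"))
  L <- seq_len_nt(ref)
  if (is.null(cds_length)) cds_length <- 3L * ((L - cds_offset) %/% 3L)
  if (cds_length %% 3 != 0) stop("classify_effects: cds_length not multiple of 3")
  cds <- seq_record(ref$id, substr(ref$residues, cds_offset + 1L,
                                   cds_offset + cds_length), "DNA")
  rc <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(variants))) {
    p0 <- variants$ref_pos[i] - cds_offset   # 1-based within CDS
    kind <- variants$kind[i]
    span <- if (kind == "deletion") nchar(variants$ref_allele[i]) else 1L
    if (kind == "insertion") {
      inside <- p0 >= 1 && p0 < cds_length   # inserted after base p0
    } else {
      inside <- p0 >= 1 && (p0 + span - 1L) <= cds_length
    }
    if (!inside) { variants$effect[i] <- "noncoding"; next }
    if (kind == "SNP") {
      if (rc[variants$ref_pos[i]] != variants$ref_allele[i]) {
        stop("classify_effects: ref allele mismatch at ", variants$ref_pos[i])
      }
      ci <- (p0 - 1L) %/% 3L              # 0-based codon index
      codon <- substr(cds$residues, ci * 3L + 1L, ci * 3L + 3L)
      within <- (p0 - 1L) %% 3L + 1L
      alt_codon <- codon
      substr(alt_codon, within, within) <- variants$alt_allele[i]
      ref_aa <- translate_codon(codon)
      alt_aa <- translate_codon(alt_codon)
      if (ref_aa == alt_aa) {
        variants$effect[i] <- "silent"
      } else {
        variants$effect[i] <- "missense"
        variants$aa_ref[i] <- ref_aa
        variants$aa_pos[i] <- ci + 1L
        variants$aa_alt[i] <- alt_aa
      }
    } else if (kind == "deletion") {
      k <- span
      if (k %% 3L != 0L) { variants$effect[i] <- "frameshift"; next }
      variants$effect[i] <- "in_frame_deletion"
      aa_pos <- (p0 - 1L) %/% 3L + 1L
      n_aa <- k %/% 3L
      ref_prot <- translate_cds(cds)$residues
      if ((p0 - 1L) %% 3L == 0L) {
        # codon-aligned: removed residues are exactly the deleted codons
        variants$aa_ref[i] <- substr(ref_prot, aa_pos, aa_pos + n_aa - 1L)
        variants$aa_alt[i] <- "-"
      } else {
        # spans a codon boundary: one fused codon remains
        del_cds <- paste0(substr(cds$residues, 1, p0 - 1L),
                          substr(cds$residues, p0 + k, cds_length))
        fused <- substr(del_cds, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
        variants$aa_ref[i] <- substr(ref_prot, aa_pos, aa_pos + n_aa)
        variants$aa_alt[i] <- translate_codon(fused)
      }
      variants$aa_pos[i] <- aa_pos
    } else { # insertion
      k <- nchar(variants$alt_allele[i])
      if (k %% 3L != 0L) { variants$effect[i] <- "frameshift"; next }
      variants$effect[i] <- "in_frame_insertion"
      aa_pos <- p0 %/% 3L + 1L   # first (possibly new) residue position
      variants$aa_pos[i] <- aa_pos
      variants$aa_ref[i] <- "-"
      if (p0 %% 3L == 0L) {
        variants$aa_alt[i] <- translate_cds(
          seq_record("ins", variants$alt_allele[i], "DNA"))$residues
      } else {
        variants$aa_alt[i] <- strrep("X", k %/% 3L)
      }
    }
  }
  variants
}

#' Construct a protein/nucleotide domain map
#'
#' @param name character vector of domain names.
#' @param aa_start,aa_end 1-based inclusive amino-acid intervals,
#'   non-overlapping and sorted.
#' @return data.frame of class `domain_map` with derived nt intervals
#'   (`nt = 3 * aa`).
#' @export
domain_map <- function(name, aa_start, aa_end) {
  stopifnot(length(name) == length(aa_start), length(aa_start) == length(aa_end),
            all(aa_end >= aa_start))
  o <- order(aa_start)
  name <- name[o]; aa_start <- as.integer(aa_start[o]); aa_end <- as.integer(aa_end[o])
  if (any(aa_start[-1] <= aa_end[-length(aa_end)])) {
    stop("domain_map: overlapping intervals")
  }
  df <- data.frame(name = name, nt_start = (aa_start - 1L) * 3L + 1L,
                   nt_end = aa_end * 3L, aa_start = aa_start, aa_end = aa_end,
                   stringsAsFactors = FALSE)
  class(df) <- c("domain_map", "data.frame")
  df
}

#' Starch synthase III domain map
#'
#' The three annotated regions of maize SSIII: N-terminal (aa 1-768),
#' homology (aa 769-1226) and catalytic (aa 1227-1674). Nucleotide bounds
#' are derived as `3 * aa` (the stop codon falls outside all domains).
#'
#' @return a [domain_map()].
#' @export
ssiii_domain_map <- function() {
  domain_map(c("N-terminal", "homology", "catalytic"),
             aa_start = c(1L, 769L, 1227L),
             aa_end = c(768L, 1226L, 1674L))
}

#' Assign variants to protein domains
#'
#' Variants with an amino-acid position are labeled with the unique
#' containing domain; positions outside the map are labeled `"outside"`.
#' Variants without an aa position (silent, noncoding, frameshift) are
#' assigned by nucleotide position within the CDS.
#'
#' @param variants classified variant data.frame.
#' @param map a [domain_map()].
#' @return the variant data.frame with `domain` filled in.
#' @export
assign_domains <- function(variants, map) {
  stopifnot(inherits(map, "domain_map"))
  validate_variant_table(variants)
  lab_aa <- function(p) {
    hit <- which(map$aa_start <= p & p <= map$aa_end)
    if (length(hit) == 1L) map$name[hit] else "outside"
  }
  lab_nt <- function(p) {
    hit <- which(map$nt_start <= p & p <= map$nt_end)
    if (length(hit) == 1L) map$name[hit] else "outside"
  }
  for (i in seq_len(nrow(variants))) {
    variants$domain[i] <- if (!is.na(variants$aa_pos[i])) {
      lab_aa(variants$aa_pos[i])
    } else {
      lab_nt(variants$ref_pos[i])
    }
  }
  variants
}

#' Summarize a variant list
#'
#' @param variants classified variant data.frame.
#' @return named list `n_snps`, `n_silent`, `n_missense`, `n_indels`
#'   (the counts partition the list: silent + missense + noncoding SNPs =
#'   n_snps).
#' @export
summarize_alleles <- function(variants) {
  validate_variant_table(variants)
  snp <- variants$kind == "SNP"
  list(n_snps = sum(snp),
       n_silent = sum(snp & variants$effect == "silent"),
       n_missense = sum(snp & variants$effect == "missense"),
       n_indels = sum(!snp))
}
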