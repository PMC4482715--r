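# In-silico restriction analysis with IUPAC-degenerate recognition sites,
# for CAPS genotyping (e.g. the BslI site created by the Zpu1 QPM SNP).

#' Construct a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition sequence, IUPAC DNA (e.g. BslI
#'   `CCNNNNNNNGG`).
#' @param cut_offset_top top-strand cut position: the strand is cleaved
#'   after the `cut_offset_top`-th base of the site (BslI: 7, i.e.
#'   `CCNNNNN^NNGG`).
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top) {
  recognition <- toupper(recognition)
  stopifnot(nzchar(recognition), valid_dna(recognition),
            cut_offset_top >= 0, cut_offset_top <= nchar(recognition))
  structure(list(name = name, recognition = recognition,
                 cut_offset_top = as.integer(cut_offset_top)),
            class = "restriction_enzyme")
}

#' Load the bundled (or a user) restriction-enzyme table
#'
#' A self-contained CSV with columns `name, recognition, cut_offset_top`.
#'
#' @param path CSV path; default the table shipped in `extdata/enzymes.csv`.
#' @param name optional enzyme name; if given, that single enzyme is
#'   returned.
#' @return a named list of [restriction_enzyme()] objects, or one enzyme.
#' @export
load_enzymes <- function(path = NULL, name = NULL) {
  path <- path %||% system.file("extdata", "enzymes.csv", package = "svkit")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  enz <- lapply(seq_len(nrow(df)), function(i) {
    restriction_enzyme(df$name[i], df$recognition[i], df$cut_offset_top[i])
  })
  names(enz) <- df$name
  if (!is.null(name)) {
    if (!name %in% names(enz)) stop("load_enzymes: unknown enzyme '", name, "'")
    return(enz[[name]])
  }
  enz
}

# TRUE at each sequence position where `pattern` (IUPAC) matches starting
# there. A sequence ambiguity code matches a pattern position only if every
# concrete resolution of the sequence code is allowed by the pattern code
# (set-subset semantics).
iupac_match_starts <- function(seq_chars, pattern) {
  n <- length(seq_chars)
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  k <- length(pc)
  if (n < k) return(logical(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    pat_set <- IUPAC_SETS[[pc[j]]]
    allowed <- vapply(names(IUPAC_SETS),
                      function(code) all(IUPAC_SETS[[code]] %in% pat_set),
                      TRUE)
    ok <- ok & allowed[seq_chars[seq.int(j, j + n - k)]]
  }
  ok
}

#' Find restriction-site start positions
#'
#' Scans the top strand and its reverse complement for the recognition
#' pattern; overlapping sites are all reported and duplicate positions
#' (e.g. for self-reverse-complementary patterns such as BslI's) are
#' collapsed.
#'
#' @param seq [seq_record()] (DNA).
#' @param enzyme a [restriction_enzyme()].
#' @return sorted integer vector of 1-based site start positions (on the
#'   top strand; a reverse-orientation site is reported at the top-strand
#'   start of its footprint).
#' @export
find_sites <- function(seq, enzyme) {
  stopifnot(inherits(seq, "seq_record"), seq$alphabet == "DNA",
            inherits(enzyme, "restriction_enzyme"))
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  fwd <- which(iupac_match_starts(chars, enzyme$recognition))
  rcpat <- revcomp(enzyme$recognition)
  rev <- if (rcpat == enzyme$recognition) integer(0) else {
    which(iupac_match_starts(chars, rcpat))
  }
  sort(unique(c(fwd, rev)))
}

# Top-strand cut positions ("cleaved after base i") for all sites.
cut_positions <- function(seq, enzyme) {
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  klen <- nchar(enzyme$recognition)
  fwd <- which(iupac_match_starts(chars, enzyme$recognition))
  cuts <- fwd - 1L + enzyme$cut_offset_top
  rcpat <- revcomp(enzyme$recognition)
  if (rcpat != enzyme$recognition) {
    rev <- which(iupac_match_starts(chars, rcpat))
    cuts <- c(cuts, rev - 1L + (klen - enzyme$cut_offset_top))
  }
  ok <- cuts >= 1L & cuts < L
  if (any(!ok)) {
    warning("digest: ", sum(!ok), " cut position(s) at the sequence ",
            "boundary skipped")
  }
  sort(unique(cuts[ok]))
}

#' Digest a linear DNA sequence
#'
#' @param seq [seq_record()] (DNA), linear.
#' @param enzyme a [restriction_enzyme()].
#' @return object of class `digest_result` with `cut_positions` (top strand
#'   cleaved after these 1-based positions) and `fragment_lengths` in
#'   sequence order. Fragment lengths always sum to the sequence length; an
#'   uncut sequence yields one fragment.
#' @export
digest <- function(seq, enzyme) {
  cuts <- cut_positions(seq, enzyme)
  L <- seq_len_nt(seq)
  frags <- diff(c(0L, cuts, L))
  structure(list(enzyme = enzyme$name, seq_id = seq$id,
                 cut_positions = cuts, fragment_lengths = as.integer(frags)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s x %s: %d cut(s); fragments [%s] nt\n",
              x$seq_id, x$enzyme, length(x$cut_positions),
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Slice a sequence record (1-based, inclusive)
#'
#' @param seq [seq_record()].
#' @param start,end 1-based inclusive bounds.
#' @return the sliced [seq_record()].
#' @export
slice_seq <- function(seq, start, end) {
  stopifnot(start >= 1, end <= seq_len_nt(seq), start <= end)
  seq_record(sprintf("%s:%d-%d", seq$id, start, end),
             substr(seq$residues, start, end), seq$alphabet)
}

#' Restriction sites gained or lost between two alleles
#'
#' Aligns the alleles, maps the alternate's site positions into reference
#' coordinates, and reports the symmetric difference — the CAPS-marker
#' prediction.
#'
#' @param ref,alt [seq_record()] objects.
#' @param enzyme a [restriction_enzyme()].
#' @param ... scoring arguments passed to [align_global()].
#' @return list with sorted integer vectors `gained` (sites present in the
#'   alternate only, in reference coordinates) and `lost` (reference only).
#' @export
differential_sites <- function(ref, alt, enzyme, ...) {
  ref_sites <- find_sites(ref, enzyme)
  alt_sites <- find_sites(alt, enzyme)
  aln <- align_global(ref, alt, ...)
  alt_in_ref <- if (length(alt_sites)) map_alt_to_ref(aln, alt_sites) else integer(0)
  list(gained = sort(setdiff(alt_in_ref, ref_sites)),
       lost = sort(setdiff(ref_sites, alt_in_ref)))
}
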