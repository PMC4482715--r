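# Domain types shared across the pipeline. Lightweight S3, data.frame-backed
# where the natural operations are tabular (variants, phenotype panels).

#' Construct a sequence record
#'
#' A single nucleotide or protein sequence with an identifier. Residues are
#' uppercased on construction and validated against the alphabet (DNA permits
#' the full IUPAC ambiguity set).
#'
#' @param id free-text identifier (non-empty).
#' @param residues sequence string (non-empty).
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param description optional free-text description.
#' @return an object of class `seq_record` with fields `id`, `residues`,
#'   `alphabet`, `description`.
#' @examples
#' seq_record("a", "acgt")$residues  # "ACGT"
#' @export
seq_record <- function(id, residues, alphabet = c("DNA", "PROTEIN"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("seq_record: empty residues for id '", id, "'")
  ok <- if (alphabet == "DNA") valid_dna(residues) else valid_protein(residues)
  if (!ok) stop("seq_record: illegal character for alphabet ", alphabet,
                " in record '", id, "'")
  structure(list(id = id, residues = residues, alphabet = alphabet,
                 description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1, 60)
  cat(sprintf("<seq_record %s> %s %d residues\n  %s%s\n",
              x$alphabet, x$id, n, head, if (n > 60) "..." else ""))
  invisible(x)
}

seq_len_nt <- function(rec) nchar(rec$residues)

#' Construct a chain-length distribution
#'
#' The per-sample table of (degree of polymerization, percent peak area)
#' produced by fluorophore-assisted capillary electrophoresis of debranched
#' amylopectin. DP values must be unique positive integers; they are sorted
#' on construction. Areas are relative (percent) and need not sum to 100;
#' see [normalize_dist()].
#'
#' @param sample_id sample identifier.
#' @param ear replicate (ear) identifier.
#' @param dp integer vector of chain lengths (glucose units), all >= 1.
#' @param area numeric vector of percent peak areas, same length, all >= 0,
#'   at least one positive.
#' @return object of class `chain_dist` with fields `sample_id`, `ear`,
#'   `dp`, `area`.
#' @export
chain_dist <- function(sample_id, ear, dp, area) {
  stopifnot(length(dp) == length(area), length(dp) >= 1L)
  dp <- as.numeric(dp)
  area <- as.numeric(area)
  if (any(dp < 1) || any(dp != round(dp))) {
    stop("chain_dist: DP values must be integers >= 1")
  }
  if (anyDuplicated(dp)) stop("chain_dist: duplicate DP values")
  if (any(area < 0)) stop("chain_dist: negative percent area")
  if (all(area == 0)) stop("chain_dist: all areas zero")
  o <- order(dp)
  structure(list(sample_id = as.character(sample_id),
                 ear = as.character(ear),
                 dp = as.integer(dp[o]), area = area[o]),
            class = "chain_dist")
}

#' @export
print.chain_dist <- function(x, ...) {
  cat(sprintf("<chain_dist> sample %s ear %s: DP %d-%d, %d points, area sum %.4g\n",
              x$sample_id, x$ear, min(x$dp), max(x$dp), length(x$dp),
              sum(x$area)))
  invisible(x)
}

# Empty variant table with the canonical column set. Variant lists are plain
# data.frames so they round-trip through CSV and bind naturally.
empty_variant_table <- function() {
  data.frame(ref_pos = integer(0), ref_allele = character(0),
             alt_allele = character(0), kind = character(0),
             effect = character(0), aa_ref = character(0),
             aa_pos = integer(0), aa_alt = character(0),
             domain = character(0), stringsAsFactors = FALSE)
}

VARIANT_KINDS <- c("SNP", "deletion", "insertion")
VARIANT_EFFECTS <- c("silent", "missense", "in_frame_deletion",
                     "in_frame_insertion", "frameshift", "noncoding",
                     "unknown")

validate_variant_table <- function(v) {
  stopifnot(is.data.frame(v))
  need <- names(empty_variant_table())
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(v)) {
    stopifnot(all(v$kind %in% VARIANT_KINDS))
    snp <- v$kind == "SNP"
    if (any(snp & (nchar(v$ref_allele) != 1L | nchar(v$alt_allele) != 1L |
                     v$ref_allele == v$alt_allele))) {
      stop("SNP rows must have single, differing alleles")
    }
    del <- v$kind == "deletion"
    if (any(del & nzchar(v$alt_allele))) {
      stop("deletion rows must have empty alt_allele")
    }
  }
  invisible(v)
}

#' Construct a run configuration
#'
#' Bundles the knobs shared by the command-line stages: RNG seed, alignment
#' scoring, significance level and the DP window used for chain analysis.
#'
#' @param seed integer RNG seed.
#' @param match,mismatch,gap_open,gap_extend alignment scoring (see
#'   [align_global()]).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param dp_min,dp_max inclusive DP window for chain-length analysis;
#'   `dp_min` must be >= 1. Defaults 6-60, the conventional window for
#'   isoamylase-debranched amylopectin traces.
#' @param enzyme_table path to the restriction-enzyme CSV (defaults to the
#'   table shipped with the package).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, match = 1, mismatch = -2, gap_open = -6,
                       gap_extend = -1, alpha = 0.05, dp_min = 6L,
                       dp_max = 60L, enzyme_table = NULL) {
  stopifnot(alpha > 0, alpha < 1, dp_min >= 1, dp_max >= dp_min)
  structure(list(seed = as.integer(seed), match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend, alpha = alpha,
                 dp_min = as.integer(dp_min), dp_max = as.integer(dp_max),
                 enzyme_table = enzyme_table %||%
                   system.file("extdata", "enzymes.csv", package = "svkit")),
            class = "run_config")
}
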