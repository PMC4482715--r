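# Shared low-level helpers: IUPAC code sets, reverse complement, logging.

# IUPAC nucleotide codes -> set of concrete bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "*", "X", "-")

valid_dna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  all(chars %in% names(IUPAC_SETS))
}

valid_protein <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  all(chars %in% AA_LETTERS)
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented symbolically (e.g. `R` -> `Y`).
#'
#' @param x single DNA string (IUPAC alphabet).
#' @return the reverse complement as a single string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) stop("revcomp: non-IUPAC character in sequence")
  paste(comp, collapse = "")
}

# stderr logger used by the CLI layer; results never go to stderr.
svk_log <- function(fmt, ...) {
  message(sprintf(paste0("[svkit] ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
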