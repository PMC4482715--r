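# Readers/writers for the plain-text formats the pipeline touches.
# FASTA parsing is line-oriented here (rather than delegating to
# Biostrings::readDNAStringSet) so parse errors can name the offending line,
# which the CLI contract requires; alignment still uses Biostrings.

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param alphabet `"DNA"` (default) or `"PROTEIN"`.
#' @return list of [seq_record()] objects, file order preserved; an empty
#'   file yields an empty list. Residues are uppercased and whitespace
#'   stripped.
#' @details Errors name the 1-based line number of a malformed header,
#'   illegal residue character, or duplicate id.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur_id <- NULL; cur_desc <- ""; cur_chunks <- character(0); cur_line <- 0L
  flush <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    res <- paste(cur_chunks, collapse = "")
    if (!nzchar(res)) stop("read_fasta: record '", cur_id,
                           "' (line ", cur_line, ") has no residues")
    recs[[length(recs) + 1L]] <<- seq_record(cur_id, res, alphabet, cur_desc)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      flush()
      hdr <- sub("^>", "", ln)
      if (!nzchar(trimws(hdr))) stop("read_fasta: empty header at line ", i)
      parts <- strsplit(trimws(hdr), "[[:space:]]+")[[1]]
      cur_id <- parts[[1]]
      cur_desc <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
      cur_chunks <- character(0); cur_line <- i
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_id)) stop("read_fasta: sequence before header at line ", i)
      chunk <- toupper(gsub("[[:space:]]", "", ln))
      ok <- if (alphabet == "DNA") valid_dna(chunk) else valid_protein(chunk)
      if (!ok) stop("read_fasta: illegal character at line ", i)
      cur_chunks <- c(cur_chunks, chunk)
    }
  }
  flush()
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate id '", ids[duplicated(ids)][1], "'")
  }
  recs
}

#' Write sequence records to FASTA
#'
#' @param records list of [seq_record()] objects.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    res <- r$residues
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))),
               con)
  }
  invisible(path)
}

#' Read a FACE chain-length table
#'
#' The CSV must have columns `sample_id, ear, DP, percent_area`; rows are
#' grouped by (sample_id, ear) into one distribution each.
#'
#' @param path CSV path.
#' @return list of [chain_dist()] objects, one per (sample_id, ear), in
#'   first-appearance order.
#' @details Duplicate (sample_id, ear, DP) rows and negative areas are
#'   errors. Areas need not sum to 100 (normalization happens downstream).
#' @export
read_chain_table <- function(path) {
  if (!file.exists(path)) stop("read_chain_table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ear", "DP", "percent_area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_chain_table: missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(df$sample_id, df$ear, df$DP, sep = "\r")
  if (anyDuplicated(key)) {
    stop("read_chain_table: duplicate (sample_id, ear, DP) row")
  }
  if (any(df$percent_area < 0)) stop("read_chain_table: negative percent_area")
  grp <- paste(df$sample_id, df$ear, sep = "\r")
  out <- lapply(unique(grp), function(g) {
    sub <- df[grp == g, , drop = FALSE]
    chain_dist(sub$sample_id[1], sub$ear[1], sub$DP, sub$percent_area)
  })
  out
}

#' Write chain-length distributions to CSV
#'
#' @param dists list of [chain_dist()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chain_table <- function(dists, path) {
  if (inherits(dists, "chain_dist")) dists <- list(dists)
  df <- do.call(rbind, lapply(dists, function(d) {
    data.frame(sample_id = d$sample_id, ear = d$ear, DP = d$dp,
               percent_area = d$area, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

PHENOTYPE_COLS <- c("ril_id", "zpu1_allele", "ssiii_allele", "ear",
                    "vitreousness", "pullulanase_a490", "onset_c", "max_c",
                    "enthalpy")

#' Read a RIL phenotype/genotype panel
#'
#' One row per RIL x ear replicate. Allele columns are restricted to
#' `"Q"` (QPM-derived) and `"W"` (W64Ao2-derived). Missing phenotype cells
#' are permitted (NA) and counted in the `n_missing` attribute.
#'
#' @param path CSV path with columns
#'   `ril_id, zpu1_allele, ssiii_allele, ear, vitreousness,
#'   pullulanase_a490, onset_c, max_c, enthalpy`.
#' @return data.frame of class `ril_panel`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("read_phenotypes: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(PHENOTYPE_COLS, names(df))
  if (length(miss)) stop("read_phenotypes: missing column(s): ",
                         paste(miss, collapse = ", "))
  as_ril_panel(df)
}

# Validate and class a phenotype data.frame.
as_ril_panel <- function(df) {
  bad <- !(df$zpu1_allele %in% c("Q", "W")) | !(df$ssiii_allele %in% c("Q", "W"))
  if (any(bad)) stop("phenotype panel: allele values must be 'Q' or 'W' (row ",
                     which(bad)[1], ")")
  num_cols <- setdiff(PHENOTYPE_COLS, c("ril_id", "zpu1_allele",
                                        "ssiii_allele", "ear"))
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  attr(df, "n_missing") <- sum(is.na(df[num_cols]))
  class(df) <- c("ril_panel", "data.frame")
  df
}

#' Write a RIL phenotype panel to CSV
#'
#' @param panel data.frame as returned by [read_phenotypes()] or
#'   [simulate_ril_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[PHENOTYPE_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Genotype class label ("Q-W" etc.) for panel rows.
genotype_class <- function(panel) {
  paste(panel$zpu1_allele, panel$ssiii_allele, sep = "-")
}
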