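# Synthetic data with the statistical structure the downstream analyses
# assume: near-identical allele pairs with planted variants, FACE-like
# bimodal chain-length distributions whose parameters depend on a 2x2
# Zpu1/SSIII genotype class, and RIL panels where vitreousness follows an
# exponential function of chain dispersity.

STOP_CODONS <- c("TAA", "TAG", "TGA")
GENOTYPE_CLASSES <- c("Q-Q", "Q-W", "W-Q", "W-W")

#' Specification for a simulated allele pair
#'
#' @param length CDS length in nt, divisible by 3 (treated as a CDS from
#'   position 1, ATG...stop).
#' @param n_snps total SNPs to plant.
#' @param n_silent how many of the SNPs must be synonymous
#'   (`n_silent <= n_snps`); the rest are missense (never nonsense).
#' @param indel_lengths lengths (nt) of deletions to plant; multiples of 3
#'   give in-frame, codon-aligned deletions.
#' @param seed optional RNG seed used by [simulate_allele_pair()].
#' @return object of class `allele_sim_spec`.
#' @export
allele_sim_spec <- function(length = 300L, n_snps = 4L, n_silent = 3L,
                            indel_lengths = integer(0), seed = NULL) {
  stopifnot(length %% 3 == 0, length >= 30, n_snps >= 0,
            n_silent >= 0, n_silent <= n_snps)
  structure(list(length = as.integer(length), n_snps = as.integer(n_snps),
                 n_silent = as.integer(n_silent),
                 indel_lengths = as.integer(indel_lengths), seed = seed),
            class = "allele_sim_spec")
}

# Random CDS: ATG, random non-stop codons, one stop.
random_cds <- function(length) {
  ncod <- length %/% 3L
  all_codons <- Biostrings::GENETIC_CODE
  sense <- names(all_codons)[!names(all_codons) %in% STOP_CODONS]
  body <- sample(sense, ncod - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# Synonymous third-position alternatives for a codon ("" if none).
synonymous_alts <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  third <- substr(codon, 3, 3)
  alts <- setdiff(c("A", "C", "G", "T"), third)
  cand <- paste0(substr(codon, 1, 2), alts)
  alts[code[cand] == code[codon]]
}

#' Simulate a reference/alternate allele pair with known variants
#'
#' The reference is a random CDS (ATG start, stop end, no internal stops);
#' the alternate differs from it by exactly the planted variant set, which
#' is returned as ground truth in reference coordinates (deletions
#' left-normalized, so truth matches [call_variants()] output exactly).
#' Planted positions fall in distinct, non-adjacent codons, hence >= 3 nt
#' apart.
#'
#' @param spec an [allele_sim_spec()].
#' @param max_tries retries before declaring the spec infeasible.
#' @return list with `ref`, `alt` ([seq_record()]s) and `truth` (a
#'   classified variant data.frame).
#' @export
simulate_allele_pair <- function(spec, max_tries = 100L) {
  stopifnot(inherits(spec, "allele_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (any(spec$indel_lengths %% 3 != 0)) {
    stop("simulate_allele_pair: only in-frame (multiple-of-3) deletions ",
         "are supported")
  }
  for (try in seq_len(max_tries)) {
    res <- try_plant_variants(spec)
    if (!is.null(res)) return(res)
  }
  stop("simulate_allele_pair: infeasible spec (could not place ",
       spec$n_snps, " SNPs / ", length(spec$indel_lengths),
       " indels after ", max_tries, " tries)")
}

try_plant_variants <- function(spec) {
  code <- Biostrings::GENETIC_CODE
  ref_seq <- random_cds(spec$length)
  ncod <- spec$length %/% 3L
  codons <- substring(ref_seq, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  used <- rep(FALSE, ncod)   # codon blocked for further planting
  used[c(1L, ncod)] <- TRUE  # keep start/stop intact
  block <- function(idx) {
    lo <- max(1L, min(idx) - 1L); hi <- min(ncod, max(idx) + 1L)
    used[lo:hi] <<- TRUE
  }
  events <- list()

  # in-frame deletions: whole codons removed. Candidate positions where the
  # deletion cannot left-shift (preceding base != last deleted base) keep
  # the planted event codon-aligned under left-normalization, so truth and
  # caller coordinates agree exactly.
  rc <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  for (k in spec$indel_lengths) {
    m <- k %/% 3L
    cand <- which(!vapply(seq_len(ncod - m + 1L), function(j) {
      p <- 3L * (j - 1L) + 1L
      any(used[j:(j + m - 1L)]) || (p > 1L && rc[p - 1L] == rc[p + k - 1L])
    }, TRUE))
    if (!length(cand)) return(NULL)
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    block(j:(j + m - 1L))
    events[[length(events) + 1L]] <-
      list(kind = "deletion", codon = j, nt_pos = 3L * (j - 1L) + 1L,
           ref_allele = paste(codons[j:(j + m - 1L)], collapse = ""),
           alt_allele = "")
  }

  # silent SNPs at third positions with a synonymous alternative
  for (s in seq_len(spec$n_silent)) {
    cand <- which(!used & vapply(codons,
                                 function(cd) length(synonymous_alts(cd)) > 0,
                                 TRUE))
    if (!length(cand)) return(NULL)
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    block(j)
    alts <- synonymous_alts(codons[j])
    alt <- if (length(alts) == 1L) alts else sample(alts, 1L)
    events[[length(events) + 1L]] <-
      list(kind = "SNP", codon = j, nt_pos = 3L * (j - 1L) + 3L,
           ref_allele = substr(codons[j], 3, 3), alt_allele = alt)
  }

  # missense SNPs: substitution changing the amino acid, never to a stop
  for (s in seq_len(spec$n_snps - spec$n_silent)) {
    placed <- FALSE
    cand <- which(!used)
    for (j in sample(cand)) {
      for (pos in sample(1:3)) {
        ref_b <- substr(codons[j], pos, pos)
        for (alt_b in sample(setdiff(c("A", "C", "G", "T"), ref_b))) {
          alt_codon <- codons[j]
          substr(alt_codon, pos, pos) <- alt_b
          if (code[alt_codon] != code[codons[j]] &&
              !alt_codon %in% STOP_CODONS) {
            block(j)
            events[[length(events) + 1L]] <-
              list(kind = "SNP", codon = j, nt_pos = 3L * (j - 1L) + pos,
                   ref_allele = ref_b, alt_allele = alt_b)
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (placed) break
    }
    if (!placed) return(NULL)
  }

  ref <- seq_record("sim_ref", ref_seq, "DNA")
  if (!length(events)) {
    truth <- empty_variant_table()
    return(list(ref = ref, alt = seq_record("sim_alt", ref_seq, "DNA"),
                truth = truth))
  }
  truth <- data.frame(
    ref_pos = vapply(events, `[[`, 0, "nt_pos"),
    ref_allele = vapply(events, `[[`, "", "ref_allele"),
    alt_allele = vapply(events, `[[`, "", "alt_allele"),
    kind = vapply(events, `[[`, "", "kind"),
    effect = "unknown", aa_ref = NA_character_, aa_pos = NA_integer_,
    aa_alt = NA_character_, domain = NA_character_, stringsAsFactors = FALSE)
  # left-normalize planted deletions so truth matches caller conventions
  for (i in which(truth$kind == "deletion")) {
    ev <- normalize_deletion(ref_seq, truth$ref_pos[i], truth$ref_allele[i])
    truth$ref_pos[i] <- ev$ref_pos
    truth$ref_allele[i] <- ev$ref_allele
  }
  truth <- truth[order(truth$ref_pos), , drop = FALSE]
  rownames(truth) <- NULL
  alt <- apply_variants(ref, truth)
  alt$id <- "sim_alt"
  truth <- classify_effects(truth, ref)
  list(ref = ref, alt = alt, truth = truth)
}

#' Default per-genotype chain-mixture parameters
#'
#' Two discretized lognormal components over integer DP: a short A-chain
#' mode and a long B-chain tail. Only the long-tail weight differs between
#' genotype classes; the default ordering of mean chain length is
#' W-Q > \{Q-Q, Q-W\} > W-W, mirroring the observed genotype ordering of
#' average chain length.
#'
#' @return named list (one entry per class `Q-Q, Q-W, W-Q, W-W`) of lists
#'   with `short_meanlog, short_sdlog, long_meanlog, long_sdlog,
#'   weight_short`.
#' @export
default_chain_params <- function() {
  base <- list(short_meanlog = log(12.5), short_sdlog = 0.30,
               long_meanlog = log(38), long_sdlog = 0.22)
  w_long <- c("Q-Q" = 0.22, "Q-W" = 0.22, "W-Q" = 0.30, "W-W" = 0.15)
  out <- lapply(w_long, function(w) c(base, list(weight_short = 1 - w)))
  names(out) <- names(w_long)
  out
}

#' Specification for a simulated RIL panel
#'
#' Defaults state the emulated world: 14 recombinant inbred lines with
#' three ears each; vitreousness responding exponentially to chain
#' dispersity with growth rate 4 (the center of the plausible range for
#' this system); pullulanase activity correlating with vitreousness at a
#' population R-squared of 0.38.
#'
#' @param n_ril number of RILs (>= 4; all four genotype classes are always
#'   represented).
#' @param ears_per_ril replicate ears per RIL (default 3).
#' @param chain_params per-class mixture parameters
#'   ([default_chain_params()]).
#' @param dp_min,dp_max DP support of simulated distributions (default
#'   6-60).
#' @param bin_noise_sd lognormal per-bin measurement noise (sd on the log
#'   scale) applied to each FACE trace before renormalization.
#' @param vit_amplitude,vit_growth amplitude a and growth rate r of the
#'   vitreousness response `V = a * exp(r * PDI)` (pixel-intensity units).
#' @param vit_noise_sd additive Gaussian noise on vitreousness (truncated
#'   at 0).
#' @param pull_intercept,pull_slope affine map from vitreousness to
#'   pullulanase A490.
#' @param pull_r2 target population R-squared of pullulanase ~ vitreousness,
#'   in (0, 1).
#' @param seed optional RNG seed.
#' @return object of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(n_ril = 14L, ears_per_ril = 3L,
                           chain_params = default_chain_params(),
                           dp_min = 6L, dp_max = 60L, bin_noise_sd = 0.05,
                           vit_amplitude = 0.15, vit_growth = 4.0,
                           vit_noise_sd = 5, pull_intercept = 0.1,
                           pull_slope = 0.004, pull_r2 = 0.38, seed = NULL) {
  stopifnot(n_ril >= 4, ears_per_ril >= 1, vit_growth > 0, vit_noise_sd >= 0,
            bin_noise_sd >= 0, dp_min >= 1, dp_max > dp_min)
  if (!(pull_r2 > 0 && pull_r2 < 1)) {
    stop("panel_sim_spec: target R-squared must be in (0, 1)")
  }
  for (cl in GENOTYPE_CLASSES) {
    p <- chain_params[[cl]]
    if (is.null(p)) stop("panel_sim_spec: missing chain parameters for ", cl)
    if (p$weight_short < 0 || p$weight_short > 1) {
      stop("panel_sim_spec: mixture weight outside [0, 1]")
    }
  }
  structure(list(n_ril = as.integer(n_ril),
                 ears_per_ril = as.integer(ears_per_ril),
                 chain_params = chain_params, dp_min = as.integer(dp_min),
                 dp_max = as.integer(dp_max), bin_noise_sd = bin_noise_sd,
                 vit_amplitude = vit_amplitude, vit_growth = vit_growth,
                 vit_noise_sd = vit_noise_sd, pull_intercept = pull_intercept,
                 pull_slope = pull_slope, pull_r2 = pull_r2, seed = seed),
            class = "panel_sim_spec")
}

# Discretized lognormal over integer DP; sdlog == 0 degenerates to a point
# mass at round(exp(meanlog)).
component_density <- function(dp, meanlog, sdlog) {
  if (sdlog == 0) {
    as.numeric(dp == round(exp(meanlog)))
  } else {
    stats::dlnorm(dp, meanlog = meanlog, sdlog = sdlog)
  }
}

#' Simulate one FACE-like chain-length distribution
#'
#' A two-component mixture (short A-chain mode plus long B-chain tail)
#' discretized over integer DP, with per-bin lognormal measurement noise,
#' normalized so areas sum to 100.
#'
#' @param class genotype class, one of `"Q-Q", "Q-W", "W-Q", "W-W"`.
#' @param spec a [panel_sim_spec()].
#' @param sample_id,ear identifiers for the resulting [chain_dist()].
#' @param seed optional RNG seed (the panel simulator leaves this NULL and
#'   drives everything from one stream).
#' @return a [chain_dist()].
#' @export
simulate_chain_distribution <- function(class, spec, sample_id = class,
                                        ear = "1", seed = NULL) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  class <- match.arg(class, GENOTYPE_CLASSES)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$chain_params[[class]]
  dp <- spec$dp_min:spec$dp_max
  if (!length(dp)) stop("simulate_chain_distribution: empty DP support")
  dens <- p$weight_short * component_density(dp, p$short_meanlog, p$short_sdlog) +
    (1 - p$weight_short) * component_density(dp, p$long_meanlog, p$long_sdlog)
  if (spec$bin_noise_sd > 0) {
    dens <- dens * exp(stats::rnorm(length(dp), 0, spec$bin_noise_sd))
  }
  if (sum(dens) <= 0) stop("simulate_chain_distribution: degenerate density")
  area <- 100 * dens / sum(dens)
  keep <- area > 0
  chain_dist(sample_id, ear, dp[keep], area[keep])
}

#' Simulate a RIL phenotype panel with chain-length distributions
#'
#' Each RIL is assigned a genotype class (round-robin, so all four classes
#' are always represented). For every RIL x ear a chain distribution is
#' drawn for its class; vitreousness is `a * exp(r * PDI)` plus truncated
#' Gaussian noise; pullulanase A490 is an affine function of vitreousness
#' with noise calibrated so the population R-squared matches the target;
#' DSC phenotypes get class-dependent means mirroring the observed genotype
#' contrasts.
#'
#' @param spec a [panel_sim_spec()].
#' @return list with `panel` (a `ril_panel` data.frame, one row per
#'   RIL x ear), `chains` (list of [chain_dist()]), and `truth` (all
#'   generating parameters, for recovery tests).
#' @export
simulate_ril_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  classes <- GENOTYPE_CLASSES[(seq_len(spec$n_ril) - 1L) %% 4L + 1L]
  ril_ids <- sprintf("RIL%03d", seq_len(spec$n_ril))

  rows <- list(); chains <- list()
  for (i in seq_len(spec$n_ril)) {
    for (e in seq_len(spec$ears_per_ril)) {
      d <- simulate_chain_distribution(classes[i], spec,
                                       sample_id = ril_ids[i],
                                       ear = as.character(e))
      chains[[length(chains) + 1L]] <- d
      pdi_e <- pdi(d)
      vit <- spec$vit_amplitude * exp(spec$vit_growth * pdi_e)
      if (spec$vit_noise_sd > 0) {
        vit <- max(0, vit + stats::rnorm(1, 0, spec$vit_noise_sd))
      }
      dsc <- dsc_means(classes[i])
      rows[[length(rows) + 1L]] <- data.frame(
        ril_id = ril_ids[i],
        zpu1_allele = substr(classes[i], 1, 1),
        ssiii_allele = substr(classes[i], 3, 3),
        ear = as.character(e),
        vitreousness = vit,
        pullulanase_a490 = NA_real_,
        onset_c = stats::rnorm(1, dsc["onset"], 0.5),
        max_c = stats::rnorm(1, dsc["max"], 0.5),
        enthalpy = stats::rnorm(1, dsc["enthalpy"], 0.6),
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)

  # pullulanase: affine in vitreousness, noise sd solved from the target
  # population R^2 (R^2 = var(signal) / (var(signal) + sd_e^2))
  signal <- spec$pull_intercept + spec$pull_slope * panel$vitreousness
  sd_sig <- stats::sd(signal)
  sd_e <- if (sd_sig > 0) {
    sd_sig * sqrt((1 - spec$pull_r2) / spec$pull_r2)
  } else 0
  panel$pullulanase_a490 <- signal + stats::rnorm(nrow(panel), 0, sd_e)
  panel <- as_ril_panel(panel)

  truth <- list(classes = stats::setNames(classes, ril_ids),
                vit_amplitude = spec$vit_amplitude,
                vit_growth = spec$vit_growth,
                vit_noise_sd = spec$vit_noise_sd,
                pull_intercept = spec$pull_intercept,
                pull_slope = spec$pull_slope, pull_noise_sd = sd_e,
                pull_r2 = spec$pull_r2,
                chain_params = spec$chain_params)
  list(panel = panel, chains = chains, truth = truth)
}

# Class-dependent DSC means (degrees C, J/g) mirroring the observed
# contrasts: Q-W hottest onset/max; enthalpy ordered W-Q > Q-W ~ W-W > Q-Q.
dsc_means <- function(class) {
  onset <- c("Q-Q" = 63.0, "Q-W" = 66.0, "W-Q" = 63.5, "W-W" = 63.2)
  maxt <- c("Q-Q" = 69.0, "Q-W" = 72.0, "W-Q" = 69.5, "W-W" = 69.2)
  enth <- c("Q-Q" = 9.5, "Q-W" = 10.8, "W-Q" = 12.0, "W-W" = 10.5)
  c(onset = onset[[class]], max = maxt[[class]], enthalpy = enth[[class]])
}
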