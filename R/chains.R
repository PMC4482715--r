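# Moments of glucan chain-length distributions and the dispersity index.
#
# With DP the chain length and A the percent peak area of each chain species
# (area is proportional to labeled-chain counts in a FACE trace):
#   number-average DP  x_n = sum(A * DP) / sum(A)
#   mass-average DP    x_w = sum(A * DP^2) / sum(A * DP)
#   dispersity (PDI)   D_X = x_w / x_n  >= 1, with equality iff monodisperse.
# All three are homogeneous of degree 0 in A, so normalization never changes
# them.

#' Rescale areas to sum to 100
#'
#' @param dist a [chain_dist()].
#' @return the distribution with `sum(area) == 100` (DP untouched).
#' @export
normalize_dist <- function(dist) {
  stopifnot(inherits(dist, "chain_dist"))
  tot <- sum(dist$area)
  if (tot <= 0) stop("normalize_dist: total area is zero")
  dist$area <- dist$area * (100 / tot)
  dist
}

#' Number-average degree of polymerization
#' @param dist a [chain_dist()].
#' @return `sum(A * DP) / sum(A)`.
#' @export
number_average_dp <- function(dist) {
  stopifnot(inherits(dist, "chain_dist"))
  sum(dist$area * dist$dp) / sum(dist$area)
}

#' Mass-average degree of polymerization
#' @param dist a [chain_dist()].
#' @return `sum(A * DP^2) / sum(A * DP)`.
#' @export
mass_average_dp <- function(dist) {
  stopifnot(inherits(dist, "chain_dist"))
  w <- dist$area * dist$dp
  sum(w * dist$dp) / sum(w)
}

#' Dispersity index of a chain-length distribution
#'
#' The ratio of mass-average to number-average DP (a.k.a. polydispersity
#' index); 1 for monodisperse chains, larger for broader distributions.
#'
#' @param dist a [chain_dist()].
#' @return `mass_average_dp(dist) / number_average_dp(dist)`.
#' @export
pdi <- function(dist) {
  mass_average_dp(dist) / number_average_dp(dist)
}

#' Average glucan chain length
#'
#' Reported as the number-average DP (the only unweighted mean the moment
#' definitions provide); switch `kind` to use the mass-average instead.
#'
#' @param dist a [chain_dist()].
#' @param kind `"number"` (default) or `"mass"`.
#' @return average chain length in glucose units.
#' @export
acl <- function(dist, kind = c("number", "mass")) {
  kind <- match.arg(kind)
  if (kind == "number") number_average_dp(dist) else mass_average_dp(dist)
}

#' Restrict a distribution to a DP window
#'
#' Rows outside `[dp_min, dp_max]` are dropped with a warning (FACE traces
#' of debranched amylopectin are conventionally analyzed from DP 6 up).
#'
#' @param dist a [chain_dist()].
#' @param dp_min,dp_max inclusive bounds (defaults 6 and 60).
#' @return the windowed distribution.
#' @export
window_dist <- function(dist, dp_min = 6L, dp_max = 60L) {
  keep <- dist$dp >= dp_min & dist$dp <= dp_max
  if (!all(keep)) {
    warning(sprintf("window_dist: dropping %d row(s) outside DP %d-%d",
                    sum(!keep), dp_min, dp_max))
    if (!any(keep)) stop("window_dist: no rows left in DP window")
    dist$dp <- dist$dp[keep]; dist$area <- dist$area[keep]
  }
  dist
}

#' Summarize replicate distributions for one sample
#'
#' Moments are computed per ear and then averaged arithmetically (the
#' replicate-mean path: the mean of per-ear dispersities, not the
#' dispersity of pooled areas).
#'
#' @param replicates list of [chain_dist()] objects sharing a `sample_id`.
#' @return object of class `dist_summary`: a list with `sample_id`,
#'   `per_ear` (data.frame: ear, x_n, x_w, pdi, acl) and `mean` (named
#'   vector of the per-ear means).
#' @export
summarize_sample <- function(replicates) {
  if (inherits(replicates, "chain_dist")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1L)
  ids <- unique(vapply(replicates, `[[`, "", "sample_id"))
  if (length(ids) != 1L) {
    stop("summarize_sample: mixed sample_ids: ", paste(ids, collapse = ", "))
  }
  per_ear <- do.call(rbind, lapply(replicates, function(d) {
    data.frame(ear = d$ear, x_n = number_average_dp(d),
               x_w = mass_average_dp(d), pdi = pdi(d), acl = acl(d),
               stringsAsFactors = FALSE)
  }))
  structure(list(sample_id = ids,
                 per_ear = per_ear,
                 mean = colMeans(per_ear[c("x_n", "x_w", "pdi", "acl")])),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("<dist_summary> %s (%d ears): x_n %.3f, x_w %.3f, PDI %.4f\n",
              x$sample_id, nrow(x$per_ear), x$mean["x_n"], x$mean["x_w"],
              x$mean["pdi"]))
  invisible(x)
}

#' Summarize every sample in a chain table
#'
#' @param dists list of [chain_dist()] (e.g. from [read_chain_table()]).
#' @param dp_min,dp_max DP window applied per distribution; NULL disables
#'   windowing.
#' @return data.frame with one row per (sample_id, ear) plus per-sample
#'   mean rows (`ear == "mean"`), columns `sample_id, ear, x_n, x_w, pdi,
#'   acl`.
#' @export
summarize_chain_table <- function(dists, dp_min = 6L, dp_max = 60L) {
  if (!is.null(dp_min)) {
    dists <- lapply(dists, window_dist, dp_min = dp_min, dp_max = dp_max)
  }
  ids <- vapply(dists, `[[`, "", "sample_id")
  out <- lapply(unique(ids), function(sid) {
    s <- summarize_sample(dists[ids == sid])
    rbind(cbind(sample_id = sid, s$per_ear, stringsAsFactors = FALSE),
          data.frame(sample_id = sid, ear = "mean", x_n = s$mean[["x_n"]],
                     x_w = s$mean[["x_w"]], pdi = s$mean[["pdi"]],
                     acl = s$mean[["acl"]], stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
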