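# The statistical battery: slope ANOVA for correlations, pairwise-t and
# Tukey HSD compact letter displays, and nonlinear exponential regression of
# vitreousness on chain dispersity with a growth-rate confidence interval.

#' Test a linear association by ANOVA of the slope
#'
#' Ordinary least squares of `y` on `x`; the p-value is from the F statistic
#' on (1, n - 2) df for slope = 0 (equivalently the squared t-test of the
#' Pearson correlation).
#'
#' @param x,y numeric vectors of equal length >= 3 (NA pairs dropped);
#'   `x` must not be constant.
#' @return object of class `slope_test` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
slope_anova <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("slope_anova: need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("slope_anova: x is constant")
  fit <- stats::lm(y ~ x)
  an <- stats::anova(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 p_value = an[["Pr(>F)"]][1],
                 n = n),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("<slope_test> slope %.4g, R^2 = %.4f, F-test p = %.4g (n = %d)\n",
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

# Pairwise two-tailed two-sample t-tests with pooled variance; returns a
# symmetric p-value matrix.
pairwise_t_matrix <- function(groups) {
  k <- length(groups)
  labs <- names(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- groups[[i]]; xj <- groups[[j]]
      ni <- length(xi); nj <- length(xj)
      sp2 <- ((ni - 1) * stats::var(xi) + (nj - 1) * stats::var(xj)) /
        (ni + nj - 2)
      se <- sqrt(sp2 * (1 / ni + 1 / nj))
      pv <- if (se == 0) {
        if (mean(xi) == mean(xj)) 1 else 0
      } else {
        tt <- (mean(xi) - mean(xj)) / se
        2 * stats::pt(-abs(tt), df = ni + nj - 2)
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  diag(p) <- 1
  p
}

# Tukey-Kramer adjusted p-values from a one-way layout (studentized range).
tukey_p_matrix <- function(groups) {
  k <- length(groups)
  labs <- names(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  df <- N - k
  if (df < 1) stop("tukey_hsd: no residual degrees of freedom")
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      pv <- if (se == 0) {
        if (mean(groups[[i]]) == mean(groups[[j]])) 1 else 0
      } else {
        q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
        stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  diag(p) <- 1
  p
}

# Drop letter columns whose membership is a subset of (or equal to, keeping
# the earlier copy) another column's.
absorb_columns <- function(cols) {
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) {
    if (!keep[a]) next
    for (b in seq_along(cols)) {
      if (a == b || !keep[b]) next
      if (all(cols[[a]] <= cols[[b]]) &&
          (!identical(cols[[a]], cols[[b]]) || a > b)) {
        keep[a] <- FALSE
        break
      }
    }
  }
  cols[keep]
}

# Compact letter display by insert-and-absorb on a significance matrix.
# Guarantees: two groups share a letter iff their pairwise test is
# non-significant at alpha. Groups are processed in decreasing mean order
# and letters assigned in that order.
cld_from_pmatrix <- function(p, means, alpha) {
  labs <- names(means)
  ord <- order(means, decreasing = TRUE)
  labs <- labs[ord]
  p <- p[labs, labs, drop = FALSE]
  k <- length(labs)
  cols <- list(rep(TRUE, k))   # letter columns: membership vectors
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (p[i, j] >= alpha) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      cols <- absorb_columns(cols)
    }
  }
  # order columns by first member, then assign letters a, b, c, ...
  first <- vapply(cols, function(cc) which(cc)[1], 0)
  cols <- cols[order(first)]
  letters_used <- letters[seq_along(cols)]
  lab_letters <- vapply(seq_len(k), function(i) {
    paste(letters_used[vapply(cols, `[`, TRUE, i)], collapse = "")
  }, "")
  stats::setNames(lab_letters, labs)
}

new_letter_grouping <- function(letters_map, p_matrix, means, alpha, method) {
  structure(list(letters = letters_map, p_matrix = p_matrix, means = means,
                 alpha = alpha, method = method),
            class = "letter_grouping")
}

#' @export
print.letter_grouping <- function(x, ...) {
  cat(sprintf("<letter_grouping> %s at alpha = %g\n", x$method, x$alpha))
  for (g in names(x$letters)) {
    cat(sprintf("  %-8s mean %10.4g  %s\n", g, x$means[[g]], x$letters[[g]]))
  }
  invisible(x)
}

check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            !is.null(names(groups)), all(nzchar(names(groups))))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2)) {
    stop("letter display: every group needs n >= 2")
  }
  groups
}

#' Compact letter display from unadjusted pairwise t-tests
#'
#' All pairwise two-tailed two-sample t-tests with pooled variance and no
#' multiplicity correction ("each pair t test"), then an insert-and-absorb
#' compact letter display: groups share a letter iff not significantly
#' different at `alpha`. Letters follow decreasing group means.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param alpha significance level (default 0.05).
#' @return object of class `letter_grouping` with `letters` (named letter
#'   strings), `p_matrix`, `means`.
#' @export
pairwise_t_letters <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  p <- pairwise_t_matrix(groups)
  means <- vapply(groups, mean, 0)
  new_letter_grouping(cld_from_pmatrix(p, means, alpha), p, means, alpha,
                      "pairwise t (pooled variance, unadjusted)")
}

#' Tukey HSD with compact letter display
#'
#' Studentized-range (Tukey-Kramer) adjusted p-values for all pairs from a
#' one-way layout, plus the same letter display as
#' [pairwise_t_letters()].
#'
#' @inheritParams pairwise_t_letters
#' @return a `letter_grouping` whose `p_matrix` holds adjusted p-values.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  p <- tukey_p_matrix(groups)
  means <- vapply(groups, mean, 0)
  new_letter_grouping(cld_from_pmatrix(p, means, alpha), p, means, alpha,
                      "Tukey HSD")
}

#' Fit an exponential growth curve V = a * exp(r * x)
#'
#' Nonlinear least squares (Gauss-Newton via [stats::nls()], port-algorithm
#' fallback), initialized from the log-linear regression of `log(pmax(y,
#' eps))` on `x`. The 95% growth-rate interval is the approximate Wald
#' interval `r +/- t(0.975, n - 2) * SE(r)`; the relationship is declared
#' significantly positive when that interval excludes 0.
#'
#' @param x predictor (e.g. chain dispersity), not all equal; length >= 4.
#' @param y response (e.g. kernel vitreousness, nonnegative).
#' @param conf_level confidence level for the growth-rate interval.
#' @return object of class `exp_growth_fit`: `amplitude`, `growth_rate`,
#'   `ci` (lower, upper), `se_growth`, `residual_se`, `converged`,
#'   `iterations`, `n`.
#' @export
fit_exponential_growth <- function(x, y, conf_level = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("fit_exponential_growth: need n >= 4")
  if (stats::sd(x) == 0) stop("fit_exponential_growth: x values all equal")
  eps <- max(1e-8, 1e-6 * max(abs(y)))
  lfit <- stats::lm(log(pmax(y, eps)) ~ x)
  start <- list(a = exp(unname(stats::coef(lfit)[1])),
                r = unname(stats::coef(lfit)[2]))
  df <- data.frame(x = x, y = y)
  ctrl <- stats::nls.control(maxiter = 200, scaleOffset = 1, warnOnly = FALSE)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(r * x), data = df, start = start, control = ctrl),
    error = function(e) tryCatch(
      stats::nls(y ~ a * exp(r * x), data = df, start = start,
                 algorithm = "port", control = ctrl),
      error = function(e2) NULL))
  if (is.null(fit)) {
    return(structure(list(amplitude = start$a, growth_rate = start$r,
                          ci = c(NA_real_, NA_real_), se_growth = NA_real_,
                          residual_se = NA_real_, converged = FALSE,
                          iterations = NA_integer_, n = n),
                     class = "exp_growth_fit"))
  }
  cf <- stats::coef(fit)
  se_r <- sqrt(stats::vcov(fit)["r", "r"])
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  structure(list(amplitude = unname(cf["a"]), growth_rate = unname(cf["r"]),
                 ci = unname(cf["r"]) + c(-1, 1) * tq * se_r,
                 se_growth = se_r,
                 residual_se = summary(fit)$sigma,
                 converged = fit$convInfo$isConv %||% TRUE,
                 iterations = fit$convInfo$finIter %||% NA_integer_,
                 n = n),
            class = "exp_growth_fit")
}

#' @export
print.exp_growth_fit <- function(x, ...) {
  cat(sprintf(paste0("<exp_growth_fit> V = %.4g * exp(%.4g * x); ",
                     "95%% CI of growth rate [%.4f, %.4f]%s (n = %d)\n"),
              x$amplitude, x$growth_rate, x$ci[1], x$ci[2],
              if (isTRUE(x$converged)) "" else " [NOT converged]", x$n))
  invisible(x)
}

#' Run the full association battery on a RIL panel
#'
#' Reproduces the study's statistical report: (i) pullulanase ~
#' vitreousness slope ANOVA; (ii) four-genotype-class letter displays for
#' pullulanase, DSC onset, DSC maximum, enthalpy and average chain length;
#' (iii) average chain length ~ PDI slope ANOVA; (iv) exponential fit of
#' vitreousness on PDI; (v) pullulanase ~ density/hardness slope tests when
#' those columns exist. Group means and regressions use RIL means (each RIL
#' first averaged over its ears) by default.
#'
#' @param panel a `ril_panel` data.frame ([read_phenotypes()] /
#'   [simulate_ril_panel()]).
#' @param chains list of [chain_dist()] whose `sample_id`s are the panel's
#'   `ril_id`s.
#' @param alpha significance level (default 0.05).
#' @param level `"ril"` (default: analyses on RIL means) or `"ear"` (all
#'   replicate-level points).
#' @return list of class `association_report`; see components in Details.
#' @details Components: `pull_vs_vitreousness` (`slope_test`),
#'   `letters` (named list of `letter_grouping` for `pullulanase_a490`,
#'   `onset_c`, `max_c`, `enthalpy`, `acl`), `acl_vs_pdi` (`slope_test`),
#'   `vitreousness_vs_pdi` (`exp_growth_fit`), optional `pull_vs_density` /
#'   `pull_vs_hardness`, and `data` (the merged per-RIL table used).
#' @export
run_association_suite <- function(panel, chains, alpha = 0.05,
                                  level = c("ril", "ear")) {
  level <- match.arg(level)
  if (!nrow(panel)) stop("run_association_suite: empty panel")
  need <- PHENOTYPE_COLS
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("run_association_suite: missing column(s): ",
                         paste(miss, collapse = ", "))
  csum <- summarize_chain_table(chains, dp_min = NULL)
  ear_rows <- csum[csum$ear != "mean", ]
  merged <- merge(as.data.frame(panel), ear_rows,
                  by.x = c("ril_id", "ear"), by.y = c("sample_id", "ear"))
  if (!nrow(merged)) {
    stop("run_association_suite: no (ril_id, ear) overlap between panel ",
         "and chain summaries")
  }
  merged$class <- genotype_class(merged)

  if (level == "ril") {
    agg_cols <- c("vitreousness", "pullulanase_a490", "onset_c", "max_c",
                  "enthalpy", "x_n", "x_w", "pdi", "acl",
                  intersect(c("density", "hardness"), names(merged)))
    dat <- stats::aggregate(merged[agg_cols],
                            by = list(ril_id = merged$ril_id,
                                      class = merged$class),
                            FUN = mean, na.rm = TRUE)
  } else {
    dat <- merged
  }

  by_class <- function(col) split(dat[[col]], dat$class)
  letters <- lapply(c(pullulanase_a490 = "pullulanase_a490",
                      onset_c = "onset_c", max_c = "max_c",
                      enthalpy = "enthalpy", acl = "acl"),
                    function(col) pairwise_t_letters(by_class(col), alpha))

  report <- list(
    pull_vs_vitreousness = slope_anova(dat$vitreousness,
                                       dat$pullulanase_a490),
    letters = letters,
    acl_vs_pdi = slope_anova(dat$pdi, dat$acl),
    vitreousness_vs_pdi = fit_exponential_growth(dat$pdi, dat$vitreousness),
    alpha = alpha, level = level, data = dat)
  for (extra in c("density", "hardness")) {
    if (extra %in% names(dat)) {
      report[[paste0("pull_vs_", extra)]] <-
        slope_anova(dat[[extra]], dat$pullulanase_a490)
    }
  }
  class(report) <- "association_report"
  report
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("<association_report> %d RIL-level rows, alpha = %g\n",
              nrow(x$data), x$alpha))
  cat("pullulanase ~ vitreousness: "); print(x$pull_vs_vitreousness)
  cat("acl ~ PDI:                  "); print(x$acl_vs_pdi)
  cat("vitreousness ~ PDI:         "); print(x$vitreousness_vs_pdi)
  for (nm in names(x$letters)) {
    cat(nm, ":\n", sep = ""); print(x$letters[[nm]])
  }
  invisible(x)
}
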