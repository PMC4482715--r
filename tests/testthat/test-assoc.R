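test_that("slope_anova recovers exact fits and rejects bad input", {
  x <- 1:5
  st <- suppressWarnings(slope_anova(x, 2 * x))  # exact fit warns in lm
  expect_equal(st$slope, 2)
  expect_equal(st$r_squared, 1)
  expect_error(slope_anova(rep(1, 5), rnorm(5)), "constant")
  expect_error(slope_anova(1:2, 1:2), "at least 3")
})

test_that("slope F-test equals the squared Pearson correlation t-test", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- 0.5 * x + rnorm(15)
    st <- slope_anova(x, y)
    ct <- cor.test(x, y)
    expect_equal(st$p_value, ct$p.value, tolerance = 1e-10)
    expect_equal(st$r_squared, unname(ct$estimate)^2, tolerance = 1e-10)
  }
})

test_that("pairwise t letter displays match expectations", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  lg <- pairwise_t_letters(g)
  expect_equal(unname(lg$letters), c("a", "a"))

  set.seed(53)
  g2 <- list(lo = rnorm(10, 0, 1), hi = rnorm(10, 100, 1))
  lg2 <- pairwise_t_letters(g2)
  expect_setequal(unname(lg2$letters), c("a", "b"))

  # three groups where only the extremes differ -> a, ab, b
  set.seed(55)
  repeat {
    g3 <- list(low = rnorm(8, 0, 2), mid = rnorm(8, 2, 2),
               high = rnorm(8, 4, 2))
    p <- svkit:::pairwise_t_matrix(g3)
    if (p["low", "high"] < 0.05 && p["low", "mid"] >= 0.05 &&
        p["mid", "high"] >= 0.05) break
  }
  lg3 <- pairwise_t_letters(g3)
  expect_equal(unname(lg3$letters[c("high", "mid", "low")]),
               c("a", "ab", "b"))

  expect_error(pairwise_t_letters(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("letter displays satisfy the share-letter biconditional", {
  set.seed(57)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    g <- setNames(lapply(seq_len(k), function(j) {
      rnorm(sample(3:8, 1), mean = sample(0:3, 1))
    }), paste0("g", seq_len(k)))
    expect_true(cld_is_sound(pairwise_t_letters(g)), info = i)
    expect_true(cld_is_sound(tukey_hsd(g)), info = i)
  }
})

test_that("Tukey HSD is conservative relative to unadjusted t-tests", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  th <- tukey_hsd(g)
  expect_equal(unname(th$letters), c("a", "a"))
  expect_true(all(th$p_matrix >= 0.99))

  # guaranteed form of the conservativeness property: against the
  # unadjusted t-test computed from the same one-way MSE and df (LSD),
  # ptukey(q, k, df) >= 2 * pt(-q / sqrt(2), df) for every k >= 2
  set.seed(59)
  for (i in 1:20) {
    g3 <- setNames(lapply(1:3, function(j) rnorm(6, j / 2)), c("a", "b", "c"))
    pth <- svkit:::tukey_p_matrix(g3)
    ns <- lengths(g3)
    df <- sum(ns) - 3
    mse <- sum(vapply(g3, function(g) sum((g - mean(g))^2), 0)) / df
    ms <- vapply(g3, mean, 0)
    for (a in 1:2) for (b in (a + 1):3) {
      se <- sqrt(mse * (1 / ns[a] + 1 / ns[b]))
      p_lsd <- 2 * pt(-abs(ms[a] - ms[b]) / se, df)
      expect_gte(pth[a, b], p_lsd - 1e-12)
    }
  }
})

test_that("Tukey HSD family-wise error stays near nominal under the null", {
  set.seed(61)
  fwer <- mean(replicate(500, {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    p <- svkit:::tukey_p_matrix(g)
    any(p[upper.tri(p)] < 0.05)
  }))
  expect_lte(fwer, 0.07)
})

test_that("exponential fit recovers noiseless parameters exactly", {
  set.seed(63)
  x <- runif(20, 1.1, 1.6)
  y <- 2 * exp(4 * x)
  fit <- fit_exponential_growth(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$amplitude - 2) / 2, 1e-6)
  expect_lt(abs(fit$growth_rate - 4) / 4, 1e-6)
  expect_true(fit$ci[1] < 4 && 4 < fit$ci[2])
  expect_lt(fit$ci[1], fit$ci[2])
})

test_that("constant response gives a growth rate indistinguishable from 0", {
  set.seed(65)
  x <- runif(12, 1, 2)
  fit <- fit_exponential_growth(x, rep(5, 12))
  expect_lt(abs(fit$growth_rate), 1e-6)
  expect_true(is.na(fit$ci[1]) || (fit$ci[1] <= 0 && fit$ci[2] >= 0))
  expect_error(fit_exponential_growth(rep(1, 5), rnorm(5)), "all equal")
  expect_error(fit_exponential_growth(1:3, 1:3), "n >= 4")
})

test_that("run_association_suite wires the panel through every analysis", {
  set.seed(67)
  sim <- simulate_ril_panel(panel_sim_spec(n_ril = 24, seed = 67))
  rep <- run_association_suite(sim$panel, sim$chains)
  expect_s3_class(rep, "association_report")
  expect_named(rep$letters, c("pullulanase_a490", "onset_c", "max_c",
                              "enthalpy", "acl"))
  # generator plants positive associations; slope tests must find them
  expect_lt(rep$pull_vs_vitreousness$p_value, 0.05)
  expect_lt(rep$acl_vs_pdi$p_value, 0.05)
  expect_gt(rep$acl_vs_pdi$slope, 0)
  # the DSC contrasts separate the extreme classes
  expect_true(cld_is_sound(rep$letters$onset_c))
  expect_false(any(strsplit(rep$letters$acl$letters[["W-Q"]], "")[[1]] %in%
                     strsplit(rep$letters$acl$letters[["W-W"]], "")[[1]]))
  # extra columns trigger the optional slope tests
  panel2 <- sim$panel
  panel2$density <- rnorm(nrow(panel2), 1.2, 0.05)
  rep2 <- run_association_suite(panel2, sim$chains)
  expect_s3_class(rep2$pull_vs_density, "slope_test")

  expect_error(run_association_suite(sim$panel[0, ], sim$chains), "empty")
})

test_that("shuffled vitreousness removes the exponential signal", {
  set.seed(69)
  sim <- simulate_ril_panel(panel_sim_spec(n_ril = 14, seed = 69))
  dat <- run_association_suite(sim$panel, sim$chains)$data
  contains0 <- mean(replicate(200, {
    fit <- fit_exponential_growth(dat$pdi, sample(dat$vitreousness))
    is.na(fit$ci[1]) || (fit$ci[1] <= 0 && fit$ci[2] >= 0)
  }))
  expect_gte(contains0, 0.9)
})
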