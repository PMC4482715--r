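test_that("simulate_allele_pair plants exactly the requested variants", {
  sim <- simulate_allele_pair(allele_sim_spec(length = 300, n_snps = 4,
                                              n_silent = 3, seed = 42))
  s <- summarize_alleles(sim$truth)
  expect_equal(s, list(n_snps = 4, n_silent = 3, n_missense = 1,
                       n_indels = 0))
  # reference is a clean CDS: ATG start, one terminal stop
  prot <- translate_cds(sim$ref)$residues
  expect_match(prot, "^M[^*]+\\*$")
  # alternate differs from reference exactly by the truth set
  expect_equal(apply_variants(sim$ref, sim$truth)$residues,
               sim$alt$residues)
})

test_that("empty spec yields identical alleles and empty truth", {
  sim <- simulate_allele_pair(allele_sim_spec(n_snps = 0, n_silent = 0,
                                              seed = 1))
  expect_equal(sim$ref$residues, sim$alt$residues)
  expect_equal(nrow(sim$truth), 0)
})

test_that("in-frame deletion changes the translation by one residue", {
  for (seed in 1:20) {
    sim <- simulate_allele_pair(allele_sim_spec(length = 300, n_snps = 0,
                                                n_silent = 0,
                                                indel_lengths = 3L,
                                                seed = seed))
    expect_equal(sim$truth$kind, "deletion")
    expect_equal(sim$truth$effect, "in_frame_deletion")
    # translate-and-diff oracle: alt protein is ref protein minus 1 residue
    pr <- strsplit(translate_cds(sim$ref)$residues, "")[[1]]
    pa <- strsplit(translate_cds(sim$alt)$residues, "")[[1]]
    expect_equal(length(pr) - length(pa), 1)
    k <- sim$truth$aa_pos[1]
    expect_equal(pa, pr[-k])
  }
})

test_that("planted variants are >= 3 nt apart, deterministic under seed", {
  for (seed in 1:25) {
    spec <- allele_sim_spec(length = 450, n_snps = 6, n_silent = 3,
                            indel_lengths = 3L, seed = seed)
    sim <- simulate_allele_pair(spec)
    expect_true(all(diff(sort(sim$truth$ref_pos)) >= 3))
  }
  s1 <- simulate_allele_pair(allele_sim_spec(seed = 99))
  s2 <- simulate_allele_pair(allele_sim_spec(seed = 99))
  expect_identical(s1, s2)
})

test_that("infeasible allele specs error after bounded retries", {
  # 96 nt = 32 codons, 30 usable; demanding 31 separated SNPs cannot fit
  expect_error(
    simulate_allele_pair(allele_sim_spec(length = 96, n_snps = 31,
                                         n_silent = 0, seed = 1),
                         max_tries = 5),
    "infeasible")
})

test_that("simulated chain distributions are valid normalized mixtures", {
  spec <- panel_sim_spec(seed = 1)
  d <- simulate_chain_distribution("Q-Q", spec, seed = 5)
  expect_s3_class(d, "chain_dist")
  expect_true(all(d$area >= 0))
  expect_equal(sum(d$area), 100, tolerance = 1e-9)
  expect_true(all(d$dp >= spec$dp_min & d$dp <= spec$dp_max))
})

test_that("degenerate mixture weight gives a monodisperse distribution", {
  params <- default_chain_params()
  for (cl in names(params)) {
    params[[cl]]$weight_short <- 1
    params[[cl]]$short_sdlog <- 0
    params[[cl]]$short_meanlog <- log(15)
  }
  spec <- panel_sim_spec(chain_params = params, bin_noise_sd = 0)
  d <- simulate_chain_distribution("W-W", spec, seed = 1)
  expect_equal(sum(d$area > 0), 1)
  expect_equal(pdi(d), 1)
  expect_equal(d$dp[d$area > 0], 15)
})

test_that("identical parameters and seed give identical distributions", {
  params <- default_chain_params()
  params[["Q-Q"]] <- params[["W-W"]]
  spec <- panel_sim_spec(chain_params = params)
  d1 <- simulate_chain_distribution("Q-Q", spec, seed = 31)
  d2 <- simulate_chain_distribution("W-W", spec, seed = 31)
  expect_equal(d1$area, d2$area)
})

test_that("configured effect direction: mean DP of W-Q exceeds W-W", {
  set.seed(123)
  spec <- panel_sim_spec()
  hits <- replicate(1000, {
    number_average_dp(simulate_chain_distribution("W-Q", spec)) >
      number_average_dp(simulate_chain_distribution("W-W", spec))
  })
  expect_gt(mean(hits), 0.99)
})

test_that("noiseless panels satisfy the exact response model", {
  sim <- simulate_ril_panel(panel_sim_spec(n_ril = 6, vit_noise_sd = 0,
                                           seed = 8))
  pdis <- vapply(sim$chains, pdi, 0)
  expected <- sim$truth$vit_amplitude * exp(sim$truth$vit_growth * pdis)
  expect_equal(sim$panel$vitreousness, expected, tolerance = 1e-12)
})

test_that("panel R-squared calibration hits the target window", {
  set.seed(77)
  sim <- simulate_ril_panel(panel_sim_spec(n_ril = 200, pull_r2 = 0.38))
  st <- slope_anova(sim$panel$vitreousness, sim$panel$pullulanase_a490)
  expect_gt(st$r_squared, 0.30)
  expect_lt(st$r_squared, 0.46)
})

test_that("panels are deterministic under a seed and vary across seeds", {
  p1 <- simulate_ril_panel(panel_sim_spec(seed = 4))
  p2 <- simulate_ril_panel(panel_sim_spec(seed = 4))
  p3 <- simulate_ril_panel(panel_sim_spec(seed = 5))
  expect_identical(p1, p2)
  expect_false(identical(p1$panel$vitreousness, p3$panel$vitreousness))
  # all four genotype classes always represented
  expect_setequal(unique(svkit:::genotype_class(p1$panel)),
                  c("Q-Q", "Q-W", "W-Q", "W-W"))
})

test_that("invalid panel specs are rejected", {
  expect_error(panel_sim_spec(pull_r2 = 1.2), "R-squared")
  expect_error(panel_sim_spec(n_ril = 3), "n_ril")
  expect_error(panel_sim_spec(vit_growth = -1))
})
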