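# Build a sumstats table whose chi-square statistics equal a chosen function
# of the LD scores exactly (noise-free regression input).
exact_chi2_sumstats <- function(ld, n, chi2, sex = "female") {
  v <- tibble::as_tibble(ld)
  rec <- data.frame(variant_id = v$variant_id, chr = v$chr, pos = v$pos,
                    ea = "A", oa = "G",
                    beta = sqrt(chi2) * 0.01, se = 0.01,
                    p = 2 * stats::pnorm(-sqrt(chi2)), n = n, eaf = 0.5)
  make_ss(rec, sex = sex)
}

test_that("the regression recovers a noise-free heritability exactly", {
  ld <- ld_scores(simulate_ld(sim_config(m_snps = 2000, n_blocks = 100,
                                         block_corr = 0.6, seed = 1)))
  n <- 40000
  h2 <- 0.25
  chi2 <- 1 + n * h2 * ld$l2 / attr(ld, "M")
  s <- exact_chi2_sumstats(ld, n, chi2)
  est <- ldsc_h2(s, ld, n_blocks = 50)
  expect_equal(est$value, 0.25, tolerance = 1e-10)
  expect_equal(est$intercept, 1, tolerance = 1e-10)
  expect_equal(est$se, 0, tolerance = 1e-8)

  # constant chi2 against constant l: slope zero
  ld0 <- ld_scores(simulate_ld(sim_config(m_snps = 1000, n_blocks = 100,
                                          block_corr = 0, seed = 1)))
  s0 <- exact_chi2_sumstats(ld0, n, rep(1, 1000))
  est0 <- ldsc_h2(s0, ld0, n_blocks = 50)
  expect_equal(est0$value, 0, tolerance = 1e-12)

  expect_error(ldsc_h2(s, ld, n_blocks = 2000), "n_blocks")
})

test_that("the null heritability estimate is covered by its jackknife SE", {
  hits <- vapply(1:40, function(seed) {
    st <- simulate_study(sim_config(m_snps = 5000, n_blocks = 250,
                                    block_corr = 0.5, h2_f = 0, h2_m = 0,
                                    n_f = 20000, n_m = 20000, seed = seed))
    e <- ldsc_h2(st$female, st$ld, n_blocks = 100)
    abs(e$value) < 2 * e$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("jackknife and analytic sandwich SEs broadly agree", {
  ratios <- vapply(1:20, function(seed) {
    st <- simulate_study(sim_config(m_snps = 5000, n_blocks = 250,
                                    block_corr = 0.3, h2_f = 0.3, h2_m = 0.3,
                                    n_f = 30000, n_m = 30000, seed = seed))
    e <- ldsc_h2(st$female, st$ld, n_blocks = 100)
    e$se / e$se_analytic
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.25)
})

test_that("liability-scale conversion matches the closed form", {
  expect_equal(liability_multiplier(0.5, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(liability_multiplier(0.01, 0.5), 0.5519, tolerance = 1e-4)

  e <- structure(list(value = 0.1, se = 0.02, kind = "h2_obs",
                      intercept = 1, intercept_se = 0.01, n_snps = 1000L,
                      n_blocks = 200L, scale_meta = NULL, flag = NA_character_),
                 class = "ldsc_estimate")
  liab <- obs_to_liability(e, K = 0.01, P = 0.5)
  expect_equal(liab$value, 0.0552, tolerance = 1e-3)
  expect_equal(liab$kind, "h2_liab")
  expect_equal(liab$scale_meta, list(K = 0.01, P = 0.5))

  # zero stays zero; the transformation is linear in the estimate
  e0 <- e; e0$value <- 0
  expect_equal(obs_to_liability(e0, 0.1, 0.4)$value, 0)
  e2 <- e; e2$value <- 3 * e$value
  expect_equal(obs_to_liability(e2, 0.1, 0.4)$value,
               3 * obs_to_liability(e, 0.1, 0.4)$value)

  expect_error(obs_to_liability(e, K = 0, P = 0.5), "between 0 and 1")
  expect_error(obs_to_liability(e, K = 0.1, P = 1), "between 0 and 1")
})

test_that("genetic correlation is 1 for self-pairs and symmetric in arguments", {
  st <- simulate_study(sim_config(m_snps = 4000, n_blocks = 200,
                                  block_corr = 0.5, h2_f = 0.3, h2_m = 0.3,
                                  rg_mf = 0.6, n_f = 30000, n_m = 30000,
                                  seed = 8))
  self <- ldsc_rg(st$female, st$female, st$ld, n_blocks = 100)
  expect_equal(self$value, 1, tolerance = 1e-10)

  ab <- ldsc_rg(st$female, st$male, st$ld, n_blocks = 100)
  ba <- ldsc_rg(st$male, st$female, st$ld, n_blocks = 100)
  expect_equal(ab$value, ba$value, tolerance = 1e-10)
  expect_equal(ab$se, ba$se, tolerance = 1e-8)
})

test_that("rg is flagged undefined when a heritability is non-positive", {
  ld <- ld_scores(simulate_ld(sim_config(m_snps = 2000, n_blocks = 100,
                                         block_corr = 0, seed = 1)))
  # noise-free null trait: slope exactly 0
  s_null <- exact_chi2_sumstats(ld, 20000, rep(1, 2000))
  s_sig <- exact_chi2_sumstats(ld, 20000, 1 + 20000 * 0.2 * ld$l2 / 2000,
                               sex = "male")
  e <- ldsc_rg(s_null, s_sig, ld, n_blocks = 50)
  expect_true(is.na(e$value))
  expect_equal(e$flag, "h2_nonpositive")
})

test_that("the one-tailed rg < 1 test matches its closed form", {
  t1 <- rg_lt1_test(0.92, 0.02)
  expect_equal(t1$z, 4)
  expect_equal(t1$p, 3.167e-5, tolerance = 1e-3)

  expect_equal(rg_lt1_test(1, 0.1)$z, 0)
  expect_equal(rg_lt1_test(1, 0.1)$p, 0.5)

  over <- rg_lt1_test(1.21, 0.1)  # estimates above 1 can never reject
  expect_lt(over$z, 0)
  expect_gt(over$p, 0.5)
})

test_that("identical male and female pairs give a zero rg difference", {
  st <- make_cross_trait_study(m_snps = 3000, n_blocks = 150, seed = 21)
  rd <- rg_diff_jackknife(st$t1f, st$t2f, st$t1f, st$t2f, st$ld,
                          n_blocks = 100)
  expect_equal(rd$diff, 0)
  expect_equal(rd$z, 0)
})

test_that("the rg difference test calibrates under equal sharing and detects
           opposite sharing", {
  null_z <- vapply(1:15, function(seed) {
    st <- make_cross_trait_study(m_snps = 4000, n_blocks = 200,
                                 rg_cross_f = 0.4, rg_cross_m = 0.4,
                                 rg_within = 1, seed = seed)
    rg_diff_jackknife(st$t1f, st$t2f, st$t1m, st$t2m, st$ld, n_blocks = 100)$z
  }, numeric(1))
  expect_gte(mean(abs(null_z) < 1.96), 0.8)

  alt_p <- vapply(1:10, function(seed) {
    st <- make_cross_trait_study(m_snps = 4000, n_blocks = 200, h2 = 0.4,
                                 n_per_sex = 200000,
                                 rg_cross_f = 0.5, rg_cross_m = -0.5,
                                 rg_within = 0, seed = seed + 100)
    rg_diff_jackknife(st$t1f, st$t2f, st$t1m, st$t2m, st$ld, n_blocks = 100)$p
  }, numeric(1))
  expect_gte(mean(alt_p < 0.05), 0.9)
})
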