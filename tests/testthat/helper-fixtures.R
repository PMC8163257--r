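# In-code fixture builders shared across the test files.

# Compare two tables column-wise, ignoring classes and metadata attributes.
expect_same_table <- function(a, b) {
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "row.names", "class")]
    x
  }
  testthat::expect_equal(strip(a), strip(b))
}

make_records <- function(n = 5, chr = 1L, pos = NULL, beta = 0.1, se = 0.05,
                         eaf = 0.3, ea = "A", oa = "G", ids = NULL) {
  beta <- rep_len(beta, n)
  se <- rep_len(se, n)
  data.frame(
    variant_id = if (is.null(ids)) paste0("rs", seq_len(n)) else ids,
    chr = rep_len(chr, n),
    pos = if (is.null(pos)) seq_len(n) * 1000 else pos,
    ea = rep_len(ea, n), oa = rep_len(oa, n),
    beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n = rep(1000, n), eaf = rep_len(eaf, n)
  )
}

make_ss <- function(records, sex = "female", trait_label = "trait",
                    trait_type = "continuous", ...) {
  new_sumstats(records, trait_label = trait_label, sex = sex,
               trait_type = trait_type, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-trait, two-sex synthetic study with controllable cross-trait effect
# correlations. Within each trait the two sexes share identical true effects
# when rg_within = 1; with rg_within = 0 the sexes are independent. Cross-sex
# cross-trait correlation is rg_within * rg_cross (product structure keeps the
# 4 x 4 effect covariance positive semidefinite).
make_cross_trait_study <- function(m_snps = 5000, n_blocks = 250,
                                   block_corr = 0.7, h2 = 0.3,
                                   n_per_sex = 50000,
                                   rg_cross_f = 0.4, rg_cross_m = 0.4,
                                   rg_within = 1, seed = 1L) {
  base <- sim_config(m_snps = m_snps, n_blocks = n_blocks,
                     block_corr = block_corr, h2_f = h2, h2_m = h2,
                     n_f = n_per_sex, n_m = n_per_sex, seed = seed)
  ld <- simulate_ld(base)
  m <- base$m_snps
  v <- h2 / m
  set.seed(seed + 7L)
  # shared/specific factor construction for the 4 effect vectors
  g1 <- rnorm(m); g2 <- rnorm(m); e1 <- rnorm(m); e2 <- rnorm(m)
  mix <- function(rc, ga, gb) {
    # pair with correlation rc from independent standard normals
    list(a = ga, b = rc * ga + sqrt(1 - rc^2) * gb)
  }
  f <- mix(rg_cross_f, g1, g2)
  mm <- if (rg_within == 1) mix(rg_cross_m, g1, g2) else mix(rg_cross_m, e1, e2)
  b <- list(t1f = sqrt(v) * f$a, t2f = sqrt(v) * f$b,
            t1m = sqrt(v) * mm$a, t2m = sqrt(v) * mm$b)

  truth_for <- function(bf, bm, seed_offset) {
    cfg <- base
    cfg$seed <- as.integer(seed + seed_offset)
    structure(list(config = cfg, ld = ld, beta_f = bf, beta_m = bm,
                   causal = seq_len(m),
                   realized_h2_f = NA_real_, realized_h2_m = NA_real_,
                   realized_rg = NA_real_),
              class = "sim_truth")
  }
  tr1 <- truth_for(b$t1f, b$t1m, 100L)
  tr2 <- truth_for(b$t2f, b$t2m, 200L)
  list(ld = ld_scores(ld),
       t1f = simulate_sumstats(tr1, "female"),
       t1m = simulate_sumstats(tr1, "male"),
       t2f = simulate_sumstats(tr2, "female"),
       t2m = simulate_sumstats(tr2, "male"))
}
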