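#' @title LD score regression estimates
#' @description Internal constructor for estimate objects carrying a value,
#'   its block-jackknife SE, and provenance.
#' @noRd
new_ldsc_estimate <- function(value, se, kind, intercept = NA_real_,
                              intercept_se = NA_real_, n_snps = NA_integer_,
                              n_blocks = NA_integer_, scale_meta = NULL,
                              flag = NA_character_, extra = list()) {
  structure(c(list(value = value, se = se, kind = kind,
                   intercept = intercept, intercept_se = intercept_se,
                   n_snps = n_snps, n_blocks = n_blocks,
                   scale_meta = scale_meta, flag = flag), extra),
            class = "ldsc_estimate")
}

#' @export
print.ldsc_estimate <- function(x, ...) {
  cat(sprintf("LDSC estimate [%s]: %.4g (SE %.4g)\n", x$kind, x$value, x$se))
  if (is.finite(x$intercept)) {
    cat(sprintf("  intercept: %.4g (SE %.4g)\n", x$intercept, x$intercept_se))
  }
  if (!is.null(x$scale_meta)) {
    cat(sprintf("  liability scale: K = %g, P = %g\n",
                x$scale_meta$K, x$scale_meta$P))
  }
  cat(sprintf("  %d SNPs, %d jackknife blocks\n", x$n_snps, x$n_blocks))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

# Weighted least squares of y on x with an intercept, via sufficient sums.
# Returns c(intercept, slope).
wls_coef <- function(sw, swx, swy, swxx, swxy) {
  denom <- sw * swxx - swx^2
  # zero-variance regressor (constant l2): slope is identically zero
  slope <- if (abs(denom) <= 1e-12 * sw * swxx) 0 else
    (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  unname(c(intercept, slope))
}

# Per-block sufficient statistics for WLS; columns w, wx, wy, wxx, wxy.
wls_block_sums <- function(x, y, w, blocks) {
  rowsum(cbind(w, w * x, w * y, w * x * x, w * x * y), blocks)
}

# Delete-one-block slopes and intercepts from block sums.
wls_jackknife <- function(S) {
  tot <- colSums(S)
  del <- sweep(-S, 2, tot, "+")
  denom <- del[, 1] * del[, 4] - del[, 2]^2
  degenerate <- abs(denom) <= 1e-12 * del[, 1] * del[, 4]
  slope <- ifelse(degenerate, 0,
                  (del[, 1] * del[, 5] - del[, 2] * del[, 3]) / denom)
  intercept <- (del[, 3] - slope * del[, 2]) / del[, 1]
  slope <- unname(slope)
  intercept <- unname(intercept)
  list(slope = slope, intercept = intercept,
       full = wls_coef(tot[1], tot[2], tot[3], tot[4], tot[5]))
}

unweighted_slope <- function(x, y) {
  vx <- stats::var(x)
  if (vx == 0) return(0)
  stats::cov(x, y) / vx
}

# LDSC regression weights: 1/max(l, 1) LD correction times an inverse squared
# heteroscedasticity term from a pre-fit heritability guess.
ldsc_weights_h2 <- function(l2, n, M, h2_guess) {
  h2g <- min(max(h2_guess, 0), 1)
  1 / pmax(l2, 1) / (1 + n * h2g * l2 / M)^2
}

align_sumstats_ld <- function(s, ld) {
  d <- dplyr::inner_join(as_tibble(s)[c("variant_id", "chr", "pos", "beta",
                                        "se", "n")],
                         as_tibble(ld)[c("variant_id", "l2")],
                         by = "variant_id")
  if (nrow(d) == 0) abort("summary statistics and LD scores share no variants")
  dplyr::arrange(d, .data$chr, .data$pos)
}

#' SNP-heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics (beta/se)^2 on N_j l_j / M with
#' a free intercept; the slope is observed-scale SNP-heritability and the
#' intercept absorbs confounding and sample overlap (1 under a clean polygenic
#' model). Weights combine the 1/max(l_j, 1) LD correction with an inverse
#' squared heteroscedasticity term based on an unweighted pre-fit, a
#' single-pass approximation to the two-step LDSC estimator. Standard errors
#' come from a delete-one-block jackknife over `n_blocks` contiguous genomic
#' blocks of near-equal variant count.
#'
#' @param s A `sumstats` object, already filtered (MAF, autosomes, HLA).
#' @param ld An `ld_scores` table with attribute `M`.
#' @param n_blocks Jackknife block count (default 200).
#' @return An `ldsc_estimate` of kind `h2_obs`; also carries the analytic
#'   (sandwich) SE as `se_analytic`.
#' @export
ldsc_h2 <- function(s, ld, n_blocks = 200) {
  stopifnot(inherits(s, "sumstats"))
  d <- align_sumstats_ld(s, ld)
  if (nrow(d) < 2 * n_blocks) {
    abort("fewer than 2 * n_blocks variants after intersection")
  }
  M <- attr(ld, "M") %||% nrow(ld)
  chi2 <- (d$beta / d$se)^2
  x <- d$n * d$l2 / M
  w <- ldsc_weights_h2(d$l2, mean(d$n), M, unweighted_slope(x, chi2))

  blocks <- assign_blocks(d$chr, d$pos, n_blocks)
  S <- wls_block_sums(x, chi2, w, blocks)
  jk <- wls_jackknife(S)

  fit <- jk$full
  res <- chi2 - fit[1] - fit[2] * x
  # heteroscedasticity-robust sandwich SE for the WLS slope
  xc <- x - sum(w * x) / sum(w)
  bread <- sum(w * xc^2)
  se_analytic <- sqrt(sum((w * xc * res)^2)) / bread

  new_ldsc_estimate(value = fit[2], se = jackknife_se(jk$slope),
                    kind = "h2_obs", intercept = fit[1],
                    intercept_se = jackknife_se(jk$intercept),
                    n_snps = nrow(d), n_blocks = n_blocks,
                    extra = list(se_analytic = se_analytic,
                                 jack_values = jk$slope))
}

#' Observed-to-liability scale conversion factor
#'
#' c = K^2 (1-K)^2 / (P (1-P) phi(t)^2) with t = qnorm(1-K), the standard
#' transformation for case-control ascertainment under the liability
#' threshold model.
#'
#' @param K Population prevalence in (0, 1).
#' @param P Sample case fraction in (0, 1).
#' @return The multiplicative conversion factor.
#' @export
liability_multiplier <- function(K, P) {
  if (any(K <= 0 | K >= 1) || any(P <= 0 | P >= 1)) {
    abort("K and P must lie strictly between 0 and 1")
  }
  t <- qnorm(1 - K)
  K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(t)^2)
}

#' Convert an observed-scale heritability estimate to the liability scale
#'
#' @param e An `ldsc_estimate` of kind `h2_obs`.
#' @param K Population prevalence.
#' @param P Sample case fraction.
#' @return An `ldsc_estimate` of kind `h2_liab` carrying `(K, P)`.
#' @export
obs_to_liability <- function(e, K, P) {
  stopifnot(inherits(e, "ldsc_estimate"))
  if (e$kind != "h2_obs") abort("input must be an observed-scale h2 estimate")
  cmul <- liability_multiplier(K, P)
  new_ldsc_estimate(value = e$value * cmul, se = e$se * cmul,
                    kind = "h2_liab", intercept = e$intercept,
                    intercept_se = e$intercept_se, n_snps = e$n_snps,
                    n_blocks = e$n_blocks, scale_meta = list(K = K, P = P),
                    flag = e$flag)
}

# Core cross-trait LDSC engine on aligned vectors. Returns full estimates and
# delete-one-block values of rg on a shared block assignment.
rg_engine <- function(z1, z2, n1, n2, l2, M, blocks) {
  chi1 <- z1^2
  chi2 <- z2^2
  y12 <- z1 * z2
  x1 <- n1 * l2 / M
  x2 <- n2 * l2 / M
  x12 <- sqrt(n1 * n2) * l2 / M

  h1g <- min(max(unweighted_slope(x1, chi1), 0), 1)
  h2g <- min(max(unweighted_slope(x2, chi2), 0), 1)
  base <- 1 / pmax(l2, 1)
  w1 <- base / (1 + n1 * h1g * l2 / M)^2
  w2 <- base / (1 + n2 * h2g * l2 / M)^2
  w12 <- base / ((1 + n1 * h1g * l2 / M) * (1 + n2 * h2g * l2 / M))

  jk1 <- wls_jackknife(wls_block_sums(x1, chi1, w1, blocks))
  jk2 <- wls_jackknife(wls_block_sums(x2, chi2, w2, blocks))
  jk12 <- wls_jackknife(wls_block_sums(x12, y12, w12, blocks))

  h2_1 <- jk1$full[2]
  h2_2 <- jk2$full[2]
  gencov <- jk12$full[2]
  rg <- if (h2_1 > 0 && h2_2 > 0) gencov / sqrt(h2_1 * h2_2) else NaN
  # delete-one h2 products can dip below zero in noisy blocks; those
  # pseudovalues are dropped downstream
  rg_del <- suppressWarnings(jk12$slope / sqrt(jk1$slope * jk2$slope))
  list(rg = rg, rg_del = rg_del, h2_1 = h2_1, h2_2 = h2_2,
       gencov = gencov, gencov_intercept = jk12$full[1],
       gencov_intercept_se = jackknife_se(jk12$intercept),
       h2_se_1 = jackknife_se(jk1$slope), h2_se_2 = jackknife_se(jk2$slope))
}

align_pair_ld <- function(s1, s2, ld) {
  d <- dplyr::inner_join(
    as_tibble(s1)[c("variant_id", "chr", "pos", "beta", "se", "n")],
    as_tibble(s2)[c("variant_id", "beta", "se", "n")],
    by = "variant_id", suffix = c("_1", "_2"))
  d <- dplyr::inner_join(d, as_tibble(ld)[c("variant_id", "l2")],
                         by = "variant_id")
  if (nrow(d) == 0) abort("inputs share no variants")
  dplyr::arrange(d, .data$chr, .data$pos)
}

#' Genetic correlation by cross-trait LD score regression
#'
#' Regresses the product of per-variant z scores on sqrt(N1 N2) l_j / M with a
#' free intercept (which absorbs phenotypic correlation in overlapping
#' samples); the slope is the genetic covariance. rg = gencov /
#' sqrt(h2_1 h2_2) with both heritabilities estimated on the same variants and
#' blocks, and the SE of the full ratio comes from a delete-one-block
#' jackknife. Estimates are never clipped to [-1, 1].
#'
#' @param s1,s2 `sumstats` objects (two sexes of one trait, or two traits
#'   within one sex).
#' @param ld An `ld_scores` table.
#' @param n_blocks Jackknife block count (default 200).
#' @return An `ldsc_estimate` of kind `rg`, flagged (value `NA`) when either
#'   heritability estimate is non-positive.
#' @export
ldsc_rg <- function(s1, s2, ld, n_blocks = 200) {
  d <- align_pair_ld(s1, s2, ld)
  if (nrow(d) < 2 * n_blocks) {
    abort("fewer than 2 * n_blocks variants after intersection")
  }
  M <- attr(ld, "M") %||% nrow(ld)
  blocks <- assign_blocks(d$chr, d$pos, n_blocks)
  eng <- rg_engine(d$beta_1 / d$se_1, d$beta_2 / d$se_2,
                   d$n_1, d$n_2, d$l2, M, blocks)

  if (!is.finite(eng$rg) || eng$h2_1 <= 0 || eng$h2_2 <= 0) {
    return(new_ldsc_estimate(value = NA_real_, se = NA_real_, kind = "rg",
                             n_snps = nrow(d), n_blocks = n_blocks,
                             flag = "h2_nonpositive",
                             extra = list(h2_1 = eng$h2_1, h2_2 = eng$h2_2,
                                          gencov = eng$gencov)))
  }
  new_ldsc_estimate(value = eng$rg, se = jackknife_se(eng$rg_del), kind = "rg",
                    intercept = eng$gencov_intercept,
                    intercept_se = eng$gencov_intercept_se,
                    n_snps = nrow(d), n_blocks = n_blocks,
                    extra = list(h2_1 = eng$h2_1, h2_2 = eng$h2_2,
                                 h2_se_1 = eng$h2_se_1, h2_se_2 = eng$h2_se_2,
                                 gencov = eng$gencov,
                                 jack_values = eng$rg_del))
}

#' One-tailed test that a genetic correlation is below one
#'
#' z = (1 - rg) / SE compared with the upper tail of the standard normal: a
#' small p indicates the between-sex genetic correlation is significantly
#' less than 1, i.e. genuine heterogeneity of genetic effects.
#'
#' @param e An `ldsc_estimate` of kind `rg` (or a numeric rg value).
#' @param se Standard error, required when `e` is numeric.
#' @return A one-row tibble with `rg`, `se`, `z`, `p`.
#' @export
rg_lt1_test <- function(e, se = NULL) {
  if (inherits(e, "ldsc_estimate")) {
    if (e$kind != "rg") abort("input must be an rg estimate")
    rg <- e$value; se <- e$se
  } else {
    rg <- e
    if (is.null(se)) abort("se is required with a numeric rg")
  }
  if (!is.finite(rg) || !is.finite(se) || se <= 0) {
    return(tibble(rg = rg, se = se, z = NA_real_, p = NA_real_))
  }
  z <- (1 - rg) / se
  tibble(rg = rg, se = se, z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Jackknife test for a sex difference in between-trait genetic correlation
#'
#' Estimates the genetic correlation of two traits separately in females and
#' males on one shared harmonized variant set and one shared genomic block
#' assignment, then forms per-block delete-one differences
#' rg_F(b) - rg_M(b) whose jackknife spread gives the SE of rg_F - rg_M.
#' Because the difference is jackknifed directly, the test is robust to
#' sample overlap between the four input cohorts. The z statistic is
#' (rg_F - rg_M) / SE with a two-sided normal p; the sign convention is
#' female minus male.
#'
#' @param f1,f2 Female `sumstats` for traits 1 and 2.
#' @param m1,m2 Male `sumstats` for traits 1 and 2.
#' @param ld An `ld_scores` table.
#' @param n_blocks Jackknife block count (default 200).
#' @return A list of class `rg_diff`: `rg_f`, `rg_m` (each an
#'   `ldsc_estimate`), `diff`, `se_diff`, `z`, `p`.
#' @export
rg_diff_jackknife <- function(f1, f2, m1, m2, ld, n_blocks = 200) {
  shared <- Reduce(intersect, list(f1$variant_id, f2$variant_id,
                                   m1$variant_id, m2$variant_id,
                                   ld$variant_id))
  if (length(shared) < 2 * n_blocks) {
    abort("fewer than 2 * n_blocks variants shared by all four inputs")
  }
  ld_s <- as_tibble(ld)[ld$variant_id %in% shared, ]
  ld_s <- dplyr::arrange(ld_s, .data$chr, .data$pos)
  take <- function(s) {
    d <- as_tibble(s)[match(ld_s$variant_id, s$variant_id), ]
    list(z = d$beta / d$se, n = d$n)
  }
  a <- take(f1); b <- take(f2); cc <- take(m1); dd <- take(m2)
  M <- attr(ld, "M") %||% nrow(ld)
  blocks <- assign_blocks(ld_s$chr, ld_s$pos, n_blocks)

  eng_f <- rg_engine(a$z, b$z, a$n, b$n, ld_s$l2, M, blocks)
  eng_m <- rg_engine(cc$z, dd$z, cc$n, dd$n, ld_s$l2, M, blocks)

  wrap <- function(eng) {
    flag <- if (!is.finite(eng$rg) || eng$h2_1 <= 0 || eng$h2_2 <= 0) {
      "h2_nonpositive"
    } else NA_character_
    new_ldsc_estimate(value = if (is.na(flag)) eng$rg else NA_real_,
                      se = jackknife_se(eng$rg_del), kind = "rg",
                      n_snps = length(shared), n_blocks = n_blocks,
                      flag = flag,
                      extra = list(h2_1 = eng$h2_1, h2_2 = eng$h2_2))
  }
  rg_f <- wrap(eng_f)
  rg_m <- wrap(eng_m)
  if (!is.na(rg_f$flag) || !is.na(rg_m$flag)) {
    return(structure(list(rg_f = rg_f, rg_m = rg_m, diff = NA_real_,
                          se_diff = NA_real_, z = NA_real_, p = NA_real_,
                          flag = "h2_nonpositive"),
                     class = "rg_diff"))
  }
  ok <- is.finite(eng_f$rg_del) & is.finite(eng_m$rg_del)
  d_del <- eng_f$rg_del[ok] - eng_m$rg_del[ok]
  se_diff <- jackknife_se(d_del)
  diff <- eng_f$rg - eng_m$rg
  # identical inputs give zero spread; report a null z rather than 0/0
  z <- if (se_diff == 0 && diff == 0) 0 else diff / se_diff
  structure(list(rg_f = rg_f, rg_m = rg_m, diff = diff, se_diff = se_diff,
                 z = z, p = 2 * pnorm(-abs(z)), flag = NA_character_),
            class = "rg_diff")
}

#' @export
print.rg_diff <- function(x, ...) {
  cat(sprintf("rg difference (female - male): %.4g (SE %.4g), z = %.3f, p = %.3g\n",
              x$diff, x$se_diff, x$z, x$p))
  cat(sprintf("  rg_F = %.4g (SE %.4g); rg_M = %.4g (SE %.4g)\n",
              x$rg_f$value, x$rg_f$se, x$rg_m$value, x$rg_m$se))
  invisible(x)
}
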