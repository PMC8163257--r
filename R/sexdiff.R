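#' Sex-difference z test for any estimated statistic
#'
#' For a statistic estimated separately in females and males with standard
#' errors, z = (stat_f - stat_m) / sqrt(se_f^2 + se_m^2), with a two-sided
#' normal p. The test is well calibrated when the two estimates are
#' independent and conservative when they are positively correlated; it
#' applies equally to SNP-heritabilities, genetic correlations, and per-SNP
#' effect sizes. Vectorized over its arguments.
#'
#' @param stat_f,se_f Female estimate(s) and standard error(s).
#' @param stat_m,se_m Male estimate(s) and standard error(s).
#' @return A tibble with columns `z` and `p`.
#' @export
sexdiff_z <- function(stat_f, se_f, stat_m, se_m) {
  if (!all(is.finite(stat_f), is.finite(se_f), is.finite(stat_m),
           is.finite(se_m))) {
    abort("sexdiff_z requires finite statistics and standard errors")
  }
  if (any(se_f <= 0) || any(se_m <= 0)) {
    abort("standard errors must be positive")
  }
  z <- (stat_f - stat_m) / sqrt(se_f^2 + se_m^2)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Per-SNP between-sex heterogeneity z scores
#'
#' Applies the sex-difference z test to every variant of a harmonized pair
#' (same effect allele in both sexes). The z score is correlated with
#' Cochran's Q but keeps the direction of the difference. Variants with
#' p < 5e-8 are flagged as genome-wide significant.
#'
#' @param pair A [harmonize_pair()] result.
#' @return A tibble of class `sexdiff_z_table` with columns `variant_id`,
#'   `chr`, `pos`, `z`, `p`, `genome_wide_sig`, in genomic order.
#' @export
snp_sexdiff <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  zt <- sexdiff_z(pair$beta_f, pair$se_f, pair$beta_m, pair$se_m)
  out <- tibble(variant_id = pair$variant_id, chr = pair$chr, pos = pair$pos,
                z = zt$z, p = zt$p, genome_wide_sig = zt$p < 5e-8)
  out <- dplyr::arrange(out, .data$chr, .data$pos)
  structure(out, class = c("sexdiff_z_table", class(tibble())),
            trait_label = attr(pair, "trait_label"))
}

#' Genomic-inflation summary of sex-difference z scores
#'
#' lambda_GC is median(z^2) divided by the chi-square(1) median (0.4549...);
#' values near 1 indicate a null-consistent distribution. The quantile table
#' pairs expected against observed -log10 p for QQ plotting (downsampled to at
#' most `max_points` rows).
#'
#' @param d A [snp_sexdiff()] table (or any tibble with `z` and `p`).
#' @param max_points Maximum rows in the quantile table.
#' @return A list with `lambda_gc` and `quantiles` (tibble: expected,
#'   observed, both -log10 p).
#' @export
qq_summary <- function(d, max_points = 10000) {
  if (nrow(d) < 1000) warn("fewer than 1000 variants; lambda_GC is unstable")
  lambda <- median(d$z^2) / qchisq(0.5, df = 1)
  n <- nrow(d)
  expected <- -log10(stats::ppoints(n))
  observed <- -log10(sort(d$p))
  if (n > max_points) {
    keep <- unique(round(seq(1, n, length.out = max_points)))
    expected <- expected[keep]
    observed <- observed[keep]
  }
  list(lambda_gc = lambda, quantiles = tibble(expected = expected,
                                              observed = observed))
}

#' Assign variants to contiguous genomic blocks of near-equal size
#'
#' Blocks are contiguous in genomic order and balanced in variant count
#' (within-chromosome sizes differ by at most one). Blocks never span a
#' chromosome boundary: the block count is apportioned across chromosomes in
#' proportion to their variant counts (largest-remainder rounding, at least
#' one block per represented chromosome).
#'
#' @param chr,pos Chromosome and position vectors sorted by (chr, pos).
#' @param n_blocks Number of blocks (default 1000).
#' @return Integer block labels `1..n_blocks` aligned with the input.
#' @export
assign_blocks <- function(chr, pos, n_blocks = 1000) {
  m <- length(chr)
  stopifnot(length(pos) == m)
  if (n_blocks > m) abort("n_blocks exceeds the number of variants")
  ord <- order(chr, pos)
  if (any(ord != seq_len(m))) abort("variants must be sorted by (chr, pos)")

  chrs <- unique(chr)
  counts <- as.integer(table(factor(chr, levels = chrs)))
  n_chr <- length(chrs)
  if (n_blocks < n_chr) {
    abort("n_blocks is smaller than the number of chromosomes present")
  }

  # largest-remainder apportionment, >= 1 block per chromosome,
  # <= variant count per chromosome
  q <- n_blocks * counts / m
  alloc <- pmax(1L, floor(q))
  alloc <- pmin(alloc, counts)
  resid <- n_blocks - sum(alloc)
  frac <- q - floor(q)
  while (resid > 0) {
    room <- which(alloc < counts)
    pick <- room[which.max(frac[room])]
    alloc[pick] <- alloc[pick] + 1L
    frac[pick] <- -Inf
    resid <- resid - 1L
  }
  while (resid < 0) {
    pick <- which(alloc > 1L)[which.max(alloc[alloc > 1L])]
    alloc[pick] <- alloc[pick] - 1L
    resid <- resid + 1L
  }

  labels <- integer(m)
  offset_var <- 0L
  offset_blk <- 0L
  for (i in seq_len(n_chr)) {
    cuts <- floor(seq_len(counts[i]) * alloc[i] / counts[i] - 1e-9)
    labels[(offset_var + 1L):(offset_var + counts[i])] <-
      offset_blk + pmin(alloc[i] - 1L, cuts) + 1L
    offset_var <- offset_var + counts[i]
    offset_blk <- offset_blk + alloc[i]
  }
  labels
}

# Delete-one-block jackknife SE from the vector of delete-one estimates.
jackknife_se <- function(theta_del) {
  theta_del <- theta_del[is.finite(theta_del)]
  B <- length(theta_del)
  if (B < 2) return(NA_real_)
  sqrt((B - 1) / B * sum((theta_del - mean(theta_del))^2))
}

#' Cross-trait correlation of sex-difference z scores with genomic jackknife
#'
#' Pearson correlation of two traits' per-SNP sex-difference z scores over the
#' intersection of their variants, with significance from a delete-one-block
#' genomic jackknife (default 1000 contiguous blocks), which absorbs the LD
#' dependence between nearby SNPs: the correlation is recomputed after
#' removing each block, SE^2 = ((B-1)/B) * sum_b (r_(b) - mean(r_(b)))^2, and
#' p is two-sided normal on r / SE.
#'
#' @param z1,z2 [snp_sexdiff()] tables, or plain numeric vectors of equal
#'   length (then taken as already aligned, blocked by order).
#' @param n_blocks Number of contiguous genomic blocks (default 1000).
#' @param use_t Use a t reference with B-1 degrees of freedom instead of the
#'   normal (default `FALSE`).
#' @return A one-row tibble of class `zcorr_result`: `trait_a`, `trait_b`,
#'   `r`, `se_jack`, `z`, `p`, `n_blocks`, `n_snps`.
#' @export
zcorr_jackknife <- function(z1, z2, n_blocks = 1000, use_t = FALSE) {
  if (is.numeric(z1) && is.numeric(z2)) {
    stopifnot(length(z1) == length(z2))
    x <- z1; y <- z2
    label_a <- "z1"; label_b <- "z2"
    blocks <- assign_blocks(rep(1L, length(x)), seq_along(x), n_blocks)
  } else {
    d <- dplyr::inner_join(as_tibble(z1)[c("variant_id", "chr", "pos", "z")],
                           as_tibble(z2)[c("variant_id", "z")],
                           by = "variant_id", suffix = c("_a", "_b"))
    d <- dplyr::arrange(d, .data$chr, .data$pos)
    if (nrow(d) < 2 * n_blocks) {
      abort("variant intersection is smaller than 2 * n_blocks")
    }
    x <- d$z_a; y <- d$z_b
    label_a <- attr(z1, "trait_label") %||% "trait_a"
    label_b <- attr(z2, "trait_label") %||% "trait_b"
    blocks <- assign_blocks(d$chr, d$pos, n_blocks)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant z vector: correlation undefined")
    return(structure(tibble(trait_a = label_a, trait_b = label_b,
                            r = NA_real_, se_jack = NA_real_, z = NA_real_,
                            p = NA_real_, n_blocks = n_blocks,
                            n_snps = length(x)),
                     class = c("zcorr_result", class(tibble()))))
  }

  # block-wise sufficient statistics so each delete-one correlation is exact
  S <- rowsum(cbind(1, x, y, x * x, y * y, x * y), blocks)
  tot <- colSums(S)
  del <- sweep(-S, 2, tot, "+")
  r_del <- (del[, 6] - del[, 2] * del[, 3] / del[, 1]) /
    sqrt((del[, 4] - del[, 2]^2 / del[, 1]) *
           (del[, 5] - del[, 3]^2 / del[, 1]))
  r_full <- cor(x, y)
  se <- jackknife_se(r_del)
  zstat <- r_full / se
  B <- sum(is.finite(r_del))
  p <- if (use_t) 2 * stats::pt(-abs(zstat), df = B - 1) else 2 * pnorm(-abs(zstat))
  structure(tibble(trait_a = label_a, trait_b = label_b, r = r_full,
                   se_jack = se, z = zstat, p = p,
                   n_blocks = n_blocks, n_snps = length(x)),
            class = c("zcorr_result", class(tibble())))
}
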