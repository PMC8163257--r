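#' Configuration for the synthetic sex-stratified GWAS generator
#'
#' The generator draws per-sex standardized additive effects from a bivariate
#' normal with per-sex variances `h2 / n_causal` and cross-sex correlation
#' `rg_mf`, then samples per-sex GWAS z scores blockwise from the polygenic
#' model: within an LD block with correlation matrix R, z ~ MVN(sqrt(N) R b, R).
#' This reproduces the LD score regression expectation
#' E[chi2_j] = 1 + N h2 l_j / M exactly, which is what the downstream
#' estimators assume.
#'
#' @param m_snps Number of variants.
#' @param n_blocks Number of LD blocks (equal-sized; last block may be shorter).
#' @param block_corr AR(1) within-block correlation decay in `[0, 1]`:
#'   cor(j, k) = block_corr^|j-k| inside a block, 0 across blocks.
#' @param h2_f,h2_m Per-sex SNP-heritability in `[0, 1)`.
#' @param rg_mf Between-sex genetic correlation in `[-1, 1]`.
#' @param prop_causal Fraction of variants with nonzero effects in `(0, 1]`.
#' @param n_f,n_m Per-sex GWAS sample sizes.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param K_f,K_m Sex-specific population prevalence (binary traits).
#' @param P_f,P_m Sex-specific sample case fraction (binary traits).
#' @param seed Integer seed; all draws are reproducible given `(config, seed)`.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 20000, n_blocks = 1000, block_corr = 0.5,
                       h2_f = 0.2, h2_m = 0.2, rg_mf = 1, prop_causal = 1,
                       n_f = 50000, n_m = 50000,
                       trait_type = c("continuous", "binary"),
                       K_f = NA_real_, K_m = NA_real_,
                       P_f = NA_real_, P_m = NA_real_, seed = 1L) {
  trait_type <- match.arg(trait_type)
  if (block_corr < 0 || block_corr > 1) {
    abort("block_corr must lie in [0, 1]")
  }
  stopifnot(h2_f >= 0, h2_f < 1, h2_m >= 0, h2_m < 1,
            abs(rg_mf) <= 1, prop_causal > 0, prop_causal <= 1,
            m_snps >= n_blocks, n_blocks >= 1)
  structure(list(m_snps = as.integer(m_snps), n_blocks = as.integer(n_blocks),
                 block_corr = block_corr, h2_f = h2_f, h2_m = h2_m,
                 rg_mf = rg_mf, prop_causal = prop_causal,
                 n_f = n_f, n_m = n_m, trait_type = trait_type,
                 K_f = K_f, K_m = K_m, P_f = P_f, P_m = P_m,
                 seed = as.integer(seed)),
            class = "sim_config")
}

ar1_ldscores <- function(k, rho) {
  # l_j = sum_i rho^(2|j-i|) within a block of size k (self included)
  vapply(seq_len(k), function(j) sum(rho^(2 * abs(j - seq_len(k)))), numeric(1))
}

#' Simulate a blockwise LD reference panel
#'
#' Builds a block-diagonal SNP correlation structure with AR(1) decay inside
#' each block, computes exact per-SNP LD scores l_j = sum_k r^2_jk (self
#' included), assigns variants to chromosomes 1-22 with regular spacing, and
#' draws effect-allele frequencies uniform on (0.05, 0.95).
#'
#' @param config A [sim_config()].
#' @return A list of class `ld_reference` with the variant table (`variants`:
#'   variant_id, chr, pos, block, idx_in_block, l2, eaf), block sizes, the
#'   AR(1) parameter and the reference SNP count `M`.
#' @export
simulate_ld <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m_snps
  b <- config$n_blocks
  rho <- config$block_corr

  base <- m %/% b
  sizes <- rep(base, b)
  extra <- m - base * b
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(b), times = sizes)
  idx_in_block <- unlist(lapply(sizes, seq_len), use.names = FALSE)

  l2 <- numeric(m)
  for (k in unique(sizes)) {
    lk <- ar1_ldscores(k, rho)
    sel <- sizes[block] == k
    l2[sel] <- lk[idx_in_block[sel]]
  }

  # spread blocks over 22 chromosomes; 5 kb spacing within a chromosome
  chr_of_block <- pmin(22L, ceiling(seq_len(b) * 22 / b))
  chr <- chr_of_block[block]
  pos <- stats::ave(rep(1, m), chr, FUN = seq_along) * 5000

  variants <- tibble(
    variant_id = paste0("rs", seq_len(m)),
    chr = chr, pos = pos, block = block, idx_in_block = idx_in_block,
    l2 = l2, eaf = runif(m, 0.05, 0.95)
  )
  structure(list(variants = variants, block_sizes = sizes, rho = rho, M = m),
            class = "ld_reference")
}

#' Extract the LD score table from an LD reference
#'
#' @param ld An `ld_reference`.
#' @return A tibble (variant_id, chr, pos, l2) of class `ld_scores` with the
#'   reference SNP count as attribute `M`.
#' @export
ld_scores <- function(ld) {
  stopifnot(inherits(ld, "ld_reference"))
  out <- ld$variants[c("variant_id", "chr", "pos", "l2")]
  structure(out, class = c("ld_scores", class(tibble())), M = ld$M)
}

#' Draw per-sex true standardized effects
#'
#' A causal subset of size `round(prop_causal * m_snps)` receives effects from
#' a bivariate normal with per-sex variances `h2 / n_causal` and cross-sex
#' correlation `rg_mf`; all other effects are zero.
#'
#' @param config A [sim_config()].
#' @return A list with numeric vectors `beta_f`, `beta_m` (standardized-genotype
#'   scale) and the integer vector `causal` of causal indices.
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$m_snps
  n_causal <- max(1L, round(config$prop_causal * m))
  causal <- sort(sample.int(m, n_causal))
  rg <- config$rg_mf
  x1 <- rnorm(n_causal)
  x2 <- rnorm(n_causal)
  bf <- numeric(m)
  bm <- numeric(m)
  bf[causal] <- sqrt(config$h2_f / n_causal) * x1
  bm[causal] <- sqrt(config$h2_m / n_causal) * (rg * x1 + sqrt(1 - rg^2) * x2)
  list(beta_f = bf, beta_m = bm, causal = causal)
}

# Quadratic form b' R b summed over blocks: variance explained under LD.
realized_variance <- function(ld, beta) {
  rho <- ld$rho
  total <- 0
  offset <- 0L
  for (k in ld$block_sizes) {
    b <- beta[(offset + 1L):(offset + k)]
    if (any(b != 0)) {
      R <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
      total <- total + drop(crossprod(b, R %*% b))
    }
    offset <- offset + k
  }
  total
}

#' Assemble the complete generating truth of a synthetic dataset
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` holding the config, the LD reference,
#'   the true per-sex effects, and realized heritabilities/effect correlation
#'   recomputed exactly from the stored effects and LD.
#' @export
simulate_truth <- function(config) {
  ld <- simulate_ld(config)
  eff <- simulate_effects(config)
  causal <- eff$causal
  realized_rg <- if (length(causal) > 1 &&
                     sd(eff$beta_f[causal]) > 0 && sd(eff$beta_m[causal]) > 0) {
    cor(eff$beta_f[causal], eff$beta_m[causal])
  } else NA_real_
  structure(list(config = config, ld = ld,
                 beta_f = eff$beta_f, beta_m = eff$beta_m, causal = causal,
                 realized_h2_f = realized_variance(ld, eff$beta_f),
                 realized_h2_m = realized_variance(ld, eff$beta_m),
                 realized_rg = realized_rg),
            class = "sim_truth")
}

#' Simulate GWAS summary statistics for one sex
#'
#' Draws per-block z vectors from MVN(sqrt(N) R b, R) where R is the block LD
#' matrix and b the true standardized effects, then converts to allelic-scale
#' beta and SE via se_j = 1 / sqrt(2 n eaf_j (1 - eaf_j)). Binary traits carry
#' the configured prevalence (K) and case fraction (P) as cohort metadata for
#' the downstream liability-scale conversion.
#'
#' @param truth A [simulate_truth()] object.
#' @param sex `"female"` or `"male"`.
#' @param residual_noise If `FALSE`, z is set to its conditional mean
#'   sqrt(N) R b with no sampling noise (useful for exactness checks).
#'
#' @return A [new_sumstats()] object.
#' @export
simulate_sumstats <- function(truth, sex = c("female", "male"),
                              residual_noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  sex <- match.arg(sex)
  cfg <- truth$config
  ld <- truth$ld
  n <- if (sex == "female") cfg$n_f else cfg$n_m
  beta_std <- if (sex == "female") truth$beta_f else truth$beta_m
  set.seed(cfg$seed + if (sex == "female") 2L else 3L)

  rho <- ld$rho
  sizes <- ld$block_sizes
  m <- ld$M
  z <- numeric(m)
  block_start <- cumsum(c(0L, sizes))

  for (k in unique(sizes)) {
    which_blocks <- which(sizes == k)
    idx <- unlist(lapply(which_blocks,
                         function(bi) block_start[bi] + seq_len(k)),
                  use.names = FALSE)
    Bm <- matrix(beta_std[idx], nrow = k)
    if (k == 1) {
      mu <- sqrt(n) * Bm
      zb <- if (residual_noise) mu + matrix(rnorm(length(mu)), nrow = 1) else mu
    } else {
      R <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
      mu <- sqrt(n) * (R %*% Bm)
      if (residual_noise) {
        if (rho == 1) {
          # singular all-ones correlation: one shared standard normal per block
          E <- matrix(rep(rnorm(ncol(Bm)), each = k), nrow = k)
        } else {
          E <- crossprod(chol(R), matrix(rnorm(k * ncol(Bm)), nrow = k))
        }
        zb <- mu + E
      } else {
        zb <- mu
      }
    }
    z[idx] <- as.vector(zb)
  }

  v <- ld$variants
  se <- 1 / sqrt(2 * n * v$eaf * (1 - v$eaf))
  rec <- tibble(variant_id = v$variant_id, chr = v$chr, pos = v$pos,
                ea = "A", oa = "G",
                beta = z * se, se = se, p = 2 * pnorm(-abs(z)),
                n = n, eaf = v$eaf)
  binary <- cfg$trait_type == "binary"
  P <- if (sex == "female") cfg$P_f else cfg$P_m
  K <- if (sex == "female") cfg$K_f else cfg$K_m
  out <- new_sumstats(
    rec, trait_label = "simulated", sex = sex, trait_type = cfg$trait_type,
    n_cases = if (binary) as.integer(round(P * n)) else NA_integer_,
    n_controls = if (binary) as.integer(round((1 - P) * n)) else NA_integer_,
    n_total = n
  )
  if (binary) attr(out, "prevalence") <- K
  out
}

#' Simulate a complete truth-known study (both sexes plus LD scores)
#'
#' @param config A [sim_config()].
#' @param trait_label Label stamped on both output tables.
#' @return A list of class `sim_study`: `truth`, `ld` (an `ld_scores` table),
#'   `female` and `male` (`sumstats`).
#' @export
simulate_study <- function(config, trait_label = "simulated") {
  truth <- simulate_truth(config)
  female <- simulate_sumstats(truth, "female")
  male <- simulate_sumstats(truth, "male")
  attr(female, "trait_label") <- trait_label
  attr(male, "trait_label") <- trait_label
  structure(list(truth = truth, ld = ld_scores(truth$ld),
                 female = female, male = male),
            class = "sim_study")
}

#' Write LD scores in the `.l2.ldscore` layout
#'
#' Writes `<prefix>.l2.ldscore` (tab-delimited CHR, SNP, BP, L2) and the
#' `<prefix>.l2.M` sidecar holding the reference SNP count.
#'
#' @param ld An `ld_scores` table (see [ld_scores()] or [read_ldscores()]).
#' @param prefix Output path prefix.
#' @return The ldscore file path, invisibly.
#' @export
write_ldscores <- function(ld, prefix) {
  out <- tibble(CHR = ld$chr, SNP = ld$variant_id, BP = ld$pos, L2 = ld$l2)
  path <- paste0(prefix, ".l2.ldscore")
  readr::write_tsv(out, path, progress = FALSE)
  writeLines(as.character(attr(ld, "M")), paste0(prefix, ".l2.M"))
  invisible(path)
}

#' Read LD scores from the `.l2.ldscore` layout
#'
#' @param prefix Path prefix such that `<prefix>.l2.ldscore` and
#'   `<prefix>.l2.M` exist.
#' @return An `ld_scores` tibble with attribute `M`.
#' @export
read_ldscores <- function(prefix) {
  path <- paste0(prefix, ".l2.ldscore")
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- readr::read_tsv(path, col_types = readr::cols(
    CHR = readr::col_character(), SNP = readr::col_character(),
    BP = readr::col_double(), L2 = readr::col_double()),
    progress = FALSE, col_select = c("CHR", "SNP", "BP", "L2"))
  m_path <- paste0(prefix, ".l2.M")
  M <- if (file.exists(m_path)) as.numeric(readLines(m_path)[1]) else nrow(d)
  out <- tibble(variant_id = d$SNP, chr = parse_chromosome(d$CHR),
                pos = d$BP, l2 = d$L2)
  structure(out, class = c("ld_scores", class(tibble())), M = M)
}
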