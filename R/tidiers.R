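#' Tidy an LD score regression estimate
#'
#' @param x An `ldsc_estimate`.
#' @param conf_level Confidence level for the normal-approximation interval.
#' @param ... Unused.
#' @return A one-row tibble: term, estimate, std.error, conf.low, conf.high.
#' @export
tidy.ldsc_estimate <- function(x, conf_level = 0.95, ...) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(term = x$kind, estimate = x$value, std.error = x$se,
         conf.low = x$value - zq * x$se, conf.high = x$value + zq * x$se)
}

#' One-row summary of an LD score regression fit
#'
#' @param x An `ldsc_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the intercept, block and SNP counts, scale
#'   metadata and any degeneracy flag.
#' @export
glance.ldsc_estimate <- function(x, ...) {
  tibble(kind = x$kind, intercept = x$intercept,
         intercept.se = x$intercept_se, n_snps = x$n_snps,
         n_blocks = x$n_blocks,
         K = x$scale_meta$K %||% NA_real_, P = x$scale_meta$P %||% NA_real_,
         flag = x$flag)
}

#' Tidy a jackknife rg-difference test
#'
#' @param x An [rg_diff_jackknife()] result.
#' @param ... Unused.
#' @return A one-row tibble with both per-sex estimates, the female-minus-male
#'   difference, its jackknife SE, z and p.
#' @export
tidy.rg_diff <- function(x, ...) {
  tibble(rg_f = x$rg_f$value, se_f = x$rg_f$se,
         rg_m = x$rg_m$value, se_m = x$rg_m$se,
         estimate = x$diff, std.error = x$se_diff,
         statistic = x$z, p.value = x$p)
}
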