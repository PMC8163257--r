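#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_tests Number of independent tests.
#' @return A one-row tibble: alpha, n_tests, threshold (full precision),
#'   threshold_4dp (rounded to 4 decimals, as conventionally reported).
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 1) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  thr <- alpha / n_tests
  tibble(alpha = alpha, n_tests = as.integer(n_tests),
         threshold = thr, threshold_4dp = round(thr, 4))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return q-values aligned with `pvals`.
#' @export
bh_fdr <- function(pvals) {
  ok <- is.finite(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Build an analysis configuration
#'
#' @param traits A list; each element a list with `label`, `female` and `male`
#'   (paths to per-sex summary-statistics files), `trait_type`, and for binary
#'   traits `P_f`, `P_m` (sample case fractions) plus `prevalence`, a named
#'   list of sources each holding `K_f` and `K_m` population prevalences.
#' @param ld_scores Path prefix for `.l2.ldscore` files ([read_ldscores()]).
#' @param column_map Column mapping for [read_sumstats()].
#' @param genes,gene_sets Optional paths to gene bounds (BED-like) and GMT
#'   gene sets for the gene-level stage.
#' @param n_blocks_ldsc Jackknife blocks for LDSC quantities (default 200).
#' @param n_blocks_zcorr Genomic blocks for z-score correlations (default 1000).
#' @param alpha Family-wise level (default 0.05).
#' @param maf_min Minor-allele-frequency filter (default 0.01).
#' @param hla_exclude Drop the chr6:25-34 Mb region before LDSC (default TRUE).
#' @param gene_top_fraction Fraction of genes selected per trait (default 0.001).
#' @param seed Integer seed recorded in the run log.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(traits, ld_scores,
                            column_map = default_column_map(),
                            genes = NULL, gene_sets = NULL,
                            n_blocks_ldsc = 200, n_blocks_zcorr = 1000,
                            alpha = 0.05, maf_min = 0.01, hla_exclude = TRUE,
                            gene_top_fraction = 0.001, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, length(traits) >= 1)
  structure(list(traits = traits, ld_scores = ld_scores,
                 column_map = column_map, genes = genes,
                 gene_sets = gene_sets, n_blocks_ldsc = n_blocks_ldsc,
                 n_blocks_zcorr = n_blocks_zcorr, alpha = alpha,
                 maf_min = maf_min, hla_exclude = hla_exclude,
                 gene_top_fraction = gene_top_fraction,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(analysis_config)))]
  if (!is.null(y$column_map)) args$column_map <- unlist(y$column_map)
  do.call(analysis_config, args)
}

load_trait_pair <- function(tr, config) {
  read_one <- function(path, sex) {
    s <- read_sumstats(path, config$column_map, trait_label = tr$label,
                       sex = sex,
                       trait_type = tr$trait_type %||% "continuous",
                       n_cases = tr[[paste0("n_cases_", substr(sex, 1, 1))]] %||% NA_integer_,
                       n_controls = tr[[paste0("n_controls_", substr(sex, 1, 1))]] %||% NA_integer_,
                       n_total = tr[[paste0("n_", substr(sex, 1, 1))]] %||% NA_integer_)
    s <- filter_common_autosomal(s, config$maf_min)
    if (isTRUE(config$hla_exclude)) s <- exclude_region(s) else s
  }
  harmonize_pair(read_one(tr$female, "female"), read_one(tr$male, "male"))
}

#' Run the full sex-differentiated architecture analysis
#'
#' Executes, per configured trait: read, MAF/autosome filtering, HLA
#' exclusion, allele harmonization; sex-specific SNP-heritability (observed
#' plus liability scale per prevalence source) with the Bonferroni-corrected
#' sex-difference z test; between-sex genetic correlation with the one-tailed
#' rg < 1 test; per-SNP sex-difference z scores with genomic-inflation
#' summaries; pairwise cross-trait correlation of z scores with the
#' 1000-block genomic jackknife; per-sex between-trait genetic correlations
#' with the jackknife rg_F - rg_M test under FDR correction; and, when gene
#' bounds plus an LD reference are supplied, gene-level statistics,
#' top-fraction selection and gene-set over-representation. Traits whose
#' heritability 95\% confidence interval includes zero in either sex are
#' flagged and excluded from correlation and sex-difference testing. Stage
#' failures are logged per trait and the run continues.
#'
#' @param config An [analysis_config()].
#' @param ld_ref Optional `ld_reference` supplying local SNP correlations for
#'   the gene stage (required for gene statistics).
#' @return A list of class `sexgwas_report`; every test table carries its
#'   multiplicity rule, family size and threshold as columns.
#' @export
run_full <- function(config, ld_ref = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  note("run_full: %d traits, seed %d", length(config$traits), config$seed)

  ld <- read_ldscores(config$ld_scores)
  labels <- vapply(config$traits, `[[`, character(1), "label")
  names(config$traits) <- labels

  pairs <- list()
  for (tr in config$traits) {
    pairs[[tr$label]] <- tryCatch(load_trait_pair(tr, config),
                                  error = function(e) {
                                    note("trait %s: load failed (%s)",
                                         tr$label, conditionMessage(e))
                                    NULL
                                  })
  }
  pairs <- purrr::compact(pairs)
  datasets <- describe_datasets(pairs)

  # -- sex-specific heritability, observed + liability per prevalence source
  h2_rows <- list()
  h2_est <- list()
  for (label in names(pairs)) {
    tr <- config$traits[[label]]
    split <- pair_to_sumstats(pairs[[label]])
    for (sex in c("female", "male")) {
      e <- tryCatch(ldsc_h2(split[[sex]], ld, config$n_blocks_ldsc),
                    error = function(err) {
                      note("trait %s (%s): h2 failed (%s)", label, sex,
                           conditionMessage(err))
                      NULL
                    })
      if (is.null(e)) next
      h2_est[[label]][[sex]] <- list(obs = e)
      h2_rows[[length(h2_rows) + 1]] <-
        dplyr::mutate(tidy(e), trait = label, sex = sex, scale = "observed",
                      prevalence_source = NA_character_)
      if ((tr$trait_type %||% "continuous") == "binary" &&
          !is.null(tr$prevalence)) {
        P <- tr[[paste0("P_", substr(sex, 1, 1))]]
        for (src in names(tr$prevalence)) {
          K <- tr$prevalence[[src]][[paste0("K_", substr(sex, 1, 1))]]
          le <- obs_to_liability(e, K, P)
          h2_est[[label]][[sex]][[src]] <- le
          h2_rows[[length(h2_rows) + 1]] <-
            dplyr::mutate(tidy(le), trait = label, sex = sex,
                          scale = "liability", prevalence_source = src)
        }
      }
    }
  }
  h2_table <- dplyr::bind_rows(h2_rows)

  # -- nonzero-h2 gate: 95% CI must exclude zero in both sexes
  passes <- vapply(names(h2_est), function(label) {
    es <- h2_est[[label]]
    length(es) == 2 && all(vapply(es, function(sx) {
      e <- sx$obs
      is.finite(e$value) && e$value > 0 && e$value - 1.96 * e$se > 0
    }, logical(1)))
  }, logical(1))
  kept <- names(h2_est)[passes]
  excluded <- setdiff(names(pairs), kept)
  if (length(excluded) > 0) {
    note("traits excluded by the nonzero-h2 gate: %s",
         paste(excluded, collapse = ", "))
  }

  # -- Eq.-1 sex-difference tests on h2 (liability scale for binary traits,
  #    observed scale otherwise; one test per trait, Bonferroni across traits)
  h2_diff_rows <- purrr::map_dfr(kept, function(label) {
    tr <- config$traits[[label]]
    binary <- (tr$trait_type %||% "continuous") == "binary" &&
      !is.null(tr$prevalence)
    srcs <- if (binary) names(tr$prevalence) else "observed"
    purrr::map_dfr(srcs, function(src) {
      ef <- if (binary) h2_est[[label]]$female[[src]] else h2_est[[label]]$female$obs
      em <- if (binary) h2_est[[label]]$male[[src]] else h2_est[[label]]$male$obs
      zt <- sexdiff_z(ef$value, ef$se, em$value, em$se)
      tibble(trait = label,
             scale = if (binary) "liability" else "observed",
             prevalence_source = if (binary) src else NA_character_,
             h2_f = ef$value, se_f = ef$se, h2_m = em$value, se_m = em$se,
             z = zt$z, p = zt$p)
    })
  })
  if (nrow(h2_diff_rows) > 0) {
    bon <- bonferroni_alpha(config$alpha, length(kept))
    h2_diff_rows <- dplyr::mutate(h2_diff_rows,
                                  multiplicity = "bonferroni",
                                  family_size = bon$n_tests,
                                  threshold = bon$threshold,
                                  significant = .data$p < bon$threshold)
  }

  # -- between-sex within-trait rg with the one-tailed rg < 1 test
  rg_within <- purrr::map_dfr(kept, function(label) {
    split <- pair_to_sumstats(pairs[[label]])
    e <- tryCatch(ldsc_rg(split$female, split$male, ld, config$n_blocks_ldsc),
                  error = function(err) NULL)
    if (is.null(e)) return(tibble())
    lt1 <- rg_lt1_test(e)
    tibble(trait = label, rg = e$value, se = e$se, flag = e$flag,
           z_lt1 = lt1$z, p_lt1 = lt1$p)
  })
  if (nrow(rg_within) > 0) {
    n_rg <- sum(is.finite(rg_within$p_lt1))
    bon <- bonferroni_alpha(config$alpha, max(1L, n_rg))
    rg_within <- dplyr::mutate(rg_within, multiplicity = "bonferroni",
                               family_size = bon$n_tests,
                               threshold = bon$threshold,
                               significant = .data$p_lt1 < bon$threshold)
  }

  # -- per-SNP sex-difference z scores and inflation summaries
  snp_z <- purrr::map(pairs[kept], snp_sexdiff)
  lambda_table <- purrr::imap_dfr(snp_z, function(d, label) {
    tibble(trait = label, lambda_gc = qq_summary(d)$lambda_gc,
           n_gws = sum(d$genome_wide_sig), n_snps = nrow(d))
  })

  # -- cross-trait sharing: Pearson correlation of z scores, genomic jackknife
  zcorr <- tibble()
  if (length(snp_z) >= 2) {
    combos <- utils::combn(names(snp_z), 2, simplify = FALSE)
    zcorr <- purrr::map_dfr(combos, function(pr) {
      tryCatch(zcorr_jackknife(snp_z[[pr[1]]], snp_z[[pr[2]]],
                               config$n_blocks_zcorr),
               error = function(err) {
                 note("zcorr %s-%s failed (%s)", pr[1], pr[2],
                      conditionMessage(err))
                 tibble()
               })
    })
    if (nrow(zcorr) > 0) {
      zcorr <- dplyr::mutate(zcorr, multiplicity = "fdr_bh",
                             family_size = nrow(zcorr), q = bh_fdr(.data$p))
    }
  }

  # -- between-trait within-sex rg and the jackknife rg_F - rg_M test
  rg_between <- tibble()
  if (length(kept) >= 2) {
    combos <- utils::combn(kept, 2, simplify = FALSE)
    rg_between <- purrr::map_dfr(combos, function(pr) {
      s1 <- pair_to_sumstats(pairs[[pr[1]]])
      s2 <- pair_to_sumstats(pairs[[pr[2]]])
      rd <- tryCatch(rg_diff_jackknife(s1$female, s2$female,
                                       s1$male, s2$male, ld,
                                       config$n_blocks_ldsc),
                     error = function(err) NULL)
      if (is.null(rd)) return(tibble())
      tibble(trait_a = pr[1], trait_b = pr[2],
             rg_f = rd$rg_f$value, se_f = rd$rg_f$se,
             rg_m = rd$rg_m$value, se_m = rd$rg_m$se,
             diff = rd$diff, se_diff = rd$se_diff, z = rd$z, p = rd$p,
             flag = rd$flag)
    })
    if (nrow(rg_between) > 0) {
      rg_between <- dplyr::mutate(rg_between, multiplicity = "fdr_bh",
                                  family_size = sum(is.finite(.data$p)),
                                  q = bh_fdr(.data$p))
    }
  }

  # -- gene-level aggregation and over-representation
  gene_tables <- NULL
  top_genes <- NULL
  enrichment <- NULL
  if (!is.null(config$genes) && !is.null(ld_ref)) {
    gene_bounds <- read_gene_bounds(config$genes)
    gene_tables <- purrr::map(snp_z, gene_stats, genes = gene_bounds,
                              ld_ref = ld_ref)
    top_genes <- top_fraction(gene_tables, config$gene_top_fraction)
    if (!is.null(config$gene_sets)) {
      background <- sort(unique(unlist(purrr::map(gene_tables, "gene_id"))))
      enrichment <- ora_enrichment(top_genes$union, read_gmt(config$gene_sets),
                                   background)
    }
  } else if (!is.null(config$genes)) {
    note("gene stage skipped: no LD reference supplied")
  }

  structure(list(datasets = datasets, h2 = h2_table,
                 h2_sexdiff = h2_diff_rows, rg_within = rg_within,
                 snp_z = snp_z, lambda = lambda_table, zcorr = zcorr,
                 rg_between = rg_between, gene_stats = gene_tables,
                 top_genes = top_genes, enrichment = enrichment,
                 excluded_traits = excluded, log = log_lines,
                 config = config),
            class = "sexgwas_report")
}

#' @export
print.sexgwas_report <- function(x, ...) {
  cat("sexgwas analysis report\n")
  cat(sprintf("  traits analyzed: %d (excluded by h2 gate: %d)\n",
              nrow(x$datasets), length(x$excluded_traits)))
  cat(sprintf("  tables: h2 (%d rows), h2_sexdiff (%d), rg_within (%d), zcorr (%d), rg_between (%d)\n",
              nrow(x$h2), nrow(x$h2_sexdiff), nrow(x$rg_within),
              nrow(x$zcorr), nrow(x$rg_between)))
  invisible(x)
}

#' Write every report table to a directory as tab-delimited text
#'
#' @param report A [run_full()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sexgwas_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, name) {
    if (!is.null(tab) && nrow(as_tibble(tab)) >= 0) {
      readr::write_tsv(as_tibble(tab), file.path(dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  wr(report$datasets, "datasets")
  wr(report$h2, "h2")
  wr(report$h2_sexdiff, "h2_sexdiff")
  wr(report$rg_within, "rg_within")
  wr(report$lambda, "lambda")
  wr(report$zcorr, "zcorr")
  wr(report$rg_between, "rg_between")
  for (label in names(report$snp_z)) {
    wr(report$snp_z[[label]], paste0("snp_z_", label))
  }
  if (!is.null(report$gene_stats)) {
    for (label in names(report$gene_stats)) {
      wr(report$gene_stats[[label]], paste0("genes_", label))
    }
  }
  if (!is.null(report$top_genes)) wr(report$top_genes$per_trait, "top_genes")
  if (!is.null(report$enrichment)) wr(report$enrichment, "enrichment")
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
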