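#' Construct a sex-stratified summary-statistics table
#'
#' A `sumstats` object is a tibble of per-variant GWAS association records for
#' one sex of one trait, carrying cohort metadata as attributes. Effect sizes
#' for binary traits are stored on the log-odds scale so that downstream
#' sex-difference tests always operate on betas.
#'
#' @param records A data frame with columns `variant_id`, `chr`, `pos`, `ea`,
#'   `oa`, `beta`, `se`, `p`, `n`, `eaf`.
#' @param trait_label Trait name.
#' @param sex `"female"` or `"male"`.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param n_cases,n_controls Case/control counts (binary traits; `NA` otherwise).
#' @param n_total Total cohort size; used as the per-variant `n` fallback.
#' @param read_report Optional named list describing row filtering at read time.
#'
#' @return A tibble of class `sumstats`.
#' @export
new_sumstats <- function(records, trait_label, sex,
                         trait_type = c("continuous", "binary"),
                         n_cases = NA_integer_, n_controls = NA_integer_,
                         n_total = NA_integer_, read_report = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  trait_type <- match.arg(trait_type)
  cols <- c("variant_id", "chr", "pos", "ea", "oa", "beta", "se", "p", "n", "eaf")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(records)[cols]
  if (anyDuplicated(out$variant_id) > 0) {
    abort("variant ids must be unique within one sumstats table")
  }
  structure(out,
            class = c("sumstats", class(tibble())),
            trait_label = trait_label, sex = sex, trait_type = trait_type,
            n_cases = n_cases, n_controls = n_controls, n_total = n_total,
            read_report = read_report)
}

sumstats_meta <- function(s) {
  list(trait_label = attr(s, "trait_label"), sex = attr(s, "sex"),
       trait_type = attr(s, "trait_type"), n_cases = attr(s, "n_cases"),
       n_controls = attr(s, "n_controls"), n_total = attr(s, "n_total"))
}

# Rebuild a sumstats object around a filtered copy of its records, keeping
# metadata and merging drop counts into the read report.
restamp_sumstats <- function(records, template, extra_report = NULL) {
  rep0 <- attr(template, "read_report") %||% list()
  m <- sumstats_meta(template)
  new_sumstats(records, m$trait_label, m$sex, m$trait_type,
               m$n_cases, m$n_controls, m$n_total,
               read_report = c(rep0, extra_report))
}

#' @export
print.sumstats <- function(x, ...) {
  m <- sumstats_meta(x)
  cat(sprintf("# GWAS summary statistics: %s (%s, %s), %d variants\n",
              m$trait_label, m$sex, m$trait_type, nrow(x)))
  if (m$trait_type == "binary" && !is.na(m$n_cases)) {
    cat(sprintf("# cases %s / controls %s\n",
                format(m$n_cases, big.mark = ","),
                format(m$n_controls, big.mark = ",")))
  }
  NextMethod()
}

parse_chromosome <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  suppressWarnings(as.integer(x))
}

#' Read sex-stratified GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited summary-statistics file with a header
#' row, renames columns according to `column_map`, drops non-autosomal and
#' malformed rows, and converts odds ratios to the log-odds scale. A read
#' report (rows read, rows kept, per-reason drop counts) is attached as the
#' `read_report` attribute.
#'
#' @param path Path to the file (plain or gzip).
#' @param column_map Named character vector mapping field names to file column
#'   names. Required fields: `variant_id`, `chr`, `pos`, `ea`, `oa`, `se`, `p`,
#'   `eaf`, and exactly one of `beta` or `or` (odds ratio, log-transformed at
#'   read time). Optional: `n` (falls back to `n_total` when absent).
#' @param trait_label,sex,trait_type,n_cases,n_controls,n_total Cohort
#'   metadata; see [new_sumstats()].
#'
#' @return A [new_sumstats()] object.
#' @export
read_sumstats <- function(path, column_map, trait_label, sex,
                          trait_type = c("continuous", "binary"),
                          n_cases = NA_integer_, n_controls = NA_integer_,
                          n_total = NA_integer_) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  column_map <- unlist(column_map)
  required <- c("variant_id", "chr", "pos", "ea", "oa", "se", "p", "eaf")
  if (!all(required %in% names(column_map))) {
    abort(paste0("column_map is missing field(s): ",
                 paste(setdiff(required, names(column_map)), collapse = ", ")))
  }
  has_beta <- "beta" %in% names(column_map)
  has_or <- "or" %in% names(column_map)
  if (has_beta == has_or) {
    abort("column_map must contain exactly one of 'beta' or 'or'")
  }

  header <- readLines(path, n = 1L)
  raw <- if (grepl("\t", header)) {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mapped column(s) absent from file: ",
                 paste(missing_cols, collapse = ", ")))
  }

  d <- tibble(
    variant_id = raw[[column_map[["variant_id"]]]],
    chr = parse_chromosome(raw[[column_map[["chr"]]]]),
    pos = suppressWarnings(as.numeric(raw[[column_map[["pos"]]]])),
    ea = toupper(raw[[column_map[["ea"]]]]),
    oa = toupper(raw[[column_map[["oa"]]]]),
    beta = suppressWarnings(as.numeric(
      raw[[column_map[[if (has_beta) "beta" else "or"]]]])),
    se = suppressWarnings(as.numeric(raw[[column_map[["se"]]]])),
    p = suppressWarnings(as.numeric(raw[[column_map[["p"]]]])),
    n = if ("n" %in% names(column_map)) {
      suppressWarnings(as.numeric(raw[[column_map[["n"]]]]))
    } else {
      as.numeric(n_total)
    },
    eaf = suppressWarnings(as.numeric(raw[[column_map[["eaf"]]]]))
  )
  if (has_or) d$beta <- log(d$beta)

  n_read <- nrow(d)
  bad_numeric <- !is.finite(d$beta) | !is.finite(d$se)
  d <- d[!bad_numeric, , drop = FALSE]
  non_autosomal <- is.na(d$chr) | d$chr < 1 | d$chr > 22
  d <- d[!non_autosomal, , drop = FALSE]
  bad_se <- d$se <= 0
  d <- d[!bad_se, , drop = FALSE]
  dup <- duplicated(d$variant_id)
  d <- d[!dup, , drop = FALSE]

  report <- list(rows_read = n_read, rows_kept = nrow(d),
                 dropped_non_numeric = sum(bad_numeric),
                 dropped_non_autosomal = sum(non_autosomal),
                 dropped_nonpositive_se = sum(bad_se),
                 dropped_duplicate_id = sum(dup))
  new_sumstats(d, trait_label, sex, trait_type, n_cases, n_controls, n_total,
               read_report = report)
}

#' Keep common autosomal variants
#'
#' Retains records with minor allele frequency strictly above `maf_min` on
#' chromosomes 1-22, preserving order.
#'
#' @param s A `sumstats` object.
#' @param maf_min Minor-allele-frequency threshold (default 0.01, i.e. MAF > 1\%).
#'
#' @return A filtered `sumstats` object.
#' @export
filter_common_autosomal <- function(s, maf_min = 0.01) {
  stopifnot(inherits(s, "sumstats"))
  maf <- pmin(s$eaf, 1 - s$eaf)
  keep <- !is.na(maf) & maf > maf_min & s$chr >= 1 & s$chr <= 22
  out <- restamp_sumstats(s[keep, , drop = FALSE], s,
                          list(dropped_maf_or_chr = sum(!keep)))
  if (nrow(out) == 0) warn("no variants remain after MAF/autosome filtering")
  out
}

#' Exclude variants in a genomic region
#'
#' Removes records falling inside a closed interval on one chromosome. The
#' default arguments drop the extended HLA/MHC region (chr6:25-34 Mb), which is
#' conventionally excluded before LD score regression because its long-range
#' LD violates the model.
#'
#' @param s A `sumstats` object.
#' @param chromosome Chromosome (1-22).
#' @param start_bp,end_bp Closed interval bounds, 1-based.
#'
#' @return A filtered `sumstats` object.
#' @export
exclude_region <- function(s, chromosome = 6L, start_bp = 25e6, end_bp = 34e6) {
  stopifnot(inherits(s, "sumstats"), start_bp < end_bp)
  drop <- s$chr == chromosome & s$pos >= start_bp & s$pos <= end_bp
  restamp_sumstats(s[!drop, , drop = FALSE], s,
                   list(dropped_region = sum(drop)))
}

#' Read a BED-like region file and exclude all its regions
#'
#' @param s A `sumstats` object.
#' @param path Tab-delimited file with columns chrom, start, end (no header).
#' @param zero_based If `TRUE` (BED convention) starts are 0-based half-open
#'   and are converted to the package's 1-based closed convention.
#'
#' @return A filtered `sumstats` object.
#' @export
exclude_regions_bed <- function(s, path, zero_based = TRUE) {
  reg <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cdd", progress = FALSE)
  reg$chrom <- parse_chromosome(reg$chrom)
  if (zero_based) reg$start <- reg$start + 1
  for (i in seq_len(nrow(reg))) {
    s <- exclude_region(s, reg$chrom[i], reg$start[i], reg$end[i])
  }
  s
}

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize a female/male summary-statistics pair onto shared effect alleles
#'
#' Intersects the two variant sets, flips the male effect (beta to -beta, eaf
#' to 1-eaf) where its alleles are swapped relative to the female file, drops
#' strand-ambiguous (A/T, C/G) variants when `drop_ambiguous` is set, and drops
#' variants whose alleles cannot be reconciled. The result is one wide tibble
#' per trait on which per-SNP sex-difference tests are well defined.
#'
#' @param female,male `sumstats` objects for the same trait.
#' @param drop_ambiguous Drop strand-ambiguous variants (default `TRUE`).
#'
#' @return A tibble of class `harmonized_pair` with columns `variant_id`,
#'   `chr`, `pos`, `ea`, `oa`, then `beta/se/p/n/eaf` suffixed `_f` and `_m`.
#'   Metadata of both inputs and a harmonization report are kept as attributes.
#' @export
harmonize_pair <- function(female, male, drop_ambiguous = TRUE) {
  stopifnot(inherits(female, "sumstats"), inherits(male, "sumstats"))
  fm <- dplyr::inner_join(
    as_tibble(female),
    as_tibble(male),
    by = "variant_id", suffix = c("_f", "_m")
  )
  if (nrow(fm) == 0) abort("no shared variants between female and male inputs")

  same <- fm$ea_f == fm$ea_m & fm$oa_f == fm$oa_m
  swapped <- fm$ea_f == fm$oa_m & fm$oa_f == fm$ea_m
  ambiguous <- paste0(fm$ea_f, "/", fm$oa_f) %in% AMBIGUOUS_PAIRS
  irreconcilable <- !(same | swapped)

  fm$beta_m[swapped] <- -fm$beta_m[swapped]
  fm$eaf_m[swapped] <- 1 - fm$eaf_m[swapped]

  keep <- !irreconcilable & !(drop_ambiguous & ambiguous)
  out <- fm[keep, c("variant_id", "chr_f", "pos_f", "ea_f", "oa_f",
                    "beta_f", "se_f", "p_f", "n_f", "eaf_f",
                    "beta_m", "se_m", "p_m", "n_m", "eaf_m")]
  names(out)[2:5] <- c("chr", "pos", "ea", "oa")
  out <- dplyr::arrange(out, .data$chr, .data$pos)

  structure(out,
            class = c("harmonized_pair", class(tibble())),
            trait_label = attr(female, "trait_label"),
            female_meta = sumstats_meta(female),
            male_meta = sumstats_meta(male),
            report = list(n_shared = nrow(fm), n_flipped = sum(swapped & keep),
                          dropped_ambiguous = sum(ambiguous & !irreconcilable &
                                                    drop_ambiguous),
                          dropped_irreconcilable = sum(irreconcilable),
                          n_kept = nrow(out)))
}

#' Split a harmonized pair back into per-sex summary statistics
#'
#' @param pair A `harmonized_pair`.
#' @return A list with elements `female` and `male`, each a `sumstats` object.
#' @export
pair_to_sumstats <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  one <- function(sfx, meta) {
    d <- tibble(variant_id = pair$variant_id, chr = pair$chr, pos = pair$pos,
                ea = pair$ea, oa = pair$oa,
                beta = pair[[paste0("beta", sfx)]],
                se = pair[[paste0("se", sfx)]],
                p = pair[[paste0("p", sfx)]],
                n = pair[[paste0("n", sfx)]],
                eaf = pair[[paste0("eaf", sfx)]])
    new_sumstats(d, meta$trait_label, meta$sex, meta$trait_type,
                 meta$n_cases, meta$n_controls, meta$n_total)
  }
  list(female = one("_f", attr(pair, "female_meta")),
       male = one("_m", attr(pair, "male_meta")))
}

#' Summarize a set of harmonized trait datasets
#'
#' Produces one row per trait: per-sex case/control (or total) counts, the
#' male:female case ratio rounded to two decimals, and the number of variants
#' retained after harmonization. For continuous traits the ratio is computed
#' on total sample sizes.
#'
#' @param pairs A list of `harmonized_pair` objects.
#' @return A tibble.
#' @export
describe_datasets <- function(pairs) {
  purrr::map_dfr(pairs, function(p) {
    fm <- attr(p, "female_meta"); mm <- attr(p, "male_meta")
    binary <- fm$trait_type == "binary"
    f_count <- if (binary) fm$n_cases else fm$n_total
    m_count <- if (binary) mm$n_cases else mm$n_total
    tibble(trait = attr(p, "trait_label"), trait_type = fm$trait_type,
           cases_f = if (binary) fm$n_cases else NA_integer_,
           controls_f = if (binary) fm$n_controls else NA_integer_,
           cases_m = if (binary) mm$n_cases else NA_integer_,
           controls_m = if (binary) mm$n_controls else NA_integer_,
           n_f = fm$n_total, n_m = mm$n_total,
           mf_case_ratio = round(m_count / f_count, 2),
           n_variants = nrow(p))
  })
}

#' Write a harmonized pair as tab-delimited text
#'
#' Fixed column order: variant_id, chr, pos, ea, oa, beta_f, se_f, p_f, n_f,
#' beta_m, se_m, p_m, n_m. Gzip-compressed when `path` ends in `.gz`.
#'
#' @param pair A `harmonized_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(pair, path) {
  cols <- c("variant_id", "chr", "pos", "ea", "oa",
            "beta_f", "se_f", "p_f", "n_f", "beta_m", "se_m", "p_m", "n_m")
  readr::write_tsv(as_tibble(pair)[cols], path, progress = FALSE)
  invisible(path)
}

#' Write per-sex summary statistics as tab-delimited text
#'
#' Emits the dialect [read_sumstats()] reads back (columns SNP, CHR, BP, A1,
#' A2, BETA, SE, P, N, EAF). Gzip-compressed when `path` ends in `.gz`.
#'
#' @param s A `sumstats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  out <- tibble(SNP = s$variant_id, CHR = s$chr, BP = s$pos, A1 = s$ea,
                A2 = s$oa, BETA = s$beta, SE = s$se, P = s$p, N = s$n,
                EAF = s$eaf)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Default column map for files written by [write_sumstats()]
#' @return Named character vector usable as `column_map` in [read_sumstats()].
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chr = "CHR", pos = "BP", ea = "A1", oa = "A2",
    beta = "BETA", se = "SE", p = "P", n = "N", eaf = "EAF")
}
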