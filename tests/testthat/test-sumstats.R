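test_that("read_sumstats parses, filters non-autosomal rows and logs drops", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "SNP CHR BP A1 A2 OR SE P FRQ",
    "rs1 1 1000 A G 1.0 0.05 1.0 0.30",
    "rs2 2 2000 C T 1.105 0.04 0.02 0.45",
    "rs3 22 3000 G A 0.95 0.06 0.40 0.10",
    "rs4 X 4000 A G 1.02 0.05 0.70 0.20",
    "rs5 3 5000 T C notanumber 0.05 0.50 0.25"
  ), path)
  cm <- c(variant_id = "SNP", chr = "CHR", pos = "BP", ea = "A1", oa = "A2",
          or = "OR", se = "SE", p = "P", eaf = "FRQ")
  s <- read_sumstats(path, cm, trait_label = "t", sex = "female",
                     trait_type = "binary", n_total = 1000)

  expect_s3_class(s, "sumstats")
  expect_equal(nrow(s), 3)
  expect_equal(s$beta[s$variant_id == "rs1"], 0)          # log(OR = 1)
  expect_equal(s$beta[s$variant_id == "rs2"], log(1.105))
  expect_equal(s$n, rep(1000, 3))                          # n_total fallback
  rep <- attr(s, "read_report")
  expect_equal(rep$rows_read, 5)
  expect_equal(rep$dropped_non_autosomal, 1)
  expect_equal(rep$dropped_non_numeric, 1)

  cm_bad <- cm[setdiff(names(cm), "se")]
  expect_error(read_sumstats(path, cm_bad, "t", "female"), "se")
  cm_wrong <- replace(cm, "se", "SE_MISSING")
  expect_error(read_sumstats(path, cm_wrong, "t", "female"), "SE_MISSING")
})

test_that("common-variant filter keeps MAF > threshold on autosomes only", {
  s <- make_ss(make_records(5, eaf = c(0.005, 0.995, 0.5, 0.011, 0.01)))
  out <- filter_common_autosomal(s)
  expect_equal(out$variant_id, c("rs3", "rs4"))  # 0.01 is not > 0.01
  expect_s3_class(out, "sumstats")

  # filtering never increases the record count, under many random tables
  set.seed(42)
  for (i in 1:20) {
    si <- make_ss(make_records(50, chr = sample(1:22, 50, TRUE),
                               eaf = runif(50)))
    expect_lte(nrow(filter_common_autosomal(si)), nrow(si))
  }
})

test_that("HLA/MHC exclusion removes a closed interval on chromosome 6", {
  s <- make_ss(make_records(
    4, chr = c(6L, 6L, 6L, 7L),
    pos = c(30e6, 24999999, 25e6, 30e6),
    ids = c("in_region", "before", "at_start", "wrong_chr")))
  out <- exclude_region(s)  # defaults: chr6, 25-34 Mb, closed
  expect_setequal(out$variant_id, c("before", "wrong_chr"))

  # exclusion and the MAF filter commute
  s2 <- make_ss(make_records(40, chr = rep(c(6L, 8L), 20),
                             pos = round(seq(20e6, 40e6, length.out = 40)),
                             eaf = rep(c(0.004, 0.3), each = 20)))
  a <- filter_common_autosomal(exclude_region(s2))
  b <- exclude_region(filter_common_autosomal(s2))
  expect_same_table(a, b)
})

test_that("allele harmonization flips swapped alleles and drops the rest", {
  f <- make_ss(make_records(4, ea = c("A", "A", "A", "A"),
                            oa = c("G", "G", "T", "G"),
                            beta = c(0.10, 0.05, 0.2, 0.3)))
  m_rec <- make_records(4, ea = c("G", "A", "A", "A"),
                        oa = c("A", "G", "T", "C"),
                        beta = c(-0.10, 0.05, 0.2, 0.3), eaf = 0.3)
  m <- make_ss(m_rec, sex = "male")

  pair <- harmonize_pair(f, m)
  expect_s3_class(pair, "harmonized_pair")
  # rs1: swapped alleles -> male beta flipped onto the female effect allele
  expect_equal(pair$beta_m[pair$variant_id == "rs1"], 0.10)
  expect_equal(pair$eaf_m[pair$variant_id == "rs1"], 0.7)
  # rs3 is strand-ambiguous (A/T), rs4 irreconcilable (A/G vs A/C)
  expect_setequal(pair$variant_id, c("rs1", "rs2"))
  expect_equal(attr(pair, "report")$dropped_ambiguous, 1)
  expect_equal(attr(pair, "report")$dropped_irreconcilable, 1)

  # keeping ambiguous variants is possible on request
  pair_keep <- harmonize_pair(f, m, drop_ambiguous = FALSE)
  expect_true("rs3" %in% pair_keep$variant_id)

  expect_error(harmonize_pair(f, make_ss(make_records(2, ids = c("zz1", "zz2")),
                                         sex = "male")),
               "no shared variants")
})

test_that("harmonization is idempotent and symmetric", {
  set.seed(7)
  n <- 30
  f <- make_ss(make_records(n, beta = rnorm(n), ea = "A", oa = "G"))
  swap <- runif(n) < 0.5
  m_rec <- make_records(n, beta = rnorm(n), ea = ifelse(swap, "G", "A"),
                        oa = ifelse(swap, "A", "G"), eaf = 0.4)
  m <- make_ss(m_rec, sex = "male")

  pair1 <- harmonize_pair(f, m)
  split <- pair_to_sumstats(pair1)
  pair2 <- harmonize_pair(split$female, split$male)
  expect_same_table(pair1, pair2)

  # swapping the argument order yields the same variants with betas agreeing
  # per variant once orientation onto the shared effect allele is accounted for
  rev <- harmonize_pair(m, f)
  expect_setequal(rev$variant_id, pair1$variant_id)
  idx <- match(pair1$variant_id, rev$variant_id)
  sign_flip <- ifelse(rev$ea[idx] == pair1$ea, 1, -1)
  expect_equal(rev$beta_f[idx] * sign_flip, pair1$beta_m)
  expect_equal(rev$beta_m[idx] * sign_flip, pair1$beta_f)
})

test_that("dataset description reproduces male:female case ratios", {
  mk_pair <- function(label, cf, cm, type = "binary") {
    f <- make_ss(make_records(3), sex = "female", trait_label = label,
                 trait_type = type, n_cases = cf, n_controls = 10000,
                 n_total = cf + 10000)
    m <- make_ss(make_records(3), sex = "male", trait_label = label,
                 trait_type = type, n_cases = cm, n_controls = 10000,
                 n_total = cm + 10000)
    harmonize_pair(f, m)
  }
  d <- describe_datasets(list(mk_pair("ASD", 7498L, 30168L),
                              mk_pair("ADHD", 4945L, 14154L),
                              mk_pair("EQ", 100L, 100L)))
  expect_equal(d$mf_case_ratio, c(4.02, 2.86, 1.00))
  expect_equal(d$n_variants, rep(3L, 3))
})

test_that("summary statistics survive a write/read round trip", {
  s <- make_ss(make_records(10, beta = rnorm(10)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, path)
  s2 <- read_sumstats(path, default_column_map(), trait_label = "trait",
                      sex = "female", n_total = 1000)
  expect_same_table(s2, s)
})
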