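make_gene_bounds <- function() {
  tibble::tibble(gene_id = c("G1", "G2", "G3"),
                 chr = c(1L, 1L, 2L),
                 start_bp = c(1000, 1500, 1000),
                 end_bp = c(2000, 2500, 3000))
}

test_that("SNP-to-gene mapping uses closed intervals and allows overlap", {
  d <- tibble::tibble(variant_id = c("s1", "s2", "s3", "s4"),
                      chr = c(1L, 1L, 1L, 2L),
                      pos = c(1000, 999, 1800, 2000),
                      z = c(1, 2, 3, 4))
  mp <- map_snps_to_genes(d, make_gene_bounds(), window_bp = 0)
  # s1 sits exactly on the start of G1: mapped; s2 is 1 bp upstream: not
  expect_setequal(mp$variant_id[mp$gene_id == "G1"], c("s1", "s3"))
  expect_false("s2" %in% mp$variant_id)
  # s3 falls inside both overlapping genes
  expect_setequal(mp$gene_id[mp$variant_id == "s3"], c("G1", "G2"))
  expect_equal(mp$gene_id[mp$variant_id == "s4"], "G3")
  # a window rescues the upstream SNP
  mp_w <- map_snps_to_genes(d, make_gene_bounds(), window_bp = 10)
  expect_true("s2" %in% mp_w$variant_id)
})

test_that("gene statistic reduces to the single-SNP chi-square test", {
  z <- 2.5
  g <- gene_stat(z, diag(1))
  expect_equal(g$p, pchisq(z^2, df = 1, lower.tail = FALSE))
  expect_equal(g$stat, z^2)

  # perfect LD collapses k SNPs to one effective test
  k <- 6
  R1 <- matrix(1, k, k)
  gk <- gene_stat(rep(z, k), R1)
  expect_equal(gk$p, pchisq(z^2, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("gene p-values are uniform for independent SNPs under the null", {
  set.seed(55)
  k <- 5
  ps <- vapply(1:2000, function(i) gene_stat(rnorm(k), diag(k))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("local LD submatrices mirror the generator's block structure", {
  ld_ref <- simulate_ld(sim_config(m_snps = 100, n_blocks = 10,
                                   block_corr = 0.6, seed = 2))
  ids <- ld_ref$variants$variant_id[1:3]   # same block, adjacent
  R <- ld_submatrix(ld_ref, ids)
  expect_equal(R[1, 2], 0.6)
  expect_equal(R[1, 3], 0.36)
  # across blocks the correlation is zero
  ids2 <- ld_ref$variants$variant_id[c(1, 11)]
  expect_equal(ld_submatrix(ld_ref, ids2)[1, 2], 0)
  expect_error(ld_submatrix(ld_ref, "nope"), "unknown variant")
})

test_that("top-fraction selection respects ties, order and deduplication", {
  set.seed(9)
  tab <- function(p) tibble::tibble(gene_id = paste0("g", seq_along(p)),
                                    chr = 1L, start_bp = 1, end_bp = 2,
                                    n_snps = 1L, stat = 1, p = p)
  p1 <- runif(1000)
  sel <- suppressWarnings(top_fraction(list(A = tab(p1)), fraction = 0.001))
  expect_equal(nrow(sel$per_trait), 1)
  expect_equal(sel$per_trait$gene_id, paste0("g", which.min(p1)))

  # order invariance
  shuf <- tab(p1)[sample(1000), ]
  sel2 <- suppressWarnings(top_fraction(list(A = shuf), fraction = 0.001))
  expect_equal(sel$union, sel2$union)

  # ties at the cutoff are all retained
  p_tie <- c(rep(0.001, 3), runif(997, 0.5, 1))
  sel3 <- suppressWarnings(top_fraction(list(A = tab(p_tie)), 0.001))
  expect_equal(nrow(sel3$per_trait), 3)

  # identical top lists across traits collapse in the union
  sel4 <- top_fraction(list(A = tab(p1), B = tab(p1)), fraction = 0.01)
  expect_equal(length(sel4$union), 10)
})

test_that("over-representation p-values match the exact hypergeometric", {
  bg <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", 1:10), miss = paste0("g", 91:100))
  res <- ora_enrichment(selected = paste0("g", 1:10), sets = sets,
                        background = bg)
  hit <- res[res$set_name == "hit", ]
  expect_equal(hit$overlap, 10)
  expect_equal(hit$p, 1 / choose(100, 10), tolerance = 1e-6)
  expect_equal(res$p[res$set_name == "miss"], 1)
  # BH q-values are monotone in p after sorting
  expect_true(all(diff(res$q[order(res$p)]) >= 0))
  expect_true(all(res$q >= res$p))

  expect_error(ora_enrichment("absent", sets, bg), "subset")
  expect_error(ora_enrichment("g1", sets, character(0)), "empty")
})

test_that("gene bounds and GMT files round-trip from disk", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.tsv")
  writeLines(c("chr1\t999\t2000\tG1", "2\t500\t900\tG2"), bed)
  gb <- read_gene_bounds(bed, zero_based = TRUE)
  expect_equal(gb$start_bp, c(1000, 501))
  expect_equal(gb$chr, c(1L, 2L))

  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(setA = c("G1", "G2", "G3"), setB = "G9"))
})

test_that("gene statistics integrate mapping, LD and aggregation", {
  st <- simulate_study(sim_config(m_snps = 500, n_blocks = 50,
                                  block_corr = 0.5, seed = 6))
  pair <- harmonize_pair(st$female, st$male)
  d <- snp_sexdiff(pair)
  # genes spanning the first SNPs of chromosome 1
  v <- st$truth$ld$variants
  genes <- tibble::tibble(gene_id = c("GA", "GB"), chr = 1L,
                          start_bp = c(min(v$pos), 50001),
                          end_bp = c(50000, 100000))
  gs <- gene_stats(d, genes, st$truth$ld)
  expect_s3_class(gs, "gene_stats")
  expect_true(all(gs$n_snps >= 1))
  expect_true(all(gs$p > 0 & gs$p <= 1))
})
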