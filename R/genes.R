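#' Read gene bounds from a BED-like table
#'
#' Four tab-delimited columns: chrom, start, end, gene_id (no header).
#' Coordinates are held 1-based inclusive internally; set `zero_based = TRUE`
#' for files following the 0-based half-open BED convention.
#'
#' @param path File path.
#' @param zero_based Convert 0-based half-open starts to 1-based closed.
#' @return A tibble (gene_id, chr, start_bp, end_bp).
#' @export
read_gene_bounds <- function(path, zero_based = FALSE) {
  d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                       col_types = "cddc", progress = FALSE)
  start <- if (zero_based) d$start + 1 else d$start
  tibble(gene_id = d$gene_id, chr = parse_chromosome(d$chrom),
         start_bp = start, end_bp = d$end)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then tab-separated member gene ids.
#'
#' @param path File path.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1))
}

#' Map SNPs to genes by position
#'
#' A SNP maps to a gene when start_bp - window <= pos <= end_bp + window
#' (closed interval); SNPs inside overlapping genes map to all of them. Genes
#' with no mapped SNPs are absent from the output.
#'
#' @param d A [snp_sexdiff()] table (variant_id, chr, pos, z).
#' @param genes A gene-bounds tibble from [read_gene_bounds()].
#' @param window_bp Symmetric window around the gene body (default 0).
#' @return A tibble (gene_id, chr, start_bp, end_bp, variant_id, pos, z).
#' @export
map_snps_to_genes <- function(d, genes, window_bp = 0) {
  d <- as_tibble(d)[c("variant_id", "chr", "pos", "z")]
  g <- as_tibble(genes)[c("gene_id", "chr", "start_bp", "end_bp")]
  joined <- dplyr::inner_join(g, d, by = "chr", relationship = "many-to-many")
  out <- dplyr::filter(joined,
                       .data$pos >= .data$start_bp - window_bp,
                       .data$pos <= .data$end_bp + window_bp)
  dplyr::arrange(out, .data$chr, .data$start_bp, .data$pos)
}

#' Gene-level sex-difference statistic with an LD-aware null
#'
#' The gene statistic is the mean squared sex-difference z over the gene's
#' SNPs. Under the null z ~ MVN(0, R) with R the local SNP correlation
#' matrix, so k * stat is the quadratic form sum_i lambda_i chi2_1 with
#' lambda_i the eigenvalues of R. The p-value uses Satterthwaite moment
#' matching of that form by a scaled chi-square: scale = sum(lambda^2) /
#' sum(lambda), df = sum(lambda)^2 / sum(lambda^2).
#'
#' @param z Numeric vector of per-SNP sex-difference z scores in the gene.
#' @param ld_submatrix SNP correlation matrix for those SNPs (positive
#'   semidefinite, same order as `z`).
#' @return A one-row tibble: n_snps, stat, scale, df, p.
#' @export
gene_stat <- function(z, ld_submatrix) {
  k <- length(z)
  if (k == 0) return(tibble(n_snps = 0L, stat = NA_real_, scale = NA_real_,
                            df = NA_real_, p = NA_real_))
  stopifnot(is.matrix(ld_submatrix), nrow(ld_submatrix) == k,
            ncol(ld_submatrix) == k)
  lambda <- eigen(ld_submatrix, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  s1 <- sum(lambda)
  s2 <- sum(lambda^2)
  if (s1 <= 0) {
    return(tibble(n_snps = k, stat = mean(z^2), scale = NA_real_,
                  df = NA_real_, p = NA_real_))
  }
  scale <- s2 / s1
  df <- s1^2 / s2
  Q <- sum(z^2)
  tibble(n_snps = k, stat = Q / k, scale = scale, df = df,
         p = pchisq(Q / scale, df = df, lower.tail = FALSE))
}

#' Local SNP correlation submatrix from a synthetic LD reference
#'
#' @param ld_ref An `ld_reference` from [simulate_ld()].
#' @param variant_ids Variants to extract, in the desired order.
#' @return The correlation matrix (AR(1) within a block, 0 across blocks).
#' @export
ld_submatrix <- function(ld_ref, variant_ids) {
  stopifnot(inherits(ld_ref, "ld_reference"))
  v <- ld_ref$variants[match(variant_ids, ld_ref$variants$variant_id), ]
  if (anyNA(v$block)) abort("unknown variant id(s) in LD reference")
  same_block <- outer(v$block, v$block, "==")
  dist <- abs(outer(v$idx_in_block, v$idx_in_block, "-"))
  R <- ifelse(same_block, ld_ref$rho^dist, 0)
  diag(R) <- 1
  R
}

#' Gene statistics for every gene with mapped SNPs
#'
#' @param d A [snp_sexdiff()] table.
#' @param genes Gene bounds tibble.
#' @param ld_ref An `ld_reference` supplying local SNP correlations.
#' @param window_bp Mapping window (default 0).
#' @return A tibble of class `gene_stats` with one row per mapped gene:
#'   gene_id, chr, start_bp, end_bp, n_snps, stat, p.
#' @export
gene_stats <- function(d, genes, ld_ref, window_bp = 0) {
  mapping <- map_snps_to_genes(d, genes, window_bp)
  out <- mapping |>
    dplyr::group_by(.data$gene_id, .data$chr, .data$start_bp, .data$end_bp) |>
    dplyr::group_modify(function(g, key) {
      gene_stat(g$z, ld_submatrix(ld_ref, g$variant_id))[
        c("n_snps", "stat", "p")]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chr, .data$start_bp)
  structure(out, class = c("gene_stats", class(tibble())),
            trait_label = attr(d, "trait_label"))
}

#' Select the top fraction of genes per trait and their union
#'
#' Per trait, the ceiling(fraction * n_genes) genes with smallest p are
#' selected; ties at the cutoff p are all included. The union across traits
#' is deduplicated.
#'
#' @param gene_tables A named list of [gene_stats()] tibbles, one per trait.
#' @param fraction Fraction of genes to take per trait (default 0.001).
#' @return A list with `per_trait` (tibble: trait, gene_id, p) and `union`
#'   (character vector of gene ids).
#' @export
top_fraction <- function(gene_tables, fraction = 0.001) {
  stopifnot(fraction > 0, fraction <= 1)
  per_trait <- purrr::imap_dfr(gene_tables, function(tab, nm) {
    tab <- dplyr::filter(as_tibble(tab), is.finite(.data$p))
    n_take <- max(1L, ceiling(fraction * nrow(tab)))
    if (nrow(tab) < 1 / fraction) {
      warn(sprintf("trait %s has fewer than %d genes; taking %d",
                   nm, ceiling(1 / fraction), n_take))
    }
    tab <- dplyr::arrange(tab, .data$p, .data$gene_id)
    cutoff <- tab$p[min(n_take, nrow(tab))]
    sel <- tab[tab$p <= cutoff, ]
    tibble(trait = nm, gene_id = sel$gene_id, p = sel$p)
  })
  list(per_trait = per_trait, union = sort(unique(per_trait$gene_id)))
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each set, the upper-tail hypergeometric probability of the observed
#' overlap between the selected gene list and the set, both intersected with
#' the background universe; q-values are Benjamini-Hochberg across sets.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `background`).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe tested.
#' @return A tibble of class `ora_result`, sorted by p: set_name, set_size,
#'   overlap, p, q.
#' @export
ora_enrichment <- function(selected, sets, background) {
  background <- unique(background)
  if (length(background) == 0) abort("background gene universe is empty")
  selected <- unique(selected)
  if (!all(selected %in% background)) {
    abort("selected genes must be a subset of the background")
  }
  n_bg <- length(background)
  n_sel <- length(selected)
  res <- purrr::imap_dfr(sets, function(genes, nm) {
    set_bg <- intersect(genes, background)
    ov <- length(intersect(set_bg, selected))
    p <- phyper(ov - 1, length(set_bg), n_bg - length(set_bg), n_sel,
                lower.tail = FALSE)
    tibble(set_name = nm, set_size = length(set_bg), overlap = ov, p = p)
  })
  res$q <- p.adjust(res$p, method = "BH")
  res <- dplyr::arrange(res, .data$p, .data$set_name)
  structure(res, class = c("ora_result", class(tibble())))
}
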