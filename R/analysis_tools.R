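#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1].
#' @param n_tests number of tests (e.g. 16,000 genes per phenotype, giving
#'   0.05/16,000 = 3.125e-6, conventionally printed as 3e-6).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1)
    stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Gene-set enrichment odds ratio with hypergeometric p-value
#'
#' Ratio of the hit proportion inside a gene set to the hit proportion in
#' the remainder of the universe:
#' \deqn{OR = \frac{hits/set}{(total\,hits - hits)/(universe - set)}}
#' with an inclusive upper-tail hypergeometric p-value,
#' P(X >= hits) when drawing `set_size` genes from a universe containing
#' `hits_total` successes.
#'
#' @param hits_in_set significant genes inside the set.
#' @param set_size size of the gene set.
#' @param hits_total significant genes in the whole universe.
#' @param universe total testable genes.
#' @return list with `odds_ratio` (`Inf` with `zero_denominator = TRUE`
#'   when no outside hits exist) and `pvalue`.
#' @export
enrichment_or <- function(hits_in_set, set_size, hits_total, universe) {
  stopifnot(hits_in_set >= 0, hits_in_set <= min(set_size, hits_total),
            set_size <= universe, hits_total <= universe)
  outside_hits <- hits_total - hits_in_set
  outside_size <- universe - set_size
  zero_denom <- outside_hits == 0 || outside_size == 0
  or <- if (zero_denom) Inf
  else (hits_in_set / set_size) / (outside_hits / outside_size)
  p <- stats::phyper(hits_in_set - 1, hits_total, universe - hits_total,
                     set_size, lower.tail = FALSE)
  list(odds_ratio = or, pvalue = p, zero_denominator = zero_denom)
}

#' Trait-trait correlation of per-gene causal Z-statistics
#'
#' Pearson correlation, over a subset of independent genes, between the
#' TWMR Z-statistics of each unordered trait pair ("expression
#' correlation" between traits), with Benjamini-Hochberg FDR across all
#' pairs. Trait columns that are constant over the gene subset yield an
#' undefined correlation, reported as NA.
#'
#' @param zmat genes x traits numeric matrix of causal Z-statistics
#'   (dimnames used for labels).
#' @param gene_subset rows to use (ids or indices); all genes by default.
#'   At least 3 genes are required.
#' @return list of traits x traits matrices `rho` (unit diagonal,
#'   symmetric), `pvalue` and `fdr` (BH-adjusted over the unordered pairs).
#' @export
trait_expression_correlation <- function(zmat, gene_subset = NULL) {
  zmat <- as.matrix(zmat)
  if (!is.null(gene_subset)) {
    idx <- if (is.character(gene_subset)) match(gene_subset, rownames(zmat))
    else gene_subset
    if (anyNA(idx)) stop("gene_subset contains genes absent from zmat")
    zmat <- zmat[idx, , drop = FALSE]
  }
  if (nrow(zmat) < 3) stop("need at least 3 genes")
  k <- ncol(zmat)
  rho <- diag(1, k)
  pval <- matrix(NA_real_, k, k); diag(pval) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(zmat[, i]) == 0 || stats::sd(zmat[, j]) == 0) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(zmat[, i], zmat[, j])
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pval[i, j] <- pval[j, i] <- ct$p.value
  }
  up <- upper.tri(pval)
  fdr <- matrix(NA_real_, k, k); diag(fdr) <- 0
  fdr[up] <- stats::p.adjust(pval[up], method = "BH")
  fdr[lower.tri(fdr)] <- t(fdr)[lower.tri(fdr)]
  dn <- list(colnames(zmat), colnames(zmat))
  dimnames(rho) <- dimnames(pval) <- dimnames(fdr) <- dn
  list(rho = rho, pvalue = pval, fdr = fdr)
}

#' Select an independent gene subset for trait-trait correlation
#'
#' Greedy policy: genes are visited in genomic order and accepted when they
#' share no instrument SNP with, and lie at least `min_dist` bp from, every
#' already-accepted gene. The policy label is attached to the result so
#' downstream output can record how the subset was produced.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start` and optionally
#'   a list-column or comma-separated `snps` of instrument ids.
#' @param min_dist minimum distance between accepted genes on the same
#'   chromosome (bp).
#' @return character vector of accepted gene ids with attribute `policy`.
#' @export
independent_genes <- function(genes, min_dist = 1e6) {
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  snp_list <- if (is.null(genes$snps)) rep(list(character(0)), nrow(genes))
  else if (is.list(genes$snps)) genes$snps
  else strsplit(as.character(genes$snps), ",", fixed = TRUE)
  kept <- integer(0)
  used_snps <- character(0)
  for (i in seq_len(nrow(genes))) {
    near <- kept[genes$chrom[kept] == genes$chrom[i] &
                   abs(genes$start[kept] - genes$start[i]) < min_dist]
    if (length(near)) next
    if (length(intersect(snp_list[[i]], used_snps))) next
    kept <- c(kept, i)
    used_snps <- c(used_snps, snp_list[[i]])
  }
  structure(genes$gene_id[kept],
            policy = "greedy: no shared instruments, >=1 Mb apart")
}

#' Classify causal genes as known or novel GWAS loci
#'
#' A gene is `known` when any GWAS SNP with p below the genome-wide
#' significance threshold lies within the gene body extended by
#' `window_bp` on both sides; otherwise `novel` (the causal signal was
#' missed by the conventional GWAS).
#'
#' @param estimates data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param gwas data.frame with `chrom`, `pos` and `pvalue`.
#' @param window_bp flanking window around the gene body.
#' @param gws_p genome-wide significance threshold.
#' @return `estimates` with an added `locus_label` column.
#' @export
classify_novel_loci <- function(estimates, gwas, window_bp = 500000,
                                gws_p = 5e-8) {
  sig <- gwas[!is.na(gwas$pvalue) & gwas$pvalue < gws_p, , drop = FALSE]
  estimates$locus_label <- vapply(seq_len(nrow(estimates)), function(i) {
    hit <- sig$chrom == estimates$chrom[i] &
      sig$pos >= estimates$start[i] - window_bp &
      sig$pos <= estimates$end[i] + window_bp
    if (any(hit)) "known" else "novel"
  }, character(1))
  estimates
}
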