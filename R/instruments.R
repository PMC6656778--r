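#' Stepwise conditional selection of independent eQTLs for one gene
#'
#' Forward stepwise approximate conditional analysis on summary statistics,
#' using reference-panel LD in place of individual-level genotypes. The
#' candidate pool is the gene's cis-eQTLs passing the marginal screen
#' (`pvalue < p_marginal`, the FDR < 0.05 equivalent). Selection starts
#' from the smallest marginal p-value; at each step the conditional
#' Z-statistic of every remaining candidate j given the selected set S is
#' computed on the standardized scale as
#' \deqn{z_{j|S} = (z_j - R_{jS} R_{SS}^{-1} z_S) /
#'   \sqrt{1 - R_{jS} R_{SS}^{-1} R_{Sj}}}
#' (the joint least-squares solution reconstructed from marginal effects
#' and LD), and the candidate with the smallest conditional p is added if
#' that p is below `p_entry`. Candidates with r^2 > `r2_collinear` to any
#' selected SNP are ineligible, guarding against collinear reconstruction.
#'
#' @param gene gene id.
#' @param eqtls data.frame of eQTL records ([read_eqtl()] columns),
#'   restricted to the gene's cis window.
#' @param panel a [ld_panel()] covering the candidate SNPs.
#' @param p_entry conditional p-value required to enter the model.
#' @param p_marginal marginal p-value screen applied to the pool.
#' @param r2_collinear collinearity guard.
#' @return the selected eQTL records with `conditional_p` filled (the
#'   conditional p at entry; the first SNP's equals its marginal p), in
#'   selection order. Zero rows when nothing passes.
#' @export
select_independent_eqtls <- function(gene, eqtls, panel, p_entry = 1e-3,
                                     p_marginal = 1.829e-5,
                                     r2_collinear = 0.9) {
  pool <- eqtls[eqtls$gene_id == gene & !is.na(eqtls$pvalue) &
                  eqtls$pvalue < p_marginal, , drop = FALSE]
  if (nrow(pool) == 0) return(pool)
  pool <- pool[order(pool$pvalue, pool$pos, pool$variant_id), , drop = FALSE]
  ld <- compute_ld(panel, pool$variant_id)
  R <- ld$r
  z <- pool$beta / pool$se
  n <- nrow(pool)
  selected <- integer(0)
  cond_p <- numeric(0)
  repeat {
    remaining <- setdiff(seq_len(n), selected)
    if (!length(remaining)) break
    if (!length(selected)) {
      best <- remaining[which.min(pool$pvalue[remaining])]
      if (pool$pvalue[best] >= p_entry) break
      selected <- best
      cond_p <- pool$pvalue[best]
      next
    }
    Rss_inv <- solve(R[selected, selected, drop = FALSE])
    pj <- rep(NA_real_, length(remaining))
    for (ii in seq_along(remaining)) {
      j <- remaining[ii]
      rjs <- R[j, selected, drop = FALSE]
      if (any(rjs^2 > r2_collinear)) next
      denom <- 1 - drop(rjs %*% Rss_inv %*% t(rjs))
      if (denom <= 0) next
      zc <- (z[j] - drop(rjs %*% Rss_inv %*% z[selected])) / sqrt(denom)
      pj[ii] <- 2 * stats::pnorm(-abs(zc))
    }
    if (all(is.na(pj))) break
    ii_best <- which.min(pj)
    if (pj[ii_best] >= p_entry) break
    selected <- c(selected, remaining[ii_best])
    cond_p <- c(cond_p, pj[ii_best])
  }
  out <- pool[selected, , drop = FALSE]
  out$conditional_p <- cond_p
  rownames(out) <- NULL
  out
}

# sentinel for loci that cannot be analyzed, carrying the reason code
locus_skip <- function(reason) {
  structure(list(reason = reason), class = "twmr_locus_skip")
}

#' Build the multivariable design for a focal gene
#'
#' Implements the locus-assembly workflow: (1) take the focal gene's
#' independent eQTLs; (2) include as exposures every gene for which any of
#' those SNPs is a significant eQTL (`fdr < fdr_max`); (3) extend the
#' instruments to each included gene's own independent eQTLs; (4) prune the
#' SNP union to pairwise r^2 < `r2_prune` (priority: focal-gene p-value,
#' then the minimum p over included genes); (5) fill `E` with marginal eQTL
#' betas (0 where a SNP is not a significant eQTL of a gene) and `G` from
#' the harmonized GWAS. SNPs absent from the GWAS are dropped with a
#' message; genes left with an all-zero E column are removed with a
#' message.
#'
#' @param focal focal gene id.
#' @param eqtls all eQTL records (harmonizable with `gwas` by variant id).
#' @param panel a [ld_panel()].
#' @param gwas harmonized GWAS table ([harmonize_alleles()] output, or any
#'   data.frame with `variant_id` and `beta_gwas`).
#' @param fdr_max marginal significance screen for locus membership.
#' @param p_marginal,p_entry,r2_collinear stepwise-selection settings
#'   (see [select_independent_eqtls()]).
#' @param r2_prune pairwise LD ceiling among retained instruments.
#' @param n_eqtl,n_gwas study sample sizes for default entry variances.
#' @return a [instrument_set()], or a `twmr_locus_skip` object carrying a
#'   machine-readable `reason` (e.g. `"no_instruments"`) when no usable SNP
#'   survives.
#' @export
build_exposure_set <- function(focal, eqtls, panel, gwas, fdr_max = 0.05,
                               p_marginal = 1.829e-5, p_entry = 1e-3,
                               r2_collinear = 0.9, r2_prune = 0.1,
                               n_eqtl = NULL, n_gwas = NULL) {
  selected <- select_independent_eqtls(focal, eqtls, panel,
                                       p_entry = p_entry,
                                       p_marginal = p_marginal,
                                       r2_collinear = r2_collinear)
  if (nrow(selected) == 0)
    return(locus_skip("no_instruments"))
  sig <- eqtls[!is.na(eqtls$fdr) & eqtls$fdr < fdr_max, , drop = FALSE]
  co_genes <- unique(sig$gene_id[sig$variant_id %in% selected$variant_id])
  genes <- c(focal, sort(setdiff(co_genes, focal)))

  per_gene <- lapply(genes, function(g) {
    if (g == focal) selected
    else select_independent_eqtls(g, eqtls, panel, p_entry = p_entry,
                                  p_marginal = p_marginal,
                                  r2_collinear = r2_collinear)
  })
  snps <- unique(unlist(lapply(per_gene, `[[`, "variant_id")))
  # deterministic ordering before pruning: focal-gene p, then min p
  focal_p <- selected$pvalue[match(snps, selected$variant_id)]
  min_p <- vapply(snps, function(s) {
    p <- sig$pvalue[sig$variant_id == s & sig$gene_id %in% genes]
    if (length(p)) min(p) else Inf
  }, numeric(1))
  priority <- ifelse(is.na(focal_p), 1 + min_p, focal_p)
  ord <- order(priority, min_p, snps)
  snps <- snps[ord]; priority <- priority[ord]

  in_gwas <- snps %in% gwas$variant_id
  if (any(!in_gwas))
    message(sum(!in_gwas), " instrument SNP(s) absent from GWAS, dropped")
  snps <- snps[in_gwas]; priority <- priority[in_gwas]
  if (!length(snps)) return(locus_skip("no_instruments"))

  ld <- compute_ld(panel, snps)
  snps <- prune(snps, ld, r2_max = r2_prune, priority = priority)

  E <- matrix(0, length(snps), length(genes),
              dimnames = list(snps, genes))
  for (j in seq_along(genes)) {
    rec <- sig[sig$gene_id == genes[j] & sig$variant_id %in% snps, ]
    E[rec$variant_id, j] <- rec$beta
  }
  nonzero <- colSums(E != 0) > 0
  if (any(!nonzero)) {
    message("gene(s) without a contributing instrument removed: ",
            paste(genes[!nonzero], collapse = ", "))
    E <- E[, nonzero, drop = FALSE]
    genes <- genes[nonzero]
  }
  if (!focal %in% genes) return(locus_skip("no_instruments"))
  G <- gwas$beta_gwas[match(snps, gwas$variant_id)]
  C <- compute_ld(panel, snps)$r
  n_eqtl <- n_eqtl %||% suppressWarnings(max(eqtls$n, na.rm = TRUE))
  n_gwas <- n_gwas %||% if ("n" %in% names(gwas))
    suppressWarnings(max(gwas$n, na.rm = TRUE)) else NA
  if (!is.finite(n_eqtl) || !is.finite(n_gwas) || n_eqtl <= 0 ||
      n_gwas <= 0)
    stop("eQTL/GWAS sample sizes unavailable: supply n_eqtl and n_gwas ",
         "or provide an 'n' column in the summary inputs")
  instrument_set(E, G, C, snps = snps, genes = genes, focal_gene = focal,
                 n_eqtl = n_eqtl, n_gwas = n_gwas)
}

#' Drop one gene from each highly co-regulated pair
#'
#' Physically close genes often share regulatory variants, making their
#' instrument effect profiles nearly collinear. For every gene pair sharing
#' at least `min_shared` independent eQTLs, the Pearson correlation r of
#' the two genes' eQTL Z-scores over the shared SNPs is computed; when
#' r^2 >= `r2_max` the gene with fewer total instruments is dropped (ties
#' broken lexicographically by gene id). Pairs sharing fewer than
#' `min_shared` SNPs are always kept (the correlation would be degenerate).
#'
#' @param zscores data.frame with columns `gene_id`, `variant_id`, `z`:
#'   each gene's independent eQTLs and their Z-scores.
#' @param r2_max squared-correlation threshold (inclusive).
#' @param min_shared minimum shared SNPs for a defined correlation.
#' @return list with `kept` (gene ids) and `dropped` (data.frame `gene_id`,
#'   `paired_with`, `r2`).
#' @export
filter_correlated_genes <- function(zscores, r2_max = 0.4, min_shared = 3) {
  genes <- sort(unique(zscores$gene_id))
  n_instr <- table(zscores$gene_id)
  dropped <- data.frame(gene_id = character(0), paired_with = character(0),
                        r2 = numeric(0), stringsAsFactors = FALSE)
  active <- genes
  if (length(genes) >= 2) {
    pairs <- utils::combn(genes, 2)
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      if (!(g1 %in% active) || !(g2 %in% active)) next
      z1 <- zscores[zscores$gene_id == g1, ]
      z2 <- zscores[zscores$gene_id == g2, ]
      shared <- intersect(z1$variant_id, z2$variant_id)
      if (length(shared) < min_shared) next
      r <- stats::cor(z1$z[match(shared, z1$variant_id)],
                      z2$z[match(shared, z2$variant_id)])
      if (is.na(r) || r^2 < r2_max) next
      loser <- if (n_instr[[g1]] < n_instr[[g2]]) g1
      else if (n_instr[[g2]] < n_instr[[g1]]) g2
      else min(g1, g2)
      active <- setdiff(active, loser)
      dropped <- rbind(dropped, data.frame(
        gene_id = loser, paired_with = setdiff(c(g1, g2), loser),
        r2 = r^2, stringsAsFactors = FALSE))
    }
  }
  list(kept = active, dropped = dropped)
}
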