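#' Run the per-gene causal screen over all focal genes
#'
#' Wires the modules together: QC-filter both summary inputs, harmonize
#' alleles, and for every requested focal gene build the multivariable
#' design ([build_exposure_set()]) and run the estimator with the
#' heterogeneity filter ([twmr_locus()]). Per-gene failures are recorded as
#' reason codes and the screen continues. Output is deterministic given the
#' inputs; shuffling input file rows changes nothing but row order.
#'
#' @param gwas,eqtl summary data.frames ([read_gwas()]/[read_eqtl()]) or
#'   file paths.
#' @param panel a [ld_panel()].
#' @param genes focal genes to screen; defaults to every gene with at
#'   least one significant eQTL (eGene).
#' @param config named list of thresholds; missing entries take the
#'   defaults of [screen_config()].
#' @param out_dir when non-NULL, writes `twmr_results.tsv` and a JSON-lines
#'   audit log `twmr_screen.log.jsonl` (one record per gene and per
#'   filtered SNP rule) there.
#' @return data.frame with one row per focal gene ([twmr_locus()] columns).
#' @export
run_screen <- function(gwas, eqtl, panel, genes = NULL,
                       config = screen_config(), out_dir = NULL) {
  config <- utils::modifyList(screen_config(), as.list(config))
  if (is.character(gwas)) gwas <- read_gwas(gwas)
  if (is.character(eqtl)) eqtl <- read_eqtl(eqtl)
  qc_g <- qc_filter(gwas)
  qc_e <- qc_filter(eqtl)
  harm <- harmonize_alleles(qc_g$kept, qc_e$kept)
  gwas_n <- qc_g$kept$n[match(harm$variant_id, qc_g$kept$variant_id)]
  gwas_h <- unique(data.frame(variant_id = harm$variant_id,
                              beta_gwas = harm$beta_gwas,
                              se_gwas = harm$se_gwas,
                              n = if (is.null(gwas_n)) NA else gwas_n,
                              stringsAsFactors = FALSE))
  eqtl_h <- data.frame(variant_id = harm$variant_id, gene_id = harm$gene_id,
                       chrom = harm$chrom, pos = harm$pos,
                       beta = harm$beta_eqtl, se = harm$se_eqtl,
                       pvalue = harm$p_eqtl, fdr = harm$fdr,
                       n = qc_e$kept$n[match(
                         paste(harm$variant_id, harm$gene_id),
                         paste(qc_e$kept$variant_id, qc_e$kept$gene_id))],
                       stringsAsFactors = FALSE)
  if (is.null(genes)) {
    genes <- sort(unique(
      eqtl_h$gene_id[!is.na(eqtl_h$fdr) & eqtl_h$fdr < config$fdr_eqtl]))
  }
  skip_row <- function(g, code) data.frame(
    gene_id = g, alpha = NA_real_, se = NA_real_, z = NA_real_,
    pvalue = NA_real_, n_snps_used = 0L, n_snps_removed = 0L,
    snps_removed = "", het_pass = FALSE, reason_code = code,
    stringsAsFactors = FALSE)
  audit <- list()
  rows <- lapply(genes, function(g) {
    res <- tryCatch({
      S <- build_exposure_set(g, eqtl_h, panel, gwas_h,
                              fdr_max = config$fdr_eqtl,
                              p_marginal = config$p_eqtl,
                              p_entry = config$p_entry,
                              r2_prune = config$r2_prune,
                              n_eqtl = config$n_eqtl,
                              n_gwas = config$n_gwas)
      if (inherits(S, "twmr_locus_skip")) skip_row(g, S$reason)
      else twmr_locus(S, p_het = config$p_het,
                      max_het_iter = config$max_het_iter)
    }, error = function(e)
      skip_row(g, paste0("error: ", conditionMessage(e))))
    res$gene_id <- g
    audit[[g]] <<- list(gene = g, reason = res$reason_code,
                        n_snps = res$n_snps_used,
                        snps_removed = res$snps_removed)
    res
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(results, file.path(out_dir, "twmr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    con <- file(file.path(out_dir, "twmr_screen.log.jsonl"), "w")
    for (a in audit)
      writeLines(jsonlite::toJSON(a, auto_unbox = TRUE), con)
    writeLines(jsonlite::toJSON(list(config = config), auto_unbox = TRUE),
               con)
    close(con)
  }
  results
}

#' Default thresholds of the causal screen
#'
#' @param fdr_eqtl marginal eQTL FDR screen for locus membership.
#' @param p_eqtl marginal eQTL p-value equivalent of the FDR screen.
#' @param p_entry conditional p-value to enter stepwise selection.
#' @param r2_prune pairwise LD ceiling among instruments.
#' @param r2_gene co-regulated gene exclusion threshold.
#' @param p_het heterogeneity removal threshold.
#' @param max_het_iter heterogeneity iteration cap.
#' @param p_sig significance threshold for reporting (0.05/16,000).
#' @param n_eqtl,n_gwas study sample sizes (required when the summary
#'   files carry no `n` column).
#' @return named list.
#' @export
screen_config <- function(fdr_eqtl = 0.05, p_eqtl = 1.829e-5,
                          p_entry = 1e-3, r2_prune = 0.1, r2_gene = 0.4,
                          p_het = 1e-4, max_het_iter = 3, p_sig = 0.05 / 16000,
                          n_eqtl = NULL, n_gwas = NULL) {
  list(fdr_eqtl = fdr_eqtl, p_eqtl = p_eqtl, p_entry = p_entry,
       r2_prune = r2_prune, r2_gene = r2_gene, p_het = p_het,
       max_het_iter = max_het_iter, p_sig = p_sig,
       n_eqtl = n_eqtl, n_gwas = n_gwas)
}
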