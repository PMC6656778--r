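#' Configuration of the multi- vs single-gene simulation study
#'
#' Defaults reproduce the study conditions of the generative model: a locus
#' of 30 SNPs and 3 genes, an eQTL cohort of 10,000 individuals and an
#' independent GWAS cohort of 100,000, per-SNP pleiotropy degree
#' l ~ Poisson(lambda) (number of genes the SNP regulates), per-gene
#' expression heritability h^2 ~ U(0.01, 0.4) split as variance h^2/l over
#' a pleiotropic SNP's target genes, confounder loadings gamma_E = 0.2 and
#' gamma_T = 0.1, and causal effects alpha ~ N(0, sd 0.05) (gene 1's alpha
#' may be fixed per scenario). Allele frequencies are q ~ U(0.05, 0.5).
#' Residual variances are set so every expression trait and the outcome
#' have unit variance; parameter draws that would make a residual variance
#' negative are redrawn (at most `max_redraws` times).
#'
#' @param n_snps,n_genes locus dimensions.
#' @param n_eqtl,n_gwas cohort sizes.
#' @param lambda_pleio Poisson mean of the per-SNP pleiotropy degree.
#' @param gamma_e,gamma_t confounder effect sizes on expression/trait.
#' @param alpha_sd SD of the causal-effect distribution.
#' @param alpha1 fixed causal effect of gene 1 (`NULL`: drawn like the
#'   others; `0` gives the null used for type-I error).
#' @param h2_range,maf_range uniform ranges for gene heritability and
#'   allele frequency.
#' @param max_redraws redraw budget before the configuration is rejected.
#' @return list of class `twmr_sim_config`.
#' @export
sim_config <- function(n_snps = 30, n_genes = 3, n_eqtl = 10000,
                       n_gwas = 100000, lambda_pleio = 0.4,
                       gamma_e = 0.2, gamma_t = 0.1, alpha_sd = 0.05,
                       alpha1 = NULL, h2_range = c(0.01, 0.4),
                       maf_range = c(0.05, 0.5), max_redraws = 100) {
  stopifnot(n_snps >= 1, n_genes >= 1, n_eqtl > 2, n_gwas > 2,
            lambda_pleio >= 0, alpha_sd >= 0,
            h2_range[1] > 0, h2_range[2] <= 1, h2_range[1] <= h2_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (gamma_e^2 >= 1 || gamma_t^2 >= 1)
    stop("confounder loadings leave no residual variance")
  structure(list(n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
                 n_eqtl = as.integer(n_eqtl), n_gwas = as.integer(n_gwas),
                 lambda_pleio = lambda_pleio, gamma_e = gamma_e,
                 gamma_t = gamma_t, alpha_sd = alpha_sd, alpha1 = alpha1,
                 h2_range = h2_range, maf_range = maf_range,
                 max_redraws = as.integer(max_redraws)),
            class = "twmr_sim_config")
}

# draw locus parameters (q, B, alpha, residual variances), redrawing any
# replicate whose implied residual variance is negative
draw_locus_params <- function(cfg) {
  for (attempt in seq_len(cfg$max_redraws)) {
    q <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    h2 <- stats::runif(cfg$n_genes, cfg$h2_range[1], cfg$h2_range[2])
    l <- pmin(stats::rpois(cfg$n_snps, cfg$lambda_pleio), cfg$n_genes)
    B <- matrix(0, cfg$n_snps, cfg$n_genes)
    for (i in which(l > 0)) {
      g <- sample.int(cfg$n_genes, l[i])
      B[i, g] <- stats::rnorm(l[i], 0, sqrt(h2[g] / l[i]))
    }
    alpha <- stats::rnorm(cfg$n_genes, 0, cfg$alpha_sd)
    if (!is.null(cfg$alpha1)) alpha[1] <- cfg$alpha1
    sig2_e <- 1 - colSums(B^2) - cfg$gamma_e^2
    sig2_t <- 1 - sum(alpha^2) - cfg$gamma_t^2
    if (all(sig2_e > 0) && sig2_t > 0)
      return(list(q = q, h2 = h2, l = l, B = B, alpha = alpha,
                  sig2_e = sig2_e, sig2_t = sig2_t,
                  redraws = attempt - 1L))
  }
  stop("no admissible parameter draw in ", cfg$max_redraws,
       " attempts; total variance exceeds 1 (reduce lambda_pleio or h2)")
}

#' Simulate one locus: eQTL cohort, GWAS cohort and summary statistics
#'
#' Draws locus parameters, then two independent individual-level cohorts
#' sharing the true effect matrix B and causal vector alpha: expression
#' \eqn{E_j = \sum_i \beta_{ij} z_i + \gamma_E c + \epsilon_j} and outcome
#' \eqn{T = \sum_j E_j \alpha_j + \gamma_T c' + \epsilon}, with genotypes
#' s ~ Binomial(2, q) standardized by the generating q, confounders c and
#' c' drawn independently per cohort and individual, and residual variances
#' chosen for unit-variance E and T. Marginal per-SNP summary statistics
#' are computed by simple linear regression within each cohort; the
#' instrument LD matrix is the genotype correlation in the eQTL cohort.
#'
#' With `keep_cohorts = FALSE` the GWAS cohort's latent expression noise is
#' integrated out analytically (the trait given genotypes is Gaussian),
#' which is distributionally identical and much cheaper; with
#' `keep_cohorts = TRUE` the full generative path is run and the
#' individual-level matrices are returned.
#'
#' @param cfg a [sim_config()].
#' @param keep_cohorts return individual-level genotype/expression/trait
#'   data for both cohorts.
#' @return list with `eqtl` (`beta` n_snps x n_genes, `se`, `C`), `gwas`
#'   (`beta`, `se`), `truth` (`B`, `alpha`, `q`, `h2`, `l`, `sig2_e`,
#'   `sig2_t`, `redraws`) and, when kept, `cohorts`.
#' @export
simulate_locus <- function(cfg = sim_config(), keep_cohorts = FALSE) {
  stopifnot(inherits(cfg, "twmr_sim_config"))
  p <- draw_locus_params(cfg)
  eq <- .sim_cohort_cpp(cfg$n_eqtl, p$q, p$B, p$alpha, cfg$gamma_e,
                        cfg$gamma_t, p$sig2_e, p$sig2_t,
                        want_trait = FALSE, want_ld = TRUE,
                        keep = keep_cohorts)
  if (keep_cohorts) {
    gw <- .sim_cohort_cpp(cfg$n_gwas, p$q, p$B, p$alpha, cfg$gamma_e,
                          cfg$gamma_t, p$sig2_e, p$sig2_t,
                          want_trait = TRUE, want_ld = FALSE, keep = TRUE)
  } else {
    # trait | genotypes: mean Z (B alpha), noise absorbing gamma_E c,
    # expression residuals, gamma_T c' and the outcome residual
    noise_sd <- sqrt(cfg$gamma_e^2 * sum(p$alpha)^2 +
                       sum(p$alpha^2 * p$sig2_e) +
                       cfg$gamma_t^2 + p$sig2_t)
    gw <- .sim_trait_summary_cpp(cfg$n_gwas, p$q,
                                 drop(p$B %*% p$alpha), noise_sd)
  }
  out <- list(
    eqtl = list(beta = eq$beta_eqtl, se = eq$se_eqtl, C = eq$C),
    gwas = list(beta = gw$beta_gwas, se = gw$se_gwas),
    truth = p)
  if (keep_cohorts)
    out$cohorts <- list(
      eqtl = list(Z = eq$Z, E = eq$E),
      gwas = list(Z = gw$Z, E = gw$E, trait = gw$trait))
  out
}

# fit one IVW design, returning estimate/se/p for the focal (first) column
fit_design <- function(E, G, C, var_E, var_G, focal = 1L) {
  if (nrow(E) < ncol(E) || qr(E)$rank < ncol(E))
    return(c(alpha = NA_real_, se = NA_real_, p = NA_real_))
  S <- instrument_set(E, G, C, var_E = var_E, var_G = var_G)
  out <- tryCatch({
    a <- estimate_causal_effects(S)
    se <- sqrt(diag(delta_variance(S, a)))
    zp <- z_and_p(a, se)
    c(alpha = unname(a[focal]), se = unname(se[focal]),
      p = unname(zp$pvalue[focal]))
  }, error = function(e) c(alpha = NA_real_, se = NA_real_, p = NA_real_))
  out
}

# fit both estimators on one simulated locus; returns a one-row data.frame
#
# selection = "significant": instruments are SNPs whose marginal eQTL p
# passes `p_sig` (the FDR < 0.05 equivalent); the multi-gene design keeps
# SNPs significant for any gene with E zeroed where a SNP is not a
# significant eQTL of a gene (the real-data convention), the single-gene
# design keeps gene 1's significant eQTLs with k = 1.
# selection = "none": both estimators use all simulated SNPs (the literal
# estimator formula on the full locus).
fit_sim_replicate <- function(sim, cfg, selection = "significant",
                              p_sig = 1.829e-5) {
  E <- sim$eqtl$beta
  G <- sim$gwas$beta
  C <- sim$eqtl$C
  vE <- sim$eqtl$se^2          # per-entry regression variances
  vG <- sim$gwas$se^2
  na <- c(alpha = NA_real_, se = NA_real_, p = NA_real_)
  if (selection == "significant") {
    sig <- 2 * stats::pnorm(-abs(E / sim$eqtl$se)) < p_sig
    keep <- which(rowSums(sig) > 0)
    Em <- (E * sig)[keep, , drop = FALSE]
    gcols <- which(colSums(Em != 0) > 0)
    multi <- if (length(keep) && 1 %in% gcols)
      fit_design(Em[, gcols, drop = FALSE], G[keep],
                 C[keep, keep, drop = FALSE],
                 vE[keep, gcols, drop = FALSE], vG[keep],
                 focal = match(1L, gcols))
    else na
    k1 <- which(sig[, 1])
    single <- if (length(k1))
      fit_design(E[k1, 1, drop = FALSE], G[k1], C[k1, k1, drop = FALSE],
                 vE[k1, 1, drop = FALSE], vG[k1])
    else na
  } else {
    multi <- fit_design(E, G, C, vE, vG)
    single <- fit_design(E[, 1, drop = FALSE], G, C,
                         vE[, 1, drop = FALSE], vG)
  }
  data.frame(alpha_true = sim$truth$alpha[1],
             alpha_multi = multi[["alpha"]], se_multi = multi[["se"]],
             p_multi = multi[["p"]],
             alpha_single = single[["alpha"]], se_single = single[["se"]],
             p_single = single[["p"]])
}

# deterministic 32-bit sub-seed per (seed, cell, replicate)
replicate_seed <- function(seed, cell, rep) {
  s <- (as.double(seed) * 2654435761 + cell * 97003 + rep * 7919) %% 2147483629
  as.integer(s)
}

#' Run the multi- vs single-gene estimator comparison
#'
#' Simulates `n_reps` independent loci per grid cell (pleiotropy level x
#' causal-effect scenario), fits both estimators to each, and aggregates
#' root-mean-squared error and the rejection rate at the nominal level.
#' Each replicate runs under its own RNG seed derived deterministically
#' from `(seed, cell, replicate)`, so any cell is reproducible in
#' isolation and the full table is byte-identical across runs with the
#' same seed.
#'
#' @param lambda_grid pleiotropy levels (Poisson means).
#' @param alpha1_values causal-effect scenarios for gene 1; `NA` means
#'   "drawn from N(0, alpha_sd) like the other genes" (the RMSE scenario);
#'   `0` is the null (type-I error); positive values are power scenarios.
#' @param n_reps replicates per cell.
#' @param seed master seed.
#' @param cfg base [sim_config()]; `lambda_pleio`/`alpha1` are overridden
#'   per cell.
#' @param nominal rejection level for power / type-I rates.
#' @param selection instrument-selection protocol. `"significant"`
#'   (default) admits only SNPs passing the marginal eQTL significance
#'   screen, zeroing `E` entries where a SNP is not a significant eQTL of
#'   a gene, and restricts the single-gene design to gene 1's significant
#'   eQTLs — the convention of the real-data pipeline. `"none"` applies
#'   the estimator formula to all simulated SNPs. Replicates where a
#'   design is unavailable (e.g. gene 1 has no significant eQTL) yield NA
#'   and are excluded from that estimator's aggregates.
#' @param p_sig marginal eQTL significance threshold used by
#'   `selection = "significant"`.
#' @return list of class `twmr_sim_result`: `replicates` (per-replicate
#'   rows) and `summary` (per-cell `rmse_multi`, `rmse_single`,
#'   `rmse_ratio`, `reject_multi`, `reject_single`, `n_reps`).
#' @export
run_comparison <- function(lambda_grid = c(0.2, 0.4, 0.6, 0.8),
                           alpha1_values = NA, n_reps = 1000, seed = 1,
                           cfg = sim_config(), nominal = 0.05,
                           selection = c("significant", "none"),
                           p_sig = 1.829e-5) {
  selection <- match.arg(selection)
  cells <- expand.grid(lambda = lambda_grid, alpha1 = alpha1_values,
                       KEEP.OUT.ATTRS = FALSE)
  reps <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg_cell <- cfg
    cfg_cell$lambda_pleio <- cells$lambda[ci]
    cfg_cell$alpha1 <- if (is.na(cells$alpha1[ci])) NULL else cells$alpha1[ci]
    rows <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(replicate_seed(seed, ci, r))
      sim <- simulate_locus(cfg_cell)
      rows[[r]] <- fit_sim_replicate(sim, cfg_cell, selection, p_sig)
    }
    cell_reps <- do.call(rbind, rows)
    cell_reps$lambda <- cells$lambda[ci]
    cell_reps$alpha1 <- cells$alpha1[ci]
    cell_reps$replicate <- seq_len(n_reps)
    reps[[ci]] <- cell_reps
  }
  replicates <- do.call(rbind, reps)
  summary <- do.call(rbind, lapply(split(
    replicates,
    paste(replicates$lambda, replicates$alpha1)),  # NA prints as a level
    function(d) data.frame(
      lambda = d$lambda[1], alpha1 = d$alpha1[1],
      rmse_multi = sqrt(mean((d$alpha_multi - d$alpha_true)^2,
                             na.rm = TRUE)),
      rmse_single = sqrt(mean((d$alpha_single - d$alpha_true)^2,
                              na.rm = TRUE)),
      reject_multi = mean(d$p_multi < nominal, na.rm = TRUE),
      reject_single = mean(d$p_single < nominal, na.rm = TRUE),
      n_reps = nrow(d),
      n_multi = sum(!is.na(d$p_multi)),
      n_single = sum(!is.na(d$p_single)))))
  summary$rmse_ratio <- summary$rmse_single / summary$rmse_multi
  rownames(summary) <- NULL
  structure(list(replicates = replicates, summary = summary,
                 nominal = nominal, seed = seed),
            class = "twmr_sim_result")
}

#' @export
print.twmr_sim_result <- function(x, digits = 3, ...) {
  cat("Multi- vs single-gene MR simulation,", x$summary$n_reps[1],
      "replicates per cell (seed", x$seed, ")\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
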