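# Instrument selection and locus assembly.

# simulate an individual-level cohort with known causal SNPs for one gene,
# returning marginal summary stats and the genotype panel
sim_eqtl_cohort <- function(n, n_snps, causal, beta, maf = 0.3,
                            ld_with = NULL, ld_noise = 0.02) {
  G <- matrix(rbinom(n * n_snps, 2, maf), n, n_snps)
  if (!is.null(ld_with)) {
    # make each proxy a noisy copy of its source column
    for (j in seq_len(n_snps)) {
      src <- ld_with[j]
      if (!is.na(src)) {
        flip <- rbinom(n, 1, ld_noise) == 1
        G[, j] <- G[, src]
        G[flip, j] <- rbinom(sum(flip), 2, maf)
      }
    }
  }
  colnames(G) <- paste0("rs", seq_len(n_snps))
  y <- drop(scale(G[, causal, drop = FALSE]) %*% beta) + rnorm(n)
  fits <- apply(G, 2, function(g) {
    f <- summary(lm(y ~ g))$coefficients
    c(beta = f["g", 1], se = f["g", 2], p = f["g", 4])
  })
  eq <- data.frame(
    variant_id = colnames(G), gene_id = "focal", chrom = "1",
    pos = seq_len(n_snps) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta = fits["beta", ], se = fits["se", ], pvalue = fits["p", ],
    fdr = pmin(fits["p", ] * 10, 1), n = n, conditional_p = NA_real_,
    stringsAsFactors = FALSE)
  rownames(eq) <- NULL
  list(eqtl = eq, panel = ld_panel(G), y = y, G = G)
}

test_that("a single-signal locus with proxies selects exactly one SNP", {
  set.seed(31)
  # SNP 1 causal, SNPs 2-6 are high-LD proxies of it
  sim <- sim_eqtl_cohort(2000, 8, causal = 1, beta = 0.3,
                         ld_with = c(NA, 1, 1, 1, 1, 1, NA, NA))
  sel <- select_independent_eqtls("focal", sim$eqtl, sim$panel)
  expect_equal(nrow(sel), 1)
  expect_true(sel$variant_id %in% paste0("rs", 1:6))
})

test_that("two independent causal SNPs are both selected with conditional p
           close to the individual-level joint fit", {
  set.seed(32)
  sim <- sim_eqtl_cohort(3000, 6, causal = c(1, 4), beta = c(0.25, 0.2))
  sel <- select_independent_eqtls("focal", sim$eqtl, sim$panel)
  expect_setequal(sel$variant_id, c("rs1", "rs4"))
  # oracle: joint regression on the simulated individuals
  joint <- summary(lm(sim$y ~ sim$G[, 1] + sim$G[, 4]))$coefficients
  p_joint <- joint[2:3, 4]
  second <- sel$variant_id[2]
  p_or <- p_joint[match(second, c("rs1", "rs4"))]
  # compare on the log scale: approximate conditional analysis vs exact fit
  expect_lt(abs(log10(sel$conditional_p[2]) - log10(p_or)),
            0.25 * abs(log10(p_or)) + 1)
})

test_that("no candidate below the marginal screen yields an empty set", {
  set.seed(33)
  sim <- sim_eqtl_cohort(500, 4, causal = 1, beta = 0.01)
  sel <- select_independent_eqtls("focal", sim$eqtl, sim$panel)
  expect_equal(nrow(sel), 0)
})

test_that("build_exposure_set assembles the documented design", {
  set.seed(34)
  n_ind <- 3000
  G <- matrix(rbinom(n_ind * 5, 2, 0.3), n_ind, 5,
              dimnames = list(NULL, paste0("rs", 1:5)))
  panel <- ld_panel(G)
  mk <- function(gene, ids, betas, ps) data.frame(
    variant_id = ids, gene_id = gene, chrom = "1",
    pos = match(ids, paste0("rs", 1:5)) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta = betas, se = 0.01, pvalue = ps, fdr = ps * 100,
    n = 10000L, conditional_p = NA_real_, stringsAsFactors = FALSE)
  # focal gene gA: strong eQTLs rs1-rs3; rs3 shared with gB; gB also rs4
  eqtl <- rbind(
    mk("gA", c("rs1", "rs2", "rs3"), c(0.30, 0.25, 0.20),
       c(1e-30, 1e-25, 1e-20)),
    mk("gB", c("rs3", "rs4"), c(0.22, 0.28), c(1e-18, 1e-26)))
  gwas <- data.frame(variant_id = paste0("rs", 1:5),
                     beta_gwas = c(0.03, 0.025, 0.04, 0.02, 0.0),
                     n = 100000L, stringsAsFactors = FALSE)
  S <- build_exposure_set("gA", eqtl, panel, gwas, n_eqtl = 1e4,
                          n_gwas = 1e5)
  expect_s3_class(S, "twmr_instrument_set")
  expect_equal(S$genes, c("gA", "gB"))        # gB joins via shared rs3
  expect_setequal(S$snps, c("rs1", "rs2", "rs3", "rs4"))
  # E zero pattern: rs1/rs2 only gA, rs3 shared, rs4 only gB
  expect_equal(sum(S$E["rs3", ] != 0), 2)
  expect_equal(sum(S$E["rs1", ] != 0), 1)
  expect_equal(sum(S$E["rs4", ] != 0), 1)
  expect_equal(unname(S$G), gwas$beta_gwas[match(S$snps, gwas$variant_id)])
  # retained SNPs satisfy the pruning threshold exhaustively
  r2 <- compute_ld(panel, S$snps)$r^2
  expect_true(all(r2[upper.tri(r2)] < 0.1))
})

test_that("locus with a lone instrument missing from GWAS is skipped", {
  set.seed(35)
  sim <- sim_eqtl_cohort(2000, 3, causal = 1, beta = 0.3)
  gwas <- data.frame(variant_id = "rs_absent", beta_gwas = 0.1,
                     n = 1e5, stringsAsFactors = FALSE)
  expect_message(
    S <- build_exposure_set("focal", sim$eqtl, sim$panel, gwas,
                            n_eqtl = 2000, n_gwas = 1e5),
    "absent")
  expect_s3_class(S, "twmr_locus_skip")
  expect_equal(S$reason, "no_instruments")
})

test_that("locus assembly is invariant to eQTL row order", {
  set.seed(36)
  sim <- sim_eqtl_cohort(2500, 6, causal = c(1, 4), beta = c(0.3, 0.2))
  gwas <- data.frame(variant_id = paste0("rs", 1:6),
                     beta_gwas = rnorm(6, 0, 0.02), n = 1e5,
                     stringsAsFactors = FALSE)
  S1 <- build_exposure_set("focal", sim$eqtl, sim$panel, gwas,
                           n_eqtl = 2500, n_gwas = 1e5)
  S2 <- build_exposure_set("focal", sim$eqtl[sample(nrow(sim$eqtl)), ],
                           sim$panel, gwas, n_eqtl = 2500, n_gwas = 1e5)
  expect_equal(S1$snps, S2$snps)
  expect_equal(S1$E, S2$E)
  expect_equal(S1$G, S2$G)
})

test_that("co-regulated gene filter drops one gene per correlated pair", {
  zs <- function(g, ids, z) data.frame(gene_id = g, variant_id = ids,
                                       z = z, stringsAsFactors = FALSE)
  ids <- paste0("rs", 1:4)
  z1 <- c(5, -3, 4, 2)
  # identical Z vectors: r^2 = 1 -> drop one (fewer instruments: gB)
  tab <- rbind(zs("gA", ids, z1), zs("gB", ids[1:3], z1[1:3]))
  out <- filter_correlated_genes(tab)
  expect_equal(out$kept, "gA")
  expect_equal(out$dropped$gene_id, "gB")
  # orthogonal Z vectors: both kept
  tab2 <- rbind(zs("gA", ids, c(1, 1, -1, -1)),
                zs("gB", ids, c(1, -1, 1, -1)))
  expect_setequal(filter_correlated_genes(tab2)$kept, c("gA", "gB"))
  # boundary: r^2 exactly 0.4 is dropped (rule is >=)
  r <- sqrt(0.4)
  z_a <- c(1, -1, 0.5, -0.5)
  z_a <- (z_a - mean(z_a)) / sd(z_a)
  resid <- c(0.3, 0.3, -0.8, 0.2)
  resid <- resid - mean(resid)
  resid <- resid - z_a * sum(resid * z_a) / sum(z_a^2)
  z_b <- r * z_a + sqrt(1 - 0.4) * resid / sqrt(mean(resid^2) * 4 / 3)
  tab3 <- rbind(zs("gA", ids, z_a), zs("gB", ids, z_b))
  expect_equal(cor(z_a, z_b)^2, 0.4, tolerance = 1e-10)
  expect_equal(nrow(filter_correlated_genes(tab3)$dropped), 1)
  # fewer than 3 shared SNPs: kept regardless of correlation
  tab4 <- rbind(zs("gA", ids[1:2], c(5, -5)), zs("gB", ids[1:2], c(5, -5)))
  expect_setequal(filter_correlated_genes(tab4)$kept, c("gA", "gB"))
})
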