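# The estimator and its sampling theory, checked against independent
# oracles: whitened least squares (lm on Cholesky-transformed data),
# finite-difference Jacobians, and Monte-Carlo resampling.

gls_oracle <- function(E, G, C) {
  # whiten by the Cholesky factor of C and fit by ordinary lm
  W <- solve(t(chol(C)))
  unname(coef(lm(drop(W %*% G) ~ drop(W %*% E) - 1)))
}

test_that("scalar design reduces to the Wald ratio", {
  a <- estimate_causal_effects(matrix(0.5), G = 0.25, C = matrix(1))
  expect_equal(unname(a), 0.5)
})

test_that("noiseless multi-gene design is recovered exactly", {
  S <- toy_instrument_set(n = 6, k = 2, alpha = c(0.3, -0.2))
  expect_equal(unname(estimate_causal_effects(S)), c(0.3, -0.2),
               tolerance = 1e-12)
})

test_that("estimator equals whitened least squares on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    k <- sample(1:min(4, n), 1)
    E <- matrix(rnorm(n * k), n, k)
    G <- rnorm(n)
    rho <- runif(1, 0, 0.7)
    C <- rho^abs(outer(1:n, 1:n, "-"))
    expect_equal(unname(estimate_causal_effects(E, G, C)),
                 gls_oracle(E, G, C), tolerance = 1e-10)
  }
})

test_that("estimator is scale-equivariant", {
  S <- toy_instrument_set(n = 8, k = 2, rho = 0.4)
  S$G <- S$G + rnorm(8, 0, 0.01)
  a <- estimate_causal_effects(S)
  S2 <- S; S2$G <- 3 * S$G
  expect_equal(estimate_causal_effects(S2), 3 * a, tolerance = 1e-12)
  S3 <- S; S3$E[, 2] <- 2 * S$E[, 2]
  a3 <- estimate_causal_effects(S3)
  expect_equal(unname(a3[2]), unname(a[2]) / 2, tolerance = 1e-12)
  expect_equal(unname(a3[1]), unname(a[1]), tolerance = 1e-12)
})

test_that("rank-deficient and underdetermined designs error with context", {
  E <- cbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))
  expect_error(estimate_causal_effects(E, G = rnorm(3)), "rank deficient")
  expect_error(estimate_causal_effects(matrix(rnorm(2), 1, 2), G = 0.1),
               "fewer instruments")
})

test_that("delta variance vanishes with error-free inputs", {
  S <- toy_instrument_set()
  V <- delta_variance(S, var_E = 0, var_G = 0)
  expect_equal(max(abs(V)), 0)
})

test_that("delta variance matches finite-difference Jacobians", {
  set.seed(7)
  n <- 5; k <- 2
  E <- matrix(rnorm(n * k, 0, 0.3), n, k)
  G <- rnorm(n, 0, 0.1)
  C <- 0.5^abs(outer(1:n, 1:n, "-"))
  var_E <- matrix(runif(n * k, 1e-5, 1e-4), n, k)
  var_G <- runif(n, 1e-5, 1e-4)
  f <- function(Evec, Gvec)
    estimate_causal_effects(matrix(Evec, n, k), Gvec, C)
  h <- 1e-6
  a0 <- f(as.vector(E), G)
  V_fd <- matrix(0, k, k)
  for (j in seq_len(n * k)) {
    Ep <- as.vector(E); Ep[j] <- Ep[j] + h
    J <- (f(Ep, G) - a0) / h
    V_fd <- V_fd + as.vector(var_E)[j] * tcrossprod(J)
  }
  for (i in seq_len(n)) {
    Gp <- G; Gp[i] <- Gp[i] + h
    J <- (f(as.vector(E), Gp) - a0) / h
    V_fd <- V_fd + var_G[i] * tcrossprod(J)
  }
  V <- delta_variance(E, alpha = a0, var_E = var_E, var_G = var_G,
                      G = G, C = C)
  expect_equal(unname(V), V_fd, tolerance = 1e-4)
})

test_that("scalar delta variance approximates the ratio-estimator formula", {
  E <- 0.4; G <- 0.12
  var_E <- 1e-4; var_G <- 2e-4
  V <- delta_variance(matrix(E), alpha = G / E, var_E = var_E,
                      var_G = var_G, G = G, C = matrix(1))
  expect_equal(drop(V), var_G / E^2 + G^2 * var_E / E^4, tolerance = 1e-10)
})

test_that("delta-method SE tracks the Monte-Carlo SD of the estimator", {
  set.seed(42)
  n <- 8; k <- 2
  B <- matrix(rnorm(n * k, 0, 0.25), n, k)
  alpha_true <- c(0.1, -0.05)
  G0 <- drop(B %*% alpha_true)
  var_E <- 1e-4; var_G <- 1e-5
  reps <- 10000
  est <- matrix(NA_real_, reps, k)
  for (r in seq_len(reps)) {
    Eh <- B + matrix(rnorm(n * k, 0, sqrt(var_E)), n, k)
    Gh <- G0 + rnorm(n, 0, sqrt(var_G))
    est[r, ] <- estimate_causal_effects(Eh, Gh, diag(n))
  }
  V <- delta_variance(B, alpha = alpha_true, var_E = var_E, var_G = var_G,
                      G = G0, C = diag(n))
  expect_lt(max(abs(sqrt(diag(V)) / apply(est, 2, sd) - 1)), 0.10)
})

test_that("z_and_p gives two-sided normal tails", {
  expect_equal(z_and_p(0, 1)$pvalue, 1)
  zp <- z_and_p(1.959964, 1)
  expect_equal(zp$pvalue, 0.05, tolerance = 1e-6)
  expect_error(z_and_p(1, 0))
})

test_that("null-locus Z statistics are standard normal", {
  set.seed(3)
  n <- 6
  B <- matrix(rnorm(n, 0, 0.3), n, 1)
  var_E <- 1e-4; var_G <- 1e-5
  z <- replicate(2000, {
    Eh <- B + rnorm(n, 0, sqrt(var_E))
    Gh <- rnorm(n, 0, sqrt(var_G))   # alpha = 0
    a <- estimate_causal_effects(Eh, Gh, diag(n))
    se <- sqrt(drop(delta_variance(Eh, alpha = a, var_E = var_E,
                                   var_G = var_G, G = Gh, C = diag(n))))
    a / se
  })
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("heterogeneity statistics match a direct formula evaluation", {
  set.seed(9)
  n <- 4
  E <- matrix(c(0.5, 0.4, 0.3, 0.6), n, 1,
              dimnames = list(paste0("rs", 1:n), "g1"))
  alpha_true <- 0.2
  G <- drop(E * alpha_true)
  S <- instrument_set(E, G, n_eqtl = 1e4, n_gwas = 1e5)
  # no deviation: all d = 0, nothing removed
  ht <- heterogeneity_test(S)
  expect_equal(ht$result$d, rep(0, n), ignore_attr = TRUE)
  expect_false(ht$result$discarded_locus)
  expect_length(ht$result$snps_removed, 0)

  # inject a direct (pleiotropic) effect at SNP 3
  G2 <- G; G2[3] <- G2[3] + 10 * sqrt(1e-5)
  S2 <- instrument_set(E, G2, n_eqtl = 1e4, n_gwas = 1e5)
  alpha_hat <- estimate_causal_effects(S2)
  var_a <- drop(delta_variance(S2, alpha_hat))
  d <- G2 - drop(E %*% alpha_hat)
  var_d <- 1e-5 + drop(E^2) * var_a + 1e-4 * alpha_hat^2 + 1e-4 * var_a
  t_stat <- d^2 / var_d
  ht2 <- heterogeneity_test(S2)
  expect_equal(ht2$result$snps_removed[1], "rs3")
  # first-round statistics equal the hand evaluation
  ht_first <- twmr:::het_stats(S2, alpha_hat)
  expect_equal(ht_first$t, unname(t_stat), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("heterogeneity removal caps at three iterations then discards", {
  E <- matrix(rep(0.5, 6), 6, 1,
              dimnames = list(paste0("rs", 1:6), "g1"))
  G <- drop(E * 0.1) + c(0.5, -0.6, 0.7, -0.8, 0, 0)  # four gross outliers
  S <- instrument_set(E, G, n_eqtl = 1e4, n_gwas = 1e5)
  ht <- heterogeneity_test(S)
  expect_length(ht$result$snps_removed, 3)
  expect_equal(ht$result$iterations_run, 3L)
  expect_true(ht$result$discarded_locus)
})

test_that("heterogeneity removal is invariant to SNP input order", {
  set.seed(15)
  S <- toy_instrument_set(n = 8, k = 2)
  S$G <- S$G + rnorm(8, 0, 0.005)
  S$G[5] <- S$G[5] + 0.2
  ht1 <- heterogeneity_test(S)
  perm <- sample(8)
  S2 <- S
  S2$snps <- S$snps[perm]; S2$E <- S$E[perm, ]; S2$G <- S$G[perm]
  S2$C <- S$C[perm, perm]
  ht2 <- heterogeneity_test(S2)
  expect_setequal(ht1$result$snps_removed, ht2$result$snps_removed)
  expect_equal(sort(ht1$instruments$snps), sort(ht2$instruments$snps))
})

test_that("twmr_locus composes the pipeline and reports reason codes", {
  S <- toy_instrument_set(n = 6, k = 2, alpha = c(0.3, -0.2))
  res <- twmr_locus(S)
  expect_equal(res$reason_code, "ok")
  expect_equal(res$alpha, 0.3, tolerance = 1e-10)
  expect_true(res$het_pass)
  expect_equal(res$gene_id, "g1")

  empty <- twmr_locus(NULL)
  expect_equal(empty$reason_code, "no_instruments")
})

test_that("single-gene estimate equals the k=1 design fit", {
  S <- toy_instrument_set(n = 5, k = 1, alpha = 0.25)
  multi <- twmr_locus(S)
  single <- single_gene_estimate(S)
  expect_equal(single$alpha, multi$alpha, tolerance = 1e-10)
  # pleiotropy-free two-gene locus with disjoint instruments:
  # single-gene equals the focal coordinate of the multi-gene fit
  E <- rbind(cbind(c(0.5, 0.4, 0.3), 0), cbind(0, c(0.6, 0.2, 0.4)))
  dimnames(E) <- list(paste0("rs", 1:6), c("g1", "g2"))
  G <- drop(E %*% c(0.3, -0.1))
  S2 <- instrument_set(E, G, n_eqtl = 1e4, n_gwas = 1e5)
  expect_equal(single_gene_estimate(S2)$alpha,
               unname(estimate_causal_effects(S2)["g1"]),
               tolerance = 1e-10)
})
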