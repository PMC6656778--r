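#' Multivariable IVW causal-effect estimator for correlated instruments
#'
#' Estimates the joint causal effect of k gene-expression exposures on an
#' outcome trait from summary statistics:
#' \deqn{\hat\alpha = (E' C^{-1} E)^{-1} (E' C^{-1} G)}
#' where `E` (n x k) holds the univariate SNP-expression effects, `G`
#' (length n) the univariate SNP-trait effects and `C` (n x n) the pairwise
#' LD correlation of the n instrument SNPs from a reference panel. This is
#' the generalized (LD-aware) inverse-variance weighted estimator; with
#' `C = I` and `k = 1` it reduces to the classical IVW combination of Wald
#' ratios.
#'
#' The system is solved through Cholesky factorizations of `C` and
#' `E'C^-1E`; neither matrix is explicitly inverted.
#'
#' @param S a `twmr_instrument_set` (see [instrument_set()]), or an E matrix
#'   when `G` and `C` are supplied separately.
#' @param G SNP-trait effect vector (ignored when `S` is an instrument set).
#' @param C LD correlation matrix (defaults to identity).
#' @return numeric vector of length k of causal-effect estimates, named by
#'   gene when gene names are available.
#' @seealso [delta_variance()], [heterogeneity_test()], [twmr_locus()]
#' @export
estimate_causal_effects <- function(S, G = NULL, C = NULL) {
  d <- as_design(S, G, C)
  n <- nrow(d$E); k <- ncol(d$E)
  if (n < k)
    stop("fewer instruments (", n, ") than exposures (", k, ")")
  qrE <- qr(d$E)
  if (qrE$rank < k) {
    dep <- colnames(d$E)[setdiff(seq_len(k), qrE$pivot[seq_len(qrE$rank)])]
    stop("E is rank deficient; dependent gene columns: ",
         paste(dep, collapse = ", "))
  }
  CiE <- solve_chol(d$C, d$E)
  A <- crossprod(d$E, CiE)
  alpha <- drop(solve_chol(A, crossprod(CiE, d$G)))
  names(alpha) <- colnames(d$E)
  alpha
}

#' Delta-method covariance of the causal-effect estimates
#'
#' First-order propagation of the sampling error of `E` and `G` through the
#' estimator map \eqn{(E, G) \mapsto \hat\alpha}:
#' \deqn{var(\hat\alpha) = J_G \, var(G) \, J_G' + \sum_{i,k} var(E_{ik})
#'   J_{E_{ik}} J_{E_{ik}}'}
#' with analytic Jacobians \eqn{J_G = (E'C^{-1}E)^{-1} E' C^{-1}} and the
#' per-entry `E` Jacobian assembled from the product rule. The `E`-`G` cross
#' term is zero because the eQTL and GWAS samples do not overlap.
#'
#' Entry variances default to `1/n_eqtl` and `1/n_gwas`, the sampling
#' variance of a standardized-scale regression coefficient; per-entry
#' squared standard errors may be supplied instead.
#'
#' @param S instrument set or E matrix (see [estimate_causal_effects()]).
#' @param alpha causal-effect vector as returned by
#'   [estimate_causal_effects()]; estimated internally when `NULL`.
#' @param var_E scalar or n x k matrix of variances of the entries of E.
#' @param var_G scalar or length-n vector of variances of the entries of G.
#' @param G,C as in [estimate_causal_effects()].
#' @return k x k covariance matrix of `alpha`; standard errors are the
#'   square roots of its diagonal.
#' @export
delta_variance <- function(S, alpha = NULL, var_E = NULL, var_G = NULL,
                           G = NULL, C = NULL) {
  d <- as_design(S, G, C)
  n <- nrow(d$E); k <- ncol(d$E)
  if (is.null(alpha)) alpha <- estimate_causal_effects(S, G, C)
  if (is.null(var_E)) var_E <- d$var_E
  if (is.null(var_G)) var_G <- d$var_G
  if (is.null(var_E) || is.null(var_G))
    stop("var_E and var_G are required (supply them or use an instrument ",
         "set carrying sample sizes)")
  var_E <- expand_var(var_E, n, k)
  var_G <- rep_len(as.numeric(var_G), n)
  if (any(var_E < 0) || any(var_G < 0)) stop("variances must be >= 0")

  CiE <- solve_chol(d$C, d$E)
  A <- crossprod(d$E, CiE)
  P <- solve_chol(A, t(CiE))              # J_G, k x n
  Ainv <- solve_chol(A, diag(k))
  resid <- d$G - drop(d$E %*% alpha)
  m <- drop(solve_chol(d$C, resid))       # (C^-1 (G - E alpha))_i
  if (!all(is.finite(P)) || !all(is.finite(m)))
    stop("non-finite Jacobian; check C for near-singularity")

  V <- P %*% (var_G * t(P))
  # d alpha / d E_{ik} = m_i * Ainv[, k] - alpha_k * P[, i]
  for (i in seq_len(n)) {
    for (kk in seq_len(k)) {
      J <- m[i] * Ainv[, kk] - alpha[kk] * P[, i]
      V <- V + var_E[i, kk] * tcrossprod(J)
    }
  }
  dimnames(V) <- list(colnames(d$E), colnames(d$E))
  V
}

#' Z-statistic and two-sided normal p-value
#'
#' @param alpha causal-effect estimate(s).
#' @param se standard error(s), positive.
#' @return list with elements `z` and `pvalue`.
#' @export
z_and_p <- function(alpha, se) {
  stopifnot(all(se > 0))
  z <- alpha / se
  list(z = z, pvalue = 2 * stats::pnorm(-abs(z)))
}

#' Iterative heterogeneity (pleiotropy) filter
#'
#' Cochran-Q-style test for instruments whose trait effect deviates from
#' the effect predicted through the modeled exposures. For SNP i,
#' \deqn{d_i = G_i - \sum_k \alpha_k E_{ik}}
#' \deqn{var(d_i) = var(G_i) + \sum_k E_{ik}^2 var(\alpha_k) +
#'   \sum_k \alpha_k^2 var(E_{ik}) + \sum_k var(E_{ik}) var(\alpha_k)}
#' and \eqn{T_i = d_i^2 / var(d_i)} is referred to a chi-squared
#' distribution with 1 df. While any SNP has \eqn{p < p_{het}} and fewer
#' than `max_iter` removals have been made, the SNP with the largest
#' \eqn{|d_i|} is removed (ties broken by variant id) and the causal
#' effects are re-estimated on the reduced set. A locus still heterogeneous
#' after `max_iter` removals is flagged `discarded_locus`.
#'
#' @param S a `twmr_instrument_set`.
#' @param alpha optional causal-effect vector for the initial test;
#'   re-estimated after every removal.
#' @param p_het removal threshold on the per-SNP chi-squared p-value.
#' @param max_iter maximum number of SNP removals.
#' @return list with `result` (a `twmr_heterogeneity` list: per-SNP `d`,
#'   `var_d`, `t`, `p` from the final round, `snps_removed`,
#'   `iterations_run`, `discarded_locus`) and `instruments` (the pruned
#'   instrument set).
#' @export
heterogeneity_test <- function(S, alpha = NULL, p_het = 1e-4, max_iter = 3) {
  stopifnot(inherits(S, "twmr_instrument_set"))
  if (is.null(alpha)) alpha <- estimate_causal_effects(S)
  removed <- character(0)
  iterations <- 0L
  discarded <- FALSE
  repeat {
    ht <- het_stats(S, alpha)
    flagged <- ht$p < p_het
    if (!any(flagged)) break
    if (iterations >= max_iter) { discarded <- TRUE; break }
    # largest |d|; ties by variant id for order-invariance
    ord <- order(-abs(ht$d), S$snps)
    worst <- S$snps[ord[1]]
    S2 <- drop_snps(S, worst)
    if (nrow(S2$E) < ncol(S2$E)) { discarded <- TRUE; break }
    S <- S2
    removed <- c(removed, worst)
    iterations <- iterations + 1L
    alpha <- estimate_causal_effects(S)
  }
  result <- structure(
    list(d = ht$d, var_d = ht$var_d, t = ht$t, p = ht$p,
         snps = S$snps, snps_removed = removed,
         iterations_run = iterations, discarded_locus = discarded),
    class = "twmr_heterogeneity")
  list(result = result, instruments = S, alpha = alpha)
}

het_stats <- function(S, alpha) {
  E <- S$E; G <- S$G
  var_E <- expand_var(S$var_E, nrow(E), ncol(E))
  var_G <- rep_len(S$var_G, nrow(E))
  var_a <- diag(delta_variance(S, alpha))
  d <- G - drop(E %*% alpha)
  var_d <- var_G +
    drop(E^2 %*% var_a) +
    drop(var_E %*% alpha^2) +
    drop(var_E %*% var_a)
  t <- d^2 / var_d
  list(d = d, var_d = var_d, t = t,
       p = stats::pchisq(t, df = 1, lower.tail = FALSE))
}

#' Full per-locus causal analysis for a focal gene
#'
#' Composition of the whole pipeline: estimate the multivariable causal
#' effects on the instrument set, run the iterative heterogeneity filter,
#' re-estimate on the pruned set, and return the focal gene's estimate with
#' its delta-method standard error, Z-statistic and two-sided p-value.
#'
#' @param S a `twmr_instrument_set` built by [build_exposure_set()] or
#'   [instrument_set()].
#' @param p_het,max_het_iter heterogeneity-filter settings.
#' @return one-row data.frame (a `CausalEstimate`): `gene_id`, `alpha`,
#'   `se`, `z`, `pvalue`, `n_snps_used`, `n_snps_removed`, `snps_removed`
#'   (comma-separated), `het_pass`, `reason_code` (`"ok"`, or a
#'   machine-readable skip reason with NA estimates).
#' @export
twmr_locus <- function(S, p_het = 1e-4, max_het_iter = 3) {
  gene <- if (inherits(S, "twmr_instrument_set")) S$focal_gene else NA_character_
  fail <- function(code) data.frame(
    gene_id = gene, alpha = NA_real_, se = NA_real_, z = NA_real_,
    pvalue = NA_real_, n_snps_used = 0L, n_snps_removed = 0L,
    snps_removed = "", het_pass = FALSE, reason_code = code,
    stringsAsFactors = FALSE)
  if (inherits(S, "twmr_locus_skip")) return(fail(S$reason))
  if (!inherits(S, "twmr_instrument_set") || length(S$snps) == 0)
    return(fail("no_instruments"))
  if (nrow(S$E) < ncol(S$E)) return(fail("too_few_snps"))
  if (qr(S$E)$rank < ncol(S$E)) return(fail("rank_deficient"))
  alpha <- estimate_causal_effects(S)
  het <- heterogeneity_test(S, alpha, p_het = p_het, max_iter = max_het_iter)
  if (het$result$discarded_locus) {
    out <- fail("het_discarded")
    out$n_snps_removed <- length(het$result$snps_removed)
    out$snps_removed <- paste(het$result$snps_removed, collapse = ",")
    return(out)
  }
  S <- het$instruments
  alpha <- het$alpha
  V <- delta_variance(S, alpha)
  se <- sqrt(diag(V))
  zp <- z_and_p(alpha, se)
  i <- match(S$focal_gene, S$genes)
  data.frame(
    gene_id = S$focal_gene, alpha = alpha[i], se = se[i], z = zp$z[i],
    pvalue = zp$pvalue[i], n_snps_used = length(S$snps),
    n_snps_removed = length(het$result$snps_removed),
    snps_removed = paste(het$result$snps_removed, collapse = ","),
    het_pass = TRUE, reason_code = "ok",
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-gene (single-exposure) comparator estimate
#'
#' The same estimator restricted to the focal gene: `E` is reduced to the
#' focal column and k is forced to 1, so other genes at the locus are no
#' longer conditioned on. Used as the comparator in the multi- vs
#' single-gene simulation study.
#'
#' @inheritParams twmr_locus
#' @param heterogeneity run the heterogeneity filter (default `FALSE`:
#'   plain single-exposure estimate).
#' @return one-row data.frame as in [twmr_locus()].
#' @export
single_gene_estimate <- function(S, heterogeneity = FALSE,
                                 p_het = 1e-4, max_het_iter = 3) {
  stopifnot(inherits(S, "twmr_instrument_set"))
  S1 <- restrict_to_gene(S, S$focal_gene)
  if (heterogeneity) return(twmr_locus(S1, p_het, max_het_iter))
  if (length(S1$snps) == 0) return(twmr_locus(S1))
  alpha <- estimate_causal_effects(S1)
  se <- sqrt(diag(delta_variance(S1, alpha)))
  zp <- z_and_p(alpha, se)
  data.frame(
    gene_id = S1$focal_gene, alpha = alpha[1], se = se[1], z = zp$z[1],
    pvalue = zp$pvalue[1], n_snps_used = length(S1$snps),
    n_snps_removed = 0L, snps_removed = "", het_pass = NA,
    reason_code = "ok", stringsAsFactors = FALSE, row.names = NULL)
}

# ---- internal helpers -------------------------------------------------

#' Assemble an instrument set
#'
#' Container for the per-locus multivariable MR design: the n instrument
#' SNPs, the k exposure genes (focal first), the n x k matrix `E` of
#' SNP-expression effects, the length-n vector `G` of SNP-trait effects and
#' the n x n LD matrix `C`.
#'
#' @param E n x k numeric matrix (columns named by gene).
#' @param G length-n numeric vector.
#' @param C n x n LD correlation matrix; identity when `NULL`.
#' @param snps,genes identifiers; defaulted from dimnames when missing.
#' @param focal_gene the gene whose causal effect the design targets;
#'   defaults to the first gene.
#' @param n_eqtl,n_gwas sample sizes of the eQTL and GWAS studies; used for
#'   the default entry variances 1/n on the standardized scale.
#' @param var_E,var_G optional explicit entry variances (squared standard
#'   errors), overriding the 1/n defaults.
#' @return object of class `twmr_instrument_set`.
#' @export
instrument_set <- function(E, G, C = NULL, snps = NULL, genes = NULL,
                           focal_gene = NULL, n_eqtl = NULL, n_gwas = NULL,
                           var_E = NULL, var_G = NULL) {
  E <- as.matrix(E)
  n <- nrow(E); k <- ncol(E)
  if (length(G) != n) stop("length(G) must equal nrow(E)")
  if (is.null(snps)) snps <- rownames(E) %||% paste0("snp", seq_len(n))
  if (is.null(genes)) genes <- colnames(E) %||% paste0("gene", seq_len(k))
  if (is.null(C)) C <- diag(n)
  C <- as.matrix(C)
  stopifnot(nrow(C) == n, ncol(C) == n)
  if (is.null(var_E)) {
    if (!is.null(n_eqtl)) var_E <- 1 / n_eqtl else
      stop("supply var_E or n_eqtl")
  }
  if (is.null(var_G)) {
    if (!is.null(n_gwas)) var_G <- 1 / n_gwas else
      stop("supply var_G or n_gwas")
  }
  dimnames(E) <- list(snps, genes)
  structure(list(focal_gene = focal_gene %||% genes[1], genes = genes,
                 snps = snps, E = E, G = as.numeric(G), C = C,
                 var_E = var_E, var_G = var_G,
                 n_eqtl = n_eqtl, n_gwas = n_gwas),
            class = "twmr_instrument_set")
}

#' @export
print.twmr_instrument_set <- function(x, ...) {
  cat("TWMR instrument set: focal gene", x$focal_gene, "\n")
  cat("  ", length(x$snps), "instrument SNPs x", length(x$genes),
      "exposure genes\n")
  invisible(x)
}

drop_snps <- function(S, ids) {
  keep <- !(S$snps %in% ids)
  S$snps <- S$snps[keep]
  S$E <- S$E[keep, , drop = FALSE]
  S$G <- S$G[keep]
  S$C <- S$C[keep, keep, drop = FALSE]
  if (is.matrix(S$var_E)) S$var_E <- S$var_E[keep, , drop = FALSE]
  if (length(S$var_G) > 1) S$var_G <- S$var_G[keep]
  S
}

restrict_to_gene <- function(S, gene) {
  j <- match(gene, S$genes)
  if (is.na(j)) stop("gene ", gene, " not in instrument set")
  keep <- S$E[, j] != 0
  S$genes <- gene
  S$focal_gene <- gene
  S$E <- S$E[keep, j, drop = FALSE]
  S$G <- S$G[keep]
  S$snps <- S$snps[keep]
  S$C <- S$C[keep, keep, drop = FALSE]
  if (is.matrix(S$var_E)) S$var_E <- S$var_E[keep, j, drop = FALSE]
  if (length(S$var_G) > 1) S$var_G <- S$var_G[keep]
  S
}

as_design <- function(S, G = NULL, C = NULL) {
  if (inherits(S, "twmr_instrument_set"))
    return(list(E = S$E, G = S$G, C = S$C,
                var_E = S$var_E, var_G = S$var_G))
  E <- as.matrix(S)
  if (is.null(G)) stop("G required when S is a plain matrix")
  if (is.null(C)) C <- diag(nrow(E))
  list(E = E, G = as.numeric(G), C = as.matrix(C),
       var_E = NULL, var_G = NULL)
}

expand_var <- function(v, n, k) {
  if (is.matrix(v)) { stopifnot(nrow(v) == n, ncol(v) == k); return(v) }
  matrix(as.numeric(v), n, k)
}

# solve A x = b through a Cholesky factorization (A symmetric pd)
solve_chol <- function(A, b) {
  R <- tryCatch(chol(A), error = function(e)
    stop("matrix not positive definite: ", conditionMessage(e)))
  backsolve(R, forwardsolve(t(R), b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
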