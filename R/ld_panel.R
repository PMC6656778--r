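#' Reference genotype panel for LD estimation
#'
#' Holds an individuals x variants dosage matrix (hard genotypes in
#' \{0, 1, 2\} or real dosages in \[0, 2\]) from which pairwise SNP
#' correlation (LD) is computed. Constant (zero-variance) variants are not
#' retained: LD with them is undefined.
#'
#' @param genotypes numeric matrix, individuals in rows, variants in
#'   columns. Missing dosages are allowed and are mean-imputed per variant
#'   when LD is computed.
#' @param variant_ids variant identifiers; defaults to column names.
#' @return object of class `twmr_ld_panel`.
#' @export
ld_panel <- function(genotypes, variant_ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(variant_ids)) stop("variant_ids required")
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids in panel")
  if (length(variant_ids) != ncol(genotypes))
    stop("variant_ids length must match ncol(genotypes)")
  v <- apply(genotypes, 2, stats::var, na.rm = TRUE)
  constant <- !is.na(v) & v == 0
  if (any(constant)) {
    message(sum(constant), " zero-variance variant(s) dropped from panel")
    genotypes <- genotypes[, !constant, drop = FALSE]
    variant_ids <- variant_ids[!constant]
  }
  colnames(genotypes) <- variant_ids
  structure(list(genotypes = genotypes, variant_index = variant_ids),
            class = "twmr_ld_panel")
}

#' @export
print.twmr_ld_panel <- function(x, ...) {
  cat("LD reference panel:", nrow(x$genotypes), "individuals x",
      length(x$variant_index), "variants\n")
  invisible(x)
}

#' Read an LD panel from a VCF file
#'
#' Uses the GT field (dosage = count of ALT alleles) or, when present, the
#' DS field. Multi-allelic sites and indels are dropped, matching the
#' SNP-biallelic scope of the harmonization step.
#'
#' @param path VCF file (may be gzipped).
#' @param field `"GT"` or `"DS"`.
#' @return a [ld_panel()].
#' @export
read_ld_panel_vcf <- function(path, field = c("GT", "DS")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the vcfR package")
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  if (field == "GT") {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(0, nrow(gt), ncol(gt))
    dos[] <- vapply(strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE),
                    function(a) sum(suppressWarnings(as.numeric(a))),
                    numeric(1))
  } else {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  }
  dos <- t(dos[snp, , drop = FALSE])
  colnames(dos) <- ids[snp]
  ld_panel(dos)
}

#' Read an LD panel from a plain two-file format
#'
#' `variants_file` is a one-column (or headered) list of variant ids in
#' matrix column order; `matrix_file` is a whitespace-delimited numeric
#' dosage matrix, individuals in rows.
#'
#' @param variants_file,matrix_file file paths.
#' @return a [ld_panel()].
#' @export
read_ld_panel_matrix <- function(variants_file, matrix_file) {
  ids <- scan(variants_file, what = character(), quiet = TRUE)
  if (length(ids) && ids[1] %in% c("variant_id", "id", "snp"))
    ids <- ids[-1]
  m <- as.matrix(utils::read.table(matrix_file, header = FALSE))
  ld_panel(m, variant_ids = ids)
}

#' Pairwise LD (correlation) matrix for a SNP set
#'
#' Pearson correlation of dosage vectors across the panel's individuals,
#' with missing dosages mean-imputed per variant. The diagonal is exactly
#' 1. If the resulting matrix is numerically near-singular (condition
#' number above `kappa_max`), a small ridge `ridge * I` is added and the
#' event is recorded in the `"regularized"` attribute, keeping the inverse
#' required by the IVW estimator well-defined.
#'
#' @param panel a [ld_panel()].
#' @param snps variant ids to include, in the requested order.
#' @param kappa_max condition-number threshold triggering regularization.
#' @param ridge ridge magnitude added to the diagonal when triggered.
#' @return object of class `twmr_ld_matrix`: list with `snp_ids` and the
#'   correlation matrix `r`.
#' @export
compute_ld <- function(panel, snps = panel$variant_index,
                       kappa_max = 1e8, ridge = 1e-6) {
  stopifnot(inherits(panel, "twmr_ld_panel"))
  missing <- setdiff(snps, panel$variant_index)
  if (length(missing))
    stop("SNP(s) not in panel: ", paste(missing, collapse = ", "))
  X <- panel$genotypes[, snps, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  }
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance SNP(s): ",
         paste(snps[v == 0], collapse = ", "))
  r <- stats::cor(X)
  diag(r) <- 1
  regularized <- FALSE
  if (ncol(r) > 1 && kappa(r, exact = TRUE) > kappa_max) {
    r <- r + diag(ridge, ncol(r))
    regularized <- TRUE
    message("LD matrix near-singular; ridge ", ridge, " added to diagonal")
  }
  structure(list(snp_ids = snps, r = r, regularized = regularized),
            class = "twmr_ld_matrix")
}

#' @export
print.twmr_ld_matrix <- function(x, ...) {
  cat("LD matrix over", length(x$snp_ids), "SNPs",
      if (x$regularized) "(ridge-regularized)" else "", "\n")
  invisible(x)
}

#' Greedy LD pruning of an instrument list
#'
#' Keeps a subset of SNPs whose pairwise squared correlation stays below
#' `r2_max`. SNPs are visited in order of increasing `priority` (lower is
#' better, e.g. the focal gene's eQTL p-value) and accepted iff their r^2
#' with every already-accepted SNP is below the threshold, so the greedy
#' result is maximal under that ordering and deterministic.
#'
#' @param snps variant ids to consider.
#' @param ld a `twmr_ld_matrix` covering at least `snps`.
#' @param r2_max squared-correlation threshold in (0, 1].
#' @param priority numeric keep-preference per SNP (lower kept first);
#'   defaults to input order. Ties are broken by input order.
#' @return character vector of retained SNPs, in acceptance order.
#' @export
prune <- function(snps, ld, r2_max = 0.1, priority = seq_along(snps)) {
  if (!is.numeric(r2_max) || length(r2_max) != 1 ||
      r2_max <= 0 || r2_max > 1)
    stop("r2_max must be in (0, 1]")
  stopifnot(inherits(ld, "twmr_ld_matrix"), length(priority) == length(snps))
  idx <- match(snps, ld$snp_ids)
  if (anyNA(idx))
    stop("SNP(s) missing from LD matrix: ",
         paste(snps[is.na(idx)], collapse = ", "))
  r2 <- ld$r[idx, idx, drop = FALSE]^2
  ord <- order(priority)
  kept <- integer(0)
  for (i in ord) {
    if (all(r2[i, kept] < r2_max)) kept <- c(kept, i)
  }
  snps[kept]
}
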