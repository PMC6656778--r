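#' Column mapping for summary-statistics files
#'
#' Summary files from different consortia name their columns differently.
#' A dialect maps the canonical field names used throughout this package to
#' the column names found in a particular file. Fields mapped to `NA` are
#' treated as absent. For eQTL files that report only Z-scores, map `z`
#' (and `n`): `se` is then derived as `1/sqrt(n)` and `beta` as `z * se`,
#' the standardized-scale conversion.
#'
#' @param variant_id,chrom,pos,effect_allele,other_allele,beta,se,pvalue,n
#'   column names in the file for each canonical field.
#' @param gene_id,fdr,z additional fields used by eQTL files.
#' @return named list of class `twmr_dialect`.
#' @export
summary_dialect <- function(variant_id = "variant_id", chrom = "chrom",
                            pos = "pos", effect_allele = "effect_allele",
                            other_allele = "other_allele", beta = "beta",
                            se = "se", pvalue = "pvalue", n = "n",
                            gene_id = "gene_id", fdr = "fdr", z = NA) {
  structure(list(variant_id = variant_id, chrom = chrom, pos = pos,
                 effect_allele = effect_allele, other_allele = other_allele,
                 beta = beta, se = se, pvalue = pvalue, n = n,
                 gene_id = gene_id, fdr = fdr, z = z),
            class = "twmr_dialect")
}

#' Read a column-mapping dialect from a YAML or JSON file
#'
#' @param path file with entries `canonical_field: column_name`.
#' @return a `twmr_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(summary_dialect, cfg)
}

keep_attr <- function(from, to) {
  attr(to, "n_dropped") <- attr(from, "n_dropped")
  to
}

read_summary_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

map_columns <- function(raw, dialect, required, optional = character(0)) {
  pick <- function(field) {
    col <- dialect[[field]]
    if (is.null(col) || is.na(col)) return(NULL)
    if (!col %in% names(raw)) return(NA)
    raw[[col]]
  }
  out <- list()
  for (f in required) {
    v <- pick(f)
    if (is.null(v) || (length(v) == 1 && is.na(v)))
      stop("required column for field '", f, "' (mapped to '",
           dialect[[f]], "') not found in file")
    out[[f]] <- v
  }
  for (f in optional) {
    v <- pick(f)
    if (!is.null(v) && !(length(v) == 1 && all(is.na(v)) && nrow(raw) != 1))
      out[[f]] <- v
  }
  out
}

finalize_records <- function(out, nrow_raw, what) {
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  # derive beta/se from z when running under a Z-score dialect
  if (is.null(df$se) && !is.null(df$z)) {
    df$se <- 1 / sqrt(df$n)
    df$beta <- df$z * df$se
  }
  df$beta <- as.numeric(df$beta)
  df$se <- as.numeric(df$se)
  bad_allele <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T")) |
    df$effect_allele == df$other_allele
  if (any(bad_allele))
    warning(sum(bad_allele), " ", what,
            " row(s) skipped: unparseable or non-SNP alleles")
  missing_es <- !bad_allele & (is.na(df$beta) | is.na(df$se) | df$se <= 0)
  if (any(missing_es))
    message(sum(missing_es), " ", what, " row(s) dropped: missing beta/se")
  df <- df[!bad_allele & !missing_es, , drop = FALSE]
  attr(df, "n_dropped") <-
    c(bad_allele = sum(bad_allele), missing_effect = sum(missing_es))
  rownames(df) <- NULL
  df
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited GWAS summary file (gzip transparently
#' supported) into the canonical per-SNP representation. Rows with missing
#' effect size or standard error are dropped with a reported count; rows
#' whose alleles are not single nucleotides are skipped with a warning.
#'
#' @param path file path.
#' @param dialect a [summary_dialect()] mapping canonical fields to the
#'   file's column names.
#' @return data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n`;
#'   attribute `n_dropped` holds per-rule drop counts.
#' @export
read_gwas <- function(path, dialect = summary_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_summary_table(path)
  out <- map_columns(raw, dialect,
                     required = c("variant_id", "chrom", "pos",
                                  "effect_allele", "other_allele"),
                     optional = c("beta", "se", "pvalue", "n", "z"))
  df <- finalize_records(out, nrow(raw), "GWAS")
  keep_attr(df, df[intersect(c("variant_id", "chrom", "pos",
                               "effect_allele", "other_allele", "beta",
                               "se", "pvalue", "n"), names(df))])
}

#' Read cis-eQTL summary statistics
#'
#' As [read_gwas()] but per SNP-gene pair, with `gene_id` and study-wide
#' `fdr` columns. No significance filtering happens at read time; FDR and
#' p-value screens are applied downstream during instrument selection.
#'
#' @inheritParams read_gwas
#' @return data.frame with the [read_gwas()] columns plus `gene_id`, `fdr`
#'   and `conditional_p` (NA until stepwise selection fills it).
#' @export
read_eqtl <- function(path, dialect = summary_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_summary_table(path)
  out <- map_columns(raw, dialect,
                     required = c("variant_id", "gene_id", "chrom", "pos",
                                  "effect_allele", "other_allele"),
                     optional = c("beta", "se", "pvalue", "n", "fdr", "z"))
  df <- finalize_records(out, nrow(raw), "eQTL")
  df$gene_id <- as.character(df$gene_id)
  if (any(!nzchar(df$gene_id))) stop("empty gene_id in eQTL file")
  df$conditional_p <- NA_real_
  keep_attr(df, df[intersect(c("variant_id", "gene_id", "chrom", "pos",
                               "effect_allele", "other_allele", "beta",
                               "se", "pvalue", "fdr", "n",
                               "conditional_p"), names(df))])
}

#' Quality-filter summary records
#'
#' Applies the standard pre-harmonization exclusions: non-autosomal
#' variants, strand-ambiguous SNPs (A/T and C/G, whose effect allele cannot
#' be oriented across studies), and the extended major histocompatibility
#' complex region chr6:26,200,000-33,800,000 (1-based, inclusive), whose
#' long-range LD violates the locus-wise independence assumptions.
#'
#' @param records data.frame from [read_gwas()] or [read_eqtl()].
#' @return list with `kept` (surviving records), `removed` (dropped records
#'   with a `qc_rule` column; a variant failing several rules is counted
#'   under the first in the order non_autosomal, strand_ambiguous, mhc) and
#'   `counts` (named integer vector per rule).
#' @export
qc_filter <- function(records) {
  chrom <- sub("^chr", "", as.character(records$chrom))
  non_auto <- !chrom %in% as.character(1:22)
  pair <- paste0(pmin(records$effect_allele, records$other_allele),
                 pmax(records$effect_allele, records$other_allele))
  ambiguous <- pair %in% c("AT", "CG")
  mhc <- chrom == "6" & records$pos >= 26200000L & records$pos <= 33800000L
  rule <- rep(NA_character_, nrow(records))
  rule[mhc] <- "mhc"
  rule[ambiguous] <- "strand_ambiguous"
  rule[non_auto] <- "non_autosomal"
  removed <- records[!is.na(rule), , drop = FALSE]
  if (nrow(removed)) removed$qc_rule <- rule[!is.na(rule)]
  counts <- c(non_autosomal = sum(rule == "non_autosomal", na.rm = TRUE),
              strand_ambiguous = sum(rule == "strand_ambiguous", na.rm = TRUE),
              mhc = sum(rule == "mhc", na.rm = TRUE))
  list(kept = records[is.na(rule), , drop = FALSE],
       removed = removed, counts = counts)
}

#' Harmonize GWAS and eQTL effect alleles on shared variants
#'
#' Joins the two sources on `variant_id` and orients both effect sizes to
#' the eQTL effect allele: matching alleles are kept as-is; swapped alleles
#' (GWAS effect allele equals the eQTL other allele) flip the sign of the
#' GWAS beta; incompatible allele pairs drop the variant with a message.
#' When both sources carry positions, a (chrom, pos) consistency check
#' drops mismatching variants with a warning.
#'
#' @param gwas QC-filtered data.frame from [read_gwas()].
#' @param eqtl QC-filtered data.frame from [read_eqtl()].
#' @return data.frame with fixed column order `variant_id`, `chrom`, `pos`,
#'   `ea`, `oa`, `beta_gwas`, `se_gwas`, `gene_id`, `beta_eqtl`, `se_eqtl`,
#'   `p_eqtl`, `fdr` (alleles oriented to the eQTL effect allele).
#' @export
harmonize_alleles <- function(gwas, eqtl) {
  dup <- unique(gwas$variant_id[duplicated(gwas$variant_id)])
  if (length(dup))
    stop("duplicate variant_id in GWAS: ", paste(dup, collapse = ", "))
  dupe <- eqtl[duplicated(eqtl[c("variant_id", "gene_id")]), ]
  if (nrow(dupe))
    stop("duplicate (variant_id, gene_id) in eQTL: ",
         paste(unique(dupe$variant_id), collapse = ", "))
  i <- match(eqtl$variant_id, gwas$variant_id)
  shared <- !is.na(i)
  eq <- eqtl[shared, , drop = FALSE]
  gw <- gwas[i[shared], , drop = FALSE]
  if (!is.null(eq$pos) && !is.null(gw$pos)) {
    mismatch <- eq$chrom != gw$chrom | eq$pos != gw$pos
    if (any(mismatch)) {
      warning(sum(mismatch), " variant(s) dropped: (chrom, pos) disagree ",
              "between sources for a shared variant_id")
      eq <- eq[!mismatch, , drop = FALSE]
      gw <- gw[!mismatch, , drop = FALSE]
    }
  }
  same <- gw$effect_allele == eq$effect_allele &
    gw$other_allele == eq$other_allele
  swapped <- gw$effect_allele == eq$other_allele &
    gw$other_allele == eq$effect_allele
  incompatible <- !same & !swapped
  if (any(incompatible))
    message(sum(incompatible),
            " record(s) dropped: incompatible allele pairs")
  keep <- !incompatible
  beta_gwas <- ifelse(swapped, -gw$beta, gw$beta)[keep]
  eq <- eq[keep, , drop = FALSE]
  gw <- gw[keep, , drop = FALSE]
  out <- data.frame(
    variant_id = eq$variant_id, chrom = eq$chrom, pos = eq$pos,
    ea = eq$effect_allele, oa = eq$other_allele,
    beta_gwas = beta_gwas, se_gwas = gw$se,
    gene_id = eq$gene_id, beta_eqtl = eq$beta, se_eqtl = eq$se,
    p_eqtl = if (is.null(eq$pvalue)) NA_real_ else eq$pvalue,
    fdr = if (is.null(eq$fdr)) NA_real_ else eq$fdr,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
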