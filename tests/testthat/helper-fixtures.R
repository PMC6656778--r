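# fixtures built in code: toy summary tables, genotype panels, designs

toy_gwas_df <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    beta = c(0.10, -0.05, 0.02),
    se = c(0.01, 0.02, 0.01),
    pvalue = c(1e-8, 0.01, 0.05),
    n = c(100000L, 100000L, 100000L),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random hard-call genotype panel with given allele frequencies
random_panel <- function(n_ind, mafs, ids = paste0("rs", seq_along(mafs))) {
  G <- sapply(mafs, function(q) rbinom(n_ind, 2, q))
  colnames(G) <- ids
  ld_panel(G)
}

# panel whose SNPs come in LD blocks: within a block, genotypes are copies
# of a template with per-entry flip probability `noise`
block_panel <- function(n_ind, block_sizes, maf = 0.3, noise = 0.05,
                        ids = NULL) {
  cols <- list()
  for (b in seq_along(block_sizes)) {
    template <- rbinom(n_ind, 2, maf)
    for (j in seq_len(block_sizes[b])) {
      flip <- rbinom(n_ind, 1, noise) == 1
      g <- template
      g[flip] <- rbinom(sum(flip), 2, maf)
      cols[[length(cols) + 1]] <- g
    }
  }
  G <- do.call(cbind, cols)
  colnames(G) <- ids %||% paste0("rs", seq_len(ncol(G)))
  ld_panel(G)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small instrument set with known structure
toy_instrument_set <- function(n = 6, k = 2, seed = 11, rho = 0,
                               alpha = c(0.3, -0.2)) {
  set.seed(seed)
  E <- matrix(rnorm(n * k, 0, 0.2), n, k,
              dimnames = list(paste0("rs", 1:n), paste0("g", 1:k)))
  C <- rho^abs(outer(1:n, 1:n, "-"))
  G <- drop(E %*% alpha[seq_len(k)])
  instrument_set(E, G, C, n_eqtl = 1e4, n_gwas = 1e5)
}
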