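# Shared fixture builders. All data are generated in code; nothing on disk.

# Build a fabric directly from a spots x samples value matrix, bypassing
# filtering/normalization, for arithmetic oracles on known numbers.
manual_fabric <- function(values, gene, spot_id = NULL,
                          samples = colnames(values)) {
  if (is.null(spot_id))
    spot_id <- paste0(gene, "_s",
                      stats::ave(seq_along(gene), gene, FUN = seq_along))
  colnames(values) <- samples
  info <- genofabric:::parse_sample_labels(samples)
  genofabric:::build_fabric_from_values(values, spot_id, gene, info,
                                        renormalize = FALSE)
}

# single-phenotype, single-spot fabric from a genes x replicas matrix
replica_fabric <- function(mat, phenotype = "P") {
  genes <- rownames(mat)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  samples <- paste0(phenotype, ".", seq_len(ncol(mat)))
  manual_fabric(mat, gene = genes, spot_id = paste0(genes, "_1"),
                samples = samples)
}

# null design: no folds, no modules, single-spot genes
null_design <- function(n_genes, seed, ...) {
  fabric_design(n_genes = n_genes,
                redundancy_dist = c(`1` = 1),
                corrupted_rate = 0,
                seed = seed, ...)
}

# recovery design used by power/sensitivity checks: 200 genes with a
# planted 4x fold at 10% biological CV in MRLlpr, plus synergistic modules
# of 10 genes driven by a strong latent replicate factor
recovery_design <- function(seed, n_fold = 200L, n_modules = 5L,
                            module_size = 10L, n_genes = 4000L) {
  folds <- data.frame(gene = seq_len(n_fold), phenotype = "MRLlpr",
                      fold = 4, cv = 0.10)
  mods <- lapply(seq_len(n_modules), function(m) {
    list(genes = n_fold + ((m - 1L) * module_size + 1L):(m * module_size),
         loadings = rep(1, module_size), latent_sd = 1.0)
  })
  fabric_design(n_genes = n_genes,
                bio_cv_range = c(0.02, 0.05),
                base_level_log_mean = log(5000),
                base_level_log_sd = 0.5,
                planted_folds = folds,
                coordination_modules = mods,
                corrupted_rate = 0,
                redundancy_dist = c(`1` = 1),
                seed = seed)
}
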