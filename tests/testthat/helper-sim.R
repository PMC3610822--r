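# Shared fixture builders. All randomness is seeded through sim_config /
# explicit set.seed so the suite is reproducible.

# noise-free, censoring-free world for exact-recovery contracts
exact_config <- function(effect_table = NULL, n_genes = 50, seed = 4) {
  sim_config(n_genes = n_genes, probes_per_gene = 3,
             effect_table = effect_table,
             noise_sd = 0, dye_bias = 0, array_offset_sd = 0,
             frac_surrogate = 0, frac_crosshyb = 0, frac_intergenic = 0,
             bg_sd = 1, base_sd = 1, seed = seed)
}

# study-like world: ~13% of genes differentially expressed, most modestly,
# a few strongly (the published prevalence of >4-fold genes is ~2%)
study_effects <- function(n_genes) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  v <- c(rep(0, round(0.84 * n_genes)),
         rep(c(1, -1), each = round(0.05 * n_genes)),
         rep(c(2, -2), each = round(0.015 * n_genes)),
         rep(c(3, -3), each = round(0.008 * n_genes)))
  v <- c(v, rep(0, max(0, n_genes - length(v))))[seq_len(n_genes)]
  data.frame(gene_id = genes, effect_MII24 = v, effect_MII48 = v,
             effect_MII72 = v, stringsAsFactors = FALSE)
}

# probe-level dataset -> contrast_result without normalization (used when
# the operation under test sits downstream of normalization)
quick_results <- function(ds, normalize = FALSE) {
  mat <- build_matrix(ds$scans, ds$annotation)
  if (normalize) mat <- normalize_matrix(mat)
  suppressMessages(
    moderate_statistics(fit_gene_model(summarize_genes(mat, ds$annotation),
                                       ds$design)))
}

make_labels <- function(conditions = c("MI16", "MII24", "MII48", "MII72"),
                        reps = 3) {
  as.vector(t(outer(conditions, paste0("_r", seq_len(reps)), paste0)))
}
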