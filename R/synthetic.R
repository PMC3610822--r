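#' Configuration of the synthetic two-color dataset
#'
#' Describes a gDNA-common-reference experiment with the published layout:
#' four developmental stages (MI16 reference, then MII24, MII48, MII72) in
#' three biological replicates, genes covered by several valid probes plus
#' cross-hybridizing and intergenic probe classes at roughly the published
#' fractions (943 / 43798 and 7234 / 43798).
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Valid probes per gene.
#' @param frac_crosshyb,frac_intergenic Fractions of all probes that are
#'   cross-hybridizing / intergenic; their sum must stay below 1.
#' @param conditions Ordered stage labels; the first is the reference.
#' @param replicates Biological replicates per stage (>= 2).
#' @param effect_table Optional data.frame \code{gene_id} plus one numeric
#'   column per non-reference condition holding true log2 effects; missing
#'   genes get 0.
#' @param noise_sd Probe-level log2 measurement noise SD.
#' @param dye_bias Coefficients (constant, linear, quadratic, ...) of a
#'   smooth curve in the standardized abundance profile of the array,
#'   added to Mg; each array multiplies the curve by its own factor drawn
#'   uniformly on [-0.5, 0.5], so a coefficient of c injects pairwise
#'   M-vs-A bias of amplitude up to about c.
#' @param base_sd SD of per-gene baseline log2(cDNA/gDNA) abundance (the
#'   dynamic range of expression).
#' @param array_offset_sd SD of a per-array constant log2 offset
#'   (labelling-efficiency differences; removed by median normalization).
#' @param bg_level Mean background level (fluorescence units).
#' @param bg_sd Background pixel SD.
#' @param frac_surrogate Fraction of probes given a low-affinity baseline
#'   (8 log2 units down) so their Cy3 net signal sits at the background
#'   floor and the surrogate-intensity rule is exercised.
#' @param de_threshold Absolute log2 effect from which a gene counts as
#'   truly differentially expressed in the truth table.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 200, probes_per_gene = 3,
                       frac_crosshyb = 943 / 43798,
                       frac_intergenic = 7234 / 43798,
                       conditions = c("MI16", "MII24", "MII48", "MII72"),
                       replicates = 3, effect_table = NULL,
                       noise_sd = 0.2, dye_bias = 0,
                       base_sd = 2, array_offset_sd = 0.05,
                       bg_level = 50, bg_sd = 5, frac_surrogate = 0.01,
                       de_threshold = 1, seed = 1) {
  stopifnot(n_genes >= 1, probes_per_gene >= 1,
            frac_crosshyb >= 0, frac_intergenic >= 0,
            frac_crosshyb + frac_intergenic < 1,
            length(conditions) >= 2, replicates >= 2,
            noise_sd >= 0, array_offset_sd >= 0,
            bg_level > 0, bg_sd > 0,
            frac_surrogate >= 0, frac_surrogate < 1)
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 frac_crosshyb = frac_crosshyb,
                 frac_intergenic = frac_intergenic,
                 conditions = conditions,
                 replicates = as.integer(replicates),
                 effect_table = effect_table,
                 noise_sd = noise_sd, dye_bias = dye_bias,
                 base_sd = base_sd, array_offset_sd = array_offset_sd,
                 bg_level = bg_level, bg_sd = bg_sd,
                 frac_surrogate = frac_surrogate,
                 de_threshold = de_threshold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate the dye-bias curve at standardized intensity z
bias_curve <- function(coef, z) {
  out <- 0
  for (k in seq_along(coef)) out <- out + coef[k] * z^(k - 1)
  out
}

#' Simulate a probe-level two-color dataset with known truth
#'
#' The Cy5 channel is a gene-independent gDNA abundance model: a log-normal
#' per-probe intensity shared by all arrays (genomic DNA is copy-number
#' flat, which is what makes it usable as a common reference). The Cy3
#' channel multiplies the same probe intensity by 2^(baseline + condition
#' effect + noise + array offset), then a smooth intensity-dependent dye
#' bias is added to Mg. Pixel statistics are emitted directly (foreground
#' mean = net + background median); a configurable fraction of probes is
#' forced weak so the surrogate background rule is exercised.
#'
#' @param config A [sim_config()].
#' @return list with \code{scans} (named list of per-array FeatureExtraction
#'   style data.frames), \code{annotation} (probe_id, class, gene_ids),
#'   \code{truth} (gene_id, effect_<condition> columns, de_flag) and
#'   \code{design} (a [design_info()]).
#' @export
generate_array_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  n_gene_probes <- ng * config$probes_per_gene
  frac_valid <- 1 - config$frac_crosshyb - config$frac_intergenic
  n_total <- ceiling(n_gene_probes / frac_valid)
  n_cross <- round(config$frac_crosshyb * n_total)
  n_inter <- n_total - n_gene_probes - n_cross
  if (n_inter < 0) n_inter <- 0

  probe_gene <- rep(genes, each = config$probes_per_gene)
  probe_ids <- paste0("P_", probe_gene, "_",
                      rep(seq_len(config$probes_per_gene), ng))
  cross_pairs <- replicate(n_cross, sample(genes, 2), simplify = FALSE)
  cross_ids <- sprintf("PX_%04d", seq_len(n_cross))
  inter_ids <- sprintf("PI_%04d", seq_len(n_inter))

  annotation <- data.frame(
    probe_id = c(probe_ids, cross_ids, inter_ids),
    class = c(rep("GENE", n_gene_probes), rep("CROSSHYB", n_cross),
              rep("INTERGENIC", n_inter)),
    gene_ids = c(probe_gene,
                 vapply(cross_pairs, paste, "", collapse = ";"),
                 rep("", n_inter)),
    stringsAsFactors = FALSE)

  # true effects: reference condition is implicitly 0
  test_conditions <- config$conditions[-1]
  effects <- matrix(0, ng, length(test_conditions),
                    dimnames = list(genes, test_conditions))
  if (!is.null(config$effect_table)) {
    et <- config$effect_table
    idx <- match(et$gene_id, genes)
    if (anyNA(idx)) stop("effect_table names unknown genes")
    for (cond in test_conditions) {
      col <- paste0("effect_", cond)
      if (!col %in% names(et)) col <- cond
      if (col %in% names(et)) effects[idx, cond] <- et[[col]]
    }
  }
  truth <- data.frame(gene_id = genes, effects,
                      de_flag = apply(abs(effects), 1, max) >=
                        config$de_threshold,
                      stringsAsFactors = FALSE)
  names(truth)[2:(1 + length(test_conditions))] <-
    paste0("effect_", test_conditions)

  n_probes <- nrow(annotation)
  # wide log-normal intensity range, as on real arrays (~2^4 .. 2^16)
  gdna_log2 <- stats::rnorm(n_probes, mean = 10, sd = 2)
  gene_base <- stats::rnorm(ng, mean = 0, sd = config$base_sd)
  names(gene_base) <- genes
  inter_base <- stats::rnorm(n_inter, mean = -8, sd = 1)

  # baseline log2(cDNA/gDNA) per probe at the reference stage
  base_mg <- numeric(n_probes)
  base_mg[seq_len(n_gene_probes)] <- gene_base[probe_gene]
  eff_of <- function(cond) {
    # per-probe log2 effect for one test condition
    e <- numeric(n_probes)
    if (cond %in% test_conditions) {
      e[seq_len(n_gene_probes)] <- effects[probe_gene, cond]
      if (n_cross > 0) {
        # a cross-hybridizing probe sees the mixture of its two genes
        e[n_gene_probes + seq_len(n_cross)] <-
          vapply(cross_pairs, function(g) {
            a <- gene_base[g] + effects[g, cond]
            log2(mean(2^a))
          }, 0)
      }
    } else if (n_cross > 0) {
      e[n_gene_probes + seq_len(n_cross)] <-
        vapply(cross_pairs, function(g) log2(mean(2^gene_base[g])), 0)
    }
    e
  }
  if (n_cross > 0) base_mg[n_gene_probes + seq_len(n_cross)] <- 0
  if (n_inter > 0) base_mg[n_gene_probes + n_cross + seq_len(n_inter)] <-
    inter_base

  # low-affinity probes: baseline pushed to the background floor so the
  # surrogate branch fires naturally on at least their reference arrays
  if (config$frac_surrogate > 0) {
    n_weak <- floor(config$frac_surrogate * n_probes)
    weak_idx <- sample.int(n_probes, n_weak)
    base_mg[weak_idx] <- base_mg[weak_idx] - 8
  }

  labels <- as.vector(t(outer(config$conditions,
                              paste0("_r", seq_len(config$replicates)),
                              paste0)))
  scans <- vector("list", length(labels))
  names(scans) <- labels
  for (li in seq_along(labels)) {
    cond <- sub("_r[0-9]+$", "", labels[li])
    offset <- stats::rnorm(1, 0, config$array_offset_sd)
    bias_mult <- stats::runif(1, -0.5, 0.5)
    noise <- stats::rnorm(n_probes, 0, config$noise_sd)
    cross_gene_part <- eff_of(cond)
    mg <- base_mg + cross_gene_part + noise + offset
    # cross-hyb probes already folded baseline+effect into cross_gene_part
    if (n_cross > 0) {
      mg[n_gene_probes + seq_len(n_cross)] <-
        cross_gene_part[n_gene_probes + seq_len(n_cross)] +
        noise[n_gene_probes + seq_len(n_cross)] + offset
    }
    if (any(config$dye_bias != 0)) {
      # intensity coordinate of the bias: the array's own abundance
      # profile, the axis the M-vs-A normalization smooths over
      z <- (mg - mean(mg)) / stats::sd(mg)
      mg <- mg + bias_mult * bias_curve(config$dye_bias, z)
    }
    cy3_log2 <- gdna_log2 + mg
    cy3_net <- 2^cy3_log2
    cy5_net <- 2^gdna_log2
    bg3 <- stats::rnorm(n_probes, config$bg_level, config$bg_level * 0.05)
    bg5 <- stats::rnorm(n_probes, config$bg_level, config$bg_level * 0.05)
    bg3 <- pmax(bg3, 1); bg5 <- pmax(bg5, 1)
    sd3 <- rep(config$bg_sd, n_probes)
    sd5 <- rep(config$bg_sd, n_probes)
    scans[[li]] <- data.frame(
      ProbeName = annotation$probe_id,
      gMeanSignal = cy3_net + bg3,
      gBGMedianSignal = bg3,
      gBGPixSDev = sd3,
      rMeanSignal = cy5_net + bg5,
      rBGMedianSignal = bg5,
      rBGPixSDev = sd5,
      stringsAsFactors = FALSE)
  }
  design <- design_from_labels(labels, config$conditions)
  list(scans = scans, annotation = annotation, truth = truth,
       design = design)
}

#' Simulate a qPCR Ct table from a truth table
#'
#' Ct decreases by one cycle per doubling of abundance: Ct = base Ct of the
#' gene - true log2 effect + noise, measured for two biological replicates
#' in technical triplicate (the published qPCR design).
#'
#' @param truth Truth data.frame from [generate_array_dataset()] (columns
#'   \code{gene_id} and \code{effect_<condition>}).
#' @param reference_gene Gene used as internal control; must be present in
#'   the truth with all-zero effects.
#' @param conditions Ordered condition labels; first is the calibrator.
#' @param ct_base Mean Ct of an unchanged gene.
#' @param noise_sd Ct measurement noise SD (cycles).
#' @param n_bio,n_tech Biological / technical replicates.
#' @param seed Integer seed.
#' @return data.frame \code{gene_id}, \code{condition}, \code{bio_rep},
#'   \code{tech_rep}, \code{ct}.
#' @export
generate_qpcr_dataset <- function(truth, reference_gene,
                                  conditions = c("MI16", "MII24",
                                                 "MII48", "MII72"),
                                  ct_base = 20, noise_sd = 0.1,
                                  n_bio = 2, n_tech = 3, seed = 1) {
  if (!reference_gene %in% truth$gene_id) {
    stop("reference gene '", reference_gene, "' absent from truth")
  }
  eff_cols <- grep("^effect_", names(truth), value = TRUE)
  ref_eff <- as.numeric(truth[truth$gene_id == reference_gene, eff_cols])
  if (any(ref_eff != 0)) {
    stop("reference gene must have zero effect in every condition")
  }
  set.seed(seed)
  gene_ct0 <- ct_base + stats::rnorm(nrow(truth), 0, 1.5)
  names(gene_ct0) <- truth$gene_id
  grid <- expand.grid(gene_id = truth$gene_id, condition = conditions,
                      bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  eff <- numeric(nrow(grid))
  for (cond in conditions[-1]) {
    col <- paste0("effect_", cond)
    if (col %in% names(truth)) {
      sel <- grid$condition == cond
      eff[sel] <- truth[[col]][match(grid$gene_id[sel], truth$gene_id)]
    }
  }
  grid$ct <- gene_ct0[grid$gene_id] - eff +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}
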