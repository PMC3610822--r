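fake_results <- function(p_rows, mc_rows = NULL) {
  n <- nrow(p_rows)
  if (is.null(mc_rows)) mc_rows <- matrix(0, n, 3)
  out <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                    Mc_24 = mc_rows[, 1], Mc_48 = mc_rows[, 2],
                    Mc_72 = mc_rows[, 3],
                    p_24 = p_rows[, 1], p_48 = p_rows[, 2],
                    p_72 = p_rows[, 3], stringsAsFactors = FALSE)
  out$fdr_24 <- adjust_fdr(out$p_24)
  out$fdr_48 <- adjust_fdr(out$p_48)
  out$fdr_72 <- adjust_fdr(out$p_72)
  out
}

test_that("the reliability filter demands p < alpha in every contrast", {
  res <- fake_results(rbind(c(0.01, 0.04, 0.02),
                            c(0.01, 0.06, 0.02)))
  kept <- select_reliable(res)
  expect_identical(kept, "g001")
  res$p_48[1] <- NA
  expect_error(select_reliable(res), "g001")
})

test_that("the reliability filter separates strong effects from nulls", {
  eff <- data.frame(gene_id = sprintf("G%04d", 101:150),
                    effect_MII24 = 3, effect_MII48 = 3, effect_MII72 = 3)
  cfg <- sim_config(n_genes = 150, probes_per_gene = 2, effect_table = eff,
                    noise_sd = 0.2, seed = 5)
  ds <- generate_array_dataset(cfg)
  res <- quick_results(ds)
  kept <- select_reliable(res)
  de <- eff$gene_id
  expect_gte(sum(de %in% kept), 45)
  expect_lte(sum(setdiff(res$gene_id, de) %in% kept), 5)
})

test_that("fold-change conversion reproduces the narrative numbers", {
  fc <- fold_change(c(7.4, 0, -4.6))
  expect_equal(fc$direction, c("up-in-MII", "flat", "up-in-MI"))
  expect_equal(fc$fold, c(169, 1, 24))
  # magnitude is symmetric, direction flips
  set.seed(4)
  mc <- runif(100, -8, 8)
  a <- fold_change(mc); b <- fold_change(-mc)
  expect_equal(a$fold, b$fold)
  strong <- abs(mc) >= 1
  expect_true(all(a$direction[strong] != b$direction[strong]))
  expect_true(all(a$direction[!strong] == "flat"))
})

test_that("max_fold_change matches the published 'up to N-fold' claims", {
  known <- load_paper_tables()$known
  expect_equal(max_fold_change(c("SCO5077", "SCO5085"), known), 6)
  expect_equal(max_fold_change("SCO5898", known), 4.3)
  expect_equal(max_fold_change("SCO3909", known), 2.5)
  expect_error(max_fold_change("SCO9999", known), "SCO9999")
})

test_that("the candidate cascade needs unknown function, conservation and effect", {
  tab <- data.frame(gene_id = c("u1", "u2", "k1"),
                    mc_24 = c(0.5, 3, 3), mc_48 = c(2.5, 3, 3),
                    mc_72 = c(1.0, 3, 3), stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("u1", "u2", "k1"),
                    known_function = c(FALSE, FALSE, TRUE),
                    conservation = c(80, 70, 90),
                    category = "unknown", stringsAsFactors = FALSE)
  expect_identical(candidate_filter(tab, ann), "u1")
  expect_error(candidate_filter(tab, ann[-1, ]), "u1")
})

test_that("the top tier keeps |Mc| >= 3 with the printed-value boundary", {
  tabs <- load_paper_tables()
  expect_length(top_filter(tabs$top_unknown), 53)
  toy <- data.frame(gene_id = c("a", "b"),
                    mc_24 = c(2.9, 0), mc_48 = c(2.9, 0),
                    mc_72 = c(2.9, 3.0), stringsAsFactors = FALSE)
  expect_identical(top_filter(toy), "b")
})

test_that("the cascade is monotone for nested thresholds", {
  tab <- load_paper_tables()$top_unknown
  ann <- data.frame(gene_id = tab$gene_id, known_function = FALSE,
                    conservation = 90, category = tab$category,
                    stringsAsFactors = FALSE)
  for (crit in list(filter_criteria(sig_abs = 1, candidate_abs = 2, top_abs = 3),
                    filter_criteria(sig_abs = 0.5, candidate_abs = 3.5,
                                    top_abs = 4.5))) {
    cand <- candidate_filter(tab, ann, crit)
    top <- top_filter(tab, crit)
    expect_true(all(top %in% cand))
    expect_lte(length(cand), nrow(tab))
  }
})

test_that("MII sign consistency counts genes with one direction", {
  one <- data.frame(gene_id = "a", mc_24 = 1, mc_48 = 2, mc_72 = 3)
  expect_equal(mii_consistency(one), 1)
  two <- data.frame(gene_id = c("a", "b"), mc_24 = c(1, 1),
                    mc_48 = c(2, -1), mc_72 = c(3, 1))
  expect_equal(mii_consistency(two), 0.5)
  # zeros are ignored
  zero <- data.frame(gene_id = c("a", "b"), mc_24 = c(0, 0),
                     mc_48 = c(2, -1), mc_72 = c(0, 1))
  expect_equal(mii_consistency(zero), 0.5)

  # simulated monotone MII programme stays consistent under noise
  ng <- 100
  set.seed(2)
  e24 <- runif(ng, 0.5, 2) * sample(c(-1, 1), ng, replace = TRUE)
  eff <- data.frame(gene_id = sprintf("G%04d", 1:ng),
                    effect_MII24 = e24, effect_MII48 = e24 * 1.5,
                    effect_MII72 = e24 * 2)
  cfg <- sim_config(n_genes = ng, probes_per_gene = 2, effect_table = eff,
                    noise_sd = 0.2, seed = 21)
  res <- quick_results(generate_array_dataset(cfg))
  expect_gte(mii_consistency(res), 0.95)
})

test_that("transcript-protein concordance classes follow the thresholds", {
  out <- proteome_concordance(c(a = 2.0, b = 0.5, c = 1.5),
                              c(a = 1.5, b = -0.3, c = -1.2))
  expect_equal(out$class, c("similar", "no-variation", "different"))
  expect_equal(unname(attr(out, "counts")), c(1L, 1L, 1L))
})

test_that("category summaries partition the gene list", {
  tab <- data.frame(gene_id = c("a", "b", "c"), mc_24 = 1:3,
                    mc_48 = 1:3, mc_72 = 1:3, stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = c("a", "b", "c"),
                    category = c("x", "x", "y"), stringsAsFactors = FALSE)
  out <- category_summary(tab, ann)
  expect_identical(vapply(out, nrow, 0L), c(x = 2L, y = 1L))
  expect_identical(sum(vapply(out, nrow, 0L)), nrow(tab))
  expect_length(category_summary(tab[0, ], ann), 0)
  expect_warning(category_summary(tab, ann[-3, ]), "unknown")

  known <- load_paper_tables()$known
  blocks <- category_summary(known,
                             data.frame(gene_id = known$gene_id,
                                        category = known$category))
  # printed secondary-metabolite block of the fixture
  expect_identical(nrow(blocks[["Secondary metabolite synthesis"]]), 20L)
})

test_that("published fixture blocks behave as printed", {
  tabs <- load_paper_tables()
  # 41 of the 53 top-tier genes sit in the Unknown block
  expect_identical(sum(tabs$top_unknown$category == "Unknown"), 41L)
  # the isorenieratene cluster is never up in MII
  iso <- tabs$secondary[tabs$secondary$gene_id %in%
                          sprintf("SCO%04d", 185:191), ]
  expect_identical(nrow(iso), 7L)
  for (i in seq_len(nrow(iso))) {
    fc <- fold_change(as.numeric(iso[i, c("mc_24", "mc_48", "mc_72")]))
    expect_true(all(fc$direction %in% c("up-in-MI", "flat")))
  }
  sel <- sprintf("SCO%04d", c(186, 188, 190, 191))
  vals <- as.matrix(tabs$secondary[match(sel, tabs$secondary$gene_id),
                                   c("mc_24", "mc_48", "mc_72")])
  expect_true(all(vals <= 0))
})

test_that("filter_report flags stages and echoes fold changes", {
  res <- fake_results(rbind(c(0.01, 0.01, 0.01), c(0.01, 0.01, 0.01),
                            c(0.5, 0.01, 0.01)),
                      rbind(c(3.5, 3.5, 3.5), c(1.5, 1.5, 1.5),
                            c(4, 4, 4)))
  ann <- data.frame(gene_id = res$gene_id, known_function = FALSE,
                    conservation = 90, category = "unknown")
  rep_ <- filter_report(res, ann)
  counts <- attr(rep_, "stage_counts")
  expect_equal(unname(counts), c(3, 2, 1, 1))
  expect_true(rep_$top[1])
  expect_false(rep_$reliable[3])
  expect_equal(rep_$direction_24, rep("up-in-MII", 3))
})
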