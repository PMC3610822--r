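gene_mat <- function(M, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(M)))
  rownames(M) <- genes
  colnames(M) <- make_labels()
  mg_matrix(M, 1)
}

test_that("probe-to-gene averaging uses the validity weights", {
  M <- rbind(c(1, 2), c(3, 4), c(1, 2), c(100, 200))
  rownames(M) <- c("p1", "p2", "p3", "p4")
  colnames(M) <- c("MI16_r1", "MI16_r2")
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    class = c("GENE", "GENE", "GENE", "CROSSHYB"),
                    gene_ids = c("gA", "gA", "gB", "gB;gA"),
                    stringsAsFactors = FALSE)
  mat <- mg_matrix(M, c(1, 1, 1, 1e-6))
  g <- summarize_genes(mat, ann)
  expect_equal(g$M["gA", "MI16_r1"], 2)               # (1 + 3) / 2
  # weight-1e-6 probe barely moves the mean: (1 + 100e-6) / (1 + 1e-6)
  expect_equal(g$M["gB", "MI16_r1"], (1 + 100e-6) / (1 + 1e-6))
  # a gene covered only by non-valid probes is dropped and reported
  ann2 <- ann; ann2$class[3] <- "CROSSHYB"
  expect_message(g2 <- summarize_genes(mg_matrix(M, c(1, 1, 1e-6, 1e-6)),
                                       ann2),
                 "dropped")
  expect_identical(sort(attr(g2, "dropped")), "gB")
  expect_false("gB" %in% rownames(g2$M))
})

test_that("the one-way model recovers group means and pooled variance", {
  vals <- c(0, 0, 0, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  fit <- fit_gene_model(gene_mat(matrix(vals, 1)),
                        design_from_labels(make_labels()))
  expect_equal(unname(fit$Mc[1, ]), c(2, 2, 2))
  expect_equal(unname(fit$sigma2), 0)
  expect_identical(fit$df_residual, 8L)

  # two-condition toy against the pooled two-sample variance
  M2 <- matrix(c(0, 1, 3, 5), 1)
  rownames(M2) <- "g1"; colnames(M2) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  fit2 <- fit_gene_model(mg_matrix(M2, 1),
                         design_from_labels(colnames(M2), c("A", "B")))
  expect_equal(unname(fit2$Mc[1, 1]), 3.5)
  pooled <- (var(c(0, 1)) + var(c(3, 5))) / 2
  expect_equal(unname(fit2$sigma2), pooled)

  # permuting arrays changes nothing
  set.seed(6)
  M3 <- matrix(rnorm(5 * 12), 5)
  mat3 <- gene_mat(M3)
  perm <- sample(12)
  mat3p <- mg_matrix(mat3$M[, perm], 1)
  d <- design_from_labels(make_labels())
  f1 <- fit_gene_model(mat3, d)
  f2 <- fit_gene_model(mat3p, d)
  expect_equal(f1$Mc, f2$Mc)
  expect_equal(f1$sigma2, f2$sigma2)
})

test_that("designs demand at least two replicates per condition", {
  labels <- c("MI16_r1", "MI16_r2", "MII24_r1")
  expect_error(design_from_labels(labels), "at least 2")
  expect_error(design_from_labels(c("oops", "MI16_r1")), "not of the form")
})

test_that("moderated t reduces to ordinary t and matches the formula", {
  set.seed(10)
  M <- matrix(rnorm(15 * 12, 0, 0.4), 15)
  fit <- fit_gene_model(gene_mat(M), design_from_labels(make_labels()))
  plain <- moderate_statistics(fit, df_prior = 0, s0 = 1)
  # ordinary t for the first contrast, computed directly
  t_manual <- fit$Mc[, 1] / (sqrt(fit$sigma2) * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(plain$t_24), unname(t_manual))

  # hand-set hyperparameters follow the posterior-variance formula
  mod <- moderate_statistics(fit, df_prior = 4, s0 = 1)
  s2_post <- (4 * 1 + 8 * fit$sigma2) / (4 + 8)
  t_expect <- fit$Mc[, 2] / (sqrt(s2_post) * sqrt(2 / 3))
  expect_equal(unname(mod$t_48), unname(t_expect))
  p_expect <- 2 * pt(-abs(t_expect), df = 12)
  expect_equal(unname(mod$p_48), unname(p_expect))
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(10)
  ng <- 80
  M <- matrix(rnorm(ng * 12, 0, 0.3), ng, 12)
  M[1:10, 4:12] <- M[1:10, 4:12] + 2
  M[41:80, ] <- M[41:80, ] * 2.5        # heterogeneous variances
  mat <- gene_mat(M)
  res <- moderate_statistics(fit_gene_model(mat,
                                            design_from_labels(make_labels())))
  cond <- factor(rep(c("MI16", "MII24", "MII48", "MII72"), each = 3),
                 levels = c("MI16", "MII24", "MII48", "MII72"))
  dm <- stats::model.matrix(~ 0 + cond)
  colnames(dm) <- levels(cond)
  cm <- limma::makeContrasts(MII24 - MI16, MII48 - MI16, MII72 - MI16,
                             levels = dm)
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(M, dm), cm))
  expect_equal(attr(res, "s0"), sqrt(eb$s2.prior), tolerance = 0.01)
  if (is.finite(eb$df.prior)) {
    expect_equal(attr(res, "df_prior"), eb$df.prior, tolerance = 0.05)
  } else {
    expect_gt(attr(res, "df_prior"), 1e5)
  }
  expect_lt(max(abs(res$t_24 - eb$t[, 1])), 0.02)
  expect_lt(max(abs(res$p_72 - eb$p.value[, 3])), 0.01)
})

test_that("null data give calibrated raw p-values", {
  set.seed(11)
  M <- matrix(rnorm(200 * 12, 0, 0.3), 200)
  res <- moderate_statistics(fit_gene_model(gene_mat(M),
                                            design_from_labels(make_labels())))
  for (p in list(res$p_24, res$p_48, res$p_72)) {
    expect_gte(mean(p < 0.05), 0.01)
    expect_lte(mean(p < 0.05), 0.10)
  }
})

test_that("all-zero residual variances fall back to ordinary t", {
  M <- matrix(rep(c(0, 1, 1, 1), each = 3), 2, 12, byrow = TRUE)
  M <- rbind(M, M)
  expect_warning(
    res <- moderate_statistics(fit_gene_model(gene_mat(M),
                                              design_from_labels(make_labels())),
                               s0 = NULL, df_prior = NULL),
    "ordinary t")
  expect_true(all(is.infinite(res$t_24)))
})

test_that("Benjamini-Hochberg adjustment matches the reference", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  set.seed(3)
  p <- runif(1000)
  adj <- adjust_fdr(p)
  expect_equal(adj, p.adjust(p, method = "BH"))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # ranking preserved: adjusted values are non-decreasing in raw order
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})
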