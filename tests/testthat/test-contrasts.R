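test_that("noise-free group differences are recovered exactly", {
  em <- make_two_group_em(n_genes = 10, delta = 2, noise_sd = 0)
  ct <- fit_contrast(em, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24")))
  expect_equal(ct$log2fc, rep(2, 10), tolerance = 1e-12)
  # identical groups: fold change 0, p near 1
  em0 <- make_two_group_em(n_genes = 10, delta = 0, noise_sd = 0)
  ct0 <- quietly(fit_contrast(em0, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24"))))
  expect_equal(ct0$log2fc, rep(0, 10), tolerance = 1e-12)
  expect_true(all(ct0$p > 0.99))
})

test_that("balanced designs without batch give the plain mean difference", {
  em <- make_two_group_em(n_genes = 25, delta = 0, noise_sd = 0.5, seed = 3)
  ct <- fit_contrast(em, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24"), covariates = character(0)))
  isB <- em$meta$genotype == "B"
  md <- rowMeans(em$values[, isB]) - rowMeans(em$values[, !isB])
  expect_equal(ct$log2fc, unname(md), tolerance = 1e-12)
})

test_that("interaction contrast equals the difference of the simple contrasts", {
  tc <- quietly(simulate_timecourse(n_genes = 30, seed = 9))
  pan <- quietly(simulate_ko_panel(tc, n_kos = 3, n_rep = 3, seed = 9))
  fits <- fit_panel(pan$expr)
  ko <- names(fits$n24)[1]
  expect_equal(fits$interaction[[ko]]$log2fc,
               fits$n24[[ko]]$log2fc - fits$i2[[ko]]$log2fc,
               tolerance = 1e-12)
})

test_that("fold-change and fdr agree with an unmoderated limma fit", {
  em <- make_two_group_em(n_genes = 40, delta = 1, noise_sd = 0.3,
                          seed = 11)
  ct <- fit_contrast(em, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24"), covariates = character(0)))
  design <- model.matrix(~ em$meta$genotype == "B")
  lf <- limma::lmFit(em$values, design)
  expect_equal(ct$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(ct$se, unname(lf$stdev.unscaled[, 2] * lf$sigma),
               tolerance = 1e-10)
})

test_that("threshold testing detects planted effects and controls the null", {
  cfg <- study_config()
  called <- 0; planted_n <- 0; false <- 0; null_n <- 0
  for (s in 1:5) {
    em <- make_two_group_em(n_genes = 200, delta = 0, noise_sd = 0.2,
                            seed = s)
    # plant |lfc| = 1.5 in the first 40 genes
    isB <- em$meta$genotype == "B"
    em$values[1:40, isB] <- em$values[1:40, isB] + 1.5
    ct <- fit_contrast(em, contrast_spec(
      list(genotype = "B", condition = "N24"),
      list(genotype = "A", condition = "N24")))
    sig <- ct$fdr <= cfg$fdr_de
    called <- called + sum(sig[1:40]); planted_n <- planted_n + 40
    false <- false + sum(sig[-(1:40)]); null_n <- null_n + 160
  }
  expect_gte(called / planted_n, 0.9)
  expect_lte(false / null_n, 0.05)
})

test_that("raising the fold-change null never adds significant genes", {
  em <- make_two_group_em(n_genes = 150, delta = 0, noise_sd = 0.3,
                          seed = 21)
  isB <- em$meta$genotype == "B"
  em$values[1:50, isB] <- em$values[1:50, isB] +
    rep(c(0.8, 1.5, 2.5), length.out = 50)
  spec <- contrast_spec(list(genotype = "B", condition = "N24"),
                        list(genotype = "A", condition = "N24"))
  lo <- fit_contrast(em, spec, study_config(fc_h0 = log2(1.5)))
  hi <- fit_contrast(em, spec, study_config(fc_h0 = log2(4)))
  set_lo <- define_deg_set(lo)$gene
  set_hi <- define_deg_set(hi)$gene
  expect_true(all(set_hi %in% set_lo))
})

test_that("degenerate designs are refused", {
  em <- make_two_group_em(n_genes = 5, noise_sd = 0.1)
  # batch identical to group: confounded
  em$meta$batch <- ifelse(em$meta$genotype == "B", "b2", "b1")
  expect_error(fit_contrast(em, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24"))), "confounded")
  # single replicate per group
  em1 <- naivexit:::em_subset_samples(em, c(1, 2))
  expect_error(fit_contrast(em1, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24"))), "replicates")
})

test_that("the naive-marker phenotype score averages the seven markers", {
  cfg <- study_config()
  ct <- make_ct(cfg$marker_genes_naive7, rep(0, 7))
  expect_equal(naive_marker_score(ct, cfg), 0)
  ct1 <- make_ct(cfg$marker_genes_naive7, rep(1, 7))
  expect_equal(naive_marker_score(ct1, cfg), 1)
  ct_miss <- make_ct(cfg$marker_genes_naive7[-1], rep(1, 6))
  expect_error(naive_marker_score(ct_miss, cfg), "Esrrb")
  # a delayed knockout keeps its naive markers up
  tc <- quietly(simulate_timecourse(n_genes = 30, noise_sd = 0, seed = 2))
  pan <- quietly(simulate_ko_panel(tc, delays_h = c(K12 = 12), n_rep = 2,
                                   noise_sd = 0.05, seed = 2))
  fits <- fit_panel(pan$expr)
  expect_gt(naive_marker_score(fits$n24$K12, cfg), 0)
})

test_that("DEG calling works on constructed and null inputs", {
  cfg <- study_config()
  # noise-free planted matrix: exactly the 40 planted genes
  em <- make_two_group_em(n_genes = 100, delta = 0, noise_sd = 0.02,
                          seed = 31)
  isB <- em$meta$genotype == "B"
  em$values[1:40, isB] <- em$values[1:40, isB] +
    rep(c(2, -2), length.out = 40)
  ct <- fit_contrast(em, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24")))
  degs <- define_deg_set(ct, cfg)
  expect_setequal(degs$gene, rownames(em$values)[1:40])
  expect_equal(degs$direction[match(rownames(em$values)[1], degs$gene)],
               "up")
  # empty-effect simulation stays near zero calls
  em0 <- make_two_group_em(n_genes = 300, delta = 0, noise_sd = 0.2,
                           seed = 32)
  ct0 <- fit_contrast(em0, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24")))
  expect_lte(nrow(define_deg_set(ct0, cfg)), 300 * cfg$fdr_de)
})

test_that("count matrices are transformed to log2 CPM before modelling", {
  set.seed(5)
  counts <- matrix(rpois(40, 100), 10, 4,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  meta <- data.frame(sample = paste0("s", 1:4),
                     genotype = rep(c("A", "B"), each = 2),
                     condition = "N24", batch = "b1", replicate = c(1, 2))
  em <- expression_matrix(counts, meta, unit = "counts")
  ct <- fit_contrast(em, contrast_spec(
    list(genotype = "B", condition = "N24"),
    list(genotype = "A", condition = "N24")))
  lcpm <- naivexit:::counts_to_log2(counts, "cpm")
  expect_equal(ct$log2fc,
               unname(rowMeans(lcpm[, 3:4]) - rowMeans(lcpm[, 1:2])),
               tolerance = 1e-12)
})
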