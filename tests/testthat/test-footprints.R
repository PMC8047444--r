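test_that("footprint candidacy applies the specificity arithmetic", {
  cfg <- study_config(footprint_size = 1)
  genes <- c("pass", "weak", "lowexpr")
  # 'weak': defining 1.0 vs other 0.6 -> 1.0 < 2 x 0.6, excluded
  def <- make_ct(genes, c(2.0, 1.0, 2.0), fdr = c(0, 0, 0),
                 mean_expr = c(5, 5, -3), name = "def")
  other <- make_ct(genes, c(0.3, 0.6, 0.2), name = "oth")
  fp <- derive_footprint(def, list(other), "Wnt", orientation = -1, cfg)
  expect_true("pass" %in% fp$genes)
  expect_false("weak" %in% fp$genes)
  expect_false("lowexpr" %in% fp$genes)  # below the FPKM >= 1 cutoff
})

test_that("joint Fgf definitions use the lower of the two fold changes", {
  cfg <- study_config(footprint_size = 1)
  genes <- c("g1", "g2")
  # g1: (2.0, 0.4); evaluated at 0.4, excluded when others reach 0.3
  fgfr1 <- make_ct(genes, c(2.0, 2.0), name = "Fgfr1")
  ptpn11 <- make_ct(genes, c(0.4, 1.8), name = "Ptpn11")
  other <- make_ct(genes, c(0.3, 0.3), name = "oth")
  fp <- derive_footprint(list(fgfr1, ptpn11), list(other), "FgfErk",
                         orientation = -1, cfg, allow_short = TRUE)
  expect_false("g1" %in% fp$genes)   # 0.4 < 2 x 0.3
  expect_true("g2" %in% fp$genes)    # 1.8 >= 0.6
  expect_equal(unname(fp$ref_lfc["g2"]), 1.8)  # sign from the weaker fit
})

test_that("short footprints error unless overridden", {
  cfg <- study_config()  # needs 50 genes
  def <- make_ct(paste0("g", 1:10), rep(2, 10))
  oth <- make_ct(paste0("g", 1:10), rep(0.1, 10))
  expect_error(derive_footprint(def, list(oth), "Wnt", -1, cfg),
               "qualify")
  fp <- derive_footprint(def, list(oth), "Wnt", -1, cfg,
                         allow_short = TRUE)
  expect_length(fp$genes, 10)
})

test_that("planted pathway signatures are recovered and stay disjoint", {
  tc <- quietly(simulate_timecourse(n_genes = 50, seed = 14))
  pws <- list(
    Wnt = list(defining_ko = "Tcf7l1", n_genes = 60, orientation = -1),
    mTORC1 = list(defining_ko = "Tsc2", n_genes = 60, orientation = 1))
  pan <- quietly(simulate_ko_panel(tc, n_kos = 12, n_rep = 3, seed = 14,
                                   pathways = pws))
  fits <- fit_panel(pan$expr)
  defs <- list(Wnt = list(defining = fits$n24$Tcf7l1, orientation = -1),
               mTORC1 = list(defining = fits$n24$Tsc2, orientation = 1))
  fps <- quietly(derive_footprints(defs, fits$n24))
  expect_length(fps$Wnt$genes, 50)
  expect_gte(mean(fps$Wnt$genes %in% pan$truth$pathways$Wnt$genes), 0.9)
  expect_gte(mean(fps$mTORC1$genes %in%
                    pan$truth$pathways$mTORC1$genes), 0.9)
  expect_length(intersect(fps$Wnt$genes, fps$mTORC1$genes), 0)
})

test_that("the defining knockout scores exactly its orientation", {
  genes <- paste0("g", 1:50)
  set.seed(15)
  ref_lfc <- sample(c(-1, 1), 50, TRUE) * runif(50, 1, 3)
  ref <- make_ct(genes, ref_lfc, name = "ref")
  fp <- structure(list(pathway = "Wnt", genes = genes,
                       ref_lfc = setNames(ref_lfc, genes),
                       orientation = -1), class = "footprint")
  act <- pathway_activity(ref, fp, ref)
  expect_equal(act$activity, -1, tolerance = 1e-12)
  expect_equal(act$spearman_r, 1)
  fp$orientation <- 1
  expect_equal(pathway_activity(ref, fp, ref)$activity, 1,
               tolerance = 1e-12)
})

test_that("activity is scale-covariant and halving fold changes halves it", {
  genes <- paste0("g", 1:50)
  set.seed(16)
  ref_lfc <- sample(c(-1, 1), 50, TRUE) * runif(50, 1, 3)
  ref <- make_ct(genes, ref_lfc)
  fp <- structure(list(pathway = "LIF", genes = genes,
                       ref_lfc = setNames(ref_lfc, genes),
                       orientation = 1), class = "footprint")
  half <- make_ct(genes, 0.5 * ref_lfc)
  a <- pathway_activity(half, fp, ref)
  expect_equal(a$directed_avg, 0.5, tolerance = 1e-12)
  expect_equal(a$spearman_r, 1)
  for (c_scale in c(0.2, 3)) {
    sc <- make_ct(genes, c_scale * ref_lfc)
    expect_equal(pathway_activity(sc, fp, ref)$directed_avg, c_scale,
                 tolerance = 1e-12)
  }
  # zero reference fold change in a footprint gene is structurally invalid
  bad_ref <- make_ct(genes, replace(ref_lfc, 1, 0))
  expect_error(pathway_activity(half, fp, bad_ref), "log2FC of 0")
})

test_that("phenotype regression recovers a planted coefficient", {
  set.seed(17)
  n <- 70
  corr <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(sprintf("KO%02d", 1:n),
                                 c("mTORC1", "LIF", "FgfErk", "Wnt",
                                   "Notch")))
  phen <- data.frame(ko = rownames(corr),
                     score = 0.8 * corr[, "Wnt"] + rnorm(n, 0, 0.01))
  fit <- phenotype_regression(corr, phen)
  expect_equal(fit$estimate[fit$term == "Wnt"], 0.8, tolerance = 0.05)
  expect_true(all(abs(fit$estimate[!fit$term %in%
                                     c("Wnt", "(Intercept)")]) < 0.05))
  # a duplicated pathway column is rank-deficient
  corr2 <- cbind(corr, Wnt2 = corr[, "Wnt"])
  expect_error(phenotype_regression(corr2, phen), "rank-deficient")
})

test_that("an unrelated phenotype yields no confident coefficients", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    corr <- matrix(rnorm(70 * 5), 70, 5,
                   dimnames = list(sprintf("KO%02d", 1:70),
                                   paste0("P", 1:5)))
    phen <- data.frame(ko = rownames(corr), score = rnorm(70))
    fit <- phenotype_regression(corr, phen)
    fit <- fit[fit$term != "(Intercept)", ]
    if (all(abs(fit$estimate) < 2 * fit$se)) hits <- hits + 1
  }
  expect_gte(hits, 12)  # ~ (1 - 0.05)^5 of seeds should be fully null
})
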