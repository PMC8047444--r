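test_that("fixing the seed fixes every generator output bit-exactly", {
  a <- quietly(simulate_timecourse(n_genes = 30, seed = 5))
  b <- quietly(simulate_timecourse(n_genes = 30, seed = 5))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  pa <- quietly(simulate_ko_panel(a, n_kos = 5, n_rep = 2, seed = 3))
  pb <- quietly(simulate_ko_panel(b, n_kos = 5, n_rep = 2, seed = 3))
  expect_identical(serialize(pa, NULL), serialize(pb, NULL))
  sa <- quietly(simulate_insertions(n_genes = 100, seed = 2))
  sb <- quietly(simulate_insertions(n_genes = 100, seed = 2))
  expect_identical(serialize(sa, NULL), serialize(sb, NULL))
})

test_that("time-course classes have the planted monotone shapes", {
  tc <- quietly(simulate_timecourse(n_genes = 100, noise_sd = 0, seed = 1))
  expect_equal(ncol(tc$expr$values), 17 * 2)
  tr <- tc$truth$genes
  mu <- naivexit:::timecourse_means(tc$truth, seq(0, 32, 2))
  nai <- tr$gene[tr$class == "naive"]
  expect_true(all(apply(mu[nai, ], 1, function(v) all(diff(v) <= 0))))
  form <- tr$gene[tr$class == "formative"]
  expect_true(all(apply(mu[form, ], 1, function(v) all(diff(v) >= 0))))
  # zero noise makes replicates identical
  r1 <- tc$expr$values[, tc$expr$meta$replicate == 1]
  r2 <- tc$expr$values[, tc$expr$meta$replicate == 2]
  expect_equal(unname(r1), unname(r2))
})

test_that("planted formative genes gain expression from 2i to N24", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    tc <- quietly(simulate_timecourse(n_genes = 60, noise_sd = 0.2,
                                      seed = s))
    mu <- naivexit:::timecourse_means(tc$truth, c(0, 24))
    form <- tc$truth$genes$class == "formative"
    lfc <- mu[form, 2] - mu[form, 1]
    hits <- hits + sum(lfc > 0); total <- total + sum(form)
  }
  expect_gte(hits / total, 0.95)
})

test_that("knockout snapshots sit at the planted trajectory times", {
  tc <- quietly(simulate_timecourse(n_genes = 40, noise_sd = 0, seed = 2))
  pan <- quietly(simulate_ko_panel(
    tc, delays_h = c(K0 = 0, K24 = 24), n_rep = 2, noise_sd = 0,
    batch_sd = 0, offset_2i_sd = 0, seed = 2))
  em <- pan$expr
  core <- tc$truth$genes$gene
  grab <- function(geno, cond)
    rowMeans(em$values[core, em$meta$genotype == geno &
                         em$meta$condition == cond, drop = FALSE])
  # delay 0: N24 equals WT N24; delay 24: N24 equals WT 2i
  expect_equal(grab("K0", "N24"), grab("WT", "N24"), tolerance = 1e-12)
  expect_equal(grab("K24", "N24"), grab("WT", "2i"), tolerance = 1e-12)
  expect_error(quietly(simulate_ko_panel(tc, delays_h = c(K = 30),
                                         seed = 1)), "\\[-8, 24\\]")
})

test_that("planted pathway shifts are recovered by the contrast engine", {
  tc <- quietly(simulate_timecourse(n_genes = 40, seed = 4))
  pan <- quietly(simulate_ko_panel(
    tc, n_kos = 6, n_rep = 4, noise_sd = 0.2, seed = 4,
    pathways = list(Wnt = list(defining_ko = "Tcf7l1", n_genes = 12,
                               lfc_range = c(2, 2), orientation = -1))))
  ct <- fit_contrast(pan$expr, contrast_spec(
    list(genotype = "Tcf7l1", condition = "N24"),
    list(genotype = "WT", condition = "N24")))
  g <- pan$truth$pathways$Wnt$genes
  ref <- pan$truth$pathways$Wnt$ref_lfc
  est <- ct$log2fc[match(g, ct$gene)]
  # mean planted |shift| is 2.0; sampling error bound ~ sd/sqrt(n)
  expect_equal(mean(est * sign(ref)), 2.0, tolerance = 0.1)
})

test_that("insertion screen honours its sampling model", {
  sim <- quietly(simulate_insertions(n_genes = 1500, p0 = 0.002,
                                     n_screens = 1, seed = 11))
  n_sites <- sum(sim$ttaa)
  frac <- nrow(sim$insertions) / n_sites
  expect_lt(abs(frac - 0.002), 3 * sqrt(0.002 * 0.998 / n_sites))
  # p0 = 0 gives an empty table
  empty <- quietly(simulate_insertions(n_genes = 50, p0 = 0,
                                       n_screens = 3, seed = 1))
  expect_equal(nrow(empty$insertions), 0L)
  # strongly enriched gene is hit in most screens
  tt <- simulate_ttaa(100, seed = 3)
  g <- names(tt)[which(tt >= 100)[1]]
  sim2 <- quietly(simulate_insertions(p0 = 0.001, n_screens = 10,
                                      ttaa = tt,
                                      enriched = setNames(50, g),
                                      seed = 3))
  n_hit <- length(unique(sim2$insertions$screen_id[
    sim2$insertions$gene == g]))
  # P(hit per screen) = 1-(1-.05)^n >= 0.99 at n >= 100
  expect_gte(n_hit, 5L)
  expect_error(quietly(simulate_insertions(
    p0 = 0.005, enriched = setNames(300, names(tt)[1]),
    ttaa = tt, seed = 1)), "exceed 1")
})

test_that("generated matrices pass the io validators", {
  tc <- quietly(simulate_timecourse(n_genes = 20, seed = 6))
  expect_s3_class(tc$expr, "expression_matrix")
  pan <- quietly(simulate_ko_panel(tc, n_kos = 3, n_rep = 2, seed = 6))
  expect_s3_class(pan$expr, "expression_matrix")
  td <- withr::local_tempdir()
  write_expression(pan$expr, file.path(td, "p.tsv"), file.path(td, "p.csv"))
  back <- read_expression(file.path(td, "p.tsv"), file.path(td, "p.csv"))
  expect_equal(back$values, pan$expr$values)
})
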