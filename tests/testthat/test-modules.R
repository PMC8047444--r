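test_that("response classification applies the rule composition", {
  genes <- c("const_up", "induced", "sign_flip", "silent")
  c2 <- list(KO1 = make_ct(genes, c(1, 0.2, 1, 0),
                           fdr = c(0.01, 0.5, 0.01, 0.9)))
  cn <- list(KO1 = make_ct(genes, c(1.2, 2, -1, 0),
                           fdr = c(0.01, 0.01, 0.01, 0.9)))
  ci <- list(KO1 = make_ct(genes, c(0, 1.8, 0, 0),
                           fdr = c(0.9, 0.01, 0.9, 0.9)))
  cls <- classify_response(c2, cn, ci, excluded_kos = character(0))
  expect_setequal(cls$constitutive, "const_up")
  expect_setequal(cls$induced, "induced")
  # significant in 2i up but N24 down: neither group
  expect_false("sign_flip" %in% c(cls$constitutive, cls$induced))
})

test_that("induced takes precedence over a constitutive qualification", {
  genes <- "both_ways"
  c2 <- list(K = make_ct(genes, 1, fdr = 0.01))
  cn <- list(K = make_ct(genes, 1, fdr = 0.01))
  ci <- list(K = make_ct(genes, 1, fdr = 0.01))
  cls <- classify_response(c2, cn, ci, excluded_kos = character(0))
  expect_setequal(cls$induced, genes)
  expect_length(cls$constitutive, 0)
})

test_that("tightening the FDR cutoff never adds response genes", {
  set.seed(18)
  genes <- paste0("g", 1:100)
  mk <- function() make_ct(genes, rnorm(100), fdr = runif(100))
  c2 <- list(A = mk(), B = mk()); cn <- list(A = mk(), B = mk())
  ci <- list(A = mk(), B = mk())
  loose <- classify_response(c2, cn, ci, study_config(fdr_de = 0.05),
                             excluded_kos = character(0))
  tight <- classify_response(c2, cn, ci, study_config(fdr_de = 0.01),
                             excluded_kos = character(0))
  expect_true(all(tight$induced %in% loose$induced))
  expect_true(all(tight$constitutive %in%
                    c(loose$constitutive, loose$induced)))
})

make_block_lfc <- function(n_per_block = 30, n_kos = 20, noise_sd = 0.1,
                           seed = 19) {
  set.seed(seed)
  patterns <- matrix(rnorm(3 * n_kos, 0, 1.5), 3, n_kos)
  lfc <- patterns[rep(1:3, each = n_per_block), ] +
    matrix(rnorm(3 * n_per_block * n_kos, 0, noise_sd), 3 * n_per_block)
  dimnames(lfc) <- list(sprintf("g%03d", 1:(3 * n_per_block)),
                        sprintf("KO%02d", 1:n_kos))
  list(lfc = lfc, truth = rep(1:3, each = n_per_block))
}

test_that("planted blocks are recovered with the elbow rule", {
  bl <- make_block_lfc()
  cs <- cluster_modules(bl$lfc, k = NA)
  expect_equal(cs$k, 3L)
  expect_gt(mclust::adjustedRandIndex(cs$membership, bl$truth), 0.95)
})

test_that("duplicated gene rows always co-cluster and order does not matter", {
  bl <- make_block_lfc(n_per_block = 10, seed = 20)
  lfc <- rbind(bl$lfc, dup_of_g001 = bl$lfc["g001", ])
  cs <- cluster_modules(lfc, k = 3)
  expect_equal(unname(cs$membership["dup_of_g001"]),
               unname(cs$membership["g001"]))
  perm <- sample(nrow(bl$lfc))
  cs_a <- cluster_modules(bl$lfc, k = 3)
  cs_b <- cluster_modules(bl$lfc[perm, ], k = 3)
  co_a <- outer(cs_a$membership, cs_a$membership, "==")
  co_b <- outer(cs_b$membership[rownames(bl$lfc)],
                cs_b$membership[rownames(bl$lfc)], "==")
  expect_true(all(co_a == co_b))
  expect_error(cluster_modules(matrix(1, 10, 4)), "constant")
})

test_that("forcing a larger k only splits, never mixes, the planted blocks", {
  bl <- make_block_lfc(seed = 22)
  cs <- cluster_modules(bl$lfc, k = 12)
  # merge the 12 clusters back by majority block: agreement must be high
  merged <- ave(bl$truth, cs$membership, FUN = function(v)
    as.integer(names(which.max(table(v)))))
  expect_gt(mclust::adjustedRandIndex(merged, bl$truth), 0.9)
})

test_that("module-phenotype correlations behave on constructed cases", {
  bl <- make_block_lfc(n_per_block = 10, n_kos = 70, seed = 23)
  cs <- cluster_modules(bl$lfc, k = 3)
  # anti-coupled phenotype: r close to -1 for the matching cluster
  phen <- data.frame(ko = colnames(bl$lfc),
                     score = -cs$mean_lfc[1, ] + rnorm(70, 0, 0.05))
  cc <- cluster_phenotype_correlation(cs, phen)
  expect_lt(cc$r[cc$cluster == rownames(cs$mean_lfc)[1]], -0.95)
  expect_equal(cc$abs_r, abs(cc$r))
  # null panel: random clusters stay weakly correlated most of the time
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    phen0 <- data.frame(ko = colnames(bl$lfc), score = rnorm(70))
    cc0 <- cluster_phenotype_correlation(cs, phen0)
    if (all(abs(cc0$r) < 0.3)) hits <- hits + 1
  }
  expect_gte(hits, 15)
})

test_that("Fisher enrichment equals the hypergeometric enumeration oracle", {
  universe <- paste0("g", 1:200)
  target <- paste0("g", 1:20)
  ann <- list(hit = paste0("g", 11:40), other = paste0("g", 150:190))
  res <- set_enrichment(target, universe, ann)
  # oracle: enumerate P(overlap >= k) for drawing |target| genes from the
  # universe with |set| marked
  enum_p <- function(K, n, N, k) {
    sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
  }
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 enum_p(res$n_set[i], 20, 200, res$n_overlap[i]),
                 tolerance = 1e-10)
  }
  # fisher.test agreement as a second, independent route
  ft <- fisher.test(matrix(c(10, 20, 10, 160), 2), alternative = "greater")
  expect_equal(res$p[res$set == "hit"], ft$p.value, tolerance = 1e-10)
})

test_that("redundant terms merge and the smallest becomes primary", {
  universe <- paste0("g", 1:100)
  target <- paste0("g", 1:10)
  ann <- list(big = paste0("g", c(1:8, 20:40)),    # 8 target genes, size 29
              small = paste0("g", c(1:6, 50:55)),  # 6 target genes, size 12
              far = paste0("g", c(90:99)))         # 0 target genes
  res <- set_enrichment(target, universe, ann, min_target_genes = 0L)
  expect_equal(res$merge_group[res$set == "big"],
               res$merge_group[res$set == "small"])  # differ by 2 genes
  expect_true(res$primary[res$set == "small"])
  expect_false(res$primary[res$set == "big"])
  expect_true(is.na(res$p_adj[res$set == "big"]))
  # BH runs over primary terms only
  expect_equal(sum(res$primary), sum(!is.na(res$p_adj)))
})

test_that("null targets produce calibrated primary-term p-values", {
  # sets are sized so their genes-of-interest memberships differ by more
  # than the merge distance: each term stands alone and the primary-term
  # p-values are plain hypergeometric nulls
  set.seed(24)
  universe <- paste0("g", 1:1000)
  ann <- lapply(1:40, function(i) sample(universe, 60))
  names(ann) <- paste0("S", 1:40)
  frac <- replicate(25, {
    target <- sample(universe, 100)
    res <- set_enrichment(target, universe, ann, min_target_genes = 0L)
    mean(res$p[res$primary] < 0.05)
  })
  expect_gte(mean(frac), 0.02)
  expect_lte(mean(frac), 0.08)
})
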