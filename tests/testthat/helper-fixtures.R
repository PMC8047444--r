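# shared fixture builders; everything is generated in code at test time

# minimal contrast table with the columns downstream stages consume
make_ct <- function(genes, lfc, fdr = rep(0, length(genes)),
                    mean_expr = rep(5, length(genes)), name = "ct") {
  tab <- data.frame(gene = genes, log2fc = lfc, stat = 0,
                    se = 0.1, df = 6, p = fdr, fdr = fdr,
                    mean_expr = mean_expr, stringsAsFactors = FALSE)
  attr(tab, "name") <- name
  class(tab) <- c("contrast_table", "data.frame")
  tab
}

# small two-group expression matrix with optional batch structure
make_two_group_em <- function(n_genes = 20, n_rep = 4, delta = 0,
                              noise_sd = 0, seed = 1, batch_split = FALSE) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  base <- runif(n_genes, 3, 8)
  cols <- list(); metas <- list()
  for (r in seq_len(n_rep)) {
    for (grp in c("A", "B")) {
      id <- paste0(grp, r)
      mu <- base + if (grp == "B") delta else 0
      cols[[id]] <- mu + rnorm(n_genes, 0, noise_sd)
      metas[[id]] <- data.frame(
        sample = id, genotype = grp,
        condition = "N24",
        batch = if (batch_split) paste0("b", (r %% 2) + 1) else "b1",
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- genes
  expression_matrix(vals, do.call(rbind, metas), unit = "log2fpkm")
}

# quiet wrapper: the generators log their seeds to stderr
quietly <- function(expr) suppressMessages(expr)
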