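#' @name contrast-engine
#' @title Differential expression contrasts with a fold-change null
#' @description
#' A transparent per-gene ordinary-least-squares engine for the panel
#' contrasts the pipeline consumes. Each gene's log2 expression is
#' regressed on group membership plus batch; significance is tested against
#' the composite null |log2FC| < log2(1.5) with a threshold t-test, and
#' p-values are Benjamini-Hochberg adjusted per contrast. The engine does
#' not moderate variances; externally computed contrast tables with the
#' same columns can be plugged into every downstream stage.
NULL

#' Specify a contrast
#'
#' @param numerator,denominator Lists with `genotype` and `condition`
#'   naming the two cells being compared. For an interaction contrast only
#'   the genotypes are used and both conditions (`N24`, `2i`) enter.
#' @param kind `"simple"` or `"interaction"` (difference of the two simple
#'   log2 fold changes KO vs control at N24 and at 2i).
#' @param covariates Covariates to adjust for; `"batch"` or empty.
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(numerator, denominator,
                          kind = c("simple", "interaction"),
                          covariates = "batch") {
  kind <- match.arg(kind)
  structure(list(numerator = numerator, denominator = denominator,
                 kind = kind, covariates = covariates),
            class = "contrast_spec")
}

# counts -> log2 scale; cpm with pseudocount or median-of-ratios size factors
counts_to_log2 <- function(values, method = c("cpm", "sizefactor")) {
  method <- match.arg(method)
  if (method == "cpm") {
    lib <- colSums(values)
    log2(sweep(values, 2, lib, "/") * 1e6 + 0.5)
  } else {
    logg <- rowMeans(log(values + 0.5))
    sf <- apply(values, 2, function(col)
      exp(stats::median((log(col + 0.5) - logg)[is.finite(logg)])))
    log2(sweep(values, 2, sf, "/") + 0.5)
  }
}

# per-gene OLS of log2 expression on group (+ batch); vectorised over genes
ols_group_fit <- function(Y, group, batch = NULL, se_floor = 1e-8) {
  X <- cbind(intercept = 1, group = group)
  if (!is.null(batch) && length(unique(batch)) > 1L) {
    B <- stats::model.matrix(~ factor(batch))[, -1L, drop = FALSE]
    colnames(B) <- paste0("batch", seq_len(ncol(B)))
    X <- cbind(X, B)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # 'group' is estimable only if it adds rank beyond the other columns
    others <- X[, colnames(X) != "group", drop = FALSE]
    if (qr(others)$rank == qx$rank)
      stop("batch is perfectly confounded with the contrast groups",
           call. = FALSE)
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  df <- nrow(X) - qx$rank
  if (df < 1L)
    stop("unreplicated design: no residual degrees of freedom",
         call. = FALSE)
  coefs <- qr.coef(qx, t(Y))
  res <- t(Y) - X %*% coefs
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qx))
  gg <- xtxi[match("group", colnames(X)), match("group", colnames(X))]
  se <- sqrt(pmax(s2 * gg, se_floor^2))
  floored <- s2 * gg < se_floor^2
  if (any(floored))
    nx_log("fit_contrast", sum(floored),
           " gene(s) with degenerate variance; se floored")
  list(lfc = coefs["group", ], se = se, df = df)
}

treat_p <- function(lfc, se, df, threshold) {
  tr <- (abs(lfc) - threshold) / se
  tl <- (abs(lfc) + threshold) / se
  stats::pt(tr, df, lower.tail = FALSE) +
    stats::pt(tl, df, lower.tail = FALSE)
}

make_contrast_table <- function(name, genes, lfc, se, df, mean_expr,
                                config) {
  p <- treat_p(lfc, se, df, config$fc_h0)
  p <- pmin(p, 1)
  data.frame(gene = genes, log2fc = unname(lfc),
             stat = unname((abs(lfc) - config$fc_h0) / se),
             se = unname(se), df = df,
             p = unname(p),
             fdr = stats::p.adjust(p, method = "BH"),
             mean_expr = unname(mean_expr),
             stringsAsFactors = FALSE) -> tab
  attr(tab, "name") <- name
  class(tab) <- c("contrast_table", "data.frame")
  tab
}

#' Fit one contrast
#'
#' @param em An [expression_matrix()]; counts are converted to
#'   log2(CPM + 0.5) before modelling.
#' @param spec A [contrast_spec()].
#' @param config A [study_config()].
#' @param norm Count normalisation: `"cpm"` or `"sizefactor"`
#'   (median-of-ratios).
#' @return A `contrast_table` data frame with per-gene `log2fc`, `stat`,
#'   `se`, `p`, `fdr` (Benjamini-Hochberg within the contrast) and
#'   `mean_expr` (larger of the two group means, log2 scale).
#' @export
fit_contrast <- function(em, spec, config = study_config(),
                         norm = c("cpm", "sizefactor")) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(spec, "contrast_spec"))
  vals <- em$values
  if (em$unit == "counts") vals <- counts_to_log2(vals, match.arg(norm))
  if (spec$kind == "interaction") {
    s_n24 <- contrast_spec(
      list(genotype = spec$numerator$genotype, condition = "N24"),
      list(genotype = spec$denominator$genotype, condition = "N24"),
      covariates = spec$covariates)
    s_2i <- contrast_spec(
      list(genotype = spec$numerator$genotype, condition = "2i"),
      list(genotype = spec$denominator$genotype, condition = "2i"),
      covariates = spec$covariates)
    a <- fit_contrast(em, s_n24, config)
    b <- fit_contrast(em, s_2i, config)
    lfc <- a$log2fc - b$log2fc
    se <- sqrt(a$se^2 + b$se^2)
    df <- a$df + b$df
    return(make_contrast_table(
      paste0(spec$numerator$genotype, "_interaction"),
      a$gene, lfc, se, df, pmax(a$mean_expr, b$mean_expr), config))
  }
  pick <- function(side)
    em$meta$genotype == side$genotype & em$meta$condition == side$condition
  in_num <- pick(spec$numerator)
  in_den <- pick(spec$denominator)
  if (sum(in_num) < 2L || sum(in_den) < 2L)
    stop("need >= 2 replicates per group (",
         sum(in_num), " vs ", sum(in_den), ")", call. = FALSE)
  idx <- in_num | in_den
  Y <- vals[, idx, drop = FALSE]
  group <- as.numeric(in_num[idx])
  batch <- if ("batch" %in% spec$covariates) em$meta$batch[idx] else NULL
  fit <- ols_group_fit(Y, group, batch)
  mean_expr <- pmax(rowMeans(vals[, in_num, drop = FALSE]),
                    rowMeans(vals[, in_den, drop = FALSE]))
  nm <- paste0(spec$numerator$genotype, "_", spec$numerator$condition,
               "_vs_", spec$denominator$genotype, "_",
               spec$denominator$condition)
  make_contrast_table(nm, rownames(Y), fit$lfc, fit$se, fit$df,
                      mean_expr, config)
}

#' Average naive-marker fold change of a knockout
#'
#' The differentiation phenotype score: the arithmetic mean log2 fold
#' change of the seven core naive markers in the KO-vs-control N24
#' contrast. Positive values indicate delayed differentiation (markers not
#' yet downregulated).
#'
#' @param contrast A `contrast_table` (KO vs control at N24).
#' @param config A [study_config()].
#' @return A single numeric score.
#' @export
naive_marker_score <- function(contrast, config = study_config()) {
  mk <- config$marker_genes_naive7
  miss <- setdiff(mk, contrast$gene)
  if (length(miss))
    stop("marker gene(s) missing from contrast: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mean(contrast$log2fc[match(mk, contrast$gene)])
}

#' Call the differentiation DEG set
#'
#' Genes differentially expressed between control N24 and 2i under the
#' fold-change-threshold test at the configured FDR, with direction labels.
#'
#' @param contrast The control N24-vs-2i `contrast_table`.
#' @param config A [study_config()].
#' @return Data frame with `gene` and `direction` (`"up"`/`"down"`).
#' @export
define_deg_set <- function(contrast, config = study_config()) {
  sig <- contrast$fdr <= config$fdr_de
  data.frame(gene = contrast$gene[sig],
             direction = ifelse(contrast$log2fc[sig] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Fit the full knockout-panel contrast families
#'
#' Convenience wrapper computing, for every knockout genotype in the panel,
#' the three contrasts downstream stages need (KO vs control at N24, at 2i,
#' and their interaction), the control differentiation contrast
#' (N24 vs 2i), and the per-KO naive-marker phenotype scores.
#'
#' @param em Panel [expression_matrix()] containing `"WT"` control samples.
#' @param config A [study_config()].
#' @param control Control genotype label.
#' @return List with `n24`, `i2`, `interaction` (named lists of
#'   `contrast_table`s per KO), `wt_diff`, and `phenotypes` (data frame
#'   `ko`, `score`).
#' @export
fit_panel <- function(em, config = study_config(), control = "WT") {
  kos <- setdiff(unique(em$meta$genotype), control)
  n24 <- list(); i2 <- list(); inter <- list()
  for (ko in kos) {
    n24[[ko]] <- fit_contrast(em, contrast_spec(
      list(genotype = ko, condition = "N24"),
      list(genotype = control, condition = "N24")), config)
    i2[[ko]] <- fit_contrast(em, contrast_spec(
      list(genotype = ko, condition = "2i"),
      list(genotype = control, condition = "2i")), config)
    inter[[ko]] <- fit_contrast(em, contrast_spec(
      list(genotype = ko), list(genotype = control),
      kind = "interaction"), config)
  }
  wt_diff <- fit_contrast(em, contrast_spec(
    list(genotype = control, condition = "N24"),
    list(genotype = control, condition = "2i")), config)
  phen <- data.frame(
    ko = kos,
    score = vapply(kos, function(k) naive_marker_score(n24[[k]], config),
                   numeric(1L)),
    stringsAsFactors = FALSE)
  list(n24 = n24, i2 = i2, interaction = inter, wt_diff = wt_diff,
       phenotypes = phen)
}

# gene x KO matrix of log2 fold changes from a list of contrast tables
lfc_matrix <- function(contrasts) {
  genes <- contrasts[[1L]]$gene
  m <- vapply(contrasts, function(ct) ct$log2fc[match(genes, ct$gene)],
              numeric(length(genes)))
  rownames(m) <- genes
  m
}
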