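#' @name naive-association
#' @title Naive-associated gene discovery
#' @description
#' A gene is naive-associated (a NAG) when its log2 fold-change pattern
#' across the knockout panel at N24 is well predicted by the patterns of
#' the seven core naive markers: each gene is regressed on the marker
#' fold-change vectors and the multiple R-squared measures their shared
#' variance. Genes at or above the configured cutoff (0.65) are NAGs, split
#' into up- and downNAGs by the sign of their fold change during normal
#' differentiation.
NULL

#' Regress one gene's knockout response on the marker responses
#'
#' Ordinary least squares with intercept; collinear marker columns are
#' handled through the pseudo-inverse (pivoted QR), so the R-squared is
#' well defined regardless of marker collinearity.
#'
#' @param gene_lfc Numeric vector of the gene's log2 fold changes over KOs.
#' @param marker_lfc Markers x KOs matrix of log2 fold changes.
#' @return List with `r2` and `coefficients` (intercept first).
#' @export
fit_naive_association <- function(gene_lfc, marker_lfc) {
  if (length(gene_lfc) != ncol(marker_lfc))
    stop("gene vector length (", length(gene_lfc),
         ") does not match marker matrix KOs (", ncol(marker_lfc), ")",
         call. = FALSE)
  n <- length(gene_lfc)
  p <- nrow(marker_lfc)
  if (n < p + 2L)
    stop("need more KOs (", n, ") than marker predictors (", p,
         ") plus intercept", call. = FALSE)
  X <- cbind(1, t(marker_lfc))
  qx <- qr(X)
  beta <- qr.coef(qx, gene_lfc)
  beta[is.na(beta)] <- 0
  fitted <- qr.fitted(qx, gene_lfc)
  rss <- sum((gene_lfc - fitted)^2)
  tss <- sum((gene_lfc - mean(gene_lfc))^2)
  r2 <- if (tss == 0) 0 else max(0, 1 - rss / tss)
  list(r2 = r2, coefficients = beta)
}

#' Call naive-associated genes across the knockout panel
#'
#' @param panel_contrasts Named list of KO-vs-control N24 `contrast_table`s
#'   (one per KO) or a pre-built gene x KO log2FC matrix.
#' @param wt_diff Control N24-vs-2i `contrast_table` supplying the
#'   differentiation direction of each gene.
#' @param config A [study_config()]; `nag_r2` is the call threshold and
#'   `marker_genes_naive7` the predictor set.
#' @return A `nag_table` data frame with per-gene `r2`, `direction`
#'   (`"up"`, `"down"`, `"none"`) and `is_nag`. Marker genes themselves are
#'   excluded from NAG calls.
#' @export
call_nags <- function(panel_contrasts, wt_diff, config = study_config()) {
  lfc <- if (is.matrix(panel_contrasts)) panel_contrasts
         else lfc_matrix(panel_contrasts)
  mk <- config$marker_genes_naive7
  miss <- setdiff(mk, rownames(lfc))
  if (length(miss))
    stop("marker gene(s) absent from panel: ",
         paste(miss, collapse = ", "), call. = FALSE)
  M <- lfc[mk, , drop = FALSE]
  genes <- rownames(lfc)
  r2 <- vapply(genes, function(g)
    fit_naive_association(lfc[g, ], M)$r2, numeric(1L))
  wt_lfc <- wt_diff$log2fc[match(genes, wt_diff$gene)]
  direction <- ifelse(is.na(wt_lfc) | wt_lfc == 0, "none",
                      ifelse(wt_lfc > 0, "up", "down"))
  is_nag <- r2 >= config$nag_r2 & !(genes %in% mk)
  res <- data.frame(gene = genes, r2 = r2, direction = direction,
                    is_nag = is_nag, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("nag_table", "data.frame")
  res
}

#' Export up/downNAG gene sets
#'
#' @param nags A `nag_table` from [call_nags()].
#' @return A `gene_set_collection` with `upNAGs` and `downNAGs`.
#' @export
nag_gene_sets <- function(nags) {
  up <- nags$gene[nags$is_nag & nags$direction == "up"]
  dn <- nags$gene[nags$is_nag & nags$direction == "down"]
  sets <- list()
  if (length(up)) sets$upNAGs <- list(genes = up,
                                      description = "NAGs up in N24")
  if (length(dn)) sets$downNAGs <- list(genes = dn,
                                        description = "NAGs down in N24")
  structure(sets, class = "gene_set_collection")
}

# total least squares (orthogonal regression) of y on x via the first
# principal axis of the centred data
tls_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  C <- stats::cov(cbind(x - mx, y - my))
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (abs(v[1L]) < 1e-12)
    stop("orthogonal regression is vertical (no finite slope)",
         call. = FALSE)
  slope <- v[2L] / v[1L]
  list(slope = slope, intercept = my - slope * mx)
}

#' Knockout transcriptome similarity by orthogonal regression
#'
#' Total-least-squares (first principal axis) regression of one knockout's
#' log2 fold changes on another's, over genes significant in either
#' contrast, plus the Pearson correlation.
#'
#' @param ko_a,ko_b `contrast_table`s for the two knockouts (vs control at
#'   N24).
#' @param config A [study_config()]; `fdr_de` defines the significance
#'   filter.
#' @param min_genes Minimum genes passing the filter.
#' @return List with `tls_slope`, `tls_intercept`, `r` and `n_genes`.
#' @export
ko_similarity <- function(ko_a, ko_b, config = study_config(),
                          min_genes = 10L) {
  genes <- intersect(ko_a$gene, ko_b$gene)
  a <- ko_a[match(genes, ko_a$gene), ]
  b <- ko_b[match(genes, ko_b$gene), ]
  keep <- a$fdr <= config$fdr_de | b$fdr <= config$fdr_de
  if (sum(keep) < min_genes)
    stop("fewer than ", min_genes, " genes significant in either knockout",
         call. = FALSE)
  fit <- tls_fit(a$log2fc[keep], b$log2fc[keep])
  list(tls_slope = fit$slope, tls_intercept = fit$intercept,
       r = stats::cor(a$log2fc[keep], b$log2fc[keep]),
       n_genes = sum(keep))
}
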