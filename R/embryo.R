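#' @name embryo-projection
#' @title Embryo-identity deconvolution and projection
#' @description
#' Panel transcriptomes are compared with embryo reference stages in three
#' ways: fraction-of-identity deconvolution (simplex-constrained least
#' squares of a bulk profile on stage signature columns), projection onto a
#' PCA fitted to the reference stages over highly variable genes, and
#' cumulative contribution curves showing where a gene set sits among the
#' loadings of a principal component. Orthogonal-regression and
#' co-regulation statistics compare fold-change responses between
#' conditions or species.
NULL

# exact simplex-constrained least squares by enumeration of support sets:
# min ||S f - b||^2 subject to f >= 0, sum(f) = 1. Stage counts are small
# (a handful of embryo stages), so all supports are tried and the KKT
# system solved exactly on each.
simplex_lsq <- function(S, b) {
  k <- ncol(S)
  if (k > 12L)
    stop("simplex solver supports up to 12 reference stages", call. = FALSE)
  best <- NULL; best_obj <- Inf
  for (mask in seq_len(2^k - 1L)) {
    A <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    SA <- S[, A, drop = FALSE]
    G <- crossprod(SA)
    kkt <- rbind(cbind(2 * G, 1), c(rep(1, length(A)), 0))
    rhs <- c(2 * crossprod(SA, b), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    fA <- sol[seq_along(A)]
    if (any(fA < -1e-9)) next
    f <- numeric(k); f[A] <- pmax(fA, 0)
    f <- f / sum(f)
    obj <- sum((S %*% f - b)^2)
    if (obj < best_obj - 1e-12) { best <- f; best_obj <- obj }
  }
  stats::setNames(best, colnames(S))
}

#' Fraction of identity of a bulk profile among reference stages
#'
#' Solves min ||S f - b||2 subject to f >= 0 and sum(f) = 1 over the genes
#' shared between the sample and the reference signatures after the
#' expression filter, yielding the fraction of each reference stage's
#' identity in the sample.
#'
#' @param sample Named numeric vector of log2 expression.
#' @param refs Gene x stage reference signature matrix (log2 scale).
#' @param min_expr Gene filter: keep genes with sample expression strictly
#'   above this (default 0, i.e. log2FPKM > 0).
#' @param min_genes Minimum shared genes after filtering.
#' @return Named numeric vector of fractions (non-negative, summing to 1).
#' @export
fraction_of_identity <- function(sample, refs, min_expr = 0,
                                 min_genes = 100L) {
  if (all(sample == 0)) stop("all-zero sample profile", call. = FALSE)
  shared <- intersect(names(sample), rownames(refs))
  keep <- shared[sample[shared] > min_expr]
  if (length(keep) < min_genes)
    stop("only ", length(keep), " shared genes pass the filter (need ",
         min_genes, ")", call. = FALSE)
  simplex_lsq(refs[keep, , drop = FALSE], sample[keep])
}

#' Select highly variable genes
#'
#' Fits a local-regression trend of the squared coefficient of variation on
#' the mean log2 expression and selects genes above the trend that also
#' pass fixed thresholds on both axes.
#'
#' @param mat Gene x sample (or cell) log2 expression matrix with at least
#'   3 columns.
#' @param min_mean Minimum mean log2 expression (x-axis threshold).
#' @param min_cv2 Minimum squared coefficient of variation (y-axis
#'   threshold).
#' @param span Loess span for the trend.
#' @return Character vector of selected genes; the fitted trend is attached
#'   as attribute `trend` (data frame `gene`, `mean_log2`, `cv2`,
#'   `trend_cv2`).
#' @export
select_variable_genes <- function(mat, min_mean = -Inf, min_cv2 = 0,
                                  span = 0.5) {
  if (ncol(mat) < 3L)
    stop("need >= 3 columns for a coefficient of variation", call. = FALSE)
  lin <- 2^mat
  mu <- rowMeans(lin)
  v <- apply(lin, 1L, stats::var)
  if (all(v < 1e-300)) stop("degenerate variance: all genes constant",
                            call. = FALSE)
  cv2 <- ifelse(mu > 0, v / mu^2, 0)
  mean_log2 <- rowMeans(mat)
  fit <- stats::loess(cv2 ~ mean_log2, span = span, degree = 2,
                      family = "symmetric")
  trend <- stats::predict(fit, mean_log2)
  sel <- cv2 > trend & mean_log2 >= min_mean & cv2 >= min_cv2
  sel[is.na(sel)] <- FALSE
  out <- rownames(mat)[sel]
  attr(out, "trend") <- data.frame(gene = rownames(mat),
                                   mean_log2 = mean_log2, cv2 = cv2,
                                   trend_cv2 = trend,
                                   stringsAsFactors = FALSE)
  out
}

#' Fit a PCA on reference profiles and project panel samples
#'
#' The PCA is fitted on the reference stage (or cell) profiles over the
#' supplied genes, centred on the reference gene means and unscaled. Panel
#' samples are centred with the reference means (not their own), giving a
#' true out-of-sample embedding. Loadings are sign-fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param refs Gene x stage reference matrix.
#' @param samples Gene x sample matrix to project (optional).
#' @param genes Genes to use (default: all shared).
#' @return List with `scores_ref`, `scores_samples`, `loadings`, `sdev`,
#'   `var_explained`, `center`.
#' @export
project_pca <- function(refs, samples = NULL, genes = NULL) {
  if (is.null(genes)) genes <- rownames(refs)
  if (!is.null(samples)) genes <- intersect(genes, rownames(samples))
  miss <- setdiff(genes, rownames(refs))
  if (length(miss))
    stop("gene(s) absent from references: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  M <- t(refs[genes, , drop = FALSE])
  if (ncol(M) < nrow(M))
    stop("need at least as many genes as reference profiles", call. = FALSE)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, "*")
  scores_ref <- sweep(pc$x, 2L, flip, "*")
  scores_samples <- NULL
  if (!is.null(samples)) {
    X <- t(samples[genes, , drop = FALSE])
    scores_samples <- sweep(X, 2L, pc$center) %*% rot
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores_ref = scores_ref, scores_samples = scores_samples,
       loadings = rot, sdev = pc$sdev, var_explained = ve,
       center = pc$center)
}

#' Cumulative contribution of a gene set to a principal component
#'
#' Genes are ranked by absolute loading (descending); at each rank the
#' cumulative count (or summed squared loading) of set members among the
#' top-ranked genes is reported, together with the same curve for a
#' comparison set.
#'
#' @param loadings Named numeric vector: one component's loadings.
#' @param gene_set Query gene set (non-empty).
#' @param comparison_set Optional comparison set (e.g. size-matched
#'   random genes).
#' @param weight `"count"` or `"sq_loading"`.
#' @return Data frame `rank`, `gene`, `cum_query` and (when supplied)
#'   `cum_comparison`.
#' @export
dimension_contribution <- function(loadings, gene_set,
                                   comparison_set = NULL,
                                   weight = c("count", "sq_loading")) {
  weight <- match.arg(weight)
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  ord <- order(-abs(loadings))
  genes <- names(loadings)[ord]
  w <- if (weight == "count") rep(1, length(genes))
       else loadings[ord]^2
  out <- data.frame(rank = seq_along(genes), gene = genes,
                    cum_query = cumsum(w * (genes %in% gene_set)),
                    stringsAsFactors = FALSE)
  if (!is.null(comparison_set))
    out$cum_comparison <- cumsum(w * (genes %in% comparison_set))
  out
}

#' Co-regulation and orthogonal-regression comparison of two responses
#'
#' Co-regulation counts genes moving beyond the threshold in both
#' conditions (same sign by default); the count is compared with the
#' independence expectation by a chi-square goodness-of-fit test. The
#' orthogonal (total least squares) regression slope and its angle to the
#' x-axis, plus the Spearman correlation, summarise the relationship.
#'
#' @param lfc_a,lfc_b Aligned log2 fold-change vectors (>= 30 genes).
#' @param threshold Absolute fold-change threshold (default 0.1).
#' @param signed Require sign agreement for co-regulation (default).
#' @return List: `observed`, `expected`, `chi2`, `chi2_p`, `rho`
#'   (Spearman), `tls_slope`, `alpha_deg`, `n`.
#' @export
coregulation_test <- function(lfc_a, lfc_b, threshold = 0.1,
                              signed = TRUE) {
  if (length(lfc_a) != length(lfc_b))
    stop("fold-change vectors differ in length", call. = FALSE)
  n <- length(lfc_a)
  if (n < 30L) stop("need >= 30 genes", call. = FALSE)
  above_a <- abs(lfc_a) > threshold
  above_b <- abs(lfc_b) > threshold
  pa <- mean(above_a); pb <- mean(above_b)
  if (signed) {
    observed <- sum(above_a & above_b & sign(lfc_a) == sign(lfc_b))
    pap <- if (pa > 0) mean(lfc_a > threshold) / pa else 0.5
    pbp <- if (pb > 0) mean(lfc_b > threshold) / pb else 0.5
    p_agree <- pap * pbp + (1 - pap) * (1 - pbp)
    expected <- n * pa * pb * p_agree
  } else {
    observed <- sum(above_a & above_b)
    expected <- n * pa * pb
  }
  chi2 <- if (expected > 0 && expected < n)
    (observed - expected)^2 / expected +
      (observed - expected)^2 / (n - expected)
  else NA_real_
  chi2_p <- if (is.na(chi2)) NA_real_
            else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fit <- tls_fit(lfc_a, lfc_b)
  list(observed = observed, expected = expected, chi2 = chi2,
       chi2_p = chi2_p,
       rho = stats::cor(lfc_a, lfc_b, method = "spearman"),
       tls_slope = fit$slope,
       alpha_deg = atan(fit$slope) * 180 / pi, n = n)
}
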