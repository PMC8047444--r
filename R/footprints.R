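#' @name pathway-footprints
#' @title Pathway expression footprints and directed activity
#' @description
#' Each signalling pathway (mTORC1, LIF, Fgf/Erk, Wnt, Notch) is
#' represented by the 50 genes responding most specifically to the knockout
#' of its upstream regulator (Tsc2; the 2i/LIF-vs-2i contrast; Fgfr1 and
#' Ptpn11 jointly; Tcf7l1; Rbpj). A gene qualifies when it is significant
#' in the defining contrast, its fold change exceeds the largest fold
#' change in all remaining conditions by a factor of two, and it is
#' expressed (FPKM/CPM of at least 1) in knockout or control. Pathway
#' activity in any knockout is the directed average fold change of the
#' footprint relative to the defining knockout, so that the defining
#' knockout itself scores exactly +1 or -1 depending on the pathway's
#' orientation.
NULL

#' Derive one pathway footprint
#'
#' @param defining A `contrast_table`, or a list of two (Fgf/Erk: the
#'   criterion is applied to the lower of the two fold changes per gene).
#' @param others List of all remaining `contrast_table`s against which
#'   specificity is measured.
#' @param pathway Pathway name.
#' @param orientation `+1` (LIF, mTORC1) or `-1` (Fgf/Erk, Wnt, Notch).
#' @param config A [study_config()].
#' @param allow_short Permit fewer than `footprint_size` genes.
#' @return A `footprint` list: `pathway`, `genes`, `ref_lfc` (signed
#'   reference log2 fold changes, named), `orientation`, `specificity`
#'   (ratio of defining to best other fold change).
#' @export
derive_footprint <- function(defining, others, pathway,
                             orientation = c(1, -1)[1],
                             config = study_config(),
                             allow_short = FALSE) {
  cand <- footprint_candidates(defining, others, config)
  if (nrow(cand) < config$footprint_size && !allow_short)
    stop("only ", nrow(cand), " genes qualify for the ", pathway,
         " footprint (need ", config$footprint_size,
         "); use allow_short to override", call. = FALSE)
  cand <- cand[order(-abs(cand$ref_lfc)), , drop = FALSE]
  keep <- utils::head(cand, config$footprint_size)
  structure(list(pathway = pathway, genes = keep$gene,
                 ref_lfc = stats::setNames(keep$ref_lfc, keep$gene),
                 orientation = orientation,
                 specificity = stats::setNames(keep$ratio, keep$gene)),
            class = "footprint")
}

footprint_candidates <- function(defining, others, config) {
  def_list <- if (inherits(defining, "contrast_table")) list(defining)
              else defining
  genes <- def_list[[1L]]$gene
  sig <- rep(TRUE, length(genes))
  expr_ok <- rep(FALSE, length(genes))
  abs_lfc <- matrix(NA_real_, length(genes), length(def_list))
  for (i in seq_along(def_list)) {
    ct <- def_list[[i]]
    ix <- match(genes, ct$gene)
    sig <- sig & !is.na(ix) & ct$fdr[ix] <= config$fdr_de
    expr_ok <- expr_ok | ct$mean_expr[ix] >= log2(config$expr_cutoff)
    abs_lfc[, i] <- abs(ct$log2fc[ix])
  }
  # the lower of the fold changes governs when two contrasts define the
  # pathway; the reference sign is taken from that weaker contrast
  wmin <- max.col(-abs_lfc, ties.method = "first")
  def_abs <- abs_lfc[cbind(seq_along(genes), wmin)]
  ref_lfc <- vapply(seq_along(genes), function(g) {
    ct <- def_list[[wmin[g]]]
    ct$log2fc[match(genes[g], ct$gene)]
  }, numeric(1L))
  other_max <- rep(0, length(genes))
  for (ct in others) {
    ix <- match(genes, ct$gene)
    other_max <- pmax(other_max, abs(ct$log2fc[ix]), na.rm = TRUE)
  }
  ratio <- def_abs / pmax(other_max, 1e-12)
  ok <- sig & expr_ok & def_abs >= config$specificity_factor * other_max &
    def_abs > 0
  data.frame(gene = genes[ok], ref_lfc = ref_lfc[ok], ratio = ratio[ok],
             stringsAsFactors = FALSE)
}

#' Derive all pathway footprints with disjointness
#'
#' Runs [derive_footprint()] per pathway after resolving genes qualifying
#' for more than one pathway: each such gene is assigned to the pathway
#' with the larger specificity ratio (logged).
#'
#' @param definitions Named list; each element
#'   `list(defining = contrast_table(s), orientation = +1/-1)`.
#' @param all_contrasts Named list of every knockout `contrast_table`
#'   (specificity for one pathway is measured against all contrasts except
#'   its own defining ones).
#' @param config A [study_config()].
#' @param allow_short Permit short footprints.
#' @return Named list of `footprint` objects (pairwise disjoint).
#' @export
derive_footprints <- function(definitions, all_contrasts,
                              config = study_config(),
                              allow_short = FALSE) {
  cand <- list()
  for (pw in names(definitions)) {
    def <- definitions[[pw]]$defining
    def_list <- if (inherits(def, "contrast_table")) list(def) else def
    def_names <- vapply(def_list, function(ct) attr(ct, "name"),
                        character(1L))
    others <- all_contrasts[!vapply(all_contrasts, function(ct)
      attr(ct, "name") %in% def_names, logical(1L))]
    cand[[pw]] <- footprint_candidates(def, others, config)
  }
  # resolve cross-pathway overlaps by the larger specificity ratio
  all_genes <- unlist(lapply(cand, `[[`, "gene"))
  dup <- unique(all_genes[duplicated(all_genes)])
  for (g in dup) {
    ratios <- vapply(names(cand), function(pw) {
      i <- match(g, cand[[pw]]$gene)
      if (is.na(i)) -Inf else cand[[pw]]$ratio[i]
    }, numeric(1L))
    winner <- names(which.max(ratios))
    nx_log("derive_footprints", "gene ", g, " assigned to ", winner)
    for (pw in setdiff(names(cand), winner))
      cand[[pw]] <- cand[[pw]][cand[[pw]]$gene != g, , drop = FALSE]
  }
  out <- list()
  for (pw in names(definitions)) {
    cc <- cand[[pw]]
    if (nrow(cc) < config$footprint_size && !allow_short)
      stop("only ", nrow(cc), " genes qualify for the ", pw, " footprint",
           call. = FALSE)
    cc <- cc[order(-abs(cc$ref_lfc)), , drop = FALSE]
    keep <- utils::head(cc, config$footprint_size)
    out[[pw]] <- structure(
      list(pathway = pw, genes = keep$gene,
           ref_lfc = stats::setNames(keep$ref_lfc, keep$gene),
           orientation = definitions[[pw]]$orientation,
           specificity = stats::setNames(keep$ratio, keep$gene)),
      class = "footprint")
  }
  out
}

#' Directed pathway activity of one knockout
#'
#' For each footprint gene g, directedFC(g) = |log2FC(KO)| with sign +1
#' when the knockout moves the gene in the same direction as the defining
#' contrast and -1 otherwise (a zero knockout fold change contributes 0).
#' The directed average is the sum over the footprint divided by the same
#' sum in the defining knockout, and the activity multiplies it by the
#' pathway orientation, so the defining knockout scores exactly
#' orientation x 1. The Spearman correlation of the 50 fold changes with
#' the reference, and its Fisher-Z p-value, accompany the score.
#'
#' @param ko `contrast_table` of the knockout being scored.
#' @param footprint A `footprint`.
#' @param reference `contrast_table` of the defining knockout (the one the
#'   footprint was derived from).
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @return Data frame row: `pathway`, `activity`, `directed_avg`,
#'   `spearman_r`, `p_fisher_z`.
#' @export
pathway_activity <- function(ko, footprint, reference,
                             cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  g <- footprint$genes
  miss <- setdiff(g, intersect(ko$gene, reference$gene))
  if (length(miss))
    stop("footprint gene(s) missing from contrast: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lfc_ko <- ko$log2fc[match(g, ko$gene)]
  lfc_ref <- reference$log2fc[match(g, reference$gene)]
  if (any(lfc_ref == 0))
    stop("reference log2FC of 0 in footprint gene(s): ",
         paste(g[lfc_ref == 0], collapse = ", "), call. = FALSE)
  s <- ifelse(sign(lfc_ko) == sign(lfc_ref) | lfc_ko == 0, 1, -1)
  num <- sum(abs(lfc_ko) * s)
  den <- sum(abs(lfc_ref))
  if (den <= 0) stop("reference denominator is not positive", call. = FALSE)
  directed_avg <- num / den
  r <- stats::cor(lfc_ko, lfc_ref, method = cor_method)
  n <- length(g)
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 3)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(pathway = footprint$pathway,
             activity = directed_avg * footprint$orientation,
             directed_avg = directed_avg,
             spearman_r = r, p_fisher_z = p,
             stringsAsFactors = FALSE)
}

#' Score pathway activities across the whole panel
#'
#' @param kos Named list of knockout `contrast_table`s.
#' @param footprints Named list of `footprint`s.
#' @param references Named list (by pathway) of defining `contrast_table`s.
#' @param cor_method Correlation statistic; see [pathway_activity()].
#' @return List with `table` (long data frame incl. Bonferroni-adjusted
#'   p over all KO x pathway tests), `activity` and `correlation`
#'   (KO x pathway matrices).
#' @export
activity_panel <- function(kos, footprints, references,
                           cor_method = "spearman") {
  rows <- list()
  for (ko in names(kos)) for (pw in names(footprints)) {
    r <- pathway_activity(kos[[ko]], footprints[[pw]], references[[pw]],
                          cor_method)
    r$ko <- ko
    rows[[length(rows) + 1L]] <- r
  }
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- pmin(tab$p_fisher_z * nrow(tab), 1)
  act <- stats::xtabs(activity ~ ko + pathway, tab)
  cr <- stats::xtabs(spearman_r ~ ko + pathway, tab)
  list(table = tab[, c("ko", "pathway", "activity", "directed_avg",
                       "spearman_r", "p_fisher_z", "p_bonferroni")],
       activity = unclass(act)[, names(footprints), drop = FALSE],
       correlation = unclass(cr)[, names(footprints), drop = FALSE])
}

#' Regress the differentiation phenotype on pathway correlations
#'
#' Multiple linear regression of the per-knockout naive-marker phenotype
#' score on the five pathway footprint correlation profiles, quantifying
#' each pathway's contribution to naive-marker deregulation.
#'
#' @param correlations KO x pathway numeric matrix (e.g.
#'   `activity_panel()$correlation`).
#' @param phenotypes Data frame `ko`, `score` (from [fit_panel()]).
#' @param min_kos Minimum number of knockouts.
#' @return Data frame `term`, `estimate`, `se`, `t`, `p`.
#' @export
phenotype_regression <- function(correlations, phenotypes, min_kos = 10L) {
  ix <- match(rownames(correlations), phenotypes$ko)
  if (anyNA(ix))
    stop("phenotype score missing for: ",
         paste(rownames(correlations)[is.na(ix)], collapse = ", "),
         call. = FALSE)
  y <- phenotypes$score[ix]
  if (length(y) < min_kos)
    stop("need >= ", min_kos, " knockouts", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, correlations)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: pathway correlation columns are
 linearly dependent", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  se <- sqrt(diag(chol2inv(qr.R(qr(X)))) * s2)
  tstat <- fit$coefficients / se
  data.frame(term = colnames(X), estimate = unname(fit$coefficients),
             se = unname(se), t = unname(tstat),
             p = unname(2 * stats::pt(-abs(tstat), df)),
             stringsAsFactors = FALSE)
}
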