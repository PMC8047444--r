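#' @name response-modules
#' @title Knockout-response classification, clustering and enrichment
#' @description
#' Genes responding to the knockouts are split into a constitutive group
#' (significantly changed in the same direction in both 2i and N24 in at
#' least one knockout) and an N24-induced group (significant at N24 and in
#' the knockout-condition interaction in at least one knockout; this group
#' takes precedence). Each group is clustered into modules by Ward-linkage
#' hierarchical clustering of the KO-vs-control N24 fold changes, and
#' modules are tested for gene-set enrichment with one-sided Fisher exact
#' tests under a redundancy-reduction rule that merges near-identical terms
#' and keeps the smallest as primary.
NULL

#' Classify constitutive vs N24-induced knockout-response genes
#'
#' @param contrasts_2i,contrasts_n24,contrasts_interaction Named lists of
#'   `contrast_table`s per knockout (aligned gene universes).
#' @param config A [study_config()]; `fdr_de` is the significance cutoff.
#' @param excluded_kos Knockouts removed before classification (global
#'   chromatin/kinase regulators whose responses swamp the panel).
#' @return List with `constitutive` and `induced` gene vectors (disjoint;
#'   induced takes precedence) and `excluded_kos`.
#' @export
classify_response <- function(contrasts_2i, contrasts_n24,
                              contrasts_interaction,
                              config = study_config(),
                              excluded_kos = c("Eed", "Suz12", "Csnk1a1")) {
  kos <- intersect(intersect(names(contrasts_2i), names(contrasts_n24)),
                   names(contrasts_interaction))
  if (!length(kos))
    stop("no shared knockouts across the three contrast families",
         call. = FALSE)
  kos <- setdiff(kos, excluded_kos)
  genes <- contrasts_n24[[kos[1L]]]$gene
  induced <- rep(FALSE, length(genes))
  constit <- rep(FALSE, length(genes))
  alpha <- config$fdr_de
  for (ko in kos) {
    c2 <- contrasts_2i[[ko]];  cn <- contrasts_n24[[ko]]
    ci <- contrasts_interaction[[ko]]
    i2 <- match(genes, c2$gene); iN <- match(genes, cn$gene)
    ii <- match(genes, ci$gene)
    sig2 <- !is.na(i2) & c2$fdr[i2] <= alpha
    sigN <- !is.na(iN) & cn$fdr[iN] <= alpha
    sigI <- !is.na(ii) & ci$fdr[ii] <= alpha
    same_dir <- sign(c2$log2fc[i2]) == sign(cn$log2fc[iN])
    induced <- induced | (sigN & sigI)
    constit <- constit | (sig2 & sigN & same_dir)
  }
  constit <- constit & !induced
  list(constitutive = genes[constit], induced = genes[induced],
       excluded_kos = excluded_kos)
}

# total within-cluster sum of squares for a hierarchical cut at k
wss_at_k <- function(m, memb) {
  sum(vapply(split(seq_len(nrow(m)), memb), function(ix) {
    sub <- m[ix, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1L)))
}

#' Cluster response genes into modules
#'
#' Ward-linkage (`"ward.D2"`) hierarchical clustering on Euclidean
#' distances of the gene x KO log2 fold-change rows. The number of clusters
#' is either fixed or chosen at the elbow (maximum second difference) of
#' the total within-cluster-variance curve over k = 2..25.
#'
#' @param lfc Gene x KO numeric matrix (KO-vs-control N24 fold changes),
#'   restricted to one response group.
#' @param k Number of clusters, or `NA` for the automatic elbow choice.
#' @param k_max Largest k scanned by the elbow rule.
#' @return A `cluster_set` list: `clusters` (named list of gene vectors),
#'   `membership`, `mean_lfc` (cluster x KO), `k`, `k_elbow`.
#' @export
cluster_modules <- function(lfc, k = 12L, k_max = 25L) {
  if (nrow(lfc) < 4L) stop("too few genes to cluster", call. = FALSE)
  if (all(abs(lfc - mean(lfc)) < 1e-12))
    stop("constant fold-change matrix cannot be clustered", call. = FALSE)
  hc <- stats::hclust(stats::dist(lfc), method = "ward.D2")
  ks <- 2:min(k_max, nrow(lfc) - 1L)
  wss <- vapply(ks, function(kk) wss_at_k(lfc, stats::cutree(hc, kk)),
                numeric(1L))
  k_elbow <- if (length(wss) >= 3L) {
    d2 <- diff(diff(wss))
    ks[which.max(d2) + 1L]
  } else ks[1L]
  if (is.na(k)) k <- k_elbow
  k <- min(k, nrow(lfc) - 1L)
  memb <- stats::cutree(hc, k)
  clusters <- split(rownames(lfc), memb)
  names(clusters) <- paste0("M", names(clusters))
  mean_lfc <- t(vapply(clusters, function(g)
    colMeans(lfc[g, , drop = FALSE]), numeric(ncol(lfc))))
  structure(list(clusters = clusters, membership = memb,
                 mean_lfc = mean_lfc, k = k, k_elbow = k_elbow,
                 hclust = hc),
            class = "cluster_set")
}

#' Correlate module expression with the differentiation phenotype
#'
#' Pearson correlation, per module, between the module's mean log2 fold
#' change across knockouts and the naive-marker phenotype score.
#'
#' @param clusters A `cluster_set`.
#' @param phenotypes Data frame `ko`, `score`.
#' @param min_kos Minimum knockouts.
#' @return Data frame `cluster`, `r`, `abs_r`.
#' @export
cluster_phenotype_correlation <- function(clusters, phenotypes,
                                          min_kos = 10L) {
  m <- clusters$mean_lfc
  ix <- match(colnames(m), phenotypes$ko)
  if (anyNA(ix))
    stop("phenotype missing for: ",
         paste(colnames(m)[is.na(ix)], collapse = ", "), call. = FALSE)
  if (ncol(m) < min_kos) stop("need >= ", min_kos, " knockouts",
                              call. = FALSE)
  y <- phenotypes$score[ix]
  r <- apply(m, 1L, function(v) {
    if (stats::sd(v) == 0)
      stop("zero-variance cluster means", call. = FALSE)
    stats::cor(v, y)
  })
  data.frame(cluster = rownames(m), r = unname(r), abs_r = unname(abs(r)),
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment with redundancy reduction
#'
#' One-sided Fisher exact (hypergeometric) test of a target gene list
#' against annotation sets restricted to the universe and to 5-500 members
#' within it. Sets whose target-gene memberships differ by five or fewer
#' genes are merged by complete-linkage clustering on the L1 distance of
#' the binary membership matrix; within each merge group the set with the
#' fewest total annotations is the primary term, and Benjamini-Hochberg
#' adjustment runs over primary terms only.
#'
#' @param target Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Background gene vector.
#' @param annotation A `gene_set_collection` (or named list of character
#'   vectors).
#' @param config A [study_config()].
#' @param min_set,max_set Annotation-size window within the universe.
#' @param min_target_genes Minimum target genes a set must contain to be
#'   tested (the module-enrichment mode uses 5).
#' @param merge_distance Maximum difference in genes of interest for two
#'   sets to be merged.
#' @return Data frame: `set`, `n_set`, `n_overlap`, `p`, `merge_group`,
#'   `primary`, `p_adj` (NA for non-primary terms).
#' @export
set_enrichment <- function(target, universe, annotation,
                           config = study_config(),
                           min_set = 5L, max_set = 500L,
                           min_target_genes = 1L,
                           merge_distance = 5L) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  out <- setdiff(target, universe)
  if (length(out))
    stop("target gene(s) outside universe: ",
         paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
  sets <- lapply(annotation, function(s) {
    g <- if (is.list(s)) s$genes else s
    intersect(g, universe)
  })
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_set & sizes <= max_set]
  if (!length(sets))
    stop("no annotation set within the size window", call. = FALSE)
  N <- length(universe); n_t <- length(target)
  rows <- lapply(names(sets), function(nm) {
    g <- sets[[nm]]
    ov <- length(intersect(g, target))
    data.frame(set = nm, n_set = length(g), n_overlap = ov,
               p = stats::phyper(ov - 1L, length(g), N - length(g), n_t,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$n_overlap >= min_target_genes, , drop = FALSE]
  if (!nrow(tab)) return(tab)
  # redundancy reduction on genes-of-interest membership only
  memb <- vapply(tab$set, function(nm) target %in% sets[[nm]],
                 logical(length(target)))
  memb <- matrix(memb, nrow = length(target))
  if (nrow(tab) > 1L) {
    d <- stats::dist(t(memb), method = "manhattan")
    hc <- stats::hclust(d, method = "complete")
    grp <- stats::cutree(hc, h = merge_distance)
  } else grp <- 1L
  tab$merge_group <- grp
  tab$primary <- FALSE
  for (g in unique(grp)) {
    ix <- which(grp == g)
    best <- ix[order(tab$n_set[ix], tab$set[ix])][1L]  # smallest term wins
    tab$primary[best] <- TRUE
  }
  tab$p_adj <- NA_real_
  tab$p_adj[tab$primary] <- stats::p.adjust(tab$p[tab$primary],
                                            method = "BH")
  rownames(tab) <- NULL
  tab
}
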