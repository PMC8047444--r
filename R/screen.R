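#' @name screen-enrichment
#' @title Insertional-mutagenesis screen enrichment statistics
#' @description
#' A haploid gene-trap screen yields integration sites at TTAA
#' tetranucleotides. Whether a gene carries more independent integrations
#' than chance expects is judged against a binomial model: a gene with n
#' TTAA sites, each hit with background probability p0, accumulates k
#' distinct hit sites with upper-tail probability P(X >= k). The background
#' p0 is the fraction of all genic TTAA sites hit in at least one screen.
#' Candidates come from two streams: a binomial stream (genes with at least
#' 26 TTAA sites, adjusted p below alpha, hit in at least two independent
#' screens) and a count stream (genes hit in five or more independent
#' screens).
NULL

#' Estimate the background integration rate p0
#'
#' The ratio of distinct genic TTAA sites hit in at least one screen to the
#' total number of TTAA sites in genes.
#'
#' @param insertions BED-like insertion data frame (columns `chrom`,
#'   `start`, `end`, `gene`, `screen_id`).
#' @param ttaa Named vector of per-gene TTAA counts.
#' @return The estimated rate in `[0, 1]`; 0 when there are no insertions.
#' @export
estimate_p0 <- function(insertions, ttaa) {
  total <- sum(as.numeric(ttaa))
  if (total == 0) stop("total TTAA count is zero", call. = FALSE)
  if (nrow(insertions) == 0) return(0)
  hit_sites <- unique(insertions[, c("gene", "chrom", "start")])
  nrow(hit_sites) / total
}

#' Binomial upper-tail probability of k or more integrations
#'
#' Exact survival probability P(X >= k) for X ~ Binomial(n, p0), evaluated
#' through the stable survival function so that rates as small as 1e-6 and
#' n up to 1e4 do not underflow.
#'
#' @param k Observed number of distinct integration sites (vectorised).
#' @param n Number of TTAA sites in the gene.
#' @param p0 Background per-site hit probability.
#' @return P(X >= k); 1 when k = 0.
#' @export
binomial_tail <- function(k, n, p0) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Rank screen candidate genes
#'
#' Computes per-gene distinct hit sites (pooled over screens), number of
#' screens hit, the binomial enrichment p-value against the background rate,
#' and the two candidate streams. The binomial stream requires at least
#' `min_ttaa` TTAA sites (genes below it would reach significance with a
#' single integration), adjusted p below `screen_alpha` and hits in at least
#' `min_screens_binomial` screens; the count stream requires hits in at
#' least `min_screens_count` screens. The candidate flag is the union, with
#' both memberships reported separately.
#'
#' @param insertions,ttaa As for [estimate_p0()].
#' @param config A [study_config()].
#' @param p0 Background rate; estimated from the data when `NULL`.
#' @param include_zero_hits Include genes without insertions in the
#'   multiple-testing adjustment (they carry p = 1).
#' @return A data frame (one row per gene) with columns `gene`,
#'   `k_distinct_sites`, `n_screens_hit`, `n_ttaa`, `p`, `p_adj`,
#'   `binomial_stream`, `count_stream`, `candidate`.
#' @export
rank_candidates <- function(insertions, ttaa, config = study_config(),
                            p0 = NULL, include_zero_hits = FALSE) {
  if (is.null(p0)) p0 <- estimate_p0(insertions, ttaa)
  if (p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly within (0, 1); got ", p0, call. = FALSE)
  genes <- names(ttaa)
  k <- integer(length(genes)); names(k) <- genes
  ns <- integer(length(genes)); names(ns) <- genes
  if (nrow(insertions)) {
    sites <- unique(insertions[, c("gene", "chrom", "start")])
    tk <- table(sites$gene)
    k[names(tk)] <- as.integer(tk)
    scr <- unique(insertions[, c("gene", "screen_id")])
    ts <- table(scr$gene)
    ns[names(ts)] <- as.integer(ts)
  }
  bad <- k > ttaa
  if (any(bad))
    stop("more distinct hit sites than TTAA sites for: ",
         paste(genes[bad], collapse = ", "), call. = FALSE)
  p <- binomial_tail(k, as.integer(ttaa), p0)
  tested <- (ttaa >= config$min_ttaa) & (include_zero_hits | k > 0)
  p_adj <- rep(NA_real_, length(genes))
  if (any(tested))
    p_adj[tested] <- stats::p.adjust(p[tested],
                                     method = config$screen_adjust)
  binomial_stream <- tested & !is.na(p_adj) &
    p_adj < config$screen_alpha & ns >= config$min_screens_binomial
  count_stream <- ns >= config$min_screens_count
  res <- data.frame(gene = genes,
                    k_distinct_sites = k,
                    n_screens_hit = ns,
                    n_ttaa = as.integer(ttaa),
                    p = p, p_adj = p_adj,
                    binomial_stream = binomial_stream,
                    count_stream = count_stream,
                    candidate = binomial_stream | count_stream,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "p0") <- p0
  res
}
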