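#' @name pathway-cluster-model
#' @title Predicting module expression from pathway activities
#' @description
#' Cluster mean fold changes across the knockout panel are regressed on the
#' five pathway activities; links not passing the adjusted significance
#' cutoff are pruned. Surviving links are then validated against the
#' wild-type time course: the model's predicted cluster trajectory must
#' follow the observed trajectory (trend test) and pathway activity must
#' lead or be simultaneous with cluster expression (precedence test via the
#' lag maximising the cross-correlation). Validation only removes links.
NULL

#' Pathway activity along the time course
#'
#' For each footprint gene, the log2 fold change relative to that gene's
#' mean over the time course, multiplied by the sign of its defining
#' contrast fold change (so movement towards the defining perturbation
#' counts positive), averaged over the footprint and multiplied by the
#' pathway orientation. The resulting series is mean-zero by construction.
#'
#' @param traj A `smoothed_trajectory` containing the footprint genes.
#' @param footprint A `footprint`.
#' @param oriented Apply the per-gene defining-contrast sign (default);
#'   `FALSE` averages raw fold changes, which cancels bidirectional
#'   footprints.
#' @return List with `pathway`, `times_h`, `activity` (numeric,
#'   mean-zero).
#' @export
timecourse_activity <- function(traj, footprint, oriented = TRUE) {
  g <- footprint$genes
  miss <- setdiff(g, traj$genes)
  if (length(miss))
    stop("footprint gene(s) missing from trajectory: ",
         paste(miss, collapse = ", "), call. = FALSE)
  M <- traj$lfc[g, , drop = FALSE]
  M <- M - rowMeans(M)
  if (oriented) M <- M * sign(footprint$ref_lfc[g])
  act <- colMeans(M) * footprint$orientation
  list(pathway = footprint$pathway, times_h = traj$times_h,
       activity = unname(act))
}

#' Regress cluster expression changes on pathway activities
#'
#' One ordinary-least-squares model per cluster, with intercept.
#' Coefficient p-values are Benjamini-Hochberg adjusted jointly across all
#' cluster x pathway coefficients and links above the cutoff are marked
#' non-significant.
#'
#' @param activities KO x pathway numeric matrix.
#' @param cluster_lfc Cluster x KO matrix of mean log2 fold changes (a
#'   single cluster may be given as a named vector).
#' @param config A [study_config()]; `pathway_model_alpha` is the cutoff.
#' @param min_kos Minimum knockouts.
#' @return Data frame (edge list): `cluster`, `pathway`, `beta`, `se`,
#'   `p`, `p_adj`, `significant`.
#' @export
fit_pathway_cluster_regression <- function(activities, cluster_lfc,
                                           config = study_config(),
                                           min_kos = 10L) {
  if (is.null(dim(cluster_lfc)))
    cluster_lfc <- matrix(cluster_lfc, nrow = 1L,
                          dimnames = list("C1", names(cluster_lfc)))
  if (nrow(activities) < min_kos)
    stop("need >= ", min_kos, " knockouts", call. = FALSE)
  kos <- rownames(activities)
  if (!identical(sort(kos), sort(colnames(cluster_lfc))))
    stop("knockouts of activities and cluster matrix differ", call. = FALSE)
  cluster_lfc <- cluster_lfc[, kos, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, activities)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design: pathway activity columns are linearly
 dependent", call. = FALSE)
  df <- nrow(X) - ncol(X)
  xtxi <- chol2inv(qr.R(qx))
  rows <- list()
  for (cl in rownames(cluster_lfc)) {
    y <- cluster_lfc[cl, ]
    beta <- qr.coef(qx, y)
    res <- y - as.numeric(X %*% beta)
    s2 <- sum(res^2) / df
    se <- sqrt(diag(xtxi) * s2)
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df)
    pw <- colnames(activities)
    rows[[cl]] <- data.frame(cluster = cl, pathway = pw,
                             beta = unname(beta[pw]), se = unname(se[pw]),
                             p = unname(p[pw]), stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  edges$p_adj <- stats::p.adjust(edges$p, method = "BH")
  edges$significant <- edges$p_adj <= config$pathway_model_alpha
  rownames(edges) <- NULL
  edges
}

# correlation of predicted vs observed with the observed series shifted by
# 'lag' hours (linear interpolation, clamped at the ends)
lagged_cor <- function(pred, obs, times, lag) {
  obs_l <- stats::approx(times, obs, xout = times + lag, rule = 2)$y
  if (stats::sd(obs_l) < 1e-12 || stats::sd(pred) < 1e-12) return(NA_real_)
  stats::cor(pred, obs_l)
}

#' Validate wiring links against the time course
#'
#' For every cluster with at least one significant link, the predicted
#' trajectory (significant betas applied to the pathway activity
#' trajectories) is compared with the observed cluster trajectory. The
#' trend test requires Pearson r at or above `config$trend_r_min`; the
#' precedence test requires the lag maximising the cross-correlation to be
#' non-negative (pathway leads or is simultaneous). Clusters failing either
#' test have all their links rejected with a reason.
#'
#' @param edges Edge list from [fit_pathway_cluster_regression()].
#' @param activity_traj Pathway x time matrix of activity trajectories
#'   (e.g. stacked [timecourse_activity()] outputs).
#' @param cluster_traj Cluster x time matrix of observed mean fold changes
#'   (relative to each cluster's time-course mean).
#' @param times_h Shared time grid.
#' @param config A [study_config()]; `trend_r_min`, `lag_max_h`,
#'   `lag_step_h` parameterise the two tests.
#' @return The edge list with `accepted` and `reason` (`"nonsignificant"`,
#'   `"trend_mismatch"`, `"no_precedence"` or `NA`) plus a
#'   `cluster_validation` attribute (per-cluster trend r and best lag).
#' @export
validate_precedence <- function(edges, activity_traj, cluster_traj,
                                times_h, config = study_config()) {
  if (ncol(activity_traj) != length(times_h) ||
      ncol(cluster_traj) != length(times_h))
    stop("time grids of trajectories and times_h differ", call. = FALSE)
  edges$accepted <- FALSE
  edges$reason <- ifelse(edges$significant, NA_character_,
                         "nonsignificant")
  lags <- seq(-config$lag_max_h, config$lag_max_h, by = config$lag_step_h)
  val <- list()
  for (cl in unique(edges$cluster)) {
    sub <- edges$cluster == cl & edges$significant
    if (!any(sub)) next
    if (!cl %in% rownames(cluster_traj))
      stop("no observed trajectory for cluster ", cl, call. = FALSE)
    pws <- edges$pathway[sub]
    pred <- colSums(activity_traj[pws, , drop = FALSE] *
                      edges$beta[sub])
    obs <- cluster_traj[cl, ]
    r <- stats::cor(pred, obs)
    cc <- vapply(lags, function(l) lagged_cor(pred, obs, times_h, l),
                 numeric(1L))
    best_lag <- if (all(is.na(cc))) NA_real_ else lags[which.max(cc)]
    val[[cl]] <- data.frame(cluster = cl, trend_r = r,
                            best_lag_h = best_lag,
                            stringsAsFactors = FALSE)
    if (!is.finite(r) || r < config$trend_r_min) {
      edges$reason[sub] <- "trend_mismatch"
    } else if (is.na(best_lag) || best_lag < 0) {
      edges$reason[sub] <- "no_precedence"
    } else {
      edges$accepted[sub] <- TRUE
    }
  }
  attr(edges, "cluster_validation") <- do.call(rbind, val)
  edges
}
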