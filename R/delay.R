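#' @name delay-timing
#' @title Differentiation delay quantification
#' @description
#' Each knockout's molecular differentiation state is read off the
#' wild-type 2i-to-N32 trajectory: per-gene log2 fold changes relative to
#' the mean 2i expression are smoothed over time (Gaussian process
#' regression, squared-exponential kernel), and a knockout's N24-vs-2i
#' fold-change profile is matched to the time point minimising the
#' Euclidean distance to the trajectory. Linear interpolation at 15-minute
#' steps between the two neighbouring time points refines the match; the
#' delay is 24 h minus the matched time, so positive values mean delayed
#' differentiation.
NULL

# negative log marginal likelihood of a zero-mean GP with SE kernel
gp_nll <- function(theta, d2, y) {
  l <- exp(theta[1L]); sf2 <- exp(2 * theta[2L]); sn2 <- exp(2 * theta[3L])
  K <- sf2 * exp(-0.5 * d2 / l^2)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

# SE-kernel GP posterior mean at the training grid, hyperparameters by
# marginal-likelihood maximisation from fixed deterministic restarts.
# noise_bound caps the GP noise sd at what the replicates actually show:
# without it a stationary kernel happily calls a sharp switch "noise".
gp_smooth_vec <- function(times, y, lengthscale_bounds = c(1, 32),
                          noise_bound = NULL) {
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-10) return(rep(mean(y), length(y)))
  d2 <- outer(times, times, "-")^2
  sn_ub <- if (is.null(noise_bound)) sdy * 2
           else max(noise_bound, sdy * 1e-3)
  lb <- log(c(lengthscale_bounds[1L], sdy * 1e-3,
              min(sdy * 1e-4, sn_ub / 10)))
  ub <- log(c(lengthscale_bounds[2L], sdy * 10, sn_ub))
  best <- NULL
  sn0 <- min(0.1 * sdy + 1e-4, sn_ub)
  starts <- list(c(4, sdy, sn0), c(8, sdy, sn0),
                 c(2, sdy, min(sdy * 2e-4, sn_ub)))
  for (st in starts) {
    o <- tryCatch(
      stats::optim(pmin(pmax(log(st), lb), ub), gp_nll, d2 = d2, y = y,
                   method = "L-BFGS-B", lower = lb, upper = ub),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(y)  # fall back to raw means
  th <- best$par
  l <- exp(th[1L]); sf2 <- exp(2 * th[2L]); sn2 <- exp(2 * th[3L])
  K <- sf2 * exp(-0.5 * d2 / l^2)
  Ky <- K; diag(Ky) <- diag(Ky) + sn2 + 1e-8
  as.numeric(K %*% solve(Ky, y))
}

#' Smooth the wild-type differentiation trajectory
#'
#' Computes per-gene log2 fold changes of the time-course samples relative
#' to the mean 2i (t = 0) expression, averages replicates per time point,
#' and smooths each gene's series over time. The smoothed fold change at
#' t = 0 is pinned to zero.
#'
#' @param em Time-course [expression_matrix()] (condition `"timecourse"`,
#'   `time_h` set; log2 scale).
#' @param genes Optional subset of genes.
#' @param method `"gp"` (squared-exponential Gaussian process, default) or
#'   `"spline"` ([stats::smooth.spline()], deterministic alternative).
#' @return A `smoothed_trajectory` list with `genes`, `times_h` and `lfc`
#'   (gene x time matrix, first column exactly 0).
#' @export
smooth_trajectory <- function(em, genes = NULL,
                              method = c("gp", "spline")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit == "counts")
    stop("smooth_trajectory needs log2-scale expression", call. = FALSE)
  tc <- em$meta$condition == "timecourse"
  if (!any(tc)) stop("no timecourse samples in matrix", call. = FALSE)
  meta <- em$meta[tc, ]
  vals <- em$values[, tc, drop = FALSE]
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(vals))
    if (length(miss))
      stop("gene(s) absent from time course: ",
           paste(miss, collapse = ", "), call. = FALSE)
    vals <- vals[genes, , drop = FALSE]
  }
  times <- sort(unique(meta$time_h))
  if (length(times) < 8L)
    stop("need at least 8 time points, got ", length(times), call. = FALSE)
  if (!0 %in% times) stop("time course must include t = 0 (2i)",
                          call. = FALSE)
  base <- rowMeans(vals[, meta$time_h == 0, drop = FALSE])
  lfc_raw <- vals - base
  n_rep <- table(meta$time_h)
  if (any(n_rep == 1L))
    nx_log("smooth_trajectory", "single replicate at t=",
           paste(names(n_rep)[n_rep == 1L], collapse = ","))
  lfc_mean <- vapply(times, function(t)
    rowMeans(lfc_raw[, meta$time_h == t, drop = FALSE]),
    numeric(nrow(vals)))
  lfc_mean <- matrix(lfc_mean, nrow = nrow(vals),
                     dimnames = list(rownames(vals), paste0("t", times)))
  # per-gene replicate noise of the time-point means, pooled across times;
  # this caps the GP noise term at what the data actually show
  tp <- factor(meta$time_h)
  resid <- lfc_raw - t(apply(lfc_raw, 1L, function(v) ave(v, tp)))
  df_noise <- ncol(lfc_raw) - nlevels(tp)
  pooled_sd <- if (df_noise > 0)
    sqrt(rowSums(resid^2) / df_noise) else rep(NA_real_, nrow(vals))
  mean_rep <- ncol(lfc_raw) / nlevels(tp)
  sm <- t(vapply(seq_len(nrow(lfc_mean)), function(i) {
    y <- lfc_mean[i, ]
    if (method == "gp") {
      nb <- if (df_noise > 0) 2 * pooled_sd[i] / sqrt(mean_rep) else NULL
      gp_smooth_vec(times, y, noise_bound = nb)
    } else stats::predict(stats::smooth.spline(times, y), times)$y
  }, numeric(ncol(lfc_mean))))
  sm <- sm - sm[, 1L]   # pin lfc at t = 0 to zero
  dimnames(sm) <- dimnames(lfc_mean)
  structure(list(genes = rownames(sm), times_h = times, lfc = sm),
            class = "smoothed_trajectory")
}

# linearly interpolate trajectory columns at arbitrary times
traj_interp <- function(traj, times_new, genes = NULL) {
  lfc <- traj$lfc
  if (!is.null(genes)) lfc <- lfc[genes, , drop = FALSE]
  out <- vapply(times_new, function(tn) {
    apply(lfc, 1L, function(y)
      stats::approx(traj$times_h, y, xout = tn, rule = 2)$y)
  }, numeric(nrow(lfc)))
  matrix(out, nrow = nrow(lfc),
         dimnames = list(rownames(lfc), paste0("t", times_new)))
}

#' Map a knockout profile onto the differentiation trajectory
#'
#' Finds the trajectory time whose log2 fold-change profile is closest
#' (Euclidean distance over the reference genes) to the knockout's
#' N24-vs-2i profile. Distances are min-max normalised per knockout; after
#' the coarse minimum (ties broken towards the earliest time), profiles are
#' linearly interpolated every 15 minutes between its two neighbouring time
#' points and the refined minimum is reported.
#'
#' @param ko_lfc Named numeric vector: the knockout's per-gene log2 fold
#'   change, N24 vs its own 2i.
#' @param traj A `smoothed_trajectory`.
#' @param reference_genes Genes over which the distance is computed
#'   (>= 5, present in both).
#' @param target_h Nominal sampling time of the knockout profile (hours);
#'   the delay is `target_h - t_matched`.
#' @return A `delay_estimate` list: `t_matched_h`, `delay_h`,
#'   `t_coarse_h`, `distance_profile` (normalised, over the coarse grid).
#' @export
map_to_trajectory <- function(ko_lfc, traj, reference_genes,
                              target_h = 24) {
  ref <- intersect(reference_genes, intersect(names(ko_lfc), traj$genes))
  if (length(ref) < 5L)
    stop("need >= 5 shared reference genes, got ", length(ref),
         call. = FALSE)
  v <- ko_lfc[ref]
  M <- traj$lfc[ref, , drop = FALSE]
  d <- sqrt(colSums((M - v)^2))
  if (max(d) - min(d) < 1e-12)
    stop("degenerate profile: distance is constant over time",
         call. = FALSE)
  dn <- (d - min(d)) / (max(d) - min(d))
  i <- which.min(d)          # which.min takes the earliest tie
  times <- traj$times_h
  lo <- times[max(1L, i - 1L)]
  hi <- times[min(length(times), i + 1L)]
  fine <- seq(lo, hi, by = 0.25)
  Mf <- traj_interp(traj, fine, genes = ref)
  df <- sqrt(colSums((Mf - v)^2))
  j <- which.min(df)
  structure(list(t_matched_h = fine[j], delay_h = target_h - fine[j],
                 t_coarse_h = times[i],
                 distance_profile = stats::setNames(dn, paste0("t", times)),
                 n_reference_genes = length(ref)),
            class = "delay_estimate")
}

#' Per-knockout N24-vs-2i fold changes
#'
#' Fits, for every knockout genotype, the contrast of its own N24 versus
#' its own 2i samples and returns the gene x KO log2 fold-change matrix the
#' delay mapper consumes.
#'
#' @param em Panel [expression_matrix()].
#' @param config A [study_config()].
#' @param genotypes Genotypes to include (default: all except `"WT"`).
#' @return Gene x KO numeric matrix.
#' @export
ko_self_lfc <- function(em, config = study_config(), genotypes = NULL) {
  if (is.null(genotypes))
    genotypes <- setdiff(unique(em$meta$genotype), "WT")
  cts <- lapply(genotypes, function(g)
    fit_contrast(em, contrast_spec(
      list(genotype = g, condition = "N24"),
      list(genotype = g, condition = "2i"),
      covariates = character(0)), config))
  names(cts) <- genotypes
  lfc_matrix(cts)
}

#' Differentiation delays for a knockout panel
#'
#' Maps every knockout onto the trajectory with each supplied reference
#' gene set (typically the 7 naive markers and the full differentiation DEG
#' set) and reports the correlation between the resulting delay series.
#'
#' @param ko_lfc Gene x KO matrix of N24-vs-2i log2 fold changes (e.g. from
#'   [ko_self_lfc()]).
#' @param traj A `smoothed_trajectory`.
#' @param reference_sets Named list of reference gene vectors.
#' @return List with `delays` (data frame: `ko`, `reference_set`,
#'   `t_matched_h`, `delay_h`) and `set_correlations` (matrix of Pearson r
#'   between reference sets, when more than one).
#' @export
delay_panel <- function(ko_lfc, traj, reference_sets) {
  stopifnot(length(reference_sets) >= 1L, !is.null(names(reference_sets)))
  rows <- list()
  for (rs in names(reference_sets)) {
    for (ko in colnames(ko_lfc)) {
      est <- map_to_trajectory(ko_lfc[, ko], traj, reference_sets[[rs]])
      rows[[length(rows) + 1L]] <-
        data.frame(ko = ko, reference_set = rs,
                   t_matched_h = est$t_matched_h, delay_h = est$delay_h,
                   stringsAsFactors = FALSE)
    }
  }
  delays <- do.call(rbind, rows)
  cors <- NULL
  if (length(reference_sets) > 1L) {
    wide <- vapply(names(reference_sets), function(rs)
      delays$delay_h[delays$reference_set == rs], numeric(ncol(ko_lfc)))
    cors <- stats::cor(wide)
  }
  list(delays = delays, set_correlations = cors)
}
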