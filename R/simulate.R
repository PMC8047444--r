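#' @name synthetic-data
#' @title Synthetic data with planted ground truth
#' @description
#' Generators for every input the pipeline consumes: a wild-type 2i to N32
#' differentiation time course sampled every 2 h, a knockout panel whose N24
#' profiles are noisy snapshots of the wild-type trajectory at KO-specific
#' delay times plus pathway-specific perturbations, a block of
#' naive-associated genes linearly coupled to the seven core markers, and
#' transposon insertion screens with per-gene TTAA site counts and planted
#' enriched genes. Each generator records its ground truth so downstream
#' stages can be scored against what was planted.
NULL

# 4-parameter logistic mean trajectories: base + delta * plogis(slope*(t-t0)).
# delta < 0 for naive (decreasing) genes, > 0 for formative, 0 for bystanders.
logistic_means <- function(genes_df, times_h) {
  m <- vapply(times_h, function(t) {
    genes_df$base + genes_df$delta *
      stats::plogis(genes_df$slope * (t - genes_df$t0))
  }, numeric(nrow(genes_df)))
  m <- matrix(m, nrow = nrow(genes_df),
              dimnames = list(genes_df$gene, paste0("t", times_h)))
  m
}

#' Simulate a wild-type differentiation time course
#'
#' Per-gene trajectories follow a four-parameter logistic in time: naive
#' genes decrease, formative genes increase, bystanders stay flat. The first
#' seven genes are the named core naive markers (decreasing). Log2-scale
#' Gaussian noise is added per replicate.
#'
#' @param n_genes Total number of genes (>= 7).
#' @param times_h Sampling times in hours; must include 0 and at least 3
#'   points overall.
#' @param n_rep Replicates per time point.
#' @param noise_sd Log2-scale Gaussian noise standard deviation.
#' @param frac_naive,frac_formative Fractions of non-marker genes assigned
#'   to the decreasing and increasing classes; the remainder are flat.
#' @param seed Integer seed; fixing it fixes every output bit-exactly.
#' @return A list with `expr` (an [expression_matrix()] of log2 values) and
#'   `truth` (gene class and curve parameters).
#' @export
simulate_timecourse <- function(n_genes = 120,
                                times_h = seq(0, 32, by = 2),
                                n_rep = 2, noise_sd = 0.2,
                                frac_naive = 0.3, frac_formative = 0.3,
                                seed = 1L) {
  if (length(times_h) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (!0 %in% times_h) stop("times_h must include 0 (2i)", call. = FALSE)
  if (n_genes < 7L) stop("need at least the 7 marker genes", call. = FALSE)
  set.seed(seed)
  nx_log("simulate_timecourse", "seed=", seed)
  markers <- c("Esrrb", "Nanog", "Tfcp2l1", "Tbx3", "Prdm14", "Klf4", "Zfp42")
  n_extra <- n_genes - 7L
  n_nai <- round(frac_naive * n_extra)
  n_for <- round(frac_formative * n_extra)
  n_bys <- n_extra - n_nai - n_for
  gene <- c(markers,
            sprintf("NAI%03d", seq_len(n_nai)),
            sprintf("FOR%03d", seq_len(n_for)),
            sprintf("BYS%03d", seq_len(n_bys)))
  class <- c(rep("naive", 7L + n_nai), rep("formative", n_for),
             rep("bystander", n_bys))
  dirn <- ifelse(class == "naive", -1, ifelse(class == "formative", 1, 0))
  genes_df <- data.frame(
    gene = gene, class = class,
    base = stats::runif(n_genes, 3, 8),
    delta = dirn * stats::runif(n_genes, 2, 4),
    t0 = stats::runif(n_genes, 8, 20),
    slope = stats::runif(n_genes, 0.3, 0.8),
    stringsAsFactors = FALSE)
  # anchor trajectories so the 2i (t = 0) value equals base
  mu <- logistic_means(genes_df, times_h)
  mu <- mu - (mu[, 1L] - genes_df$base)
  genes_df$base0 <- genes_df$base  # value at t = 0 after anchoring
  nt <- length(times_h)
  vals <- matrix(NA_real_, n_genes, nt * n_rep)
  sample_id <- character(nt * n_rep)
  time_v <- numeric(nt * n_rep)
  rep_v <- integer(nt * n_rep)
  j <- 0L
  for (ti in seq_len(nt)) {
    for (r in seq_len(n_rep)) {
      j <- j + 1L
      vals[, j] <- mu[, ti] + stats::rnorm(n_genes, 0, noise_sd)
      sample_id[j] <- sprintf("TC_t%02g_r%d", times_h[ti], r)
      time_v[j] <- times_h[ti]
      rep_v[j] <- r
    }
  }
  dimnames(vals) <- list(gene, sample_id)
  meta <- data.frame(sample = sample_id, genotype = "WT",
                     condition = "timecourse", batch = "tc1",
                     replicate = rep_v, time_h = time_v,
                     stringsAsFactors = FALSE)
  em <- expression_matrix(vals, meta, unit = "log2fpkm")
  list(expr = em,
       truth = list(genes = genes_df, times_h = times_h,
                    noise_sd = noise_sd, seed = seed))
}

# evaluate the noise-free anchored trajectory of a simulated time course
# at arbitrary times (hours); returns gene x time matrix
timecourse_means <- function(truth, times_h) {
  g <- truth$genes
  mu <- logistic_means(g, times_h)
  at0 <- logistic_means(g, 0)[, 1L]
  mu - (at0 - g$base)
}

#' Simulate a knockout differentiation panel
#'
#' Each knockout's N24 expression is the wild-type trajectory evaluated at
#' `24 - delay` hours, plus pathway-specific perturbations for planted
#' footprint genes, plus batch offsets and log2-scale noise; 2i profiles are
#' the wild-type 2i state plus small KO-specific offsets. Optional gene
#' blocks are appended: pathway footprint genes (flat in the wild type,
#' shifted by their pathway's activity in each KO) and naive-associated
#' genes whose cross-KO fold change is a linear combination of the seven
#' marker fold-change vectors, with noise scaled to a target R-squared.
#'
#' @param timecourse Output of [simulate_timecourse()] (its truth supplies
#'   the wild-type trajectory).
#' @param n_kos Number of knockouts (excluding defining KOs added for
#'   pathways not already present).
#' @param delays_h Named or unnamed vector of planted delays in hours
#'   (within `[-8, 24]`); default `runif(n_kos, 0, 16)`.
#' @param n_rep Replicates per genotype and condition.
#' @param noise_sd Log2 noise sd per sample.
#' @param batch_sd Sd of per-batch, per-gene additive offsets.
#' @param n_batches Number of batches; KOs are assigned round-robin and
#'   wild-type controls are included in every batch.
#' @param offset_2i_sd Sd of the small KO-specific 2i offsets.
#' @param nag Optional list `list(n_coupled, n_null, target_r2)` describing
#'   the appended naive-associated gene block.
#' @param pathways Optional named list; each element
#'   `list(defining_ko, n_genes, lfc_range, orientation, activity)` plants a
#'   pathway footprint. `activity` is a per-KO vector in roughly
#'   `[-0.2, 0.2]` (defaults to small random values); the defining KO always
#'   has activity 1.
#' @param seed Integer seed.
#' @return A list with `expr` (log2 [expression_matrix()]) and `truth`
#'   (delays, NAG block, pathway genes with reference fold changes, batch
#'   assignments).
#' @export
simulate_ko_panel <- function(timecourse, n_kos = 70, delays_h = NULL,
                              n_rep = 3, noise_sd = 0.2, batch_sd = 0.1,
                              n_batches = 7, offset_2i_sd = 0.05,
                              nag = NULL, pathways = NULL, seed = 1L) {
  set.seed(seed)
  nx_log("simulate_ko_panel", "seed=", seed)
  tc_truth <- timecourse$truth
  if (is.null(delays_h)) delays_h <- stats::runif(n_kos, 0, 16)
  if (any(delays_h < -8 | delays_h > 24))
    stop("planted delays must lie within [-8, 24] h", call. = FALSE)
  kos <- if (!is.null(names(delays_h)) && all(nzchar(names(delays_h))))
    names(delays_h) else sprintf("KO%03d", seq_along(delays_h))
  names(delays_h) <- kos
  # defining KOs for pathways get delay 0 unless already present
  if (!is.null(pathways)) {
    for (pw in names(pathways)) {
      dk <- pathways[[pw]]$defining_ko
      if (!dk %in% kos) {
        kos <- c(kos, dk)
        delays_h <- c(delays_h, stats::setNames(0, dk))
      }
    }
  }
  n_kos <- length(kos)
  max_t <- max(tc_truth$times_h)
  if (any(24 - delays_h < 0 | 24 - delays_h > max_t))
    stop("requested delay outside simulated time range", call. = FALSE)

  core <- tc_truth$genes
  mu_2i <- timecourse_means(tc_truth, 0)[, 1L]
  mu_n24 <- timecourse_means(tc_truth, 24)[, 1L]
  markers <- core$gene[1:7]
  # noise-free marker log2FC (KO vs WT, N24) implied by the planted delays
  snap <- timecourse_means(tc_truth, 24 - delays_h)  # gene x KO
  marker_lfc <- snap[markers, , drop = FALSE] - mu_n24[markers]

  extra_genes <- character(0)
  extra_mu_wt <- numeric(0)          # flat WT level of appended genes
  pathway_truth <- list()
  pw_shift <- NULL                   # appended-gene x KO N24 shifts
  if (!is.null(pathways)) {
    for (pw in names(pathways)) {
      p <- pathways[[pw]]
      ng <- if (is.null(p$n_genes)) 60L else p$n_genes
      rng <- if (is.null(p$lfc_range)) c(1.5, 2.5) else p$lfc_range
      g <- sprintf("%s_g%03d", pw, seq_len(ng))
      ref <- sample(c(-1, 1), ng, replace = TRUE) *
        stats::runif(ng, rng[1], rng[2])
      act <- p$activity
      if (is.null(act)) act <- stats::rnorm(n_kos, 0, 0.05)
      act <- stats::setNames(rep_len(act, n_kos), kos)
      act[p$defining_ko] <- 1
      shift <- outer(ref, act)       # gene x KO
      rownames(shift) <- g
      base <- stats::runif(ng, 3, 8)
      extra_genes <- c(extra_genes, g)
      extra_mu_wt <- c(extra_mu_wt, stats::setNames(base, g))
      pw_shift <- rbind(pw_shift, shift)
      pathway_truth[[pw]] <- list(genes = g,
                                  ref_lfc = stats::setNames(ref, g),
                                  defining_ko = p$defining_ko,
                                  orientation = if (is.null(p$orientation)) 1
                                                else p$orientation,
                                  activity = act)
    }
  }

  nag_truth <- NULL
  nag_shift <- NULL
  if (!is.null(nag)) {
    n_c <- nag$n_coupled; n_0 <- nag$n_null
    r2 <- if (is.null(nag$target_r2)) 0.8 else nag$target_r2
    gc <- sprintf("NAGC%03d", seq_len(n_c))
    g0 <- sprintf("NAGN%03d", seq_len(n_0))
    w <- matrix(stats::rnorm(n_c * 7), n_c, 7)
    sig <- w %*% marker_lfc          # coupled gene x KO signal
    # normalise each planted signal to unit sd so the R2 calibration is
    # exact per gene, and budget the fold-change measurement noise the
    # contrast engine will add (two group means at n_rep replicates) into
    # the planted-noise variance: the target R2 then refers to the data as
    # analysed, not to an unobservable noise-free layer
    sig <- sig / apply(sig, 1, stats::sd)
    meas_var <- 2 * noise_sd^2 / n_rep
    eps_sd <- sqrt(pmax((1 - r2) / r2 - meas_var, 1e-6))
    coupled <- sig + matrix(stats::rnorm(n_c * n_kos), n_c) * eps_sd
    nullm <- matrix(stats::rnorm(n_0 * n_kos), n_0, n_kos)
    shift <- rbind(coupled, nullm)
    rownames(shift) <- c(gc, g0)
    base <- stats::runif(n_c + n_0, 3, 8)
    # give NAG genes a wild-type differentiation direction for the up/down
    # split: half up, half down at N24
    dirn <- sample(rep(c(1, -1), length.out = n_c + n_0))
    extra_genes <- c(extra_genes, gc, g0)
    extra_mu_wt <- c(extra_mu_wt, stats::setNames(base, c(gc, g0)))
    nag_shift <- shift
    nag_truth <- data.frame(gene = c(gc, g0),
                            coupled = c(rep(TRUE, n_c), rep(FALSE, n_0)),
                            wt_direction = dirn,
                            stringsAsFactors = FALSE)
    nag_truth$target_r2 <- ifelse(nag_truth$coupled, r2, NA_real_)
  }

  all_genes <- c(core$gene, extra_genes)
  ng_all <- length(all_genes)
  # mean N24 profile per KO
  mean_n24 <- matrix(NA_real_, ng_all, n_kos,
                     dimnames = list(all_genes, kos))
  mean_n24[core$gene, ] <- snap
  if (length(extra_genes))
    mean_n24[extra_genes, ] <- extra_mu_wt[extra_genes]
  if (!is.null(pw_shift))
    mean_n24[rownames(pw_shift), ] <-
      mean_n24[rownames(pw_shift), ] + pw_shift
  if (!is.null(nag_shift)) {
    # WT N24 level of a NAG gene moves by its direction; KO response adds
    # the planted coupling on top of the WT N24 level
    wtshift <- nag_truth$wt_direction * 1.5
    mean_n24[rownames(nag_shift), ] <-
      extra_mu_wt[rownames(nag_shift)] + wtshift + nag_shift
  }
  mu_2i_all <- c(mu_2i, extra_mu_wt)[all_genes]
  mu_n24_wt <- c(mu_n24, extra_mu_wt)[all_genes]
  if (!is.null(nag_shift))
    mu_n24_wt[rownames(nag_shift)] <-
      mu_n24_wt[rownames(nag_shift)] + nag_truth$wt_direction * 1.5

  batches <- paste0("b", ((seq_len(n_kos) - 1L) %% n_batches) + 1L)
  names(batches) <- kos
  batch_levels <- paste0("b", seq_len(n_batches))
  batch_off <- matrix(stats::rnorm(ng_all * n_batches, 0, batch_sd),
                      ng_all, n_batches,
                      dimnames = list(all_genes, batch_levels))
  off_2i <- matrix(stats::rnorm(ng_all * n_kos, 0, offset_2i_sd),
                   ng_all, n_kos, dimnames = list(all_genes, kos))

  cols <- list(); metas <- list()
  add_sample <- function(id, mu, batch, genotype, cond, r) {
    cols[[id]] <<- mu + batch_off[, batch] +
      stats::rnorm(ng_all, 0, noise_sd)
    metas[[id]] <<- data.frame(sample = id, genotype = genotype,
                               condition = cond, batch = batch,
                               replicate = r, time_h = NA_real_,
                               stringsAsFactors = FALSE)
  }
  for (b in batch_levels) for (cond in c("2i", "N24")) {
    mu <- if (cond == "2i") mu_2i_all else mu_n24_wt
    for (r in seq_len(n_rep))
      add_sample(sprintf("WT_%s_%s_r%d", b, cond, r), mu, b, "WT", cond, r)
  }
  for (ko in kos) {
    b <- batches[ko]
    for (r in seq_len(n_rep)) {
      add_sample(sprintf("%s_2i_r%d", ko, r), mu_2i_all + off_2i[, ko],
                 b, ko, "2i", r)
      add_sample(sprintf("%s_N24_r%d", ko, r), mean_n24[, ko],
                 b, ko, "N24", r)
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- all_genes
  meta <- do.call(rbind, metas)
  em <- expression_matrix(vals, meta, unit = "log2fpkm")
  list(expr = em,
       truth = list(delays_h = delays_h, batches = batches,
                    nag = nag_truth, pathways = pathway_truth,
                    marker_lfc = marker_lfc, noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate per-gene TTAA site counts
#'
#' Counts follow a shifted negative binomial (minimum `ttaa_min`),
#' mimicking the spread of piggyBac integration opportunities across genes
#' of different lengths.
#'
#' @param n_genes Number of genes.
#' @param ttaa_mu,ttaa_size Negative binomial mean and size of the shifted
#'   part.
#' @param ttaa_min Minimum number of sites per gene.
#' @param seed Integer seed.
#' @return Named integer vector of TTAA counts (genes `G00001`, ...).
#' @export
simulate_ttaa <- function(n_genes, ttaa_mu = 52, ttaa_size = 2,
                          ttaa_min = 4, seed = 1L) {
  set.seed(seed)
  n <- ttaa_min + stats::rnbinom(n_genes, size = ttaa_size, mu = ttaa_mu)
  stats::setNames(as.integer(n), sprintf("G%05d", seq_len(n_genes)))
}

#' Simulate transposon insertion screens
#'
#' Every TTAA site of gene g is hit independently with probability
#' `p0 * multiplier(g)` in each screen. Planted enriched genes carry a rate
#' multiplier; all other genes are hit at the uniform background rate.
#'
#' @param n_genes Number of genes (ignored when `ttaa` is supplied).
#' @param p0 Background per-site, per-screen integration probability
#'   (0 < p0 < 0.01).
#' @param enriched Named numeric vector of rate multipliers (names are gene
#'   ids); empty for a pure null screen.
#' @param n_screens Number of independent screens.
#' @param ttaa Optional named TTAA count vector (e.g. from
#'   [simulate_ttaa()]); drawn internally otherwise.
#' @param seed Integer seed.
#' @return A list with `insertions` (BED-like data frame), `ttaa` (named
#'   counts) and `truth` (enriched gene names and rates).
#' @export
simulate_insertions <- function(n_genes = 2000, p0 = 5e-4,
                                enriched = numeric(0), n_screens = 10,
                                ttaa = NULL, seed = 1L) {
  if (p0 < 0 || p0 >= 0.01)
    stop("p0 must lie in [0, 0.01)", call. = FALSE)
  set.seed(seed)
  nx_log("simulate_insertions", "seed=", seed)
  if (is.null(ttaa)) ttaa <- simulate_ttaa(n_genes, seed = seed)
  genes <- names(ttaa)
  if (length(enriched)) {
    bad <- setdiff(names(enriched), genes)
    if (length(bad))
      stop("enriched gene(s) not in TTAA table: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  rate <- rep(p0, length(ttaa))
  names(rate) <- genes
  rate[names(enriched)] <- p0 * enriched
  if (any(rate > 1))
    stop("rate multiplier makes hit probability exceed 1", call. = FALSE)
  # fixed genomic layout: gene i at offset (i-1)*1e5, sites every 20 bp
  offs <- (seq_along(ttaa) - 1L) * 1e5
  names(offs) <- genes
  site_gene <- rep.int(seq_along(ttaa), ttaa)
  site_idx <- sequence(ttaa)
  site_p <- rate[site_gene]
  n_sites <- length(site_gene)
  recs <- vector("list", n_screens)
  for (s in seq_len(n_screens)) {
    hit <- which(stats::runif(n_sites) < site_p)
    if (!length(hit)) next
    gi <- site_gene[hit]
    start <- offs[gi] + (site_idx[hit] - 1L) * 20L
    recs[[s]] <- data.frame(chrom = "chr1", start = start,
                            end = start + 4L, gene = genes[gi],
                            screen_id = sprintf("s%02d", s),
                            stringsAsFactors = FALSE)
  }
  ins <- do.call(rbind, recs)
  if (is.null(ins))
    ins <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene = character(0),
                      screen_id = character(0), stringsAsFactors = FALSE)
  rownames(ins) <- NULL
  list(insertions = ins, ttaa = ttaa,
       truth = list(enriched = names(enriched), multiplier = enriched,
                    p0 = p0, n_screens = n_screens, seed = seed))
}

#' Simulate a planted pathway-to-module wiring diagram
#'
#' Builds per-KO pathway activities, cluster mean fold changes generated
#' from a sparse linear wiring (each cluster responds to a subset of
#' pathways), and matched time-course trajectories in which every pathway's
#' activity precedes its target clusters by a planted lag.
#'
#' @param n_kos Number of knockouts.
#' @param n_pathways,n_clusters Diagram dimensions.
#' @param wiring Optional `n_clusters x n_pathways` coefficient matrix
#'   (zeros for absent links); a sparse random diagram is drawn otherwise.
#' @param lag_h Planted lag (hours) by which pathway activity precedes
#'   cluster expression in the time course; scalar or per-cluster vector.
#' @param noise_sd Noise sd on cluster mean fold changes across KOs.
#' @param times_h Time grid for the trajectories.
#' @param seed Integer seed.
#' @return List with `activities` (KO x pathway), `cluster_lfc`
#'   (cluster x KO), `activity_traj` (pathway x time), `cluster_traj`
#'   (cluster x time), `times_h` and `truth` (wiring matrix and lags).
#' @export
simulate_wiring <- function(n_kos = 70, n_pathways = 3, n_clusters = 4,
                            wiring = NULL, lag_h = 4, noise_sd = 0.05,
                            times_h = seq(0, 32, by = 2), seed = 1L) {
  set.seed(seed)
  nx_log("simulate_wiring", "seed=", seed)
  pws <- paste0("PW", seq_len(n_pathways))
  cls <- paste0("C", seq_len(n_clusters))
  kos <- sprintf("KO%03d", seq_len(n_kos))
  if (is.null(wiring)) {
    wiring <- matrix(0, n_clusters, n_pathways, dimnames = list(cls, pws))
    for (i in seq_len(n_clusters)) {
      k <- sample(1:2, 1L)
      j <- sample(n_pathways, k)
      wiring[i, j] <- sample(c(-1, 1), k, replace = TRUE) *
        stats::runif(k, 0.8, 1.6)
    }
  }
  acts <- matrix(stats::rnorm(n_kos * n_pathways), n_kos, n_pathways,
                 dimnames = list(kos, pws))
  cl_lfc <- wiring %*% t(acts) +
    matrix(stats::rnorm(n_clusters * n_kos, 0, noise_sd), n_clusters)
  dimnames(cl_lfc) <- list(cls, kos)
  lag_h <- rep_len(lag_h, n_clusters)
  # smooth mean-zero pathway activity curves: logistic ramps at distinct
  # inflection times, mean-subtracted
  t0 <- seq(8, 20, length.out = n_pathways)
  sgn <- rep_len(c(-1, 1), n_pathways)
  curve_at <- function(j, t) sgn[j] * stats::plogis(0.4 * (t - t0[j]))
  act_traj <- t(vapply(seq_len(n_pathways), function(j) {
    v <- curve_at(j, times_h); v - mean(v)
  }, numeric(length(times_h))))
  dimnames(act_traj) <- list(pws, paste0("t", times_h))
  cl_traj <- t(vapply(seq_len(n_clusters), function(i) {
    v <- numeric(length(times_h))
    for (j in seq_len(n_pathways)) {
      if (wiring[i, j] != 0)
        v <- v + wiring[i, j] * curve_at(j, times_h - lag_h[i])
    }
    v - mean(v)
  }, numeric(length(times_h))))
  dimnames(cl_traj) <- list(cls, paste0("t", times_h))
  list(activities = acts, cluster_lfc = cl_lfc, activity_traj = act_traj,
       cluster_traj = cl_traj, times_h = times_h,
       truth = list(wiring = wiring, lag_h = lag_h, seed = seed))
}

#' Write simulated screen data and ground truth to a directory
#'
#' @param sim Output of [simulate_insertions()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_screen_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_insertions(sim, file.path(dir, "insertions.tsv"),
                   file.path(dir, "ttaa.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
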