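#' Study configuration
#'
#' Central container for the thresholds and marker definitions used across
#' the pipeline. Defaults reproduce the analysis conventions of the knockout
#' panel study design: a fold-change null of 1.5x for differential
#' expression, an R-squared cutoff of 0.65 for naive-associated gene calls,
#' a binomial screen alpha of 0.01 restricted to genes with at least 26 TTAA
#' sites, 50-gene pathway footprints with a 2x specificity factor, and 12
#' clusters per response group.
#'
#' @param marker_genes_naive7 Character vector of the seven core naive
#'   pluripotency markers used for the phenotype score and NAG regression.
#' @param fc_h0 Log2 fold-change threshold of the differential expression
#'   null hypothesis (genes must exceed this to be called).
#' @param fdr_de FDR cutoff for differential expression calls.
#' @param nag_r2 Multiple R-squared cutoff for naive-associated gene calls.
#' @param screen_alpha Adjusted p-value cutoff for the insertion screen.
#' @param min_ttaa Minimum TTAA sites for a gene to enter the binomial test.
#' @param min_screens_binomial Minimum independent screens hit for the
#'   binomial candidate stream.
#' @param min_screens_count Minimum independent screens hit for the
#'   count-based candidate stream.
#' @param footprint_size Number of genes per pathway footprint.
#' @param specificity_factor Factor by which a footprint gene's defining
#'   fold change must exceed the largest fold change in other conditions.
#' @param expr_cutoff Minimum expression (linear FPKM/CPM scale) in knockout
#'   or control for footprint candidacy.
#' @param cluster_k_constitutive,cluster_k_induced Number of modules for the
#'   constitutive and induced response groups; `NA` selects k automatically
#'   by the within-cluster-variance elbow.
#' @param pathway_model_alpha Adjusted p-value cutoff for pathway-to-cluster
#'   regression links.
#' @param screen_adjust Multiple-testing method for the screen
#'   (`"BH"` or `"bonferroni"`).
#' @param trend_r_min Minimum Pearson correlation between predicted and
#'   observed cluster trajectories for a wiring link to pass the trend test.
#' @param lag_max_h,lag_step_h Lag grid half-width and step (hours) for the
#'   precedence cross-correlation.
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config()
#' cfg$fc_h0 == log2(1.5)
#' @export
study_config <- function(marker_genes_naive7 = c("Esrrb", "Nanog", "Tfcp2l1",
                                                 "Tbx3", "Prdm14", "Klf4",
                                                 "Zfp42"),
                         fc_h0 = log2(1.5),
                         fdr_de = 0.05,
                         nag_r2 = 0.65,
                         screen_alpha = 0.01,
                         min_ttaa = 26L,
                         min_screens_binomial = 2L,
                         min_screens_count = 5L,
                         footprint_size = 50L,
                         specificity_factor = 2.0,
                         expr_cutoff = 1.0,
                         cluster_k_constitutive = 12L,
                         cluster_k_induced = 12L,
                         pathway_model_alpha = 0.01,
                         screen_adjust = c("BH", "bonferroni"),
                         trend_r_min = 0.5,
                         lag_max_h = 8,
                         lag_step_h = 0.5,
                         seed = 1L) {
  screen_adjust <- match.arg(screen_adjust)
  cfg <- list(marker_genes_naive7 = marker_genes_naive7,
              fc_h0 = fc_h0, fdr_de = fdr_de, nag_r2 = nag_r2,
              screen_alpha = screen_alpha, min_ttaa = as.integer(min_ttaa),
              min_screens_binomial = as.integer(min_screens_binomial),
              min_screens_count = as.integer(min_screens_count),
              footprint_size = as.integer(footprint_size),
              specificity_factor = specificity_factor,
              expr_cutoff = expr_cutoff,
              cluster_k_constitutive = cluster_k_constitutive,
              cluster_k_induced = cluster_k_induced,
              pathway_model_alpha = pathway_model_alpha,
              screen_adjust = screen_adjust,
              trend_r_min = trend_r_min,
              lag_max_h = lag_max_h, lag_step_h = lag_step_h,
              seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  num_keys <- c("fc_h0", "fdr_de", "nag_r2", "screen_alpha", "min_ttaa",
                "min_screens_binomial", "min_screens_count", "footprint_size",
                "specificity_factor", "expr_cutoff", "pathway_model_alpha")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("config field '", k, "' must be a single positive number",
           call. = FALSE)
  }
  if (length(cfg$marker_genes_naive7) < 1L)
    stop("marker gene list must be non-empty", call. = FALSE)
  invisible(cfg)
}

#' Read a study configuration from a YAML file
#'
#' Keys present in the file override the corresponding [study_config()]
#' defaults; unknown keys are an error.
#'
#' @param path Path to a YAML document.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(study_config, vals)
}

#' @export
print.study_config <- function(x, ...) {
  cat("study_config\n")
  cat("  naive markers: ", paste(x$marker_genes_naive7, collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  DE: H0 |log2FC| < %.4f, FDR <= %.2f\n", x$fc_h0, x$fdr_de))
  cat(sprintf("  NAG R2 >= %.2f; screen alpha %.2g (min TTAA %d)\n",
              x$nag_r2, x$screen_alpha, x$min_ttaa))
  invisible(x)
}

# stage-tagged logging to stderr; every stochastic stage logs its seed
nx_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(..., collapse = "")))
}
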