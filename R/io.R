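#' Expression matrix with sample metadata
#'
#' Construct a validated gene-by-sample expression container. The unit of
#' the values is recorded explicitly so that downstream operations can
#' refuse to mix raw counts with log2-scale data.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @param meta Data frame of per-sample metadata with columns `sample`,
#'   `genotype`, `condition` (one of `"2i"`, `"N24"`, `"timecourse"`,
#'   `"2i_LIF"`), `batch`, `replicate` and optional `time_h`. Rows must
#'   cover every column of `values`.
#' @param unit One of `"counts"`, `"log2fpkm"`, `"log2cpm"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, meta,
                              unit = c("log2fpkm", "log2cpm", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (anyNA(values))
    stop("missing values are not permitted in expression matrices",
         call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample", "genotype", "condition", "batch", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(colnames(values), meta$sample)
  if (length(absent))
    stop("sample(s) present in matrix but absent from sheet: ",
         paste(absent, collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  rownames(meta) <- meta$sample
  ok_cond <- c("2i", "N24", "timecourse", "2i_LIF")
  bad <- setdiff(unique(meta$condition), ok_cond)
  if (length(bad))
    stop("unknown condition value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!"time_h" %in% names(meta)) meta$time_h <- NA_real_
  tc <- meta$condition == "timecourse"
  if (any(tc & !is.finite(meta$time_h)))
    stop("every timecourse sample needs time_h; missing for: ",
         paste(meta$sample[tc & !is.finite(meta$time_h)], collapse = ", "),
         call. = FALSE)
  if (unit == "counts" && (any(values < 0) || any(values != round(values))))
    stop("counts unit requires non-negative integral values", call. = FALSE)
  structure(list(values = values, meta = meta, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("  conditions: ",
      paste(names(table(x$meta$condition)), table(x$meta$condition),
            sep = ":", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample sheet
#'
#' The matrix is a TSV with a header row of sample identifiers and gene
#' identifiers in the first column; the sample sheet is a CSV keyed by
#' sample identifier.
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet Path to the sample sheet CSV.
#' @param unit Declared unit of the values; see [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, sample_sheet,
                            unit = c("log2fpkm", "log2cpm", "counts")) {
  unit <- match.arg(unit)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression file ", path, ": need gene column plus >= 1 sample",
         call. = FALSE)
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1L)))
    stop("expression file ", path, ": non-numeric values in column '",
         names(tab)[-1L][bad[1L]], "'", call. = FALSE)
  }
  rownames(vals) <- genes
  # read identifiers as strings: labels like "2i" must not be type-coerced
  meta <- utils::read.csv(sample_sheet, stringsAsFactors = FALSE,
                          colClasses = "character")
  if ("replicate" %in% names(meta))
    meta$replicate <- as.integer(meta$replicate)
  if ("time_h" %in% names(meta))
    meta$time_h <- suppressWarnings(as.numeric(meta$time_h))
  expression_matrix(vals, meta, unit = unit)
}

#' Write an expression matrix and sample sheet to disk
#'
#' @param x An `expression_matrix`.
#' @param path Output TSV path for the values.
#' @param sample_sheet Output CSV path for the metadata.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, sample_sheet) {
  stopifnot(inherits(x, "expression_matrix"))
  # 17 significant digits make the text round-trip value-exact
  fmt <- apply(x$values, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(gene = rownames(x$values), fmt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(x$meta, sample_sheet, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: set name, description and member genes separated by
#' tabs, one set per line. Duplicate genes within a set are removed with a
#' warning; duplicate set names and empty sets are errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of class `gene_set_collection`; each element has
#'   `genes` and `description`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT ", path, " line ", i, ": set with no genes", call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("GMT ", path, " line ", i, ": empty set '", f[1L], "'",
           call. = FALSE)
    if (anyDuplicated(genes)) {
      warning("GMT ", path, " line ", i, ": duplicate genes in set '",
              f[1L], "' removed", call. = FALSE)
      genes <- unique(genes)
    }
    nms[i] <- f[1L]
    sets[[i]] <- list(genes = genes, description = f[2L])
  }
  if (anyDuplicated(nms))
    stop("GMT ", path, ": duplicate set name '",
         nms[duplicated(nms)][1L], "'", call. = FALSE)
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.character(s)) s <- list(genes = s, description = "")
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read transposon insertion sites and per-gene TTAA counts
#'
#' Insertions are a BED-like TSV (`chrom`, `start` 0-based, `end` half-open,
#' `gene`, `screen_id`); TTAA counts are a two-column TSV (`gene`,
#' `n_ttaa`). Every insertion must fall in a gene present in the TTAA table.
#'
#' @param path Insertion TSV path.
#' @param ttaa_path TTAA count TSV path.
#' @return A list with `insertions` (data frame) and `ttaa` (named integer
#'   vector of site counts).
#' @export
read_insertions <- function(path, ttaa_path) {
  ins <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "gene", "screen_id")
  miss <- setdiff(req, names(ins))
  if (length(miss))
    stop("insertion file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(ins$start < 0))
    stop("insertion file ", path, ": negative coordinate at line ",
         which(ins$start < 0)[1L], call. = FALSE)
  if (any(ins$end - ins$start != 4L))
    stop("insertion file ", path, ": interval not 4 bp (TTAA) at line ",
         which(ins$end - ins$start != 4L)[1L], call. = FALSE)
  tt <- utils::read.delim(ttaa_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "n_ttaa") %in% names(tt)))
    stop("TTAA file ", ttaa_path, " needs columns gene, n_ttaa",
         call. = FALSE)
  if (any(tt$n_ttaa < 1L))
    stop("TTAA file ", ttaa_path, ": n_ttaa must be >= 1", call. = FALSE)
  ttaa <- stats::setNames(as.integer(tt$n_ttaa), tt$gene)
  unknown <- setdiff(unique(ins$gene), names(ttaa))
  if (length(unknown))
    stop("insertion gene(s) absent from TTAA table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dup <- duplicated(ins[, c("gene", "chrom", "start", "screen_id")])
  if (any(dup)) {
    warning("removed ", sum(dup), " duplicate insertion record(s)",
            call. = FALSE)
    ins <- ins[!dup, , drop = FALSE]
  }
  list(insertions = ins, ttaa = ttaa)
}

#' Write insertion and TTAA tables
#'
#' @param screen A list as returned by [read_insertions()] or
#'   [simulate_insertions()].
#' @param path,ttaa_path Output TSV paths.
#' @return Invisibly, `screen`.
#' @export
write_insertions <- function(screen, path, ttaa_path) {
  utils::write.table(screen$insertions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = names(screen$ttaa),
                                n_ttaa = as.integer(screen$ttaa)),
                     ttaa_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(screen)
}

# subset an expression_matrix by sample index/logical, keeping metadata in sync
em_subset_samples <- function(x, idx) {
  expression_matrix(x$values[, idx, drop = FALSE],
                    x$meta[idx, , drop = FALSE], unit = x$unit)
}

stop_if_unit_mismatch <- function(a, b) {
  ua <- if (inherits(a, "expression_matrix")) a$unit else a
  ub <- if (inherits(b, "expression_matrix")) b$unit else b
  log_units <- c("log2fpkm", "log2cpm")
  if ((ua == "counts") != (ub == "counts"))
    stop("cannot mix counts with log2-scale expression (", ua, " vs ",
         ub, ")", call. = FALSE)
  invisible(TRUE)
}
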