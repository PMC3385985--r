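#' Construct a count matrix with per-sample library sizes
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param totals Optional named numeric vector of total mapped reads per
#'   sample. Defaults to the column sums. Totals below the column sums are
#'   rejected: a library cannot contain fewer mapped reads than were counted
#'   on features.
#' @return A `count_matrix` object (list with `counts` and `totals`).
#' @export
count_matrix <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (anyNA(counts)) stop("missing values in counts")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"
  cs <- colSums(counts)
  if (is.null(totals)) {
    totals <- cs
  } else {
    if (is.null(names(totals))) stop("totals must be named by sample id")
    miss <- setdiff(colnames(counts), names(totals))
    if (length(miss)) stop("totals missing for sample(s): ",
                           paste(miss, collapse = ", "))
    totals <- totals[colnames(counts)]
    if (any(totals < cs)) stop("per-sample totals below column sums")
  }
  structure(list(counts = counts, totals = totals), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples; median library size", stats::median(x$totals), "\n")
  invisible(x)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `genotype`, `replicate`. Every genotype
#' intended for a statistical comparison needs at least two replicates.
#'
#' @param path Path to a TSV file.
#' @return data.frame with columns sample_id, genotype, replicate.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "genotype", "replicate"), names(d))
  if (length(need)) stop("design missing column(s): ",
                         paste(need, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in design")
  d
}

#' Write a sample design table
#' @param design data.frame as returned by [read_sample_design()].
#' @param path Output path.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count table
#'
#' TSV whose first column holds feature ids and whose remaining column names
#' are sample ids. Columns are reordered to match the design; every sample
#' named in the design must be present.
#'
#' An optional comment line `#totals<TAB>s1=N<TAB>s2=M...` directly above the
#' header supplies per-sample total mapped reads; otherwise totals default to
#' column sums (see [count_matrix()]).
#'
#' @param path Path to a TSV file.
#' @param design Sample design data.frame; its `sample_id` column fixes the
#'   sample order.
#' @return A `count_matrix` object.
#' @export
read_count_table <- function(path, design) {
  first <- readLines(path, n = 1L)
  totals <- NULL
  skip <- 0L
  if (startsWith(first, "#totals")) {
    skip <- 1L
    kv <- strsplit(sub("^#totals\t?", "", first), "\t")[[1]]
    kv <- kv[nzchar(kv)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    totals <- stats::setNames(
      as.numeric(vapply(parts, `[`, "", 2L)),
      vapply(parts, `[`, "", 1L)
    )
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, skip = skip,
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("count table needs a feature column plus samples")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count column in ", path)
  rownames(mat) <- ids
  miss <- setdiff(design$sample_id, colnames(mat))
  if (length(miss)) stop("design sample(s) absent from count table: ",
                         paste(miss, collapse = ", "))
  mat <- mat[, design$sample_id, drop = FALSE]
  if (!is.null(totals)) totals <- totals[design$sample_id]
  count_matrix(mat, totals = totals)
}

#' Write a count matrix as TSV
#'
#' Emits the optional `#totals` comment line so [read_count_table()]
#' round-trips library sizes exactly.
#'
#' @param cm A `count_matrix` object.
#' @param path Output path.
#' @param feature_col Name for the feature-id column.
#' @export
write_count_table <- function(cm, path, feature_col = "feature_id") {
  stopifnot(inherits(cm, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#totals\t", paste0(colnames(cm$counts), "=",
                                        cm$totals, collapse = "\t")), con)
  df <- data.frame(id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Samples belonging to a genotype
#' @param design Sample design data.frame.
#' @param genotype Genotype label.
#' @return Character vector of sample ids.
#' @export
genotype_samples <- function(design, genotype) {
  s <- design$sample_id[design$genotype == genotype]
  if (!length(s)) stop("no samples for genotype ", genotype)
  s
}
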