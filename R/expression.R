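#' RPKM-normalized expression from gene-level counts
#'
#' RPKM = count / (gene length in kb x total mapped reads in millions),
#' reported as log2 values. Gene lengths come from the collapsed exon-union
#' model of the annotation. Zeros are floored on the log2 scale: by default
#' at log2 of half the smallest positive RPKM in the matrix, so that zero
#' counts sort strictly below everything observed.
#'
#' Totals default to library column sums; supply explicit totals on the
#' count matrix when "mapped reads" should include non-exonic mappings.
#'
#' @param cm A `count_matrix` of gene-level counts.
#' @param annotation A [genome_annotation()]; must cover every gene in `cm`.
#' @param zero_log2 Optional explicit log2 value for zero RPKM.
#' @return An `expression_matrix`: list with `log2_rpkm`, `rpkm`, `counts`,
#'   `totals`, `length_kb`.
#' @export
compute_rpkm <- function(cm, annotation, zero_log2 = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  lens <- gene_lengths(annotation)
  miss <- setdiff(rownames(cm$counts), names(lens))
  if (length(miss)) stop("genes absent from annotation: ",
                         paste(utils::head(miss), collapse = ", "))
  len_kb <- lens[rownames(cm$counts)] / 1000
  if (any(len_kb <= 0)) stop("zero-length gene model")
  if (any(cm$totals <= 0)) stop("zero total mapped reads in a sample")
  rpkm <- sweep(cm$counts / len_kb, 2, cm$totals / 1e6, "/")
  if (is.null(zero_log2)) {
    pos <- rpkm[rpkm > 0]
    zero_log2 <- if (length(pos)) log2(min(pos) / 2) else 0
  }
  l2 <- ifelse(rpkm > 0, log2(rpkm), zero_log2)
  dimnames(l2) <- dimnames(rpkm)
  structure(list(log2_rpkm = l2, rpkm = rpkm, counts = cm$counts,
                 totals = cm$totals, length_kb = len_kb),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$log2_rpkm), "genes x",
      ncol(x$log2_rpkm), "samples (log2 RPKM)\n")
  invisible(x)
}

# Two-sample Student t-test (pooled variance) on log2 RPKM, with a
# convention for degenerate inputs: both groups constant and equal ->
# p = 1 (nothing to see); both constant but different -> p = 0 (perfect
# separation at zero noise). The pooled test keeps its nominal size at
# n = 3, where the Welch approximation runs conservative.
student_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Per-gene differential expression between two genotypes
#'
#' Genes enter testing only if their mean raw count across replicates is at
#' least `min_mean_reads` in at least one of the two groups (the read-depth
#' quality filter). Tested genes get a two-sided two-sample t-test (pooled
#' variance) on log2 RPKM;
#' raw p-values are compared to `alpha` for the significance call and
#' Benjamini-Hochberg adjusted p-values over the tested genes are reported
#' alongside. Direction is the sign of the group-A minus group-B mean
#' difference, reported for significant genes.
#'
#' @param expr An `expression_matrix` from [compute_rpkm()].
#' @param group_a,group_b Character vectors of sample ids (each of length
#'   >= 2). Group A is the condition of interest (e.g. mutant), group B the
#'   reference (e.g. control): "up" means higher in A.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param min_mean_reads Read-depth filter (default 10).
#' @param hit_table Optional `gene_hit_table`; adds a `has_binding_site`
#'   column.
#' @return data.frame (one row per gene): gene_id, tested, mean_a, mean_b,
#'   log2fc, t, p, p_adj, significant, direction ("up"/"down", NA when not
#'   significant), twofold (|log2fc| >= 1, for significant genes), and
#'   has_binding_site when a hit table is given.
#' @export
differential_expression <- function(expr, group_a, group_b, alpha = 0.05,
                                    min_mean_reads = 10,
                                    hit_table = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need >= 2 replicates per group")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  miss <- setdiff(c(group_a, group_b), colnames(expr$log2_rpkm))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))

  ca <- expr$counts[, group_a, drop = FALSE]
  cb <- expr$counts[, group_b, drop = FALSE]
  tested <- rowMeans(ca) >= min_mean_reads | rowMeans(cb) >= min_mean_reads
  la <- expr$log2_rpkm[, group_a, drop = FALSE]
  lb <- expr$log2_rpkm[, group_b, drop = FALSE]
  mean_a <- rowMeans(la)
  mean_b <- rowMeans(lb)

  n <- nrow(expr$log2_rpkm)
  tstat <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  for (i in which(tested)) {
    w <- student_p(la[i, ], lb[i, ])
    tstat[i] <- w$t
    p[i] <- w$p
  }
  p_adj <- rep(NA_real_, n)
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")

  log2fc <- mean_a - mean_b
  significant <- tested & !is.na(p) & p < alpha
  direction <- ifelse(significant, ifelse(log2fc > 0, "up", "down"),
                      NA_character_)
  twofold <- significant & abs(log2fc) >= 1

  out <- data.frame(
    gene_id = rownames(expr$log2_rpkm),
    tested = tested, mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
    t = tstat, p = p, p_adj = p_adj, significant = significant,
    direction = direction, twofold = twofold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(hit_table)) {
    stopifnot(inherits(hit_table, "gene_hit_table"))
    out$has_binding_site <- unname(hit_table$has_site[out$gene_id])
    out$has_binding_site[is.na(out$has_binding_site)] <- FALSE
  }
  out
}

#' Classify genetic rescue of differential expression
#'
#' For every gene differentially expressed in the mutant-vs-control
#' comparison, asks what happened in the rescue-vs-control comparison:
#' \describe{
#'   \item{rescued}{no longer significant in rescue vs control — expression
#'     reverted to control-like.}
#'   \item{partial}{still significant, same direction as in the mutant, but
#'     the fold-change shrank to at most `(1 - rho)` of the mutant
#'     fold-change (default rho = 0.5: at least half the effect undone).}
#'   \item{not_rescued}{everything else.}
#' }
#' Genes absent from or untested in the rescue table count as not
#' significant there (insufficient rescue-sample signal reads as reverted).
#'
#' @param de_mut DE table for mutant vs control ([differential_expression()]).
#' @param de_resc DE table for rescue vs the same control.
#' @param rho Minimum fraction of the mutant effect that must be undone for
#'   a still-significant gene to count as partially rescued.
#' @return data.frame with gene_id, status (rescued/partial/not_rescued),
#'   log2fc_mutant, log2fc_rescue — one row per mutant-DE gene.
#' @export
classify_rescue <- function(de_mut, de_resc, rho = 0.5) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (!length(intersect(de_mut$gene_id, de_resc$gene_id))) {
    stop("mutant and rescue DE tables share no genes")
  }
  mut <- de_mut[de_mut$significant, , drop = FALSE]
  idx <- match(mut$gene_id, de_resc$gene_id)
  r_sig <- ifelse(is.na(idx), FALSE, de_resc$significant[idx])
  r_lfc <- ifelse(is.na(idx), 0, de_resc$log2fc[idx])
  same_sign <- sign(r_lfc) == sign(mut$log2fc)
  shrunk <- abs(r_lfc) <= (1 - rho) * abs(mut$log2fc)
  status <- ifelse(!r_sig, "rescued",
                   ifelse(same_sign & shrunk, "partial", "not_rescued"))
  data.frame(gene_id = mut$gene_id, status = status,
             log2fc_mutant = mut$log2fc, log2fc_rescue = r_lfc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap and direction concordance of two DE gene sets
#'
#' Intersects the significant genes of two DE tables and tallies how many
#' intersection genes move in the same versus opposite directions.
#'
#' @param de_a,de_b DE tables from [differential_expression()].
#' @return list with n_a, n_b, n_intersect, n_same_direction,
#'   n_opposite_direction, and the intersecting gene ids.
#' @export
overlap_summary <- function(de_a, de_b) {
  a <- de_a[de_a$significant, , drop = FALSE]
  b <- de_b[de_b$significant, , drop = FALSE]
  shared <- intersect(a$gene_id, b$gene_id)
  da <- a$direction[match(shared, a$gene_id)]
  db <- b$direction[match(shared, b$gene_id)]
  same <- sum(da == db)
  list(n_a = nrow(a), n_b = nrow(b), n_intersect = length(shared),
       n_same_direction = same,
       n_opposite_direction = length(shared) - same,
       genes = shared)
}
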