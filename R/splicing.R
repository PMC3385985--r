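#' Splice index between two genotypes for one gene
#'
#' The per-gene splice index is the product-moment correlation between the
#' two genotypes' relative exon-usage vectors (per-exon count divided by the
#' gene total, replicates pooled upstream). An index near 1 means the two
#' genotypes distribute reads across exons the same way; low or negative
#' values flag altered splicing.
#'
#' A gene is `sufficient` only when both genotype totals reach `min_reads`
#' (default 200); genes below that floor keep their index but are never
#' candidates. Degenerate inputs: fewer than 2 exons, or exactly one
#' genotype with a constant proportion vector, are not assessable (NA
#' index); two constant vectors are trivially identical and score 1.
#'
#' @param exon_counts_a,exon_counts_b Numeric vectors of per-exon counts
#'   (same exon order) for the two genotypes.
#' @param min_reads Read floor per genotype (default 200).
#' @return One-row data.frame: index, total_a, total_b, sufficient,
#'   assessable.
#' @export
splice_index <- function(exon_counts_a, exon_counts_b, min_reads = 200) {
  if (length(exon_counts_a) != length(exon_counts_b)) {
    stop("exon count vectors differ in length")
  }
  if (any(exon_counts_a < 0) || any(exon_counts_b < 0)) {
    stop("negative exon counts")
  }
  ta <- sum(exon_counts_a)
  tb <- sum(exon_counts_b)
  sufficient <- ta >= min_reads && tb >= min_reads
  if (length(exon_counts_a) < 2 || ta == 0 || tb == 0) {
    return(data.frame(index = NA_real_, total_a = ta, total_b = tb,
                      sufficient = sufficient, assessable = FALSE))
  }
  pa <- exon_counts_a / ta
  pb <- exon_counts_b / tb
  ca <- stats::sd(pa) == 0
  cb <- stats::sd(pb) == 0
  if (ca && cb) {
    idx <- 1
  } else if (ca || cb) {
    return(data.frame(index = NA_real_, total_a = ta, total_b = tb,
                      sufficient = sufficient, assessable = FALSE))
  } else {
    idx <- stats::cor(pa, pb)
  }
  data.frame(index = idx, total_a = ta, total_b = tb,
             sufficient = sufficient, assessable = TRUE)
}

#' Splice-index screen across genes
#'
#' Pools replicates by summation per genotype, computes the splice index per
#' gene, and flags candidates: sufficient read depth, index below the
#' cutoff, and (when a hit table is supplied) a predicted binding site.
#'
#' @param exon_tab data.frame with columns gene_id, exon_index and one
#'   column per sample.
#' @param design Sample design data.frame.
#' @param genotype_a,genotype_b Genotype labels to compare.
#' @param hit_table Optional `gene_hit_table` for the binding-site condition
#'   on candidacy; without it, candidacy is depth + index only.
#' @param min_reads Per-genotype read floor (default 200).
#' @param cutoff Splice-index candidacy cutoff (default 0.7).
#' @return data.frame, one row per gene: gene_id, index, total_a, total_b,
#'   sufficient, assessable, has_binding_site, candidate.
#' @export
splice_screen <- function(exon_tab, design, genotype_a, genotype_b,
                          hit_table = NULL, min_reads = 200, cutoff = 0.7) {
  sa <- genotype_samples(design, genotype_a)
  sb <- genotype_samples(design, genotype_b)
  miss <- setdiff(c(sa, sb), names(exon_tab))
  if (length(miss)) stop("sample(s) missing from exon table: ",
                         paste(miss, collapse = ", "))
  genes <- unique(exon_tab$gene_id)
  rows <- lapply(genes, function(gid) {
    e <- exon_tab[exon_tab$gene_id == gid, , drop = FALSE]
    e <- e[order(e$exon_index), , drop = FALSE]
    a <- rowSums(e[, sa, drop = FALSE])
    b <- rowSums(e[, sb, drop = FALSE])
    cbind(data.frame(gene_id = gid, stringsAsFactors = FALSE),
          splice_index(a, b, min_reads = min_reads))
  })
  out <- do.call(rbind, rows)
  out$has_binding_site <- if (is.null(hit_table)) NA else {
    hs <- unname(hit_table$has_site[out$gene_id])
    ifelse(is.na(hs), FALSE, hs)
  }
  site_ok <- if (is.null(hit_table)) TRUE else out$has_binding_site
  out$candidate <- out$sufficient & out$assessable &
    !is.na(out$index) & out$index < cutoff & site_ok
  rownames(out) <- NULL
  out
}

#' Beta posterior for a junction-usage proportion
#'
#' Conjugate update of the Jeffreys beta(1/2, 1/2) prior, which encodes the
#' biological expectation that reads across a given exon-exon junction tend
#' to be either very uncommon or common.
#'
#' @param successes,failures Non-negative integer counts.
#' @return `beta_posterior`: list with shape parameters a = successes + 1/2,
#'   b = failures + 1/2 and the posterior mean.
#' @export
junction_posterior <- function(successes, failures) {
  if (length(successes) != 1 || length(failures) != 1 ||
      successes < 0 || failures < 0 ||
      successes != round(successes) || failures != round(failures)) {
    stop("successes and failures must be single non-negative integers")
  }
  a <- successes + 0.5
  b <- failures + 0.5
  structure(list(a = a, b = b, mean = a / (a + b)),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%.1f, %.1f), mean %.4f\n", x$a, x$b, x$mean))
  invisible(x)
}

#' Posterior tail probability P(theta >= theta0)
#' @param posterior A `beta_posterior`.
#' @param theta0 Reference proportion in \[0, 1\].
#' @export
beta_tail <- function(posterior, theta0) {
  stopifnot(inherits(posterior, "beta_posterior"))
  stats::pbeta(theta0, posterior$a, posterior$b, lower.tail = FALSE)
}

#' P(theta_A > theta_B) for two independent beta posteriors
#'
#' Computes P(A > B) = integral over x of f_A(x) * F_B(x) dx, with f_A the
#' posterior density of theta_A and F_B the posterior CDF of theta_B, by
#' adaptive quadrature.
#'
#' @param post_a,post_b `beta_posterior` objects.
#' @param rel_tol Integration tolerance.
#' @return Probability in \[0, 1\].
#' @export
prob_greater <- function(post_a, post_b, rel_tol = 1e-8) {
  stopifnot(inherits(post_a, "beta_posterior"),
            inherits(post_b, "beta_posterior"))
  f <- function(x) {
    stats::dbeta(x, post_a$a, post_a$b) *
      stats::pbeta(x, post_b$a, post_b$b)
  }
  v <- stats::integrate(f, 0, 1, rel.tol = rel_tol,
                        subdivisions = 500L)$value
  min(max(v, 0), 1)
}

junction_failure_count <- function(gene_junctions, target_donor,
                                   target_acceptor, genotype,
                                   failure_mode) {
  j <- gene_junctions
  is_target <- j$donor == target_donor & j$acceptor == target_acceptor
  if (failure_mode == "alternate_second") {
    sel <- j$donor == target_donor & !is_target
  } else if (failure_mode == "all_other") {
    sel <- !is_target
  } else {
    stop("unknown failure mode: ", failure_mode)
  }
  sum(j[[genotype]][sel])
}

#' Compare usage of one exon-exon junction between two genotypes
#'
#' Successes are reads across the junction of interest. Failures depend on
#' the chosen definition: `alternate_second` counts junctions sharing the
#' target's donor exon but landing on an alternate acceptor; `all_other`
#' counts every other junction of the gene. Each genotype's usage
#' proportion gets a Jeffreys-prior beta posterior, and the two posteriors
#' are compared by numerical integration.
#'
#' @param gene_junctions data.frame of one gene's junctions: columns donor,
#'   acceptor, and one count column per genotype (replicates pooled).
#' @param target_junction Length-2 integer vector c(donor, acceptor).
#' @param genotype_a,genotype_b Names of the two genotype count columns.
#' @param failure_mode `"alternate_second"` or `"all_other"`.
#' @return list: junction id, failure_mode, successes/failures per genotype,
#'   `posterior_a`, `posterior_b`, `p_a_greater` = P(theta_A > theta_B), and
#'   `p_two_sided` = 2 min(P, 1 - P), the reported two-sided value.
#' @export
junction_compare <- function(gene_junctions, target_junction, genotype_a,
                             genotype_b,
                             failure_mode = c("alternate_second",
                                              "all_other")) {
  failure_mode <- match.arg(failure_mode)
  d <- target_junction[1]
  a <- target_junction[2]
  if (d >= a) stop("target junction must have donor index < acceptor index")
  hit <- gene_junctions$donor == d & gene_junctions$acceptor == a
  if (!any(hit)) stop("target junction not present in gene junction table")
  res <- list(donor = d, acceptor = a, failure_mode = failure_mode)
  for (side in c("a", "b")) {
    gt <- if (side == "a") genotype_a else genotype_b
    if (is.null(gene_junctions[[gt]])) stop("no counts for genotype ", gt)
    s <- sum(gene_junctions[[gt]][hit])
    f <- junction_failure_count(gene_junctions, d, a, gt, failure_mode)
    res[[paste0("successes_", side)]] <- s
    res[[paste0("failures_", side)]] <- f
    res[[paste0("posterior_", side)]] <- junction_posterior(s, f)
  }
  p <- prob_greater(res$posterior_a, res$posterior_b)
  res$p_a_greater <- p
  res$p_two_sided <- 2 * min(p, 1 - p)
  res
}
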