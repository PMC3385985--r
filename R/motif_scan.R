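#' The three TDP-43 binding-site motifs
#'
#' TDP-43 binds UG-rich single-stranded RNA. Searched at the DNA level the
#' published site classes are:
#' \describe{
#'   \item{1}{`(GT){3,}T{3,}` — a UG repeat run ending in a U run
#'     ((UG)mUn); minimum length 9.}
#'   \item{2}{`(GT){2,}(GTA){1}(TG){3,}` — a UG run interrupted by a single
#'     UA ((UG)mUA(UG)n); minimum length 13.}
#'   \item{3}{`(GT){4,}` not followed by `T{3,}` — a pure UG repeat
#'     ((UG)n), excluded when it runs into a U-tract (that situation is
#'     motif 1's); minimum length 8. Implemented as a negative lookahead,
#'     so a (GT) run that would trail into TTT can still match a shorter
#'     prefix of the run whose following context is not TTT.}
#' }
#'
#' @return data.frame with columns motif_id, pattern (PCRE, forward strand)
#'   and min_len.
#' @export
motif_definitions <- function() {
  data.frame(
    motif_id = c(1L, 2L, 3L),
    pattern = c("(GT){3,}T{3,}",
                "(GT){2,}(GTA){1}(TG){3,}",
                "(GT){4,}(?!T{3,})"),
    min_len = c(9L, 13L, 8L),
    stringsAsFactors = FALSE
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

scan_forward <- function(sequence, motifs) {
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    m <- gregexpr(motifs$pattern[i], sequence, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m) - 1L               # to 0-based
    lens <- attr(m, "match.length")
    out[[length(out) + 1L]] <- data.frame(
      start = starts, end = starts + lens, strand = "+",
      motif_id = motifs$motif_id[i],
      match = substring(sequence, starts + 1L, starts + lens),
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else empty_hits()
}

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             motif_id = integer(0), match = character(0),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for TDP-43 binding-site motifs
#'
#' Reports, per motif and strand, the maximal non-overlapping leftmost
#' matches. Double-stranded mode is for genomic gene regions: the minus
#' strand is searched by scanning the reverse complement with the forward
#' patterns and mirroring the spans back onto forward coordinates, which is
#' equivalent to applying the reverse-complement patterns to the forward
#' text. Single-stranded molecules (introns, mRNAs) use `forward_only`.
#'
#' N bases never match any motif.
#'
#' @param sequence A single nucleotide string over A/C/G/T/N.
#' @param motifs Motif table, as from [motif_definitions()] (subsettable).
#' @param search_mode `"double_stranded"` or `"forward_only"`.
#' @return data.frame of hits with columns start, end (0-based half-open,
#'   forward coordinates), strand, motif_id, match (the matched text as read
#'   on the hit strand, i.e. the reverse complement of the forward slice for
#'   minus-strand hits), ordered by (start, motif_id, strand).
#' @export
scan_sequence <- function(sequence, motifs = motif_definitions(),
                          search_mode = c("double_stranded",
                                          "forward_only")) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("sequence must be a single string")
  }
  search_mode <- match.arg(search_mode)
  hits <- scan_forward(sequence, motifs)
  if (search_mode == "double_stranded") {
    n <- nchar(sequence)
    rc_hits <- scan_forward(revcomp(sequence), motifs)
    if (nrow(rc_hits)) {
      mapped <- rc_hits
      mapped$start <- n - rc_hits$end
      mapped$end <- n - rc_hits$start
      mapped$strand <- "-"
      hits <- rbind(hits, mapped)
    }
  }
  hits[order(hits$start, hits$motif_id, hits$strand), , drop = FALSE]
}

# Per-base feature classes for one gene, relative to the gene interval.
# Precedence across transcripts: UTR > exon > intron; bases of the gene span
# covered by no transcript feature are treated as intronic context.
gene_base_classes <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  txs <- annotation$transcripts$tx_id[
    annotation$transcripts$gene_id == gene_id]
  n <- g$end - g$start
  cls <- rep("intron", n)
  f <- annotation$features[annotation$features$tx_id %in% txs, ,
                           drop = FALSE]
  paint <- function(cls, rows, label) {
    for (i in seq_len(nrow(rows))) {
      a <- rows$start[i] - g$start + 1L
      b <- rows$end[i] - g$start
      cls[a:b] <- label
    }
    cls
  }
  cls <- paint(cls, f[f$type == "exon", , drop = FALSE], "exon")
  cls <- paint(cls, f[f$type == "five_prime_utr", , drop = FALSE],
               "five_prime_utr")
  cls <- paint(cls, f[f$type == "three_prime_utr", , drop = FALSE],
               "three_prime_utr")
  cls
}

classify_span <- function(base_classes, start_rel, end_rel) {
  tab <- table(base_classes[(start_rel + 1L):end_rel])
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  if ("intron" %in% top) return("intron")
  for (pref in c("five_prime_utr", "three_prime_utr", "exon")) {
    if (pref %in% top) return(pref)
  }
  top[1]
}

#' Predict binding-site genes across a genome annotation
#'
#' Scans every gene region double-stranded on the genomic text, assigns each
#' hit a feature class (intron, exon, 5'UTR, 3'UTR) from the gene's
#' transcript models, and tabulates per-gene hit presence. A hit spanning a
#' feature boundary is classed by the majority of its bases, with ties going
#' to intron. For minus-strand genes the minus-strand genomic hits are the
#' ones lying on the transcribed molecule, so single-stranded (RNA-level)
#' sites are covered by the double-stranded genomic search.
#'
#' @param annotation A [genome_annotation()] object.
#' @param sequences Sequence set from [read_fasta()]; must contain every
#'   gene's seqid.
#' @param motifs Motif table, default [motif_definitions()].
#' @return A `gene_hit_table`: list with
#'   \describe{
#'     \item{hits}{per-hit data.frame (gene_id, seqid, start, end, strand,
#'       motif_id, match, feature_class) in genomic coordinates}
#'     \item{by_class}{data.frame gene_id x motif_id x feature_class with
#'       hit counts}
#'     \item{has_site}{named logical, one entry per annotated gene}
#'   }
#' @export
annotate_gene_hits <- function(annotation, sequences,
                               motifs = motif_definitions()) {
  stopifnot(inherits(annotation, "genome_annotation"))
  unknown <- setdiff(annotation$genes$seqid, names(sequences))
  if (length(unknown)) stop("seqid(s) missing from sequences: ",
                            paste(unknown, collapse = ", "))
  all_hits <- list()
  g <- annotation$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    txt <- substring(sequences[[g$seqid[i]]], g$start[i] + 1L, g$end[i])
    h <- scan_sequence(txt, motifs, "double_stranded")
    if (!nrow(h)) next
    no_tx <- !any(annotation$transcripts$gene_id == gid)
    if (no_tx) {
      warning("gene ", gid, " has no transcript; hits classed as 'gene'")
      h$feature_class <- "gene"
    } else {
      cls <- gene_base_classes(annotation, gid)
      h$feature_class <- vapply(seq_len(nrow(h)), function(j) {
        classify_span(cls, h$start[j], h$end[j])
      }, character(1))
    }
    h$gene_id <- gid
    h$seqid <- g$seqid[i]
    h$start <- h$start + g$start[i]
    h$end <- h$end + g$start[i]
    all_hits[[length(all_hits) + 1L]] <- h
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    cbind(empty_hits(),
          data.frame(feature_class = character(0), gene_id = character(0),
                     seqid = character(0), stringsAsFactors = FALSE))
  hits <- hits[, c("gene_id", "seqid", "start", "end", "strand", "motif_id",
                   "match", "feature_class"), drop = FALSE]
  rownames(hits) <- NULL
  by_class <- if (nrow(hits)) {
    agg <- stats::aggregate(
      list(n_hits = rep(1L, nrow(hits))),
      by = list(gene_id = hits$gene_id, motif_id = hits$motif_id,
                feature_class = hits$feature_class),
      FUN = sum
    )
    agg[order(agg$gene_id, agg$motif_id, agg$feature_class), , drop = FALSE]
  } else {
    data.frame(gene_id = character(0), motif_id = integer(0),
               feature_class = character(0), n_hits = integer(0))
  }
  rownames(by_class) <- NULL
  has_site <- stats::setNames(g$gene_id %in% hits$gene_id, g$gene_id)
  structure(list(hits = hits, by_class = by_class, has_site = has_site),
            class = "gene_hit_table")
}

#' @export
print.gene_hit_table <- function(x, ...) {
  cat("gene_hit_table:", nrow(x$hits), "hits;",
      sum(x$has_site), "of", length(x$has_site), "genes with a site\n")
  invisible(x)
}

#' Genomic distribution of binding sites
#'
#' Counts genes per (motif, feature class). A gene with several hits of the
#' same motif in the same class contributes one; a gene with hits in two
#' classes contributes one to each.
#'
#' @param hit_table A `gene_hit_table` from [annotate_gene_hits()].
#' @return data.frame motif_id x feature_class with a `n_genes` column,
#'   covering all (motif, class) combinations (zeros included).
#' @export
distribution_summary <- function(hit_table) {
  stopifnot(inherits(hit_table, "gene_hit_table"))
  classes <- c("intron", "exon", "five_prime_utr", "three_prime_utr")
  grid <- expand.grid(motif_id = motif_definitions()$motif_id,
                      feature_class = classes, stringsAsFactors = FALSE)
  b <- hit_table$by_class
  grid$n_genes <- vapply(seq_len(nrow(grid)), function(i) {
    sel <- b$motif_id == grid$motif_id[i] &
      b$feature_class == grid$feature_class[i]
    length(unique(b$gene_id[sel]))
  }, integer(1))
  grid
}

#' Write motif hits as BED6
#'
#' 0-based half-open intervals; name column is the motif id; score 0;
#' strand column carries the hit strand.
#'
#' @param hits Per-hit data.frame (the `hits` element of a
#'   `gene_hit_table`).
#' @param path Output path.
#' @export
write_bed_hits <- function(hits, path) {
  bed <- data.frame(hits$seqid, hits$start, hits$end, hits$motif_id, 0L,
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
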