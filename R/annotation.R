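#' Read a multi-record FASTA file into a sequence set
#'
#' Loads nucleotide sequences and normalizes them to uppercase. The returned
#' object is a named character vector (one element per record) restricted to
#' the alphabet A/C/G/T/N; any other letter is rejected so downstream motif
#' scanning can assume a clean alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   FASTA record ids (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    out <- character(0)
    names(out) <- character(0)
    return(out)
  }
  # read without alphabet coercion so invalid letters are caught here
  # rather than silently dropped
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_sequence_set(seqs)
  seqs
}

#' Write a sequence set to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  validate_sequence_set(sequences)
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

validate_sequence_set <- function(sequences) {
  if (length(sequences) == 0) return(invisible(TRUE))
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("every sequence must have a non-empty id")
  }
  if (anyDuplicated(names(sequences))) stop("duplicate sequence ids")
  if (any(nchar(sequences) == 0)) {
    stop("empty sequence for id(s): ",
         paste(names(sequences)[nchar(sequences) == 0], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence(s) contain letters outside A/C/G/T/N: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a genome annotation
#'
#' The container for gene models used throughout the pipeline. All
#' coordinates are internal convention: 0-based, half-open (start inclusive,
#' end exclusive). GFF3 IO converts to/from the 1-based inclusive convention
#' at the file boundary.
#'
#' Introns are derived per transcript as the gaps between that transcript's
#' sorted exons, so a transcript with k exons always carries k - 1 introns.
#'
#' @param genes data.frame with columns gene_id, seqid, start, end, strand.
#' @param transcripts data.frame with columns tx_id, gene_id.
#' @param features data.frame with columns tx_id, type (one of "exon",
#'   "five_prime_utr", "three_prime_utr"), start, end.
#' @return An object of class `genome_annotation` with elements `genes`,
#'   `transcripts`, `features` and derived `introns` (tx_id, start, end).
#' @export
genome_annotation <- function(genes, transcripts, features) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  need(genes, c("gene_id", "seqid", "start", "end", "strand"), "genes")
  need(transcripts, c("tx_id", "gene_id"), "transcripts")
  need(features, c("tx_id", "type", "start", "end"), "features")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(transcripts$tx_id)) stop("duplicate transcript ids")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (!all(transcripts$gene_id %in% genes$gene_id)) {
    stop("transcript refers to unknown gene")
  }
  if (!all(features$tx_id %in% transcripts$tx_id)) {
    stop("feature refers to unknown transcript")
  }
  ok_types <- c("exon", "five_prime_utr", "three_prime_utr")
  if (!all(features$type %in% ok_types)) {
    stop("feature type must be one of: ", paste(ok_types, collapse = ", "))
  }
  check_iv <- function(start, end, what) {
    if (any(start < 0) || any(end <= start)) {
      stop(what, ": intervals must satisfy 0 <= start < end")
    }
  }
  check_iv(genes$start, genes$end, "genes")
  if (nrow(features)) check_iv(features$start, features$end, "features")

  # exon checks + intron derivation, per transcript
  tx_gene <- stats::setNames(transcripts$gene_id, transcripts$tx_id)
  g_start <- stats::setNames(genes$start, genes$gene_id)
  g_end <- stats::setNames(genes$end, genes$gene_id)
  introns <- list()
  exons <- features[features$type == "exon", , drop = FALSE]
  for (tx in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping exons in transcript ", tx)
    }
    gid <- tx_gene[[tx]]
    if (any(e$start < g_start[[gid]]) || any(e$end > g_end[[gid]])) {
      stop("exon of transcript ", tx, " lies outside gene ", gid)
    }
    if (nrow(e) > 1) {
      introns[[tx]] <- data.frame(
        tx_id = tx,
        start = e$end[-nrow(e)],
        end = e$start[-1],
        stringsAsFactors = FALSE
      )
    }
  }
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(tx_id = character(0), start = integer(0), end = integer(0))
  rownames(introns) <- NULL
  structure(
    list(genes = genes, transcripts = transcripts, features = features,
         introns = introns),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      sum(x$features$type == "exon"), "exons,",
      nrow(x$introns), "derived introns\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon (and optional five_prime_UTR / three_prime_UTR)
#' features linked by Parent attributes. GFF3 1-based inclusive intervals are
#' converted to the internal 0-based half-open convention; a GFF3 interval
#' \[100, 150\] becomes internal \[99, 150) of length 51.
#'
#' @param path Path to a GFF3 file.
#' @param sequences Optional sequence set (from [read_fasta()]); when given,
#'   every gene's seqid must be present and every gene must fit within its
#'   sequence.
#' @return A [genome_annotation()] object.
#' @export
read_gff3 <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$Parent <- vapply(
    as.list(S4Vectors::mcols(gr)$Parent),
    function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
    character(1)
  )
  df$ID <- as.character(S4Vectors::mcols(gr)$ID)
  # 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end

  g <- df[df$type == "gene", , drop = FALSE]
  m <- df[df$type == "mRNA", , drop = FALSE]
  f <- df[df$type %in% c("exon", "five_prime_UTR", "three_prime_UTR"), ,
          drop = FALSE]
  if (!nrow(g)) stop("no gene features in ", path)
  if (any(is.na(g$ID))) stop("gene feature without ID attribute")
  if (any(is.na(m$Parent))) stop("mRNA feature without Parent attribute")
  if (any(is.na(f$Parent))) stop("exon/UTR feature without Parent attribute")

  genes <- data.frame(
    gene_id = g$ID, seqid = as.character(g$seqnames),
    start = g$start0, end = g$end0, strand = as.character(g$strand),
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(tx_id = m$ID, gene_id = m$Parent,
                            stringsAsFactors = FALSE)
  type_map <- c(exon = "exon", five_prime_UTR = "five_prime_utr",
                three_prime_UTR = "three_prime_utr")
  features <- data.frame(
    tx_id = f$Parent, type = unname(type_map[f$type]),
    start = f$start0, end = f$end0, stringsAsFactors = FALSE
  )
  if (!is.null(sequences)) {
    unknown <- setdiff(genes$seqid, names(sequences))
    if (length(unknown)) stop("gene seqid(s) not in sequence set: ",
                              paste(unknown, collapse = ", "))
    too_far <- genes$end > nchar(sequences[genes$seqid])
    if (any(too_far)) stop("gene(s) extend past their sequence: ",
                           paste(genes$gene_id[too_far], collapse = ", "))
  }
  genome_annotation(genes, transcripts, features)
}

#' Write a genome annotation to GFF3
#'
#' Emits gene, mRNA, exon and UTR records with ID/Parent attributes,
#' converting internal 0-based half-open coordinates back to GFF3 1-based
#' inclusive. [read_gff3()] of the output reproduces the annotation.
#'
#' @param annotation A [genome_annotation()] object.
#' @param path Output path.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  tx <- annotation$transcripts
  f <- annotation$features
  tx_gene <- stats::setNames(tx$gene_id, tx$tx_id)
  g_seq <- stats::setNames(g$seqid, g$gene_id)
  g_strand <- stats::setNames(g$strand, g$gene_id)
  rows <- character(0)
  line <- function(seqid, type, start0, end0, strand, attrs) {
    paste(seqid, "tbphseq", type, start0 + 1L, end0, ".", strand, ".",
          attrs, sep = "\t")
  }
  for (i in seq_len(nrow(g))) {
    rows <- c(rows, line(g$seqid[i], "gene", g$start[i], g$end[i],
                         g$strand[i], paste0("ID=", g$gene_id[i])))
    for (t in tx$tx_id[tx$gene_id == g$gene_id[i]]) {
      ft <- f[f$tx_id == t, , drop = FALSE]
      t_start <- if (nrow(ft)) min(ft$start) else g$start[i]
      t_end <- if (nrow(ft)) max(ft$end) else g$end[i]
      rows <- c(rows, line(g$seqid[i], "mRNA", t_start, t_end, g$strand[i],
                           paste0("ID=", t, ";Parent=", g$gene_id[i])))
      type_map <- c(exon = "exon", five_prime_utr = "five_prime_UTR",
                    three_prime_utr = "three_prime_UTR")
      ft <- ft[order(ft$start), , drop = FALSE]
      for (j in seq_len(nrow(ft))) {
        rows <- c(rows, line(g$seqid[i], type_map[[ft$type[j]]], ft$start[j],
                             ft$end[j], g$strand[i], paste0("Parent=", t)))
      }
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Gene lengths from the collapsed exon-union model
#'
#' Length of each gene in bases as the size of the union of all exons across
#' that gene's transcripts; genes without exon records fall back to the gene
#' interval length.
#'
#' @param annotation A [genome_annotation()] object.
#' @return Named integer vector of lengths (bases), one per gene.
#' @export
gene_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  tx_gene <- stats::setNames(annotation$transcripts$gene_id,
                             annotation$transcripts$tx_id)
  ex <- annotation$features[annotation$features$type == "exon", , drop = FALSE]
  ex$gene_id <- unname(tx_gene[ex$tx_id])
  out <- stats::setNames(as.integer(g$end - g$start), g$gene_id)
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end))
    out[[gid]] <- sum(IRanges::width(ir))
  }
  out
}
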