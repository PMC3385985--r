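#' Configuration for the synthetic TBPH study
#'
#' Bundles every tunable of the ground-truthed generator. Defaults mirror
#' the design of the fly CNS study the pipeline targets: five genotypes
#' (control A1, null mutant G2, genetic rescue, D42>LacZ driver control,
#' D42>TBPH overexpression) with 3 replicates each except rescue (2);
#' planted differential expression skewed 3:1 upward in the knockout
#' contrast and 3:1 downward in the overexpression contrast; 44% of
#' knockout-DE genes fully rescued and 8% partially rescued; most planted
#' binding sites intronic; negative-binomial counts at low biological
#' dispersion; and a rescue cross of 4000 progeny per arm with 10% rescue
#' and 1% mutant survival against 1:2:1 Mendelian class frequencies.
#'
#' @param seed Integer seed (mandatory); generators derive their own
#'   sub-seeds from it so each stage is independently reproducible.
#' @param n_genes Number of genes in the toy genome.
#' @param genes_per_chrom Genes per synthetic chromosome.
#' @param exon_range,exon_len_range,intron_len_range Gene-structure ranges
#'   (counts and base lengths).
#' @param utr5_len,utr3_len UTR lengths carved from the terminal exons.
#' @param spacer Intergenic spacer length.
#' @param base_probs Background base composition (A, C, G, T).
#' @param gt_factor Multiplier suppressing the GT dinucleotide (and its
#'   minus-strand mirror AC) in the background Markov chain; 0 gives a
#'   motif-free background on both strands.
#' @param plant_rates 3 x 4 matrix (motif x feature class) of per-gene
#'   planting probabilities.
#' @param replicates Named integer vector: replicates per genotype.
#' @param log2_mean_range Range of baseline log2 mean counts.
#' @param dispersion Negative-binomial dispersion alpha (var = mu +
#'   alpha mu^2).
#' @param de_fraction Fraction of genes planted DE per contrast.
#' @param lfc_range Range of planted |log2 fold-change|.
#' @param up_fraction_ko,up_fraction_oe Fraction of planted DE genes that
#'   are upregulated in the knockout and overexpression contrasts.
#' @param rescue_fraction,partial_fraction Fractions of knockout-DE genes
#'   planted as fully and partially rescued.
#' @param partial_restore Fraction of the mutant log2 shift that partially
#'   rescued genes keep in the rescue genotype (default 0.4, strictly
#'   inside the partial-rescue classification region so planted labels are
#'   recoverable).
#' @param junction_depth Reads per sample over each gene's junctions.
#' @param switch_fraction Fraction of eligible (>= 3 exon) genes with a
#'   planted isoform switch per contrast.
#' @param iso_props Two-isoform mixing proportions in the reference state.
#' @param cross_total,cross_freqs,s_rescue,s_mutant,s_balancer Cross
#'   simulation truth: progeny per arm, Mendelian class frequencies, and
#'   class survival probabilities.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 200,
                             genes_per_chrom = 50,
                             exon_range = c(2L, 6L),
                             exon_len_range = c(100L, 300L),
                             intron_len_range = c(80L, 400L),
                             utr5_len = 40L, utr3_len = 60L,
                             spacer = 200L,
                             base_probs = c(A = 0.3, C = 0.2, G = 0.2,
                                            T = 0.3),
                             gt_factor = 0.2,
                             plant_rates = NULL,
                             replicates = c(A1 = 3L, G2 = 3L, rescue = 2L,
                                            D42_LacZ = 3L, D42_TBPH = 3L),
                             log2_mean_range = c(4, 10),
                             dispersion = 0.05,
                             de_fraction = 0.10,
                             lfc_range = c(1, 2.5),
                             up_fraction_ko = 0.75,
                             up_fraction_oe = 0.25,
                             rescue_fraction = 0.44,
                             partial_fraction = 0.08,
                             partial_restore = 0.4,
                             junction_depth = 1000L,
                             switch_fraction = 0.2,
                             iso_props = c(0.8, 0.2),
                             cross_total = 4000L,
                             cross_freqs = c(lethal = 0.25, balancer = 0.5,
                                             experimental = 0.25),
                             s_rescue = 0.10, s_mutant = 0.01,
                             s_balancer = 1) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(plant_rates)) {
    plant_rates <- matrix(
      rep(c(0.15, 0.03, 0.02, 0.04), each = 3), nrow = 3,
      dimnames = list(1:3, c("intron", "exon", "five_prime_utr",
                             "three_prime_utr")))
  }
  if (any(c(de_fraction, rescue_fraction, partial_fraction,
            partial_restore, switch_fraction, up_fraction_ko,
            up_fraction_oe, plant_rates) < 0) ||
      any(c(de_fraction, rescue_fraction, partial_fraction,
            partial_restore, switch_fraction, up_fraction_ko,
            up_fraction_oe, plant_rates) > 1)) {
    stop("fractions and rates must be in [0, 1]")
  }
  if (any(c(s_rescue, s_mutant, s_balancer) < 0) ||
      any(c(s_rescue, s_mutant, s_balancer) > 1)) {
    stop("survival probabilities must be in [0, 1]")
  }
  if (abs(sum(cross_freqs) - 1) > 1e-8) stop("cross_freqs must sum to 1")
  structure(as.list(environment()), class = "synthetic_config")
}

# Background sequence with tunable dinucleotide suppression: P(T | G) and
# its strand mirror P(C | A) are both multiplied by gt_factor, so spurious
# motif content is controlled symmetrically on the two strands.
markov_background <- function(n, base_probs, gt_factor) {
  bases <- names(base_probs)
  trans <- matrix(rep(base_probs, each = 4), nrow = 4,
                  dimnames = list(bases, bases))
  trans["G", "T"] <- trans["G", "T"] * gt_factor
  trans["A", "C"] <- trans["A", "C"] * gt_factor
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1, cumsum))
  out <- integer(n)
  u <- stats::runif(n)
  state <- sample.int(4, 1, prob = base_probs)
  out[1] <- state
  for (i in seq_len(n)[-1]) {
    state <- findInterval(u[i], cum[state, ]) + 1L
    out[i] <- state
  }
  paste(bases[out], collapse = "")
}

# A concrete instance of one motif, parameterized so an instance of one
# motif never contains a match of another (repeat counts kept below the
# thresholds where patterns start to nest).
motif_instance <- function(motif_id) {
  if (motif_id == 1) {
    paste0(strrep("GT", sample(3:4, 1)), strrep("T", sample(3:5, 1)))
  } else if (motif_id == 2) {
    paste0(strrep("GT", 2L), "GTA", strrep("TG", sample(3:4, 1)))
  } else {
    strrep("GT", sample(4:7, 1))
  }
}

#' Generate a toy genome with planted binding-site motifs
#'
#' Lays out genes (one transcript each, UTRs carved from the terminal
#' exons) along synthetic chromosomes, fills the background from a
#' GT-depleted Markov chain, and plants concrete motif instances into
#' randomly chosen features at the configured per-(motif, class) rates.
#' Each planted instance is flanked by neutral bases (CC before, AA after)
#' so the scanner recovers exactly the recorded span.
#'
#' @param config A [synthetic_config()].
#' @return list: `sequences` (named character vector), `annotation`
#'   ([genome_annotation()]), `truth` (data.frame of planted instances:
#'   gene_id, motif_id, feature_class, seqid, start, end, strand,
#'   instance).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% config$genes_per_chrom + 1L)

  genes <- list(); feats <- list(); txs <- list()
  cursor <- stats::setNames(rep(0L, length(unique(chrom_of))),
                            unique(chrom_of))
  for (i in seq_len(n)) {
    gid <- sprintf("gene%03d", i)
    chr <- chrom_of[i]
    n_ex <- sample(config$exon_range[1]:config$exon_range[2], 1)
    ex_len <- sample(config$exon_len_range[1]:config$exon_len_range[2],
                     n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) {
      sample(config$intron_len_range[1]:config$intron_len_range[2],
             n_ex - 1, replace = TRUE)
    } else integer(0)
    strand <- sample(c("+", "-"), 1)
    g_start <- cursor[[chr]] + config$spacer
    pos <- g_start
    ex <- matrix(0L, nrow = n_ex, ncol = 2)
    for (e in seq_len(n_ex)) {
      ex[e, ] <- c(pos, pos + ex_len[e])
      pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
    }
    g_end <- ex[n_ex, 2]
    cursor[[chr]] <- g_end
    tid <- paste0(gid, ".t1")
    genes[[i]] <- data.frame(gene_id = gid, seqid = chr, start = g_start,
                             end = g_end, strand = strand,
                             stringsAsFactors = FALSE)
    txs[[i]] <- data.frame(tx_id = tid, gene_id = gid,
                           stringsAsFactors = FALSE)
    f <- data.frame(tx_id = tid, type = "exon", start = ex[, 1],
                    end = ex[, 2], stringsAsFactors = FALSE)
    # 5'UTR at the transcription start: left end on +, right end on -
    if (n_ex >= 2) {
      if (strand == "+") {
        u5 <- c(ex[1, 1], ex[1, 1] + config$utr5_len)
        u3 <- c(ex[n_ex, 2] - config$utr3_len, ex[n_ex, 2])
      } else {
        u5 <- c(ex[n_ex, 2] - config$utr5_len, ex[n_ex, 2])
        u3 <- c(ex[1, 1], ex[1, 1] + config$utr3_len)
      }
      f <- rbind(f,
                 data.frame(tx_id = tid, type = "five_prime_utr",
                            start = u5[1], end = u5[2],
                            stringsAsFactors = FALSE),
                 data.frame(tx_id = tid, type = "three_prime_utr",
                            start = u3[1], end = u3[2],
                            stringsAsFactors = FALSE))
    }
    feats[[i]] <- f
  }
  genes <- do.call(rbind, genes)
  annotation <- genome_annotation(genes, do.call(rbind, txs),
                                  do.call(rbind, feats))

  chrom_len <- stats::setNames(cursor + config$spacer, names(cursor))
  sequences <- vapply(names(chrom_len), function(ch) {
    markov_background(chrom_len[[ch]], config$base_probs, config$gt_factor)
  }, character(1))

  # class intervals per gene for planting, after UTR/exon precedence
  class_intervals <- function(gid) {
    tid <- paste0(gid, ".t1")
    f <- annotation$features[annotation$features$tx_id == tid, ,
                             drop = FALSE]
    iv <- list()
    utr <- f[f$type != "exon", , drop = FALSE]
    for (j in seq_len(nrow(utr))) {
      iv[[length(iv) + 1L]] <- list(class = utr$type[j],
                                    start = utr$start[j], end = utr$end[j])
    }
    ex <- f[f$type == "exon", , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      s <- ex$start[j]; e <- ex$end[j]
      for (k in seq_len(nrow(utr))) {   # carve UTRs out of the exon body
        if (utr$start[k] <= s && utr$end[k] > s) s <- utr$end[k]
        if (utr$end[k] >= e && utr$start[k] < e) e <- utr$start[k]
      }
      if (e > s) iv[[length(iv) + 1L]] <- list(class = "exon",
                                               start = s, end = e)
    }
    introns <- annotation$introns[annotation$introns$tx_id == tid, ,
                                  drop = FALSE]
    for (j in seq_len(nrow(introns))) {
      iv[[length(iv) + 1L]] <- list(class = "intron",
                                    start = introns$start[j],
                                    end = introns$end[j])
    }
    iv
  }

  truth <- list()
  classes <- colnames(config$plant_rates)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    chr <- genes$seqid[i]
    iv <- class_intervals(gid)
    occupied <- matrix(numeric(0), ncol = 2)
    for (m in 1:3) {
      for (cl in classes) {
        if (stats::runif(1) >= config$plant_rates[m, cl]) next
        inst <- motif_instance(m)
        need <- nchar(inst) + 8L   # CC/AA flanks plus 2-base class margin
        of_class <- Filter(function(x) x$class == cl, iv)
        if (!length(of_class)) next   # gene has no feature of this class
        cand <- Filter(function(x) (x$end - x$start) >= need, of_class)
        if (!length(cand)) {
          stop("feature of class ", cl, " too short for motif ", m,
               " in gene ", gid)
        }
        placed <- FALSE
        for (try in 1:10) {
          f1 <- cand[[sample.int(length(cand), 1)]]
          off <- sample(0:(f1$end - f1$start - need), 1)
          s <- f1$start + off + 4L        # genomic start of the instance
          e <- s + nchar(inst)
          if (nrow(occupied) &&
              any(occupied[, 1] < e + 2 & occupied[, 2] > s - 2)) next
          seq_chr <- sequences[[chr]]
          substr(seq_chr, s - 1L, e + 2L) <- paste0("CC", inst, "AA")
          sequences[[chr]] <- seq_chr
          occupied <- rbind(occupied, c(s - 2, e + 2))
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = gid, motif_id = m, feature_class = cl, seqid = chr,
            start = s, end = e, strand = "+", instance = inst,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) next   # crowded gene; planting skipped this cell
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), motif_id = integer(0),
               feature_class = character(0), seqid = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               instance = character(0))
  list(sequences = sequences, annotation = annotation, truth = truth)
}

sample_exact <- function(x, size) {
  if (size <= 0) return(x[0])
  x[sample.int(length(x), size)]
}

#' Generate gene-level count matrices with planted DE and rescue structure
#'
#' Negative-binomial counts around genotype-specific means. Knockout-DE
#' genes shift the mutant mean by the planted log2 fold-change;
#' overexpression-DE genes shift the D42>TBPH mean; rescued genes revert to
#' the control mean in the rescue genotype, partially rescued genes revert
#' halfway (on the log2 scale), unrescued genes keep the mutant mean.
#'
#' @param config A [synthetic_config()].
#' @param gene_ids Gene ids; default `gene001` style matching
#'   [generate_genome()] under the same config.
#' @return list: `counts` (a `count_matrix`), `design` (sample design
#'   data.frame), `truth` (per-gene data.frame with de_ko, lfc_ko,
#'   direction_ko, rescue_status, de_oe, lfc_oe, direction_oe).
#' @export
generate_counts <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(n))
  stopifnot(length(gene_ids) == n)

  reps <- config$replicates
  design <- data.frame(
    sample_id = unlist(lapply(names(reps), function(g) {
      paste0(g, "_r", seq_len(reps[[g]]))
    })),
    genotype = rep(names(reps), reps),
    replicate = unlist(lapply(reps, seq_len)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  mu0 <- 2^stats::runif(n, config$log2_mean_range[1],
                        config$log2_mean_range[2])
  n_de <- round(config$de_fraction * n)
  if (config$de_fraction > 0 && n_de < 1) {
    warning("de_fraction too small for n_genes; zero DE genes planted")
    n_de <- 0L
  }
  plant_contrast <- function(up_fraction) {
    idx <- sample_exact(seq_len(n), n_de)
    lfc <- rep(0, n)
    if (n_de > 0) {
      n_up <- round(up_fraction * n_de)
      sgn <- rep(c(1, -1), c(n_up, n_de - n_up))
      lfc[idx] <- sgn * stats::runif(n_de, config$lfc_range[1],
                                     config$lfc_range[2])
    }
    list(de = seq_len(n) %in% idx, lfc = lfc)
  }
  ko <- plant_contrast(config$up_fraction_ko)
  oe <- plant_contrast(config$up_fraction_oe)

  rescue_status <- rep(NA_character_, n)
  de_idx <- which(ko$de)
  n_resc <- round(config$rescue_fraction * length(de_idx))
  n_part <- round(config$partial_fraction * length(de_idx))
  shuffled <- sample(de_idx)
  status <- rep("not_rescued", length(de_idx))
  status[seq_len(n_resc)] <- "rescued"
  if (n_part > 0) status[n_resc + seq_len(n_part)] <- "partial"
  rescue_status[shuffled] <- status

  mu <- cbind(
    A1 = mu0,
    G2 = mu0 * 2^ko$lfc,
    rescue = mu0 * 2^ifelse(is.na(rescue_status), 0,
                            ifelse(rescue_status == "rescued", 0,
                                   ifelse(rescue_status == "partial",
                                          config$partial_restore * ko$lfc,
                                          ko$lfc))),
    D42_LacZ = mu0,
    D42_TBPH = mu0 * 2^oe$lfc
  )
  size <- 1 / config$dispersion
  counts <- sapply(seq_len(nrow(design)), function(j) {
    stats::rnbinom(n, mu = mu[, design$genotype[j]], size = size)
  })
  dimnames(counts) <- list(gene_ids, design$sample_id)

  truth <- data.frame(
    gene_id = gene_ids,
    de_ko = ko$de, lfc_ko = ko$lfc,
    direction_ko = ifelse(ko$de, ifelse(ko$lfc > 0, "up", "down"),
                          NA_character_),
    rescue_status = rescue_status,
    de_oe = oe$de, lfc_oe = oe$lfc,
    direction_oe = ifelse(oe$de, ifelse(oe$lfc > 0, "up", "down"),
                          NA_character_),
    stringsAsFactors = FALSE
  )
  list(counts = count_matrix(counts), design = design, truth = truth)
}

# Two-isoform model per gene: isoform 1 skips exon 3, isoform 2 skips
# exon 2 (mutually exclusive internal exons); for 3-exon genes the
# isoforms are exons {1,2} and {1,3}.
gene_isoforms <- function(n_ex) {
  if (n_ex == 3) list(c(1L, 2L), c(1L, 3L))
  else list(setdiff(seq_len(n_ex), 3L), setdiff(seq_len(n_ex), 2L))
}

#' Generate exon and junction count tables with planted isoform switches
#'
#' Each eligible gene (>= 3 exons) expresses two isoforms that differ in a
#' pair of mutually exclusive internal exons. Reference genotypes mix the
#' isoforms at `iso_props`; switch genes have the proportions reversed in
#' the mutant (and, for an independently drawn set, in the overexpression
#' genotype), while the rescue genotype returns to reference proportions.
#' Per sample, `junction_depth` reads are distributed multinomially across
#' isoforms; exon counts and junction counts are then tallied from the
#' isoform structure.
#'
#' @param config A [synthetic_config()].
#' @param annotation [genome_annotation()] from [generate_genome()] (fixes
#'   exon counts per gene).
#' @return list: `exon_tab` (gene_id, exon_index, one column per sample),
#'   `junction_tab` (gene_id, donor, acceptor, one column per sample),
#'   `design`, `truth` (gene_id, eligible, switch_ko, switch_oe).
#' @export
generate_junctions <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(annotation, "genome_annotation"))
  if (config$junction_depth < 1) stop("junction depth must be >= 1")
  set.seed(config$seed + 2L)
  reps <- config$replicates
  design <- data.frame(
    sample_id = unlist(lapply(names(reps), function(g) {
      paste0(g, "_r", seq_len(reps[[g]]))
    })),
    genotype = rep(names(reps), reps),
    replicate = unlist(lapply(reps, seq_len)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ex_per_gene <- table(annotation$transcripts$gene_id[
    match(annotation$features$tx_id[annotation$features$type == "exon"],
          annotation$transcripts$tx_id)])
  genes <- annotation$genes$gene_id
  n_ex <- as.integer(ex_per_gene[genes])
  eligible <- genes[!is.na(n_ex) & n_ex >= 3]
  n_switch <- round(config$switch_fraction * length(eligible))
  switch_ko <- sample_exact(eligible, n_switch)
  switch_oe <- sample_exact(eligible, n_switch)

  exon_rows <- list(); junc_rows <- list()
  for (gid in eligible) {
    E <- n_ex[match(gid, genes)]
    isos <- gene_isoforms(E)
    juncs <- unique(do.call(rbind, lapply(isos, function(ex) {
      if (length(ex) < 2) return(NULL)
      cbind(ex[-length(ex)], ex[-1])
    })))
    p_ref <- config$iso_props
    p_of <- function(genotype) {
      sw <- (genotype == "G2" && gid %in% switch_ko) ||
        (genotype == "D42_TBPH" && gid %in% switch_oe)
      if (sw) rev(p_ref) else p_ref
    }
    ex_mat <- matrix(0L, nrow = E, ncol = nrow(design))
    ju_mat <- matrix(0L, nrow = nrow(juncs), ncol = nrow(design))
    for (j in seq_len(nrow(design))) {
      iso_reads <- as.integer(stats::rmultinom(1, config$junction_depth,
                                               p_of(design$genotype[j])))
      for (ii in seq_along(isos)) {
        ex_mat[isos[[ii]], j] <- ex_mat[isos[[ii]], j] + iso_reads[ii]
        ex_iso <- isos[[ii]]
        for (k in seq_len(length(ex_iso) - 1)) {
          row <- which(juncs[, 1] == ex_iso[k] & juncs[, 2] == ex_iso[k + 1])
          ju_mat[row, j] <- ju_mat[row, j] + iso_reads[ii]
        }
      }
    }
    colnames(ex_mat) <- design$sample_id
    colnames(ju_mat) <- design$sample_id
    exon_rows[[gid]] <- cbind(
      data.frame(gene_id = gid, exon_index = seq_len(E),
                 stringsAsFactors = FALSE),
      as.data.frame(ex_mat))
    junc_rows[[gid]] <- cbind(
      data.frame(gene_id = gid, donor = juncs[, 1], acceptor = juncs[, 2],
                 stringsAsFactors = FALSE),
      as.data.frame(ju_mat))
  }
  truth <- data.frame(
    gene_id = genes,
    eligible = genes %in% eligible,
    switch_ko = genes %in% switch_ko,
    switch_oe = genes %in% switch_oe,
    stringsAsFactors = FALSE
  )
  list(exon_tab = do.call(rbind, c(exon_rows, make.row.names = FALSE)),
       junction_tab = do.call(rbind, c(junc_rows, make.row.names = FALSE)),
       design = design, truth = truth)
}

#' Simulate cross progeny counts with known survival probabilities
#'
#' Each arm draws class totals from a multinomial over the Mendelian
#' frequencies and adult survivors from per-class binomials.
#'
#' @param config A [synthetic_config()].
#' @return list: `cross` (a `cross_counts` object) and `truth` (total
#'   progeny per arm, class survival probabilities, true ratio).
#' @export
generate_cross <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 3L)
  arm <- function(s_exp) {
    classes <- as.integer(stats::rmultinom(1, config$cross_total,
                                           config$cross_freqs))
    c(balancer = stats::rbinom(1, classes[2], config$s_balancer),
      survivors = stats::rbinom(1, classes[3], s_exp))
  }
  r <- arm(config$s_rescue)
  m <- arm(config$s_mutant)
  list(
    cross = cross_counts(r[["balancer"]], r[["survivors"]],
                         m[["balancer"]], m[["survivors"]],
                         freqs = config$cross_freqs),
    truth = list(total = config$cross_total,
                 s_rescue = config$s_rescue, s_mutant = config$s_mutant,
                 s_balancer = config$s_balancer,
                 ratio = config$s_rescue / config$s_mutant)
  )
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_genome()], [generate_counts()],
#' [generate_junctions()] and [generate_cross()] under one config.
#'
#' @param config A [synthetic_config()].
#' @return list with elements genome, counts, junctions, cross.
#' @export
simulate_study <- function(config) {
  genome <- generate_genome(config)
  counts <- generate_counts(config,
                            gene_ids = genome$annotation$genes$gene_id)
  junctions <- generate_junctions(config, genome$annotation)
  cross <- generate_cross(config)
  list(genome = genome, counts = counts, junctions = junctions,
       cross = cross)
}
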