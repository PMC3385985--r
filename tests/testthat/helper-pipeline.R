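# Full seeded pipeline run writing every stage's outputs as text files;
# used by the determinism test and mirrored by the analysis drivers.
run_full_pipeline <- function(out_dir, seed, n_genes = 80) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- synthetic_config(seed = seed, n_genes = n_genes)
  st <- simulate_study(cfg)
  out <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                            quote = FALSE,
                                            row.names = FALSE)

  write_fasta(st$genome$sequences, out("genome.fa"))
  write_gff3(st$genome$annotation, out("genes.gff3"))
  write_count_table(st$counts$counts, out("gene_counts.tsv"))
  write_sample_design(st$counts$design, out("design.tsv"))

  ht <- annotate_gene_hits(st$genome$annotation, st$genome$sequences)
  write_bed_hits(ht$hits, out("motif_hits.bed"))
  tsv(ht$by_class, "gene_hits.tsv")
  tsv(distribution_summary(ht), "hit_distribution.tsv")

  expr <- compute_rpkm(st$counts$counts, st$genome$annotation)
  d <- st$counts$design
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    df
  }
  de_ko <- differential_expression(expr, genotype_samples(d, "G2"),
                                   genotype_samples(d, "A1"),
                                   hit_table = ht)
  de_rs <- differential_expression(expr, genotype_samples(d, "rescue"),
                                   genotype_samples(d, "A1"))
  de_oe <- differential_expression(expr, genotype_samples(d, "D42_TBPH"),
                                   genotype_samples(d, "D42_LacZ"),
                                   hit_table = ht)
  tsv(fmt(de_ko), "de_knockout.tsv")
  tsv(fmt(de_oe), "de_overexpression.tsv")
  tsv(fmt(classify_rescue(de_ko, de_rs)), "rescue_classes.tsv")
  ov <- overlap_summary(de_ko, de_oe)
  tsv(data.frame(n_a = ov$n_a, n_b = ov$n_b,
                 n_intersect = ov$n_intersect,
                 n_same = ov$n_same_direction,
                 n_opposite = ov$n_opposite_direction), "overlap.tsv")

  sc <- splice_screen(st$junctions$exon_tab, st$junctions$design,
                      "G2", "A1", hit_table = ht)
  tsv(fmt(sc), "splice_index.tsv")

  fit <- fit_rescue_model(st$cross$cross, draws = 1e4, seed = seed + 7L)
  tsv(fmt(as.data.frame(fit$summary)), "rescue_model.tsv")
  invisible(out_dir)
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)), basename(files))
}
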