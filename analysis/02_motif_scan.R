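#!/usr/bin/env Rscript
# Scan every gene region for the three TDP-43 binding-site motifs, class
# each hit by gene feature, and summarize the genomic distribution of
# predicted target genes. Checks recall against the planted truth.

suppressMessages(library(tbphseq))

out <- "results/study"
seqs <- read_fasta(file.path(out, "genome.fa"))
ann <- read_gff3(file.path(out, "genes.gff3"), sequences = seqs)
truth <- read.delim(file.path(out, "truth_motifs.tsv"))

ht <- annotate_gene_hits(ann, seqs)
write_bed_hits(ht$hits, file.path(out, "motif_hits.bed"))
write.table(ht$by_class, file.path(out, "gene_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ds <- distribution_summary(ht)
write.table(ds, file.path(out, "hit_distribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

h <- ht$hits
recovered <- vapply(seq_len(nrow(truth)), function(i) {
  any(h$gene_id == truth$gene_id[i] & h$start == truth$start[i] &
      h$end == truth$end[i] & h$motif_id == truth$motif_id[i] &
      h$feature_class == truth$feature_class[i])
}, logical(1))

cat(sprintf(
  "Motif scan: %d hits in %d of %d genes (%.0f%% with a predicted site);
planted-instance recall %.3f (%d instances). Intronic hits dominate:
%.0f%% of gene-level (motif, class) calls are intronic, as expected for
UG-repeat sites.\n",
  nrow(h), sum(ht$has_site), length(ht$has_site),
  100 * mean(ht$has_site), mean(recovered), nrow(truth),
  100 * sum(ds$n_genes[ds$feature_class == "intron"]) / sum(ds$n_genes)))
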