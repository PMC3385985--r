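#!/usr/bin/env Rscript
# Binding-site enrichment in the DE sets against the expressed-gene
# background, in the style of the published genome-scale contingency
# analysis, plus the same computation on the published counts themselves.

suppressMessages(library(tbphseq))

out <- "results/study"
design <- read_sample_design(file.path(out, "design.tsv"))
de_ko <- read.delim(file.path(out, "de_knockout.tsv"))
ht_tab <- read.delim(file.path(out, "gene_hits.tsv"))

background <- de_ko$gene_id[de_ko$tested]
marked <- unique(ht_tab$gene_id)
query <- de_ko$gene_id[de_ko$significant]
r <- set_enrichment(k = length(intersect(query, marked)),
                    n = length(query),
                    K = length(intersect(background, marked)),
                    N = length(background))
write.table(data.frame(N = r$N, K = r$K, n = r$n, k = r$k, fold = r$fold,
                       p = r$p, log10_p = r$log10_p),
            file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf(
  "Binding sites among knockout-DE genes: %d of %d vs background %d of
%d; fold %.2f, upper-tail hypergeometric p = %.3g.\n",
  r$k, r$n, r$K, r$N, r$fold, r$p))

# the published genome-scale tables, recomputed with the same machinery;
# agreement is expected in order of magnitude only, since the original
# test is unnamed
pub <- list(
  c(k = 3018, n = 3742, K = 7897, N = 15065),  # targets expressed in CNS
  c(k = 400,  n = 910,  K = 3001, N = 7897))   # sites among DE genes
for (tab in pub) {
  e <- set_enrichment(tab[["k"]], tab[["n"]], tab[["K"]], tab[["N"]])
  cat(sprintf(
    "Published counts k=%d n=%d K=%d N=%d: p = %.3g (log10 p = %.1f).\n",
    tab[["k"]], tab[["n"]], tab[["K"]], tab[["N"]], e$p, e$log10_p))
}
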