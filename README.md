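# tbphseq

An R package re-implementing, as a tested and reusable pipeline, the
computational analysis of a TBPH (the *Drosophila* ortholog of human
TDP-43, the ALS/FTLD RNA-binding protein) loss-of-function versus
overexpression RNA-seq study: motif-based binding-site prediction,
RPKM differential expression with genetic-rescue classification,
splice-index and beta-binomial exon-junction statistics, set enrichment
with a custom background, and a Bayesian model of genetic-rescue
survival. It is written for computational biologists who want the
statistical machinery of such a study as callable, property-tested
functions, exercised end to end on synthetic data with known ground
truth rather than on any particular sequencing run.

## What it computes

**Binding-site prediction.** Gene regions are scanned double-stranded
for the three published TDP-43 site classes, as DNA-level regular
expressions: `(GT){3,}T{3,}` ((UG)<sub>m</sub>U<sub>n</sub>),
`(GT){2,}(GTA){1}(TG){3,}` ((UG)<sub>m</sub>UA(UG)<sub>n</sub>), and
`(GT){4,}` not followed by `T{3,}` ((UG)<sub>n</sub>). Hits are
attributed to introns, exons, 5′UTRs or 3′UTRs and summarized per gene.

**Differential expression.** RPKM = reads / (gene kb × mapped reads in
millions), analysed as log2 values; genes with a mean of ≥ 10 reads in
at least one genotype are tested by a two-sided two-sample t-test, with
Benjamini–Hochberg adjusted p-values reported alongside raw ones.
Mutant-DE genes are classified as rescued, partially rescued, or not
rescued from the rescue-vs-control comparison.

**Splicing.** A per-gene splice index — the product-moment correlation
of relative exon usage between genotypes (≥ 200 reads each) — flags
candidates below 0.7 that carry a predicted binding site. Individual
exon–exon junctions are modelled as binomial proportions with a Jeffreys
beta(1/2, 1/2) prior and compared between genotypes by
P(θ<sub>A</sub> > θ<sub>B</sub>) under two failure definitions
(alternate-acceptor junctions, or all other junctions of the gene).

**Enrichment.** One-sided hypergeometric upper tail
P(X ≥ k | n, K, N) in log space, so genome-scale tables (p down to
10<sup>−369</sup> and beyond) keep a finite log10 p.

**Rescue survival.** From cross progeny counts, a conjugate Monte Carlo
model (Dirichlet-constrained Mendelian frequencies; total progeny from
the balancer-adult count via the normal approximation to the binomial;
Jeffreys beta-binomial survival per arm) yields the posterior of the
rescue:mutant survival-probability ratio ρ with credible intervals.

## Worked example

The `analysis/` directory holds numbered drivers that run the full study
on a seeded synthetic dataset (`STUDY_SEED`, default 42), writing tables
under `results/study/`. `Rscript analysis/01_simulate.R` followed by
`Rscript analysis/02_motif_scan.R` prints:

```
Simulated study (seed 42): 200 genes on 4 chromosomes, 153 planted motif
instances, 14 samples, 20 planted knockout-DE genes, 32 splice-switch
genes, cross of 4000 progeny per arm (true survival ratio 10).
Motif scan: 153 hits in 111 of 200 genes (56% with a predicted site);
planted-instance recall 1.000 (153 instances).
```

Recall 1.000 means every planted motif instance was recovered at its
exact genomic span, motif and feature class. Continuing with
`03_differential_expression.R` through `06_rescue_cross.R` runs the DE
contrasts and rescue classification, the splice screen and junction
posteriors, the enrichment tables, and the survival model, ending with:

```
Cross: rescue arm 104 survivors / 1981 balancer adults; mutant arm 9 /
1996. Posterior survival-ratio median 11.5, 95% credible interval
[5.8, 25.4], one-sided lower bound 6.4 (true simulated ratio 10)
```

i.e. from adult counts alone the model recovers the simulated truth
(ρ = 10) inside its credible interval and states the ">x:1 at 95%
confidence" style bound (here ρ > 6.4).

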