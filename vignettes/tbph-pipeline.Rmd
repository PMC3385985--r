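---
title: "Models and methods of the tbphseq pipeline"
author: "tbphseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the tbphseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbphseq)
```

# The biological problem

TDP-43 is an RNA-binding protein central to ALS and FTLD pathology; its
*Drosophila* ortholog TBPH binds UG-repeat RNA through two RNA-recognition
motifs. A standard experimental design for dissecting its function in the
larval CNS contrasts five genotypes: a control excision line (A1), a TBPH
null (G2), a genetic rescue (G2 with TBPH re-expressed from its own
promoter region), a GAL4 driver control (D42>LacZ), and motor-neuron
overexpression (D42>TBPH). `tbphseq` implements the computational side of
such a study as reusable, tested functions:

1. prediction of candidate TBPH target genes by UG-motif scanning of a
   genome annotation;
2. RPKM-based differential expression (DE) between genotypes, with
   genetic-rescue classification of mutant DE genes;
3. a splice-index screen and a beta-binomial posterior comparison of
   exon--exon junction usage;
4. hypergeometric set enrichment against a custom (tissue-expressed)
   background;
5. a conjugate Bayesian model of the rescue:mutant survival-probability
   ratio from cross progeny counts.

Because the original sequencing data are not required for any of the
statistical machinery, the package ships a synthetic-data generator that
emulates the study design with fully known ground truth; every stage is
exercised end to end against that truth.

# Motif scanning

Three DNA-level patterns encode the published TDP-43 site classes
(U is T at the DNA level):

| motif | pattern | site class | min length |
|---|---|---|---|
| 1 | `(GT){3,}T{3,}` | (UG)mUn | 9 |
| 2 | `(GT){2,}(GTA){1}(TG){3,}` | (UG)mUA(UG)n | 13 |
| 3 | `(GT){4,}` not followed by `T{3,}` | (UG)n | 8 |

Motif 3 as printed in the source literature carries the tail
`[^T{3,}]`, which is not a valid character class; we read the intent as
"a pure UG run that does not trail into a U-tract" (that situation is
motif 1's) and implement it as a negative lookahead. One consequence of
lookahead-plus-backtracking semantics, adopted deliberately: a run of
five or more GT units followed by `TTT` still yields a motif-3 match of
all but its last GT unit, because the shortened match no longer abuts the
T-tract. Matches are greedy/maximal and non-overlapping within a motif;
different motifs may overlap (gene-level deduplication makes this
immaterial for the distribution summaries).

Gene regions are scanned **double-stranded**: the minus strand is handled
by scanning the reverse complement with the forward patterns and
mirroring the spans, which is equivalent to applying reverse-complement
patterns to the forward text and makes strand symmetry exact by
construction. Single-stranded molecules (mRNAs, excised introns) use
`forward_only`. For a minus-strand gene, the sites on the transcribed
molecule are exactly the minus-strand genomic hits, so the double-stranded
gene-region scan covers the RNA-level search; the gene span (rather than
concatenated transcript features) is the scanned region.

Each hit is assigned a feature class (intron, exon, 5'UTR, 3'UTR) from
the transcript models: bases get classes with precedence UTR > exon >
intron across transcripts, a boundary-spanning hit takes the majority
class of its bases, and ties go to intron (introns dominate UG content,
so the tie rule is the conservative attribution). `N` bases never match.
Genes with several hits count once per (motif, class) cell in the
distribution summary.

Correctness is anchored to two independent oracles in the test suite: a
run-length analyser that derives the unique maximal decomposition of each
candidate site, and (for tiny inputs) exhaustive substring enumeration
over all repeat decompositions. The scanner must agree with both on
thousands of random sequences, including GT-rich compositions designed to
stress overlap handling.

# Expression and differential expression

Expression is quantified as RPKM: reads per kilobase of gene model per
million mapped reads, analysed throughout as log2 values. Gene length is
the collapsed union of exons across transcripts. Per-sample totals
default to the column sums of the gene-level table but can be supplied
explicitly, because "mapped reads" may legitimately include non-exonic
mappings; the choice matters. With strongly asymmetric planted effects
and column-sum totals, composition bias shifts every null gene's RPKM in
the opposite direction — the classical argument for scaling-factor
normalization, which this RPKM-faithful pipeline deliberately does not
apply. The calibration and recovery analyses therefore fix library
totals where isolating test behaviour from composition effects is the
point. Zero counts are floored on the log2 scale at half the smallest
positive RPKM in the matrix (configurable), which keeps zeros strictly
below all observed values without producing infinities; such genes
rarely pass the testing filter anyway.

Genes are tested only if their mean raw count reaches 10 reads in at
least one genotype of the pair. Tested genes get a two-sided two-sample
t-test on log2 RPKM. We use the pooled-variance Student test rather than
the Welch variant: at n = 3 the Welch degrees-of-freedom approximation is
measurably conservative (null rejection at nominal 0.05 runs near 0.035),
while the pooled test holds its size on the generator's equal-variance
groups — and exact size at the nominal level is one of this pipeline's
acceptance properties. Significance is raw p < alpha (default 0.05);
Benjamini–Hochberg adjusted p-values over the tested genes are reported
alongside, mirroring the dual raw/adjusted reporting convention of the
original analysis (the adjusted values stand in for the edgeR-adjusted
values there; the edgeR dispersion machinery itself is out of scope).
Direction is the sign of the group-A-minus-group-B mean difference, and
a 2-fold flag marks |log2FC| >= 1.

At these settings the detection rate for a planted one-unit log2 shift at
negative-binomial dispersion 0.05 with n = 3 vs 3 is about 0.8 (the
acceptance script computes it each run); unit shifts at triplicate
sampling sit on the edge of detectability, which is worth remembering
when interpreting DE counts from designs of this size.

## Rescue classification

For genes DE in mutant-vs-control, the rescue-vs-control comparison
partitions them:

* **rescued** — no longer significant in rescue vs control;
* **partial** — still significant, same direction, but with
  |log2FC_rescue| <= (1 − rho)·|log2FC_mutant| (rho = 0.5 by default:
  at least half the effect undone);
* **not_rescued** — everything else.

The partial rule is an operational definition of this package ("partially
rescued" has no standard quantitative meaning). Genes untested in the
rescue comparison count as not significant there. Note the interaction
with the synthetic truth: the generator restores partially rescued genes
to 40% of the mutant shift rather than exactly 50%, because a planted
value sitting exactly on the classification boundary is unrecoverable in
the presence of any measurement noise; 40% leaves margin on both sides
(still significant vs control, comfortably below the partial ceiling).

# Splicing

## Splice index

The per-gene splice index is the product-moment correlation between two
genotypes' relative exon-usage vectors (per-exon counts over the gene
total, replicates pooled by summation — the comparison is between
genotypes, not replicates). This reconstructs the "correlation
coefficient" index of the commercial analysis platform used in the
original study, whose exact formula is proprietary; the product-moment
correlation of usage proportions is the documented stand-in. An index
near 1 means proportional exon usage; values below 0.7 in a gene with a
predicted binding site and at least 200 reads in each genotype flag a
splicing candidate. Degenerate cases: under 2 exons, or exactly one
constant proportion vector, are "not assessable"; two constant vectors
are trivially identical (index 1).

One structural caveat: a single differentially used exon cannot depress
the index, because two vectors differing in one coordinate are always
perfectly correlated. The synthetic generator therefore plants
*mutually exclusive* exon pairs (isoform 1 skips exon 3, isoform 2 skips
exon 2), which is also the event type the index detects best in real
data; single-cassette-exon changes are better caught by the junction
model below.

## Junction posteriors

For a junction of interest, successes are its read counts; failures are
either the counts of junctions sharing its donor exon but landing on an
alternate acceptor (`alternate_second`) or all other junctions of the
gene (`all_other`) — both published failure definitions are implemented.
Each genotype's usage proportion theta gets a Jeffreys beta(1/2, 1/2)
prior, chosen because junction usage tends to be either rare or dominant,
and the conjugate posterior beta(s + 1/2, f + 1/2). Two genotypes are
compared by P(theta_A > theta_B), computed by adaptive quadrature of
the integral of f_A(x) F_B(x) (relative tolerance 1e-8, well inside the
0.005 Monte-Carlo agreement the acceptance properties demand), reported
together with the symmetric two-sided value 2·min(P, 1 − P). Because the
phrase "the P value for a binomial event" admits a one-sample reading,
the posterior tail P(theta >= theta0) is also exposed (`beta_tail`).

# Set enrichment

Enrichment of a marked set in a query against a custom background is the
upper tail of the hypergeometric law, P(X >= k) for n draws from N
containing K marked — the one-sided Fisher exact test. The tail is an
exact summation of log-space binomial coefficients combined by
log-sum-exp, so genome-scale tables with astronomically small tails
return finite log10 p (the 15,065-gene configuration with 7,897
expressed and 3,742 predicted targets, 3,018 of them expressed, lands
near log10 p = −369). Always supplying the tissue-expressed background
rather than the whole genome is the guard against expression bias the
original analysis used (its 7,897-gene control-expressed background).
The original study does not name its test; recomputing on its printed
2x2 counts reproduces the printed P values in order of magnitude (and,
for the DE-by-binding-site table, nearly exactly), which is documented
here but never asserted as equality.

# The rescue survival model

The genetic cross behind the rescue experiment produces three progeny
classes at theoretical Mendelian frequencies 1:2:1 — balancer
homozygotes (lethal, never observed), balancer-marked heterozygotes
(viable nonmutants carrying the dominant marker), and the experimental
class (rescue genotype in one arm, unrescued mutant in the other). Only
adults are counted, so the total progeny of each arm is latent. Per
Monte Carlo draw:

1. class frequencies f are drawn from a Dirichlet prior centred on
   (1/4, 1/2, 1/4) with concentration 500, making the prior sd of the
   1/4 class about 2% — "within a few percent" of Mendelian expectation;
2. the arm's total progeny T is estimated from its balancer-adult count
   B through the normal approximation to the binomial,
   T ~ Normal(B/p, sqrt(B(1−p))/p) with p = f_bal·s_bal (balancer
   survival s_bal defaults to 1, configurable);
3. the implied experimental-class size round(T·f_exp) and the observed
   survivor count feed a Jeffreys beta-binomial update of that arm's
   survival probability;
4. the ratio rho = s_rescue/s_mutant is recorded.

The model as described is conjugate given T, so 10^5 plain Monte Carlo
draws over the conjugate updates replace general MCMC exactly and fast;
summaries are the posterior median, an equal-tailed credible interval,
and the one-sided lower credible bound (the ">x:1 ratio at 95%
confidence" style of statement). With no survivors in either arm the
ratio posterior is log-symmetric about 1, as it should be. Calibration
is checked by simulation: across 200 simulated crosses of 4,000 progeny
per arm with true ratio 10, the 95% interval covers the truth at a rate
statistically compatible with 0.95.

# The synthetic study

The generator is the package's definition of the study conditions, not a
tuning knob. Defaults: 200 genes (one transcript each, 2–6 exons,
UTRs carved from terminal exons) on chromosomes of 50 genes; background
sequence from a first-order Markov chain in which the GT dinucleotide
and its strand mirror AC are suppressed fivefold, keeping spurious motif
content low but nonzero on both strands (setting the factor to 0 gives a
provably motif-free background); planted motif instances at
per-(motif, class) rates favouring introns, each flanked by neutral CC/AA
bases so the scanner must recover the exact recorded span; instance
repeat counts are capped so no planted instance of one motif contains a
match of another. Counts are negative-binomial (var = mu + alpha·mu^2,
alpha = 0.05 — low biological noise at triplicate scale) around
genotype-specific means: 10% of genes DE per contrast, 3:1 up in the
knockout and 3:1 down in the overexpression contrast (the asymmetry the
fly study reported), |log2FC| uniform on [1, 2.5]; of knockout-DE genes
44% fully rescued, 8% partially (40% of the shift retained, see above).
Junction data: eligible (>= 3-exon) genes express two isoforms differing
in mutually exclusive exons at 0.8/0.2 proportions, reversed in switch
genes (20% of eligible genes per contrast), 1,000 reads per sample
distributed multinomially. Crosses: 4,000 progeny per arm, survival 0.10
(rescue), 0.01 (mutant), 1 (balancer).

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: GC and length biases, positional read
coverage, shared dispersion structure across genes, correlated
replicates, batch effects, isoform complexity beyond two isoforms,
unannotated junctions, and real genome repeat structure. The pipeline's
statistical guarantees (scanner exactness, test calibration, posterior
correctness, label recovery under strong effects) are exactly the
properties that survive this idealization.

## Problem sizes and reproducibility

The shipped analyses use deliberately desk-scale sizes: 200-gene genomes
for scanning and splicing, 2,000 genes for DE calibration and power, 150
genes with four replicates for rescue-label recovery, 200 simulated
crosses at 10^4 draws (10^5 for single fits) for the survival model.
Every generator takes a mandatory seed and derives per-stage sub-seeds,
so a full pipeline run is byte-identical across repetitions; the
`analysis/` drivers honour `STUDY_SEED` and `scripts/acceptance.R`
derives everything from `--seed`.

# Known limitations

* RPKM without scaling-factor normalization inherits composition bias
  under asymmetric regulation; totals are configurable precisely so a
  user can supply externally mapped totals.
* The pooled t-test assumes equal group variances; with real
  heteroskedastic data at larger n, a Welch or moderated test would be
  the safer default.
* The splice index is blind to single-exon usage changes (see above) and
  the 0.7 cutoff is inherited from the original screen, not re-derived.
* The enrichment test conditions on fixed set sizes; it is not a
  substitute for annotation-clustering tools, which are deliberately out
  of scope.
* The survival model's normal approximation to the binomial requires a
  reasonably large balancer count; the implementation refuses arms
  without balancer adults rather than extrapolating.
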