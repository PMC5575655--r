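---
title: "Methods: the lncfunnel discovery and co-expression pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lncfunnel discovery and co-expression pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices behind them, and what the
synthetic-data validation does and does not demonstrate.

## The analysis problem

Staged bulk RNA-seq of a developing tissue (the motivating design is
skeletal muscle sampled at a fetal, a neonatal and an adult time point,
three biological replicates each) yields an assembled transcript set in
which known mRNAs mix with unannotated transcripts. The pipeline answers,
in order: which unannotated transcripts are credible lncRNAs; where they
sit relative to the gene annotation; how they are expressed across stages;
which change between stages; which protein-coding genes they plausibly
target; and how those lncRNA–target pairs organise into a co-expression
network enriched for biological themes of interest.

## Coordinate conventions

All internal interval arithmetic is 0-based, half-open. GTF (1-based,
closed) is converted exactly once, at the `read_gtf()` / `write_gtf()`
boundary, and that conversion is itself tested. Exons within a transcript
must be sorted, non-overlapping and at least 1 bp; a transcript's span is
the hull of its exons and its spliced length the sum of exon lengths —
these are derived, never trusted from input.

## The discovery funnel

Novel transcripts pass three gates, each recorded per transcript so the
funnel is auditable:

* **Structure.** Spliced length ≥ 200 nt (a 200 nt transcript is kept) and
  exon count ≥ 2. Single-exon transcripts are excluded because assembly
  artefacts and unspliced fragments concentrate there; the pipeline
  deliberately targets multi-exon lncRNAs.
* **Coding-potential consensus.** Each enabled method votes coding or
  noncoding; only a unanimous noncoding vote survives (intersection
  semantics — one coding vote anywhere removes the transcript). The
  methods mirror the decision structure of the classic external tools
  while remaining fully in-package and trainable from the data at hand:
  * an ORF-length rule (default: coding when the longest sense-strand
    ATG-to-stop ORF reaches 300 nt, the conventional 100-codon floor);
  * a logistic model on the Fickett TESTCODE score and the hexamer usage
    log-ratio;
  * a logistic model on all four features (longest ORF length, ORF
    coverage, Fickett, hexamer);
  * optionally, a user-supplied protein-domain hit table (off by default,
    since it needs an external database).

  The logistic models are trained per run on the reference mRNA sequences
  (coding class) against mononucleotide-shuffled copies of them (noncoding
  class). Shuffling preserves base composition while destroying codon
  structure, ORFs and hexamer bias, which is exactly the contrast the
  features measure. The in-frame hexamer background tables come from the
  same split. Training is seeded, so discovery is deterministic given
  identical inputs.
* **Expression.** Maximum FPKM across all samples strictly greater than
  0.1. The maximum (rather than mean or all-samples) is used so
  stage-specific transcripts are not discarded; the choice is exposed as a
  parameter.

The Fickett score uses the published position/composition lookup tables
(bundled as in-source constants); it is strand-specific by construction.
The hexamer ratio is the mean over frame-0, step-3 hexamers of
`log(coding_freq / noncoding_freq)` with pseudocounted tables; hexamers
containing `N` are skipped.

## Positional classification

With precedence antisense > intronic > lincRNA: antisense requires an
exon–exon overlap with a protein-coding gene on the opposite strand (the
strongest positional signal, hence the top of the precedence order);
intronic requires the whole transcript inside one intron with no exonic
overlap on either strand (either-strand containment is the default and can
be restricted to the host strand); everything else is lincRNA. A lncRNA on
a chromosome missing from the reference is reported as lincRNA with a
warning rather than an error, so a partial annotation degrades gracefully.
Class percentages are reported to one decimal, and the rounding residue
(the deviation of their sum from 100) is attached to the result rather
than silently absorbed, since one-decimal class percentages legitimately
sum to 99.9 or 100.1.

## Quantification

FPKM is always computed inside the package from integer counts —
`count / (length/10^3) / (library_size/10^6)` — making this operation the
single quantification authority; FPKM is never read in. Library size
defaults to the column sum of counts and can be overridden with external
mapped-fragment totals. Gene-level FPKM sums transcript FPKM within a gene
(additive under the shared per-sample normaliser, so per-sample totals are
conserved — a tested invariant). Replicate correlations and the
co-expression screen both work on `log10(FPKM + 1)`: expression spans
orders of magnitude, and the log transform keeps a few highly expressed
features from dominating Pearson correlations; `+1` keeps zeros finite. A
feature is "expressed" in a stage when its stage-mean FPKM exceeds 0.1
(the same floor as discovery, configurable), and stage-specific when
expressed in exactly one stage; the stage-specific fraction is taken over
features expressed somewhere.

## Differential expression

Replicates are pooled within stage and each feature is tested with the
MA-plot random-sampling statistic: conditioned on the pooled total
`k1 + k2`, the count in one group is Binomial with success probability
`q = n1/(n1 + n2)` given by the library totals, and the normal
approximation gives a two-sided p-value. A pooled total of zero returns
`z = 0, p = 1` by convention. Fold change is computed separately, on
stage-mean FPKM with pseudocount 0.01 (so stage-specific features stay
finite), as experiment over control; contrasts are labelled
`control_vs_experiment` with the earlier stage as control, so "up" means
higher later in development. BH correction runs within each contrast, and
calls require FDR < 0.05 **and** |log2FC| > 1, both strict.

Two properties are worth stating plainly:

* The statistic models *sampling* noise of pooled libraries. Under
  Poisson-distributed counts the conditional binomial is exact, and the
  type-I calibration suite verifies the FDR-level control in that regime
  (negative-binomial dispersion 0.01, effectively technical noise). Under
  realistic biological overdispersion the statistic is anti-conservative —
  with dispersion 0.05 the null fraction of FDR < 0.05 calls rises well
  above 0.05. That is an inherent limitation of the pooled-binomial
  approach (replicate-aware dispersion models are deliberately out of
  scope), not a defect of the implementation, and users should read the
  calls accordingly.
* The normal approximation tracks the exact binomial test within a factor
  of two across the decision-relevant p range (p ≥ 1e-4) for near-balanced
  library totals (q between roughly 0.48 and 0.52, which is where pooled
  stage totals of a balanced design sit). In the far tail, or under strong
  library imbalance, the approximation deteriorates; the oracle tests
  bound it only in the regime the design actually occupies.

Venn partitioning of the three contrasts' DE sets and hierarchical
clustering of DE features (rows z-scored, distance `1 − Pearson`, average
linkage, rows pre-sorted by id for a deterministic tree with id-order
tie-breaks; zero-variance rows dropped with a warning) reproduce the
standard reporting figures.

## Target prediction and the network

*Cis*: a protein-coding gene is a candidate target when the gap between
gene span and lncRNA span is at most 100 kb and the spans do not overlap.
Distances are span-to-span and strand-agnostic ("upstream and downstream"
applied to both sides); the window is a parameter.

*Trans*: a windowed complementarity score — the best fraction of matching
positions in any fixed-length window (default 100 nt) over every ungapped
alignment of the lncRNA against the reverse-complemented mRNA, computed in
a small C++ kernel. A perfectly complementary window scores 1; unrelated
sequences sit near 0.25 and essentially never reach the default threshold
of 0.9. This is a deliberate proxy for dedicated lncRNA–mRNA
hybridisation tools, documented as such: it captures extended
complementarity, not hybridisation free energy.

Candidate pairs are screened on co-expression: Pearson r of
`log10(FPKM+1)` profiles across the nine samples, p from the t-test of r
on n − 2 degrees of freedom, edge retained when r > 0.8 (signed — the
screen looks for co-regulation; an absolute-value mode is available) and
p < 0.05. Networks carry node kind (lncRNA/gene) and regulation (the DE
call) and edge mode (cis/trans), serialised as SIF, GraphML or a flat
edge table. The keyword subnetwork keeps edges whose gene endpoint has at
least one annotation term whose name contains a keyword
(case-insensitive substring; defaults: myoblast, muscle development,
skeletal development).

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X ≥ k)` with BH correction across terms (significant at corrected
p ≤ 0.05); score-based enrichment is a plain two-sample KS test of term
genes' scores (typically DE p-values) against non-term genes' scores
(significant at p ≤ 0.05). Graph-aware decorrelation of nested ontology
terms is out of scope; annotation arrives as flat term-to-gene TSV maps,
with no database dependency. The universe defaults to all annotated genes
and is configurable. Top-term tables sort with a term-id tie-break so
reports are stable.

## The synthetic study design

The generator's defaults are the fixed conditions under which the package
validates itself: 3 chromosomes of 1.5 Mb; 120 multi-exon protein-coding
genes (4–9 exons) whose designed transcripts carry an ATG…stop ORF of
roughly 75% of the spliced length under a 16-codon preferred-codon bias
(weight 8:1, the learnable coding signature); 30 lincRNAs, 15 intronic and
15 antisense lncRNAs placed by the same rules the classifier tests
(lincRNAs ≥ 2 kb from any gene; intronic strictly inside a reserved 3 kb
intron; antisense overlapping a terminal exon on the opposite strand);
25 coding decoys (gene-like novel transcripts, the funnel's false-positive
probes); 25 junk transcripts that violate the structural filters by
construction; 3 stages × 3 replicates of negative-binomial counts
(`var = mu + d mu^2`, d = 0.05) around planted per-stage means, with
planted |log2FC| = 2, a 33% stage-specific fraction among lncRNAs and 4%
among genes (mirroring the motivating study's reported fractions), lncRNA
baseline means below mRNA means, and 12 cis + 6 trans lncRNA–target pairs
sharing a monotone stage profile with an independent jitter sized
analytically so the expected sample-level correlation matches the planted
0.95. Trans-pair target mRNAs carry a 150 nt reverse-complement segment of
their partner lincRNA in the 3' UTR. At `nb_dispersion = 0` the generator
degenerates, by documented convention, to noise-free counts equal to the
rounded means.

Problem sizes throughout (230 transcripts, 9 samples, 1,000-sequence ORF
oracle sweeps, 20-seed null calibration at 200 features) were chosen as the
smallest designs that exercise every code path and give stable
statistics.

What passing on this design shows: the filters implement their definitions
exactly; the classifiers can learn a codon-bias contrast; positional
classes, planted fold changes and planted pairs are recovered under
moderate noise; the whole pipeline is deterministic given a seed. What it
does not show: performance on real assemblies (fragmentary transcripts,
positional ambiguity, multi-isoform genes), classifier transfer across
species, or DE calibration under biological overdispersion — the generator
plants exactly the structure the methods assume, so recovery rates here
are upper bounds.

## Numerical and degenerate-input choices

Threshold boundaries follow their wording everywhere: length ≥ 200 is
kept, FPKM exactly 0.1 is discarded, FDR exactly 0.05 and |log2FC| exactly
1 are not called, enrichment at corrected p exactly 0.05 is significant.
`N`-containing codons never start or stop an ORF; `N` hexamers are
skipped. Zero-variance profiles yield `NA` correlations (replicates) or a
recorded screen failure (pairs) rather than errors. Empty networks and
empty gene sets serialise and report as valid empty results. GTF header
date comments are stripped on write so identical annotations give
byte-identical files.

## Known limitations

Pooled-binomial DE ignores biological replicate variance (see above);
the trans-target score is a complementarity proxy; positional subclasses
beyond linc/intronic/antisense (sense-overlapping, bidirectional) are not
assigned; enrichment has no ontology-graph awareness; FPKM (not TPM) is
the only expression unit, with no effective-length correction.
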