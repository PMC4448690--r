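# stresslnc

Acute oxidative stress reshapes the transcriptome of human fibroblasts in a
strikingly asymmetric way: most protein-coding mRNAs go down while thousands
of long noncoding RNAs (lncRNAs) — above all promoter-associated antisense
ncRNAs (paancRNAs) transcribed divergently from coding-gene promoters — are
transiently induced, accompanied by bidirectional RNA polymerase II pausing
and a redistribution of lncRNAs into polysome fractions. `stresslnc`
implements the computational pipeline needed to characterize such
stress-induced lncRNAs, end to end and fully testable on synthetic data with
known ground truth:

* **Transcript loci** — parse GTF/BED12 annotations into `TranscriptSet`
  objects, merge transcripts into gene loci by same-strand exonic overlap
  (transitive closure), and pick each locus's representative transcript
  (highest RPKM in any condition; ties by spliced length, then id).
* **Expression filters** — RPKM quantification
  (`rpkm = reads · 10⁹ / (length · library size)`); the detection /
  differential rule *treated/control RPKM > 1.5 with treated reads > 10 and
  treated RPKM > 1* (mirrored for down-regulation); intron/exon fold-change
  quadrants; gene-structure comparison of up vs down genes
  (Mann–Whitney–Wilcoxon on length and exon number).
* **Positional classification** — every lncRNA is assigned one of four
  classes relative to the nearest coding gene, with precedence
  overlapping > promoter-associated > terminal-associated > distal, windows
  (0, 5 kb] up-/downstream, and concurrent/opposite orientation; a
  promoter-associated opposite-strand lncRNA is a paancRNA.
* **PolII profiles** — traveling ratio `TR = mean promoter density
  (TSS −30..+300) / mean gene-body density (+301..TES)` from bedGraph
  coverage, strand-aware RPM metaprofiles around anchor sets, and paired
  TR-shift summaries between conditions.
* **Polysome shifts** — the three-pool microarray procedure: normexp
  background correction, per-category (coding/noncoding) log2 quantile
  normalization, replicate QC by clustering, per-pool stress-vs-control
  contrasts (RT/RN/RL/RH), transcriptional classification
  (p < 0.1, |fold| ≥ 1.5), the translational D-rule
  `d1 = |RN−RL|, d2 = |RL−RH|, d3 = |RN−RH|` (shift when any ≥ 1), and
  highest-ratio trend pools.
* **Sequence features** — longest-ORF search, Bennetzen–Hall coding bias
  index `CBI = (N_opt − N_rand)/(N_tot − N_rand)`, PWM scanning of promoter
  sequences, and motif co-occurrence summaries.
* **Synthetic data** — generators for annotations with planted lncRNA
  classes, negative-binomial count matrices with planted fold changes,
  PolII coverage with transient bidirectional promoter pausing, and
  polysome arrays with planted (class, trend) labels.

## Worked example

```r
library(stresslnc)

cfg <- simConfig(seed = 101, n_coding_genes = 10,
                 lnc_counts = c(distal = 5, overlapping = 5,
                                terminal_associated = 5,
                                promoter_associated = 5))
ann <- generateAnnotation(cfg)
asn <- classifyLncrna(ann$lnc, buildGeneIndex(ann$coding))
table(asn$klass)
#>              distal         overlapping promoter_associated terminal_associated
#>                   5                   5                   5                   5

mean(asn$klass == ann$truth$klass[match(asn$lnc_id, ann$truth$lnc_id)])
#> [1] 1
```

All 20 planted lncRNAs are recovered in their intended class. The same
closed loop drives the deeper checks: differential calls on simulated counts
recover the planted up-regulated fraction, traveling ratios recover the
planted pausing gain, and the polysome D-rule recovers planted
translational-shift labels.

The published worked-example arithmetic is reproduced directly:

```r
summarizeDe(callDifferential(sprintf("l%05d", 1:21311),
  treated_reads = 100, treated_rpkm = c(rep(6, 14639), rep(2, 6672)),
  control_reads = 100, control_rpkm = 2))$pct_up
#> [1] 68.7
```

i.e. 14,639 of 21,311 detected lncRNAs (68.7%) called up-regulated.

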