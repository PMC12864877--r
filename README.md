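# apamir

Quantitative analysis of alternative-polyadenylation (APA) driven 3'UTR
shortening and its interplay with muscle-specific miRNA (myomiR)
repression during myogenic differentiation.

When muscle stem cells differentiate into myotubes, many transcripts
switch from a distal to a proximal poly(A) site. The discarded segment —
the alternative UTR (aUTR) between the two cleavage sites — is where AGO2
binding and miR-1/133/206 target sites concentrate, so shortening lets
differentiation-critical mRNAs escape myomiR repression exactly when those
miRNAs are induced. `apamir` implements the full quantitative toolchain
for this question, for anyone analyzing 3'-end sequencing, fractionated
RNA-seq, CLIP peaks, or conservation tracks around APA events:

* **poly(A)-site calling** — untemplated-T read filtering (>= 2 Ts),
  single-linkage clustering of 3'-end positions, top-two isoform
  selection, annotation-guided read assignment, and a minimal SAM reader;
* **APA classification** — the relative expression difference
  `RED = ((d2+c)/(p2+c)) / ((d1+c)/(p1+c))` (condition 1 = reference,
  condition 2 = comparison), classified *lengthen* if RED > 1.2,
  *shorten* if RED < 5/6, gated by a BH-adjusted two-sided Fisher exact
  p < 0.05 and mode-specific read filters, with replicate-concordance
  flags and cross-dataset recapitulation fractions;
* **aUTR features** — strand-aware aUTR derivation, UGUA (CFIm) motif
  frequency, PAS hexamer location, coverage-on-aUTR;
* **AGO2 / myomiR analysis** — increased-peak flagging (normalized
  coverage FC > 2) and exact candidate-sequence scanning inside increased
  peaks, with per-class proportions;
* **conservation** — interval means, strand-aware site metaprofiles, and
  exact/approximate Wilcoxon rank-sum comparisons with CDF tables;
* **expression metrics** — RPKM, cytoplasm/nucleus ratio, polysome
  enrichment, tertile splits, per-class box summaries;
* **a synthetic-cohort generator** with recorded ground truth (planted
  classes, effect sizes, peaks, target sites, conservation plateaus), so
  every stage above is verifiable end to end at desk scale.

See the methods vignette (`vignettes/apa-myomir-methods.Rmd`) for the
statistical model, generator design, and parameter rationale.

## Worked example

Simulate a 300-gene cohort (25% shortened, 15% lengthened genes planted),
classify APA events from the isoform counts, and relate the classes to
AGO2 binding and myomiR candidate sites:

```r
library(apamir)

cfg <- cohort_config(n_genes = 300, frac_shorten = 0.25, frac_lengthen = 0.15,
                     depth_per_gene = 300, seed = 42)
cohort <- simulate_cohort(cfg, reads = FALSE)

res <- classify_apa_table(cohort$counts, mode = "quantseq")
table(res$apa_class)
#> lengthen       nc  shorten
#>       45      182       73
```

Of the 75 planted shortened genes, 70 are recovered at depth 300 (the
rest fall below the FDR gate) alongside 3 borderline false positives from
the unchanged majority, which otherwise stays `nc`. Each call carries its
evidence:

```r
head(res[res$apa_class == "shorten",
         c("gene", "p1", "d1", "p2", "d2", "red_ratio", "red_log2", "q_value")], 3)
#>     gene  p1  d1  p2 d2 red_ratio  red_log2      q_value
#> 1 g00001 146 146 171 72 0.4227405 -1.242156 1.615654e-05
#> 5 g00005 100 124 137 72 0.4256298 -1.232329 8.299163e-05
#> 8 g00008 159 184 153 75 0.4252094 -1.233754 1.449066e-05
```

`g00001` moved from 1:1 distal:proximal odds in the reference to 72:171
in myotubes — a RED of 0.42 (log2 -1.24), far below the 5/6 shortening
threshold, at q ~ 1.6e-5.

```r
autrs <- derive_autrs(cohort$models, cohort$sequences)
fl <- flag_increased_peaks(cohort$peaks, autrs)   # FC > 2, pseudocount 0.5
sc <- scan_cohort_candidates(autrs, fl, cfg$candidates)
class_proportions(setNames(fl$gene_flags$increased_peak, fl$gene_flags$gene),
                  setNames(res$apa_class, res$gene))
#>      class n_genes n_flagged proportion
#> 1  shorten      73        52   71.23288
#> 2 lengthen      45        23   51.11111
#> 3       nc     182        92   50.54945
```

Genes called *shorten* carry increased AGO2 peaks in their aUTRs far more
often (71%) than lengthened or unchanged genes (~51%) — the signature of
shortening as a miRNA-evasion mechanism. Individual target hits report
their containment chain (hit inside increased peak inside aUTR):

```r
head(sc$hits[, c("gene", "mirna", "autr_offset", "peak_id")], 3)
#>     gene          mirna autr_offset peak_id
#> 1 g00001 miR-1/206-8mer         942 pk00002
#> 2 g00001 miR-1/206-7mer         942 pk00002
#> 3 g00007 miR-1/206-8mer         356 pk00008
```

`run_pipeline(run_config(...))` chains all stages (simulation or real
inputs -> pA sites -> classification -> aUTR features -> AGO2/myomiR ->
conservation -> expression) into one seeded, byte-deterministic run that
writes every intermediate TSV plus `report.json` and an MD5 manifest. A
thin command-line front-end lives at `inst/scripts/apamir.R`
(`simulate` / `run` subcommands).

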