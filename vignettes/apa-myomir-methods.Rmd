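---
title: "Methods: quantifying 3'UTR shortening and myomiR targeting with apamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying 3'UTR shortening and myomiR targeting with apamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apamir)
```

## The problem

During muscle stem cell (satellite cell) differentiation into myotubes,
many mRNAs switch from a distal to a proximal cleavage-and-polyadenylation
site, shortening their 3'UTRs at the same time as the muscle-specific
miRNAs miR-1, miR-133 and miR-206 (the "myomiRs") are sharply induced. The
segment lost by shortening — the alternative UTR (aUTR), the interval
between the proximal and distal cleavage sites — is exactly where
Argonaute-2 (AGO2) binding and myomiR target sites concentrate, so
shortening removes repressive elements precisely when repression is
strongest. `apamir` implements the quantitative side of this analysis as a
reusable, fully testable pipeline: poly(A)-site calling from 3'-end
evidence, classification of per-gene 3'UTR change, aUTR sequence features
(UGUA/CFIm motifs, PAS hexamers), AGO2 peak fold-change flagging with
candidate-site scanning, conservation aggregation, and export/translation
metrics.

Because the public datasets behind such analyses are large and external,
the package ships a synthetic-cohort generator with recorded ground truth.
Every stage can then be verified at desk scale: the generator defines the
study conditions and the tests measure whether the analysis operations
recover what was planted.

## The RED statistic and APA classification

For each gene, proximal (`p`) and distal (`d`) isoform counts in a
reference condition (proliferating cells, condition 1) and a comparison
condition (myotubes, condition 2) form a 2x2 table. The relative
expression difference is the cross-condition ratio of distal-to-proximal
odds,

$$\mathrm{RED} = \frac{(d_2 + c)/(p_2 + c)}{(d_1 + c)/(p_1 + c)},$$

with a pseudocount `c = 0.5` applied to the ratio only, never to the test
counts. Its log2 is the delta-log2(d-pA/p-pA) form; the two scales are
exposed side by side. The classification rule is:

* **lengthen** iff RED > 6/5 (= 1.2),
* **shorten** iff RED < 5/6 (~0.83),
* **nc** otherwise,

in each case additionally requiring a Benjamini-Hochberg adjusted
two-sided Fisher exact p-value below `alpha = 0.05` and a mode-specific
read filter: QuantSeq-style data require at least 50 reads per gene over
both conditions; fractionated RNA-seq mode requires each isoform to exceed
5 reads in at least one sample of the compared pair. The two printed
thresholds are reciprocal, which is why RED is treated as an odds ratio;
exact boundary values classify as `nc` because the inequalities are
strict. Replicates are pooled (summed) for the 2x2 table; a separate
`reproducible` flag additionally requires every replicate pair's RED log2
to share the sign of the pooled value. We chose pooling plus sign
concordance over a hierarchical replicate model because it matches a
two-replicate design without inventing distributional structure the data
cannot constrain.

`red_log2` is computed as a sum of four logarithms rather than
`log2(red_ratio)` so that swapping the two condition labels negates it
bit-for-bit; `log2` of a ratio of ratios does not guarantee that in
floating point. Multiple testing is corrected per contrast (one gene
family per comparison), not across contrasts.

The Fisher test is implemented by direct hypergeometric enumeration (sum
of all table probabilities not exceeding the observed one, with a 1e-7
relative guard on the comparison), and BH by the standard step-up; both
are cross-checked in the test suite against `stats::fisher.test`,
`stats::p.adjust` and independent brute-force oracles.

## Poly(A)-site calling from 3'-end evidence

3'-end reads carry untemplated T residues from the poly(A) tail; reads
with fewer than 2 such residues are treated as internal-priming artifacts
and removed. Surviving cleavage positions are clustered by single linkage
with a 24 nt window (a common choice in 3'-end processing; the window is a
parameter), each cluster represented by its maximal-support position with
ties resolved toward the transcriptionally 5'-most coordinate, and the two
highest-support sites inside the last-exon 3'UTR become the proximal and
distal isoforms. An annotation-guided alternative
(`assign_reads_to_annotated_pas`) assigns each read to the nearest
annotated site within 24 nt, with equidistant reads resolving 5'-ward so
output is deterministic.

Coordinates follow the BED-end convention: a cleavage coordinate is the
0-based position immediately after the last transcribed base (plus
strand) or the 0-based start of the last transcribed base (minus strand).
Under this convention the aUTR is the half-open genomic interval between
the two coordinates on either strand and its length is their difference —
the reason this convention was chosen.

## aUTR sequence features

UGUA, the CFIm (cleavage factor I) recognition element, is counted by
sliding-window matching on the sense strand only, normalized by aUTR
length; the motif has no nontrivial self-overlap, so the overlap question
is moot, but overlapping occurrences would be counted. PAS hexamers are
searched in the 40 nt window upstream of each cleavage site against the
canonical AATAAA/ATTAAA plus ten common single-base variants (the list is
configurable); when several variants match, the hit closest to the
cleavage site is reported. The window width and variant list are package
choices — the field's descriptions of "nearby" signals are not precise —
and both are parameters.

## AGO2 peaks and myomiR candidate sites

Peaks (consumed as intervals with per-condition depth-normalized coverage;
peak calling itself is upstream of this package) are kept when they
overlap an aUTR by at least one base and flagged *increased* when the
coverage fold change `(cov2 + 0.5)/(cov1 + 0.5)` strictly exceeds 2. A
gene is flagged when at least one increased peak lies in its aUTR — the
minimal aggregation rule consistent with reporting gene proportions.
Candidate myomiR target sequences are matched as exact substrings of the
aUTR sense sequence restricted to increased-peak footprints, so every
reported hit satisfies hit within peak within aUTR. The shipped candidate
table (miR-1/206 7mer and 8mer seed matches, miR-133 7mer) is supplied by
this package and clearly replaceable; exact matching reflects the
alignment of fixed candidate sequences rather than thermodynamic target
prediction, which is out of scope.

## Conservation

Per-base conservation (phastCons-like, values in [0, 1]) is consumed as a
bedGraph-style interval track. Interval means exclude uncovered bases;
metaprofiles average across sites at each aligned offset, orienting sites
5' to 3' on the mRNA and anchoring unequal-length sites at their 5' start
(flank default 50 nt). Distribution comparisons use a two-sided Wilcoxon
rank-sum test: full enumeration of the Mann-Whitney U permutation
distribution when `min(nA, nB) <= 8` and `nA + nB <= 20`, otherwise the
normal approximation with tie correction (no continuity correction;
documented because the p-values depend on it).

## Export and translation metrics

RPKM is `count / (length/1000) / (library/1e6)`. The cytoplasm-to-nucleus
ratio and polysome enrichment are pseudocounted ratios (`eps = 0.1` RPKM,
guarding zeros) whose cross-condition changes are log2 ratios of ratios;
both negate exactly under condition swap. Shortened genes are split into
shortening-magnitude tertiles by |RED log2| with deterministic tie-breaks
on gene id and remainders assigned to the higher-magnitude groups first.
Box summaries use type-7 (linear interpolation) quartiles and Tukey
1.5 IQR whiskers — stated explicitly because boxplot statistics depend on
the quantile convention. Differential expression of 3'-processing factors
is out of scope; a descriptive library-normalized log2 fold change is
provided for heatmap-style reporting and is labelled as such.

## The synthetic cohort

The generator lays out `n_genes` two-site genes on one pseudo-chromosome,
1 kb apart, strands alternating so all strand logic is exercised. Class
labels (shorten/lengthen/nc) are assigned by deterministic rounding of the
configured fractions followed by a seeded permutation — planted class
counts are exact, which keeps recovery tests sharp. Key defaults and their
provenance:

| parameter | default | rationale |
|---|---|---|
| `frac_shorten` / `frac_lengthen` | 0.07 / 0.06 | observed proportions of shortened/lengthened genes among all analyzed genes in differentiating satellite cells |
| `effect_red_log2` | 1 | a clear but not extreme isoform-usage shift (odds doubled); real effect-size distributions are not published, so this is a package choice |
| `depth_per_gene` | 300 | desk-scale 3'-end coverage at which the classifier operates comfortably |
| `nb_dispersion` | 0.1 | typical biological overdispersion for bulk counts; 0 degrades to Poisson |
| `p_peak_by_class` | 0.68 / 0.55 / 0.53 | reported proportions of shortened/lengthened/unchanged mRNAs with increased AGO2 peaks in aUTRs |
| `p_site_by_class` | 0.28 / 0.16 / 0.14 | reported proportions with myomiR sites inside increased peaks |
| `site_conservation` | 0.75 | middle of the reported "moderate (0.7-0.8)" conservation of target sites |
| `background_conservation` | 0.30 | genome-wide background level |
| `pas_conservation` | 0.75 (shorten) / 0.55 (other) | shortened genes carry the more conserved signals; the 0.2 gap makes the rank-sum comparison decisively detectable |
| `cfi_recap` | 0.67 / 0.64 | reported recapitulation of differentiation-induced shortening by CFI-68 / CFI-25 knockdown |
| `ugua_enrich_factor` | 3 | a clear CFIm-substrate enrichment over the 1/256 i.i.d. background rate |
| `internal_priming_rate` | 0.1 | fraction of 3'-end reads lacking untemplated-T evidence |
| `end_jitter_sd` | 3 nt | typical cleavage-site heterogeneity in 3'-end data |

Counts are simulated as per-replicate gene totals drawn negative-binomial
(mean `depth/R`, variance `mu + phi mu^2`) and then split between the two
isoforms by a conditional binomial draw whose distal:proximal odds are 1
in the reference condition and `2^planted_red_log2` in the comparison.
This separates expression noise (the NB layer, shared by both isoforms)
from isoform choice (a per-molecule Bernoulli given the planted usage),
which is how the 2x2 Fisher test models the data; putting independent NB
noise on each isoform would instead inject the full biological dispersion
into every gene's cross-condition RED and make effects of one log2 unit
intrinsically hard to classify at any depth.

Scaffold sequences are scrubbed of a reserved k-mer list — UGUA, the PAS
variants, the candidate sequences, their reversals, and the reverse
complements of all of these — before any planting, so every motif counted
downstream was planted deliberately and at a known rate (closure under
reverse complement keeps minus-strand sense sequences clean too). This is
a planted-truth purity choice: recovery tests then measure the analysis,
not the random background, and a scrambled (reversed) candidate provably
has zero matches rather than a small random number. AATAAA hexamers are
planted 21 nt upstream of every cleavage site; background UGUA motifs at
`ugua_background_rate` per nt (times `ugua_enrich_factor` in
shortened-class aUTRs); elevated AGO2 peaks (coverage ratio drawn in
[2.5, 6], so FC > 2 detection is unambiguous modulo the pseudocount) with
probability `p_peak_by_class`; candidate sites inside those peaks with
conditional probability `p_site_by_class / p_peak_by_class`; and a
non-elevated background peak (ratio in [0.4, 1.8]) anywhere in the 3'UTR
with probability 0.9 so fold-change discrimination is actually exercised.
3'-end reads get rounded Gaussian positional jitter and untemplated-T
counts of 2-6 (uniform — the count only needs to exercise the >= 2
filter, not model tail length) except for internal-priming artifacts,
which draw from {0, 1}.

What the generator does **not** emulate: genomic A-rich internal-priming
context, overlapping genes and multi-isoform 3'UTRs, non-uniform read
coverage, mappability artifacts, peak-calling noise, miRNA expression
dynamics, and any coupling between expression level and APA class.
Passing recovery tests therefore demonstrates correctness of the
operations under the stated statistical structure, not performance on
real sequencing data.

## Problem sizes and numerical choices

The test suite runs cohorts of 120-2000 genes: null calibration and
effect recovery use 2000 genes at depth 300 (counts only); proportion
recovery uses 1000 genes per class with full sequence layers; read-level
site recovery uses 250 genes at depth 60. These sizes put binomial
standard errors well inside the tolerances being checked while keeping a
full run in a few minutes on one CPU. Degenerate inputs are contracts,
not surprises: empty cohorts are valid, all-zero genes are flagged rather
than classified, degenerate Fisher margins return p = 1, fully uncovered
intervals report missing coverage, and genes with a single called site
raise a typed no-alternative-pA condition.

## Limitations

* Real-data mode consumes pre-quantified inputs (counts, peak intervals,
  bedGraph tracks); it does not trim, align, call peaks, or model
  poly(A)-site likelihoods.
* The "reproducible event" definition (pooled significance plus
  replicate sign concordance) is one reasonable choice among several; the
  flag is reported separately so downstream filters can ignore it.
* Exact candidate-sequence lists vary between studies; the shipped
  myomiR table is a package default, not a published appendix.
* The rank-sum exact branch enumerates only small groups; larger groups
  use the tie-corrected normal approximation, whose p-values differ from
  exact enumeration in the tails.
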