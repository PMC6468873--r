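---
title: "Methods: integrated germline–tumor two-hit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated germline–tumor two-hit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`germsoma` prioritizes candidate tumor suppressor genes from paired
germline–tumor whole-exome variant calls under Knudson's two-hit model: a
gene is a candidate when a rare deleterious germline variant (first hit)
is joined by a somatic second hit — a distinct somatic SNV/indel or loss
of heterozygosity (LOH) of the wild-type allele — in the matched tumor.
This vignette documents the statistical model, every tunable parameter
with its default and rationale, the synthetic-data generator's stated
world, the numerical choices, and the known limitations.

## Inputs and conventions

The pipeline consumes *post-annotation* variant tables: the six
pathogenicity predictors (PhyloP ≥ 1.6, SIFT, PolyPhen2, MutationTaster,
LRT, CADD ≥ 15), CADD Phred scores and population allele counts are read
as precomputed columns, never recomputed. Variants use 1-based VCF
coordinates; gene intervals are 0-based half-open BED on disk and
converted to 1-based inclusive once, on read. Missing population
frequency (a variant absent from the control repository) is treated as
frequency 0 — absence from ~60k exomes is evidence of rarity, and the
published candidate tables print such variants as `0/60,706`.

## Filter cascades

Germline first-hit candidates satisfy depth ≥ `min_depth` (10×,
inclusive), population AF < `max_pop_af_germline` (0.001, strict), and
deleteriousness: consequence `truncating`, or `missense` with
`n_pass ≥ min_predictors` (3 of 6). Somatic second-hit candidates
additionally require depth ≥ 10× in *both* members of the pair (matched
normal depth from the caller's `normal_depth` column, else a site lookup
in the germline table, else 0 — so sites with no germline information
fail), tumor VAF ≥ `min_tumor_vaf` (0.20, inclusive as printed), and
exclusion of calls identical to a germline variant (same
chrom/pos/ref/alt), which are re-called germline variants rather than
somatic events.

Two points the underlying protocol leaves open are resolved here and
exposed as configuration:

* the germline AF cutoff is not stated numerically in the protocol's
  germline section; 0.1% is adopted because that is the cutoff the same
  protocol states explicitly for its case-control analysis;
* whether the germline cascade used the same ≥ 3/6 predictor rule as the
  somatic one is not stated; the rule is applied symmetrically.

Functional prioritization ("function compatible with cancer") is modeled
as transparent keyword flagging over a user-supplied gene→function map
(`apply_function_prioritization()`): candidates are annotated and sorted,
never removed, and the keyword list is user-editable — no gene list is
hard-coded.

## LOH from allelic imbalance

At a credibly heterozygous germline site (germline VAF in [0.3, 0.7],
depth ≥ 10 — a definition the protocol leaves open; the band is the
conventional exome het window), the tumor VAF stays near 0.5 unless one
allele was somatically lost. Under copy-neutral LOH at tumor purity $p$
the retained-allele VAF is $(1+p)/2$ and the lost-allele VAF $(1-p)/2$:
tumor cells contribute two copies of the retained allele and none of the
lost one, stroma stays 1/1. At the typical 70–80% tumor-cell content of
macrodissected colorectal samples (the generator's default $p = 0.75$)
the expected VAFs are 0.875/0.125.

The caller works on the folded deviation $d_i = |\mathrm{VAF}_i - 0.5|$,
which makes detection insensitive to which haplotype was lost (phase
varies site to site); allele assignment is resolved afterwards per
variant.

**Segmentation.** Each chromosome's ordered sites are partitioned by
recursive segmentation using the circular-binary-segmentation statistic:
the window $(i, j]$ maximizing the pooled-variance two-sample $t$ between
in-window and out-of-window $d$ values is found by exhaustive scan, and
the split is accepted when a seeded permutation test on that maximal $t$
gives $p < \alpha$ (default 0.01, matching the conventional CBS default).
Accepted windows recurse into up to three parts. A design note: a plain
single-breakpoint binary segmentation was implemented first and measurably
failed on interior LOH segments — a focal window inflates the permutation
null on both sides of any single cut (observed $p \approx 0.02$ at a
folded shift of 0.37) — which is precisely why the established method
tests windows; the window statistic was therefore adopted.

**Testing.** Within a segment, each site gets an exact two-sided binomial
test of the tumor alt count against $\mathrm{Binomial}(\text{depth},
0.5)$; site p-values are combined by Fisher's method
($-2\sum\log p_i \sim \chi^2_{2m}$). A segment is called LOH when the
combined $p <$ `alpha_loh` (0.01) **and** the mean folded shift ≥
`shift_min` (0.15). The effect-size floor prevents calling LOH on
significance alone (at depth 500 a shift of 0.05 is highly significant
but biologically uninterpretable as allelic loss); 0.15 corresponds to
purity ≈ 0.3 under the copy-neutral model, below which single-sample
exome LOH calls are not credible anyway. The protocol states no LOH
significance threshold or minimum informative-site count; `min_sites = 5`
and the defaults above are this package's choices, flagged as such.

A gene is called LOH when any imbalanced segment overlaps its interval;
when the germline first hit lies inside that segment, its tumor VAF
resolves whether the *wild-type* allele was lost (VAF > 0.5 ⇒ the
variant-bearing allele was retained), the configuration that actually
fulfills the two-hit model.

## Two-hit pairing

One candidate per (gene, sample) with at least one filtered germline hit
and one second hit. A somatic variant is a second hit only when distinct
from the first hit — any of chrom/pos/ref/alt differing counts as
distinct (a somatic call at the first-hit position with a different
alternate allele is a different event; the protocol does not address this
corner). Classes `somatic_snv`, `loh` and `both` are disjoint, so
summaries obey inclusion–exclusion exactly. Germline CNVs are not
accepted as first hits (the underlying study evaluated and discarded all
of its germline CNV candidates); a germline indel paired with a somatic
SNV is allowed by construction.

## Burden and signature refitting

Somatic single-nucleotide variants are counted into the standard 96
channels (6 pyrimidine-strand substitution classes × 16 trinucleotide
contexts, substitution-major order; purine-reference mutations
reverse-complemented). Burden is $n/30$ mutations per Mb under the
30 Mb callable-exome convention, classified hypermutated at ≥ 90
(boundary inclusive — the operational figure-legend convention) and
ultrahypermutated at > 500. Burden uses all somatic SNVs
pre-pathogenicity-filter (the protocol does not say which set it used;
all PASS calls is the convention of burden tools, and it is configurable
by filtering the input).

Refitting solves $\min_{e \ge 0} \lVert S e - c \rVert_2$ on raw counts
with an in-package Lawson–Hanson active-set NNLS (deterministic; KKT
conditions verified in the test suite), reporting exposures, proportional
contributions and the reconstruction cosine. No sparsity penalty or
signature pre-selection is applied — plain NNLS refitting is the modeled
procedure; modern refitting practice sometimes regularizes, and that is a
documented deviation from those tools, not from the modeled procedure.
Contributions are scale-invariant in the catalog, so refitting counts vs
frequencies differ only in the exposure scale.

## Case-control enrichment

Eligible variants are rare (control AF < 0.1%, strict) and potentially
pathogenic (CADD > 15, strict — CADD exactly 15 is excluded). Each
variant's 2×2 table (case alt/ref alleles vs control alt/ref alleles) is
tested with an exact two-sided Fisher test under the probability-ordering
definition: the p-value sums hypergeometric probabilities of all tables
with the observed margins whose probability is ≤ that of the observed
table, with a $10^{-7}$ relative tie tolerance (implementations differ in
tie handling; stating the definition makes the tests exact). Alleles
(2N haplotypes) are the counting unit, matching repository
`allele_count/allele_number` fields; carrier counting is a configuration
away but not the default, as the protocol does not specify it. A gene is
highlighted when strictly more than 50% of its tested variants reach
$\alpha$ (default 0.05 — the protocol prints no threshold; per-variant
significance is reported uncorrected, with Benjamini–Hochberg behind a
flag).

## The synthetic cohort: what it states and what it does not

`cohort_config()` defaults state the emulated study design: 18 paired
samples, 2 tumors failing the 70% shared-coverage QC, purity 0.75, mean
depth 100× (Poisson), 8 designed het sites per 10 kb gene, 30 Mb exome.
`study_cohort_config()` fixes the 16 passing-sample burdens to a vector
with median exactly 58.8 mutations/Mb, five values ≥ 90 (one > 500), and
the worked-example values 96.9, 61.0 and 30.8 among them; somatic
catalogs are drawn from a mixture dominated 0.8/0.2 by a clock-like-style
synthetic signature. Het-site reads are binomial: germline at 0.5, tumor
at 0.5, or $(1 \pm p)/2$ inside planted LOH with per-site random phase
(except the first-hit site, where the wild-type allele is always the lost
one — that is the planted biology being tested). Catalog sizes are exact
($\mathrm{round}(\text{burden} \times 30)$ SNVs), so burden recovery is
exact by construction.

What a green test therefore establishes: the pipeline's decision rules,
statistics and bookkeeping are correct for binomially-sampled reads from
the stated generative model. What it does not establish: robustness to
FFPE artifacts, strand bias, mapping errors, subclonal copy-number
changes, uneven capture efficiency, or real human genome structure
(synthetic contigs, uniformly spaced sites). A uniform base-error
parameter exists but defaults to 0.

## Numerical choices

* Permutation p-values use the add-one estimator $(b+1)/(n+1)$ (never
  exactly 0) with early stopping once significance is impossible; early
  stopping cannot change an accept/reject outcome, only runtime.
* The window maximizer breaks ties (a window and its complement share the
  same $t$ algebraically) toward the narrowest, then leftmost window, so
  the exhaustive-search oracle and the vectorized path agree exactly.
* Site binomial p-values are clamped to $[\,\texttt{double.xmin}, 1]$
  before Fisher combination.
* NNLS uses QR on the passive set, a dual-feasibility tolerance of
  $10^{-10}$ scaled by $\max|A^\top b|$, and handles rank-deficient
  passive sets by zeroing undetermined coefficients.
* Chromosome-level permutation seeds derive deterministically from the
  run seed and the chromosome name (kept below $2^{31}$), so per-sample
  results are reproducible and order-independent.
* All boundary semantics are fixed and tested: depth ≥ 10 and VAF ≥ 20%
  inclusive, QC ≥ 70% inclusive, hypermutation ≥ 90 inclusive,
  ultrahypermutation > 500 strict, AF < 0.1% and CADD > 15 strict.

## Limitations

* Epigenetic silencing (promoter methylation) is invisible to this
  analysis; genes inactivated that way are missed by design.
* No absolute copy-number estimation or subclonality deconvolution: the
  LOH model is copy-neutral with a single clonal population.
* The allelic-imbalance statistic is this package's exactly-testable
  formulation (binomial per site + Fisher combination) of the published
  idea of inferring LOH from germline–tumor allelic imbalance; it is not
  a verbatim reimplementation of any published tool's likelihood model.
* Manual curation steps of the original workflow (literature review,
  protein-domain inspection, visual read validation) are represented only
  by the transparent keyword-flagging stage.
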