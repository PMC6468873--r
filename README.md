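# germsoma

Integrated germline–tumor exome analysis for prioritizing candidate tumor
suppressor genes in familial cancer, built around Knudson's two-hit
hypothesis.

## The problem

Some colorectal cancer families show strong aggregation of the disease but
carry no mutation in the known hereditary CRC genes (*APC*, *MUTYH*, the
mismatch-repair family, *POLE*/*POLD1*). When both germline and tumor
whole-exome sequencing are available for such patients, a tumor suppressor
gene can be nominated when **both** of its alleles are inactivated: a rare,
deleterious **germline variant** (first hit) plus a **somatic second hit**
in the matched tumor — either a different somatic SNV/indel or somatic loss
of heterozygosity (LOH) removing the wild-type allele. `germsoma`
implements that integrated analysis as a tested, reusable pipeline:

1. **Sample QC** — a tumor/normal pair is analyzed only when ≥ 70% of the
   shared exome regions are covered at ≥ 10× (boundary inclusive).
2. **Filter cascades** — germline candidates must be covered (≥ 10×), rare
   (population allele frequency < 0.1%, absent-from-repository = 0) and
   deleterious (truncating, or missense passing ≥ 3 of 6 predictors:
   PhyloP ≥ 1.6, SIFT, PolyPhen2, MutationTaster, LRT, CADD ≥ 15).
   Somatic candidates additionally need ≥ 10× in *both* samples, tumor
   VAF ≥ 20%, and must not recall a germline variant.
3. **LOH from allelic imbalance** — at germline-heterozygous sites the
   tumor VAF should stay near 0.5; the folded deviation |VAF − 0.5| is
   segmented per chromosome with the circular-binary-segmentation
   statistic (max segment-vs-rest t over windows, seeded permutation
   stopping rule), and each segment is tested by exact per-site binomial
   tests against Binomial(depth, ½) combined with Fisher's method, with
   an effect-size floor (mean shift ≥ 0.15) so significance alone never
   calls LOH. Under copy-neutral LOH at tumor purity *p* the expected VAF
   is (1 ± *p*)/2 — 0.875/0.125 at *p* = 0.75.
4. **Two-hit pairing** — one candidate per (gene, sample) with classes
   `somatic_snv`, `loh`, or `both`; the lost allele is resolved from the
   first hit's tumor VAF (> 0.5 ⇒ the wild-type allele was lost).
5. **Somatic profiling** — 96-channel mutational catalogs
   (pyrimidine-strand convention), tumor mutational burden
   (*n*/30 mutations per Mb; hypermutated ≥ 90, ultrahypermutated > 500)
   and signature refitting by non-negative least squares
   (`exposures = argmin₍e≥0₎ ‖S·e − counts‖₂`, Lawson–Hanson).
6. **Case-control enrichment** — per rare (control AF < 0.1%), potentially
   pathogenic (CADD > 15) variant, a two-sided Fisher exact test of case
   vs control allele counts; a gene is highlighted when strictly more than
   half of its tested variants are significant.

A synthetic-cohort generator (`generate_cohort()`) emits paired variant
tables, het-site allele depths, signature mixtures and a machine-readable
ground truth, so the entire pipeline is exercised end to end without any
patient data.

## Worked example

```r
library(germsoma)

cfg <- cohort_config(n_samples = 4, burden_per_mb = c(30, 20, 96.9, 20), seed = 11)
gen <- generate_cohort(cfg, "cohort")
rep <- run_pipeline(run_config("cohort", "out", seed = 11))

rep$qc[, c("sample_id", "qc_shared_ge10x_fraction", "qc_pass")]
#>   sample_id qc_shared_ge10x_fraction qc_pass
#> 1       S01                   0.8621    TRUE
#> 2       S02                   0.4528   FALSE
#> 3       S03                   0.9733    TRUE
#> 4       S04                   0.6410   FALSE

rep$candidates[, c("gene", "sample_id", "second_hit_class", "wildtype_allele_lost")]
#>      gene sample_id second_hit_class wildtype_allele_lost
#> 1 GENE002       S03              loh                 TRUE
#> 2 GENE004       S01              loh                 TRUE
#> 3 GENE006       S03              loh                 TRUE

rep$burden
#>   sample_id n_snv mutations_per_mb        class
#> 1       S01   900             30.0       normal
#> 2       S03  2907             96.9 hypermutated

round(rep$exposures, 3)
#>        S01   S03
#> SIG1 0.777 0.812
#> SIG2 0.219 0.186
#> SIG3 0.000 0.000
#> SIG4 0.004 0.002
#> SIG5 0.000 0.000
```

Two of the four tumors fail the 70% shared-coverage QC and are discarded.
Every planted two-hit gene on a passing sample is recovered with its
second-hit class, and `wildtype_allele_lost = TRUE` records that the
imbalanced segment retained the variant-bearing allele (tumor VAF of the
first hit > 0.5). S03 was simulated at 96.9 mutations/Mb (2907 SNVs / 30
Mb) and is classified hypermutated; the NNLS refit recovers the planted
0.8/0.2 signature mixture.

A command-line interface mirrors the stages
(`inst/cli/germsoma <subcommand>`): `simulate`, `qc`, `filter`, `loh`,
`twohit`, `signatures`, `enrich`, `run-all`; exit codes are 0 (ok),
1 (data error), 2 (config error).

## Layout

- `R/` — core model & IO, filter cascades, LOH caller, two-hit pairing,
  signatures/NNLS, enrichment, synthetic data, pipeline, CLI.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles (`helper-oracles.R`).
- `vignettes/germline-tumor-two-hit.Rmd` — methods: model, assumptions,
  parameter defaults, numerical choices, limitations.
- `inst/extdata/crc_candidate_genes.tsv` — published 16-gene candidate
  table (gene, variant, predictor score, population frequency, function).
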