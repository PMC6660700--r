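# mosascan

Detection and characterization of clinically relevant somatic mosaic SNVs
from exome read counts.

Clinical exome sequencing routinely reports variants assumed to be
constitutional, but a small, diagnostically important fraction are
postzygotic (mosaic): present in only part of the patient's cells and
visible in sequencing data as a skewed alternate allele fraction
(AAF = alt reads / total reads). `mosascan` is aimed at clinical
bioinformaticians and method developers who need a tested, reusable
implementation of AAF-threshold mosaic calling and its validation
machinery:

* **Mosaic calling.** A diploid variant (autosome, or X in a female) is a
  mosaic candidate when AAF < 0.36 or AAF > 0.64; a hemizygous variant
  (non-PAR X in a male) when 0.10 ≤ AAF ≤ 0.90. The 36%/64% cutoffs are a
  binomial confidence interval in disguise: for a heterozygote at depth
  *d*, AAF ∈ 0.5 ± z₁₋α/₂·0.5/√d with probability 1−α, which at d = 48,
  α = 0.05 gives (0.359, 0.641). Fixed and depth-adaptive policies,
  exact Clopper–Pearson CIs on every estimate, minimum depth 20×.
* **Trio origin.** De novo / inherited / parental-mosaic assignment from
  trio read counts, with a UPD/AOH suspicion flag for inherited variants
  observed at a mosaic-range AAF in the proband.
* **Cohort statistics.** A bundled, machine-readable reconstruction of a
  published 120-variant diagnostic cohort table (80 proband + 40
  parental/grandparental mosaic variants across ~12,000 exomes) and a
  summary module that reproduces its printed aggregates exactly.
* **Simulation.** Read-count-level operating characteristics of threshold
  policies (validated against exact binomial tail sums) and synthetic trio
  cohorts with planted truth, written as VCF 4.2 + PED + truth TSV.

## Worked example

```r
library(mosascan)

## cohort summary over the bundled 120-record table
rep <- summarize_cohort(load_cohort_fixture())
#> mosascan: excluded from AAF means (no reported AAF): 81M-PGM, 106-PLACEHOLDER
rep
#> <summary_report>
#>   120 variants in 107 genes (80 proband, 40 parental)
#>   inheritance: AD=62 AD_AR=5 AD_somatic=10 AR=8 XL=33 somatic_only=2
#>   classification: pathogenic=41 likely_pathogenic=33 VOUS=46
#>   consequence: missense=81 nonsense=17 frameshift=14 inframe_indel=2 splice=6 other=0
#>   mean AAF%: male X 34.9 (n=16), diploid proband 20.2 (n=65), diploid parental 14.8 (n=37)
```

That is: 120 reported mosaic variants in 107 disease genes, 67 in AD or
AD/AR genes, a 81/17/16/6 missense/nonsense/frameshift-or-inframe/splice
spectrum, mean mosaic AAF ≈ 20.2% in proband diploid contexts versus
≈ 34.8% for male X-linked variants (where a constitutional variant would
sit near 100%).

```r
## classify one observation: 24 alt reads of 130 in a female, autosome
classify_observation(24, 130, sex = "female", chrom_class = "autosome")
#>   alt_reads total_reads       aaf    ci_low   ci_high ploidy_context               status
#> 1        24         130 0.1846154 0.1219833 0.2625039        diploid candidate_mosaic_low

## where the fixed cutoffs come from
derive_het_thresholds(48, 0.05, "normal")
#>   depth     lower     upper
#> 1    48 0.3585518 0.6414482

## trio origin with UPD screening, over a VCF + PED
calls <- trio_pipeline("trio.vcf", "fam.ped")

## type-I error of the fixed policy at 130x (exact, no Monte Carlo)
exact_flag_probability(0.5, 130)
#> [1] 0.001092561
```

A command-line interface wraps the same functionality
(`inst/cli/mosascan`): subcommands `call`, `trio`, `summarize`,
`thresholds`, `simulate oc`, `simulate cohort`; see `?mosascan_main`.

## Documentation

The methods vignette (`vignettes/mosascan-methods.Rmd`) describes the
model and its assumptions, the provenance of every default, what the
synthetic data does and does not emulate, and known limitations.
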