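# subclonemix

Deconstruct the subclonal structure of a tumor from droplet digital PCR
(ddPCR) panels measured across many samples of the same tumor — the
situation of patient-derived xenograft (PDX) treatment studies, where
dozens of residual tumors from different treatment arms are profiled at
a handful of loci for mutant allele frequency (AF, a fraction in
\[0,1\]) or absolute copy number (CN, mean copies per cell).

The package is built around a two-subclone mixture model. A sample that
is a fraction *p* subclone 1 and 1 − *p* subclone 2 has expectations

    CN(p) = p·c1 + (1−p)·c2
    AF(p) = (p·m1 + (1−p)·m2) / (p·T1 + (1−p)·T2)

with per-locus integer genotypes (*m* mutant of *T* total copies) and
subclone mean copy numbers *c*. On top of that model it provides:

- **integer genotype calling** from a single (AF, CN) pair
  (`call_integer_genotype`): T = round(CN), m minimizing |AF − m/T|;
- **subclone genotype inference** by regressing every marker on an
  anchor AF and extrapolating to the pure-subclone anchor values
  (`infer_subclone_endpoints`, `genotype_subclones`);
- **per-sample mixing fractions** by interpolating the anchor CN
  between the subclone copy numbers (`estimate_fractions`);
- **bottleneck-outlier detection** via median-centered z-scores for
  stable loci and perpendicular distance to mixing lines for
  mixing-controlled loci (`classify_outliers`);
- **cohort statistics**: Pearson correlation matrices, Welch tests with
  Benjamini–Hochberg correction, volume-change association, cohort
  prevalences (`correlation_matrix`, `cohort_differential_tests`,
  `volume_association`, `prevalence_by_cohort`);
- a **seeded synthetic-data generator** with ground truth
  (`simulate_two_subclone_panel`, `simulate_spatial_drift_panel`) so
  every stage is testable end to end.

See the vignette (`vignettes/subclone-deconstruction.Rmd`) for the
model, its assumptions, identifiability analysis and limitations.

## Worked example

```r
library(subclonemix)

# one homogeneous sample: AF 0.33, CN 2.9 at ERBB4
call_integer_genotype(0.33, 2.9)
#> $m: 1    $t: 3    $residual: 0.00333   (1 of 3 copies mutant)

# a simulated 47-sample panel with mixing fractions spanning (0,1)
# and 10% injected bottleneck outliers
sim <- simulate_two_subclone_panel(simulation_config(
  n_samples = 47, fraction_distribution = "uniform",
  outlier_rate = 0.1, seed = 7))

ep  <- infer_subclone_endpoints(sim$table)       # anchor: LRP1B_AF
gen <- genotype_subclones(ep)
gen$calls[gen$calls$gene %in% c("LRP1B", "ERBB4", "AR"),
          c("gene", "m1", "t1", "m2", "t2")]
#>     gene m1 t1 m2 t2
#> 5  ERBB4  1  3  0  1
#> 6  LRP1B  1  4  0  2
#> 11    AR  0  2  0  4
```

Subclone 1 carries 1 mutant LRP1B copy of 4 and 1 mutant ERBB4 copy of
3; subclone 2 is wild-type diploid at LRP1B with an AR amplification —
the generator's ground-truth genotypes, recovered from the measurements
alone.

```r
p <- estimate_fractions(sim$table, gen$subclone1, gen$subclone2)
round(head(p, 4), 3)
#>  S001  S002  S003  S004
#> 0.930 0.401 0.180 0.014        # fraction of cells in subclone 1

classify_outliers(sim$table)
#> outlier_calls: 5 of 47 samples flagged (max 1 dimensions, 5 distinct patterns)
#> flagged fraction by source: xenograft=0.11
```

Five samples violate the two-subclone geometry (|z| > 3 on a stable
locus or distance > 0.07 from a mixing line); four were injected by the
simulator, and the call matrix in `$calls` gives the dimension and
direction (+1 excess / −1 deficient) of each deviation.
`run_full_pipeline()` chains all stages and writes
genotypes/fractions/outliers/tests/correlation CSVs plus a markdown
summary; `inst/scripts/deconstruct.R` wraps it for the shell.

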