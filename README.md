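# spikechip

Spike-in calibrated ChIP-seq and strand-specific RNA-seq quantification
for genomes whose copy number changes underfoot — the situation in
replicatively ageing budding yeast, where extrachromosomal rDNA circles
amplify the rDNA array several-fold while histone marks redistribute
genome-wide.

Sequencing-depth normalization silently assumes equal chromatin per
sample, which is exactly what ageing breaks. `spikechip` implements the
reference-chromatin (spike-in) calibration instead: a constant mass of
foreign-species chromatin is mixed into every sample, reads are
disambiguated between the two genomes (cross-mappers discarded in both
directions), and each ChIP library is scaled by

```
factor = (1 / D_ChIP) × (D_input / Y_input)
```

where `D_ChIP` and `D_input` are uniquely mapping spike-genome reads in
the ChIP and matched input libraries and `Y_input` is the input read count
on the target genome outside rDNA and mitochondrial sequence. Normalized
signal is then proportional to mark amount per cell. On top of this the
package provides:

* per-1 kb-window copy-number profiles from input coverage, with
  amplified-region detection (the excluded-region set);
* copy-number-corrected window densities (normalized ChIP ÷ input) and
  rDNA vs euchromatin compartment accounting, with the rDNA array
  collapsed onto its 9 kb consensus repeat;
* promoter quantification (TSS to TSS+500 bp, strand-aware) over an
  automatically curated unambiguous-promoter gene set, and TSS ± 2 kb
  metagene profiles;
* strand-specific RNA-seq normalization on mRNA-orientation ORF reads
  (rDNA and mtDNA excluded), sense/antisense quantification under the
  dUTP convention, and the age-versus-histone-depletion expression
  filter with a per-gene audit trail;
* a fully seeded synthetic-data generator that emulates the two-genome
  experimental design (rDNA amplification, rDNA silencing loss, promoter
  peak gains coupled to expression, rising antisense transcription, mild
  H3 decline, constant spike mass) and records every latent parameter,
  so each estimator can be checked against closed-form truth.

Functions take tibbles first and return tibbles, so stages chain with the
pipe; fitted/summary objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` helpers.

## Worked example

```r
library(spikechip)
run <- run_pipeline(pipeline_config(seed = 1))
run
#> <spikechip_run>
#>   rDNA amplification (terminal): 6.93
#>   rDNA H3K4me3 share: 2.2% -> 39.2%
#>   total H3K4me3 fold: 2.11 | euchromatic H3 fold: 0.76
#>   median antisense fold: 1.96
#>   unambiguous genes: 3934/3997 | filter pass: 122
#>   promoter~expression Spearman: 0.926
#>   outputs: /tmp/.../spikechip_run
```

Reading the numbers: the input libraries recover the simulated 7-fold
rDNA amplification (6.93 estimated); spike-calibrated totals show the
rDNA's share of all H3K4me3 rising from ~2% at log phase to ~39% at 48 h
while total per-cell H3K4me3 roughly doubles — driven by copy number, not
per-copy density; euchromatic H3 declines mildly (×0.76); antisense
transcription rises genome-wide; and per-gene promoter H3K4me3 changes
track mRNA induction (Spearman 0.93). Every stage's table is written to
the output directory with a hashed manifest; the same config and seed
reproduce the tree byte for byte.

Individual stages compose the same way on real pre-counted data:

```r
lab  <- disambiguate_reads(reads)                       # dual-genome reads
summ <- assignment_summary(lab, genome)                 # Y and D per sample
fact <- norm_factor_table(chip_summary = summ, input_summary = summ,
                          pairing = pairing)
dens <- window_density(chip_counts, input_counts, fact) # CN-corrected
comp <- compartment_totals(apply_norm(chip_counts, fact),
                           exclude = excluded, samples = samples)
```

Readers for chrom.sizes, GFF3/GTF, BED excluded regions and BED6 TSS
tables are included (`read_chrom_sizes()`, `read_gff_genes()`,
`read_bed_regions()`, `read_tss_table()`); a toy annotation under
`inst/extdata/` shows the expected schemas.

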