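---
title: "Quantifying chromatin in a genome that changes size: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin in a genome that changes size: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Replicatively aged yeast mother cells accumulate extrachromosomal rDNA
circles, so by late age the rDNA repeat can be several-fold amplified while
the rest of the genome stays at copy number one. Two standard practices of
ChIP-seq analysis break in this situation:

1. **Depth normalization misleads.** If an old cell simply contains more
   chromatin (and more of one locus), scaling every library to equal read
   counts erases exactly the biology of interest. `spikechip` instead uses
   a constant mass of foreign-genome chromatin spiked into each sample
   before immunoprecipitation. With reads assigned between the two
   genomes, the per-sample factor

   $$\left(\frac{1}{D_{\mathrm{ChIP}}}\right)\times
     \frac{D_{\mathrm{input}}}{Y_{\mathrm{input}}}$$

   is applied to target-genome ChIP counts, where $D$ counts uniquely
   mapping spike-genome reads in the ChIP and input libraries and
   $Y_{\mathrm{input}}$ counts input reads on the target genome outside
   rDNA and mitochondrial sequence. The first term calibrates ChIP depth
   to the fixed spike mass; the second converts to a per-genome scale, so
   normalized signal is proportional to mark amount *per cell*.
   Multiplying all ChIP counts and $D_{\mathrm{ChIP}}$ by a common depth
   factor cancels algebraically — the package asserts this exactly.

2. **Coverage conflates occupancy and copy number.** A window with
   7-fold amplified DNA shows 7-fold input coverage regardless of
   chromatin state. For per-copy occupancy the normalized ChIP count in
   each 1 kb window is divided by the matched input count
   (`window_density()`); for *total per-cell* amounts the normalized ChIP
   counts are summed as they are (`compartment_totals()`), because the
   amplification is then part of the answer.

Reads from the collapsed rDNA array all map to one consensus repeat unit
(9 kb by convention), so the unit's input coverage relative to single-copy
euchromatin estimates total array copy number, and the expanded interval
around the array (Chr XII 451,000–491,000 in the reference genome) is
excluded from all euchromatic accounting.

## Coordinate and assignment conventions

All coordinates are 0-based half-open; GFF3 (1-based closed) is converted
at the reader boundary (`read_gff_genes()`), BED passes through unchanged.
Read disambiguation is symmetric: any read with alignments in both genomes
is discarded from both (`disambiguate_reads()`), making the result
independent of the order of the two cross-mapping passes; the categories
partition the read set by construction, a property the tests check against
per-row re-classification. "Uniquely mapping" is decided upstream at
ingestion (one reported alignment, or a mapping-quality threshold when
reading from alignments); the package takes the flag as given.

## Promoters, the unambiguous gene set, and profiles

Promoter signal is quantified in fixed windows from the TSS to 500 bp
*downstream in the direction of transcription* — the strand handling is
this package's choice, as a direction-free reading would average promoter
and terminator sequence for minus-strand genes. TSSs come from an
experimental table where available (strongest site per gene), otherwise
the CDS start substitutes, strand-aware. A gene enters the analysis set
only if its promoter window overlaps no excluded region and no *other*
gene's ORF body on either strand; the gene with the contaminated promoter
is dropped, not the overlapping ORF, since the set being curated is the
set of analysable promoters, not the annotation. Overlap of a single base
pair disqualifies — no length threshold is applied to the overlapping ORF,
because any such threshold would be arbitrary. Selection is monotone
(removing genes can only decontaminate), so re-running it on its own
output is a no-op, which the tests assert.

Metagene profiles average normalized signal in strand-oriented bins over
TSS ± 2 kb with equal weight per gene; genes whose flanks cross a
chromosome end are dropped. Offsets are defined so that reflecting the
genome (positions, strands and TSSs) reproduces the identical profile —
an exactness the tests exploit.

## Expression: normalization, antisense, and the age/depletion filter

For opposite-strand-specific (dUTP) RNA-seq libraries the mRNA of a gene
yields reads *antisense* to its ORF. Size factors are therefore per-sample
totals of mRNA-orientation reads over ORFs, excluding rDNA-locus and
mitochondrial genes: in aged cells polyadenylated rDNA non-coding RNAs can
take over a large fraction of the library, and leaving them in would
deflate every other gene. Samples are rescaled to the smallest eligible
total. Antisense (pervasive) transcription is the same-strand read count
per gene under the same factors. A consequence worth stating: because
factors equalize mRNA totals, a genome-wide antisense rise is measured
*relative to the mRNA economy of the cell* — if mean mRNA content also
drifts with age, the measured antisense fold is the latent antisense
multiplier divided by the mRNA mass ratio. The generator's truth record
carries this closed form, and the recovery tests compare against it rather
than against the raw multiplier.

The age/depletion filter selects genes whose expression rises with age
more than 2-fold *relative to the average gene* but rises less than 2-fold
on histone depletion, excluding genes repressed by the galactose-to-
glucose shift of the depletion experiment (their depletion response is
confounded). "Relative to the average" is operationalized by rescaling
each sample to a common mean gene signal before computing per-gene
changes; the mean (not the median, not post-log) was chosen as the most
literal reading, and the un-centred mode remains available. Age change is
computed in two modes — the difference of mean normalized counts and the
ratio — because both conventions circulate for this comparison; the filter
defaults to ratio mode with the difference stored alongside. Missing
galactose flags are an error, never silently treated as "not repressed".

## The synthetic experiment

`simulate_chromatin_counts()` and `simulate_expression()` draw from one
latent model, seeded once, so chromatin and expression data share a gene
programme. The genome (`sim_genome()`) is sized like the system being
emulated: ~12 Mb of euchromatin over six chromosomes, an 86 kb
mitochondrial contig, and a collapsed rDNA unit on chrXII with 150
baseline copies — the baseline count is a generator assumption, taken as a
parameter. Study conditions are the generator defaults: three ages (log,
24 h, 48 h), rDNA amplification 1→4→7-fold, per-copy rDNA H3K4me3 rising
from 20% of the euchromatic average to parity at 48 h, a mild euchromatic
H3 decline (×0.8), an antisense rate rising 1→2→3-fold, promoter peaks
proportional to each gene's relative expression, subtelomeric fixture
regions that amplify with age (the excluded-region class), and a constant
spike-in chromatin mass (5% of log-phase DNA mass). ChIP and input are
simulated in duplicate and RNA-seq in five replicates per time point.

Counts are negative-binomial around segment-mass expectations
(mass = density × copies × length), with Poisson as the zero-dispersion
limit and `noise = "none"` returning exact expectations for analytic
checks. Dispersions are set by data type: 0.01 for input DNA libraries
(near-technical), 0.02 for ChIP duplicates, 0.05 for RNA-seq biological
replicates. Two representations of each H3K4me3 ChIP library are emitted —
per-window counts and read-level 5′ positions — so the pipeline is
testable with and without the alignment-ingestion layer; they are
independent draws of the same library model, and their compartment shares
agree to within counting noise.

What the generator does *not* emulate: sequence-level reads (no FASTQ, no
mappability or GC structure), PCR duplicates, spatially correlated
coverage biases, nucleosome-scale signal shape beyond a fixed promoter
peak, and cell-to-cell heterogeneity. Passing tests therefore demonstrate
correctness of the quantification algebra and estimator behaviour under
realistic count noise, not robustness to alignment artefacts.

## Numerical choices

* **Copy-number reference.** The per-window CN track divides by the
  *median* euchromatic per-base density — robust, and the definition used
  for the per-window contract. For the scalar rDNA copy-number estimate,
  the median of low-coverage windows is integer-quantized (at ~3 reads per
  window it sits several percent from the mean), so when the
  excluded-region set is supplied `rdna_copy_number()` uses the unbiased
  mean density over non-excluded euchromatin: the masking already removes
  amplified sequence, so the mean needs no robustness.
* **Class-level density.** Comparing mean per-window ChIP/input ratios
  between window classes inherits an upward Jensen bias of roughly the
  squared CV of the input counts, which differs between high- and low-
  coverage classes. `compartment_density()` therefore aggregates as the
  ratio of sums; the per-window track remains available for profiles.
* **Zero-input windows** carry no copy-number information; their density
  is `NA` with a `low_input` flag (floor configurable), never a silent
  zero. Degenerate spike counts (`D = 0` or `Y = 0`) are explicit errors.
* **Terminal windows** shorter than 1 kb are kept; densities are
  per-base, so window length cancels and tiling length-conservation stays
  exact.
* **Input normalization in density mode.** One description of the
  copy-number correction divides by raw input, another by spike-normalized
  input. Both are implemented (`mode = "raw"` / `"spike"`); the default is
  `"spike"`, under which the factor algebra reduces the input side to
  division by $Y_{\mathrm{input}}$, making ratios comparable across
  samples.
* **Fold-change references.** Compartment fold-changes use the mean of
  the reference-age (log) samples; the reference is configurable.

## Problem sizes

The default verification runs use the full 12 Mb genome (≈12,000 windows),
4,000 genes, 2 × 10⁶ reads per ChIP/input library and 10⁶ per RNA library;
recovery checks at amplification {2, 4, 7} run at 10⁵ input reads, and the
compartment-fraction grid uses four ChIP replicates to put the estimator's
standard error well inside the two-percentage-point band being checked.
With these sizes the whole pipeline runs in about a minute on one core.

## Known limitations

Promoter windows are fixed geometry — no peak calling, by design. The
spike-in factor assumes constant spike mass per sample; pipetting error in
the spike itself is not modelled and would propagate directly. The
antisense quantification attributes all same-strand reads within an ORF to
antisense transcription, with no attempt to separate readthrough from
internal initiation. Statistical testing of per-window differences,
differential-expression significance, clustering and enrichment analysis
are out of scope: the package produces the calibrated quantities those
tools consume.
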