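# amplicall

Genotype calling from multiplexed amplicon sequencing for marker-assisted
selection panels.

Breeding programs genotype many samples at a modest panel of trait-linked
loci (disease resistance, quality, pre-harvest sprouting, ...). In the
multiplexed amplicon design, each locus is amplified with a locus-specific
primer pair, every sample is tagged with a DNA barcode through a two-round
fusion-primer library build, and the pool is sequenced in bulk. `amplicall`
turns the resulting FASTQ into per-sample, per-marker genotype calls:

1. **demultiplex** reads into samples by barcode (Hamming prefix match,
   tolerance 1);
2. **assign** each read to a marker by its M13-tail + forward-primer prefix
   (tolerance 2), trimming the prefix and trailing adapter;
3. **align** each insert to its marker's reference amplicon with a banded
   global affine-gap aligner and extract the base observed at every
   annotated variant site (A/C/G/T, or N for a gap or uncovered site);
4. **count and call**: tabulate per-site allele counts, compute the percent
   favorable-allele reads, derive per-marker cutoffs from in-run positive
   controls, and call genotypes.

The calling model is allele read fraction against a control-anchored
cutoff. In a polyploid such as bread wheat, a primer pair may co-amplify
1, 2 or 3 homoeologous subgenomes; with `a` favorable alleles among the
target genome's two and only wild-type homoeologs, the expected favorable
read fraction is

    %favorable = 100 * a / (2c),   c = genomes co-amplified (1, 2, 3)

i.e. 100/50/0, 50/25/0 or 33.3/16.7/0 — so thresholds must be per-marker.
A sample calls `homozygous_positive` when its percentage is at or above
the minimum observed among the run's positive controls (with a depth-aware
binomial guard band; see the methods vignette), `homozygous_negative`
below, `no_call_low_depth` under 10 accepted reads. Dominant null-allele
markers (indel/alien-fragment loci where one allele yields no amplicon)
are called by presence/absence, with zero reads flagged
`null_allele_putative` — cautiously, since a true null is indistinguishable
from PCR failure.

A synthetic read simulator with full ground truth (read layout, homoeolog
co-amplification, negative-binomial depth, substitution error, contaminant
spike-in) makes the entire pipeline testable end to end; it is first-class,
tested code.

## Worked example

Simulate a 12-sample x 6-marker run (3 positive controls, 1 negative
control, ~200 reads per sample-marker pair, 0.5% substitution error, 3%
contaminant spike) and genotype it:

```r
library(amplicall)

expected_allele_fraction(c("AA", "TT"))   # favorable hom + 1 wild-type homoeolog
#> [1] 50

p   <- make_default_panel(n_markers = 6, seed = 11, n_samples = 12)
sc  <- sim_scenario(p, reads_per_marker = 200, seed = 42)
sim <- simulate_reads(sc)
sim
#> <sim_result> 13518 reads (13112 structured + 406 contaminant) -> .../reads.fastq

run <- run_pipeline(sim$fastq, p)
run
#> <amplicall_run> 13518 reads in; 108 calls over 6 markers
#>   unassigned barcode 427 | unassigned marker 16 | alignment rejected 0
#>   calls: homozygous_negative=49, homozygous_positive=53, null_allele_putative=6
```

The 427 unassigned reads are the 406 structured-less contaminants plus a
handful of reads with barcode errors beyond tolerance. `M02` here is a
semi-genome-specific marker, so homozygous-favorable samples sit near 50%
favorable reads and wild-type samples near 0%:

```r
head(run$calls[run$calls$marker_id == "M02",
               c("sample_id", "site_id", "depth", "percent_favorable", "call")])
#>    sample_id site_id depth percent_favorable                call
#> 25       NC1    S115    78          0.000000 homozygous_negative
#> 26       PC1    S115   307         46.579805 homozygous_positive
#> 27       PC2    S115    55         52.727273 homozygous_positive
#> 28       PC3    S115   292         53.767123 homozygous_positive
#> 29       S01    S115   137          0.729927 homozygous_negative
#> 30       S02    S115   313          0.000000 homozygous_negative
```

Every call matches the simulated truth:

```r
truth <- sim$truth; truth$call <- truth$expected_call
concordance(run$calls, truth)
#> <amp_concordance> overall 1.000 over 108 compared calls
```

`run_pipeline(..., outdir = "out")` additionally writes the allele-count,
cutoff, call and call-rate TSVs plus a JSON/text run report. A thin CLI
with subcommands `simulate`, `run`, `concordance`, `validate-panel` and
`build-primers` is installed at `inst/exec/amplicall`.

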