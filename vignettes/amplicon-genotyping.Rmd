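---
title: "Genotype calling from multiplexed amplicon sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype calling from multiplexed amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicall)
```

## The problem

Marker-assisted selection programs screen large numbers of breeding lines at
a modest panel of trait-linked loci. Multiplexed amplicon sequencing does
this in one sequencing run: each locus is amplified with a locus-specific
primer pair, each sample is tagged with a DNA barcode through a two-round
fusion-primer library build, everything is pooled and sequenced, and the
genotype at each annotated SNP is read off the fraction of sequencing reads
carrying the favorable (trait-associated) base.

`amplicall` implements the analysis side of this design: read sorting,
alignment, allele counting, and genotype calling, together with the
expected allele-fraction model needed to interpret read fractions in a
polyploid crop, and a synthetic read simulator so the whole pipeline can be
validated against a known truth without any sequencing data.

## Library structure and fusion primers

The first PCR uses the locus-specific primers tailed with universal
sequences: an M13-derived tail (`GATGTAAAACGACGGCCAGTG`) on the forward
side, a truncated P1/B adapter (`CCTCTCTATGGGCAGTCGGTGAT`) on the reverse
side. The second PCR adds, 5' to 3', the A adapter
(`CCATCTCATCCCTGCGTGTCTCCGACTCAG`), a sample barcode of 10--12 nt, and the
same M13 tail. After the instrument strips the A adapter, a read therefore
runs: barcode, M13 tail, forward primer, insert, reverse-complemented
reverse primer, P1/B adapter. `expected_read_layout()` encodes this
structure; the simulator emits it and the read sorter trims it. A
configuration point left open by instrument variation -- whether raw reads
still retain the A adapter -- is handled by the layout being explicit: reads
are expected to begin at the barcode, which matches standard basecalling
behavior.

## The expected allele-fraction model

Bread wheat is hexaploid; a primer pair may amplify only its target
subgenome (genome-specific), one homoeologous copy as well
(semi-genome-specific), or all three (non-genome-specific). Co-amplified
homoeologs carry the wild-type base, so they dilute the favorable-allele
read fraction. Assuming equal amplification of all templates, a sample
whose target-genome genotype has $a$ favorable alleles out of 2, amplified
together with $c - 1$ wild-type homoeologous genomes, is expected to show

$$\mathrm{\%favorable} = 100 \cdot \frac{a}{2c}, \qquad c \in \{1, 2, 3\}.$$

`expected_allele_fraction()` returns this value exactly: 100/50/0 for one
genome, 50/25/0 for two, and $100/3$, $100/6$, 0 for three -- values that
truncate to the familiar 33 and 16 when printed as integers. The model's
practical consequence is that a homozygous-favorable sample at a
non-genome-specific marker shows only ~33% favorable reads, so fixed
global thresholds are unusable and calling must be anchored per marker.

## Pipeline

1. **Demultiplexing.** Read prefixes are compared to every barcode at its
   own length by Hamming distance (default tolerance 1 mismatch). Ties go
   to the longer barcode; exact ties are unassigned. Barcodes must be
   pairwise separated by more than the tolerance or the run aborts --
   mixed-length sets are compared over the shorter length.
2. **Marker assignment.** Within each sample, the expected `M13 tail +
   forward primer` prefix of each marker is matched the same way
   (default tolerance 2 mismatches, substitutions only). The prefix is
   stripped and the trailing reverse-primer/adapter segment trimmed when it
   matches within 25% of its length.
3. **Alignment.** Each insert is aligned to its marker's reference insert
   region (the reference amplicon minus both primer spans) with a banded
   global affine-gap aligner (match +1, mismatch −1, gap open −2, gap
   extend −1, band ±10 diagonals, minimum identity 0.9). Each read was
   already assigned to a single short reference, so a database-search
   aligner would add nothing; an exact pairwise dynamic program is simpler
   and deterministic. Ties are broken diagonal > gap-in-read >
   gap-in-reference, so identical inputs give identical alignments. We use
   a plain global alignment rather than free end-gaps: after trimming, the
   insert is coextensive with the reference insert, a short read simply
   pays its end gaps, and every uncovered or gapped site is observed as
   `N` (null allele or deletion) either way. The banded score is provably
   identical to the unbanded optimum whenever the true indel displacement
   is within the band; the test suite verifies this against an independent
   full dynamic-programming oracle on a thousand random pairs.
4. **Counting and calling.** Accepted reads contribute one observation per
   annotated site (multi-SNP amplicons yield one observation per site per
   read); observations are tabulated into A/C/G/T/N counts per (sample,
   marker, site), including explicit zero rows so absence of reads is
   visible to the null-allele logic.

## Calling rules

The percent favorable reads is $100 \, n_\mathrm{fav} / n_\mathrm{total}$,
computed and compared at full precision and displayed to one decimal;
third bases arising from sequencing error stay in the denominator, per the
literal definition. A site with fewer than 10 accepted reads is
`no_call_low_depth` -- lowering this cutoff demonstrably admits false
positives, and 10 total reads at the site is the interpretation adopted
for "reads per allele" (flagged as an interpretation, since a per-allele
reading would double the requirement).

**Control anchoring.** Each run must carry positive-control samples known
homozygous favorable. The cutoff for a (marker, site) is the *minimum*
percent favorable among qualifying in-run controls (depth at or above the
minimum); a single control degenerates to its own value. A marker without
a qualifying control yields `no_call_no_control` -- cutoffs are
deliberately not portable across runs.

**Guard band.** The control cutoff estimates the positive class's own read
fraction. A positive sample's observed fraction is an independent binomial
draw around the same level, so comparing it to the control minimum with a
bare $\ge$ would misclassify a sample that draws slightly low -- with $R$
controls, roughly $1/(R+1)$ of true positives would fall under the control
minimum regardless of depth. The caller therefore compares against
$\max(\mathrm{cutoff} - z\,\mathrm{SE},\ \mathrm{cutoff}/2)$, where SE is
the binomial standard error of the cutoff fraction at the sample's own
depth (shrunk by one pseudo-observation so it stays positive at 0 and
100%), and $z$ defaults to 4. The floor at half the cutoff keeps the
threshold well above the negative class, whose expected fraction is near
zero at every specificity class; the form is monotone in the cutoff, so
raising a cutoff can never turn a negative call positive. A percentage
exactly equal to the raw cutoff always calls positive, preserving the
"equal to or greater" rule; `cutoff_guard_sd = 0` restores the literal
rule for users who want it.

**Dominant null-allele markers.** For indel- or alien-fragment-derived
markers one allele produces no amplicon at all. These are presence/absence
calls: depth at or above the minimum is `homozygous_positive`, exactly
zero reads is `null_allele_putative`, and anything in between is
`no_call_low_depth`. The null call always carries a caution flag because a
true null is indistinguishable from PCR failure; a dominant marker never
calls `homozygous_negative`.

**Heterozygotes.** Off by default. The panels this design targets are
inbred lines, and in a polyploid background the het/hom separation is
compressed (50 vs 100 at best, 16.7 vs 33.3 at worst). When enabled, an
explicit percent band must be supplied, ideally anchored on a synthetic
heterozygote control (an equal mix of favorable and wild-type DNA).

**Concordance.** `concordance()` computes the proportion of matched calls
between two call tables over the samples compared, per marker and overall.
Non-confident calls are excluded from the denominator by default (matching
how scored genotypes are compared between assay systems); a flag counts
them as mismatches instead.

## The simulator

`simulate_reads()` exists so that every pipeline stage has a ground-truth
oracle. It emulates:

* the full read layout above, per sample and marker;
* homoeolog co-amplification: each marker gets $c$ genome templates, the
  non-target ones carrying wild-type bases plus a fixed 2% background
  divergence at non-site positions (a property of the genome, drawn once
  per marker, not per read);
* template sampling: each read draws uniformly from the $2c$
  allele-resolved haplotypes -- the equal-amplification premise of the
  fraction model;
* depth variation: per-pair read counts are negative-binomial around a
  configurable mean (default 800 reads per sample-marker pair, near the
  ~900 average of a well-tuned run; dispersion size 5, reflecting the
  orders-of-magnitude per-marker spread real runs show; `Inf` fixes depth
  exactly for analytic tests);
* sequencing error: i.i.d. substitutions at a configurable rate (default
  0.5%, a plausible single-pass substitution rate; stated as an
  assumption, not a measured value);
* contamination: a configurable fraction (default 3%) of random unrelated
  reads with no valid barcode or primer structure, emulating a spike-in of
  a foreign library;
* nulls: dominant-marker null genotypes and designated (sample, marker)
  pairs emit zero reads.

Default ground truth draws only homozygous genotypes, matching inbred
variety panels; positive controls are forced homozygous favorable and
negative controls wild type or null. All randomness is fixed by one seed;
the same scenario reproduces the same FASTQ byte for byte.

What the simulator does *not* model: PCR-cycle dynamics and
primer-competition effects between pooling tiers (depth differences are
modeled only through per-marker means), homopolymer/indel errors typical
of semiconductor flowgrams (substitutions only), quality-score structure
(constant Q30 placeholders), and chimeric reads. Passing the simulation
suite therefore demonstrates the correctness of the *analysis logic* under
a realistic read-generating process, not robustness to every artifact of a
particular chemistry.

## Numerical and degenerate-input choices

* Variant positions are 1-based on the reference amplicon, which includes
  both primers; positions inside a primer span are rejected at validation.
* All sequences are upper-cased on ingest; percent comparisons happen at
  full precision (rounding only at display) to avoid boundary artifacts at
  the cutoff.
* The expected fraction is kept as an exact rational; a floor is applied
  only when comparing to integer-printed tables.
* Zero-depth sites have *undefined* (NA) percent favorable, never 0 -- the
  distinction is what makes null-allele logic sound.
* An empty insert after trimming contributes no observations; a read whose
  alignment identity falls below 0.9 is rejected and counted.
* Problem sizes used in the test suite (tens of samples, ~10 markers,
  depths 30--10,000) were chosen to make every stochastic assertion sharp
  at comfortable runtime; they match the scale of a real plate-format run.

## Known limitations

* The guard-banded threshold is a pragmatic safeguard, not a genotype
  likelihood model; a binomial-mixture dosage caller would be the natural
  extension and is intentionally out of scope.
* Barcode and primer matching are substitution-only (no indels), matching
  the fixed-position read layout; indel-tolerant demultiplexing would
  require gapped prefix alignment.
* Each read is aligned only to the marker its primer assigned it to;
  cross-marker realignment is not attempted.
* A panel whose forward primers are within the assignment tolerance of one
  another is rejected at validation rather than resolved probabilistically.
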