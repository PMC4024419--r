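---
title: "Methods: repeat-mediated deletion analysis with aludel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated deletion analysis with aludel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aludel)
```

# Scope and model

aludel characterises a single large genomic deletion produced by
non-allelic homologous recombination (NAHR) between two interspersed
repeat copies, and builds the downstream diagnostics around it. The
underlying model is an *equal crossover*: two co-oriented, homologous but
non-allelic repeat copies align out of register during meiosis, and a
crossover within a block of perfect identity joins the 5' part of the
upstream copy to the 3' part of the downstream copy, deleting everything
between the aligned positions. Two consequences drive the design:

* For equal-length, co-oriented copies the deletion length equals the
  distance between the copy starts, independent of where within the
  copies the crossover occurred.
* The crossover's identical block survives in the mutant as **breakpoint
  microhomology**: a deletion flanked by an `mh`-bp identical block has
  exactly `mh + 1` placements that produce the same mutant sequence, so
  the "true" breakpoint is unknowable from sequence alone. aludel reports
  the most-3' placement (the HGVS normalisation rule) as the canonical
  name and keeps the full ambiguity window on the call object.

# Coordinates

Internally every interval is 1-based inclusive, carried by
IRanges/GRanges — the native convention of the Bioconductor containers the
package is built on. Interchange formats keep their own conventions, with
conversion confined to the I/O boundary: the RepeatMasker `.out` dialect
and HGVS strings are 1-based inclusive, BED export is 0-based half-open,
and the VCF record places POS on the base before the deletion as symbolic
alleles require.

# Repeat catalogue

`parseRepeatMaskerOut()` consumes the whitespace-delimited `.out` dialect
(score, divergence/deletion/insertion percentages, query window
coordinates with a parenthesised remaining-bases column, `+`/`C`
orientation, repeat name, class/family, repeat coordinates, linkage id).
`C` is treated as minus strand, the standard reading of the format. The
window length is recovered from the per-row invariant
`query end + query left = window length`, so window-relative coordinates
need no side channel.

`summarizeRepeats()` merges overlapping annotations per group before
counting coverage (no base counted twice), counts *elements* as distinct
linkage ids (so an interrupted LINE split into three fragments is one
element), and reports the interspersed total excluding the
`Simple_repeat` and `Low_complexity` classes. Reported fractions are
rounded half-up to two decimals; conventional half-up rather than R's
round-half-even, so printed percentages match hand arithmetic on the
table.

`findRecombinogenicPairs()` considers ordered pairs with identical
subfamily name (a flag relaxes this to class/family — the default is
strict because NAHR substrates are typically subfamily-identical) and
identical orientation, and scores each pair by global pairwise alignment
of the two repeat subsequences, identity = matches / alignment columns.
No identity metric is canonical for this purpose; alignment-column
identity was chosen as the conventional one. Candidates are ranked by
identity, ties broken by smaller inter-repeat distance (closer pairs
recombine more readily). The predicted deletion range brackets what an
equal crossover can produce: minimum `start(B) − end(A)`, maximum
`end(B) − start(A)`.

# Breakpoint mapping

`mapDeletionJunction()` mirrors the classical bench procedure — the
breakpoint is the last nucleotide of identity between wild-type and
mutant — as a deterministic algorithm:

1. Anchor each junction end in the reference with an exact k-mer seed
   (default `anchorK = 25`). If the terminal k-mer is not unique in the
   reference (it may sit inside a repeat), the window slides inward until
   a unique one is found; the implied alignment of the junction terminus
   is kept. No heuristic aligner is needed at locus scale, and the result
   is reproducible to the base.
2. Extend base-by-base identity rightward from the left anchor and
   leftward from the right anchor. By default extension stops at the
   first mismatch — appropriate for Sanger-consensus junctions, which is
   the intended input. An error-tolerant mode (`maxMismatch > 0`) absorbs
   up to that many mismatches per side; it is off by default and
   documented as changing microhomology semantics, since tolerated
   mismatches make "identity" approximate.
3. The two extensions must jointly cover the junction; their overlap is
   the microhomology. A junction they cannot cover (an unexplained
   insertion) or that implies a non-positive deletion length is rejected
   with a specific error rather than force-fitted.

Sequence handling is case-insensitive and any non-ACGT character
terminates extension, so masked references degrade loudly, not silently.

`microhomologyLength()` and `normalize3Prime()` are pure functions of
reference and interval, checked in the test suite against an exhaustive
slide oracle that re-derives the equivalent-placement set by string
equality at every start position.

HGVS handling validates rather than repairs: `parseHgvsG()` computes the
implied length `end − start + 1` and flags disagreement with a stated
`del<n>` suffix without correcting either. This matters because published
descriptions of one and the same event can disagree: the locus that
motivated this package was printed with two mutually inconsistent genomic
coordinate pairs (3925 vs 3926 bp, offset by about 4.4 kb, against two
different reference records). Each string is internally consistent; the
package validates both and deliberately does not decide which is
authoritative. Similarly, published descriptions of the analysed window
itself can disagree with the repeat table's caption; the packaged fixture
follows the table (9358 bp), which is the only version whose arithmetic
is reproducible.

`cDeletionLength()` resolves cDNA endpoints with signed intronic offsets
against an exon map (contiguous cDNA coordinates, matching genomic
widths); for a fully deleted exon spanning c.s–c.e with offsets u and v
the genomic length is `u + (e − s + 1) + v`.

# Virtual PCR

`findBindingSites()` scans both strands with a mismatch budget (default
0) but requires the 3'-terminal `exact3Prime` bases (default 5) to match
exactly — a mismatched 3' terminus prevents polymerase extension, which
is the physically meaningful failure mode. `N` in a primer matches any
template base. `predictAmplicons()` pairs plus-strand forward sites with
minus-strand reverse sites whose footprints are ordered on both edges
(this makes the rule exactly invariant under strand mirroring) and sizes
products inclusive of both primer footprints — the convention under
which a published 4526 bp wild-type junction amplicon minus a 3925 bp
deletion gives the observed ≈500–600 bp mutant product.

Detectability models the reach of the extension protocol, not product
specificity: default `maxProductLen = 2000` for standard PCR,
raised (e.g. 12000) for long-range mode. The two-reaction genotype call
is a total function over the four outcome combinations; multiple or
nonspecific products are reported, never errored, and only the intended
product's detectability feeds the call. Primer annealing temperatures are
carried as annotations only — thermodynamics is out of scope.

# Founder haplotypes

Under consanguinity, an affected individual homozygous by descent carries
the founder haplotype twice, so homozygous genotypes are phased trivially
and no general phasing algorithm is implemented — that inference is the
point of the module. Alleles are integer fragment sizes in bp with no
stutter or binning model. A candidate founder haplotype must be carried
homozygously and completely by affecteds of at least two distinct
families; a family supports a candidate when all its typed affecteds
match at every typed marker. The `relax` flag tolerates one discordant
marker per affected, encoding the common situation where a founder
haplotype segregates alongside a one-step microsatellite variant
(e.g. 129–188 alongside 129–186) without resolving which is ancestral.
Marker panels are user-supplied; two packaged panel fixtures reflect the
fact that published marker namings for the same locus can differ between
a study's methods and results, a discrepancy the package documents rather
than resolves.

# Simulator

`simulateLocus()` emulates the features of the real system that the
analysis depends on:

* i.i.d. uniform A/C/G/T background (default 9358 bp) with 19 planted
  repeat copies covering ≈51% of the window — the gross landscape of the
  motivating locus — including two co-oriented copies of one Alu-like
  subfamily 3910 bp apart at 5% divergence, interrupted LINE-like
  fragments sharing a linkage id, a simple repeat, and two DNA-transposon
  fragments.
* Repeat copies are point-mutated windows of packaged **synthetic**
  consensus sequences (seeded random, ~300 bp Alu-like and ~1 kb
  L1-like); they are labelled synthetic everywhere because only the
  identity structure matters to the algorithms, not biological sequence
  content.
* The crossover is clean equal recombination: no conversion tracts, no
  junction indels. When a target microhomology is configured (default
  35 bp, range 0–60), an identical block of exactly that length is
  planted around the crossover with mismatch guards immediately outside
  it, so the truth microhomology is exact by construction; with
  `mhLen = NULL` the copies' natural identity structure is used instead.
* Junction reads are long error-free fragments (default 500 bp flanks),
  mirroring direct Sanger sequencing of a junction amplicon; an optional
  substitution error rate up to 0.1 exists but defaults to 0.
* Pedigrees: ten families, one affected (homozygous founder haplotype
  129–188 by descent) and two carrier parents each, with non-founder
  alleles drawn from four-allele frequency tables. `founder = NULL`
  yields the no-founder null model used to check the spurious-sharing
  rate against its closed form.

Determinism: all draws derive from the master seed through independent
sub-streams (background, repeat mutation, pedigree, read errors), so
identical (config, seed) gives byte-identical output and changing one
plan leaves the other outputs unchanged.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequencing reads with realistic error/quality
models, gene-conversion tracts or junction indels, heterogeneous repeat
ages, population structure beyond a single founder allele, marker
mutation/stutter, and recombination between the marker panel and the
locus. The end-to-end guarantees (exact breakpoint and microhomology
recovery, 100% genotype concordance) are statements about clean
junctions and error-free markers.

# Problem sizes and numerical choices

The default test and acceptance runs use the sizes the methods are meant
for: ~9.4 kb loci, deletions of 0.5–6 kb, microhomology 0–60 bp (200
seeded replicates for the recovery sweep), cohorts of ~30 samples, and
1000 Monte-Carlo replicates for the null-model founder check, which is
compared to the analytic product of homozygosity probabilities within
three binomial standard errors. Exhaustive oracles (per-base coverage
bitmaps, full-offset binding-site scans, all-placement slide checks) back
every non-trivial computation on smaller instances. Ties in pair ranking
are broken deterministically (identity, then inter-repeat distance, then
coordinates); reported fractions round half-up at two decimals; all
percentage comparisons in tests are exact because the quantities are
ratios of integers.

# Limitations

Single contiguous deletions only — no multi-deletion or inversion
junctions, no read-level SV calling from alignments. Repeat *detection*
is out of scope: the catalogue consumes existing RepeatMasker-style
annotation or simulator truth, it does not rediscover repeats. Primer
design and thermodynamics are out of scope; the virtual PCR evaluates
given primers. Founder analysis performs no linkage LOD computation or
haplotype dating.
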