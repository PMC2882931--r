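---
title: "varkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{varkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varkit)
```

varkit is a self-contained toolkit for population variation data. It keeps a
reference genome together with variants, per-individual genotypes, linkage
disequilibrium, transcript-level consequence predictions and resequencing
coverage in one inspectable dataset, and it makes the expensive parts —
genotype storage and LD — cheap by design: genotypes are delta-compressed
into fixed genomic windows and LD is computed on the fly rather than stored.
This vignette explains the models behind each component, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
test substrate does and does not demonstrate.

## Coordinates and the data model

All coordinates are 1-based, fully closed intervals. Insertions are
represented with `start = end + 1`, the insertion point sitting between the
two flanking bases. Variation features (placements of a variant on the
reference) always express their alleles on the **forward** strand: alleles of
reverse-strand mappings are reverse-complemented at feature creation, while
the feature's `strand` field records the original mapping orientation. That
orientation is deliberately retained — flank compression (below) needs to
know on which strand the variant's 5′/3′ flanks were read.

Structural variants carry four coordinates (`outer_start <= inner_start <=
inner_end <= outer_end`) because their breakpoints are usually known only to
within a range; region queries are judged against the outer, most generous
interval, so a query touching only the uncertain flank still reports the SV.

A dataset persists as a directory of tab-separated text tables plus a FASTA
reference, a binary sidecar holding the genotype blobs (addressed by offset
and length), and a JSON manifest carrying a format version. The store is
diff-able and greppable; loading verifies the manifest and reproduces every
table value-identically and every blob bit-for-bit.

## Flank mapping and QC

A variant enters the toolkit assembly-independently: a name, an allele list
(reference allele first, deletions written `-`) and raw 5′/3′ flanking
sequences. `map_flanks()` searches for the composite
`flank_up + reference_allele + flank_down` **exactly**, on both strands of
every region. Exact search is the deliberate desk-scale mapping engine; the
operation's contract (every placement, allele-delimiting coordinates, no
cap) is what matters, and a fuzzy aligner could be swapped in behind it.
Overlapping occurrences count separately; a palindromic composite matching
both strands at one locus is counted once, on the forward strand, because it
is a single physical placement.

`apply_qc()` then enforces three failure rules: no mapping (`NO_MAPPING`),
more than `max_mappings` placements (`TOO_MANY_MAPPINGS`, default N = 3), and
disagreement between the declared reference allele and the genome at a
mapped location (`ALLELE_MISMATCH`; for deletions the deleted reference bases
are compared, for insertions only flank adjacency is checked, since there is
no reference allele to compare). Whitelisted variants — e.g. clinically
significant ones — are never failed; when such a variant exceeds the cap we
keep the N leftmost placements (by region, then start) but set `map_weight`
to the *true* placement count, so table growth stays bounded without lying
about multiplicity. The N-cap is applied genome-wide, not per region.
`purge_failed()` deletes all supplementary data of failed variants (features,
alleles, flanks, frequencies, annotations, and genotypes located via the
variant's pre-purge feature coordinates), leaving only a name/source/reason
tombstone; it is idempotent.

Flank compression replaces a raw flank by coordinates whenever it exactly
equals the reference adjacent to the mapped allele, respecting the mapping
strand: for a reverse-strand feature the variant's 5′ flank is the reverse
complement of the reference immediately 3′ of the feature, and the stored
coordinate record carries strand −1 so `restore_flank()` can reproduce the
original sequence exactly. Compression is only ever applied when restoration
is the identity.

## The genotype codec

One compressed row holds all single-base genotypes of one individual inside
one fixed window. Windows are genome-anchored and 1-based: window *k* covers
`[k·W + 1, (k+1)·W]` with `W = 100000` bp by default. Anchoring windows to
the genome (rather than to each row's first genotype) means a region query
touches only the rows of overlapping windows.

The blob is a repeating triplet: distance from the previous genotype,
allele 1, allele 2. The first genotype's distance is always zero and is not
stored — its absolute position lives in the row's `start` field and is
restored during decoding. Distances are unsigned LEB128 (7 bits per byte,
little-endian, high bit = continuation); alleles are single ASCII bytes over
`A/C/G/T/N`, with `N` the missing-allele sentinel so the layout stays
uniform. For n genotypes whose gaps are all under 128 bp — the common case
for dense genotyping — the row costs exactly `3n − 1` bytes; the worst case
inside a 100 kb window is `2n + 3(n−1)` bytes, since no in-window distance
needs more than three LEB128 bytes. Decoding validates as it goes and
reports the byte offset of any truncation, invalid allele byte or LEB128
overrun.

Heterozygous allele pairs are stored in input order and compared
order-insensitively where that matters; multi-base genotypes never enter the
compressed table and are routed to a separate uncompressed multi-bp table.

## On-the-fly linkage disequilibrium

For two biallelic loci, genotypes are tabulated as a 3×3 table `n[i][j]` of
copies of allele A (first seen at locus 1) and allele B (first seen at
locus 2), excluding individuals missing either genotype. Every cell except
the double heterozygote has unambiguous phase; the EM algorithm resolves the
remainder:

* **E-step** — each double heterozygote is assigned to the coupling
  configuration (AB/ab) with weight
  `p_AB·p_ab / (p_AB·p_ab + p_Ab·p_aB)`, else repulsion (Ab/aB);
* **M-step** — expected haplotype counts are renormalised over `2·n`.

Iteration starts at linkage equilibrium (`p_AB = p_A·p_B`) and stops when no
frequency moves by more than `tol = 1e-10`, with a cap of 1000 iterations.
Both controls are our declared defaults, not values taken from elsewhere.
Two consequences of the equilibrium start are worth knowing. First, the EM
preserves the sample allele frequencies exactly at every iteration. Second,
the degenerate table in which *every* individual is a double heterozygote has
the equilibrium point as a fixed point, so it converges immediately to
D = 0 — a documented behaviour rather than a numerical accident (for that
table the likelihood is symmetric in the two phase assignments and provides
no information to prefer either).

From converged frequencies: `D = p_AB − p_A·p_B`;
`D' = |D| / D_max` with `D_max = min(p_A·q_B, q_A·p_B)` for positive D and
`min(p_A·p_B, q_A·q_B)` otherwise (reported as 0 when D = 0, avoiding 0/0);
`r² = D² / (p_A·q_A·p_B·q_B)`. Monomorphic loci make LD undefined and are
skipped with a recorded reason by `pairwise_ld()`, which otherwise computes
every in-slice pair within `max_distance` directly from the compressed
store. Homozygous-throughout (inbred) individuals need no special casing —
they simply contribute phase-known haplotypes.

## Consequence prediction

Transcript models carry exons in transcript (5′→3′) order, optional genomic
CDS bounds, and a protein-coding or non-coding biotype. `classify()` applies
rules on the transcript's coding strand:

* CDS substitutions translate the reference and alternate codon with the
  standard genetic code: `STOP_GAINED`, `STOP_LOST`, `SYNONYMOUS_CODING` or
  `NON_SYNONYMOUS_CODING`, with codon change, peptide change, cDNA and
  protein positions reported.
* CDS indels whose net length change is not divisible by 3 are
  `FRAMESHIFT_CODING`; in-frame indels are classed `NON_SYNONYMOUS_CODING`
  because they alter the peptide without disrupting the frame.
* The first/last 2 intronic bases are `ESSENTIAL_SPLICE_SITE`; intronic
  bases 3–8 from a junction, and the last 3 exonic bases at a junction, are
  `SPLICE_SITE` (which may co-occur with a coding type).
* Exonic-but-not-CDS positions are `5PRIME_UTR`/`3PRIME_UTR` by transcript
  orientation; intron interiors are `INTRONIC`; within 5 kb of the
  transcript are `UPSTREAM`/`DOWNSTREAM`; non-coding exons are
  `WITHIN_NON_CODING_GENE`; a supplied regulatory set adds
  `REGULATORY_REGION`; anything else is `INTERGENIC`, which never co-occurs
  with another type.

The 5 kb flank and the 2/3–8/3 splice windows are declared constants chosen
to match long-standing annotation conventions. Variants spanning an
exon/intron boundary take the union of the per-position types. The severity
ranking is the fixed order of `CONSEQUENCE_TYPES`, most severe first;
`most_severe` is always the highest-ranked member of a call's type set.
`predict_novel()` runs the same rules for an arbitrary location/allele
against every transcript within 5 kb — the variant need not exist in the
dataset — and returns calls sorted by severity.

## Resequencing views

Read alignments are represented compactly as coverage intervals per
individual, region and positive integer *level* (an opaque depth class —
importers may bin real depths upstream). Overlapping or adjacent intervals
of the same level merge at insertion. Where intervals of different levels
overlap, `coverage_at()` reports the maximum level; summing is a plausible
alternative convention, but a maximum matches the "highest depth class
attained" reading of levels and keeps the piecewise output stable under
re-insertion of the same data.

`individual_sequence()` reconstructs an individual's sequence over a slice:
start from the reference, substitute homozygous non-reference single-base
genotypes, render heterozygous sites as IUPAC ambiguity codes (R = A/G and
so on), and lowercase-mask positions with no coverage. The contract is
length-preserving — indels are refused and belong in VCF export — so the
output is always FASTA-legal and exactly as long as the slice.

## Interchange and the command line

FASTA, GFF3/GTF and BED are read with Biostrings and rtracklayer; VCF import
uses vcfR. REF/ALT become the allele string (reference first, `/`-separated);
single-base unphased genotypes go to the compressed store, indels to the
multi-bp table; phased separators are accepted but stored unphased, matching
the LD engine's assumption. The `inst/cli/varkit.R` script exposes the
pipeline (`import`, `map`/`qc`, `genotypes`, `ld`, `consequences`,
`individual-seq`, `coverage`, `fixtures`) as a thin wrapper over `main()`;
exit codes are 0/1/2 for success/failure/usage error.

## The synthetic substrate, and what tests do and do not show

The fixture generators are first-class, tested code. `make_genome()` draws
uniform A/C/G/T; `plant_variant()` embeds k non-overlapping copies of a
random flank+allele+flank composite and records the truth;
`random_transcript()` builds exon/intron structures with in-frame CDS on
either strand; `simulate_genotypes()` draws two haplotypes per individual
i.i.d. from stated two-locus haplotype frequencies (random union of gametes,
i.e. Hardy–Weinberg at the haplotype level — exactly the EM's likelihood, so
parameter recovery is a fair test of the estimator). All generators are pure
functions of their seed and restore the caller's RNG state.

This substrate emulates what the algorithms consume: exact flank context,
dense single-base genotypes, HWE populations, clean transcript models. It
does not emulate sequencing error, population structure, recombination maps,
repetitive genomes (where exact flank search would under-map relative to a
fuzzy aligner), or CDS-incomplete transcripts. Passing tests therefore
demonstrate algorithmic correctness under the stated models, not robustness
to messy production annotation.

Problem sizes used by the test suite were chosen as comfortable desk scale:
codec fuzzing uses 10^4 random rows, the EM is checked against a 1e-5
resolution likelihood grid on 100 random tables (agreement within 1e-3) and
recovers truth within 3 binomial standard errors in ≥ 95% of 200 replicates
of 1000 individuals, and the consequence rules are checked against a
translate-and-diff oracle on 1000 random coding SNPs across both strands.

## Known limitations

* The mapper is exact-match only; mismatched or gapped flanks do not map.
* LD is pairwise and biallelic; no multi-locus haplotypes, no phasing output.
* Consequence prediction has no protein-impact scores and rejects
  CDS-incomplete transcripts rather than patching them.
* The persistence format is single-writer, whole-dataset; there is no
  incremental update or server deployment story.
* Assembly exceptions (haplotypic/pseudo-autosomal duplication bookkeeping)
  are out of scope, though the model permits multiple mappings per variant.

## A worked example

```{r example}
genome <- make_genome(c(chr1 = 20000L), seed = 42)
pv <- plant_variant(genome, flank_len = 20L, k = 2L,
                    alleles = c("A", "G"), seed = 43)
ds <- new_dataset(pv$genome)
ds <- add_variation(ds, "rs_demo", c("A", "G"), pv$flank_up, pv$flank_down)
ds <- apply_qc(ds, "rs_demo", map_flanks(ds, "rs_demo"))
ds$variation_features

sim <- simulate_genotypes(300, c(0.45, 0.05, 0.05, 0.45),
                          positions = c(1000L, 1500L), seed = 44)
ds <- store_genotypes(ds, sim$genotypes)
pairwise_ld(ds, slice("chr1", 1, 2000))[, c("pos1", "pos2", "D_prime", "r2")]
```
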