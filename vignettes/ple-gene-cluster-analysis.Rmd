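---
title: "Annotating and screening the pig liver esterase gene cluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and screening the pig liver esterase gene cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plegenes)
```

Pig liver esterase (PLE) is a family of nearly identical carboxylesterase
isoenzymes encoded by tandemly clustered genes. Because both exons and
introns are highly similar across family members, short-read or PCR-fragment
approaches cannot stitch individual genes together; the family was resolved
by sequencing whole BAC clones and then running a chain of dry-lab analyses.
`plegenes` implements that chain: spliced annotation of a reference cDNA
onto BAC-scale contigs, promoter inverted-repeat detection, clone-overlap
ordering of the cluster, diagnostic-residue classification of the encoded
isoenzymes, and simulation of the pooled PCR screen that located the clones
in the first place. A synthetic-data generator reproduces the published
locus geometry with known ground truth, so every stage is testable without
any external download.

## Spliced annotation

### Model

A gene model is obtained by aligning the full reference cDNA (the γ-type
coding sequence, 1698 nt in this family) against genomic sequence with a
two-state dynamic program:

* **Exon state** — per-column scores: match +2, mismatch −3, gap −4
  (linear). The alignment is *fitting*: the cDNA must be consumed entirely,
  the genomic flanks are free.
* **Intron state** — entered only where the genomic sequence reads `GT`,
  left only at an `AG`, the canonical splice dinucleotides. Each intron
  costs a flat, length-independent penalty of −10, with length constrained
  to `[min_intron, max_intron]` = [40, 20000] nt. The length window is
  enforced exactly via a sliding-window maximum over donor candidates
  (monotone deque), keeping the DP at O(nm) time.

The maximum-score model over both strands is reported; if no alignment
scores above zero, an empty model is returned rather than an error, so
decoy contigs annotate to an empty list.

The flat intron penalty is deliberate: intron lengths in this family vary
from 281 to 5440 nt with no length signal worth modelling, and a flat cost
is the minimal encoding of "prefer fewer introns". Scores are package
defaults (`align_params()`), not published values — the original analysis
names only the splice-site rule, not a scoring scheme.

### Anchored mode

`full_dp` runs the DP over the whole input and serves as the exact oracle.
`anchored` (the default) first finds exact `anchor_k`-mer (k = 15) matches
of the cDNA in the genomic sequence, clusters them by genomic position
(split at gaps larger than `max_intron`), and runs the *same* DP inside the
cluster window padded by `max_intron + |cDNA|` on each side. Because the
optimal alignment of a real gene cannot extend beyond that margin, the
windowed optimum equals the global optimum whenever the gene produces
seeds; the unit tests assert score- and interval-identity of the two modes
on random instances. Seedless inputs shorter than 20 kb fall back to the
full matrix, so anchored mode remains exact on oracle-scale instances; a
seedless 100-kb contig is reported empty (a real gene at this identity
always seeds). We chose windowed-DP refinement over per-gap banded
refinement of a chained anchor skeleton because it turns "anchored ≈
full DP" into "anchored = full DP" at negligible cost on these window
sizes (a ~40-kb gene window by a 1.7-kb cDNA takes on the order of a
second in the compiled DP).

Tie-breaking is deterministic: among equal-score moves the traceback
prefers exon moves (diagonal, then genomic gap, then cDNA gap) over closing
an intron, and among equal-score donors the leftmost. This is a greedy
realisation of "fewest introns, leftmost donors"; it does not enumerate all
co-optimal alignments.

`annotate_contig()` finds multi-gene contigs by iterative masking: align,
mask the found gene span with `N`, realign, and stop when the best
remaining score falls below 50% of the first gene's score (clones in this
family carry one or two genes; the threshold suppresses partial trailing
copies cut by clone windows, whose fitting alignments score far below a
complete gene).

## Promoter inverted repeats

The regulatory regions of the PLE genes contain a 720-bp reverse-complement
pair — copies at promoter coordinates −5132..−4413 and −802..−83 (the
convention throughout: +1 is the A of the start codon, −1 the base just
upstream, no position 0), separated by 3611 bp — capable of forming a
stem-loop. `find_inverted_repeats()` matches the sequence against its own
reverse complement: exact 20-mer seeds are extended to maximal exact runs
on their anti-diagonal, and runs on the same diagonal are chained when the
bases between them, counted as mismatches, stay within
`max_mismatch_rate` × chained length (default 2%; whether the real copies
are exact is not stated, so the budget is a package default). Requiring
every arm to start and end in an exact run of at least the seed length is
what keeps a planted exact repeat from "bleeding" into its random flanks
under the mismatch budget — without it, any mismatch-tolerant maximal
extension gains a few chance-complementary flanking bases and no planted
length is exactly recoverable. Overlapping (hairpin-contiguous) arms are
trimmed so copy 1 ends strictly before copy 2 begins; pairs contained in
longer pairs are dropped. `separation` is `start(copy2) − end(copy1)` on
the signed scale, the arithmetic that gives 3611 for the published copies.

`brute_force_inverted_repeats()` enumerates exact runs directly from the
full n × n match matrix and applies the same chaining — an independent
O(n²) oracle, refused above 2 kb, used in property tests against the fast
finder (at mismatch rate 0, where maximality is unambiguous).

## Clone assembly

`trim_vector()` locates the cloning vector (exact match first, then an
end-anchored tolerant search verified by global alignment at ≥95%
identity), removes it, and rejoins the flanks — consistent with an
arbitrarily linearised circular BAC. `pairwise_overlaps()` pairs clone
inserts by shared 31-mers, takes the modal seed diagonal, and verifies the
implied overlap base-by-base (substitution-only; the generator introduces
no indels, and real overlaps in this family were reported at ~99% identity
— `min_identity` defaults to 99%, `min_overlap` to 2 kb against real
overlaps of ≥6 kb). Both orientations are tried.

`order_clones()` treats clones as nodes and overlaps as edges. Components
must be simple paths — branching or cyclic components are an error naming
the clones, never a guessed order — and are linearised by propagating
orientation and signed offsets from an endpoint. Gene order is read off
clone offsets plus per-clone gene annotations; repeated sightings of the
same gene from overlapping clones are merged when their master-frame
positions agree within 20 kb (half a typical gene-plus-spacer unit).

## Isoenzyme classification

Translation uses the standard code; the signal peptide is *positional*
(residues 1–18, the family's fixed length — no de novo prediction), the
ER-retention signal is the C-terminal tetrapeptide (`HAEL` in PLE), and
diagnostic positions use mature-peptide numbering (signal peptide removed).
The 25 diagnostic positions and the residues of the eleven known
isoenzymes are bundled as a TSV fixture; `classify_isoform()` returns the
reference with the fewest mismatches, declaring "novel" when the minimum
exceeds zero. Ties keep the reference table's column order, so a profile
identical to two references (the PLE-1 column is identical to γ-PLE)
reports the earlier, canonical column. Ambiguous residues (`X`) always
count as mismatches — a conservative choice.

## In-silico PCR and the pooled screen

Primer matching is exact by default; with a mismatch allowance, mismatches
remain forbidden in the 3′-terminal 5 nt (polymerase extension requires a
matched 3′ end). Products include both primers, are capped at
`max_product` = 10 kb, and are searched in both orientations. A template
is *called* positive when a product falls within ±5% of a panel pair's
expected size — a gel-resolution window, since gel-based size calling is
not base-exact.

The screen follows the published three-step geometry for a library of
384-well plates (16 rows × 24 columns): one pooled template per plate,
then 24 pools of 16 wells within each positive plate (the within-plate
pools are column pools; the published description of step 2 can be read as
either rows or columns, and 24 × 16 is the reading adopted — it is
configurable through the layout geometry), then single wells.
`pcr_count` counts templates amplified (pools plus singles), the quantity
to compare against 384 × plates for a naive screen.

## The synthetic-data generator

The generator's defaults are the published study conditions:

* exon sizes `52, 208, 145, 134, 154, 105, 105, 39, 141, 81, 148, 132, 73,
  181` (identical across the four genes; sum 1698 nt, 565 aa + stop);
* per-gene intron sizes from the bundled table (five rows: PLE-1, the two
  PLE-B9 copies, PLE-C4, PLE-G2);
* 6000-nt promoters (measured from the ATG — whether the published 6-kb
  regulatory region is ATG- or TSS-anchored is not stated, and the ATG is
  assumed) carrying the 720-nt repeat pair at −5132 and −802; the second
  copy is planted at −802..−83, i.e. exactly 720 nt, although the published
  interval notation −802/−82 would span 721 — internal consistency is
  preferred over reproducing a likely off-by-one;
* ~22-kb intergenic spacers; gene order PLE-G2, PLE-1, PLE-B9;
* an 8128-nt vector stand-in (a fixed-seed random sequence bundled as
  FASTA and labelled synthetic — the true pCC1BAC sequence is not bundled;
  users may supply the real vector);
* 16 × 24-well plates; the real library is 500 plates of 384 wells.

Values the study does not state were fixed once: decoy inserts default to
2000 nt (decoys only need to be PCR-negative templates; their length does
not enter the pooling logic), and the generator plants amplicon cassettes
for primer pairs 1 and 2 (the two single-product screening pairs; the
double products of pairs 4–6 arise in reality from intron-size differences
between gene copies, which fixed per-gene intron tables make deterministic
rather than polymorphic).

Base composition is uniform i.i.d. ACGT except at forced motifs (start and
stop codons, splice dinucleotides, planted repeats, primer cassettes,
diagnostic codons). Internal stop codons are excluded by sampling coding
codons from the 61 sense codons. Two further choices keep ground truth
annotatable:

* **Mutation protection.** Point mutations (rate ≤ 5%, per gene copy)
  never touch splice dinucleotides, start/stop codons, diagnostic codons,
  or the 3′-terminal 5 nt of planted primer sites.
* **Repeat boundary guards.** One base just outside each planted repeat
  arm is forced to break complementarity, making the planted pair exactly
  maximal; without guards, chance complementarity extends the maximal pair
  past the planted 720 nt in a large fraction of seeds and no exact length
  is recoverable by any finder.
* **Nearest-codon recoding.** Per-isoform diagnostic residues are planted
  by recoding the shared base CDS with the codon *closest* to the original
  (deterministic on ties), emulating point-mutation divergence. This
  matters for annotation: random codon choices can pile three mismatches
  onto an exon boundary, where an optimal aligner will legitimately prefer
  an alternative splice over the planted one. With single-nucleotide
  recoding the planted structure is the unique optimum in all tested
  seeds.

What the generator does **not** emulate: sequencing error profiles and
assembly (clones are finished sequences), isochore/GC structure, indel
polymorphism between gene copies, intron-size polymorphism within one
gene, and transcription-factor-binding content of the promoters. Passing
round-trip tests therefore demonstrate correctness of the algorithms under
substitution-only divergence on realistic geometry — not robustness to
assembly artefacts or structural variation in real BAC data.

## Problem sizes in the test suite

The suite regenerates everything in code: single genes (~34–40 kb) for the
structure round trips (all four genes at five seeds each), an ~190-kb
three-gene master locus plus a ~74-kb second locus for the five-clone
ordering round trip, a 20-plate library (7680 wells, 2-kb decoys) with
five planted positives for the screen round trip, and 100-instance oracle
suites (≤3 kb for alignment, ≤2 kb for repeats). These sizes keep the full
suite in the minutes range on one CPU while exercising every code path at
the published geometry; the cluster and library scales are the package's
own choices and are documented where tests construct them.

## Known limitations

* The aligner models substitutions and short indels but only GT-AG introns
  (by design); GC-AG or AT-AC splice sites are out of scope.
* Spliced alignment against a diverged reference can in principle prefer
  an alternative splice when many substitutions cluster at a junction; the
  round-trip guarantees hold for the generator's divergence model, not for
  arbitrary references.
* Overlap verification is substitution-only; indel-containing overlaps
  would need the alignment-based path (the reported `gaps` field is then 0
  by construction).
* The gene-span length of a model is reported but never asserted against a
  single published span value, because the published per-gene span and the
  sum of the published exon and intron sizes differ slightly (33,759 vs
  33,767 for PLE-1) and the span convention used there is not stated.
* The brute-force repeat oracle and fast finder are provably identical
  only at mismatch rate 0; with a nonzero budget, both use the same
  chaining rule but "all maximal chains" is enumerated greedily.
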