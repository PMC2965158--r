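---
title: "Predicting terminal restriction fragment sizes from partial 16S sequences"
author: "trftax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting terminal restriction fragment sizes from partial 16S sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trftax)
```

## The problem

Terminal-restriction fragment length polymorphism (T-RFLP) fingerprints a
microbial community by PCR-amplifying the 16S rRNA gene with a
fluorescently end-labeled primer, digesting the amplicons with a
restriction endonuclease, and sizing only the labeled terminal fragments
(T-RFs) on a capillary sequencer. Each chromatogram peak aggregates every
community member whose first cut site sits at the same distance from the
labeled primer. The fingerprint alone carries no taxonomy; to interpret a
peak one must know which organisms would produce a fragment of that size.

Clone libraries sequenced with the same primer would settle this, but
directional Sanger reads typically lose their first 10-30 bases to
quality trimming, exactly the region between the labeled primer and the
first reliable base. An in silico digest of the read therefore
underestimates the true T-RF by an unknown offset. This package closes
that gap with full-length reference sequences: the closest reference
tells us how many bases are missing, and taxonomy comes along for free.

## The method

For a sample read $S$, a labeled primer $P$ and an enzyme $E$:

1. **Subset** the reference database to sequences of the right domain
   whose ungapped length strictly exceeds a threshold (Bacteria
   $> 1200$ nt, Archaea $> 900$ nt) and that contain $P$ within the
   allowed mismatch budget (`find_primer()`, substitution-only, primer
   IUPAC codes act as base sets, ambiguous subject bases count as
   mismatches). The best primer hit (fewest mismatches, then leftmost)
   is stored as the coordinate anchor.
2. **Retrieve** candidate closest references by shared distinct k-mers
   (`seed_rank()`, default $k = 11$, top 25 candidates) and re-rank them
   by exact Smith-Waterman local alignment (`best_hits()`; match $+5$,
   mismatch $-4$, gap open 10, extend 0.5, a gap of length $L$ costing
   $10 + 0.5L$).
3. **Digest in silico.** A cut "at $p$" cleaves the labeled strand
   between bases $p$ and $p+1$. Recognition sites are matched on both
   orientations; for a top-strand site match at $s$ the labeled-strand
   cut is $s - 1 + o_t$, for a reverse-complement match
   $s - 1 + (|site| - o_b)$, with both offsets recorded in top-strand
   coordinates of the canonical site (HhaI `GCG^C` is 3/1). Palindromic
   sites yield one merged cut per occurrence.
4. **Bridge the gap.** With the best hit's alignment starting at
   reference position $r$ and sample position $q$, and the primer anchor
   at $p_0$, the missing stretch is
   $\mathrm{gap} = (r - p_0) - (q - 1)$, clamped at 0 when the alignment
   begins at or upstream of the primer. The estimated T-RF is
   $\mathrm{gap} + t(S)$ where $t(S)$ is the distance from the sample's
   first base through the base before its first cut
   (`method = "sample-site"`).
5. **Fall back** to the reference's own terminal fragment
   (`method = "reference-estimated"`) when the sample carries no cut
   site, or when the reference's first cut is undetectable on the
   sample: either the cut position itself precedes the alignment start,
   or the recognition site producing it straddles the truncation point
   (the sample then holds only a partial site and would otherwise report
   the next site downstream). Such rows carry the `cut-in-gap` flag.
6. **Label peaks.** Predictions are matched to observed peak tables
   within a size tolerance (nearest peak, ties to the smaller size), a
   sample's taxon label is accepted when it matches peaks under at least
   `required` distinct enzymes, and accepted samples are tallied per
   lineage.

All positions are 1-based inclusive; fragment lengths count nucleotides
from the labeled primer's 5' base through the last base before the cut.

Reverse-primer runs reuse this geometry unchanged: references are
reverse-complemented so the labeled primer reads forward, and sample
reads are taken as written (directional reads off the labeling primer
are already on that strand).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `max_mismatch` (primer) | 1 | bases | degenerate 16S primers tolerate a mismatch; exposed because no universal value exists |
| `min_length` | 1200 (Bacteria) / 900 (Archaea) | nt | strict `>`; near-full-length references are required to bridge the 5' gap |
| `k` / `top_m` (seeding) | 11 / 25 | - | k = 11 mirrors the default word size of nucleotide homology search; 25 candidates are re-ranked exactly, so `top_m` trades runtime for robustness on very similar references |
| match/mismatch | +5 / -4 | score | standard nucleotide scoring for distant homologs |
| gap open/extend | 10 / 0.5 | score | standard affine penalties for rRNA-scale local alignment |
| `min_identity` | 80 | % | below this the best hit is unlikely to share fragment geometry; rows are flagged `low-confidence`, never dropped |
| `tolerance` (peaks) | 2 | nt | typical size-calling error of capillary electrophoresis; report it with results, and calibrate with `drift_correct()` when anchor fragments are available |
| `n_hits` | 1 | - | more hits show how conserved a fragment size is within a taxon; one row per hit, rank-ordered |

## The synthetic community generator

`generate_fixture()` builds the conditions the method is designed for:
references of 1250-1450 nt carrying a planted primer site and at least
one planted recognition site per enzyme (100-380 nt downstream of the
primer, on top of chance background sites), sample reads of 450 nt with
5' truncations uniform on 10-30 nt, and per-enzyme peak tables holding
the true sizes with at most 0.5 nt jitter plus decoy peaks. Everything
derives from one seed, and the generator restores the caller's RNG
state.

Per-base substitutions (`mutation_rate`) emulate evolutionary divergence
between the sampled organism and its closest database relative -- the
regime in which the tool is actually used when no complementary clone
library exists. Consequently the truth table is the digest of each
sample's own mutated, untruncated amplicon, while the reference database
stays clean. Substitutions are applied only beyond a 40 nt conserved
block downstream of the primer's first base, reflecting that common 16S
primers sit in conserved regions and that divergence concentrates in the
variable regions; this also keeps the primer anchor findable, as it is
in real data.

What the generator does **not** emulate: indels between sample and
reference (real 16S relatives have them; the gap arithmetic tolerates
them only as well as the local alignment places its start), chimeras,
sequencing errors beyond substitutions, pseudo-gaps from partial
digestion, multiple rRNA operons per genome, and realistic phylogenetic
correlation structure among references (references are mutually random).
Passing fixtures therefore demonstrates the coordinate arithmetic and
the matching logic, not database coverage: on real data the dominant
error source is a best hit whose fragment geometry differs from the
sampled organism, which no simulator of this kind can certify away.

## Numerical and degenerate-input choices

- Digestion conserves length by construction
  (`sum(full_digest(s, e)) == nchar(s)`); cuts at position 0 or at the
  sequence end create no fragments; out-of-range cuts from outside
  cutters are discarded with a warning.
- Seed ties break by reference id ascending; final hit order is
  alignment score, then seed score, then id -- fully deterministic.
- The local alignment engine is `Biostrings::pairwiseAlignment`; its
  traceback is deterministic, and scores are verified in the test suite
  against an independent textbook Gotoh dynamic program. Percent
  identity counts identical columns over all columns, gaps included.
- A zero-score alignment (no positive-scoring extension) yields an
  empty result with `NA` identity; samples with no scoring candidate at
  all produce one row flagged `unassignable`.
- Peak-match ties at equal distance go to the smaller peak size;
  matching is independent of prediction order.
- Empty reference subsets warn rather than error at construction and
  error only when a pipeline run would be meaningless.

## Problem sizes used by the shipped tests

The test and acceptance runs use 50 references x 200 samples x 3
enzymes (CfoI, HaeIII, AluI), 450 nt reads, truncations 10-30 nt, and a
1% divergence setting for the mutated condition; oracle comparisons run
on 200 random instances per primitive. These sizes exercise every code
path while keeping a full run on a single CPU in the low minutes.

## Known limitations

- Taxonomic labels are candidate assignments by closest hit, not
  identifications; the package deliberately reports `n_hits` alternates
  and percent identity so users can inspect ambiguous cases, and the
  multi-enzyme consensus exists precisely because single-enzyme fragment
  sizes collide across broad groups.
- Substitution-only primer matching (no indels) matches how degenerate
  primers are designed, but a reference with an indel inside the primer
  region will be excluded from the subset.
- Methylation sensitivity, star activity and partial digestion are out
  of scope; predictions assume complete digestion.
- The reference header dialect
  (`>id|lineage|first_nongap_fwd|first_nongap_rev`) is this package's
  own; upstream alignment databases do not publish one, so preparing a
  reference FASTA requires a one-off reformatting step by the user.
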