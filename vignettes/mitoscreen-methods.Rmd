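---
title: "Screening mitovirus-like genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mitovirus-like genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## The screening problem

Transcriptome shotgun assemblies are full of virus-like contigs. A candidate
mitovirus genome is a small (roughly 2–5 kb) +ssRNA molecule whose entire
coding capacity is one RNA-dependent RNA polymerase (RdRp). Two codon-level
signatures separate the classical, mitochondrially replicating viruses from
a basal lineage adapted to the cytoplasmic translation machinery:

* classical genomes are deduced under the mold mitochondrial code
  (translation table 4), where UGA encodes tryptophan, and typically carry
  several internal in-frame UGA codons together with high genome AU content
  (often 60–70%);
* basal-lineage genomes encode tryptophan exclusively as UGG, carry no
  internal UGA, and sit at lower AU (generally below 60%).

A third architecture — a long uninterrupted ORF on the antisense strand — is
the hallmark of ambigrammatic narnaviruses and serves as an exclusion
signal. `mitoscreen` operationalizes these contrasts as a deterministic
pipeline over plain FASTA input.

## The pipeline

### ORF deduction

Each frame of a strand is partitioned by in-frame stop codons; each
stop-free segment yields at most one ORF, starting at the first permitted
start codon and ending at the closing stop. This mirrors the
"longest ORF per stop" behavior of common ORF finders; nested ORFs are not
reported. Conventions that the literature leaves implicit are fixed here
explicitly:

* coordinates are 1-based and end-inclusive (a protein slice 265–463 spans
  199 residues);
* `nt_len` includes the terminal stop codon, and the forward screening
  filter is strict (`> 1000 nt`) while the reverse ambigrammatic scan is
  inclusive (`>= 1000 nt`), following the different phrasings of the two
  criteria;
* the forward screen reads the + strand only (assembled contigs are
  oriented transcripts) and requires an AUG start; the reverse scan permits
  any start codon, because an antisense ORF's start is not interpretable
  from the sense assembly;
* codons containing `N` translate to `X`, never act as stops, and are
  excluded from codon-usage counts so ambiguity cannot bias the UGA/UGG
  statistics. This N policy is this package's declared decision; upstream
  web tools do not document theirs.

The candidate code order is table 4 then table 1. A genome whose ORF is
stop-free under both codes is reported under table 4; the architecture call
is unaffected because such an ORF contains no UGA either way.

### Architecture call

The decision order is: ambigrammatic (reverse ORF ≥ 1000 nt) first, then
"no single long ORF" → unclassified, then `UGA_FREE` (zero internal UGA
*and* at least one UGG — requiring a tryptophan keeps the statement
"W is encoded only by UGG" non-vacuous), then `UGA_CONTAINING`, else
unclassified. The UGA/UGG ratio is reported as `NA` when no UGG exists;
0 or infinity would fabricate information. "Internal" means every codon of
the coding span except the terminal stop; the start codon is included. AU
content is computed genome-wide (not ORF-only) because the compositional
signature described for these genomes is a property of the whole molecule.

### Curation filter chain

Records pass, in order and with short-circuiting: (1) the single-long-ORF
filter — "single" is taken literally, so a contig with two long forward
ORFs is rejected as not matching the one-polymerase genome plan; (2) an
ordered scan for the six conserved RdRp motifs I–VI on the deduced protein;
(3) greedy deduplication at > 90% pairwise identity. Every elimination is
recorded with a reason code (`orf_absent`, `motif_absent`, `redundant`),
and the audit trail is written as TSV.

**Motifs instead of e-values.** Conserved-domain database scoring is tied
to curated profile databases and cannot be reproduced offline, so the
domain criterion is re-expressed as ordered presence of six degenerate
patterns (fixed letters, `X` wildcards, bracketed alternatives, an optional
per-motif mismatch budget at fixed positions). The shipped defaults are a
*synthetic fixture* — RdRp-flavored, including the universal `GDD`
catalytic core as motif IV's anchor and an invariant tryptophan in motif I —
not an alignment-derived profile; real screens should supply their own
patterns via the YAML config. This substitution preserves the biological
criterion (RdRp domain presence with ordered motifs) while making the
filter deterministic and desk-computable.

**Identity, reproducibly.** Published identity scores depend on the chosen
aligner. Here pairwise identity is defined once and exactly: global
end-to-end dynamic programming with match +1, mismatch 0, gap −1 (linear),
deterministic traceback preference (diagonal, then gap in the first
sequence, then gap in the second), identity = identical columns divided by
alignment length with gap columns in the denominator. The scoring is
deliberately simple so that results are bit-reproducible across machines;
it is implemented in C++ and cross-checked in the test suite against an
independent aligner for the optimal score. Deduplication visits records by
decreasing length (ties broken by id) and joins a record to the first
cluster whose *representative* exceeds the threshold, so the longest (most
complete) contig of each group is kept — what a curator would do. Two exact
shortcuts skip hopeless alignments without changing any result: identity
can never exceed 100·min(len)/max(len), and along any optimal-score
alignment it cannot exceed 2·min(len)/(la+lb+min(len)−score).

### Tree diagnostics

Trees are consumed as Newick with mandatory branch lengths; inference is
out of scope. "Generalized midpoint rooting" is implemented as classical
midpoint rooting: the root is placed at the midpoint of the longest
leaf-to-leaf path, ties broken by the lexicographically smallest leaf-label
pair. If the midpoint falls exactly on an internal node (tolerance 1e-9),
that node becomes the root and no zero-length edge is inserted. Midpoint
rooting never changes a patristic distance, and after rooting the maximum
root-to-tip depth equals half the tree diameter; both properties are
asserted in the test suite against an independent midpoint implementation.
Clade depth is reported three ways — stem length, mean root-to-tip and mean
MRCA-to-tip — because published "clade branch length" figures (e.g. a
shallow clade at 0.1 vs a deep clade at 0.5 substitutions per site) rarely
state which of these they mean; reporting all three makes any reading
checkable.

## The synthetic-genome generator

The generator is first-class, tested code: it provides ground truth for
every pipeline stage. Each genome is built as

1. a protein scaffold: the six motif canonical instances in order,
   separated by random linkers;
2. back-translation under the preset's genetic code with *exponential AU
   tilting*: synonymous codons are drawn with weight
   `exp(beta * codon-AU-fraction)`, and `beta` is bisected per genome
   (interval [−30, 30], up to 100 iterations, failure is an error reporting
   the achievable range) until the realized ORF AU is within 0.4 percentage
   points of the drawn target;
3. tryptophans written as UGA with the preset's probability (table-4
   presets only; if the probability is positive but the binomial draw
   yields no UGA, one tryptophan is forced to UGA so the planted label
   cannot flip at small tryptophan counts);
4. an AUG start, a UAA/UAG terminal stop, and UTRs whose composition closes
   the remaining gap to the genome-wide AU target (final accuracy ±0.5
   percentage points, asserted at generation time); the 5' UTR ends with an
   in-frame UAA guard so the deduced ORF always starts at the planted AUG;
5. rejection sampling until the reverse strand carries no ORF ≥ 1000 nt and
   the forward long ORF is unique (both accidents are rare but real); the
   `ambigram` preset instead embeds a ≥ 1200 nt reverse-frame stretch by
   excluding the three codons whose reverse complements are stops
   (UUA, CUA, UCA) from a 400-codon window;
6. self-verification: the emitted genome is run through the package's own
   classifier and must reproduce its planted label, UGA/UGG counts, ORF
   coordinates and motif positions — disagreement is an error, never a
   silently wrong fixture.

### Presets as study conditions

| preset | code | AU target | UGA:W fraction | role |
|---|---|---|---|---|
| `arkeo` | 1 | Normal(54.6, 4.1) truncated to [45, 59.9] | 0 | basal lineage |
| `mitovirinae` | 4 | Uniform(60, 70) | 0.5 | classical mitoviruses |
| `kvara` | 4 | Uniform(67, 73) | 0.5 | Kvaramitovirus-like |
| `ambigram` | 1 | as `arkeo` | 0 | narnavirus-like control |

Genome length is Uniform(2151, 4955) nt and UTRs are 30–150 nt per side for
all presets. The truncation keeps every basal-lineage genome below 60% AU,
the stated property of that clade; its side effect is a mild downward bias
of the realized cohort moments relative to the untruncated parameters
(about −0.7 on the mean, −0.8 on the SD), which stays well inside the
recovery tolerances used in the tests (±1.0 and ±1.5). The UGA:W fraction
of 0.5 is a placeholder: the sources say only that classical mitoviruses
carry "several" internal UGAs, so the parameter is exposed in the preset
rather than hidden. High-AU presets additionally bias linker residues
toward amino acids owning all-A/U codons (F, I, K, L, N, Y), mirroring the
residue composition of AU-rich viral proteomes; without that bias a uniform
scaffold cannot reach a 73% AU target by synonymous choice alone.

Decoys mirror the three failure modes the filter chain must catch:
`short_orf` genomes are built below 1 kb so no long ORF can exist;
`motif_deleted` genomes have one motif span randomized (and are re-drawn if
the motif still matches by chance); `near_duplicate` genomes copy a valid
parent with ~2% substitutions — placed so they never create an in-frame
stop, never touch a motif span, and keep identity safely above the 90%
threshold, so the decoy reaches (and fails at) the dedup stage. Each decoy
self-verifies its intended elimination reason at generation time.

### What the generator does not emulate

Synthetic genomes have idealized structure: exactly one ORF, motifs in
canonical form, linkers with no homology between genomes, no sequencing
error beyond optional `N`s, no truncated contigs, and no evolutionary
relatedness between cohort members (fixture trees are generated
independently of the sequences). Passing tests therefore demonstrate that
the pipeline's logic is faithful to its stated rules — not that the shipped
motif defaults would recover real RdRps, nor that identity-based
deduplication matches any particular aligner's output on diverged natural
sequences.

## Problem sizes and numerical choices

The test suite exercises: ORF deduction against a brute-force six-frame
oracle on 200 random sequences up to 3 kb; deduplication against an
all-pairs single-linkage oracle on cohorts up to 15 records; midpoint
rooting on random 20-leaf trees (patristic preservation and depth balance
at 1e-9); label recovery across all four presets; and cohort-level AU
recovery on 144 basal-lineage genomes at a fixed seed — sizes chosen to
give stable statistics (standard error of the cohort AU mean ≈ 0.34
percentage points at n = 144) while keeping a full run inside a few
minutes. Floating-point comparisons use 1e-9 absolute tolerances
throughout; cohort summary statistics additionally agree with a direct
two-pass computation to 1e-9 relative.

## Known limitations

* The motif defaults are illustrative; sensitivity/specificity on real
  data is entirely determined by user-supplied patterns.
* Identity is defined by one fixed scoring scheme; numbers are not directly
  comparable to ClustalW or BLAST identities, only internally consistent.
* Reverse-ORF detection reports any ≥ 1 kb antisense ORF, with no attempt
  to judge coding potential.
* `N` handling is conservative (exclusion); heavily ambiguous contigs may
  be unclassifiable even when a human curator could call them.
* Single-leaf "clades" have zero MRCA depth by convention; stem length of
  the whole leaf set is reported as 0.
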