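---
title: "Classifying HdrA: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying HdrA: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrascan)
library(dplyr)
```

## The problem and the model

HdrA, the bifurcating subunit of soluble heterodisulfide reductase, is a
modular protein: a conserved FAD-binding thioredoxin reductase core
decorated with a variable complement of iron-sulfur cluster domains, an
optional C-terminal MvhD ([2Fe-2S]) fusion, and — in one lineage — an
inserted GltD (glutamate synthase small subunit) domain. `hdrascan` treats a
protein's *domain architecture* (the ordered list of these domains) as the
classification object. The scheme has two levels:

* **4 major types**, defined by the thioredoxin reductase (TRX_FAD)
  complement: one TRX_FAD → type I; one TRX_FAD plus a terminal MvhD →
  type Ia; two TRX_FAD → type II; one TRX_FAD plus an inserted GltD →
  type III. The decision order is fixed (TRX count first, then GltD, then
  MvhD, then the type I default), and two combinations — GltD with two
  TRX_FAD, or GltD with a terminal MvhD — are outside the scheme and raise
  an error rather than being forced into a type.
* **28 classes**, one per distinct architecture template, partitioned
  13/5/7/3 across the types, with 2 to 8 domains per template. Class
  assignment is an exact ordered match of the resolved architecture against
  the templates of the assigned type; an architecture matching no template
  is reported `unassigned` together with the nearest template by token edit
  distance, because a closed catalog cannot anticipate every real protein.

The catalog ships as an editable TSV. Twelve classes are pinned by their
published descriptions (A0, A1, A1-C, A6, A12, A2-1, A3, A4, A3+MVH, A9,
A9-TRX-C, A10); the remaining sixteen templates are a synthetic
transcription by the package authors, constrained by the published global
structure of the scheme (class counts per type, the 2–8 domain range, and
the type definitions). They are internally consistent — validation enforces
all of the global constraints plus type/template consistency and pairwise
distinctness at load time — but individual unpinned templates should not be
read as authoritative renderings of any specific published class cartoon.
The `A9-TRX-C` template in particular is transcribed as A9 plus a C-terminal
extra iron-sulfur domain: its name hints at a C-terminal
thioredoxin-reductase-related feature, but a literal second TRX_FAD would
collide with the type II definition.

## From motifs to architectures

When no external domain evidence is supplied, domains are detected from
deterministic motif patterns (editable TSV; `X` = any residue):

| motif | pattern | biology |
|---|---|---|
| FES4 | `C-X2-C-X2-C-X3-C` | bacterial-ferredoxin [4Fe-4S] binding site |
| FE2S2 | `C-X2-C` | half of a [2Fe-2S] (MvhD-type) site |
| ROSSMANN_NAD | `G-X-G-X-X-G` | NAD⁺-preferring dinucleotide fingerprint |
| ROSSMANN_NADP | `G-X-G-X-X-A` | NADP⁺-preferring variant |

The scanner reports *every* occurrence, including overlaps; a hit's score is
its number of fixed pattern positions (patterns are all-or-nothing, so the
score ranks different motifs competing for a span, not instances of one
motif). Assembly into domains is rule-based, with start-to-start distance
windows:

* two FES4 motifs within **60** residues → one ferredoxin domain (two
  clusters); the first pair after a TRX_FAD is the inserted `Fd_ins`, the
  second the C-terminal `Fd_C`;
* a single FES4: the first one starting inside the N-terminal **80**-residue
  window (before any TRX_FAD) is `FeS_N`; one immediately following a
  TRX_FAD is `TRX_FeS`; all others are `FeS_extra`;
* two Rossmann fingerprints **80–300** residues apart → one `TRX_FAD`
  (greedy left-to-right pairing); an unpaired fingerprint flanked by FES4
  motifs on both sides → `GltD`;
* two FE2S2 half-motifs **25–40** residues apart, outside any FES4 hit and
  starting within the C-terminal **150** residues → `MvhD`.

Overlaps are resolved deterministically: higher score, then longer span,
then leftmost. The window constants are exported through
`assembly_rules()` and are calibrated to the packaged synthetic templates —
they reproduce the span scale of real HdrA cartoons, but on real proteins
the external evidence pathway (a CD-Search-style hit TSV mapped through the
synonym table) is authoritative and overrides builtin motifs on overlapping
spans. This division of trust exists because published domain annotations
come from profile models that a four-pattern motif set cannot replace.

## Residue calling and competence

Bifurcation competence is read from two residues — the lysine that
stabilizes the FADH⁻ intermediate at N5 of FAD and the glutamate that holds
that lysine in place (K409/E356 in the *M. thermolithotrophicus* numbering).
Calls are positional: the query is globally aligned to a reference anchor
(affine gaps, BLOSUM62; open 10, extend 0.5 per residue; selenocysteine `U`
scored as cysteine so Sec-containing proteins align normally; `X` scores 0),
and the query residue in each anchored reference column is reported.
Pairwise alignment to the reference was chosen over calling from a full MSA:
on conserved cores both give the same answer, and pairwise calls are
independent of the sample composition. Queries whose alignment identity
falls below **15%** (identical columns over alignment length) are reported
`unalignable` — below the twilight zone, positional equivalence is
meaningless. Competence requires *both* residues (`competent` /
`partial` / `absent`), and the per-residue flags are always emitted
alongside because the two sites are informative separately.

The same machinery drives the molybdopterin oxidoreductase active-site
check, with a three-position anchor frame: cysteine at the 118-equivalent →
`catalytic`; serine there → `serine_substituted` (abolishes catalysis,
preserves the fold); no cysteine but proline/phenylalanine at the
234/235-equivalents → `cofactor_blocked` (side chains occlude the
Mo/W-bisPGD pocket); anything else → `ambiguous`. The packaged anchors are
deterministic synthetic frames, not published reference proteins: they are
stand-ins that exercise exactly the same code path, and an analyst with the
real reference sequences substitutes them via `reference_anchor()`.

## Phylogeny preparation

Four steps, each its own verb:

* `greedy_cluster()` — redundancy reduction at **0.80** identity, identity
  defined as identical alignment columns over the *shorter* sequence (the
  convention of greedy clustering tools, so fragments cluster with their
  parents). Records are processed in decreasing length order (ties by id),
  which makes the clustering independent of input order; the first-founded
  cluster wins ties.
* `split_type2()` — type II sequences are cut at the floor of the midpoint
  of the inter-TRX linker. The published protocol splits within the MSA
  without stating a boundary; the linker midpoint is the symmetric,
  deterministic choice, and each half provably contains exactly one TRX
  span.
* `excise_gltd()` — the GltD insertion is removed and the flanks
  concatenated; spans touching a terminus are rejected because GltD is an
  insertion, not a terminal fusion.
* `trim_msa_columns()` — a column is kept iff the Shannon entropy of its
  non-gap residues is ≤ **1.5 bits** and its gap fraction is ≤ **0.2**;
  all-gap columns are always removed. This is a deliberate simplification
  of block-based entropy trimmers (no BLOSUM similarity smoothing, no block
  gathering), so it is *not* expected to reproduce any published trimmed
  core length bit-exactly; it is expected to — and, on the synthetic
  fixture, measurably does — keep conserved core columns and drop noisy
  insert columns. Entropy is computed over non-gap residues only, in bits.

The manually curated core-region mask (`extract_segment_mask()`) ships
empty: contact-shell segments are a property of a specific reference
structure, which the analyst supplies.

## Gene neighborhoods and function inference

Manual cluster identification "by transcription direction and gaps" is
operationalized as: same contig, same strand (configurable), intergenic gap
≤ **200 nt** (configurable; stated in every output header). Single
intervening genes on the opposite strand break a cluster under the default
rule — the conservative reading of co-transcription. Overlapping features
are kept with their gap treated as 0, with a warning.

Function inference is a data-driven rulebook (editable TSV), evaluated
most-specific-first per field: mid-potential carrier, high-potential arm,
low-potential arm, and notes. One ordering decision deserves record: a
type III hdrA whose cluster also contains *mvhADG* is assigned **NADH** as
carrier (with H₂ evolution as the low-potential arm), not H₂ — for the
GltD-carrying type III complex, the hydrogenase genes are read as the
H₂-evolving arm rather than the donor, so the type III row precedes the
mvh row. A prediction is labeled `validated` only when every fired row is
marked experimentally validated; everything else is `predicted`. Every
prediction cites the rows that fired.

## The synthetic generator: what it emulates, what it does not

`simulate_proteins()` builds records by concatenating per-domain consensus
templates joined by random 20–60-residue linkers, then applying point
substitutions at a per-residue rate. Three properties make the generator a
usable ground truth:

* **Motif exclusivity.** Filler positions (template interiors and linkers)
  are drawn from an alphabet without C and G, and template filler comes from
  a fixed non-periodic pseudo-random stream. Every motif occurrence is
  therefore planted, so at substitution rate 0 recovery is exact by
  construction — and the aperiodic filler keeps alignment registers
  unambiguous, which positional residue calling needs. (A repetitive filler
  demonstrably admits near-optimal alignments shifted by one filler period,
  which silently corrupts anchored calls.)
* **Protected truth.** Substitutions avoid motif-critical positions (and
  the K/E sites) unless `corrupt_motifs = TRUE`, so classifier robustness
  to background divergence and scanner robustness to motif decay are
  separately testable.
* **Determinism.** Each generator call seeds a single RNG
  (`withr::with_seed`); identical seeds give byte-identical output, and the
  seed is recorded in the record provenance.

What the generator does **not** emulate: tree-structured sequence evolution
(no phylogenetic signal; clustering tests use identity structure only),
realistic domain-length variation, compositional bias, genome-scale contigs,
or real linker/domain sequence content. Consequently, passing the synthetic
recovery suite shows the *machinery* is correct — parsers, scanner,
assembly, catalog match, residue mapping, clustering arithmetic — not that
the motif windows are well-calibrated for any particular real protein
family; on real data the external-evidence pathway carries that weight.

`simulate_msa()` emulates only the statistical contrast the trimmer keys on
(near-conserved core columns, ≥ 90% dominant-residue frequency and gap-free,
versus uniform-random insert columns with 30% gaps), and
`simulate_neighborhood()` places oriented genes with specified gaps and
records the intended partition.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale problem sizes chosen to
exercise every code path with comfortable margins: 280 synthetic proteins
(10 per class) for recovery, 1,000 random 500-residue sequences for
scanner/oracle equivalence, 300 random short pairs plus an exhaustive
enumeration of all pairs up to length 2 over a 4-letter alphabet for
aligner/oracle equivalence (the full cross-product of all sequences up to
length 8 is combinatorially out of reach; the sampled property covers the
same DP recurrences), a 10×150 alignment fixture, and 100 random
neighborhood layouts.

Degenerate inputs are defined rather than left to chance: empty FASTA input
is an empty table; a protein with no motif hits has an empty architecture
and is `not-hdrA`; an alignment against an empty sequence is an error; a
trim that removes every column warns and returns an empty alignment; a
cluster without hdrA cannot be scored. Floating-point comparisons in tests
use exact equality where the arithmetic is exact (integer scores, counts)
and `testthat` tolerance elsewhere.

## Known limitations

* The builtin motif set is minimal by design; real HdrA domain calling
  should feed CD-Search (or equivalent) hits through the external pathway.
* The 16 unpinned catalog templates are synthetic transcriptions (above).
* The trimmer is not a BMGE reimplementation and will not reproduce its
  column selections exactly.
* Residue calls are pairwise and positional; structural equivalence (e.g.
  compensating shifts in the FAD pocket) is out of scope, as are structure
  prediction, MSA computation, and tree inference, which belong to the
  surrounding toolchain.
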