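# hdrascan

Soluble heterodisulfide reductase (HdrABC) is the electron-bifurcating hub of
methane- and alkane-metabolizing archaea: its subunit A (HdrA) carries the
FAD that splits electron pairs between the high-potential heterodisulfide
CoM-S-S-CoB and low-potential ferredoxin (flavin-based electron bifurcation,
FBEB), or merges them in reverse (confurcation, FBEC). HdrA is highly
modular — iron-sulfur cluster domains are gained and lost around a conserved
FAD-binding thioredoxin reductase core — and that modularity encodes which
electron carriers a given Hdr complex can use.

`hdrascan` is an R package for surveying this diversity from sequence alone.
It is written for microbial genomicists who have HdrA candidate proteins
(and, optionally, their gene neighborhoods) and want reproducible,
rule-based answers to four questions:

1. **Which HdrA is this?** Conserved motifs — the bacterial-ferredoxin
   [4Fe-4S] motif `C-X2-C-X2-C-X3-C`, the paired `C-X2-C` half-motifs of a
   [2Fe-2S] (MvhD) site, and the Rossmann dinucleotide fingerprint
   `G-X-G-X-X-G` (NAD⁺) versus `G-X-G-X-X-A` (NADP⁺) — are scanned,
   assembled into an ordered domain architecture, and matched against a
   28-class catalog organized into 4 major types: type I (one thioredoxin
   reductase domain), type Ia (C-terminal MvhD fusion), type II (two
   thioredoxin reductase domains), and type III (inserted GltD domain).
   External CD-Search-style domain evidence can override the builtin scan.
2. **Can it bifurcate?** The two FAD-stabilizing residues (the K409- and
   E356-equivalents of the *Methanothermococcus thermolithotrophicus*
   reference frame; K stabilizes the FADH⁻ intermediate at N5, E positions
   the K) are read off a global alignment to a reference anchor and graded
   competent / partial / absent.
3. **What does its gene cluster do?** Genes are clustered by transcription
   direction and intergenic gap (defaults: same strand, ≤ 200 nt), and a
   packaged rulebook infers the mid-potential carrier (H₂, F₄₂₀H₂, formate,
   NADH), the high-potential arm (HdrBC or HdrD), and the low-potential arm
   (Fd, CO₂→formyl-MFR, H₂ evolution) from cluster composition — including
   the molybdopterin oxidoreductase active-site check (Cys118 present /
   serine-substituted / Pro234+Phe235 cofactor-blocked) that distinguishes a
   catalytic formate-dehydrogenase subunit from a non-catalytic structural
   scaffold.
4. **Is it ready for phylogenetics?** Greedy 80%-identity clustering,
   splitting of type II sequences at the inter-TRX linker midpoint, excision
   of the type III GltD insertion, and entropy/gap trimming of alignment
   columns produce a phylogeny-ready core set.

Every stage is testable without downloads: a synthetic-data generator
(`simulate_proteins()`, `simulate_neighborhood()`, `simulate_msa()`) plants
known classes, residues, cluster layouts, and alignment columns, and the
test suite scores the pipeline against that ground truth.

## Worked example

```r
library(hdrascan)
library(dplyr)

proteins <- bind_rows(
  simulate_proteins("A1",   3, seed = 101)$proteins,
  simulate_proteins("A2-1", 2, seed = 102)$proteins,
  simulate_proteins("A9",   1, seed = 103)$proteins)

survey <- hdra_survey(proteins)
survey
#> <hdra_survey>
#>   proteins:        6
#>   classified HdrA: 6
#>   types:           I=3 Ia=2 III=1

tidy(survey)
#> # A tibble: 6 × 6
#>   protein_id class_name major_type evidence             filter_status competence
#>   <chr>      <chr>      <chr>      <chr>                <chr>         <chr>
#> 1 A1_001     A1         I          FeS_N,TRX_FAD,TRX_F… passed        competent
#> 2 A1_002     A1         I          FeS_N,TRX_FAD,TRX_F… passed        competent
#> 3 A1_003     A1         I          FeS_N,TRX_FAD,TRX_F… passed        competent
#> 4 A2_1_001   A2-1       Ia         FeS_N,TRX_FAD,TRX_F… passed        competent
#> 5 A2_1_002   A2-1       Ia         FeS_N,TRX_FAD,TRX_F… passed        competent
#> 6 A9_001     A9         III        TRX_FAD,TRX_FeS,Glt… passed        competent
```

Each row is one protein: the matched class template is the `evidence`, the
`major_type` encodes which electron-carrier repertoire is plausible, and
`competence` reports whether both FAD-stabilizing residues are present (here
all planted, so all competent). `glance(survey)` gives the one-row summary,
`autoplot(survey)` draws the domain-architecture cartoons, and
`run_hdra_pipeline()` does the same from FASTA/GFF3 files on disk, writing
one TSV per stage plus a run manifest.

The packaged tables are editable TSVs under `inst/extdata/`: the 28-class
catalog, the motif set, the domain-label synonym table, and the FBEB/FBEC
rulebook.

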