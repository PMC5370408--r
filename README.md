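# aaRScreen

Screening of archaeal-type tRNA identities and non-canonical class Ic
aminoacyl-tRNA synthetases in bacterial contigs.

## The problem

In bacteria, tyrosyl-tRNA synthetase (TyrRS) recognizes a tRNA^Tyr with a
G1-C72 acceptor-stem pair and a long variable arm (V-arm), while archaea
and eukaryotes use a tRNA^Tyr with C1-G72 and no V-arm. For tryptophan the
bacterial discriminator base is G73, the archaeal/eukaryal one A73 (with
G1-C72). These identity rules normally lock each aaRS•tRNA pair into its
own domain of life — which makes bacterial genomes that carry
*archaeal-type* Tyr/Trp pairs, chimeric tRNAs (C1-G72 *with* a V-arm),
novel TrpRS clades (TrpRS-A1/A2, the latter with a
C-x<sub>22</sub>-C-x<sub>6</sub>-C-x<sub>2</sub>-C iron-sulfur cysteine
motif), tRNA-less ORFs bearing HIGH/KMSKS-like motifs (ORF1), and
B2-domain-fused TyrRSs remarkable signatures of lateral gene transfer and
of the plasticity of the genetic-code machinery.

`aaRScreen` re-implements that screen as a tested, deterministic pipeline
for anyone analysing (meta)genomic contigs:

* **Cloverleaf parsing and identity typing** — canonical numbering 1..76,
  extraction of the 1-72 pair, N73, anticodon and V-arm, and
  classification as `bacterial`, `archaeal_eukaryal`,
  `chimeric_C1G72_with_Varm` or `ambiguous` with per-element evidence.
* **aaRS annotation** — degenerate HIGH (`[HNQ][ILVMAFG]G[HN]`) and KMSKS
  (`[KR][MLIVF]S[KS][SG]`) scanners, the Fe-S C-x22-C-x6-C-x2-C motif,
  tryptophan-content audit, BLOSUM62-positives similarity
  (global alignment, terminal gaps excluded), nearest-reference lineage
  typing at the 40% similarity threshold, B2/S4 domain-architecture
  segmentation and sliding-window recombination-breakpoint detection.
* **Locus analysis** — GFF3 + FASTA loading, ORF1 candidate calling (the
  conjunction of operon context, no significant similarity to any
  reference, and HIGH/KMSKS-like hits), detection of the operon patterns
  (tRNA^Trp(A73)–ORF1–TrpRS-A1, optionally followed by a bacteria-type
  TrpRS or headed by a *trp* repressor gene, and archaeal
  TrpRS-A2/A-like clusters), and per-genome dual-identity summaries.
* **Phylogenetics** — progressive alignment, trimming to the class Ic
  core (from 13 columns upstream of the HIGH motif to the end of the
  anticodon-binding domain), Poisson-corrected distances
  (d = −ln(1 − p)), canonical neighbor-joining with deterministic
  tie-breaking, bootstrap supports, clade assignment, and a
  Robinson-Foulds permutation test of gene-tree congruence
  (p = (1 + #{perm RF ≤ obs}) / (n<sub>perm</sub> + 1)) for
  co-evolution of ORF1 with TrpRS-A.
* **Synthetic data** — every signal above can be planted in
  FASTA/GFF3 contigs and protein families evolved along a known tree,
  with a complete truth table, so the whole pipeline is testable as a
  closed loop.

## Worked example

```r
library(aaRScreen)

sc <- generateContigs(list(
  contigSpec(c("trna_trp_A73", "orf1", "trprs_a1", "trprs_bacterial"),
             seed = 5, contig = "c1", genome = "genomeA"),
  contigSpec(c("trna_trp_G73", "filler"), seed = 6, contig = "c2",
             genome = "genomeA"),
  contigSpec(c("trna_tyr_chimeric", "tyrs_archaeal"), seed = 7,
             contig = "c3", genome = "genomeB")))
rep <- runScreen(sc$features, sc$contigs)
rep
#> ScreenReport: 3 tRNA call(s), 5 protein call(s), 2 operon call(s), 2 genome(s)

rep@trna[, c("id", "isotype", "domain_type", "n73", "v_arm_len")]
#>       id isotype              domain_type n73 v_arm_len
#> 1 c1_f01     Trp        archaeal_eukaryal   A         0
#> 2 c2_f01     Trp                bacterial   G         0
#> 3 c3_f01     Tyr chimeric_C1G72_with_Varm   A        13

rep@operons[, c("contig", "pattern", "members")]
#>   contig                               pattern                     members
#> 1     c1                     tRNA_ORF1_TrpRSA1        c1_f01,c1_f02,c1_f03
#> 2     c1 tRNA_ORF1_TrpRSA1_plus_bacterialTrpRS c1_f01,c1_f02,c1_f03,c1_f04

rep@genomes[, c("genome", "lineages", "dual_identity")]
#>    genome               lineages dual_identity
#> 1 genomeA bacteria_type,TrpRS_A1          TRUE
#> 2 genomeB   archaea_eukarya_type         FALSE
```

Reading the output: contig c1 carries the canonical operon — an
archaeal-identity tRNA^Trp (A73, G1-C72), an ORF1 candidate (unassigned by
similarity but carrying HIGH/KMSKS-like motifs), a TrpRS-A1 and a
downstream bacteria-type TrpRS. Genome A also has a bacterial tRNA^Trp
(G73) elsewhere, so it is flagged `dual_identity`: both Trp identity sets
coexist. Contig c3 shows the chimeric tRNA^Tyr (C1-G72 *with* a 13-nt
V-arm) next to an archaea/eukarya-type TyrRS.

Real screens use `runScreen("annots.gff3", "contigs.fna", refs =
readReferenceSet("refs.faa", "labels.tsv"))`; the bundled references are
synthetic stand-ins for testing.

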