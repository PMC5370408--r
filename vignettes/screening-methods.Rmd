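---
title: "Methods: screening archaeal tRNA identities and non-canonical class Ic aaRSs"
author: "aaRScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening archaeal tRNA identities and non-canonical class Ic aaRSs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaRScreen)
```

# Scope and model

`aaRScreen` detects, on annotated nucleotide contigs, the molecular
signatures that distinguish the bacterial from the archaeal/eukaryal
Tyr- and Trp-tRNA identity sets, and annotates the non-canonical class Ic
aminoacyl-tRNA synthetases (aaRSs) that accompany the archaeal-type tRNAs
in some bacteria. The pipeline is organised as independent, individually
testable stages — cloverleaf parsing and identity typing, motif and
similarity annotation of proteins, gene-neighbourhood (operon) analysis,
and distance phylogenetics with a congruence test — plus a synthetic-data
generator that plants every one of these signals with known ground truth.

## tRNA cloverleaf and identity elements

A tRNA gene is mapped onto canonical cloverleaf numbering 1..76. Every
canonical segment has a fixed length (acceptor stem 7+7 nt, the two-base
connector, D-arm 16 nt, anticodon arm 17 nt with the anticodon at 34–36,
T-arm 17 nt, discriminator 73, CCA end); only the variable region between
the anticodon arm and the T-arm varies. The fold is therefore an
*anchored mapping*: the variable-region length is recovered from the
total gene length and the mapping is validated against the acceptor
stem, where at least 6 of the 7 pairs must be Watson–Crick or G·U. We
chose this over a Needleman–Wunsch alignment to a template because, for
coding-strand genes without introns (the only inputs in scope, and
exactly what the generator emits — its mutation model is
substitution-only), the mapping is exact, deterministic, and has no
tunable scoring; a thermodynamic folder would add nothing to
position-resolved identity elements. Genes whose acceptor stem fails the
pairing rule are reported as structured "unfoldable" records rather than
errors, so batch screens degrade per record.

The identity rules are a literal rule table over the extracted elements.
tRNA^Tyr: G1-C72 with a V-arm is bacterial; C1-G72 without a V-arm is
archaeal/eukaryal; C1-G72 *with* a V-arm is the chimeric configuration;
everything else is ambiguous. tRNA^Trp: G73 is bacterial regardless of
the 1-72 pair; A73 with G1-C72 is archaeal/eukaryal; everything else is
ambiguous, with the conflicting elements enumerated in the evidence. A
variable region of at least 10 nt counts as a V-arm (the type II tRNA
convention); 4–9-nt variable loops count as absent. The threshold is a
convention, not a fitted value; it is the standard type I/type II
boundary.

## aaRS annotation

*Motifs.* HIGH and KMSKS are matched with degenerate patterns
(`[HNQ][ILVMAFG]G[HN]`, `[KR][MLIVF]S[KS][SG]`), reported as
non-overlapping hits selected greedily left to right; the patterns are
arguments, and the defaults are the class I consensus loosened enough to
catch "motif-like" variants. The iron–sulfur motif is the exact spacing
C-x22-C-x6-C-x2-C (34 residues, four cysteines); overlapping matches are
all reported. Both scanners are validated against brute-force
position-by-position oracles in the tests.

*Similarity.* "Similarity" is the BLOSUM62 positives fraction of a global
affine-gap alignment (gap open 10, extension 0.5): columns whose residue
pair scores positive, divided by the alignment columns after excluding
terminal gaps. This matches the "Positives" notion behind BLASTp-derived
collection thresholds; a `mode = "full"` variant divides by the full
alignment length instead, since the original threshold's denominator is
not recorded anywhere. The function canonically orders its two arguments
before aligning, which makes it exactly symmetric. Lineage typing is
nearest-reference over a labeled reference set: the query adopts the
family and lineage of its most similar reference if that similarity
reaches the threshold (default 0.40), otherwise it is `unassigned`. Ties
break lexicographically by reference id; evidence lists the top three
references. A `requireFesForA2` flag demotes TrpRS-A2 calls lacking the
Fe–S motif. We use nearest-reference rather than profile HMMs because it
reproduces the BLAST-similarity collection logic with no external model
files and is exactly testable.

*Architecture.* The catalytic core spans the first HIGH hit to the end of
the first subsequent KMSKS hit; the anticodon-binding domain (ABD)
follows it. A B2 domain is called when the region upstream of HIGH
matches a B2 reference locally at or above the similarity threshold over
at least half the reference length (a linker is emitted when ≥ 10
residues separate B2 from the core), and an S4-like C-terminal domain
symmetrically from the post-core region — the bacteria-type TyrRS
signature. Without a HIGH anchor the architecture is empty and flagged.

*Breakpoints.* Two near-identical sequences are aligned globally;
identity is computed in sliding windows (default 30 columns, step 10)
along the alignment, gap columns counting as mismatches. Windows are
classified high (≥ 0.9) or low (≤ 0.5) and a breakpoint is reported at
the midpoint between the centers of consecutive differently-classified
windows. Positions are alignment columns; when the swapped block aligns
with internal gaps the downstream junction shifts by the alignment's
excess length, which the tests account for. A threshold-crossing
detector was chosen over an HMM segmentation because the target
phenomenon is a discrete domain swap with two junctions.

## Locus analysis

Features are loaded from GFF3 + FASTA with referential-integrity checks;
minus-strand sequences are reverse-complemented before any downstream
call while written coordinates are preserved. Within each contig and
strand, features are ordered 5'→3' in transcription order and chained
while intergenic gaps stay within `maxGap` (default 150 nt — a
conventional operon-spacing heuristic, configurable). ORF1 candidates
are the *conjunction* of three conditions: (a) the CDS sits between an
archaeal-identity tRNA^Trp(A73) upstream and a TrpRS-A-called CDS
downstream in its chain, or anywhere in a chain carrying a
TrpRS-A2/A-like call; (b) the classifier returned `unassigned`; (c) at
least one HIGH-like and one KMSKS-like hit. Length bounds (120–450
residues) exclude trivial ORFs. Operon patterns are matched as
consecutive role windows — tRNA^Trp(A73)–ORF1–TrpRS-A1, the same
followed by a bacteria-type TrpRS, the same headed by a *trp* repressor
gene (recognised by annotation label, not by a sequence model) — while
the archaeal TrpRS-A2/A-like cluster pattern requires only
co-localisation within a chain, not adjacency, because linkage rather
than strict operon structure is what characterises those loci.
Overlapping patterns are each reported, and no call ever spans two
contigs or strands. Genome summaries count tRNA identities per isotype
and flag `dual_identity` when bacterial-type and archaeal/eukaryal-type
calls coexist for one isotype.

## Phylogenetics

*Alignment.* Progressive alignment with a 3-mer-distance average-linkage
guide tree and profile–profile Needleman–Wunsch merges (affine gaps,
BLOSUM62; the inner DP is compiled code). Sequences are processed in
lexicographic id order, so the result is input-order invariant up to row
order.

*Core trimming.* The retained window runs from `upstream` columns
(default 13) before the first HIGH anchor column — clamped at column
1 — to the end of the anticodon-binding domain, supplied either as a
column index or inferred as the last non-gap column of a designated
reference row (the package cannot rediscover domain ends from structures,
so the reference row stands in for curated structural knowledge). Inside
the window, columns that are majority gaps (> 50%) are removed as a
proxy for nonconserved insertions; anchor columns are never removed.

*Distances and trees.* Pairwise distances are Poisson-corrected,
d = −ln(1 − p), with p the mismatch fraction over mutually ungapped
columns — the uniform-rates model, with no gamma correction. Pairs
sharing fewer than 20 ungapped columns are an error; p ≥ 0.95 is capped
with a warning. Trees are canonical neighbor-joining with Q-matrix ties
broken by the smallest row-major index pair, so construction is
deterministic; negative branch estimates are clamped at zero. We infer
trees by NJ rather than maximum likelihood deliberately: the claims the
trees support here are clade-grouping claims, NJ on additive distances
is provably exact (a property the tests exercise over random trees), and
every step is oracle-testable; externally computed ML trees can be
supplied as Newick wherever a `phylo` is accepted. Bootstrap supports
resample alignment columns, rebuild distance + NJ trees, and report the
percentage of replicates containing each internal bipartition; a
zero-divergence alignment returns an unresolved star tree rather than a
spuriously resolved one. Clade assignment returns the label of the
smallest bipartition side containing the query and references of exactly
one label, falls back to the nearest labeled leaf by path length, and
reports ties instead of resolving them silently.

*Congruence.* Two trees restricted to their shared leaves are compared
by Robinson–Foulds distance; the null distribution permutes the leaf
labels of the second tree, and p = (1 + #{perm RF ≤ observed}) /
(n_perm + 1) with the permutation count (default 999) and seed recorded
in the result. Because RF between random topologies is strongly
concentrated near its maximum, the permutation p is discrete and mildly
conservative; with 999 permutations the measured type-I error at
α = 0.05 over 500 independent-topology trials is ≈ 0.03. Fewer
permutations coarsen the p-grid and make the test noticeably more
conservative, which is why 999 is the default.

# The synthetic-data generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline's guarantees are stated.

*tRNAs* are built from a fixed 76-nt consensus per isotype
(perfectly-paired stems, 5-nt type I variable loop) with the requested
1-72 pair, N73, anticodon and V-arm substituted in; V-arms are paired
hairpins of exactly the requested length (0 or 10–39 nt). Point
mutations are applied per site with the requested probability (0–0.3),
drawn uniformly over A,C,G,T, never at positions 1, 72, 73 or the
anticodon; because the model is substitution-only, the V-arm length is
exact by construction.

*Protein families* evolve a random root (with motifs planted literally —
HIGH, KMSKS, or the four Fe–S cysteines — and those columns frozen)
along a known tree under a Poisson substitution model with a flat
20-letter replacement distribution. Realistic exchangeability (JTT-like
matrices) is deliberately absent: the generator's job is known topology
and controllable divergence, not biochemical realism. Two families built
on one tree object share the true topology exactly, which is the ground
truth for the congruence tests. Default branch lengths are uniform at
`subsPerSite` (default 0.1 expected substitutions per site per branch —
enough divergence for resolved trees at 300 residues without
saturation).

*Contigs* assemble feature templates (archaeal/bacterial tRNAs, ORF1
with and without its motifs, the five aaRS lineages, a B2-TyrRS fusion,
a labeled trp-repressor stand-in, fillers) in a requested order,
separated by random intergenic sequence (default 30 nt) and 50-nt
flanks, on either strand. Protein features derive from deterministic
per-lineage prototype sequences — random proteins with planted motifs,
fixed by internal seeds — mutated at 5% per site with motif columns
protected; prototypes are *synthetic stand-ins* for curated reference
sets, and real references can be supplied as FASTA + label TSV. Because
the prototypes are mutually random, between-lineage similarity sits at
the random-alignment background (≈ 0.25 positives fraction), safely
below the 0.40 threshold, while within-lineage features stay above 0.9 —
so classification margins in the tests are structural, not tuned.
trp-repressor and filler features are arbitrary labeled ORFs; the locus
logic needs labels, not homology. The truth table records every planted
element, lineage and implied operon pattern, and all generation is
deterministic given the spec and seed.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate on real data: realistic codon usage or GC
content, sequencing error, fragmented or misassembled contigs, tRNA
introns, post-transcriptional modification, rate heterogeneity across
sites, and genuinely homologous inter-lineage divergence (real TrpRS-A1
vs A2 are related clades, not independent random sequences). On real
metagenomes the similarity threshold, operon gap and ORF1 length bounds
remain judgement calls that the configuration exposes.

# Numerical choices and problem sizes

Tie-breaks are everywhere deterministic (lexicographic ids for
references and alignment order; smallest index pair in NJ; fixed state
preference in the alignment traceback). All randomness flows through
explicit seeds, and provenance blocks record the configuration actually
used. The test suite validates the stages at the following scales: the
identity rule table exhaustively over all 128 element combinations per
isotype and on 1,000 noisy genes; scanners against oracles on 1,000
random 300-mers; operon detection on 200 mixed-layout contigs
(precision = recall = 1 against truth); NJ on 200 random additive trees
(n ≤ 12) and 200 noisy quartets against a least-squares oracle (±5%
multiplicative noise — the near-additive regime where NJ and
least-squares should and do agree ≥ 95% of the time); congruence
calibration over 500 independent-topology trials at 999 permutations;
breakpoints over 100 random domain-swap constructions. The acceptance
script re-runs the same computations from scratch at comparable sizes
and writes each value with the problem size used.

# Known limitations

The cloverleaf mapping assumes intron-free, full-length genes between 60
and 110 nt; genes with indels in the invariant arms will fail the
acceptor-stem check rather than re-anchor. Identity typing ignores the
2-71 and 3-70 pairs and all modification-dependent determinants. The
classifier is only as good as its reference set, and the bundled
references are synthetic. NJ supports clade-grouping claims, not branch
lengths or rooted histories; rooting is the caller's responsibility
(e.g. with a designated outgroup when reading external trees). The
congruence test keys leaves by name: pairing ORF1 with TrpRS-A trees
presumes one pair per genome/contig id, and duplicated gene copies must
be disambiguated upstream.
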