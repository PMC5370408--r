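# Synthetic-data generator: tRNA genes with configurable identity
# elements, protein families evolved along a known tree, and FASTA/GFF3
# contigs assembling the gene-neighbourhood layouts the screen detects.
# Every emitted feature carries a truth record, so the full pipeline can
# be validated as a closed loop.

# ---------------------------------------------------------------------
# tRNA generation
# ---------------------------------------------------------------------

# Fixed canonical consensus (76 nt with the 5-nt type I variable loop).
# Stems are perfectly complementary so the generator's output folds by
# construction; the 1-72 pair, N73, anticodon and variable arm are
# substituted in from the spec.
.TRNA_BODY <- list(
  acc5_2_7  = "GGCGGC",             # canonical 2-7
  link_8_9  = "TA",
  d_stem5   = "GCTC", d_loop = "AGTTGGTA", d_stem3 = "GAGC",
  pos26     = "A",
  ac_stem5  = "CTGGC", ac_stem3 = "GCCAG",
  var_loop  = "AGGTC",              # type I variable loop (no V-arm)
  t_stem5   = "GGTTC", t_loop = "GAAATCT", t_stem3 = "GAACC",
  acc3_66_71 = "GCCGCC"             # reverse complement of canonical 2-7
)

.DEFAULT_ANTICODON <- c(Tyr = "GTA", Trp = "CCA")

# Hairpin filling a V-arm of exactly `len` nt (paired stem, 3-4 nt loop).
.vArmSeq <- function(len) {
  k <- (len - 3L) %/% 2L
  loop <- len - 2L * k
  stem5 <- paste(rep(c("G", "C", "A", "C"), length.out = k), collapse = "")
  paste0(stem5, paste(rep("T", loop), collapse = ""), .revcomp(stem5))
}

.parsePair <- function(pair) {
  ch <- .chars(gsub("[^ACGT]", "", toupper(pair)))
  if (length(ch) != 2L)
    stop("invalid 'pair': must name two bases, e.g. \"G-C\"")
  ch
}

#' Generate a synthetic tRNA gene with known identity elements
#'
#' Builds a tRNA gene from a fixed canonical consensus, substituting in
#' the requested 1-72 base pair, discriminator N73, variable-arm length
#' and anticodon, then applies uniform point mutations outside the
#' constrained positions (canonical 1, 72, 73 and the anticodon are never
#' mutated; substitutions preserve length, so the variable-arm length is
#' exact by construction).
#'
#' @param isotype "Tyr" or "Trp".
#' @param pair ordered 1-72 pair as a string, e.g. `"G-C"` or `"C-G"`.
#' @param n73 discriminator base.
#' @param vArmLen variable-arm length in nt: 0 (absent; the consensus
#'   5-nt type I variable loop is used) or 10..39.
#' @param anticodon 3-nt anticodon in gene coordinates; defaults to the
#'   isotype's canonical anticodon (Tyr GTA, Trp CCA).
#' @param mutationRate per-site mutation probability in `[0, 0.3]`,
#'   applied outside the constrained positions; replacement bases are
#'   drawn uniformly from A,C,G,T.
#' @param seed integer seed; generation is deterministic given the spec
#'   and seed.
#' @param id feature identifier recorded in the truth row.
#' @return list with `sequence` (character DNA) and `truth` (one-row
#'   data.frame: id, isotype, pair_1_72, n73, v_arm_len, anticodon,
#'   domain_type).
#' @examples
#' generateTrna("Trp", pair = "G-C", n73 = "A", vArmLen = 0, seed = 7)$truth
#' @export
generateTrna <- function(isotype = c("Tyr", "Trp"), pair = "G-C",
                         n73 = "A", vArmLen = 0L, anticodon = NULL,
                         mutationRate = 0, seed = 1L, id = "trna") {
  isotype <- match.arg(isotype)
  pr <- .parsePair(pair)
  n73 <- toupper(n73)
  if (!n73 %in% .DNA) stop("invalid 'n73': must be one of A,C,G,T")
  vArmLen <- as.integer(vArmLen)
  if (!(vArmLen == 0L || (vArmLen >= 10L && vArmLen <= 39L)))
    stop("invalid 'vArmLen': must be 0 (absent) or between 10 and 39")
  if (is.null(anticodon)) anticodon <- .DEFAULT_ANTICODON[[isotype]]
  anticodon <- toupper(anticodon)
  if (nchar(anticodon) != 3L || !all(.chars(anticodon) %in% .DNA))
    stop("invalid 'anticodon': must be 3 nt over A,C,G,T")
  if (mutationRate < 0 || mutationRate > 0.3)
    stop("invalid 'mutationRate': must lie in [0, 0.3]")

  b <- .TRNA_BODY
  var <- if (vArmLen == 0L) b$var_loop else .vArmSeq(vArmLen)
  V <- nchar(var)
  seq <- paste0(pr[1L], b$acc5_2_7, b$link_8_9,
                b$d_stem5, b$d_loop, b$d_stem3, b$pos26,
                b$ac_stem5, "CT", anticodon, "AA", b$ac_stem3,
                var, b$t_stem5, b$t_loop, b$t_stem3,
                b$acc3_66_71, pr[2L], n73, "CCA")
  ch <- .chars(seq)
  constrained <- c(1L, 34:36, 67L + V, 68L + V)
  ch <- .withSeed(seed, .mutateChars(ch, mutationRate, constrained))
  prof <- new("IdentityProfile", pair1 = pr[1L], pair72 = pr[2L], n73 = n73,
              vArmPresent = vArmLen >= 10L, vArmLen = vArmLen,
              anticodon = anticodon,
              isotypeHint = switch(anticodon, GTA = "Tyr", CCA = "Trp",
                                   "other"))
  dtype <- if (prof@isotypeHint == "other") NA_character_ else
    classifyIdentity(prof)@domainType
  list(sequence = paste(ch, collapse = ""),
       truth = data.frame(id = id, isotype = isotype,
                          pair_1_72 = paste0(pr[1L], "-", pr[2L]),
                          n73 = n73, v_arm_len = vArmLen,
                          anticodon = anticodon, domain_type = dtype,
                          stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------
# Protein families evolved along a known tree
# ---------------------------------------------------------------------

.MOTIF_LITERALS <- c(HIGH = "HIGH", KMSKS = "KMSKS")

# Planted-motif layout -> (text, constrained offsets within the motif)
.plantMotif <- function(ch, name, pos) {
  if (name %in% names(.MOTIF_LITERALS)) {
    txt <- .chars(.MOTIF_LITERALS[[name]])
    ch[pos:(pos + length(txt) - 1L)] <- txt
    attr(ch, "constrained") <- c(attr(ch, "constrained"),
                                 pos:(pos + length(txt) - 1L))
  } else if (name == "FeS_C4") {
    cs <- pos + c(0L, 23L, 30L, 33L)
    ch[cs] <- "C"
    attr(ch, "constrained") <- c(attr(ch, "constrained"), cs)
  } else stop("unknown motif name: ", name)
  ch
}

.motifLength <- function(name)
  switch(name, HIGH = 4L, KMSKS = 5L, FeS_C4 = 34L,
         stop("unknown motif name: ", name))

#' Evolve a synthetic protein family along a known tree
#'
#' Draws a random root sequence, plants the requested motifs, and evolves
#' it along a phylogeny under a Poisson substitution model with a flat
#' replacement distribution over the 20 amino acids. Motif columns are
#' never mutated (for the Fe-S motif, only the four cysteines are
#' constrained), so every leaf carries the planted motifs intact. Two
#' families generated on the same `tree` share the true topology exactly,
#' which is the construction behind the tree-congruence tests.
#'
#' @param nLeaves number of leaves (>= 3); ignored when `tree` is given
#'   except as a consistency check.
#' @param rootLength root sequence length in residues.
#' @param tree optional `phylo` object fixing the topology; when `NULL` a
#'   random topology is drawn. Edges without lengths get `subsPerSite`.
#' @param subsPerSite expected substitutions per site per branch; 0 gives
#'   identical copies of the root.
#' @param motifs named integer vector of planted motif start positions,
#'   e.g. `c(HIGH = 40, KMSKS = 200)`; names from HIGH, KMSKS, FeS_C4.
#'   The default plants HIGH and KMSKS at 15% and 65% of the root
#'   length; use an empty vector for a motif-free family.
#' @param exclude amino-acid letters excluded from the root and from
#'   replacement draws (e.g. `"W"` for tryptophan-free families).
#' @param seed integer seed.
#' @param prefix leaf-name prefix used when the tree is generated here.
#' @return list with `sequences` (`AAStringSet`, one per leaf), `tree`
#'   (`phylo` with the true topology and branch lengths), `truth`
#'   (data.frame of leaf ids) and `motifs`.
#' @examples
#' fam <- generateProteinFamily(6, rootLength = 120, subsPerSite = 0.05,
#'                              seed = 3)
#' fam$tree
#' @export
generateProteinFamily <- function(nLeaves, rootLength = 300L, tree = NULL,
                                  subsPerSite = 0.1, motifs = NULL,
                                  exclude = character(), seed = 1L,
                                  prefix = "L") {
  nLeaves <- as.integer(nLeaves)
  if (nLeaves < 3L) stop("'nLeaves' must be at least 3")
  if (is.null(motifs))
    motifs <- c(HIGH = max(1L, round(0.15 * rootLength)),
                KMSKS = round(0.65 * rootLength))
  if (subsPerSite < 0) stop("'subsPerSite' must be non-negative")
  if (length(motifs)) {
    spans <- lapply(seq_along(motifs), function(i) {
      s <- as.integer(motifs[i])
      s:(s + .motifLength(names(motifs)[i]) - 1L)
    })
    all <- unlist(spans)
    if (anyDuplicated(all) || min(all) < 1L || max(all) > rootLength)
      stop("planted motif positions must be non-overlapping and within ",
           "the root length")
  }
  .withSeed(seed, {
    if (is.null(tree)) {
      tree <- ape::rtree(nLeaves, rooted = TRUE, br = NULL)
      tree$tip.label <- sprintf("%s%02d", prefix, seq_len(nLeaves))
      tree$edge.length <- rep(subsPerSite, nrow(tree$edge))
    } else {
      if (ape::Ntip(tree) != nLeaves)
        stop("'tree' has ", ape::Ntip(tree), " leaves but 'nLeaves' is ",
             nLeaves)
      if (is.null(tree$edge.length))
        tree$edge.length <- rep(subsPerSite, nrow(tree$edge))
    }
    alphabet <- setdiff(.AA20, exclude)
    root <- sample(alphabet, rootLength, replace = TRUE)
    for (i in seq_along(motifs))
      root <- .plantMotif(root, names(motifs)[i], as.integer(motifs[i]))
    constrained <- unique(attr(root, "constrained"))
    root <- as.vector(root)
    tr <- reorder(tree, "cladewise")   # parent precedes child
    nodeSeq <- vector("list", ape::Ntip(tr) + tr$Nnode)
    nodeSeq[[ape::Ntip(tr) + 1L]] <- root
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      p <- 1 - exp(-tr$edge.length[e])
      nodeSeq[[child]] <- .mutateChars(nodeSeq[[parent]], p, constrained,
                                       alphabet)
    }
    tips <- vapply(seq_len(ape::Ntip(tr)),
                   function(i) paste(nodeSeq[[i]], collapse = ""), "")
    names(tips) <- tr$tip.label
    list(sequences = Biostrings::AAStringSet(tips), tree = tree,
         truth = data.frame(leaf = tr$tip.label, stringsAsFactors = FALSE),
         motifs = motifs)
  })
}

# ---------------------------------------------------------------------
# Synthetic lineage references and feature prototypes
# ---------------------------------------------------------------------

# Deterministic synthetic prototype proteins, one per aaRS lineage.
# These stand in for curated reference sets (which the package does not
# ship); they are random sequences with planted class I motifs, so
# between-lineage similarity sits at the random-background level while
# within-lineage derived sequences stay close to their prototype.
.prototypeAa <- function(seed, length = 320L, high = 40L, kmsks = 210L,
                         fes = NA_integer_, exclude = character(),
                         scrubHigh = TRUE) {
  .withSeed(seed, {
    ch <- sample(setdiff(.AA20, exclude), length, replace = TRUE)
    ch[1L] <- "M"
    planted <- integer(0)
    if (!is.na(high)) {
      ch <- .plantMotif(ch, "HIGH", high); planted <- c(planted, high)
    }
    if (!is.na(kmsks)) ch <- .plantMotif(ch, "KMSKS", kmsks)
    if (!is.na(fes)) ch <- .plantMotif(ch, "FeS_C4", fes)
    ch <- as.vector(ch)
    if (scrubHigh) {
      # remove accidental HIGH-pattern matches so the planted motif is
      # the unique core anchor
      repeat {
        hits <- .scanDegenerate(ch, .CLASS_I_PATTERNS$HIGH)
        hits <- setdiff(hits, planted)
        if (!length(hits)) break
        ch[hits[1L] + 2L] <- "P"
      }
    }
    paste(ch, collapse = "")
  })
}

#' Bundled synthetic reference set for aaRS lineage typing
#'
#' Returns deterministic synthetic prototype proteins for the seven
#' lineages the screen distinguishes (bacterial and archaeal/eukaryal
#' TyrRS and TrpRS, TrpRS-A1, TrpRS-A2 with the Fe-S cysteine motif, and
#' TrpRS-A-like), labeled for [classifyAars()]. The TrpRS-A1 prototype is
#' tryptophan-free, matching the striking composition of those proteins.
#' These are synthetic stand-ins, not curated biological sequences; real
#' screens should supply their own labeled FASTA via
#' [readReferenceSet()].
#'
#' @return list with `sequences` (`AAStringSet`) and `labels`
#'   (data.frame: id, family, lineage).
#' @export
lineageReferences <- function() {
  s4 <- .domainReferenceSeqs()
  seqs <- c(
    ref_TrpRS_bacterial = .prototypeAa(101L),
    ref_TrpRS_archaeal  = .prototypeAa(102L),
    ref_TrpRS_A1        = .prototypeAa(103L, exclude = "W"),
    ref_TrpRS_A2        = .prototypeAa(104L, fes = 110L),
    ref_TrpRS_A_like    = .prototypeAa(105L, length = 340L),
    ref_TyrRS_bacterial = paste0(.prototypeAa(106L, length = 300L,
                                              kmsks = 200L), s4$S4),
    ref_TyrRS_archaeal  = .prototypeAa(107L)
  )
  labels <- data.frame(
    id = names(seqs),
    family = c("TrpRS", "TrpRS", "TrpRS", "TrpRS", "TrpRS",
               "TyrRS", "TyrRS"),
    lineage = c("bacteria_type", "archaea_eukarya_type", "TrpRS_A1",
                "TrpRS_A2", "TrpRS_A_like", "bacteria_type",
                "archaea_eukarya_type"),
    stringsAsFactors = FALSE)
  list(sequences = Biostrings::AAStringSet(seqs), labels = labels)
}

.domainReferenceSeqs <- function() {
  list(B2 = .prototypeAa(108L, length = 90L, high = NA, kmsks = NA),
       S4 = .prototypeAa(109L, length = 80L, high = NA, kmsks = NA))
}

#' Bundled synthetic B2 and S4-like domain references
#'
#' Synthetic stand-ins for the PheRS-beta B2 domain and the S4-like
#' C-terminal domain used by [detectArchitecture()]; user-supplied FASTA
#' references can replace them.
#'
#' @return named `AAStringSet` with entries `B2` and `S4`.
#' @export
domainReferences <- function() {
  s <- .domainReferenceSeqs()
  Biostrings::AAStringSet(c(B2 = s$B2, S4 = s$S4))
}

.orf1Prototype <- function(ablateMotifs = FALSE) {
  p <- .prototypeAa(110L, length = 160L, high = 30L, kmsks = 110L,
                    exclude = "W")
  if (ablateMotifs) {
    ch <- .chars(p)
    ch[30:33] <- c("D", "E", "D", "E")
    ch[110:114] <- c("D", "E", "D", "E", "D")
    p <- paste(ch, collapse = "")
  }
  p
}

# One codon per amino acid; standard genetic code, so translate() is the
# exact inverse.
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.reverseTranslate <- function(aa) {
  paste0(paste(.CODON[.chars(aa)], collapse = ""), "TAA")
}

# ---------------------------------------------------------------------
# Contig assembly
# ---------------------------------------------------------------------

.FEATURE_TEMPLATES <- c("trna_trp_A73", "trna_trp_G73", "orf1",
                        "orf1_no_motifs", "trprs_a1", "trprs_a2",
                        "trprs_a_like", "trprs_bacterial", "trp_repressor",
                        "trna_tyr", "trna_tyr_archaeal",
                        "trna_tyr_chimeric", "tyrs_archaeal", "b2_tyrs",
                        "filler")

# Divergence of contig protein features from their lineage prototype;
# close enough for confident nearest-reference typing, far enough that
# features are not byte-copies of the references.
.FEATURE_PROTEIN_RATE <- 0.05

.buildFeature <- function(template, seed, id) {
  trna <- function(...) {
    g <- generateTrna(..., seed = seed, id = id)
    list(dna = g$sequence, kind = "tRNA", truth = g$truth)
  }
  prot <- function(proto, family, lineage, exclude = character()) {
    # protect the planted motifs (and the start) from feature-level noise
    hits <- rbind(scanClassIMotifs(proto), scanFeSMotif(proto))
    constrained <- unique(c(1L, unlist(lapply(seq_len(nrow(hits)),
      function(k) hits$start[k]:hits$end[k]))))
    aa <- .withSeed(seed, paste(
      .mutateChars(.chars(proto), .FEATURE_PROTEIN_RATE,
                   constrained = constrained,
                   alphabet = setdiff(.AA20, exclude)), collapse = ""))
    list(dna = .reverseTranslate(aa), kind = "CDS",
         truth = data.frame(id = id, family = family, lineage = lineage,
                            stringsAsFactors = FALSE))
  }
  refs <- function(nm) as.character(lineageReferences()$sequences[[nm]])
  switch(template,
    trna_trp_A73 = trna("Trp", pair = "G-C", n73 = "A", vArmLen = 0L),
    trna_trp_G73 = trna("Trp", pair = "A-T", n73 = "G", vArmLen = 0L),
    trna_tyr = trna("Tyr", pair = "G-C", n73 = "A", vArmLen = 13L),
    trna_tyr_archaeal = trna("Tyr", pair = "C-G", n73 = "A", vArmLen = 0L),
    trna_tyr_chimeric = trna("Tyr", pair = "C-G", n73 = "A", vArmLen = 13L),
    orf1 = prot(.orf1Prototype(), NA_character_, "ORF1_like",
                exclude = "W"),
    orf1_no_motifs = prot(.orf1Prototype(ablateMotifs = TRUE),
                          NA_character_, NA_character_, exclude = "W"),
    trprs_a1 = prot(refs("ref_TrpRS_A1"), "TrpRS", "TrpRS_A1",
                    exclude = "W"),
    trprs_a2 = prot(refs("ref_TrpRS_A2"), "TrpRS", "TrpRS_A2"),
    trprs_a_like = prot(refs("ref_TrpRS_A_like"), "TrpRS", "TrpRS_A_like"),
    trprs_bacterial = prot(refs("ref_TrpRS_bacterial"), "TrpRS",
                           "bacteria_type", exclude = "W"),
    tyrs_archaeal = prot(refs("ref_TyrRS_archaeal"), "TyrRS",
                         "archaea_eukarya_type"),
    b2_tyrs = {
      dom <- .domainReferenceSeqs()
      linker <- .prototypeAa(111L, length = 25L, high = NA, kmsks = NA)
      proto <- paste0(dom$B2, substring(linker, 2L),
                      substring(refs("ref_TyrRS_archaeal"), 2L))
      prot(proto, "TyrRS", "archaea_eukarya_type")
    },
    filler = .withSeed(seed, list(
      dna = .reverseTranslate(paste0("M", .randAa(119L))), kind = "CDS",
      truth = data.frame(id = id, family = NA_character_,
                         lineage = NA_character_,
                         stringsAsFactors = FALSE))),
    trp_repressor = .withSeed(seed, list(
      dna = .reverseTranslate(paste0("M", .randAa(99L))), kind = "CDS",
      truth = data.frame(id = id, family = NA_character_,
                         lineage = NA_character_,
                         stringsAsFactors = FALSE))),
    stop("unknown feature template: ", template))
}

# Operon patterns implied by a layout (the generator-side truth).
.layoutOperons <- function(layout, ids, gap, maxGap = 150L) {
  out <- list()
  if (gap > maxGap) return(data.frame())
  add <- function(pattern, members)
    out[[length(out) + 1L]] <<- data.frame(
      pattern = pattern, members = paste(members, collapse = ","),
      stringsAsFactors = FALSE)
  base <- c("trna_trp_A73", "orf1", "trprs_a1")
  n <- length(layout)
  for (i in seq_len(max(0L, n - 2L))) {
    if (!identical(layout[i:(i + 2L)], base)) next
    add("tRNA_ORF1_TrpRSA1", ids[i:(i + 2L)])
    if (i + 3L <= n && layout[i + 3L] == "trprs_bacterial")
      add("tRNA_ORF1_TrpRSA1_plus_bacterialTrpRS", ids[i:(i + 3L)])
    if (i > 1L && layout[i - 1L] == "trp_repressor")
      add("trpR_headed", ids[(i - 1L):(i + 2L)])
  }
  arch <- layout %in% c("trprs_a2", "trprs_a_like")
  if (any(arch) && any(layout == "trna_trp_A73") && any(layout == "orf1")) {
    mem <- which(arch | layout %in% c("trna_trp_A73", "orf1"))
    add("archaeal_cluster_A2", ids[mem])
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Specify one synthetic contig
#'
#' @param layout character vector of feature templates, in transcription
#'   order along the chosen strand; see Details for the template names.
#' @param intergenicGap nt of random sequence between adjacent features.
#' @param strand "+" or "-": on "-" the whole layout is placed on the
#'   minus strand (reverse-complemented in contig space).
#' @param seed integer seed for this contig.
#' @param contig,genome identifiers recorded in the GFF3 and truth table.
#'
#' @details Templates: `trna_trp_A73`, `trna_trp_G73`, `trna_tyr`
#'   (bacterial), `trna_tyr_archaeal`, `trna_tyr_chimeric`, `orf1`,
#'   `orf1_no_motifs`, `trprs_a1`, `trprs_a2`, `trprs_a_like`,
#'   `trprs_bacterial`, `trp_repressor`, `tyrs_archaeal`, `b2_tyrs`,
#'   `filler`.
#' @return A `contigSpec` list understood by [generateContigs()].
#' @export
contigSpec <- function(layout, intergenicGap = 30L, strand = "+",
                       seed = 1L, contig = "contig01",
                       genome = "genome01") {
  if (!length(layout)) stop("'layout' must be non-empty")
  bad <- setdiff(layout, .FEATURE_TEMPLATES)
  if (length(bad)) stop("unknown feature template(s): ",
                        paste(bad, collapse = ", "))
  if (intergenicGap < 0L) stop("'intergenicGap' must be >= 0")
  if (!strand %in% c("+", "-")) stop("'strand' must be '+' or '-'")
  structure(list(layout = layout, intergenicGap = as.integer(intergenicGap),
                 strand = strand, seed = as.integer(seed), contig = contig,
                 genome = genome), class = "contigSpec")
}

#' Generate synthetic contigs with a known truth table
#'
#' Assembles each [contigSpec()] into a contig: features are built from
#' their templates in layout order, separated by random intergenic
#' sequence, flanked by 50 nt of random sequence, and placed on the
#' requested strand. Coordinates in the returned annotation are 1-based
#' inclusive and consistent with the contig lengths; minus-strand
#' features are reverse-complemented in contig space. The truth table
#' records every feature's planted identity elements, lineage and operon
#' membership.
#'
#' @param specs a [contigSpec()] or list of them.
#' @return list with `contigs` (`DNAStringSet`), `features` (`GRanges`
#'   with `type`, `ID` and `label` columns, GFF3-ready), and `truth`
#'   (list of data.frames `features` and `operons`).
#' @examples
#' sc <- generateContigs(contigSpec(c("trna_trp_A73", "orf1", "trprs_a1"),
#'                                  seed = 5))
#' sc$truth$operons
#' @export
generateContigs <- function(specs) {
  if (is(specs, "contigSpec")) specs <- list(specs)
  stopifnot(all(vapply(specs, is, TRUE, "contigSpec")))
  contigs <- character(0)
  featRows <- list(); truthRows <- list(); operonRows <- list()
  for (spec in specs) {
    n <- length(spec$layout)
    ids <- sprintf("%s_f%02d", spec$contig, seq_len(n))
    feats <- lapply(seq_len(n), function(i)
      .buildFeature(spec$layout[i], seed = spec$seed * 1000L + i,
                    id = ids[i]))
    gapSeqs <- .withSeed(spec$seed * 1000L + 500L, {
      c(.randDna(50L),
        vapply(seq_len(max(0L, n - 1L)),
               function(i) .randDna(spec$intergenicGap), ""),
        .randDna(50L))
    })
    # plus-strand assembly in layout order
    pieces <- character(0); starts <- integer(n); ends <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      pieces <- c(pieces, gapSeqs[i]); pos <- pos + nchar(gapSeqs[i])
      starts[i] <- pos + 1L
      pieces <- c(pieces, feats[[i]]$dna); pos <- pos + nchar(feats[[i]]$dna)
      ends[i] <- pos
    }
    pieces <- c(pieces, gapSeqs[n + 1L])
    seq <- paste(pieces, collapse = "")
    L <- nchar(seq)
    if (spec$strand == "-") {
      seq <- .revcomp(seq)
      newStarts <- L - ends + 1L; ends <- L - starts + 1L
      starts <- newStarts
    }
    contigs[spec$contig] <- seq
    ord <- order(starts)
    featRows[[spec$contig]] <- data.frame(
      contig = spec$contig, id = ids[ord], template = spec$layout[ord],
      kind = vapply(feats[ord], function(f) f$kind, ""),
      start = starts[ord], end = ends[ord], strand = spec$strand,
      genome = spec$genome, stringsAsFactors = FALSE)
    tr <- .rbindFill(lapply(feats, function(f) f$truth))
    tr <- tr[match(ids, tr$id), , drop = FALSE]
    tr$contig <- spec$contig; tr$genome <- spec$genome
    tr$template <- spec$layout
    tr$kind <- vapply(feats, function(f) f$kind, "")
    tr$start <- starts; tr$end <- ends; tr$strand <- spec$strand
    truthRows[[spec$contig]] <- tr
    op <- .layoutOperons(spec$layout, ids, spec$intergenicGap)
    if (nrow(op)) {
      op$contig <- spec$contig
      operonRows[[spec$contig]] <- op
    }
  }
  featDf <- do.call(rbind, featRows)
  gr <- GenomicRanges::GRanges(
    seqnames = featDf$contig,
    ranges = IRanges::IRanges(featDf$start, featDf$end),
    strand = featDf$strand)
  mcols(gr)$type <- featDf$kind
  mcols(gr)$ID <- featDf$id
  mcols(gr)$label <- featDf$template
  mcols(gr)$genome <- featDf$genome
  mcols(gr)$phase <- ifelse(featDf$kind == "CDS", 0L, NA_integer_)
  GenomeInfoDb::seqlengths(gr) <-
    setNames(nchar(contigs)[as.character(GenomeInfoDb::seqlevels(gr))],
             GenomeInfoDb::seqlevels(gr))
  truth <- .rbindFill(truthRows)
  lead <- c("contig", "genome", "id", "template", "kind", "start", "end",
            "strand")
  truth <- truth[, c(lead, setdiff(names(truth), lead)), drop = FALSE]
  rownames(truth) <- NULL
  operons <- if (length(operonRows)) {
    o <- do.call(rbind, operonRows); rownames(o) <- NULL
    o[, c("contig", "pattern", "members")]
  } else data.frame(contig = character(0), pattern = character(0),
                    members = character(0), stringsAsFactors = FALSE)
  list(contigs = Biostrings::DNAStringSet(contigs), features = gr,
       truth = list(features = truth, operons = operons))
}

#' Write a generated contig set to FASTA + GFF3 + truth TSV
#'
#' @param x result of [generateContigs()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (fasta, gff3, truth features TSV,
#'   truth operons TSV).
#' @export
writeContigSet <- function(x, dir, prefix = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fna")),
    gff3 = file.path(dir, paste0(prefix, ".gff3")),
    truth_features = file.path(dir, paste0(prefix, ".truth_features.tsv")),
    truth_operons = file.path(dir, paste0(prefix, ".truth_operons.tsv")))
  Biostrings::writeXStringSet(x$contigs, paths[["fasta"]])
  rtracklayer::export(x$features, paths[["gff3"]], format = "gff3")
  write.table(x$truth$features, paths[["truth_features"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x$truth$operons, paths[["truth_operons"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
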