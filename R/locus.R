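# Gene-neighbourhood analysis: loading GFF3+FASTA features, attaching
# tRNA identity and aaRS type calls, ORF1 candidate calling, operon
# pattern detection, and per-genome identity summaries.

#' Load annotated features from GFF3 + FASTA
#'
#' Reads a GFF3 annotation and its contig FASTA, checks referential
#' integrity (every feature's contig must exist and contain its span),
#' and attaches each feature's coding-strand sequence: minus-strand
#' features are reverse-complemented before any downstream call, while
#' the recorded coordinates stay exactly as written (1-based inclusive).
#'
#' @param gff path to a GFF3 file, or a `GRanges` as produced by
#'   [generateContigs()].
#' @param fasta path to the contig FASTA, or a `DNAStringSet`.
#' @return `GRanges` with metadata columns `type`, `ID`, `label` (when
#'   present) and `sequence` (coding-strand).
#' @export
loadFeatures <- function(gff, fasta) {
  gr <- if (is(gff, "GRanges")) gff else
    rtracklayer::import(gff, format = "gff3")
  contigs <- if (is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  want <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(want), names(contigs))
  if (length(missing))
    stop("GFF3 references contig(s) absent from the FASTA: ",
         paste(missing, collapse = ", "))
  lens <- nchar(as.character(contigs))[want]
  over <- which(BiocGenerics::end(gr) > lens | BiocGenerics::start(gr) < 1L)
  if (length(over))
    stop("feature(s) span outside their contig: ",
         paste(mcols(gr)$ID[over], collapse = ", "))
  seqs <- vapply(seq_along(gr), function(i) {
    s <- substr(as.character(contigs[[want[i]]]),
                BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i])
    if (as.character(BiocGenerics::strand(gr))[i] == "-") .revcomp(s) else s
  }, "")
  mcols(gr)$sequence <- seqs
  gr
}

.translateCds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, 3L * (nchar(dna) %/% 3L))),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Attach identity and type calls to loaded features
#'
#' Runs the cloverleaf classifier on every tRNA feature and the motif
#' scanners plus nearest-reference classifier on every CDS feature,
#' recording the results as metadata columns. Per-record failures (e.g.
#' unfoldable tRNAs) are recorded in the `note` column, never raised.
#'
#' @param features `GRanges` from [loadFeatures()].
#' @param refs labeled reference set for [classifyAars()].
#' @param cfg a [classifierConfig()].
#' @return The `GRanges` with columns `isotype`, `domain_type`,
#'   `v_arm_len`, `n73`, `family`, `lineage`, `similarity`, `n_high`,
#'   `n_kmsks`, `n_fes`, `trp_free`, `protein`, `note`.
#' @export
annotateFeatures <- function(features, refs = lineageReferences(),
                             cfg = classifierConfig()) {
  n <- length(features)
  mc <- mcols(features)
  mc$isotype <- NA_character_; mc$domain_type <- NA_character_
  mc$v_arm_len <- NA_integer_; mc$n73 <- NA_character_
  mc$family <- NA_character_; mc$lineage <- NA_character_
  mc$similarity <- NA_real_
  mc$n_high <- NA_integer_; mc$n_kmsks <- NA_integer_
  mc$n_fes <- NA_integer_; mc$trp_free <- NA
  mc$protein <- NA_character_; mc$note <- ""
  for (i in seq_len(n)) {
    kind <- mc$type[i]
    seq <- mc$sequence[i]
    if (kind == "tRNA") {
      res <- tryCatch({
        cl <- foldCloverleaf(seq)
        if (!cl@foldable) list(note = cl@reason) else {
          prof <- extractIdentityProfile(cl)
          call <- tryCatch(classifyIdentity(prof), error = function(e) NULL)
          list(isotype = prof@isotypeHint,
               domain_type = if (is.null(call)) NA_character_ else
                 call@domainType,
               v_arm_len = prof@vArmLen, n73 = prof@n73,
               note = if (is.null(call)) "anticodon not Tyr/Trp" else "")
        }
      }, error = function(e) list(note = conditionMessage(e)))
      for (nm in names(res)) mc[[nm]][i] <- res[[nm]]
    } else if (kind == "CDS") {
      res <- tryCatch({
        aa <- .translateCds(seq)
        hits <- scanClassIMotifs(aa)
        call <- classifyAars(aa, refs, cfg)
        list(protein = aa,
             n_high = sum(hits$motif == "HIGH"),
             n_kmsks = sum(hits$motif == "KMSKS"),
             n_fes = nrow(scanFeSMotif(aa)),
             trp_free = auditTrpContent(aa)$trp_free,
             family = call@family, lineage = call@lineage,
             similarity = call@similarity, note = "")
      }, error = function(e) list(note = conditionMessage(e)))
      for (nm in names(res)) mc[[nm]][i] <- res[[nm]]
    }
  }
  mcols(features) <- mc
  features
}

# Features of one contig in transcription order (5'->3' on their strand),
# split into co-transcriptional chains at strand changes or gaps larger
# than maxGap.
.strandChains <- function(features, maxGap) {
  out <- list()
  for (ctg in unique(as.character(GenomicRanges::seqnames(features)))) {
    f <- features[as.character(GenomicRanges::seqnames(features)) == ctg]
    for (str in c("+", "-")) {
      g <- f[as.character(BiocGenerics::strand(f)) == str]
      if (!length(g)) next
      ord <- order(BiocGenerics::start(g))
      if (str == "-") ord <- rev(ord)
      g <- g[ord]
      if (length(g) == 1L) { out <- c(out, list(g)); next }
      s <- BiocGenerics::start(g); e <- BiocGenerics::end(g)
      gap <- if (str == "+") s[-1L] - e[-length(e)] - 1L else
        s[-length(s)] - e[-1L] - 1L
      brk <- c(0L, which(gap > maxGap), length(g))
      for (k in seq_len(length(brk) - 1L))
        out <- c(out, list(g[(brk[k] + 1L):brk[k + 1L]]))
    }
  }
  out
}

.roleOf <- function(mc) {
  n <- nrow(mc)
  role <- rep("other", n)
  isTrpA73 <- mc$type == "tRNA" & !is.na(mc$isotype) & mc$isotype == "Trp" &
    !is.na(mc$domain_type) & mc$domain_type == "archaeal_eukaryal"
  role[isTrpA73] <- "trna_trp_A73"
  if (!is.null(mc$orf1_like)) role[isTRUEatomic(mc$orf1_like)] <- "orf1"
  cds <- mc$type == "CDS"
  lin <- ifelse(is.na(mc$lineage), "", mc$lineage)
  role[cds & lin == "TrpRS_A1"] <- "trprs_a1"
  role[cds & lin == "TrpRS_A2"] <- "trprs_a2"
  role[cds & lin == "TrpRS_A_like"] <- "trprs_a_like"
  fam <- ifelse(is.na(mc$family), "", mc$family)
  role[cds & fam == "TrpRS" & lin == "bacteria_type"] <- "trprs_bacterial"
  if (!is.null(mc$label))
    role[cds & !is.na(mc$label) & mc$label == "trp_repressor"] <- "trpR"
  role
}

isTRUEatomic <- function(x) !is.na(x) & x

#' Flag ORF1 candidate CDS features
#'
#' A CDS is flagged `ORF1_like` iff all three conditions hold: (a) it
#' sits between a tRNA-Trp(A73) feature (upstream) and a TrpRS-A-called
#' CDS (downstream) in the same co-transcriptional chain, or anywhere
#' inside a chain carrying a TrpRS-A2 / TrpRS-A-like call; (b) the
#' nearest-reference classifier returned `unassigned` (ORF1 has no
#' significant similarity to any known protein); and (c) it carries at
#' least one HIGH-like and one KMSKS-like motif hit. Length bounds
#' exclude trivial ORFs.
#'
#' @param features annotated `GRanges` from [annotateFeatures()].
#' @param maxGap maximum intergenic gap (nt) within a chain.
#' @param lengthBounds allowed protein length range in residues.
#' @return The `GRanges` with a logical `orf1_like` column.
#' @export
callOrf1Candidates <- function(features, maxGap = 150L,
                               lengthBounds = c(120L, 450L)) {
  mc <- mcols(features)
  mc$orf1_like <- FALSE
  chains <- .strandChains(features, maxGap)
  flagged <- character(0)
  for (ch in chains) {
    m <- mcols(ch)
    lin <- ifelse(is.na(m$lineage), "", m$lineage)
    trpA <- m$type == "tRNA" & !is.na(m$isotype) & m$isotype == "Trp" &
      !is.na(m$domain_type) & m$domain_type == "archaeal_eukaryal"
    trpRsA <- lin %in% c("TrpRS_A1", "TrpRS_A2", "TrpRS_A_like")
    archCluster <- any(lin %in% c("TrpRS_A2", "TrpRS_A_like"))
    for (i in seq_along(ch)) {
      if (m$type[i] != "CDS" || is.na(m$protein[i])) next
      plen <- nchar(m$protein[i])
      if (plen < lengthBounds[1L] || plen > lengthBounds[2L]) next
      condA <- archCluster ||
        (any(trpA[seq_len(i - 1L)]) &&
         any(trpRsA[seq_len(length(ch) - i) + i]))
      condB <- lin[i] == "unassigned"
      condC <- isTRUEatomic(m$n_high[i] >= 1L) &&
        isTRUEatomic(m$n_kmsks[i] >= 1L)
      if (condA && condB && condC) flagged <- c(flagged, m$ID[i])
    }
  }
  mc$orf1_like <- mc$ID %in% flagged
  mcols(features) <- mc
  features
}

.OPERON_PATTERNS <- list(
  tRNA_ORF1_TrpRSA1 = c("trna_trp_A73", "orf1", "trprs_a1"),
  tRNA_ORF1_TrpRSA1_plus_bacterialTrpRS =
    c("trna_trp_A73", "orf1", "trprs_a1", "trprs_bacterial"),
  trpR_headed = c("trpR", "trna_trp_A73", "orf1", "trprs_a1")
)

#' Detect operon structures among annotated features
#'
#' Orders the features of each contig in transcription order (5'->3' on
#' their strand), breaks them into chains at strand changes or
#' intergenic gaps above `maxGap`, and slides the pattern templates over
#' each chain: `tRNA_ORF1_TrpRSA1` (tRNA-Trp(A73), ORF1, TrpRS-A1 in
#' order), its extension followed by a bacteria-type TrpRS, the variant
#' headed by a trp-repressor gene, and `archaeal_cluster_A2` (a chain
#' co-locating a TrpRS-A2 / TrpRS-A-like call with a tRNA-Trp(A73) and
#' an ORF1, without an adjacency requirement). Overlapping patterns are
#' each reported. No call ever spans two contigs or two strands.
#'
#' @param features annotated `GRanges` with `orf1_like` calls (see
#'   [callOrf1Candidates()]).
#' @param maxGap maximum internal gap in nt (default 150, a conventional
#'   operon-spacing heuristic).
#' @return data.frame with columns `contig`, `pattern`, `members`
#'   (comma-separated feature ids in transcription order), `strand`,
#'   `max_internal_gap`.
#' @export
detectOperons <- function(features, maxGap = 150L) {
  chains <- .strandChains(features, maxGap)
  out <- list()
  emit <- function(ch, idx, pattern) {
    s <- BiocGenerics::start(ch)[idx]; e <- BiocGenerics::end(ch)[idx]
    str <- as.character(BiocGenerics::strand(ch))[1L]
    gaps <- if (length(idx) > 1L) {
      if (str == "+") s[-1L] - e[-length(e)] - 1L
      else s[-length(s)] - e[-1L] - 1L
    } else 0L
    out[[length(out) + 1L]] <<- data.frame(
      contig = as.character(GenomicRanges::seqnames(ch))[1L],
      pattern = pattern,
      members = paste(mcols(ch)$ID[idx], collapse = ","),
      strand = as.character(BiocGenerics::strand(ch))[1L],
      max_internal_gap = max(gaps),
      stringsAsFactors = FALSE)
  }
  for (ch in chains) {
    role <- .roleOf(as.data.frame(mcols(ch)))
    n <- length(role)
    for (pat in names(.OPERON_PATTERNS)) {
      tpl <- .OPERON_PATTERNS[[pat]]
      k <- length(tpl)
      if (n < k) next
      for (i in seq_len(n - k + 1L))
        if (identical(role[i:(i + k - 1L)], tpl)) emit(ch, i:(i + k - 1L), pat)
    }
    if (any(role %in% c("trprs_a2", "trprs_a_like")) &&
        any(role == "trna_trp_A73") && any(role == "orf1"))
      emit(ch, which(role %in% c("trna_trp_A73", "orf1", "trprs_a2",
                                 "trprs_a_like")), "archaeal_cluster_A2")
  }
  if (!length(out))
    return(data.frame(contig = character(0), pattern = character(0),
                      members = character(0), strand = character(0),
                      max_internal_gap = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize tRNA identities and aaRS lineages per genome
#'
#' Aggregates per-feature calls into per-genome counts of tRNA-Tyr /
#' tRNA-Trp by identity-domain type and an aaRS lineage inventory, and
#' flags genomes with dual identity: both a bacterial-type and an
#' archaeal/eukaryal-type call present for the same isotype (the
#' configuration where a bacterial tRNA-Trp(G73) coexists with a
#' tRNA-Trp(A73)).
#'
#' @param features annotated `GRanges`.
#' @param genomeOf optional named character vector mapping contig name to
#'   genome id; contigs map to themselves by default. When the features
#'   carry a `genome` column it is used directly.
#' @return data.frame, one row per genome: counts per isotype x domain
#'   type, `lineages` inventory, `dual_identity`.
#' @export
summarizeGenome <- function(features, genomeOf = NULL) {
  mc <- mcols(features)
  ctg <- as.character(GenomicRanges::seqnames(features))
  genome <- if (!is.null(genomeOf)) unname(genomeOf[ctg])
    else if (!is.null(mc$genome)) as.character(mc$genome)
    else ctg
  combos <- expand.grid(iso = c("Tyr", "Trp"),
                        dt = c("bacterial", "archaeal_eukaryal",
                               "chimeric_C1G72_with_Varm", "ambiguous"),
                        stringsAsFactors = FALSE)
  rows <- lapply(unique(genome), function(g) {
    sel <- genome == g
    row <- data.frame(genome = g, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(combos))) {
      cnt <- sum(sel & mc$type == "tRNA" &
                 !is.na(mc$isotype) & mc$isotype == combos$iso[k] &
                 !is.na(mc$domain_type) & mc$domain_type == combos$dt[k])
      row[[paste0("n_", combos$iso[k], "_", combos$dt[k])]] <- cnt
    }
    lins <- mc$lineage[sel & mc$type == "CDS" & !is.na(mc$lineage) &
                       mc$lineage != "unassigned"]
    row$lineages <- paste(sort(unique(lins)), collapse = ",")
    dual <- FALSE
    for (iso in c("Tyr", "Trp")) {
      bact <- row[[paste0("n_", iso, "_bacterial")]] > 0L
      arch <- row[[paste0("n_", iso, "_archaeal_eukaryal")]] > 0L
      if (bact && arch) dual <- TRUE
    }
    row$dual_identity <- dual
    row
  })
  do.call(rbind, rows)
}
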