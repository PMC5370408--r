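# Pairwise similarity, nearest-reference lineage typing, domain
# architecture, and recombination-breakpoint detection.
#
# "Similarity" throughout is the BLOSUM62 positives fraction of a global
# affine-gap alignment, i.e. the quantity BLAST reports as "Positives";
# the collection thresholds this screen inherits were defined on that
# scale. Identity is reported alongside.

.alignPair <- function(a, b, type = "global") {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = type)
}

.alignedChars <- function(pa) {
  list(p = .chars(as.character(Biostrings::alignedPattern(pa))),
       s = .chars(as.character(Biostrings::alignedSubject(pa))))
}

# Strip terminal-gap columns (the leading/trailing runs where only one
# sequence has started/ended).
.trimTerminalGaps <- function(p, s) {
  n <- length(p)
  i <- 1L
  while (i <= n && (p[i] == "-" || s[i] == "-")) i <- i + 1L
  j <- n
  while (j >= i && (p[j] == "-" || s[j] == "-")) j <- j - 1L
  if (i > j) return(list(p = character(0), s = character(0)))
  list(p = p[i:j], s = s[i:j])
}

.similarityFromAlignment <- function(p, s, mode = "aligned") {
  full <- length(p)
  if (mode == "aligned") {
    tr <- .trimTerminalGaps(p, s)
    p <- tr$p; s <- tr$s
  }
  ncol <- length(p)
  if (ncol == 0L) return(c(similarity = 0, identity = 0))
  both <- p != "-" & s != "-"
  B <- .blosum62()
  pos <- sum(B[cbind(p[both], s[both])] > 0)
  idn <- sum(p[both] == s[both])
  denom <- if (mode == "aligned") ncol else full
  c(similarity = pos / denom, identity = idn / denom)
}

#' Global-alignment similarity between two proteins
#'
#' Aligns two proteins globally (Needleman-Wunsch, BLOSUM62, affine
#' gaps) and returns the positives fraction: alignment columns where the
#' BLOSUM62 score of the residue pair is positive, divided by the number
#' of alignment columns. By default terminal-gap columns are excluded
#' from the denominator (`mode = "aligned"`); `mode = "full"` divides by
#' the full alignment length instead. The function is symmetric in its
#' arguments by construction (the pair is aligned in a canonical order).
#'
#' @param a,b non-empty amino-acid sequences.
#' @param mode "aligned" (default) or "full".
#' @param details when `TRUE`, return a list with `similarity`,
#'   `identity`, `score` and the aligned strings.
#' @return numeric(1) similarity in `[0, 1]`, or the detail list.
#' @examples
#' pairwiseSimilarity("MKTAYIAKQR", "MKTAYIAKQR")
#' @export
pairwiseSimilarity <- function(a, b, mode = c("aligned", "full"),
                               details = FALSE) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)[1L]); b <- toupper(as.character(b)[1L])
  if (!nchar(a) || !nchar(b)) stop("both sequences must be non-empty")
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  pa <- .alignPair(a, b)
  al <- .alignedChars(pa)
  v <- .similarityFromAlignment(al$p, al$s, mode)
  if (!details) return(unname(v["similarity"]))
  list(similarity = unname(v["similarity"]),
       identity = unname(v["identity"]),
       score = Biostrings::score(pa),
       pattern = paste(if (swapped) al$s else al$p, collapse = ""),
       subject = paste(if (swapped) al$p else al$s, collapse = ""))
}

#' Classifier configuration for lineage typing
#'
#' @param similarityThreshold minimum similarity for a lineage call
#'   (default 0.40, the collection threshold this screen inherits from
#'   BLASTp practice).
#' @param requireFesForA2 when `TRUE`, a TrpRS_A2 call additionally
#'   requires an Fe-S C-x22-C-x6-C-x2-C hit in the query; without one the
#'   call is demoted to unassigned with an explanatory note.
#' @param mode similarity denominator, see [pairwiseSimilarity()].
#' @return list of class `classifierConfig`.
#' @export
classifierConfig <- function(similarityThreshold = 0.40,
                             requireFesForA2 = FALSE,
                             mode = c("aligned", "full")) {
  if (similarityThreshold <= 0 || similarityThreshold > 1)
    stop("'similarityThreshold' must lie in (0, 1]")
  structure(list(similarityThreshold = similarityThreshold,
                 requireFesForA2 = isTRUE(requireFesForA2),
                 mode = match.arg(mode)),
            class = "classifierConfig")
}

#' Read a labeled reference set (FASTA + label TSV)
#'
#' The label file must have columns `id`, `family`, `lineage`; ids must
#' match the FASTA names.
#'
#' @param fasta path to a protein FASTA.
#' @param labels path to a tab-separated label table.
#' @return list with `sequences` (`AAStringSet`) and `labels`
#'   (data.frame), the format [classifyAars()] expects.
#' @export
readReferenceSet <- function(fasta, labels) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lab <- read.delim(labels, stringsAsFactors = FALSE)
  need <- c("id", "family", "lineage")
  if (!all(need %in% names(lab)))
    stop("label table must have columns id, family, lineage")
  missing <- setdiff(lab$id, names(seqs))
  if (length(missing))
    stop("labels reference sequences absent from the FASTA: ",
         paste(missing, collapse = ", "))
  list(sequences = seqs[lab$id], labels = lab)
}

#' Classify an aaRS protein by nearest labeled reference
#'
#' Computes the similarity of the query to every labeled reference and
#' adopts the family and lineage of the nearest one, provided its
#' similarity reaches the configured threshold; otherwise the lineage is
#' `unassigned`. Ties are broken by lexicographic reference id. Evidence
#' lists the top three references with their similarities.
#'
#' @param protein amino-acid sequence.
#' @param refs a reference set as returned by [lineageReferences()] or
#'   [readReferenceSet()].
#' @param cfg a [classifierConfig()].
#' @return An [AarsTypeCall-class] object.
#' @examples
#' refs <- lineageReferences()
#' classifyAars(as.character(refs$sequences[[1]]), refs)
#' @export
classifyAars <- function(protein, refs, cfg = classifierConfig()) {
  if (!length(refs$sequences)) stop("reference set is empty")
  protein <- toupper(as.character(protein)[1L])
  ids <- names(refs$sequences)
  sims <- vapply(ids, function(id)
    pairwiseSimilarity(protein, as.character(refs$sequences[[id]]),
                       mode = cfg$mode), 0)
  ord <- order(-sims, ids)
  lab <- refs$labels[match(ids[ord], refs$labels$id), , drop = FALSE]
  top <- head(data.frame(reference = ids[ord], family = lab$family,
                         lineage = lab$lineage,
                         similarity = unname(sims[ord]),
                         stringsAsFactors = FALSE), 3L)
  best <- top[1L, ]
  assigned <- best$similarity >= cfg$similarityThreshold
  lineage <- if (assigned) best$lineage else "unassigned"
  family <- if (assigned) best$family else "unknown"
  note <- character(0)
  if (assigned && lineage == "TrpRS_A2" && cfg$requireFesForA2 &&
      nrow(scanFeSMotif(protein)) == 0L) {
    lineage <- "unassigned"
    note <- "TrpRS_A2 demoted: no Fe-S C-x22-C-x6-C-x2-C motif in query"
  }
  ev <- top
  if (length(note)) attr(ev, "note") <- note
  new("AarsTypeCall", family = family, lineage = lineage,
      bestReference = best$reference, similarity = best$similarity,
      evidence = ev, threshold = cfg$similarityThreshold)
}

#' Detect the domain architecture of a class Ic aaRS protein
#'
#' Segments the protein N-to-C: an optional B2 domain (called when the
#' region upstream of the first HIGH hit matches the B2 reference at or
#' above the similarity threshold), an optional linker between B2 and the
#' catalytic core, the catalytic core spanning HIGH..KMSKS, the
#' anticodon-binding domain (ABD) after KMSKS, and an optional S4-like
#' C-terminal domain (called from similarity of the post-core region to
#' the S4 reference, as in bacteria-type TyrRS). Absent segments are
#' omitted. Without a HIGH hit the architecture is returned empty with a
#' warning flag.
#'
#' @param protein amino-acid sequence.
#' @param refs named `AAStringSet` (or character) with optional entries
#'   `B2` and `S4`; defaults to the bundled synthetic
#'   [domainReferences()].
#' @param threshold similarity threshold for B2/S4 calls.
#' @return A [DomainArchitecture-class] object.
#' @export
detectArchitecture <- function(protein, refs = domainReferences(),
                               threshold = 0.40) {
  protein <- toupper(as.character(protein)[1L])
  n <- nchar(protein)
  hits <- scanClassIMotifs(protein)
  highs <- hits[hits$motif == "HIGH", , drop = FALSE]
  seg <- function(segment, start, end, evidence)
    data.frame(segment = segment, start = as.integer(start),
               end = as.integer(end), evidence = evidence,
               stringsAsFactors = FALSE)
  if (nrow(highs) == 0L)
    return(new("DomainArchitecture", segments = seg(character(0),
               integer(0), integer(0), character(0)), warning = TRUE))
  high <- highs[1L, ]
  kms <- hits[hits$motif == "KMSKS" & hits$start > high$end, , drop = FALSE]
  segments <- list()
  refChar <- function(nm)
    if (!is.null(refs) && nm %in% names(refs))
      as.character(refs[[nm]]) else NULL
  # B2: match the N-terminal region against the B2 reference
  b2end <- 0L
  b2ref <- refChar("B2")
  if (!is.null(b2ref) && high$start > 20L) {
    nterm <- substr(protein, 1L, high$start - 1L)
    la <- .alignPair(nterm, b2ref, type = "local")
    al <- .alignedChars(la)
    v <- .similarityFromAlignment(al$p, al$s, mode = "aligned")
    span <- Biostrings::pattern(la)
    if (v[["similarity"]] >= threshold &&
        (BiocGenerics::end(span) - BiocGenerics::start(span) + 1L) >=
          0.5 * nchar(b2ref)) {
      b2end <- BiocGenerics::end(span)
      segments <- c(segments, list(seg(
        "B2", BiocGenerics::start(span), b2end,
        sprintf("similarity %.2f to B2 reference", v[["similarity"]]))))
    }
  }
  if (b2end > 0L && high$start - b2end > 10L)
    segments <- c(segments, list(seg(
      "linker", b2end + 1L, high$start - 1L,
      "region between B2 domain and catalytic core")))
  warningFlag <- FALSE
  if (nrow(kms)) {
    coreEnd <- kms$end[1L]
    segments <- c(segments, list(seg(
      "catalytic_core", high$start, coreEnd,
      sprintf("HIGH %d-%d .. KMSKS %d-%d", high$start, high$end,
              kms$start[1L], coreEnd))))
    # S4-like: match the post-core region against the S4 reference
    s4start <- 0L
    s4ref <- refChar("S4")
    if (!is.null(s4ref) && n - coreEnd > 20L) {
      cterm <- substr(protein, coreEnd + 1L, n)
      la <- .alignPair(cterm, s4ref, type = "local")
      al <- .alignedChars(la)
      v <- .similarityFromAlignment(al$p, al$s, mode = "aligned")
      span <- Biostrings::pattern(la)
      if (v[["similarity"]] >= threshold &&
          (BiocGenerics::end(span) - BiocGenerics::start(span) + 1L) >=
            0.5 * nchar(s4ref)) {
        s4start <- coreEnd + BiocGenerics::start(span)
        segments <- c(segments, list(seg(
          "ABD", coreEnd + 1L, s4start - 1L,
          "anticodon-binding domain (post-KMSKS)")))
        segments <- c(segments, list(seg(
          "S4_like", s4start, coreEnd + BiocGenerics::end(span),
          sprintf("similarity %.2f to S4 reference", v[["similarity"]]))))
      }
    }
    if (s4start == 0L && coreEnd < n)
      segments <- c(segments, list(seg(
        "ABD", coreEnd + 1L, n, "anticodon-binding domain (post-KMSKS)")))
  } else {
    warningFlag <- TRUE
  }
  segdf <- if (length(segments)) do.call(rbind, segments) else
    seg(character(0), integer(0), integer(0), character(0))
  segdf <- segdf[order(segdf$start), , drop = FALSE]
  rownames(segdf) <- NULL
  new("DomainArchitecture", segments = segdf, warning = warningFlag)
}

#' Detect recombination breakpoints between two near-identical sequences
#'
#' Globally aligns the two sequences, computes per-window identity along
#' the alignment (gap columns count as mismatches), classifies windows
#' as high (identity >= `highThr`) or low (identity <= `lowThr`), and
#' reports a breakpoint at every transition between a high plateau and a
#' low one. The breakpoint position is the midpoint (alignment column)
#' between the centers of the two flanking classified windows. A pair of
#' contigs whose shared gene differs only in a swapped internal domain
#' yields exactly two breakpoints flanking the swap.
#'
#' @param a,b amino-acid (or nucleotide) sequences.
#' @param window window width in alignment columns (>= 10).
#' @param step step between window starts.
#' @param highThr,lowThr identity thresholds with `highThr > lowThr`.
#' @return A [BreakpointReport-class] object.
#' @export
detectBreakpoints <- function(a, b, window = 30L, step = 10L,
                              highThr = 0.9, lowThr = 0.5) {
  window <- as.integer(window); step <- as.integer(step)
  if (window < 10L) stop("'window' must be at least 10")
  if (highThr <= lowThr) stop("'highThr' must exceed 'lowThr'")
  pa <- .alignPair(toupper(a), toupper(b))
  al <- .alignedChars(pa)
  ncol <- length(al$p)
  if (ncol < window) stop("alignment too short for the window (",
                          ncol, " < ", window, ")")
  match <- as.numeric(al$p == al$s & al$p != "-")
  cs <- c(0, cumsum(match))
  starts <- seq(1L, ncol - window + 1L, by = step)
  ident <- (cs[starts + window] - cs[starts]) / window
  centers <- starts + (window - 1) / 2
  track <- data.frame(start = starts, end = starts + window - 1L,
                      center = centers, identity = ident)
  state <- ifelse(ident >= highThr, "H", ifelse(ident <= lowThr, "L", NA))
  keep <- which(!is.na(state))
  bp <- numeric(0)
  if (length(keep) >= 2L) {
    st <- state[keep]
    change <- which(st[-1L] != st[-length(st)])
    bp <- (centers[keep[change]] + centers[keep[change + 1L]]) / 2
  }
  new("BreakpointReport", track = track, breakpoints = bp,
      window = window, step = step, highThreshold = highThr,
      lowThreshold = lowThr)
}
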