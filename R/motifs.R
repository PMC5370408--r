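# Class I aaRS motif scanning: degenerate HIGH / KMSKS patterns, the
# Fe-S four-cysteine spacing motif, and the tryptophan-content audit.

# Default degenerate patterns. Each pattern is a list of allowed-letter
# sets, one per position; the defaults follow the class I consensus
# while staying loose enough to catch "motif-like" variants.
.CLASS_I_PATTERNS <- list(
  HIGH = list(c("H", "N", "Q"), c("I", "L", "V", "M", "A", "F", "G"),
              "G", c("H", "N")),
  KMSKS = list(c("K", "R"), c("M", "L", "I", "V", "F"), "S",
               c("K", "S"), c("S", "G"))
)

# All match start positions of a degenerate pattern (overlaps included).
.scanDegenerate <- function(ch, pattern) {
  m <- length(pattern)
  n <- length(ch)
  if (n < m) return(integer(0))
  ok <- ch[seq_len(n - m + 1L)] %in% pattern[[1L]]
  for (k in seq_len(m - 1L))
    ok <- ok & ch[seq_len(n - m + 1L) + k] %in% pattern[[k + 1L]]
  which(ok)
}

# Greedy left-to-right non-overlapping selection of match starts.
.greedyNonOverlap <- function(starts, len) {
  keep <- integer(0)
  last <- -len
  for (s in starts) {
    if (s >= last + len) {
      keep <- c(keep, s)
      last <- s
    }
  }
  keep
}

.motifHitFrame <- function(motif, starts, len, ch, patternId) {
  data.frame(
    motif = rep(motif, length(starts)),
    start = starts, end = starts + len - 1L,
    matched_text = vapply(starts, function(s)
      paste(ch[s:(s + len - 1L)], collapse = ""), ""),
    pattern_id = rep(patternId, length(starts)),
    stringsAsFactors = FALSE)
}

.checkProtein <- function(protein) {
  protein <- toupper(as.character(protein)[1L])
  ch <- .chars(protein)
  if (length(ch) && !all(ch %in% c(.AA20, "X")))
    stop("protein alphabet must be the 20 amino acids plus X")
  ch
}

#' Scan a protein for class I HIGH and KMSKS motifs
#'
#' Scans with degenerate patterns (defaults: HIGH = `[HNQ]-[ILVMAFG]-G-[HN]`,
#' KMSKS = `[KR]-[MLIVF]-S-[KS]-[SG]`), reporting all non-overlapping
#' matches of each pattern, selected greedily left to right. The two
#' motifs are scanned independently.
#'
#' @param protein character(1) amino-acid sequence (20 letters + X).
#' @param patterns named list of degenerate patterns (each a list of
#'   allowed-letter vectors); defaults to the class I consensus patterns.
#' @return data.frame of hits with columns `motif`, `start`, `end`
#'   (1-based inclusive), `matched_text`, `pattern_id`, ordered by
#'   ascending start.
#' @examples
#' scanClassIMotifs("AAAHIGHAAAKMSKSAAA")
#' @export
scanClassIMotifs <- function(protein, patterns = .CLASS_I_PATTERNS) {
  ch <- .checkProtein(protein)
  if (!length(ch)) return(.motifHitFrame(character(0), integer(0), 0L,
                                         ch, character(0)))
  hits <- lapply(names(patterns), function(nm) {
    len <- length(patterns[[nm]])
    starts <- .greedyNonOverlap(.scanDegenerate(ch, patterns[[nm]]), len)
    .motifHitFrame(nm, starts, len, ch, "degenerate_default")
  })
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Scan a protein for the Fe-S four-cysteine spacing motif
#'
#' Matches spans of exactly C-x22-C-x6-C-x2-C (34 residues in total, four
#' cysteines). Overlapping matches are all reported.
#'
#' @inheritParams scanClassIMotifs
#' @return data.frame of hits (`motif` = "FeS_C4"), one row per match.
#' @export
scanFeSMotif <- function(protein) {
  ch <- .checkProtein(protein)
  n <- length(ch)
  offsets <- c(0L, 23L, 30L, 33L)
  starts <- integer(0)
  if (n >= 34L) {
    cand <- seq_len(n - 33L)
    keep <- rep(TRUE, length(cand))
    for (o in offsets) keep <- keep & ch[cand + o] == "C"
    starts <- cand[keep]
  }
  .motifHitFrame("FeS_C4", starts, 34L, ch, "C-x22-C-x6-C-x2-C")
}

#' Count tryptophan residues
#'
#' Tryptophan-content audit: several of the proteins this screen targets
#' (ORF1, the TrpRS-A1 partners and the co-resident bacteria-type TrpRSs)
#' are entirely tryptophan-free, a composition worth flagging.
#'
#' @inheritParams scanClassIMotifs
#' @return list with `count` (number of W residues) and `trp_free`
#'   (logical, `count == 0`).
#' @export
auditTrpContent <- function(protein) {
  ch <- .checkProtein(protein)
  count <- sum(ch == "W")
  list(count = count, trp_free = count == 0L)
}
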