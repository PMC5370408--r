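# Progressive multiple alignment and motif-anchored core trimming.
#
# The aligner is the classic progressive scheme: a k-mer distance guide
# tree (average-linkage) and profile-profile Needleman-Wunsch merges
# with affine gaps under BLOSUM62. Sequences are processed in a
# canonical (lexicographic id) order, so the result is invariant to the
# input order up to row order.

.kmerCounts <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  table(substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

.kmerDistance <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, .kmerCounts, k = k)
  lens <- nchar(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    common <- intersect(names(counts[[i]]), names(counts[[j]]))
    shared <- sum(pmin(counts[[i]][common], counts[[j]][common]))
    denom <- max(1L, min(lens[i], lens[j]) - k + 1L)
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  d
}

# 20-letter frequency matrix of an aligned character matrix (rows =
# sequences); gap and X columns contribute nothing.
.profileFreq <- function(mat) {
  L <- ncol(mat)
  f <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, .AA20))
  for (a in .AA20) f[, a] <- colSums(mat == a) / nrow(mat)
  f
}

.mergeProfiles <- function(A, B, subs, gapOpen, gapExt) {
  fa <- .profileFreq(A); fb <- .profileFreq(B)
  score <- fa %*% subs %*% t(fb)
  path <- nw_profile_cpp(score, gapOpen, gapExt)
  n <- length(path$a)
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = n,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  out[seq_len(nrow(A)), path$a > 0L] <- A[, path$a[path$a > 0L],
                                          drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), path$b > 0L] <- B[, path$b[path$b > 0L],
                                                    drop = FALSE]
  out
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively: pairwise k-mer distances
#' define an average-linkage guide tree, and profiles are merged bottom-up
#' with affine-gap profile-profile Needleman-Wunsch under BLOSUM62.
#' Sequences are ordered canonically by id internally, so permuting the
#' input changes nothing but the row order of the result (which follows
#' the input order).
#'
#' @param seqs named character vector or `AAStringSet` (>= 1 sequence).
#' @param gapOpen,gapExt affine gap penalties.
#' @param k k-mer length for the guide-tree distance.
#' @return `AAStringSet` of gapped rows, all the same width, in the
#'   input order; ungapping any row returns its input sequence.
#' @examples
#' alignProgressive(c(a = "MKTAYIAK", b = "MKTAYIAK"))
#' @export
alignProgressive <- function(seqs, gapOpen = 10, gapExt = 0.5, k = 3L) {
  seqs <- setNames(toupper(as.character(seqs)), names(seqs))
  if (!length(seqs)) stop("need at least one sequence")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (length(seqs) == 1L) return(Biostrings::AAStringSet(seqs))
  inputOrder <- names(seqs)
  seqs <- seqs[order(names(seqs))]
  subs <- .blosum62()[.AA20, .AA20]
  profiles <- lapply(names(seqs), function(id)
    matrix(.chars(seqs[[id]]), nrow = 1L, dimnames = list(id, NULL)))
  if (length(seqs) == 2L) {
    merged <- .mergeProfiles(profiles[[1L]], profiles[[2L]], subs,
                             gapOpen, gapExt)
  } else {
    hc <- hclust(as.dist(.kmerDistance(seqs, k)), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    pick <- function(x) if (x < 0L) profiles[[-x]] else nodes[[x]]
    for (r in seq_len(nrow(hc$merge))) {
      nodes[[r]] <- .mergeProfiles(pick(hc$merge[r, 1L]),
                                   pick(hc$merge[r, 2L]),
                                   subs, gapOpen, gapExt)
    }
    merged <- nodes[[length(nodes)]]
  }
  rows <- apply(merged, 1L, paste, collapse = "")
  Biostrings::AAStringSet(rows[inputOrder])
}

# Alignment columns of a motif's hits, per row: scan each ungapped row
# and map residue indices through the gaps.
.anchorColumns <- function(mat, motif = "HIGH") {
  cols <- integer(0)
  for (r in seq_len(nrow(mat))) {
    res <- which(mat[r, ] != "-")
    seq <- paste(mat[r, res], collapse = "")
    hits <- scanClassIMotifs(seq)
    hits <- hits[hits$motif == motif, , drop = FALSE]
    if (nrow(hits))
      cols <- c(cols, res[hits$start[1L]:hits$end[1L]])
  }
  sort(unique(cols))
}

#' Trim an alignment to the class Ic phylogenetic core
#'
#' Restricts the alignment to the region used for class Ic aaRS
#' phylogenetics: from a fixed number of columns upstream of the first
#' HIGH-motif anchor column (13 by default, clamped at column 1) to the
#' end of the anticodon-binding domain, then removes columns that are
#' majority gaps (> 50%) inside that window as a proxy for nonconserved
#' insertions. HIGH anchor columns are never removed, and row order is
#' preserved.
#'
#' @param msa `AAStringSet` (gapped, equal width) or character matrix.
#' @param upstream columns retained upstream of the first HIGH anchor.
#' @param abdEnd column index of the anticodon-binding-domain end, or
#'   `NULL` to take the last non-gap column of `refRow`.
#' @param refRow row id whose last residue defines `abdEnd` when
#'   `abdEnd` is `NULL` (defaults to the first row).
#' @param maxGapFrac gap fraction above which an in-window column is
#'   dropped.
#' @return `AAStringSet` of the trimmed rows (original order), with the
#'   retained original column indices in `attr(, "columns")`.
#' @export
trimToCore <- function(msa, upstream = 13L, abdEnd = NULL, refRow = NULL,
                       maxGapFrac = 0.5) {
  if (upstream < 0L) stop("'upstream' must be >= 0")
  mat <- if (is.matrix(msa)) msa else {
    rows <- as.character(msa)
    do.call(rbind, lapply(rows, .chars))
  }
  if (is.null(rownames(mat)) && !is.matrix(msa))
    rownames(mat) <- names(msa)
  anchors <- .anchorColumns(mat, "HIGH")
  if (!length(anchors))
    stop("no HIGH anchor column found in any row; ",
         "run the motif scan on unaligned sequences to verify inputs")
  if (is.null(abdEnd)) {
    r <- if (is.null(refRow)) 1L else match(refRow, rownames(mat))
    if (is.na(r)) stop("refRow not found: ", refRow)
    abdEnd <- max(which(mat[r, ] != "-"))
  }
  startCol <- max(1L, min(anchors) - as.integer(upstream))
  window <- startCol:min(abdEnd, ncol(mat))
  gapFrac <- colMeans(mat[, window, drop = FALSE] == "-")
  keep <- window[gapFrac <= maxGapFrac | window %in% anchors]
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  res <- Biostrings::AAStringSet(out)
  names(res) <- rownames(mat)
  attr(res, "columns") <- keep
  res
}
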